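# Default model specification: cost-utility of extended-window intravenous
# alteplase vs standard medical therapy for posterior circulation ischemic
# stroke (Chinese healthcare system perspective, 2024 CNY).
#
# Every scalar/vector parameter is a block {value, low, high, source}.
# source: PAPER   = printed in the source trial/model publication chain
#         ASSUMED = packaged default chosen by this package (user-overridable);
#                   ranges marked ASSUMED are symmetric plausibility intervals.
model: pcis-alteplase-cua
currency: CNY-2024
config:
  start_age: 64
  horizon: 30
  cycle_length: 0.25
  half_cycle_correction: true
  rng_seed: 1234
  psa_iterations: 1000
strategies:
  - name: standard
    includes_drug_cost: false
    mrs_at_3mo:
      value: [0.2564, 0.3504, 0.1197, 0.1197, 0.0342, 0.0342, 0.0855]
      low:   [0.1773, 0.2640, 0.0609, 0.0609, 0.0013, 0.0013, 0.0348]
      high:  [0.3355, 0.4369, 0.1785, 0.1785, 0.0671, 0.0671, 0.1361]
      source: PAPER
    sich_incidence: {value: 0.0087, low: 0.0, high: 0.0409, source: PAPER}
  - name: alteplase
    includes_drug_cost: true
    mrs_at_3mo:
      value: [0.3913, 0.3478, 0.1565, 0.0261, 0.0174, 0.0087, 0.0522]
      low:   [0.3021, 0.2608, 0.0901, 0.0,    0.0,    0.0,    0.0115]
      high:  [0.4805, 0.4349, 0.2229, 0.0552, 0.0413, 0.0257, 0.0928]
      source: PAPER
    sich_incidence: {value: 0.0172, low: 0.0, high: 0.0257, source: PAPER}
utilities:
  u_mrs:
    value: [0.95, 0.89, 0.67, 0.44, 0.16, 0.10, 0.0]
    low:   [0.855, 0.801, 0.603, 0.396, 0.144, 0.09, 0.0]
    high:  [1.0, 0.979, 0.737, 0.484, 0.176, 0.11, 0.0]
    source: PAPER (ranges ASSUMED, +-10% capped at 1)
  u_recurrence: {value: 0.42, low: 0.378, high: 0.462, source: PAPER (range ASSUMED)}
  d_sich: {value: 0.38, low: 0.342, high: 0.418, source: PAPER (range ASSUMED)}
costs:
  acute_hosp_by_mrs:
    value: [15000, 18000, 25000, 35000, 45000, 55000, 20000]
    low:   [11250, 13500, 18750, 26250, 33750, 41250, 15000]
    high:  [18750, 22500, 31250, 43750, 56250, 68750, 25000]
    source: ASSUMED
  annual_care_mrs01: {value: 8000, low: 6000, high: 10000, source: ASSUMED}
  annual_care_mrs25: {value: 40000, low: 30000, high: 50000, source: ASSUMED}
  recurrent_stroke_event: {value: 30000, low: 22500, high: 37500, source: ASSUMED}
  sich_event: {value: 20000, low: 15000, high: 25000, source: ASSUMED}
  alteplase_price_20mg: {value: 1700, source: PAPER}
  alteplase_price_50mg: {value: 3400, source: PAPER}
  alteplase_base_case: {value: 2550, low: 1700, high: 3400, source: PAPER}
life_table:
  source: PAPER
  bands:
    - {age: 60, annual_mortality: 0.00760}
    - {age: 65, annual_mortality: 0.01266}
    - {age: 70, annual_mortality: 0.02159}
    - {age: 75, annual_mortality: 0.03731}
    - {age: 80, annual_mortality: 0.06340}
    - {age: 85, annual_mortality: 0.15120}
mortality:
  hr_by_mrs:
    value: [1.0, 1.0, 1.11, 1.27, 1.71, 2.37]
    low:   [1.0, 1.0, 0.89, 1.02, 1.37, 1.90]
    high:  [1.2, 1.2, 1.30, 1.52, 2.05, 2.84]
    source: PAPER
  post_stroke_excess_hr: {value: 1.0, source: ASSUMED}
recurrence:
  annual_recurrence_by_mrs:
    value: [0.02, 0.02, 0.04, 0.04, 0.06, 0.06]
    low:   [0.01, 0.01, 0.02, 0.02, 0.03, 0.03]
    high:  [0.03, 0.03, 0.06, 0.06, 0.09, 0.09]
    source: ASSUMED
  case_fatality: {value: 0.21, low: 0.1575, high: 0.2625, source: PAPER (range ASSUMED)}
  p_stay_given_survive: {value: 0.5, source: ASSUMED}
discount:
  annual_rate: {value: 0.05, low: 0.0, high: 0.08, source: PAPER}
thresholds:
  gdp_per_capita: {value: 95749, source: PAPER}
uncertainty:
  mrs_concentration: 115
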