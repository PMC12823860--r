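test_that("tornado sweeps recover the base-case ICER at base values", {
  b <- default_model_spec()
  base_icer <- run_base_case(b)$cea$icer
  entries <- strokeCUA:::sensitivity_parameters(b)
  picks <- c("alteplase mRS 0 proportion at 3 months",
             "sICH incidence (standard)", "death HR mRS 4", "utility mRS 2",
             "annual cost for mRS 2-5", "alteplase drug cost",
             "annual recurrence probability mRS 5",
             "recurrent stroke case fatality")
  for (label in picks) {
    e <- entries[[label]]
    expect_false(is.null(e))
    icer_at_base <- run_base_case(e$set(b, e$base))$cea$icer
    expect_equal(icer_at_base, base_icer, tolerance = 1e-9, info = label)
  }
})

test_that("tornado entries are sorted and zero-width ranges give zero span", {
  b <- default_model_spec()
  b$strategies[[1]]$sich_range <-
    param_range(b$strategies[[1]]$sich_incidence, b$strategies[[1]]$sich_incidence)
  tor <- one_way_sensitivity(b, parameters = c("sICH incidence (standard)",
                                               "annual cost for mRS 2-5",
                                               "alteplase drug cost"))
  expect_s3_class(tor, "tornado_table")
  expect_true(all(diff(tor$span) <= 0))
  expect_equal(tor$span[tor$parameter == "sICH incidence (standard)"], 0)
  expect_equal(tor$span,
               abs(tor$icer_at_high - tor$icer_at_low), tolerance = 1e-12)
})

test_that("the discount-rate sweep brackets the base case", {
  b <- default_model_spec()
  tor <- one_way_sensitivity(b, parameters = "annual discount rate")
  base <- attr(tor, "base_icer")
  lo <- min(tor$icer_at_low, tor$icer_at_high)
  hi <- max(tor$icer_at_low, tor$icer_at_high)
  expect_lte(lo, base + 1e-9)
  expect_gte(hi, base - 1e-9)
  expect_gt(tor$span, 0)
})

test_that("the mRS-component sweep preserves the simplex", {
  b <- default_model_spec()
  b2 <- strokeCUA:::set_mrs_component(b, 2, 4, 0.0552)
  p <- as.numeric(b2$strategies[[2]]$mrs_at_3mo)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[4], 0.0552)
  # remaining components keep their relative proportions
  p0 <- as.numeric(b$strategies[[2]]$mrs_at_3mo)
  expect_equal(p[-4] / sum(p[-4]), p0[-4] / sum(p0[-4]), tolerance = 1e-12)
  expect_warning(strokeCUA:::set_mrs_component(b, 1, 2, 1.4), "clipped")
})

test_that("PSA is reproducible under a fixed seed", {
  b <- default_model_spec()
  a <- run_psa(b, n_iterations = 25, seed = 5)
  bb <- run_psa(b, n_iterations = 25, seed = 5)
  expect_identical(a$draws, bb$draws)
  expect_identical(a$ceac, bb$ceac)
  cc <- run_psa(b, n_iterations = 25, seed = 6)
  expect_false(identical(a$draws$delta_cost, cc$draws$delta_cost))
})

test_that("PSA sampled parameters center on their base-case values", {
  b <- default_model_spec()
  psa <- run_psa(b, n_iterations = 400, seed = 17)
  d <- psa$draws
  mc_ok <- function(x, target) {
    abs(mean(x) - target) < 3 * sd(x) / sqrt(length(x))
  }
  expect_true(mc_ok(d$sich_intervention, 0.0172))
  expect_true(mc_ok(d$sich_comparator, 0.0087))
  expect_true(mc_ok(d$drug_cost, 2550))
  expect_true(mc_ok(d$case_fatality, 0.21))
  expect_true(mc_ok(d$u_mrs0, 0.95))
})

test_that("the CEAC is a two-strategy partition, monotone on positive-gain draws", {
  b <- default_model_spec()
  psa <- run_psa(b, n_iterations = 200, seed = 31)
  expect_true(all(psa$ceac$p_intervention >= 0 & psa$ceac$p_intervention <= 1))
  expect_equal(psa$ceac$p_intervention + psa$ceac$p_comparator,
               rep(1, nrow(psa$ceac)))

  # CEAC at WTP 0 equals the fraction of cost-saving draws
  expect_equal(psa$ceac$p_intervention[psa$ceac$wtp == 0],
               mean(psa$draws$delta_cost < 0))

  # conditional on delta-QALY > 0 the acceptability curve is non-decreasing
  pos <- psa$draws[psa$draws$delta_qaly > 0, ]
  curve <- vapply(psa$ceac$wtp,
                  function(l) mean(l * pos$delta_qaly - pos$delta_cost > 0), 0)
  expect_true(all(diff(curve) > -1e-12))
})

test_that("degenerate PSA distributions collapse to the base case", {
  b <- default_model_spec()
  base <- run_base_case(b)
  zero <- function(x) param_range(x, x)
  for (si in 1:2) {
    b$strategies[[si]]$sich_range <- zero(b$strategies[[si]]$sich_incidence)
  }
  b$utility_ranges <- list(
    u_mrs = param_range(b$utilities$u_mrs, b$utilities$u_mrs),
    u_recurrence = zero(b$utilities$u_recurrence),
    d_sich = zero(b$utilities$d_sich))
  b$cost_ranges <- list(
    acute_hosp_by_mrs = param_range(b$costs$acute_hosp_by_mrs, b$costs$acute_hosp_by_mrs),
    annual_care_mrs01 = zero(b$costs$annual_care_mrs01),
    annual_care_mrs25 = zero(b$costs$annual_care_mrs25),
    recurrent_stroke_event = zero(b$costs$recurrent_stroke_event),
    sich_event = zero(b$costs$sich_event),
    alteplase_base_case = zero(b$costs$alteplase_base_case))
  b$mortality$hr_range <- param_range(b$mortality$hr_by_mrs, b$mortality$hr_by_mrs)
  b$recurrence$recurrence_range <- param_range(b$recurrence$annual_recurrence_by_mrs,
                                               b$recurrence$annual_recurrence_by_mrs)
  b$recurrence$case_fatality_range <- zero(b$recurrence$case_fatality)
  b$uncertainty$mrs_concentration <- 1e12     # pins the Dirichlet to its mean

  psa <- run_psa(b, n_iterations = 1, seed = 3)
  expect_equal(psa$draws$delta_cost, base$cea$delta_cost, tolerance = 1e-3)
  expect_equal(psa$draws$delta_qaly, base$cea$delta_qaly, tolerance = 1e-3)
})

test_that("CEAC crossing interpolates the 0.5 threshold", {
  flat <- data.frame(wtp = 0:5 * 1000, p_intervention = rep(1, 6))
  expect_identical(ceac_crossing(flat), list(wtp = 0, crossed = FALSE))

  step <- data.frame(wtp = c(0, 1000, 2000), p_intervention = c(0, 0, 1))
  out <- ceac_crossing(step)
  expect_true(out$crossed)
  expect_equal(out$wtp, 1500)

  never <- data.frame(wtp = 0:3 * 1000, p_intervention = rep(0.2, 4))
  out2 <- ceac_crossing(never)
  expect_false(out2$crossed)
  expect_equal(out2$wtp, 3000)
})
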