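# The 3-month decision-tree phase. Each arm's trial-observed mRS distribution
# at month 3 is taken as the state of the cohort for the first quarter; the
# quarter's costs (acute hospitalization, first-quarter care, drug, sICH
# management) and QALYs (state utilities minus the one-time sICH disutility)
# are accrued undiscounted at t = 0.

#' Run the 3-month decision tree for one strategy
#'
#' Computes the cycle-0 ledger of a strategy: the mRS distribution entering
#' the Markov model, and the first-quarter cost, QALY and life-year totals.
#' Patients dead at 3 months (mRS 6) are credited no life-years or QALYs for
#' the quarter, but their acute hospitalization cost is still incurred. sICH
#' enters as a one-time management cost plus a one-time QALY decrement
#' (`d_sich * cycle_length`); sICH mortality is assumed to be already
#' embodied in the trial's 3-month mRS distribution.
#'
#' @param strategy A [strategy_params()].
#' @param costs A [cost_set()].
#' @param utilities A [utility_set()].
#' @param cycle_length Cycle length in years (default one quarter).
#' @return A list of class `tree_outcome` with `initial_distribution`,
#'   `cost_3mo`, `qaly_3mo`, `ly_3mo`.
#' @export
run_decision_tree <- function(strategy, costs, utilities, cycle_length = 0.25) {
  stopifnot(inherits(strategy, "strategy_params"),
            inherits(costs, "cost_set"),
            inherits(utilities, "utility_set"))
  p <- as.numeric(strategy$mrs_at_3mo)          # mRS 0..6
  alive <- p[1:6]

  ly <- (1 - p[7]) * cycle_length
  qaly <- sum(p * utilities$u_mrs) * cycle_length -
    strategy$sich_incidence * utilities$d_sich * cycle_length

  annual_care <- c(rep(costs$annual_care_mrs01, 2), rep(costs$annual_care_mrs25, 4))
  cost <- sum(p * costs$acute_hosp_by_mrs) +
    sum(alive * annual_care) * cycle_length +
    strategy$sich_incidence * costs$sich_event +
    if (strategy$includes_drug_cost) costs$alteplase_base_case else 0

  structure(list(initial_distribution = strategy$mrs_at_3mo,
                 cost_3mo = cost, qaly_3mo = qaly, ly_3mo = ly),
            class = "tree_outcome")
}
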