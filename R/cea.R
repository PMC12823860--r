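# Incremental cost-effectiveness outcomes and the GDP-threshold decision
# rule: below 1x per-capita GDP per QALY = highly cost-effective, between
# 1x and 3x = cost-effective, above 3x = not cost-effective; dominance
# overrides thresholds.

#' Incremental cost-effectiveness of one strategy over another
#'
#' @param intervention,comparator `strategy_result`s from the same
#'   configuration (horizon, discounting).
#' @return A list of class `cea_result`: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer` (NA when undefined), and `dominance` — one of
#'   `"none"`, `"dominant"` (cheaper and more effective), `"dominated"`
#'   (costlier and less effective), or `"southwest"` (cheaper but less
#'   effective; the ICER is reported but never auto-classified).
#' @export
compute_icer <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  dl <- intervention$total_ly - comparator$total_ly

  dominance <- "none"
  if (de > 0 && dc <= 0 || de >= 0 && dc < 0) dominance <- "dominant"
  else if (de < 0 && dc >= 0 || de <= 0 && dc > 0) dominance <- "dominated"
  else if (de < 0 && dc < 0) dominance <- "southwest"

  icer <- if (de != 0) dc / de else NA_real_
  structure(list(delta_cost = dc, delta_qaly = de, delta_ly = dl,
                 icer = icer, dominance = dominance),
            class = "cea_result")
}

#' Classify a CEA result against GDP-based WTP thresholds
#'
#' Dominance overrides the ICER bands: a dominant intervention is "highly
#' cost-effective" and a dominated one "not cost-effective" regardless of
#' thresholds; the southwest quadrant (cheaper, less effective) is returned
#' as `"southwest (not classified)"`. An ICER exactly at a band boundary is
#' assigned to the middle band ("cost-effective").
#'
#' @param cea A `cea_result`.
#' @param thresholds A [cea_thresholds()].
#' @return A single classification string.
#' @export
classify_cea <- function(cea, thresholds) {
  stopifnot(inherits(cea, "cea_result"), inherits(thresholds, "cea_thresholds"))
  if (cea$dominance == "dominant") return("highly cost-effective")
  if (cea$dominance == "dominated") return("not cost-effective")
  if (cea$dominance == "southwest") return("southwest (not classified)")
  if (is.na(cea$icer)) {
    # delta_qaly == 0, not caught by dominance: equal effect, classify by cost
    return(if (cea$delta_cost > 0) "not cost-effective" else "highly cost-effective")
  }
  if (cea$icer < thresholds$wtp_1x) "highly cost-effective"
  else if (cea$icer <= thresholds$wtp_3x) "cost-effective"
  else "not cost-effective"
}

#' Net monetary benefit of a strategy
#'
#' `NMB(lambda) = lambda * total_qaly - total_cost`. The incremental NMB of
#' two strategies changes sign exactly at `lambda = ICER` when the QALY
#' difference is positive.
#'
#' @param result A `strategy_result` (or any list with `total_qaly`,
#'   `total_cost`).
#' @param wtp Willingness-to-pay per QALY (CNY); non-negative, vectorized.
#' @return NMB in CNY.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$total_qaly - result$total_cost
}

#' Run the base-case analysis
#'
#' Runs both strategies of a bundle through the decision tree and Markov
#' model, computes incremental outcomes of the second (intervention)
#' strategy versus the first (comparator), and classifies the result.
#'
#' @param bundle A `model_spec` bundle; the first strategy is the
#'   comparator, the second the intervention.
#' @param ... Passed to [run_cohort()] (e.g. `discount_rate`).
#' @return A list of class `base_case_result` with `comparator`,
#'   `intervention` (`strategy_result`s), `cea` (`cea_result`),
#'   `classification`, and `thresholds`.
#' @export
run_base_case <- function(bundle, ...) {
  comp <- run_strategy(bundle, 1L, ...)
  intv <- run_strategy(bundle, 2L, ...)
  cea <- compute_icer(intv, comp)
  structure(list(comparator = comp, intervention = intv, cea = cea,
                 classification = classify_cea(cea, bundle$thresholds),
                 thresholds = bundle$thresholds),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  arms <- c("comparator", "intervention")
  for (a in arms) {
    cat(sprintf("%-12s: %9.0f CNY  %6.3f QALYs  %6.3f LYs\n", a,
                x[[a]]$total_cost, x[[a]]$total_qaly, x[[a]]$total_ly))
  }
  cat(sprintf("incremental : %9.0f CNY  %6.3f QALYs  %6.3f LYs\n",
              x$cea$delta_cost, x$cea$delta_qaly, x$cea$delta_ly))
  if (x$cea$dominance == "none") {
    cat(sprintf("ICER        : %.0f CNY/QALY (WTP 1x = %.0f, 3x = %.0f)\n",
                x$cea$icer, x$thresholds$wtp_1x, x$thresholds$wtp_3x))
  } else {
    cat("dominance   :", x$cea$dominance, "\n")
  }
  cat("conclusion  :", x$classification, "\n")
  invisible(x)
}
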