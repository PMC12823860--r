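# Markov cohort engine. States: mRS 0..5 (alive) and the absorbing state
# Dead (which absorbs both the trial's 3-month deaths and all model deaths).
# Each 3-month cycle, patients face age- and mRS-specific background
# mortality first; survivors face recurrence; recurrent strokes are fatal
# with the case-fatality probability, and survivors either remain in their
# state or shift one mRS level worse (capped at mRS 5). Payoffs use a
# trapezoidal half-cycle correction and annual discounting.

#' Convert an annual probability to a per-cycle probability
#'
#' Standard rate conversion: the annual probability is mapped to a hazard
#' rate, scaled by the hazard ratio and cycle length, and mapped back:
#' `1 - exp(-hr * (-log(1 - p_annual)) * cycle_length)`. `p_annual = 1`
#' returns 1 (limit of the formula).
#'
#' @param p_annual Annual probability in `[0, 1]`.
#' @param cycle_length Cycle length in years.
#' @param hr Hazard ratio (> 0) applied on the rate scale.
#' @return Per-cycle probability. Vectorized over all arguments.
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_length, hr = 1) {
  stopifnot(all(p_annual >= 0), all(p_annual <= 1), all(hr > 0))
  out <- 1 - exp(-hr * (-log1p(-p_annual)) * cycle_length)
  out[rep_len(p_annual, length(out)) >= 1] <- 1
  out
}

#' Per-cycle background mortality for an age and mRS state
#'
#' Looks up the 5-year age band containing `age` (ages beyond the last band
#' use the last band's rate; ages below the first band use the first band's),
#' then applies the state's death hazard ratio times the global post-stroke
#' excess hazard ratio through [annual_prob_to_cycle()].
#'
#' @param age Age in years.
#' @param mrs mRS level 0..5 (alive states only).
#' @param life_table A [life_table()].
#' @param mortality A [mortality_model()].
#' @param cycle_length Cycle length in years.
#' @return Per-cycle death probability. Vectorized over `mrs`.
#' @export
mortality_for <- function(age, mrs, life_table, mortality, cycle_length = 0.25) {
  stopifnot(all(mrs >= 0), all(mrs <= 5))
  band <- findInterval(age, life_table$age_lower)
  band <- max(band, 1L)                      # ages below the first band
  p_annual <- life_table$annual_mortality[band]
  hr <- mortality$hr_by_mrs[mrs + 1L] * mortality$post_stroke_excess_hr
  annual_prob_to_cycle(p_annual, cycle_length, hr)
}

#' One Markov cycle transition
#'
#' Applies the within-cycle event tree to a state-occupancy vector:
#' background death first, then recurrence among survivors (fatal with the
#' case-fatality probability; survivors stay put with
#' `p_stay_given_survive`, else shift one mRS level worse, capped at mRS 5),
#' with the no-event mass remaining in place. Event flows are returned for
#' payoff attribution.
#'
#' @param occupancy Numeric 7-vector (mRS 0..5 alive, Dead) summing to 1.
#' @param age Age in years during the cycle (for the life-table lookup).
#' @param bundle A `model_spec` bundle (life table, mortality, recurrence).
#' @param cycle_length Cycle length in years.
#' @return List with `occupancy` (next 7-vector), `recurrence_survivor_flow`
#'   (mass arriving in each alive state via survived recurrence),
#'   `recurrence_total` (all recurrence mass, fatal included), and
#'   `deaths` (mass entering Dead this cycle).
#' @export
build_cycle_transition <- function(occupancy, age, bundle, cycle_length = 0.25) {
  stopifnot(length(occupancy) == 7L)
  alive <- occupancy[1:6]
  rec <- bundle$recurrence

  d <- mortality_for(age, 0:5, bundle$life_table, bundle$mortality, cycle_length)
  r <- annual_prob_to_cycle(rec$annual_recurrence_by_mrs, cycle_length, 1)

  dead_bg <- alive * d
  surv <- alive - dead_bg
  rec_mass <- surv * r
  rec_dead <- rec_mass * rec$case_fatality
  rec_surv <- rec_mass - rec_dead
  stay <- rec_surv * rec$p_stay_given_survive
  worse <- rec_surv - stay

  new_alive <- surv - rec_mass + stay
  # shift 'worse' one state up, capping at mRS 5
  new_alive[2:6] <- new_alive[2:6] + worse[1:5]
  new_alive[6] <- new_alive[6] + worse[6]

  rec_flow <- stay
  rec_flow[2:6] <- rec_flow[2:6] + worse[1:5]
  rec_flow[6] <- rec_flow[6] + worse[6]

  deaths <- sum(dead_bg) + sum(rec_dead)
  list(occupancy = c(new_alive, occupancy[7] + deaths),
       recurrence_survivor_flow = rec_flow,
       recurrence_total = sum(rec_mass),
       deaths = deaths)
}

#' Propagate a cohort through the Markov phase
#'
#' Iterates cycles `k = 1 .. n_markov_cycles` from a decision-tree outcome.
#' The age used in cycle `k` is `start_age + cycle_length * k`. Per-cycle
#' QALYs value the (half-cycle-corrected) occupancy at the state utilities,
#' with the recurrence-survivor flow valued at the recurrence utility
#' instead of its destination-state utility for the event cycle; per-cycle
#' costs are quarterly care costs by mRS group plus the recurrent-stroke
#' event cost on the recurrence flow. All increments are discounted by
#' `(1 + rate)^(-cycle_length * k)`; the decision-tree quarter enters the
#' totals undiscounted.
#'
#' @param tree_outcome A `tree_outcome` from [run_decision_tree()].
#' @param bundle A `model_spec` bundle.
#' @param config A [model_config()]; defaults to the bundle's.
#' @param discount_rate Optional override of the bundle's annual discount
#'   rate.
#' @return A list of class `strategy_result`: `total_cost`, `total_qaly`,
#'   `total_ly`, and `trace` (a data.frame with one row per cycle, cycle 0
#'   being the decision tree).
#' @export
run_cohort <- function(tree_outcome, bundle, config = bundle$config,
                       discount_rate = bundle$discount$annual_rate) {
  stopifnot(inherits(tree_outcome, "tree_outcome"))
  cl <- config$cycle_length
  n_cycles <- config$n_markov_cycles
  u <- bundle$utilities$u_mrs[1:6]
  u_rec <- bundle$utilities$u_recurrence
  annual_care <- c(rep(bundle$costs$annual_care_mrs01, 2),
                   rep(bundle$costs$annual_care_mrs25, 4))
  c_rec <- bundle$costs$recurrent_stroke_event

  occ <- as.numeric(tree_outcome$initial_distribution)
  trace <- vector("list", n_cycles + 1L)
  trace[[1]] <- c(cycle = 0, age = config$start_age,
                  setNames(occ, c(paste0("mrs", 0:5), "dead")),
                  recurrence_flow = 0,
                  cost = tree_outcome$cost_3mo,
                  qaly = tree_outcome$qaly_3mo,
                  ly = tree_outcome$ly_3mo)

  total_cost <- tree_outcome$cost_3mo
  total_qaly <- tree_outcome$qaly_3mo
  total_ly <- tree_outcome$ly_3mo

  for (k in seq_len(n_cycles)) {
    age <- config$start_age + cl * k
    step <- build_cycle_transition(occ, age, bundle, cl)
    new_occ <- step$occupancy
    w <- if (config$half_cycle_correction) (occ + new_occ) / 2 else new_occ
    disc <- (1 + discount_rate)^(-cl * k)

    rec_flow <- step$recurrence_survivor_flow
    qaly_inc <- (sum(w[1:6] * u) + sum(rec_flow * (u_rec - u))) * cl * disc
    ly_inc <- sum(w[1:6]) * cl * disc
    cost_inc <- (sum(w[1:6] * annual_care) * cl +
                   step$recurrence_total * c_rec) * disc

    total_cost <- total_cost + cost_inc
    total_qaly <- total_qaly + qaly_inc
    total_ly <- total_ly + ly_inc

    trace[[k + 1L]] <- c(cycle = k, age = age,
                         setNames(new_occ, c(paste0("mrs", 0:5), "dead")),
                         recurrence_flow = step$recurrence_total,
                         cost = cost_inc, qaly = qaly_inc, ly = ly_inc)
    occ <- new_occ
  }

  structure(list(total_cost = total_cost,
                 total_qaly = total_qaly,
                 total_ly = total_ly,
                 trace = as.data.frame(do.call(rbind, trace))),
            class = "strategy_result")
}

#' Run decision tree plus Markov model for one arm
#'
#' Convenience wrapper: [run_decision_tree()] then [run_cohort()].
#'
#' @param bundle A `model_spec` bundle.
#' @param arm Strategy name or index in `bundle$strategies`.
#' @param ... Passed to [run_cohort()] (e.g. `discount_rate`).
#' @return A `strategy_result`.
#' @export
run_strategy <- function(bundle, arm, ...) {
  strategy <- bundle$strategies[[arm]]
  if (is.null(strategy)) stop("run_strategy: unknown strategy '", arm, "'")
  tree <- run_decision_tree(strategy, bundle$costs, bundle$utilities,
                            bundle$config$cycle_length)
  run_cohort(tree, bundle, ...)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy result: %.0f CNY, %.3f QALYs, %.3f life-years (%d cycles)\n",
              x$total_cost, x$total_qaly, x$total_ly, nrow(x$trace) - 1L))
  invisible(x)
}
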