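# Individual-level microsimulation used as an independent validation oracle
# for the cohort engine: identical event probabilities, ordering and payoff
# rules, but applied to simulated patient trajectories. Because the cohort
# model is the exact expectation of this process, mean per-patient totals
# converge to the cohort totals at rate 1/sqrt(n).

#' Microsimulate individual patient trajectories for one arm
#'
#' Simulates `n_individuals` patients through the decision tree (initial mRS
#' state and sICH event drawn from the arm's probabilities) and all Markov
#' cycles, with the same event ordering and per-cycle payoff rules as
#' [run_cohort()], including the trapezoidal half-cycle weighting and
#' discounting. Returns mean per-patient totals with Monte-Carlo standard
#' errors.
#'
#' @param bundle A `model_spec` bundle.
#' @param arm Strategy name or index.
#' @param n_individuals Number of simulated patients.
#' @param seed RNG seed (integer); identical seeds give identical results.
#' @param config A [model_config()]; defaults to the bundle's.
#' @param discount_rate Optional discount-rate override.
#' @return A list of class `microsim_result`: `total_cost`, `total_qaly`,
#'   `total_ly` (per-patient means), `se` (standard errors of the three
#'   means), and `n`.
#' @export
microsimulate <- function(bundle, arm, n_individuals, seed,
                          config = bundle$config,
                          discount_rate = bundle$discount$annual_rate) {
  stopifnot(n_individuals >= 1)
  strategy <- bundle$strategies[[arm]]
  if (is.null(strategy)) stop("microsimulate: unknown strategy '", arm, "'")
  set.seed(as.integer(seed))

  n <- as.integer(n_individuals)
  cl <- config$cycle_length
  u6 <- bundle$utilities$u_mrs[1:6]
  u_state <- c(u6, 0)                                   # Dead has utility 0
  u_rec <- bundle$utilities$u_recurrence
  care <- c(rep(bundle$costs$annual_care_mrs01, 2),
            rep(bundle$costs$annual_care_mrs25, 4), 0)
  acute <- bundle$costs$acute_hosp_by_mrs
  c_rec <- bundle$costs$recurrent_stroke_event
  rec <- bundle$recurrence
  hcc <- config$half_cycle_correction

  # decision tree: initial state 1..7 (mRS 0..6), sICH bernoulli
  state <- sample.int(7L, n, replace = TRUE,
                      prob = as.numeric(strategy$mrs_at_3mo))
  sich <- runif(n) < strategy$sich_incidence
  alive0 <- state < 7L
  qaly <- u_state[state] * cl - sich * bundle$utilities$d_sich * cl
  ly <- alive0 * cl
  cost <- acute[state] + care[state] * cl +
    sich * bundle$costs$sich_event +
    (if (strategy$includes_drug_cost) bundle$costs$alteplase_base_case else 0)

  r_cycle <- annual_prob_to_cycle(rec$annual_recurrence_by_mrs, cl, 1)

  for (k in seq_len(config$n_markov_cycles)) {
    age <- config$start_age + cl * k
    d_cycle <- mortality_for(age, 0:5, bundle$life_table, bundle$mortality, cl)
    disc <- (1 + discount_rate)^(-cl * k)

    alive <- state < 7L
    s0 <- state
    if (any(alive)) {
      ia <- which(alive)
      sa <- state[ia]
      dies <- runif(length(ia)) < d_cycle[sa]
      recurs <- !dies & (runif(length(ia)) < r_cycle[sa])
      rec_dies <- recurs & (runif(length(ia)) < rec$case_fatality)
      rec_surv <- recurs & !rec_dies
      moves <- rec_surv & (runif(length(ia)) >= rec$p_stay_given_survive)

      new_s <- sa
      new_s[moves] <- pmin(new_s[moves] + 1L, 6L)
      new_s[dies | rec_dies] <- 7L
      state[ia] <- new_s

      w_start <- if (hcc) 0.5 else 0
      w_end <- if (hcc) 0.5 else 1
      q_inc <- (w_start * u_state[s0[ia]] + w_end * u_state[new_s]) * cl
      q_inc[rec_surv] <- q_inc[rec_surv] +
        (u_rec - u_state[new_s[rec_surv]]) * cl
      l_inc <- (w_start + w_end * (new_s < 7L)) * cl
      c_inc <- (w_start * care[s0[ia]] + w_end * care[new_s]) * cl +
        recurs * c_rec

      qaly[ia] <- qaly[ia] + q_inc * disc
      ly[ia] <- ly[ia] + l_inc * disc
      cost[ia] <- cost[ia] + c_inc * disc
    }
  }

  se <- function(x) sd(x) / sqrt(n)
  structure(list(total_cost = mean(cost),
                 total_qaly = mean(qaly),
                 total_ly = mean(ly),
                 se = list(cost = se(cost), qaly = se(qaly), ly = se(ly)),
                 n = n),
            class = "microsim_result")
}
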