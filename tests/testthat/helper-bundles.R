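# Shared fixtures, built in code. random_bundle() draws a valid but
# arbitrary parameter bundle for property tests; deterministic_bundle()
# switches off all chance events for conservation checks.

random_bundle <- function(seed) {
  set.seed(seed)
  b <- default_model_spec()
  rdirichlet1 <- function(a) { g <- rgamma(length(a), a); g / sum(g) }
  for (si in 1:2) {
    p <- rdirichlet1(as.numeric(b$strategies[[si]]$mrs_at_3mo) * 40 + 0.5)
    b$strategies[[si]]$mrs_at_3mo <- mrs_distribution(p)
    b$strategies[[si]]$sich_incidence <- runif(1, 0, 0.05)
  }
  b$utilities$u_mrs <- c(sort(runif(6, 0.05, 1), decreasing = TRUE), 0)
  b$utilities$u_recurrence <- runif(1, 0.2, 0.8)
  b$utilities$d_sich <- runif(1, 0, 0.5)
  b$costs$acute_hosp_by_mrs <- b$costs$acute_hosp_by_mrs * runif(7, 0.5, 1.5)
  b$costs$annual_care_mrs01 <- b$costs$annual_care_mrs01 * runif(1, 0.5, 1.5)
  b$costs$annual_care_mrs25 <- b$costs$annual_care_mrs25 * runif(1, 0.5, 1.5)
  b$costs$recurrent_stroke_event <- b$costs$recurrent_stroke_event * runif(1, 0.5, 1.5)
  b$costs$sich_event <- b$costs$sich_event * runif(1, 0.5, 1.5)
  b$mortality$hr_by_mrs <- sort(runif(6, 1, 3))
  b$mortality$post_stroke_excess_hr <- runif(1, 1, 1.2)
  b$recurrence$annual_recurrence_by_mrs <- sort(runif(6, 0, 0.15))
  b$recurrence$case_fatality <- runif(1, 0.05, 0.5)
  b$recurrence$p_stay_given_survive <- runif(1)
  b$discount$annual_rate <- runif(1, 0, 0.08)
  b
}

# no mortality, no recurrence, no discounting, utility 1 for all alive
# states, whole cohort alive in one state: every quarter must contribute
# exactly 0.25 QALYs and life-years.
deterministic_bundle <- function() {
  b <- default_model_spec()
  b$life_table$annual_mortality <- rep(0, nrow(b$life_table))
  b$recurrence$annual_recurrence_by_mrs <- rep(0, 6)
  b$discount$annual_rate <- 0
  b$utilities$u_mrs <- c(rep(1, 6), 0)
  b$utilities$u_recurrence <- 1
  b$utilities$d_sich <- 0
  for (si in 1:2) {
    b$strategies[[si]]$mrs_at_3mo <- mrs_distribution(c(1, 0, 0, 0, 0, 0, 0))
    b$strategies[[si]]$sich_incidence <- 0
  }
  b
}

# strategy_result stub for ICER/NMB arithmetic tests
fake_result <- function(cost, qaly, ly = qaly) {
  structure(list(total_cost = cost, total_qaly = qaly, total_ly = ly),
            class = "strategy_result")
}
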