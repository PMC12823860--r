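# Synthetic two-arm trial generator. Emulates the structure of the source
# data: multinomial 3-month mRS counts and binomial sICH counts per arm,
# plus literature-style cost/utility parameters perturbed around a known
# ground truth. Every generated bundle is a valid model-spec input, so the
# whole pipeline can be exercised and parameter recovery quantified without
# any external data.

# Wald-style 95% interval for a proportion, clipped to [0, 1]
.wald_range <- function(p, n) {
  half <- 1.96 * sqrt(pmax(p * (1 - p), 0) / n)
  param_range(pmax(p - half, 0), pmin(p + half, 1))
}

#' Generate an observed trial-like parameter bundle from a known truth
#'
#' Draws 3-month mRS counts multinomially and sICH counts binomially from
#' the truth bundle's strategy parameters at the given arm sizes, converts
#' them to observed proportions with Wald-style ranges, and (optionally)
#' perturbs cost and utility point estimates around truth — gamma noise with
#' CV 0.2 for costs, beta noise anchored at the true value for utilities.
#' The result passes the same validation as a loaded model-spec file.
#'
#' @param truth A `model_spec` bundle acting as ground truth.
#' @param n_int,n_comp Arm sizes for the intervention (second strategy) and
#'   comparator (first strategy).
#' @param seed RNG seed; identical seeds give identical bundles.
#' @param perturb_costs,perturb_utilities Add sampling-style noise to
#'   cost/utility point estimates? (Trial outcome data are always resampled.)
#' @return A `model_spec` bundle with attribute `truth_seed`.
#' @export
generate_trial_bundle <- function(truth, n_int = 115L, n_comp = 115L,
                                  seed = truth$config$rng_seed,
                                  perturb_costs = FALSE,
                                  perturb_utilities = FALSE) {
  stopifnot(inherits(truth, "model_spec"), n_int >= 1, n_comp >= 1)
  set.seed(as.integer(seed))
  obs <- truth
  n_arm <- c(n_comp, n_int)  # strategies are (comparator, intervention)

  for (si in seq_along(truth$strategies)) {
    st <- truth$strategies[[si]]
    n <- as.integer(n_arm[si])
    counts <- as.vector(rmultinom(1, n, as.numeric(st$mrs_at_3mo)))
    p_obs <- counts / n
    obs$strategies[[si]]$mrs_at_3mo <-
      structure(p_obs, class = "mrs_distribution", names = paste0("mrs", 0:6))
    obs$strategies[[si]]$mrs_range <- .wald_range(p_obs, n)
    sich_obs <- rbinom(1, n, st$sich_incidence) / n
    obs$strategies[[si]]$sich_incidence <- sich_obs
    obs$strategies[[si]]$sich_range <- .wald_range(sich_obs, n)
  }

  if (perturb_costs) {
    noisy_cost <- function(m) {
      out <- m
      idx <- m > 0
      # gamma noise with CV 0.2: shape 25, scale m/25
      out[idx] <- rgamma(sum(idx), shape = 25, scale = m[idx] / 25)
      out
    }
    obs$costs$acute_hosp_by_mrs <- noisy_cost(truth$costs$acute_hosp_by_mrs)
    obs$costs$annual_care_mrs01 <- noisy_cost(truth$costs$annual_care_mrs01)
    obs$costs$annual_care_mrs25 <- noisy_cost(truth$costs$annual_care_mrs25)
    obs$costs$recurrent_stroke_event <- noisy_cost(truth$costs$recurrent_stroke_event)
    obs$costs$sich_event <- noisy_cost(truth$costs$sich_event)
  }
  if (perturb_utilities) {
    noisy_u <- function(m, conc = 100) {
      out <- m
      idx <- m > 0 & m < 1
      out[idx] <- rbeta(sum(idx), m[idx] * conc, (1 - m[idx]) * conc)
      out
    }
    u <- noisy_u(truth$utilities$u_mrs)
    obs$utilities$u_mrs <- sort(u, decreasing = TRUE) * (truth$utilities$u_mrs > 0)
    obs$utilities$u_recurrence <- noisy_u(truth$utilities$u_recurrence)
    obs$utilities$d_sich <- noisy_u(truth$utilities$d_sich)
  }

  attr(obs, "truth_seed") <- as.integer(seed)
  obs
}

#' Parameter-recovery experiment
#'
#' Generates `n_replicates` observed bundles from a truth bundle, runs the
#' full base-case model on each, and summarizes the sampling distribution of
#' incremental cost, incremental QALYs and the ICER against the model run at
#' truth. Used to check that trial-scale sampling noise leaves the economic
#' conclusion identifiable.
#'
#' @param truth A `model_spec` bundle (ground truth).
#' @param n_replicates Number of replicate trials (>= 2).
#' @param n_int,n_comp Arm sizes per replicate.
#' @param seed Base RNG seed; replicate `r` uses `seed + r`.
#' @return A list of class `recovery_result`: `truth` (the truth-run
#'   `cea_result`), `replicates` (data.frame of per-replicate `delta_cost`,
#'   `delta_qaly`, `icer`), `bias` (mean signed errors), and
#'   `icer_interval` (2.5/97.5 percentiles of replicate ICERs).
#' @export
recovery_experiment <- function(truth, n_replicates = 200L,
                                n_int = 115L, n_comp = 115L, seed = 1L) {
  stopifnot(n_replicates >= 2)
  truth_run <- run_base_case(truth)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    obs <- generate_trial_bundle(truth, n_int = n_int, n_comp = n_comp,
                                 seed = as.integer(seed) + r)
    res <- run_base_case(obs)
    reps[[r]] <- data.frame(replicate = r,
                            delta_cost = res$cea$delta_cost,
                            delta_qaly = res$cea$delta_qaly,
                            icer = res$cea$icer)
  }
  reps <- do.call(rbind, reps)
  icer_q <- quantile(reps$icer, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(list(
    truth = truth_run$cea,
    replicates = reps,
    bias = c(delta_cost = mean(reps$delta_cost) - truth_run$cea$delta_cost,
             delta_qaly = mean(reps$delta_qaly) - truth_run$cea$delta_qaly,
             icer = mean(reps$icer, na.rm = TRUE) - truth_run$cea$icer),
    icer_interval = c(lower = icer_q[1], upper = icer_q[2])),
    class = "recovery_result")
}
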