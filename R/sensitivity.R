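# One-way (tornado) and probabilistic sensitivity analysis. Every uncertain
# parameter carries a range in the model-spec file; OWSA re-runs the model at
# each bound, PSA samples all parameters jointly (Dirichlet for whole mRS
# distributions, beta for probabilities and utilities, gamma for costs and
# hazard ratios) and summarizes draws on the cost-effectiveness plane and as
# a cost-effectiveness acceptability curve.

# ---- parameter descriptors --------------------------------------------------

# One swappable scalar parameter: label, bounds, base value, and a setter
# returning a modified bundle. Setters assign directly (no re-validation) so
# that sweeps may cross soft invariants such as utility monotonicity.
.param_entry <- function(label, base, low, high, set) {
  list(label = label, base = base, low = low, high = high, set = set)
}

# Replace component `comp` (1..7) of a strategy's mRS distribution with
# `value`, rescaling the remaining six components proportionally so the
# simplex constraint holds. Values are clipped to [0, 1] with a warning.
set_mrs_component <- function(bundle, strategy_idx, comp, value) {
  if (value < 0 || value > 1) {
    warning("mRS component clipped to [0, 1]")
    value <- min(max(value, 0), 1)
  }
  p <- as.numeric(bundle$strategies[[strategy_idx]]$mrs_at_3mo)
  rest <- sum(p[-comp])
  if (rest > 0) p[-comp] <- p[-comp] * (1 - value) / rest
  p[comp] <- value
  bundle$strategies[[strategy_idx]]$mrs_at_3mo <-
    structure(p, class = "mrs_distribution", names = paste0("mrs", 0:6))
  bundle
}

#' Enumerate the model's uncertain parameters
#'
#' Builds the list of scalar parameters that the one-way sensitivity
#' analysis sweeps: every mRS proportion (varied with proportional
#' renormalization of the remaining mass), sICH incidences, death hazard
#' ratios, utilities, costs, recurrence inputs and the discount rate — each
#' with the range recorded in the model spec. Parameters without a range are
#' skipped.
#'
#' @param bundle A `model_spec` bundle.
#' @return A named list of parameter descriptors (label, base, low, high,
#'   setter).
#' @keywords internal
sensitivity_parameters <- function(bundle) {
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  for (si in seq_along(bundle$strategies)) {
    s <- bundle$strategies[[si]]
    if (!is.null(s$mrs_range)) {
      for (i in 1:7) {
        local({
          si0 <- si; i0 <- i
          add(.param_entry(
            sprintf("%s mRS %d proportion at 3 months", s$name, i0 - 1L),
            as.numeric(s$mrs_at_3mo)[i0], s$mrs_range$low[i0], s$mrs_range$high[i0],
            function(b, v) set_mrs_component(b, si0, i0, v)))
        })
      }
    }
    if (!is.null(s$sich_range)) {
      local({
        si0 <- si
        add(.param_entry(
          sprintf("sICH incidence (%s)", s$name),
          s$sich_incidence, s$sich_range$low, s$sich_range$high,
          function(b, v) { b$strategies[[si0]]$sich_incidence <- v; b }))
      })
    }
  }

  if (!is.null(bundle$mortality$hr_range)) {
    for (i in 1:6) {
      local({
        i0 <- i
        add(.param_entry(
          sprintf("death HR mRS %d", i0 - 1L),
          bundle$mortality$hr_by_mrs[i0],
          bundle$mortality$hr_range$low[i0], bundle$mortality$hr_range$high[i0],
          function(b, v) { b$mortality$hr_by_mrs[i0] <- v; b }))
      })
    }
  }

  if (!is.null(bundle$utility_ranges$u_mrs)) {
    for (i in 1:6) {
      local({
        i0 <- i
        add(.param_entry(
          sprintf("utility mRS %d", i0 - 1L),
          bundle$utilities$u_mrs[i0],
          bundle$utility_ranges$u_mrs$low[i0], bundle$utility_ranges$u_mrs$high[i0],
          function(b, v) { b$utilities$u_mrs[i0] <- v; b }))
      })
    }
  }
  if (!is.null(bundle$utility_ranges$u_recurrence)) {
    add(.param_entry("utility during recurrence cycle",
                     bundle$utilities$u_recurrence,
                     bundle$utility_ranges$u_recurrence$low,
                     bundle$utility_ranges$u_recurrence$high,
                     function(b, v) { b$utilities$u_recurrence <- v; b }))
  }
  if (!is.null(bundle$utility_ranges$d_sich)) {
    add(.param_entry("sICH disutility", bundle$utilities$d_sich,
                     bundle$utility_ranges$d_sich$low,
                     bundle$utility_ranges$d_sich$high,
                     function(b, v) { b$utilities$d_sich <- v; b }))
  }

  cr <- bundle$cost_ranges
  if (!is.null(cr$acute_hosp_by_mrs)) {
    for (i in 1:7) {
      local({
        i0 <- i
        add(.param_entry(
          sprintf("acute hospitalization cost mRS %d", i0 - 1L),
          bundle$costs$acute_hosp_by_mrs[i0],
          cr$acute_hosp_by_mrs$low[i0], cr$acute_hosp_by_mrs$high[i0],
          function(b, v) { b$costs$acute_hosp_by_mrs[i0] <- v; b }))
      })
    }
  }
  scalar_costs <- c(annual_care_mrs01 = "annual cost for mRS 0-1",
                    annual_care_mrs25 = "annual cost for mRS 2-5",
                    recurrent_stroke_event = "recurrent stroke event cost",
                    sich_event = "sICH event cost",
                    alteplase_base_case = "alteplase drug cost")
  for (fld in names(scalar_costs)) {
    if (is.null(cr[[fld]])) next
    local({
      fld0 <- fld
      add(.param_entry(scalar_costs[[fld0]], bundle$costs[[fld0]],
                       cr[[fld0]]$low, cr[[fld0]]$high,
                       function(b, v) { b$costs[[fld0]] <- v; b }))
    })
  }

  if (!is.null(bundle$recurrence$recurrence_range)) {
    for (i in 1:6) {
      local({
        i0 <- i
        add(.param_entry(
          sprintf("annual recurrence probability mRS %d", i0 - 1L),
          bundle$recurrence$annual_recurrence_by_mrs[i0],
          bundle$recurrence$recurrence_range$low[i0],
          bundle$recurrence$recurrence_range$high[i0],
          function(b, v) { b$recurrence$annual_recurrence_by_mrs[i0] <- v; b }))
      })
    }
  }
  if (!is.null(bundle$recurrence$case_fatality_range)) {
    add(.param_entry("recurrent stroke case fatality",
                     bundle$recurrence$case_fatality,
                     bundle$recurrence$case_fatality_range$low,
                     bundle$recurrence$case_fatality_range$high,
                     function(b, v) { b$recurrence$case_fatality <- v; b }))
  }

  add(.param_entry("annual discount rate", bundle$discount$annual_rate,
                   bundle$discount$range$low, bundle$discount$range$high,
                   function(b, v) { b$discount$annual_rate <- v; b }))

  names(entries) <- vapply(entries, `[[`, character(1), "label")
  entries
}

# ---- one-way sensitivity analysis -------------------------------------------

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full model with each uncertain parameter set to its lower and
#' upper bound, all other parameters held at base case, and reports the ICER
#' at each bound. Entries are sorted by decreasing span for tornado
#' plotting. mRS-distribution components are varied with proportional
#' renormalization of the remaining mass.
#'
#' @param bundle A `model_spec` bundle.
#' @param parameters Optional character vector of parameter labels to sweep
#'   (default: all with ranges).
#' @return A data.frame of class `tornado_table`: `parameter`, `low`,
#'   `high` (input bounds), `icer_at_low`, `icer_at_high`, `span`, plus the
#'   base-case ICER as attribute `base_icer`.
#' @export
one_way_sensitivity <- function(bundle, parameters = NULL) {
  base <- run_base_case(bundle)
  entries <- sensitivity_parameters(bundle)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, names(entries))
    if (length(missing)) stop("unknown parameters: ", paste(missing, collapse = ", "))
    entries <- entries[parameters]
  }

  icer_at <- function(entry, value) {
    b <- entry$set(bundle, value)
    if (entry$label == "annual discount rate") {
      run_base_case(b, discount_rate = value)$cea$icer
    } else {
      run_base_case(b)$cea$icer
    }
  }

  rows <- lapply(entries, function(e) {
    lo <- icer_at(e, e$low)
    hi <- icer_at(e, e$high)
    data.frame(parameter = e$label, low = e$low, high = e$high,
               icer_at_low = lo, icer_at_high = hi,
               span = abs(hi - lo))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$cea$icer
  class(out) <- c("tornado_table", "data.frame")
  out
}

# ---- probabilistic sensitivity analysis -------------------------------------

# All samplers for one bundle, keyed by what they perturb.
.psa_samplers <- function(bundle) {
  conc <- bundle$uncertainty$mrs_concentration
  s <- list()
  for (si in seq_along(bundle$strategies)) {
    st <- bundle$strategies[[si]]
    s[[paste0("mrs_", si)]] <- dirichlet_from_distribution(st$mrs_at_3mo, conc)
    s[[paste0("sich_", si)]] <-
      beta_from_mean_ci(st$sich_incidence, st$sich_range)
  }
  ur <- bundle$utility_ranges
  for (i in 1:6) {
    rng <- if (is.null(ur$u_mrs)) NULL else
      param_range(ur$u_mrs$low[i], ur$u_mrs$high[i])
    s[[paste0("u_mrs_", i)]] <- beta_from_mean_ci(bundle$utilities$u_mrs[i], rng)
  }
  s$u_recurrence <- beta_from_mean_ci(bundle$utilities$u_recurrence, ur$u_recurrence)
  s$d_sich <- beta_from_mean_ci(bundle$utilities$d_sich, ur$d_sich)

  cr <- bundle$cost_ranges
  for (i in 1:7) {
    rng <- if (is.null(cr$acute_hosp_by_mrs)) NULL else
      param_range(cr$acute_hosp_by_mrs$low[i], cr$acute_hosp_by_mrs$high[i])
    s[[paste0("acute_", i)]] <-
      gamma_from_mean_range(bundle$costs$acute_hosp_by_mrs[i], rng)
  }
  for (fld in c("annual_care_mrs01", "annual_care_mrs25",
                "recurrent_stroke_event", "sich_event", "alteplase_base_case")) {
    s[[fld]] <- gamma_from_mean_range(bundle$costs[[fld]], cr[[fld]])
  }

  hr <- bundle$mortality$hr_range
  for (i in 1:6) {
    rng <- if (is.null(hr)) NULL else param_range(hr$low[i], hr$high[i])
    s[[paste0("hr_", i)]] <-
      gamma_from_mean_range(bundle$mortality$hr_by_mrs[i], rng)
  }

  rr <- bundle$recurrence$recurrence_range
  for (i in 1:6) {
    rng <- if (is.null(rr)) NULL else param_range(rr$low[i], rr$high[i])
    s[[paste0("recur_", i)]] <-
      beta_from_mean_ci(bundle$recurrence$annual_recurrence_by_mrs[i], rng)
  }
  s$case_fatality <- beta_from_mean_ci(bundle$recurrence$case_fatality,
                                       bundle$recurrence$case_fatality_range)
  s
}

#' Probabilistic sensitivity analysis
#'
#' Samples all uncertain parameters jointly and independently across blocks
#' (`n_iterations` times), re-runs both strategies per draw, and records the
#' incremental cost and QALY pair. The CEAC reports, at each
#' willingness-to-pay value, the fraction of draws in which the intervention
#' has the higher net monetary benefit (the comparator's probability is the
#' complement).
#'
#' @param bundle A `model_spec` bundle.
#' @param n_iterations Number of PSA draws (default: the bundle's
#'   `psa_iterations`).
#' @param seed RNG seed (default: the bundle's `rng_seed`).
#' @param wtp_grid WTP grid for the CEAC (CNY/QALY); default 0 to 120,000
#'   in steps of 1,000.
#' @return A list of class `psa_result`: `draws` (data.frame with
#'   `draw`, `delta_cost`, `delta_qaly` and a few sampled-parameter
#'   columns), `ceac` (data.frame `wtp`, `p_intervention`, `p_comparator`),
#'   `seed`, `n_iterations`.
#' @export
run_psa <- function(bundle, n_iterations = bundle$config$psa_iterations,
                    seed = bundle$config$rng_seed,
                    wtp_grid = seq(0, 120000, by = 1000)) {
  stopifnot(n_iterations >= 1)
  set.seed(as.integer(seed))
  samplers <- .psa_samplers(bundle)
  draws <- lapply(samplers, draw_sampler, n = n_iterations)

  dc <- de <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    b <- bundle
    for (si in seq_along(b$strategies)) {
      p <- draws[[paste0("mrs_", si)]][it, ]
      b$strategies[[si]]$mrs_at_3mo <-
        structure(p / sum(p), class = "mrs_distribution",
                  names = paste0("mrs", 0:6))
      b$strategies[[si]]$sich_incidence <- draws[[paste0("sich_", si)]][it]
    }
    b$utilities$u_mrs[1:6] <- vapply(1:6, function(i) draws[[paste0("u_mrs_", i)]][it], 0)
    b$utilities$u_recurrence <- draws$u_recurrence[it]
    b$utilities$d_sich <- draws$d_sich[it]
    b$costs$acute_hosp_by_mrs <- vapply(1:7, function(i) draws[[paste0("acute_", i)]][it], 0)
    b$costs$annual_care_mrs01 <- draws$annual_care_mrs01[it]
    b$costs$annual_care_mrs25 <- draws$annual_care_mrs25[it]
    b$costs$recurrent_stroke_event <- draws$recurrent_stroke_event[it]
    b$costs$sich_event <- draws$sich_event[it]
    b$costs$alteplase_base_case <- draws$alteplase_base_case[it]
    b$mortality$hr_by_mrs <- vapply(1:6, function(i) draws[[paste0("hr_", i)]][it], 0)
    b$recurrence$annual_recurrence_by_mrs <-
      vapply(1:6, function(i) draws[[paste0("recur_", i)]][it], 0)
    b$recurrence$case_fatality <- draws$case_fatality[it]

    res <- run_base_case(b)
    dc[it] <- res$cea$delta_cost
    de[it] <- res$cea$delta_qaly
  }

  p_int <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), 0)
  structure(list(
    draws = data.frame(draw = seq_len(n_iterations),
                       delta_cost = dc, delta_qaly = de,
                       sich_comparator = draws$sich_1,
                       sich_intervention = draws$sich_2,
                       drug_cost = draws$alteplase_base_case,
                       u_mrs0 = draws$u_mrs_1,
                       case_fatality = draws$case_fatality),
    ceac = data.frame(wtp = wtp_grid,
                      p_intervention = p_int,
                      p_comparator = 1 - p_int),
    seed = as.integer(seed),
    n_iterations = as.integer(n_iterations)),
    class = "psa_result")
}

#' WTP value where the intervention's acceptability first exceeds 0.5
#'
#' Linear interpolation between the CEAC grid points bracketing probability
#' 0.5. If the curve starts at or above 0.5 the grid minimum is returned; if
#' it never reaches 0.5 the grid maximum is returned; both cases are flagged
#' with `crossed = FALSE`.
#'
#' @param ceac The `ceac` data.frame of a `psa_result` (columns `wtp`,
#'   `p_intervention`).
#' @return List with `wtp` (CNY/QALY) and `crossed` (logical).
#' @export
ceac_crossing <- function(ceac) {
  p <- ceac$p_intervention
  w <- ceac$wtp
  if (p[1] >= 0.5) return(list(wtp = w[1], crossed = FALSE))
  idx <- which(p >= 0.5)
  if (!length(idx)) return(list(wtp = w[length(w)], crossed = FALSE))
  i <- idx[1]
  frac <- (0.5 - p[i - 1]) / (p[i] - p[i - 1])
  list(wtp = w[i - 1] + frac * (w[i] - w[i - 1]), crossed = TRUE)
}
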