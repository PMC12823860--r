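#' @importFrom stats rbeta rgamma rbinom rmultinom runif setNames quantile sd
#' @importFrom utils modifyList write.csv
NULL

# ---- domain type constructors -----------------------------------------------

#' Probability distribution over mRS levels 0-6
#'
#' The central state summary of the model: the probability that a patient
#' occupies each modified Rankin Scale level (0 = no symptoms ... 5 = severe
#' disability, 6 = dead) at a given time point.
#'
#' @param p Numeric vector of length 7 (mRS 0..6). Must be non-negative and
#'   sum to 1; sums within 1e-3 of 1 are renormalized, larger deviations are
#'   rejected.
#' @return A numeric vector of class `mrs_distribution`.
#' @export
mrs_distribution <- function(p) {
  if (length(p) != 7L || !is.numeric(p)) {
    stop("mrs_distribution: 'p' must be a numeric vector of length 7 (mRS 0..6)")
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("mrs_distribution: probabilities must lie in [0, 1]")
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-3) {
    stop(sprintf("mrs_distribution: probabilities sum to %.6f (must be 1 within 1e-3)", s))
  }
  if (abs(s - 1) > 1e-9) p <- p / s
  structure(as.numeric(p), class = "mrs_distribution",
            names = paste0("mrs", 0:6))
}

#' Parameter range (interpreted as a 95% interval for sampling)
#'
#' @param low,high Numeric bounds, `low <= high`, in the units of the parent
#'   parameter.
#' @return A list of class `param_range`.
#' @export
param_range <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == length(high))
  if (any(low > high)) stop("param_range: low must not exceed high")
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = "param_range")
}

#' Parameters defining one treatment strategy (arm)
#'
#' @param name Arm label.
#' @param mrs_at_3mo [mrs_distribution()] of outcomes at month 3.
#' @param sich_incidence Probability of symptomatic intracranial hemorrhage.
#' @param includes_drug_cost Logical; does this arm incur the thrombolytic
#'   drug acquisition cost?
#' @param mrs_range Optional `param_range` with vector bounds for the seven
#'   mRS proportions (used by sensitivity analyses).
#' @param sich_range Optional `param_range` for the sICH incidence.
#' @return A list of class `strategy_params`.
#' @export
strategy_params <- function(name, mrs_at_3mo, sich_incidence,
                            includes_drug_cost,
                            mrs_range = NULL, sich_range = NULL) {
  if (!inherits(mrs_at_3mo, "mrs_distribution")) {
    mrs_at_3mo <- mrs_distribution(mrs_at_3mo)
  }
  if (!is.numeric(sich_incidence) || sich_incidence < 0 || sich_incidence > 1) {
    stop("strategy_params: sich_incidence must be a probability in [0, 1]")
  }
  structure(list(name = as.character(name),
                 mrs_at_3mo = mrs_at_3mo,
                 sich_incidence = as.numeric(sich_incidence),
                 includes_drug_cost = isTRUE(includes_drug_cost),
                 mrs_range = mrs_range,
                 sich_range = sich_range),
            class = "strategy_params")
}

#' Utility weights for health states and events
#'
#' @param u_mrs Utilities for mRS 0..6 (QALY weight per year); must be
#'   non-increasing in mRS level and `u_mrs[7]` (death) must be 0.
#' @param u_recurrence Utility applied during a recurrence cycle (replaces the
#'   state utility for recurrence survivors in the event cycle).
#' @param d_sich One-time disutility per sICH event.
#' @return A list of class `utility_set`.
#' @export
utility_set <- function(u_mrs, u_recurrence, d_sich) {
  stopifnot(length(u_mrs) == 7L)
  if (any(u_mrs < 0 | u_mrs > 1)) stop("utility_set: utilities must lie in [0, 1]")
  if (u_mrs[7] != 0) stop("utility_set: utility of the dead state (mRS 6) must be 0")
  if (any(diff(u_mrs) > 1e-12)) {
    stop("utility_set: u_mrs must be non-increasing in mRS level")
  }
  if (u_recurrence < 0 || u_recurrence > 1) stop("utility_set: u_recurrence must lie in [0, 1]")
  if (d_sich < 0 || d_sich > 1) stop("utility_set: d_sich must lie in [0, 1]")
  structure(list(u_mrs = as.numeric(u_mrs),
                 u_recurrence = as.numeric(u_recurrence),
                 d_sich = as.numeric(d_sich)),
            class = "utility_set")
}

#' Cost parameters (2024 CNY)
#'
#' @param acute_hosp_by_mrs One-time acute hospitalization cost for the
#'   3-month decision-tree phase, by mRS 0..6.
#' @param annual_care_mrs01 Annual post-stroke care cost for mRS 0-1.
#' @param annual_care_mrs25 Annual post-stroke care cost for mRS 2-5.
#' @param recurrent_stroke_event One-time cost per recurrent stroke.
#' @param sich_event One-time cost per sICH event.
#' @param alteplase_price_20mg,alteplase_price_50mg National procurement
#'   prices per vial.
#' @param alteplase_base_case Base-case drug cost; must equal the mean of the
#'   two vial prices.
#' @return A list of class `cost_set`.
#' @export
cost_set <- function(acute_hosp_by_mrs, annual_care_mrs01, annual_care_mrs25,
                     recurrent_stroke_event, sich_event,
                     alteplase_price_20mg, alteplase_price_50mg,
                     alteplase_base_case = (alteplase_price_20mg + alteplase_price_50mg) / 2) {
  stopifnot(length(acute_hosp_by_mrs) == 7L)
  vals <- c(acute_hosp_by_mrs, annual_care_mrs01, annual_care_mrs25,
            recurrent_stroke_event, sich_event,
            alteplase_price_20mg, alteplase_price_50mg, alteplase_base_case)
  if (any(vals < 0)) stop("cost_set: all costs must be non-negative")
  if (abs(alteplase_base_case - (alteplase_price_20mg + alteplase_price_50mg) / 2) > 1e-6) {
    stop("cost_set: alteplase_base_case must equal the mean of the 20 mg and 50 mg prices")
  }
  structure(list(acute_hosp_by_mrs = as.numeric(acute_hosp_by_mrs),
                 annual_care_mrs01 = as.numeric(annual_care_mrs01),
                 annual_care_mrs25 = as.numeric(annual_care_mrs25),
                 recurrent_stroke_event = as.numeric(recurrent_stroke_event),
                 sich_event = as.numeric(sich_event),
                 alteplase_price_20mg = as.numeric(alteplase_price_20mg),
                 alteplase_price_50mg = as.numeric(alteplase_price_50mg),
                 alteplase_base_case = as.numeric(alteplase_base_case)),
            class = "cost_set")
}

#' Age-banded background mortality life table
#'
#' @param age_lower Lower bound (years) of each 5-year band, starting at 60.
#' @param annual_mortality Annual probability of death in each band; must be
#'   strictly increasing across bands and lie in (0, 1).
#' @return A data.frame of class `life_table`.
#' @export
life_table <- function(age_lower, annual_mortality) {
  stopifnot(length(age_lower) == length(annual_mortality))
  if (any(annual_mortality <= 0 | annual_mortality >= 1)) {
    stop("life_table: annual mortality must lie in (0, 1)")
  }
  if (any(diff(annual_mortality) <= 0)) {
    stop("life_table: annual mortality must be strictly increasing across age bands")
  }
  if (is.unsorted(age_lower, strictly = TRUE)) {
    stop("life_table: age bands must be strictly increasing")
  }
  structure(data.frame(age_lower = as.numeric(age_lower),
                       annual_mortality = as.numeric(annual_mortality)),
            class = c("life_table", "data.frame"))
}

#' Excess-mortality model for post-stroke survivors
#'
#' Background mortality in alive states is multiplied (on the hazard scale)
#' by an mRS-specific hazard ratio and a global post-stroke excess hazard
#' ratio.
#'
#' @param hr_by_mrs Hazard ratios for alive states mRS 0..5; non-decreasing.
#' @param post_stroke_excess_hr Global multiplier applied to all alive states.
#' @param hr_range Optional `param_range` with vector bounds for the six HRs.
#' @return A list of class `mortality_model`.
#' @export
mortality_model <- function(hr_by_mrs, post_stroke_excess_hr = 1,
                            hr_range = NULL) {
  stopifnot(length(hr_by_mrs) == 6L)
  if (any(hr_by_mrs <= 0)) stop("mortality_model: hazard ratios must be positive")
  if (any(diff(hr_by_mrs) < -1e-12)) {
    stop("mortality_model: hr_by_mrs must be non-decreasing in mRS level")
  }
  if (post_stroke_excess_hr <= 0) stop("mortality_model: post_stroke_excess_hr must be positive")
  structure(list(hr_by_mrs = as.numeric(hr_by_mrs),
                 post_stroke_excess_hr = as.numeric(post_stroke_excess_hr),
                 hr_range = hr_range),
            class = "mortality_model")
}

#' Recurrent stroke model
#'
#' @param annual_recurrence_by_mrs Annual recurrence probabilities for mRS
#'   0..5; non-decreasing (higher disability carries higher recurrence risk).
#' @param case_fatality Probability of death given a recurrent stroke.
#' @param p_stay_given_survive Probability a recurrence survivor remains in
#'   the same mRS state; otherwise they shift one state worse (capped at
#'   mRS 5).
#' @param recurrence_range,case_fatality_range Optional `param_range`s.
#' @return A list of class `recurrence_model`.
#' @export
recurrence_model <- function(annual_recurrence_by_mrs, case_fatality,
                             p_stay_given_survive = 0.5,
                             recurrence_range = NULL,
                             case_fatality_range = NULL) {
  stopifnot(length(annual_recurrence_by_mrs) == 6L)
  if (any(annual_recurrence_by_mrs < 0 | annual_recurrence_by_mrs >= 1)) {
    stop("recurrence_model: annual recurrence probabilities must lie in [0, 1)")
  }
  if (any(diff(annual_recurrence_by_mrs) < -1e-12)) {
    stop("recurrence_model: annual_recurrence_by_mrs must be non-decreasing in mRS level")
  }
  if (case_fatality < 0 || case_fatality > 1) {
    stop("recurrence_model: case_fatality must lie in [0, 1]")
  }
  if (p_stay_given_survive < 0 || p_stay_given_survive > 1) {
    stop("recurrence_model: p_stay_given_survive must lie in [0, 1]")
  }
  structure(list(annual_recurrence_by_mrs = as.numeric(annual_recurrence_by_mrs),
                 case_fatality = as.numeric(case_fatality),
                 p_stay_given_survive = as.numeric(p_stay_given_survive),
                 recurrence_range = recurrence_range,
                 case_fatality_range = case_fatality_range),
            class = "recurrence_model")
}

#' Discounting specification
#'
#' @param annual_rate Annual discount rate applied to all future costs and
#'   health outcomes; must lie in the sensitivity range `[0, 0.08]`.
#' @param range `param_range` for one-way sensitivity analysis.
#' @return A list of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate, range = param_range(0, 0.08)) {
  if (annual_rate < 0 || annual_rate > 0.08) {
    stop("discount_spec: annual_rate must lie in [0, 0.08]")
  }
  structure(list(annual_rate = as.numeric(annual_rate), range = range),
            class = "discount_spec")
}

#' Model run configuration
#'
#' The cohort enters the model at `start_age`, spends one `cycle_length`
#' quarter in the decision tree, then `horizon / cycle_length - 1` Markov
#' cycles (119 for a 30-year horizon at 3-month cycles).
#'
#' @param start_age Cohort starting age (years).
#' @param horizon Time horizon (years).
#' @param cycle_length Cycle length (years).
#' @param half_cycle_correction Apply trapezoidal half-cycle correction?
#' @param rng_seed Default RNG seed for stochastic components.
#' @param psa_iterations Default number of PSA draws.
#' @return A list of class `model_config`, with the derived field
#'   `n_markov_cycles`.
#' @export
model_config <- function(start_age = 64, horizon = 30, cycle_length = 0.25,
                         half_cycle_correction = TRUE, rng_seed = 1234L,
                         psa_iterations = 1000L) {
  n_cycles <- horizon / cycle_length - 1
  if (abs(n_cycles - round(n_cycles)) > 1e-9 || n_cycles < 1) {
    stop("model_config: horizon must be a positive integer multiple of cycle_length")
  }
  structure(list(start_age = as.numeric(start_age),
                 horizon = as.numeric(horizon),
                 cycle_length = as.numeric(cycle_length),
                 n_markov_cycles = as.integer(round(n_cycles)),
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 rng_seed = as.integer(rng_seed),
                 psa_iterations = as.integer(psa_iterations)),
            class = "model_config")
}

#' GDP-based willingness-to-pay thresholds
#'
#' @param gdp_per_capita Per-capita GDP (CNY). `wtp_1x` and `wtp_3x` are
#'   derived as 1x and 3x this value.
#' @return A list of class `cea_thresholds`.
#' @export
cea_thresholds <- function(gdp_per_capita) {
  if (gdp_per_capita <= 0) stop("cea_thresholds: gdp_per_capita must be positive")
  structure(list(gdp_per_capita = as.numeric(gdp_per_capita),
                 wtp_1x = as.numeric(gdp_per_capita),
                 wtp_3x = 3 * as.numeric(gdp_per_capita)),
            class = "cea_thresholds")
}

# ---- model-spec file I/O ----------------------------------------------------

# pull a {value, low, high, source} block out of parsed YAML; low/high optional
.block <- function(node, field, what) {
  if (is.null(node[[field]])) stop(sprintf("model spec: missing field '%s' in %s", field, what))
  b <- node[[field]]
  if (!is.list(b) || is.null(b$value)) {
    stop(sprintf("model spec: field '%s' must be a {value, low, high, source} block", field))
  }
  b
}

.block_range <- function(b) {
  if (is.null(b$low) || is.null(b$high)) return(NULL)
  param_range(unlist(b$low), unlist(b$high))
}

#' Load a model specification file
#'
#' Reads a YAML parameter file (see the packaged
#' `extdata/default_model.yaml` for the schema), validates every domain-type
#' invariant, and returns the full parameter bundle. mRS distributions whose
#' entries sum to within 1e-3 of 1 are renormalized; larger deviations are
#' rejected with an error naming the offending field.
#'
#' @param path Path to the model-spec file. Defaults to the packaged base-case
#'   configuration.
#' @return A list of class `model_spec` with elements `config`, `strategies`
#'   (named list of [strategy_params()]), `utilities`, `costs`, `life_table`,
#'   `mortality`, `recurrence`, `discount`, `thresholds`, `uncertainty`.
#' @export
load_model_spec <- function(path = default_model_path()) {
  if (!file.exists(path)) stop("load_model_spec: file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (required in c("config", "strategies", "utilities", "costs", "life_table",
                     "mortality", "recurrence", "discount", "thresholds")) {
    if (is.null(raw[[required]])) {
      stop("model spec: missing top-level section '", required, "'")
    }
  }

  cfg_raw <- raw$config
  config <- model_config(
    start_age = cfg_raw$start_age %||% 64,
    horizon = cfg_raw$horizon %||% 30,
    cycle_length = cfg_raw$cycle_length %||% 0.25,
    half_cycle_correction = cfg_raw$half_cycle_correction %||% TRUE,
    rng_seed = cfg_raw$rng_seed %||% 1234L,
    psa_iterations = cfg_raw$psa_iterations %||% 1000L
  )

  strategies <- lapply(raw$strategies, function(s) {
    mrs_b <- .block(s, "mrs_at_3mo", paste0("strategy '", s$name, "'"))
    sich_b <- .block(s, "sich_incidence", paste0("strategy '", s$name, "'"))
    p <- unlist(mrs_b$value)
    if (abs(sum(p) - 1) > 1e-3) {
      stop(sprintf(
        "model spec: strategy '%s' mrs_at_3mo sums to %.4f; must be 1 within 1e-3",
        s$name, sum(p)))
    }
    strategy_params(
      name = s$name,
      mrs_at_3mo = mrs_distribution(p),
      sich_incidence = sich_b$value,
      includes_drug_cost = s$includes_drug_cost,
      mrs_range = .block_range(mrs_b),
      sich_range = .block_range(sich_b)
    )
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  if (length(strategies) != 2L) {
    stop("model spec: exactly two strategies (comparator first, intervention second) are required")
  }

  u <- raw$utilities
  utilities <- utility_set(
    u_mrs = unlist(.block(u, "u_mrs", "utilities")$value),
    u_recurrence = .block(u, "u_recurrence", "utilities")$value,
    d_sich = .block(u, "d_sich", "utilities")$value
  )
  u_ranges <- list(
    u_mrs = .block_range(u$u_mrs),
    u_recurrence = .block_range(u$u_recurrence),
    d_sich = .block_range(u$d_sich)
  )

  co <- raw$costs
  costs <- cost_set(
    acute_hosp_by_mrs = unlist(.block(co, "acute_hosp_by_mrs", "costs")$value),
    annual_care_mrs01 = .block(co, "annual_care_mrs01", "costs")$value,
    annual_care_mrs25 = .block(co, "annual_care_mrs25", "costs")$value,
    recurrent_stroke_event = .block(co, "recurrent_stroke_event", "costs")$value,
    sich_event = .block(co, "sich_event", "costs")$value,
    alteplase_price_20mg = .block(co, "alteplase_price_20mg", "costs")$value,
    alteplase_price_50mg = .block(co, "alteplase_price_50mg", "costs")$value,
    alteplase_base_case = .block(co, "alteplase_base_case", "costs")$value
  )
  cost_ranges <- list(
    acute_hosp_by_mrs = .block_range(co$acute_hosp_by_mrs),
    annual_care_mrs01 = .block_range(co$annual_care_mrs01),
    annual_care_mrs25 = .block_range(co$annual_care_mrs25),
    recurrent_stroke_event = .block_range(co$recurrent_stroke_event),
    sich_event = .block_range(co$sich_event),
    alteplase_base_case = .block_range(co$alteplase_base_case)
  )

  lt <- raw$life_table$bands
  lifetab <- life_table(
    age_lower = vapply(lt, `[[`, numeric(1), "age"),
    annual_mortality = vapply(lt, `[[`, numeric(1), "annual_mortality")
  )

  mo <- raw$mortality
  mortality <- mortality_model(
    hr_by_mrs = unlist(.block(mo, "hr_by_mrs", "mortality")$value),
    post_stroke_excess_hr = .block(mo, "post_stroke_excess_hr", "mortality")$value,
    hr_range = .block_range(mo$hr_by_mrs)
  )

  re <- raw$recurrence
  recurrence <- recurrence_model(
    annual_recurrence_by_mrs = unlist(.block(re, "annual_recurrence_by_mrs", "recurrence")$value),
    case_fatality = .block(re, "case_fatality", "recurrence")$value,
    p_stay_given_survive = .block(re, "p_stay_given_survive", "recurrence")$value,
    recurrence_range = .block_range(re$annual_recurrence_by_mrs),
    case_fatality_range = .block_range(re$case_fatality)
  )

  di <- .block(raw$discount, "annual_rate", "discount")
  discount <- discount_spec(di$value,
                            range = .block_range(di) %||% param_range(0, 0.08))

  thresholds <- cea_thresholds(.block(raw$thresholds, "gdp_per_capita", "thresholds")$value)

  bundle <- structure(list(
    config = config,
    strategies = strategies,
    utilities = utilities,
    utility_ranges = u_ranges,
    costs = costs,
    cost_ranges = cost_ranges,
    life_table = lifetab,
    mortality = mortality,
    recurrence = recurrence,
    discount = discount,
    thresholds = thresholds,
    uncertainty = list(
      mrs_concentration = raw$uncertainty$mrs_concentration %||% 115
    ),
    provenance = .collect_provenance(raw)
  ), class = "model_spec")
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.collect_provenance <- function(raw) {
  src <- function(b) if (is.list(b) && !is.null(b$source)) b$source else NA_character_
  list(
    mrs_at_3mo = vapply(raw$strategies, function(s) src(s$mrs_at_3mo), character(1)),
    sich_incidence = vapply(raw$strategies, function(s) src(s$sich_incidence), character(1)),
    utilities = src(raw$utilities$u_mrs),
    costs = src(raw$costs$acute_hosp_by_mrs),
    life_table = raw$life_table$source %||% NA_character_,
    mortality = src(raw$mortality$hr_by_mrs),
    recurrence = src(raw$recurrence$annual_recurrence_by_mrs)
  )
}

#' Path to the packaged base-case model specification
#' @return File path of `extdata/default_model.yaml`.
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.yaml", package = "strokeCUA",
              mustWork = TRUE)
}

#' Load the packaged base-case parameter bundle
#' @return A `model_spec` bundle (see [load_model_spec()]).
#' @export
default_model_spec <- function() load_model_spec(default_model_path())

#' Write a parameter bundle back to a model-spec file
#'
#' Emits the same YAML schema read by [load_model_spec()]; provenance tags
#' (PAPER vs ASSUMED) recorded at load time are preserved. Numeric fields
#' round-trip exactly: `load_model_spec(write_model_spec(b, f))` equals `b`.
#'
#' @param bundle A `model_spec` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_spec"))
  prov <- bundle$provenance
  blk <- function(value, range = NULL, source = NA_character_) {
    b <- list(value = value)
    if (!is.null(range)) { b$low <- range$low; b$high <- range$high }
    if (!is.na(source)) b$source <- source
    b
  }
  out <- list(
    model = "pcis-alteplase-cua",
    currency = "CNY-2024",
    config = list(
      start_age = bundle$config$start_age,
      horizon = bundle$config$horizon,
      cycle_length = bundle$config$cycle_length,
      half_cycle_correction = bundle$config$half_cycle_correction,
      rng_seed = bundle$config$rng_seed,
      psa_iterations = bundle$config$psa_iterations
    ),
    strategies = unname(lapply(seq_along(bundle$strategies), function(i) {
      s <- bundle$strategies[[i]]
      list(name = s$name,
           includes_drug_cost = s$includes_drug_cost,
           mrs_at_3mo = blk(as.numeric(s$mrs_at_3mo), s$mrs_range,
                            prov$mrs_at_3mo[i]),
           sich_incidence = blk(s$sich_incidence, s$sich_range,
                                prov$sich_incidence[i]))
    })),
    utilities = list(
      u_mrs = blk(bundle$utilities$u_mrs, bundle$utility_ranges$u_mrs, prov$utilities),
      u_recurrence = blk(bundle$utilities$u_recurrence, bundle$utility_ranges$u_recurrence),
      d_sich = blk(bundle$utilities$d_sich, bundle$utility_ranges$d_sich)
    ),
    costs = list(
      acute_hosp_by_mrs = blk(bundle$costs$acute_hosp_by_mrs,
                              bundle$cost_ranges$acute_hosp_by_mrs, prov$costs),
      annual_care_mrs01 = blk(bundle$costs$annual_care_mrs01, bundle$cost_ranges$annual_care_mrs01),
      annual_care_mrs25 = blk(bundle$costs$annual_care_mrs25, bundle$cost_ranges$annual_care_mrs25),
      recurrent_stroke_event = blk(bundle$costs$recurrent_stroke_event,
                                   bundle$cost_ranges$recurrent_stroke_event),
      sich_event = blk(bundle$costs$sich_event, bundle$cost_ranges$sich_event),
      alteplase_price_20mg = blk(bundle$costs$alteplase_price_20mg),
      alteplase_price_50mg = blk(bundle$costs$alteplase_price_50mg),
      alteplase_base_case = blk(bundle$costs$alteplase_base_case,
                                bundle$cost_ranges$alteplase_base_case)
    ),
    life_table = list(
      source = prov$life_table,
      bands = unname(lapply(seq_len(nrow(bundle$life_table)), function(i) {
        list(age = bundle$life_table$age_lower[i],
             annual_mortality = bundle$life_table$annual_mortality[i])
      }))
    ),
    mortality = list(
      hr_by_mrs = blk(bundle$mortality$hr_by_mrs, bundle$mortality$hr_range,
                      prov$mortality),
      post_stroke_excess_hr = blk(bundle$mortality$post_stroke_excess_hr)
    ),
    recurrence = list(
      annual_recurrence_by_mrs = blk(bundle$recurrence$annual_recurrence_by_mrs,
                                     bundle$recurrence$recurrence_range,
                                     prov$recurrence),
      case_fatality = blk(bundle$recurrence$case_fatality,
                          bundle$recurrence$case_fatality_range),
      p_stay_given_survive = blk(bundle$recurrence$p_stay_given_survive)
    ),
    discount = list(
      annual_rate = blk(bundle$discount$annual_rate, bundle$discount$range)
    ),
    thresholds = list(
      gdp_per_capita = blk(bundle$thresholds$gdp_per_capita)
    ),
    uncertainty = list(mrs_concentration = bundle$uncertainty$mrs_concentration)
  )
  # precision 17 makes every double round-trip bit-exactly through YAML
  writeLines(yaml::as.yaml(out, precision = 17), path)
  invisible(path)
}
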