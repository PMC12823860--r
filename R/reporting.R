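# Run assembly: each analysis subcommand writes its tables plus a manifest
# (timestamp, config hash, seed, file list) into an output directory, so a
# run is reproducible from its own artifacts. A thin Rscript wrapper over
# cua_main() is shipped in inst/cli/strokecua.

.config_hash <- function(path) {
  # stable content hash of the config file (polynomial hash mod 2^31 - 1)
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' @param out_dir Output directory.
#' @param subcommand Analysis subcommand that produced the run.
#' @param config_path Path of the model-spec file used.
#' @param seed Seed used (or NA for deterministic runs).
#' @param files Character vector of output files written (relative paths).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(out_dir, subcommand, config_path, seed, files) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subcommand = subcommand,
    config = list(path = config_path, hash = .config_hash(config_path)),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    package_version = as.character(utils::packageVersion("strokeCUA")),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  basename(path)
}

#' Run an analysis subcommand and write its outputs
#'
#' Programmatic equivalent of the shipped command-line wrapper. Subcommands:
#' `base-case` (JSON summary + per-arm cohort traces), `owsa` (tornado
#' table), `psa` (draws + CEAC tables), `synth` (synthetic observed
#' model-spec file + truth sidecar). Every run writes `manifest.json`.
#'
#' @param subcommand One of `"base-case"`, `"owsa"`, `"psa"`, `"synth"`.
#' @param config Path to a model-spec file (default: packaged base case).
#' @param out Output directory (created if needed).
#' @param seed Seed for stochastic subcommands (default: config's seed).
#' @param iterations PSA iteration override.
#' @param discount Discount-rate override.
#' @param wtp_max Upper end of the CEAC WTP grid (CNY/QALY).
#' @return Invisibly, the primary result object of the subcommand.
#' @export
run_analysis <- function(subcommand = c("base-case", "owsa", "psa", "synth"),
                         config = default_model_path(), out = ".",
                         seed = NULL, iterations = NULL, discount = NULL,
                         wtp_max = 120000) {
  subcommand <- match.arg(subcommand)
  bundle <- load_model_spec(config)
  if (!is.null(discount)) bundle$discount$annual_rate <- discount
  if (!is.null(seed)) bundle$config$rng_seed <- as.integer(seed)
  if (!is.null(iterations)) bundle$config$psa_iterations <- as.integer(iterations)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  result <- switch(subcommand,
    "base-case" = {
      res <- run_base_case(bundle)
      summary <- list(
        comparator = list(name = bundle$strategies[[1]]$name,
                          total_cost = res$comparator$total_cost,
                          total_qaly = res$comparator$total_qaly,
                          total_ly = res$comparator$total_ly),
        intervention = list(name = bundle$strategies[[2]]$name,
                            total_cost = res$intervention$total_cost,
                            total_qaly = res$intervention$total_qaly,
                            total_ly = res$intervention$total_ly),
        delta_cost = res$cea$delta_cost,
        delta_qaly = res$cea$delta_qaly,
        delta_ly = res$cea$delta_ly,
        icer = res$cea$icer,
        dominance = res$cea$dominance,
        classification = res$classification,
        thresholds = list(wtp_1x = res$thresholds$wtp_1x,
                          wtp_3x = res$thresholds$wtp_3x)
      )
      jsonlite::write_json(summary, file.path(out, "base_case.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      files <- c(files, "base_case.json",
                 .write_table(res$comparator$trace, file.path(out, "trace_comparator.csv")),
                 .write_table(res$intervention$trace, file.path(out, "trace_intervention.csv")))
      res
    },
    "owsa" = {
      tor <- one_way_sensitivity(bundle)
      files <- c(files, .write_table(as.data.frame(tor), file.path(out, "tornado.csv")))
      tor
    },
    "psa" = {
      psa <- run_psa(bundle, n_iterations = bundle$config$psa_iterations,
                     seed = bundle$config$rng_seed,
                     wtp_grid = seq(0, wtp_max, by = 1000))
      files <- c(files,
                 .write_table(psa$draws[c("draw", "delta_cost", "delta_qaly")],
                              file.path(out, "psa_draws.csv")),
                 .write_table(psa$ceac, file.path(out, "ceac.csv")))
      psa
    },
    "synth" = {
      obs <- generate_trial_bundle(bundle, seed = bundle$config$rng_seed)
      write_model_spec(obs, file.path(out, "synthetic_observed.yaml"))
      write_model_spec(bundle, file.path(out, "synthetic_truth.yaml"))
      files <- c(files, "synthetic_observed.yaml", "synthetic_truth.yaml")
      obs
    })

  write_run_manifest(out, subcommand, config,
                     seed = bundle$config$rng_seed, files = files)
  invisible(result)
}

#' Command-line entry point
#'
#' Thin argv parser over [run_analysis()]; used by the shipped
#' `inst/cli/strokecua` wrapper script.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("psa", "--seed", "1", "--iterations", "500", "--out", "run1")`.
#' @return Integer exit code (0 on success), invisibly.
#' @export
cua_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: strokecua <base-case|owsa|psa|synth>",
    "[--config PATH] [--seed INT] [--iterations INT]",
    "[--discount FLOAT] [--wtp-max FLOAT] [--out DIR]")
  if (!length(argv) || argv[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(0L))
  }
  sub <- argv[1]
  if (!sub %in% c("base-case", "owsa", "psa", "synth")) {
    message("unknown subcommand: ", sub, "\n", usage); return(invisible(2L))
  }
  opts <- list(config = default_model_path(), out = ".", seed = NULL,
               iterations = NULL, discount = NULL, wtp_max = 120000)
  rest <- argv[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(rest)) {
      message("unknown or valueless flag: ", rest[i], "\n", usage)
      return(invisible(2L))
    }
    val <- rest[i + 1L]
    opts[[key]] <- if (key %in% c("config", "out")) val else as.numeric(val)
    i <- i + 2L
  }
  status <- tryCatch({
    run_analysis(sub, config = opts$config, out = opts$out, seed = opts$seed,
                 iterations = opts$iterations, discount = opts$discount,
                 wtp_max = opts$wtp_max)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
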