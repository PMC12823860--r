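# Construction of PSA sampling distributions from point estimates and ranges.
# Ranges are read as symmetric Wald-style 95% intervals, so moment matching
# uses SD = (high - low) / 3.92. Zero-width ranges degrade gracefully to
# fixed-value samplers.

#' Beta distribution from a mean and a 95% range
#'
#' Moment-matching fit: the returned shapes satisfy
#' `alpha / (alpha + beta) = mean` and the implied SD equals
#' `(high - low) / 3.92` (truncated below the binomial-variance bound
#' `mean * (1 - mean)` when the range is implausibly wide). Exact
#' CI-matching is not attempted.
#'
#' @param mean Point estimate, strictly inside (0, 1).
#' @param range A [param_range()] (or `NULL` / zero-width for a fixed value).
#' @return A list of class `param_sampler` with fields `family`
#'   (`"beta"` or `"fixed"`), `mean`, and for beta fits `alpha`, `beta`.
#' @export
beta_from_mean_ci <- function(mean, range = NULL) {
  if (!is.null(range) && !inherits(range, "param_range")) {
    range <- param_range(range[1], range[2])
  }
  if (is.null(range) || (range$high - range$low) <= 0) {
    if (mean < 0 || mean > 1) stop("beta_from_mean_ci: mean must lie in [0, 1]")
    return(fixed_sampler(mean))
  }
  if (mean <= 0 || mean >= 1) {
    stop("beta_from_mean_ci: mean must lie strictly in (0, 1) for a beta fit")
  }
  s <- (range$high - range$low) / 3.92
  v <- min(s^2, 0.999 * mean * (1 - mean))
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", mean = mean,
                 alpha = mean * nu, beta = (1 - mean) * nu),
            class = "param_sampler")
}

#' Gamma distribution from a mean and a 95% range
#'
#' Moment-matching fit with `SD = (high - low) / 3.92`:
#' `shape = (mean / SD)^2`, `scale = SD^2 / mean`, so `shape * scale = mean`
#' exactly.
#'
#' @param mean Point estimate, strictly positive.
#' @param range A [param_range()] (or `NULL` / zero-width for a fixed value).
#' @return A `param_sampler` with fields `family` (`"gamma"` or `"fixed"`),
#'   `mean`, and for gamma fits `shape`, `scale`.
#' @export
gamma_from_mean_range <- function(mean, range = NULL) {
  if (!is.null(range) && !inherits(range, "param_range")) {
    range <- param_range(range[1], range[2])
  }
  if (is.null(range) || (range$high - range$low) <= 0) {
    if (mean < 0) stop("gamma_from_mean_range: mean must be non-negative")
    return(fixed_sampler(mean))
  }
  if (mean <= 0) stop("gamma_from_mean_range: mean must be positive for a gamma fit")
  s <- (range$high - range$low) / 3.92
  structure(list(family = "gamma", mean = mean,
                 shape = (mean / s)^2, scale = s^2 / mean),
            class = "param_sampler")
}

#' Dirichlet distribution over a 7-state mRS simplex
#'
#' Keeps the simplex constraint coherent when sampling a whole mRS
#' distribution: the parameter vector is `concentration * p` (entries floored
#' at 1e-6 before scaling), so the sampler's expectation equals `p`.
#'
#' @param dist An [mrs_distribution()] (or 7-vector summing to 1).
#' @param concentration Positive scalar; larger values concentrate samples
#'   around `dist` (the packaged default, 115, is the granularity scale of
#'   the trial arms).
#' @return A `param_sampler` with `family = "dirichlet"` and field `alpha`.
#' @export
dirichlet_from_distribution <- function(dist, concentration) {
  if (concentration <= 0) stop("dirichlet_from_distribution: concentration must be positive")
  p <- pmax(as.numeric(dist), 1e-6)
  structure(list(family = "dirichlet", mean = as.numeric(dist),
                 alpha = concentration * p),
            class = "param_sampler")
}

#' @rdname beta_from_mean_ci
#' @export
fixed_sampler <- function(mean) {
  structure(list(family = "fixed", mean = as.numeric(mean)),
            class = "param_sampler")
}

#' Draw from a parameter sampler
#'
#' @param sampler A `param_sampler`.
#' @param n Number of draws.
#' @return For scalar families, a numeric vector of length `n`; for
#'   `dirichlet`, an `n x 7` matrix whose rows sum to 1.
#' @export
draw_sampler <- function(sampler, n = 1L) {
  stopifnot(inherits(sampler, "param_sampler"))
  switch(sampler$family,
    fixed = rep(sampler$mean, n),
    beta = rbeta(n, sampler$alpha, sampler$beta),
    gamma = rgamma(n, shape = sampler$shape, scale = sampler$scale),
    dirichlet = {
      k <- length(sampler$alpha)
      g <- matrix(rgamma(n * k, shape = rep(sampler$alpha, each = n)), nrow = n)
      g / rowSums(g)
    },
    stop("unknown sampler family: ", sampler$family)
  )
}
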