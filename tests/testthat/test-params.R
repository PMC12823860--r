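test_that("packaged defaults load the printed trial parameters", {
  b <- default_model_spec()

  expect_equal(as.numeric(b$strategies$alteplase$mrs_at_3mo),
               c(0.3913, 0.3478, 0.1565, 0.0261, 0.0174, 0.0087, 0.0522))
  expect_equal(b$utilities$u_mrs, c(0.95, 0.89, 0.67, 0.44, 0.16, 0.10, 0))
  expect_equal(b$strategies$alteplase$sich_incidence, 0.0172)
  expect_equal(b$strategies$standard$sich_incidence, 0.0087)
  expect_equal(b$mortality$hr_by_mrs, c(1, 1, 1.11, 1.27, 1.71, 2.37))
  expect_equal(b$recurrence$case_fatality, 0.21)
  expect_equal(b$costs$alteplase_base_case,
               (b$costs$alteplase_price_20mg + b$costs$alteplase_price_50mg) / 2)
  expect_equal(b$thresholds$wtp_1x, 95749)
  expect_equal(b$thresholds$wtp_3x, 3 * 95749)
  expect_identical(b$config$n_markov_cycles, 119L)

  # the standard arm's printed proportions sum to 1.0001 and are renormalized
  expect_equal(sum(as.numeric(b$strategies$standard$mrs_at_3mo)), 1, tolerance = 1e-12)
  expect_false(b$strategies$standard$includes_drug_cost)
  expect_true(b$strategies$alteplase$includes_drug_cost)
})

test_that("type validation rejects invariant violations", {
  # simplex violations beyond 1e-3 are rejected, smaller ones renormalized
  expect_error(mrs_distribution(c(0.9, 0, 0, 0, 0, 0, 0)), "sum")
  renorm <- mrs_distribution(c(0.4005, 0.3, 0.1, 0.1, 0.05, 0.03, 0.02))
  expect_equal(sum(renorm), 1, tolerance = 1e-12)
  expect_error(mrs_distribution(c(-0.1, 0.4, 0.2, 0.2, 0.1, 0.1, 0.1)), "\\[0, 1\\]")

  expect_error(param_range(2, 1), "low")
  expect_error(utility_set(c(0.9, 0.95, 0.6, 0.4, 0.2, 0.1, 0), 0.4, 0.3),
               "non-increasing")
  expect_error(utility_set(c(0.9, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05), 0.4, 0.3),
               "dead")
  expect_error(cost_set(rep(-1, 7), 1, 1, 1, 1, 1700, 3400), "non-negative")
  expect_error(cost_set(rep(1, 7), 1, 1, 1, 1, 1700, 3400,
                        alteplase_base_case = 3000), "mean")
  expect_error(life_table(c(60, 65), c(0.02, 0.01)), "increasing")
  expect_error(mortality_model(c(2, 1, 1, 1, 1, 1)), "non-decreasing")
  expect_error(recurrence_model(c(0.05, 0.02, rep(0.06, 4)), 0.2), "non-decreasing")
  expect_error(discount_spec(0.1), "0.08")
  expect_error(strategy_params("x", rep(1/7, 7), 1.5, FALSE), "probability")
  expect_error(model_config(horizon = 30, cycle_length = 0.26), "multiple")
})

test_that("random corruptions of a valid bundle fail schema validation", {
  base <- yaml::read_yaml(default_model_path())
  corruptions <- list(
    function(r) { r$strategies[[1]]$mrs_at_3mo$value[1] <- 0.9; r },     # sum >> 1
    function(r) { r$utilities$u_mrs$value[7] <- 0.2; r },                # dead utility
    function(r) { r$utilities$u_mrs$value <- rev(r$utilities$u_mrs$value); r },
    function(r) { r$costs$sich_event$value <- -5; r },
    function(r) { r$mortality$hr_by_mrs$value <- c(3, 1, 1, 1, 1, 1); r },
    function(r) { r$life_table$bands[[2]]$annual_mortality <- 0.001; r },
    function(r) { r$discount$annual_rate$value <- 0.5; r },
    function(r) { r$strategies[[2]]$sich_incidence$value <- 1.2; r },
    function(r) { r$costs$alteplase_base_case$value <- 9999; r },
    function(r) { r$utilities <- NULL; r }
  )
  for (i in seq_along(corruptions)) {
    bad <- corruptions[[i]](base)
    tmp <- withr::local_tempfile(fileext = ".yaml")
    writeLines(yaml::as.yaml(bad, precision = 17), tmp)
    expect_error(load_model_spec(tmp), info = paste("corruption", i))
  }
})

test_that("model-spec files round-trip exactly", {
  b <- load_model_spec(default_model_path())
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(b, tmp)
  b2 <- load_model_spec(tmp)

  for (si in 1:2) {
    expect_identical(as.numeric(b2$strategies[[si]]$mrs_at_3mo),
                     as.numeric(b$strategies[[si]]$mrs_at_3mo))
    expect_identical(b2$strategies[[si]]$sich_incidence,
                     b$strategies[[si]]$sich_incidence)
    expect_identical(b2$strategies[[si]]$mrs_range, b$strategies[[si]]$mrs_range)
  }
  expect_identical(b2$utilities, b$utilities)
  expect_identical(b2$costs, b$costs)
  expect_identical(b2$life_table$annual_mortality, b$life_table$annual_mortality)
  expect_identical(b2$mortality$hr_by_mrs, b$mortality$hr_by_mrs)
  expect_identical(b2$recurrence, b$recurrence)
  expect_identical(b2$discount$annual_rate, b$discount$annual_rate)
  expect_identical(b2$thresholds, b$thresholds)
  # provenance tags survive the round trip
  expect_match(b2$provenance$costs, "ASSUMED")
  expect_match(b2$provenance$life_table, "PAPER")
})

test_that("beta fits match their mean and Monte-Carlo draws agree", {
  s <- beta_from_mean_ci(0.0172, param_range(0, 0.0257))
  expect_equal(s$alpha / (s$alpha + s$beta), 0.0172, tolerance = 1e-6)

  set.seed(11)
  x <- draw_sampler(s, 1e5)
  expect_lt(abs(mean(x) - 0.0172), 3 * sd(x) / sqrt(length(x)))
  expect_true(all(x >= 0 & x <= 1))

  # zero-width interval degrades to a fixed-value sampler
  fixed <- beta_from_mean_ci(0.5, param_range(0.5, 0.5))
  expect_identical(fixed$family, "fixed")
  expect_identical(draw_sampler(fixed, 5), rep(0.5, 5))
  expect_error(beta_from_mean_ci(1.5, param_range(0.1, 0.2)), "mean")
})

test_that("gamma fits match their mean and Monte-Carlo draws agree", {
  s <- gamma_from_mean_range(2550, param_range(1700, 3400))
  expect_equal(s$shape * s$scale, 2550, tolerance = 1e-6)
  # SD set from the range width as (high - low) / 3.92
  expect_equal(sqrt(s$shape) * s$scale, (3400 - 1700) / 3.92, tolerance = 1e-6)

  set.seed(12)
  x <- draw_sampler(s, 1e5)
  expect_lt(abs(mean(x) - 2550), 3 * sd(x) / sqrt(length(x)))
  expect_true(all(x > 0))

  expect_identical(gamma_from_mean_range(300, param_range(300, 300))$family, "fixed")
  expect_error(gamma_from_mean_range(-10, param_range(1, 2)), "positive")
})

test_that("dirichlet sampler preserves the simplex and its mean", {
  p <- c(0.3913, 0.3478, 0.1565, 0.0261, 0.0174, 0.0087, 0.0522)
  s <- dirichlet_from_distribution(p, 115)
  expect_equal(s$alpha / sum(s$alpha), p, tolerance = 1e-4)

  set.seed(13)
  x <- draw_sampler(s, 1e5)
  expect_equal(rowSums(x), rep(1, nrow(x)), tolerance = 1e-12)
  for (j in 1:7) {
    expect_lt(abs(mean(x[, j]) - p[j]), 3 * sd(x[, j]) / sqrt(nrow(x)))
  }

  # a degenerate distribution concentrates all mass on its support
  s0 <- dirichlet_from_distribution(c(1, 0, 0, 0, 0, 0, 0), 50)
  x0 <- draw_sampler(s0, 1000)
  expect_gt(mean(x0[, 1]), 0.999)
  expect_error(dirichlet_from_distribution(p, 0), "positive")
})
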