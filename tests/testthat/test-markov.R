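test_that("annual-to-cycle probability conversion matches the closed form", {
  expect_identical(annual_prob_to_cycle(0, 0.25, 1), 0)
  expect_identical(annual_prob_to_cycle(1, 0.25, 2), 1)
  expect_equal(annual_prob_to_cycle(0.00760, 0.25, 1), 0.001905439, tolerance = 1e-6)
  expect_equal(annual_prob_to_cycle(0.00760, 0.25, 2.37), 0.004509998, tolerance = 1e-6)

  # vectorizes over the hazard ratio
  hr <- c(1, 1, 1.11, 1.27, 1.71, 2.37)
  expect_length(annual_prob_to_cycle(0.0076, 0.25, hr), 6L)

  # doubling the HR exactly doubles the cycle rate (hazard scale)
  p1 <- annual_prob_to_cycle(0.1, 0.25, 1.3)
  p2 <- annual_prob_to_cycle(0.1, 0.25, 2.6)
  expect_equal(-log(1 - p2), 2 * -log(1 - p1), tolerance = 1e-12)
})

test_that("mortality lookup uses 5-year bands with clamped extremes", {
  b <- default_model_spec()
  expect_equal(mortality_for(64, 0, b$life_table, b$mortality),
               0.001905439, tolerance = 1e-6)
  # beyond the last band: the 85+ rate applies for the rest of the horizon
  expect_equal(mortality_for(93, 3, b$life_table, b$mortality),
               annual_prob_to_cycle(0.15120, 0.25, 1.27))
  # below the first band: clamped to the first band
  expect_equal(mortality_for(50, 0, b$life_table, b$mortality),
               mortality_for(60, 0, b$life_table, b$mortality))
})

test_that("one cycle transition reproduces the hand-computed event flows", {
  b <- default_model_spec()
  # calibrate the inputs so the per-cycle probabilities are exactly
  # d = 0.01 and r = 0.02 (invert the rate conversion), cf 0.21, p_stay 0.5
  b$life_table$annual_mortality <- rep(1 - (1 - 0.01)^4, nrow(b$life_table))
  b$mortality$hr_by_mrs <- rep(1, 6)
  b$mortality$post_stroke_excess_hr <- 1
  b$recurrence$annual_recurrence_by_mrs <- rep(1 - (1 - 0.02)^4, 6)
  b$recurrence$case_fatality <- 0.21
  b$recurrence$p_stay_given_survive <- 0.5

  occ <- c(0, 0, 0, 1, 0, 0, 0)                     # whole cohort at mRS 3
  step <- build_cycle_transition(occ, 70, b)
  expect_equal(step$occupancy[7], 0.01 + 0.99 * 0.02 * 0.21, tolerance = 1e-9)
  expect_equal(step$occupancy[5], 0.99 * 0.02 * 0.79 * 0.5, tolerance = 1e-9)
  expect_equal(sum(step$occupancy), 1, tolerance = 1e-12)
  expect_equal(step$recurrence_total, 0.99 * 0.02, tolerance = 1e-9)

  # identity transition when nothing can happen
  b0 <- b
  b0$life_table$annual_mortality <- rep(0, nrow(b0$life_table))
  b0$recurrence$annual_recurrence_by_mrs <- rep(0, 6)
  occ_any <- c(0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1)
  expect_equal(build_cycle_transition(occ_any, 70, b0)$occupancy, occ_any)

  # full case fatality sends all recurrence mass to Dead
  b1 <- b
  b1$recurrence$case_fatality <- 1
  step1 <- build_cycle_transition(occ, 70, b1)
  expect_equal(step1$occupancy[7], 0.01 + 0.99 * 0.02, tolerance = 1e-9)
  expect_equal(sum(step1$recurrence_survivor_flow), 0)
})

test_that("occupancy is conserved and the Dead state is absorbing", {
  for (seed in 1:20) {
    b <- random_bundle(seed)
    res <- run_strategy(b, sample(1:2, 1))
    occ <- as.matrix(res$trace[, c(paste0("mrs", 0:5), "dead")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(occ[, "dead"]) > -1e-12))
  }
})

test_that("a cohort that cannot die accrues exactly the 30-year horizon", {
  b <- deterministic_bundle()
  res <- run_strategy(b, 1L)
  expect_equal(res$total_ly, 30, tolerance = 1e-9)
  expect_equal(res$total_qaly, res$total_ly)       # all utilities are 1
  expect_identical(nrow(res$trace), 120L)          # tree quarter + 119 cycles
})

test_that("totals are monotone in the discount rate", {
  b <- default_model_spec()
  r0 <- run_strategy(b, 2L, discount_rate = 0)
  r5 <- run_strategy(b, 2L, discount_rate = 0.05)
  r8 <- run_strategy(b, 2L, discount_rate = 0.08)
  expect_gt(r0$total_qaly, r5$total_qaly)
  expect_gt(r5$total_qaly, r8$total_qaly)
  expect_gt(r0$total_cost, r5$total_cost)
  expect_gt(r0$total_ly, r5$total_ly)
})

test_that("improving the initial distribution never decreases total QALYs", {
  for (seed in 1:5) {
    b <- random_bundle(seed)
    p <- as.numeric(b$strategies[[2]]$mrs_at_3mo)
    better <- p
    eps <- 0.5 * p[4]
    better[4] <- better[4] - eps; better[1] <- better[1] + eps
    b2 <- b
    b2$strategies[[2]]$mrs_at_3mo <- mrs_distribution(better)
    expect_gte(run_strategy(b2, 2L)$total_qaly, run_strategy(b, 2L)$total_qaly)
  }
})

test_that("microsimulation is deterministic and matches the cohort when event-free", {
  b <- deterministic_bundle()
  ms <- microsimulate(b, 1L, 1, seed = 99)
  co <- run_strategy(b, 1L)
  expect_equal(ms$total_qaly, co$total_qaly, tolerance = 1e-12)
  expect_equal(ms$total_cost, co$total_cost, tolerance = 1e-12)
  expect_equal(ms$total_ly, co$total_ly, tolerance = 1e-12)

  b2 <- default_model_spec()
  a <- microsimulate(b2, 2L, 500, seed = 7)
  bb <- microsimulate(b2, 2L, 500, seed = 7)
  expect_identical(a, bb)
})

test_that("microsimulation means converge to the cohort totals", {
  b <- default_model_spec()
  co <- run_strategy(b, 2L)
  ms <- microsimulate(b, 2L, 50000, seed = 21)
  expect_lt(abs(ms$total_cost - co$total_cost), 3 * ms$se$cost)
  expect_lt(abs(ms$total_qaly - co$total_qaly), 3 * ms$se$qaly)
  expect_lt(abs(ms$total_ly - co$total_ly), 3 * ms$se$ly)
})
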