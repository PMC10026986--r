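test_that("integrate-and-fire reduces to the constant-rate closed form", {
  rr <- synthesize_rr_integrate_and_fire(0, 1.0, 10)
  expect_equal(rr$intervals, rep(1, 10), tolerance = 1e-9)
  rr2 <- synthesize_rr_integrate_and_fire(0.25, 1.0, 10)
  expect_equal(rr2$intervals, rep(0.8, length(rr2$intervals)),
               tolerance = 1e-9)
})

test_that("beat count tracks the integrated rate for sinusoidal input", {
  m <- function(t) 0.2 * sin(2 * pi * 0.1 * t)
  rr <- synthesize_rr_integrate_and_fire(m, 1.1, 300)
  expected <- integrate(function(t) 1.1 + m(t), 0, 300)$value
  n_beats <- length(rr$intervals)        # beats after the one at t = 0
  expect_lte(abs(n_beats - expected), 1)
})

test_that("non-positive instantaneous rate names the offending time", {
  expect_error(
    synthesize_rr_integrate_and_fire(function(t) -2 * (t > 5), 1.0, 10),
    "non-positive at t = 5")
})

test_that("degenerate coefficient generator emits constant intervals", {
  b <- laguerre_basis(0.2, 8, 500)
  rr <- synthesize_rr_from_coeffs(list(g0 = 0.8, g1 = rep(0, 9)), b,
                                  init_intervals = rep(0.8, 5),
                                  obs_noise_sd = 0, n_beats = 20)
  expect_equal(rr$intervals, rep(0.8, 25), tolerance = 1e-12)
})

test_that("generated intervals exactly satisfy the generating model", {
  b <- laguerre_basis(0.2, 8, 500)
  fx <- make_recovery_series(b, n_beats = 120, seed = 1,
                             obs_noise_sd = 0)
  reg <- convolve_rr(fx$rr, b)
  x <- fx$rr$intervals
  for (i in c(1, 40, 120)) {
    k <- fx$n_init + i - 1
    expect_equal(x[fx$n_init + i],
                 fx$g0 + sum(fx$g1 * reg$values[k, ]),
                 tolerance = 1e-10)
  }
})

test_that("coefficient generator is deterministic under a fixed seed", {
  b <- laguerre_basis(0.2, 8, 500)
  r1 <- make_recovery_series(b, n_beats = 100, seed = 5)
  r2 <- make_recovery_series(b, n_beats = 100, seed = 5)
  expect_identical(r1$rr$intervals, r2$rr$intervals)
})

test_that("infeasible coefficient configurations raise an error", {
  b <- laguerre_basis(0.2, 8, 500)
  expect_error(
    synthesize_rr_from_coeffs(list(g0 = -1, g1 = rep(0, 9)), b,
                              init_intervals = rep(0.8, 5),
                              n_beats = 10),
    "non-positive")
})

test_that("adaptive Markov band-power generator honours its closed forms", {
  grid <- 0:49
  # kappa = 1, no drive, no noise: a frozen random walk stays put
  bp <- synthesize_bandpower(1, 0, 0, grid, init = 5)
  expect_equal(bp$power[, 1, 1], rep(5, 50))
  # kappa = 0, no drive: collapses after the first step, then floored
  expect_message(
    bp0 <- synthesize_bandpower(0, 0, 0, grid, init = 5,
                                floor_eps = 1e-6),
    "floored 49")
  expect_equal(bp0$power[1, 1, 1], 5)
  expect_equal(bp0$power[-1, 1, 1], rep(1e-6, 49))
  expect_equal(attr(bp0, "n_floored"), 49L)
})

test_that("band-power generator validates its inputs", {
  expect_error(synthesize_bandpower(1.2, 0, 0, 0:9), "kappa")
  expect_error(synthesize_bandpower(0.5, 0, 0, c(0, 1, 3)), "uniform")
})

test_that("protocol dataset has the full study geometry", {
  cfg <- synthetic_config(n_subjects = 2, seed = 3)
  expect_equal(cfg$n_subjects, 2L)
  expect_equal(nrow(cfg$condition_plan), 4L)
  expect_equal(cfg$condition_plan$duration, c(60, 300, 300, 300))
  expect_length(cfg$channels, 9)
  expect_length(cfg$bands, 5)

  ds <- generate_protocol_dataset(small_protocol_config(seed = 3))
  expect_length(ds$subjects, 2)
  sub <- ds$subjects[[1]]
  expect_named(sub$conditions,
               c("rest", "stress1", "stress2", "stress3"))
  for (cc in sub$conditions) {
    # every beat lies inside its condition window
    expect_true(all(cc$rr$beat_times >= cc$onset - 1e-9))
    expect_true(all(cc$rr$beat_times <= cc$onset + cc$duration + 1e-9))
    # ground truth retained for every planted parameter
    expect_true(all(c("c_sai", "c_pai", "kappa", "g_s", "g_p") %in%
                    names(cc$truth)))
  }
})

test_that("datasets are reproducible and stable under added subjects", {
  d1 <- generate_protocol_dataset(small_protocol_config(seed = 11))
  d2 <- generate_protocol_dataset(small_protocol_config(seed = 11))
  expect_identical(d1$subjects[[1]]$conditions$rest$rr$intervals,
                   d2$subjects[[1]]$conditions$rest$rr$intervals)
  expect_identical(d1$subjects[[2]]$conditions$stress3$bandpower$power,
                   d2$subjects[[2]]$conditions$stress3$bandpower$power)
  # adding a subject must not perturb existing ones
  d3 <- generate_protocol_dataset(small_protocol_config(n_subjects = 3,
                                                        seed = 11))
  expect_identical(d1$subjects[[2]]$conditions$stress1$rr$intervals,
                   d3$subjects[[2]]$conditions$stress1$rr$intervals)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(baseline_rate_hz = 0.4), "baseline_rate")
  expect_error(synthetic_config(condition_plan = data.frame(
    label = c("a", "a"), duration = c(10, 10))), "unique")
  expect_error(synthetic_config(condition_plan = data.frame(
    label = c("a", "b"), duration = c(10, -1))), "positive")
})

test_that("surrogate stress reports follow the configured profile", {
  cfg <- synthetic_config(n_subjects = 37, seed = 2)
  rep1 <- surrogate_stress_reports(cfg)
  expect_equal(dim(rep1), c(37L, 3L))
  expect_true(all(rep1 >= 1 & rep1 <= 7))
  expect_equal(unname(apply(rep1, 2, median)), c(1, 4, 5))
  expect_equal(unname(apply(rep1, 2, mad, constant = 1)), c(0, 1, 1))
  # zero dispersion: everyone reports the median
  rep0 <- surrogate_stress_reports(cfg, dispersion = 0)
  expect_true(all(rep0[, 1] == 1 & rep0[, 2] == 4 & rep0[, 3] == 5))
  # fixed seed reproduces
  expect_identical(surrogate_stress_reports(cfg),
                   surrogate_stress_reports(cfg))
})
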