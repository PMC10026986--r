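# deterministic zero-mean autonomic fluctuation series for fit tests
osc_autonomic <- function(n, grid = seq_len(n) - 1) {
  structure(list(beat_times = grid,
                 sai = 3 * sin(2 * pi * 0.10 * grid),
                 pai = 2 * sin(2 * pi * 0.18 * grid + 1)),
            class = "autonomic_series")
}

test_that("constant RR yields zero modulation and the right baseline", {
  rr <- rr_series(seq(0, 80, by = 0.8))
  m <- estimate_modulation(rr, 1:79)
  expect_equal(m$baseline, rep(1.25, 79), tolerance = 1e-12)
  expect_equal(m$m, rep(0, 79), tolerance = 1e-12)
})

test_that("modulation estimation requires grid coverage", {
  rr <- rr_series(seq(0, 40, by = 0.8))
  expect_error(estimate_modulation(rr, 0:60), "coverage")
})

test_that("a planted sinusoidal modulation is recovered from beats", {
  m_fun <- function(t) 0.2 * sin(2 * pi * 0.1 * t)
  rr <- synthesize_rr_integrate_and_fire(m_fun, 1.1, 300)
  grid <- 1:298
  mh <- estimate_modulation(rr, grid)
  expect_gt(cor(mh$m, m_fun(grid)), 0.95)
})

test_that("noiseless control coefficients are identified exactly", {
  n <- 120
  aut <- osc_autonomic(n)
  m <- list(grid = aut$beat_times, m = 2 * aut$sai + 0 * aut$pai)
  fit <- fit_brain_to_heart(m, aut)
  expect_true(any(fit$valid))
  expect_lt(max(abs(fit$c_sai[fit$valid] - 2)), 1e-8)
  expect_lt(max(abs(fit$c_pai[fit$valid])), 1e-8)
})

test_that("collinear windows are masked, not fatal", {
  n <- 60
  grid <- seq_len(n) - 1
  s <- sin(2 * pi * 0.1 * grid)
  aut <- structure(list(beat_times = grid, sai = s, pai = 2 * s),
                   class = "autonomic_series")
  m <- list(grid = grid, m = s)
  expect_message(fit <- fit_brain_to_heart(m, aut), "masked invalid")
  expect_false(any(fit$valid))
})

test_that("windowed estimates are unbiased under additive noise", {
  n <- 400
  aut <- osc_autonomic(n)
  truth_s <- 1.5; truth_p <- -0.8
  m0 <- truth_s * aut$sai + truth_p * aut$pai
  set.seed(21)
  reps <- sapply(1:20, function(i) {
    m <- list(grid = aut$beat_times,
              m = m0 + rnorm(n, sd = 0.1 * sd(m0)))
    fit <- fit_brain_to_heart(m, aut)
    c(mean(fit$c_sai[fit$valid]), mean(fit$c_pai[fit$valid]))
  })
  expect_lt(abs(mean(reps[1, ]) - truth_s) / abs(truth_s), 0.05)
  expect_lt(abs(mean(reps[2, ]) - truth_p) / abs(truth_p), 0.05)
})

test_that("brain-to-heart ratio lags its denominator by one step", {
  n <- 60
  aut <- osc_autonomic(n)
  m <- list(grid = aut$beat_times, m = 0.5 * aut$sai)
  fit <- fit_brain_to_heart(m, aut)
  pw <- array(1, dim = c(n, 1, 1))
  bp1 <- band_power_series(aut$beat_times, pw, "Cz", "alpha")
  cs <- brain_to_heart_coupling(fit, bp1, "alpha", "Cz", "SAI")
  # unit denominator: sdg equals the coefficient series
  expect_equal(cs$sdg[cs$valid], fit$c_sai[cs$valid])
  # random denominators: independent elementwise division oracle
  set.seed(8)
  pw2 <- array(runif(n, 0.5, 2), dim = c(n, 1, 1))
  bp2 <- band_power_series(aut$beat_times, pw2, "Cz", "alpha")
  cs2 <- brain_to_heart_coupling(fit, bp2, "alpha", "Cz", "SAI")
  idx <- which(cs2$valid)
  expect_equal(cs2$sdg[idx], fit$c_sai[idx] / pw2[idx - 1, 1, 1],
               tolerance = 1e-12)
  # zero coefficients give zero coupling
  fit0 <- fit
  fit0$c_sai[] <- 0
  cs0 <- brain_to_heart_coupling(fit0, bp2, "alpha", "Cz", "SAI")
  expect_true(all(cs0$sdg[cs0$valid] == 0))
})

test_that("grid mismatch between fit and band power is rejected", {
  n <- 60
  aut <- osc_autonomic(n)
  fit <- fit_brain_to_heart(list(grid = aut$beat_times,
                                 m = 0.5 * aut$sai), aut)
  bp <- band_power_series(aut$beat_times + 0.5,
                          array(1, dim = c(n, 1, 1)), "Cz", "alpha")
  expect_error(brain_to_heart_coupling(fit, bp, "alpha", "Cz"),
               "grids do not match")
})

test_that("kappa is recovered from zero-mean AR(1) fluctuations", {
  errs <- sapply(1:10, function(s) {
    set.seed(40 + s)
    n <- 300
    y <- as.numeric(arima.sim(list(ar = 0.7), n, sd = 0.05))
    fit <- fit_heart_to_brain(list(grid = seq_len(n) - 1, values = y),
                              window_s = n - 1)
    abs(median(fit$kappa[fit$kappa_valid]) - 0.7)
  })
  expect_lte(median(errs), 0.05)
})

test_that("residual identity reconstructs a constant power series", {
  n <- 80
  bp <- band_power_series(seq_len(n) - 1, array(4, dim = c(n, 1, 1)),
                          "Cz", "alpha")
  fit <- fit_heart_to_brain(bp, "alpha", "Cz")
  kap <- fit$kappa[fit$kappa_valid][1]
  # kappa_hat * P + psi reproduces P exactly
  expect_equal(kap * 4 + fit$psi, rep(4, n - 1), tolerance = 1e-9)
})

test_that("planted heart drive is recovered from generated band power", {
  # the drive is identified on the fluctuation scale (the operating
  # mean of raw power is absorbed into the slope; methods vignette)
  set.seed(33)
  n <- 400
  grid <- seq_len(n) - 1
  sai_fl <- 2 * sin(2 * pi * 0.1 * grid) + rnorm(n, sd = 0.3)
  drive <- 5 * (1 - 0.7) + 0.3 * sai_fl
  bp <- synthesize_bandpower(0.7, drive, noise_sd = 0.01, grid,
                             init = 5)
  y <- as.numeric(bp$power[, 1, 1])
  fit <- fit_heart_to_brain(list(grid = grid, values = y - mean(y)),
                            window_s = 60)
  # psi(t) pairs with drive(t) by construction of the lag convention
  planted <- 0.3 * sai_fl[-n]
  expect_gt(cor(fit$psi, planted), 0.9)
  # constant-gain readout within 10%
  gain <- sum(fit$psi * sai_fl[-n]) / sum(sai_fl[-n]^2)
  expect_lt(abs(gain - 0.3) / 0.3, 0.10)
})

test_that("constant-zero power windows are masked invalid", {
  n <- 60
  y <- rep(0, n)
  expect_message(
    fit <- fit_heart_to_brain(list(grid = seq_len(n) - 1, values = y)),
    "masked invalid")
  expect_false(any(fit$kappa_valid))
})

test_that("heart-to-brain ratio follows its construction", {
  n <- 100
  grid <- seq_len(n) - 1
  aut <- structure(list(beat_times = grid, sai = 5 + sin(0.2 * grid),
                        pai = 4 + cos(0.2 * grid)),
                   class = "autonomic_series")
  # X identically 1: sdg equals psi
  aut1 <- structure(list(beat_times = grid, sai = rep(1, n),
                         pai = rep(1, n)), class = "autonomic_series")
  psi <- rnorm(n - 1)
  fit <- list(psi = psi, psi_grid = grid[-n], band = "alpha",
              channel = "Cz")
  cs <- heart_to_brain_coupling(fit, aut1, "SAI")
  expect_equal(cs$sdg[cs$valid], psi[cs$valid])
  # psi = 0 gives sdg = 0
  fit0 <- list(psi = rep(0, n - 1), psi_grid = grid[-n],
               band = "alpha", channel = "Cz")
  cs0 <- heart_to_brain_coupling(fit0, aut, "SAI")
  expect_true(all(cs0$sdg[cs0$valid] == 0))
  # planted psi = 0.3 * X: ratio is exactly 0.3 everywhere valid
  x <- aut$sai[-n]
  fit3 <- list(psi = 0.3 * x, psi_grid = grid[-n], band = "alpha",
               channel = "Cz")
  cs3 <- heart_to_brain_coupling(fit3, aut, "SAI")
  expect_true(all(abs(cs3$sdg[cs3$valid] - 0.3) < 1e-12))
})

test_that("near-zero denominators are masked, never clipped", {
  n <- 60
  grid <- seq_len(n) - 1
  x <- c(rep(2, 30), rep(0, 5), rep(2, 25))
  aut <- structure(list(beat_times = grid, sai = x, pai = x),
                   class = "autonomic_series")
  fit <- list(psi = rep(1, n - 1), psi_grid = grid[-n],
              band = "alpha", channel = "Cz")
  cs <- heart_to_brain_coupling(fit, aut, "SAI")
  expect_false(any(cs$valid[31:35]))
  expect_true(all(is.na(cs$sdg[31:35])))
})

test_that("masked points never propagate into condensations", {
  n <- 200
  grid <- seq_len(n) - 1
  vals <- rnorm(n)
  valid <- rep(TRUE, n)
  vals[50:60] <- 1e9
  valid[50:60] <- FALSE
  win <- data.frame(label = "all", onset = 0, duration = n)
  cd <- condense_markers(vals, grid, win, valid = valid,
                         normalize = FALSE)
  cd_ref <- condense_markers(vals[-(50:60)], grid[-(50:60)], win,
                             normalize = FALSE)
  expect_equal(cd$median, cd_ref$median)
  expect_equal(cd$mad, cd_ref$mad)
  expect_equal(cd$n_valid, n - 11L)
})

test_that("zero heart drive stays within the permutation noise floor", {
  set.seed(55)
  n <- 300
  grid <- seq_len(n) - 1
  bp <- synthesize_bandpower(0.7, 3 * (1 - 0.7), noise_sd = 0.2, grid,
                             init = 3)
  fit <- fit_heart_to_brain(bp, "alpha", "Cz")
  aut <- structure(list(beat_times = grid,
                        sai = 40 + 5 * sin(2 * pi * 0.1 * grid),
                        pai = 55 + 7 * sin(2 * pi * 0.18 * grid)),
                   class = "autonomic_series")
  cs <- heart_to_brain_coupling(fit, aut, "SAI")
  observed <- mad(cs$sdg[cs$valid], constant = 1)
  nulls <- sapply(1:100, function(i) {
    sh <- sample(n - 1)
    aut_p <- aut
    aut_p$sai <- aut$sai[c(sh, n)]
    csp <- heart_to_brain_coupling(fit, aut_p, "SAI")
    mad(csp$sdg[csp$valid], constant = 1)
  })
  expect_lte(observed, quantile(nulls, 0.95))
})

test_that("planted couplings are recovered from a protocol dataset", {
  ds <- generate_protocol_dataset(small_protocol_config(
    n_subjects = 2, seed = 42, channels = "Cz", bands = "alpha"))
  for (sub in ds$subjects) {
    cs_est <- cs_tr <- cp_est <- cp_tr <- mcor <- c()
    for (cc in sub$conditions) {
      tr <- cc$truth
      g2 <- tr$grid[tr$grid <= max(cc$rr$beat_times)]
      idx <- seq_along(g2)
      mh <- estimate_modulation(cc$rr, g2)
      mcor <- c(mcor, cor(mh$m, tr$m[idx]))
      aut <- structure(list(beat_times = tr$grid, sai = tr$sai_fl,
                            pai = tr$pai_fl),
                       class = "autonomic_series")
      fit <- suppressMessages(fit_brain_to_heart(mh, aut))
      ok <- fit$valid
      cs_est <- c(cs_est, fit$c_sai[ok])
      cs_tr <- c(cs_tr, tr$c_sai[idx][ok])
      cp_est <- c(cp_est, fit$c_pai[ok])
      cp_tr <- c(cp_tr, tr$c_pai[idx][ok])
    }
    expect_gt(mean(mcor), 0.95)
    expect_gt(cor(cs_est, cs_tr), 0.8)
    expect_gt(cor(cp_est, cp_tr), 0.8)
  }
})
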