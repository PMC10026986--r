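#' Integrate-and-fire heartbeat generation
#'
#' Emits a beat whenever the running integral of the instantaneous rate
#' \eqn{\mu + m(t)} since the previous beat reaches 1 (unit threshold).
#' For constant modulation \eqn{m \equiv c} this makes the interbeat
#' interval exactly \eqn{1 / (\mu + c)}.  A beat is placed at time 0 and
#' crossing times are located by linear interpolation of the trapezoidal
#' cumulative integral on a fine grid.
#'
#' @param m Modulation of the heart rate about baseline, in Hz: either a
#'   function of time, a single number, or a list/data.frame with elements
#'   \code{t} and \code{m} (linearly interpolated).
#' @param baseline_rate_hz Baseline heart rate \eqn{\mu} in beats/s.
#' @param duration Length of the simulation in seconds.
#' @param dt Integration step in seconds (default 0.01).
#' @param start_time Time origin for the emitted beats (default 0).
#' @return An [rr_series()].
#' @examples
#' rr <- synthesize_rr_integrate_and_fire(0, 1.0, 10)
#' rr$intervals            # all exactly 1 s
#' @export
synthesize_rr_integrate_and_fire <- function(m, baseline_rate_hz, duration,
                                             dt = 0.01, start_time = 0) {
  if (!is.finite(baseline_rate_hz) || baseline_rate_hz <= 0)
    stop("baseline_rate_hz must be positive")
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive")
  tt <- seq(0, duration, by = dt)
  mv <- if (is.function(m)) {
    m(tt)
  } else if (is.numeric(m) && length(m) == 1L) {
    rep(m, length(tt))
  } else if (is.list(m) && all(c("t", "m") %in% names(m))) {
    stats::approx(m$t, m$m, xout = tt, rule = 2)$y
  } else stop("m must be a function, a scalar, or a list with t and m")
  rate <- baseline_rate_hz + mv
  bad <- which(rate <= 0)
  if (length(bad))
    stop("instantaneous rate non-positive at t = ", tt[bad[1]], " s")
  ci <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2 * dt))
  nb <- floor(ci[length(ci)])
  if (nb < 2L) stop("fewer than 2 beats over the requested duration")
  thr <- seq_len(nb)
  # first index with ci >= threshold (left-open so exact hits resolve)
  hi <- findInterval(thr, ci, left.open = TRUE) + 1L
  lo <- hi - 1L
  tb <- tt[lo] + (thr - ci[lo]) / (ci[hi] - ci[lo]) * dt
  rr_series(start_time + c(0, tb))
}

#' Generate an RR series forward from Laguerre coefficients
#'
#' Runs the time-varying autoregressive heartbeat model as a generator:
#' each new interval is
#' \eqn{RR(k) = g_0(k) + \sum_j g_{1,j}(k) L_j(k) + \epsilon_{RR}(k)},
#' where the Laguerre regressors \eqn{L_j(k)} are recomputed from the
#' already-generated past (same truncation rule as [convolve_rr()], so
#' re-estimating the model from the output is exactly self-consistent).
#'
#' @param coeffs List with \code{g0} (scalar or length-\code{n_beats}
#'   vector, seconds) and \code{g1} (length-\code{max_order + 1} vector or
#'   \code{n_beats x (max_order + 1)} matrix).
#' @param basis A [laguerre_basis()].
#' @param init_intervals Seed history of positive intervals in seconds.
#' @param obs_noise_sd Observation noise standard deviation in seconds.
#' @param n_beats Number of new intervals to generate.
#' @return An [rr_series()] containing the seed history followed by the
#'   generated intervals; beat times start at 0.
#' @export
synthesize_rr_from_coeffs <- function(coeffs, basis, init_intervals,
                                      obs_noise_sd = 0, n_beats = 100L) {
  stopifnot(inherits(basis, "laguerre_basis"))
  if (length(init_intervals) < 1L || any(init_intervals <= 0))
    stop("init_intervals must be a non-empty positive history")
  n_beats <- as.integer(n_beats)
  p <- basis$max_order + 1L
  g0 <- rep_len(as.numeric(coeffs$g0), n_beats)
  g1 <- coeffs$g1
  g1 <- if (is.matrix(g1)) {
    if (ncol(g1) != p) stop("g1 must have max_order + 1 columns")
    g1[rep_len(seq_len(nrow(g1)), n_beats), , drop = FALSE]
  } else {
    matrix(rep(as.numeric(g1), each = n_beats), nrow = n_beats)
  }
  phi <- basis$functions
  nl <- nrow(phi)
  hist <- as.numeric(init_intervals)
  eps <- if (obs_noise_sd > 0) stats::rnorm(n_beats, sd = obs_noise_sd)
         else numeric(n_beats)
  for (i in seq_len(n_beats)) {
    k <- length(hist)
    nmax <- min(k, nl)
    L <- crossprod(phi[seq_len(nmax), , drop = FALSE],
                   hist[k:(k - nmax + 1L)])
    val <- g0[i] + drop(g1[i, , drop = FALSE] %*% L) + eps[i]
    if (!is.finite(val) || val <= 0)
      stop("generated interval ", i, " is non-positive; ",
           "coefficient/noise configuration infeasible")
    hist <- c(hist, val)
  }
  rr_series(cumsum(c(0, hist)))
}

#' Generate a band-power series from the adaptive Markov model
#'
#' Runs \eqn{EEG_F(t) = \kappa_F EEG_F(t-1) + \Psi_F(t-1) + \epsilon_F(t)}
#' forward on a uniform 1-s grid.  Generated values below
#' \code{floor_eps} are floored there (power must stay positive); the
#' number of floored points is recorded in attribute \code{n_floored} and
#' reported via a message.
#'
#' @param kappa Autoregressive constant, \eqn{|\kappa| \le 1}.
#' @param heart_drive Numeric drive sequence \eqn{\Psi_F(t)} aligned with
#'   \code{grid} (its value at \code{grid[i]} feeds the transition into
#'   \code{grid[i + 1]}).
#' @param noise_sd Innovation standard deviation (microvolt^2 scale).
#' @param grid Uniform 1-s time stamps.
#' @param init Starting power value at \code{grid[1]}.
#' @param floor_eps Positive flooring epsilon (default 1e-6).
#' @param channel,band Labels for the returned series.
#' @return A [band_power_series()] with one channel and one band, with
#'   attribute \code{n_floored}.
#' @export
synthesize_bandpower <- function(kappa, heart_drive, noise_sd, grid,
                                 init = 1, floor_eps = 1e-6,
                                 channel = "Cz", band = "alpha") {
  if (abs(kappa) > 1)
    stop("|kappa| must be <= 1 for stationarity of the undriven part")
  if (length(grid) > 1L && any(abs(diff(grid) - 1) > 1e-9))
    stop("grid must be uniform with a 1-s step")
  n <- length(grid)
  drive <- rep_len(as.numeric(heart_drive), n)
  x <- numeric(n)
  x[1] <- init
  eps <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  for (i in seq_len(n - 1L))
    x[i + 1L] <- kappa * x[i] + drive[i] + eps[i + 1L]
  nfl <- sum(x < floor_eps)
  if (nfl > 0) {
    x[x < floor_eps] <- floor_eps
    message("synthesize_bandpower: floored ", nfl,
            " non-positive power values at ", floor_eps)
  }
  out <- band_power_series(grid, array(x, dim = c(n, 1L, 1L)),
                           channels = channel, bands = band)
  attr(out, "n_floored") <- nfl
  out
}

#' Configuration for the protocol simulator
#'
#' Describes the simulated study: number of subjects, the ordered
#' condition plan (1-min rest followed by three ~5-min graded stressors),
#' montage and bands, baseline heart rate, and the planted coupling
#' structure.  Condition effects are planted on the \emph{variances} of
#' the coupling trajectories, not their means: stressors widen the
#' moment-to-moment excursions of the brain-to-heart control coefficients
#' and of the heart-to-brain drive gains, mirroring variability (not
#' median) being the discriminative quantity.
#'
#' @param n_subjects Number of simulated subjects (default 37).
#' @param condition_plan Data frame with columns \code{label} and
#'   \code{duration} (s), in protocol order.
#' @param channels,bands Montage and band labels.
#' @param baseline_rate_hz Baseline heart rate in beats/s (default 1.1;
#'   must lie in (0.5, 3)).
#' @param coupling_means Named list: \code{c_sai}, \code{c_pai}
#'   (brain-to-heart control coefficient means, Hz per a.u.) and
#'   \code{drive_sai}, \code{drive_pai} (heart-to-brain gain means).
#' @param coupling_variances Named list, one entry per condition label,
#'   each a list with \code{c} (variance of the control-coefficient
#'   fluctuation) and \code{drive} (variance of the drive-gain
#'   fluctuation).  Rest is smaller than the stressors by default.
#' @param band_gain Named multiplier per band for the heart-to-brain
#'   drive; bands with gain 0 carry no heart drive (null bands for
#'   false-positive checks).  Default plants the strongest drive in alpha
#'   and none in delta.
#' @param noise_sd Named list: \code{m} (Hz, jitter on the modulation
#'   entering the integrate-and-fire model) and \code{power}
#'   (microvolt^2, band-power innovation).
#' @param seed Integer master seed, expanded into per-subject per-stream
#'   child seeds.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    n_subjects = 37L,
    condition_plan = data.frame(
      label = c("rest", "stress1", "stress2", "stress3"),
      duration = c(60, 300, 300, 300)),
    channels = eeg_channels(),
    bands = names(eeg_bands()),
    baseline_rate_hz = 1.1,
    coupling_means = list(c_sai = 0.004, c_pai = -0.003,
                          drive_sai = 0.015, drive_pai = 0.01),
    coupling_variances = list(
      rest    = list(c = 2.5e-5, drive = 4e-6),
      stress1 = list(c = 1e-4,   drive = 2.25e-4),
      stress2 = list(c = 2.25e-4, drive = 6.25e-4),
      stress3 = list(c = 4e-4,   drive = 1.6e-3)),
    band_gain = c(delta = 0, theta = 0.6, alpha = 1, beta = 0.6,
                  gamma = 0.5),
    noise_sd = list(m = 0.01, power = 0.15),
    seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be positive")
  if (!all(c("label", "duration") %in% names(condition_plan)))
    stop("condition_plan needs label and duration columns")
  if (any(condition_plan$duration <= 0))
    stop("all condition durations must be positive")
  if (anyDuplicated(condition_plan$label))
    stop("condition labels must be unique")
  if (baseline_rate_hz <= 0.5 || baseline_rate_hz >= 3.0)
    stop("baseline_rate_hz must lie in (0.5, 3.0) beats/s")
  if (!all(condition_plan$label %in% names(coupling_variances)))
    stop("coupling_variances must name every condition")
  if (any(unlist(coupling_variances) < 0))
    stop("variances must be >= 0")
  if (!all(bands %in% names(band_gain)))
    stop("band_gain must name every band")
  structure(list(n_subjects = n_subjects, condition_plan = condition_plan,
                 channels = channels, bands = bands,
                 baseline_rate_hz = baseline_rate_hz,
                 coupling_means = coupling_means,
                 coupling_variances = coupling_variances,
                 band_gain = band_gain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic protocol config: ", x$n_subjects, " subjects, conditions ",
      paste0(x$condition_plan$label, " (", x$condition_plan$duration, " s)",
             collapse = ", "), "\n", sep = "")
  cat("  ", length(x$channels), " channels x ", length(x$bands),
      " bands, baseline rate ", x$baseline_rate_hz, " Hz, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# simulate one subject-condition; internal
simulate_condition <- function(config, subject, cond_idx) {
  cp <- config$condition_plan
  label <- cp$label[cond_idx]
  dur <- cp$duration[cond_idx]
  onset <- c(0, cumsum(cp$duration))[cond_idx]
  grid <- onset + seq(0, dur - 1)
  n <- length(grid)
  vars <- config$coupling_variances[[label]]
  mu <- config$baseline_rate_hz
  cm <- config$coupling_means

  set.seed(child_seed(config$seed, subject, cond_idx, 1L))
  # latent autonomic fluctuations: narrowband LF (~0.1 Hz, sympathetic)
  # and HF (~0.25 Hz, vagal) rhythms about positive operating levels;
  # the distinct bands keep SAI and PAI separable inside a 15-s window
  # and inside the pass-band of the sliding-baseline removal
  sai_z <- osc_path(n, 0.10)
  pai_z <- osc_path(n, 0.18)
  sai_lat <- 10 + 6 * sai_z
  pai_lat <- 14 + 8 * pai_z

  # brain-to-heart control coefficients: slow drift (~50 s correlation
  # time) with condition-dependent variance around a fixed mean
  sd_c <- sqrt(vars$c)
  c_sai <- cm$c_sai + sd_c * ar1_path(n, phi = 0.98)
  c_pai <- cm$c_pai + sd_c * ar1_path(n, phi = 0.98)
  # the modulation is driven by the autonomic fluctuations: the constant
  # operating levels of SAI / PAI belong to the baseline rate, so only
  # the zero-mean oscillatory parts enter m (keeping the planted
  # combination representable by the no-intercept windowed fit)
  sai_fl <- 6 * sai_z
  pai_fl <- 8 * pai_z
  m <- c_sai * sai_fl + c_pai * pai_fl
  if (config$noise_sd$m > 0)
    m <- m + stats::rnorm(n, sd = config$noise_sd$m)
  # feasibility guard: keep the instantaneous rate above 0.4 Hz so no
  # interval exceeds 2.5 s; scaling m and the stored coefficients
  # together preserves recoverability
  worst <- max(abs(m))
  cap <- mu - 0.4
  if (worst > cap) {
    s <- cap / worst
    m <- m * s; c_sai <- c_sai * s; c_pai <- c_pai * s
  }
  rr <- synthesize_rr_integrate_and_fire(list(t = grid - onset, m = m),
                                         mu, dur, start_time = onset)

  # heart-to-brain: adaptive Markov band power with planted drive
  set.seed(child_seed(config$seed, subject, cond_idx, 2L))
  nb <- length(config$bands)
  nch <- length(config$channels)
  chan_factor <- stats::runif(nch, 0.8, 1.2)
  kappa <- stats::runif(nb, 0.55, 0.8)
  names(kappa) <- config$bands
  base_power <- c(delta = 20, theta = 15, alpha = 12, beta = 8,
                  gamma = 5)[config$bands]
  base_power[is.na(base_power)] <- 10
  sd_d <- sqrt(vars$drive)
  g_s <- g_p <- matrix(0, n, nb, dimnames = list(NULL, config$bands))
  for (bi in seq_len(nb)) {
    bg <- config$band_gain[[config$bands[bi]]]
    if (bg > 0) {
      # gain variability is read out pointwise through the drive, so a
      # ~10-s correlation time gives each condition many effective draws
      g_s[, bi] <- bg * (cm$drive_sai + sd_d * ar1_path(n, phi = 0.9))
      g_p[, bi] <- bg * (cm$drive_pai + sd_d * ar1_path(n, phi = 0.9))
    }
  }
  pow <- array(0, dim = c(n, nch, nb))
  nfl <- 0L
  for (ci in seq_len(nch)) for (bi in seq_len(nb)) {
    # drive carries the planted gains applied to the a.u. autonomic
    # series; recentred so the band keeps its operating power level
    drive <- chan_factor[ci] *
      (g_s[, bi] * sai_lat + g_p[, bi] * pai_lat)
    drive <- drive - mean(drive) + base_power[bi] * (1 - kappa[bi])
    x <- numeric(n)
    x[1] <- base_power[bi]
    eps <- stats::rnorm(n, sd = config$noise_sd$power)
    for (i in seq_len(n - 1L))
      x[i + 1L] <- kappa[bi] * x[i] + drive[i] + eps[i + 1L]
    nfl <- nfl + sum(x < 1e-6)
    x[x < 1e-6] <- 1e-6
    pow[, ci, bi] <- x
  }
  bp <- band_power_series(grid, pow, config$channels, config$bands)

  list(label = label, onset = onset, duration = dur,
       rr = rr, bandpower = bp,
       truth = list(grid = grid, sai_lat = sai_lat, pai_lat = pai_lat,
                    sai_fl = sai_fl, pai_fl = pai_fl,
                    sai_z = sai_z, pai_z = pai_z,
                    c_sai = c_sai, c_pai = c_pai, m = m,
                    kappa = kappa, g_s = g_s, g_p = g_p,
                    chan_factor = chan_factor, n_floored = nfl))
}

#' Forward-simulate a protocol-structured dataset
#'
#' Generates, for every subject and condition, a coupled RR series
#' (integrate-and-fire driven by a modulation built from latent autonomic
#' fluctuations and planted control coefficients) and a full
#' channel-by-band power series (adaptive Markov model with planted
#' heart-drive gains), with condition-dependent coupling variance and all
#' ground-truth trajectories retained for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return Object of class \code{protocol_dataset}: list with
#'   \code{config}, \code{condition_plan} (with onsets), \code{subjects}
#'   (each a list of per-condition records with \code{rr},
#'   \code{bandpower}, \code{truth}) and \code{stress_reports}.
#' @export
generate_protocol_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cp <- config$condition_plan
  cp$onset <- c(0, cumsum(cp$duration))[seq_len(nrow(cp))]
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    conds <- lapply(seq_len(nrow(cp)), function(ci)
      simulate_condition(config, s, ci))
    names(conds) <- cp$label
    list(id = s, conditions = conds)
  })
  reports <- surrogate_stress_reports(config)
  structure(list(config = config, condition_plan = cp,
                 subjects = subjects, stress_reports = reports),
            class = "protocol_dataset")
}

#' @export
print.protocol_dataset <- function(x, ...) {
  cat("Protocol dataset: ", length(x$subjects), " subjects x ",
      nrow(x$condition_plan), " conditions (",
      paste(x$condition_plan$label, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Surrogate self-reported stress scores
#'
#' Draws integer stress scores (1--7) per subject for each stressor so
#' that the group medians follow a configured monotone profile (default
#' medians 1, 4, 5 with MADs 0, 1, 1).  Scores are constructed from fixed
#' deviation counts and shuffled across subjects, so the group median
#' equals the target exactly at any n.
#'
#' @param config A [synthetic_config()] (uses its seed and stressor
#'   count), or an integer number of subjects.
#' @param medians Target medians, one per stressor (default \code{c(1, 4,
#'   5)}).
#' @param dispersion Multiplier on the deviation profile; 0 makes every
#'   subject report the median (default 1).
#' @param seed Seed override (defaults to the config seed).
#' @return Integer matrix subjects x stressors.
#' @export
surrogate_stress_reports <- function(config, medians = c(1, 4, 5),
                                     dispersion = 1, seed = NULL) {
  if (inherits(config, "synthetic_config")) {
    n <- config$n_subjects
    if (is.null(seed)) seed <- child_seed(config$seed, 0L, 0L, 9L)
    n_stress <- sum(config$condition_plan$label != "rest")
    if (n_stress >= 1L) medians <- rep_len(medians, n_stress)
  } else {
    n <- as.integer(config)
    if (is.null(seed)) seed <- 1L
  }
  set.seed(seed)
  out <- vapply(seq_along(medians), function(i) {
    md <- medians[i]
    spread <- if (md <= 1 || md >= 7) {
      # clamped end of the scale: deviations one-sided, MAD 0
      c(rep(0, ceiling(0.7 * n)), rep(1, n - ceiling(0.7 * n)))
    } else {
      # symmetric thirds: median preserved, MAD 1
      k <- floor(n / 3)
      c(rep(-1, k), rep(0, n - 2 * k), rep(1, k))
    }
    d <- round(spread * dispersion)
    as.integer(pmin(pmax(md + sample(d), 1), 7))
  }, integer(n))
  out <- matrix(out, nrow = n)
  rownames(out) <- paste0("subj", seq_len(n))
  colnames(out) <- paste0("stress", seq_along(medians))
  out
}

#' Write a protocol dataset as delimited text
#'
#' One directory per subject with \code{rr.csv} (t_beat_s, rr_s),
#' \code{power.csv} (t_s, channel, band, power_uv2) and a shared
#' \code{conditions.csv} (label, onset_s, duration_s), plus
#' \code{ground_truth.csv} sidecars (per-condition planted coupling
#' trajectories) and a flat \code{config.txt}.
#'
#' @param dataset A \code{protocol_dataset}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_protocol_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "protocol_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- dataset$condition_plan
  utils::write.csv(data.frame(label = cp$label, onset_s = cp$onset,
                              duration_s = cp$duration),
                   file.path(dir, "conditions.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- dataset$config
  keys <- c(n_subjects = cfg$n_subjects,
            baseline_rate_hz = cfg$baseline_rate_hz, seed = cfg$seed,
            channels = paste(cfg$channels, collapse = ";"),
            bands = paste(cfg$bands, collapse = ";"))
  writeLines(paste(names(keys), keys, sep = "="),
             file.path(dir, "config.txt"))
  for (sub in dataset$subjects) {
    sd <- file.path(dir, sprintf("subject_%02d", sub$id))
    dir.create(sd, showWarnings = FALSE)
    rr_all <- do.call(rbind, lapply(sub$conditions, function(cc)
      data.frame(t_beat_s = cc$rr$beat_times,
                 rr_s = c(NA, cc$rr$intervals))))
    utils::write.csv(rr_all, file.path(sd, "rr.csv"),
                     row.names = FALSE, quote = FALSE)
    for (cc in sub$conditions) {
      write_bandpower(cc$bandpower,
                      file.path(sd, paste0("power_", cc$label, ".csv")))
      tr <- cc$truth
      utils::write.csv(data.frame(t_s = tr$grid, c_sai = tr$c_sai,
                                  c_pai = tr$c_pai, sai_lat = tr$sai_lat,
                                  pai_lat = tr$pai_lat),
                       file.path(sd, paste0("ground_truth_", cc$label,
                                            ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
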