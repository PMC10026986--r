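#' Heart-rate modulation about a sliding baseline
#'
#' Interpolates the instantaneous rate \eqn{1/RR} (assigned at interval
#' midpoints) onto a uniform 1-s grid and removes a sliding-window
#' baseline: for every stamp, the baseline is the mean rate over the
#' centred window, and \eqn{m(t)} is the residual fluctuation.  A constant
#' RR series therefore yields \eqn{m \equiv 0} exactly.
#'
#' @param rr An [rr_series()].
#' @param grid Uniform time stamps in seconds; must lie inside the beat
#'   span of \code{rr}.
#' @param window_s Baseline window length in seconds (default 15).
#' @return Object of class \code{modulation_series}: list with
#'   \code{grid}, \code{m} (Hz), \code{rate}, \code{baseline},
#'   \code{window_s}.
#' @export
estimate_modulation <- function(rr, grid, window_s = 15) {
  stopifnot(inherits(rr, "rr_series"))
  grid <- as.numeric(grid)
  if (min(grid) < min(rr$beat_times) - 1e-9 ||
      max(grid) > max(rr$beat_times) + 1e-9)
    stop("grid extends beyond the RR series coverage")
  bt <- rr$beat_times
  mid <- (bt[-1] + bt[-length(bt)]) / 2
  rate <- stats::approx(mid, 1 / rr$intervals, xout = grid, rule = 2)$y
  step <- if (length(grid) > 1L) grid[2] - grid[1] else 1
  w <- max(1L, round(window_s / step))
  baseline <- running_mean(rate, w)
  structure(list(grid = grid, m = rate - baseline, rate = rate,
                 baseline = baseline, window_s = window_s),
            class = "modulation_series")
}

#' Brain-to-heart control coefficients
#'
#' Fits, in every sliding window, the no-intercept regression
#' \deqn{m(t) = C_{SAI}(t)\, SAI(t) + C_{PAI}(t)\, PAI(t)}
#' by least squares, assigning the coefficient pair to the window-centre
#' stamp.  Windows whose two-column design matrix has condition number
#' above \code{max_cond} (rank-deficient or collinear SAI/PAI) are masked
#' invalid rather than aborting the fit.
#'
#' @param m A [estimate_modulation()] result, or a list with \code{grid}
#'   and \code{m}.
#' @param autonomic An \code{autonomic_series}; resampled to the grid by
#'   linear interpolation.
#' @param window_s Window length in seconds (default 15).
#' @param max_cond Condition-number mask threshold (default 1e8).
#' @return Object of class \code{bh_fit}: list with \code{grid},
#'   \code{c_sai}, \code{c_pai}, \code{valid}, \code{sai}, \code{pai},
#'   \code{window_s}.
#' @export
fit_brain_to_heart <- function(m, autonomic, window_s = 15,
                               max_cond = 1e8) {
  stopifnot(inherits(autonomic, "autonomic_series"))
  grid <- m$grid
  mv <- m$m
  n <- length(grid)
  step <- if (n > 1L) grid[2] - grid[1] else 1
  w <- max(3L, round(window_s / step))
  if (n < w) stop("series shorter than one window")
  s <- interp_to(autonomic$beat_times, autonomic$sai, grid)
  p <- interp_to(autonomic$beat_times, autonomic$pai, grid)
  Sss <- roll_sum(s * s, w); Spp <- roll_sum(p * p, w)
  Ssp <- roll_sum(s * p, w)
  Ssm <- roll_sum(s * mv, w); Spm <- roll_sum(p * mv, w)
  det <- Sss * Spp - Ssp^2
  tr <- Sss + Spp
  disc <- sqrt(pmax((Sss - Spp)^2 + 4 * Ssp^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  pos <- is.finite(det) & l2 > 0
  ok <- pos
  ok[pos] <- sqrt(l1[pos] / l2[pos]) <= max_cond
  cs <- cp <- rep(NA_real_, length(det))
  cs[ok] <- (Spp[ok] * Ssm[ok] - Ssp[ok] * Spm[ok]) / det[ok]
  cp[ok] <- (Sss[ok] * Spm[ok] - Ssp[ok] * Ssm[ok]) / det[ok]
  # window j covers grid[j .. j+w-1]; assign to its centre stamp
  centre <- seq_along(det) + (w - 1L) %/% 2L
  c_sai <- c_pai <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  c_sai[centre] <- cs
  c_pai[centre] <- cp
  valid[centre] <- ok
  if (any(!ok))
    message("fit_brain_to_heart: ", sum(!ok),
            " window(s) masked invalid (ill-conditioned design)")
  structure(list(grid = grid, c_sai = c_sai, c_pai = c_pai,
                 valid = valid, sai = s, pai = p, window_s = window_s),
            class = "bh_fit")
}

#' Directional brain-to-heart coupling series
#'
#' Forms the coupling coefficient
#' \eqn{SDG_{EEG_F \to X}(t) = C_X(t) / EEG_F(t-1)} on the shared 1-s
#' grid, with a one-step lag on the band power.  Points whose lagged
#' denominator falls below \code{eps} times the median band power, or
#' whose coefficient window was masked, are marked invalid.
#'
#' @param fit A [fit_brain_to_heart()] result.
#' @param bandpower A [band_power_series()] on the same grid.
#' @param band,channel Which band-power series to use as denominator.
#' @param branch \code{"SAI"} or \code{"PAI"}.
#' @param eps Relative denominator guard (default 1e-6).
#' @return A \code{coupling_series}.
#' @export
brain_to_heart_coupling <- function(fit, bandpower, band, channel,
                                    branch = c("SAI", "PAI"),
                                    eps = 1e-6) {
  branch <- match.arg(branch)
  stopifnot(inherits(fit, "bh_fit"), inherits(bandpower, "band_power_series"))
  if (length(fit$grid) != length(bandpower$grid) ||
      any(abs(fit$grid - bandpower$grid) > 1e-9))
    stop("coefficient and band-power grids do not match")
  cx <- if (branch == "SAI") fit$c_sai else fit$c_pai
  eegf <- bandpower$power[, channel, band]
  n <- length(cx)
  lagged <- c(NA_real_, eegf[-n])
  guard <- eps * stats::median(eegf)
  valid <- fit$valid & !is.na(lagged) & abs(lagged) >= guard
  sdg <- rep(NA_real_, n)
  sdg[valid] <- cx[valid] / lagged[valid]
  coupling_series(direction = "brain_to_heart", branch = branch,
                  band = band, channel = channel, grid = fit$grid,
                  sdg = sdg, valid = valid)
}

#' Heart-to-brain autoregressive fit
#'
#' Fits, per sliding window, the adaptive Markov model
#' \eqn{EEG_F(t) = \kappa_F EEG_F(t-1) + \Psi_F(t-1) + \epsilon_F} by
#' no-intercept least squares of the power on its one-step lag, and
#' identifies the heart-drive term with the pointwise residual
#' \eqn{\Psi_F(t-1) = EEG_F(t) - \hat\kappa_F\, EEG_F(t-1)} (the
#' innovation \eqn{\epsilon_F} is absorbed into \eqn{\Psi_F}; see the
#' methods vignette).
#'
#' @param bandpower A [band_power_series()], or a list with \code{grid}
#'   and \code{values} holding a single power (or power-fluctuation)
#'   series on a uniform grid.
#' @param band,channel Which series to fit (ignored for a plain series).
#' @param window_s Window length in seconds (default 15, matching the
#'   brain-to-heart direction).  Note the no-intercept fit identifies
#'   \eqn{\kappa_F} only up to the mean structure of the series: for a
#'   series with a large operating mean the slope tends to 1 and the
#'   mean recurs in \eqn{\Psi_F}; see the methods vignette.
#' @return Object of class \code{hb_fit}: list with \code{grid},
#'   \code{kappa} (at window-centre stamps, NA elsewhere),
#'   \code{kappa_valid}, \code{psi} (defined on \code{grid[1..n-1]}),
#'   \code{window_s}.
#' @export
fit_heart_to_brain <- function(bandpower, band = NULL, channel = NULL,
                               window_s = 15) {
  if (inherits(bandpower, "band_power_series")) {
    y <- bandpower$power[, channel, band]
    grid <- bandpower$grid
  } else if (is.list(bandpower) &&
             all(c("grid", "values") %in% names(bandpower))) {
    y <- as.numeric(bandpower$values)
    grid <- as.numeric(bandpower$grid)
  } else stop("bandpower must be a band_power_series or a grid/values list")
  n <- length(y)
  step <- if (n > 1L) grid[2] - grid[1] else 1
  w <- max(3L, round(window_s / step))      # lag pairs per window
  if (n < w + 1L) stop("need at least window_s + 1 grid points")
  x1 <- y[-n]                               # EEG(t-1)
  y1 <- y[-1L]                              # EEG(t)
  Sxx <- roll_sum(x1 * x1, w)
  Sxy <- roll_sum(x1 * y1, w)
  ok <- Sxx > 1e-12
  kap <- rep(NA_real_, length(Sxx))
  kap[ok] <- Sxy[ok] / Sxx[ok]
  # window j covers pairs j..j+w-1, i.e. grid points j..j+w
  centre <- seq_along(kap) + w %/% 2L
  kappa <- rep(NA_real_, n)
  kv <- rep(FALSE, n)
  kappa[centre] <- kap
  kv[centre] <- ok
  if (any(!ok))
    message("fit_heart_to_brain: ", sum(!ok),
            " window(s) masked invalid (degenerate power)")
  # pointwise kappa for the residual drive: nearest fitted window centre
  if (!any(ok)) {
    psi <- rep(NA_real_, n - 1L)
  } else {
    kc <- grid[centre][ok]
    kvals <- kap[ok]
    kpt <- stats::approx(kc, kvals, xout = grid[-1L],
                         method = "constant", rule = 2, f = 0.5)$y
    psi <- y1 - kpt * x1
  }
  structure(list(grid = grid, kappa = kappa, kappa_valid = kv,
                 psi = psi, psi_grid = grid[-n],
                 band = band, channel = channel, window_s = window_s),
            class = "hb_fit")
}

#' Directional heart-to-brain coupling series
#'
#' Forms \eqn{SDG_{X \to EEG_F}(t) = \Psi_F(t) / X(t)} on the drive grid
#' (no lag on the denominator).  Points where \eqn{|X(t)|} falls below
#' \code{eps} times its median magnitude are masked.
#'
#' @param fit A [fit_heart_to_brain()] result, or a list with
#'   \code{psi} and \code{psi_grid}.
#' @param autonomic An \code{autonomic_series}, or a list with
#'   \code{beat_times} and the branch series; resampled by linear
#'   interpolation.
#' @param branch \code{"SAI"} or \code{"PAI"}.
#' @param band,channel Labels for the returned series (default from
#'   \code{fit}).
#' @param eps Relative denominator guard (default 1e-6).
#' @return A \code{coupling_series}.
#' @export
heart_to_brain_coupling <- function(fit, autonomic,
                                    branch = c("SAI", "PAI"),
                                    band = NULL, channel = NULL,
                                    eps = 1e-6) {
  branch <- match.arg(branch)
  grid <- fit$psi_grid
  psi <- fit$psi
  if (is.null(band)) band <- fit$band
  if (is.null(channel)) channel <- fit$channel
  xsrc <- if (branch == "SAI") autonomic$sai else autonomic$pai
  x <- interp_to(autonomic$beat_times, xsrc, grid)
  guard <- eps * stats::median(abs(x))
  valid <- is.finite(psi) & abs(x) >= guard
  sdg <- rep(NA_real_, length(psi))
  sdg[valid] <- psi[valid] / x[valid]
  coupling_series(direction = "heart_to_brain", branch = branch,
                  band = band, channel = channel, grid = grid,
                  sdg = sdg, valid = valid)
}

#' Time-resolved directional coupling series
#'
#' One (direction, branch, band, channel) combination of the SV-SDG
#' coupling coefficients on a 1-s grid, with a validity mask; masked
#' points are excluded from every condensation.
#'
#' @param direction \code{"brain_to_heart"} or \code{"heart_to_brain"}.
#' @param branch \code{"SAI"} or \code{"PAI"}.
#' @param band,channel Labels.
#' @param grid Time stamps in seconds.
#' @param sdg Coupling values (NA where invalid).
#' @param valid Logical mask.
#' @return Object of class \code{coupling_series}.
#' @export
coupling_series <- function(direction, branch, band, channel, grid, sdg,
                            valid) {
  stopifnot(direction %in% c("brain_to_heart", "heart_to_brain"),
            branch %in% c("SAI", "PAI"),
            length(grid) == length(sdg), length(sdg) == length(valid))
  if (any(valid & !is.finite(sdg)))
    stop("non-finite coupling value marked valid")
  structure(list(direction = direction, branch = branch, band = band,
                 channel = channel, grid = grid, sdg = sdg,
                 valid = valid),
            class = "coupling_series")
}

#' @export
print.coupling_series <- function(x, ...) {
  v <- x$sdg[x$valid]
  cat("Coupling series ", x$direction, " ", x$branch,
      if (x$direction == "brain_to_heart") " <- " else " -> ",
      x$band, "@", x$channel, ": ", sum(x$valid), "/", length(x$valid),
      " valid points, median ", signif(stats::median(v), 4),
      ", MAD ", signif(stats::mad(v, constant = 1), 4), "\n", sep = "")
  invisible(x)
}

#' Write coupling series as delimited text
#'
#' Long format \code{t_s, direction, branch, band, channel, value, valid}.
#'
#' @param series A \code{coupling_series} or a list of them.
#' @param path Output file path.
#' @export
write_coupling <- function(series, path) {
  if (inherits(series, "coupling_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(x)
    data.frame(t_s = x$grid, direction = x$direction, branch = x$branch,
               band = x$band, channel = x$channel, value = x$sdg,
               valid = x$valid)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
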