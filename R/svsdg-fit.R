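#' Fit the bidirectional brain-heart coupling model
#'
#' The package's central fitting function.  From one subject's RR series
#' and band-power series it estimates, on a shared 1-s grid:
#' \itemize{
#'   \item the autonomic indices SAI and PAI (Laguerre expansion + Kalman
#'     filter) from the RR intervals;
#'   \item the heart-rate modulation \eqn{m(t)} about its sliding
#'     baseline;
#'   \item the brain-to-heart control coefficients \eqn{C_{SAI}(t)},
#'     \eqn{C_{PAI}(t)} (windowed no-intercept regression of \eqn{m} on
#'     SAI and PAI) and the per-band, per-channel coupling ratios
#'     \eqn{C_X(t) / EEG_F(t-1)};
#'   \item the heart-to-brain autoregressive constants \eqn{\kappa_F} and
#'     drive \eqn{\Psi_F}, and the ratios \eqn{\Psi_F(t) / X(t)}.
#' }
#'
#' @param rr An [rr_series()] covering the band-power grid.
#' @param bandpower A [band_power_series()] on a 1-s grid.
#' @param window_s Sliding-window length in seconds for all windowed
#'   fits (default 15).
#' @param warmup_beats Kalman warm-up (default 20; the autonomic series
#'   starts after this many beats, and the coupling grid is clipped
#'   accordingly).
#' @param autonomic Optionally, a precomputed \code{autonomic_series} to
#'   use instead of estimating one from \code{rr}.
#' @param ... Further arguments to [kalman_estimate_coeffs()].
#' @return Object of class \code{svsdg_fit}: list with \code{grid},
#'   \code{autonomic}, \code{modulation}, \code{bh} (the
#'   [fit_brain_to_heart()] result), \code{couplings} (named list of 180
#'   \code{coupling_series} for a full 9-channel, 5-band run),
#'   \code{kappa} (band x channel matrix of window-median
#'   autoregressive constants), \code{window_s}.
#' @examples
#' \donttest{
#' ds <- generate_protocol_dataset(synthetic_config(
#'   n_subjects = 1, condition_plan = data.frame(
#'     label = c("rest", "stress1", "stress2", "stress3"),
#'     duration = c(60, 120, 120, 120))))
#' sub <- ds$subjects[[1]]
#' fit <- svsdg(merge_rr(lapply(sub$conditions, `[[`, "rr")),
#'              merge_bandpower(lapply(sub$conditions, `[[`, "bandpower")))
#' print(fit)
#' }
#' @export
svsdg <- function(rr, bandpower, window_s = 15, warmup_beats = 20L,
                  autonomic = NULL, ...) {
  stopifnot(inherits(rr, "rr_series"),
            inherits(bandpower, "band_power_series"))
  if (is.null(autonomic))
    autonomic <- estimate_autonomic(rr, warmup_beats = warmup_beats, ...)
  # clip the grid to the span where both streams are defined
  lo <- max(min(bandpower$grid), ceiling(min(autonomic$beat_times)))
  hi <- min(max(bandpower$grid), floor(max(rr$beat_times)))
  keep <- bandpower$grid >= lo - 1e-9 & bandpower$grid <= hi + 1e-9
  if (sum(keep) < window_s + 2L)
    stop("overlap between RR and band-power coverage is shorter than ",
         "one window")
  bp <- band_power_series(bandpower$grid[keep],
                          bandpower$power[keep, , , drop = FALSE],
                          bandpower$channels, bandpower$bands)
  m <- estimate_modulation(rr, bp$grid, window_s)
  bh <- fit_brain_to_heart(m, autonomic, window_s)
  couplings <- list()
  kappa <- matrix(NA_real_, length(bp$bands), length(bp$channels),
                  dimnames = list(bp$bands, bp$channels))
  for (ch in bp$channels) {
    for (bd in bp$bands) {
      hb <- fit_heart_to_brain(bp, bd, ch, window_s)
      kappa[bd, ch] <- stats::median(hb$kappa[hb$kappa_valid])
      for (br in c("SAI", "PAI")) {
        cs <- brain_to_heart_coupling(bh, bp, bd, ch, br)
        couplings[[coupling_id(cs)]] <- cs
        cs <- heart_to_brain_coupling(hb, autonomic, br)
        couplings[[coupling_id(cs)]] <- cs
      }
    }
  }
  structure(list(grid = bp$grid, autonomic = autonomic, modulation = m,
                 bh = bh, couplings = couplings, kappa = kappa,
                 window_s = window_s),
            class = "svsdg_fit")
}

coupling_id <- function(x)
  paste(x$direction, x$branch, x$band, x$channel, sep = ".")

#' @export
print.svsdg_fit <- function(x, ...) {
  cat("SV-SDG coupling fit over ", length(x$grid), " s (",
      length(x$couplings), " directional coupling series, window ",
      x$window_s, " s)\n", sep = "")
  vb <- mean(x$bh$valid)
  cat("  brain-to-heart windows valid: ", round(100 * vb, 1), "%\n",
      sep = "")
  cat("  median kappa by band: ",
      paste(rownames(x$kappa),
            signif(apply(x$kappa, 1, stats::median), 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.svsdg_fit <- function(object, ...) {
  mads <- vapply(object$couplings, function(cs)
    stats::mad(cs$sdg[cs$valid], constant = 1), numeric(1))
  meta <- parse_feature_names(paste0(names(object$couplings), ".mad"))
  out <- data.frame(meta[, c("direction", "branch", "band", "channel")],
                    mad = mads, row.names = NULL)
  class(out) <- c("summary.svsdg_fit", class(out))
  out
}

#' @export
print.summary.svsdg_fit <- function(x, ...) {
  cat("Coupling variability (MAD over valid points), by direction:\n")
  for (d in unique(x$direction)) {
    sub <- x[x$direction == d, ]
    agg <- stats::aggregate(mad ~ band + branch, data = sub, median)
    cat("  ", d, ":\n", sep = "")
    print.data.frame(agg, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Extract condensed coupling coefficients from a fit
#'
#' @param object An \code{svsdg_fit}.
#' @param condensation \code{"mad"} (default) or \code{"median"} over
#'   valid points.
#' @param ... Unused.
#' @return Named numeric vector, one entry per coupling series, names in
#'   the canonical \code{direction.branch.band.channel.tag} form.
#' @export
coef.svsdg_fit <- function(object, condensation = c("mad", "median"),
                           ...) {
  condensation <- match.arg(condensation)
  fn <- if (condensation == "mad") {
    function(v) stats::mad(v, constant = 1)
  } else stats::median
  out <- vapply(object$couplings, function(cs) fn(cs$sdg[cs$valid]),
                numeric(1))
  names(out) <- paste0(names(object$couplings), ".", condensation)
  out
}

#' @export
plot.svsdg_fit <- function(x, band = "alpha", channel = "Cz", ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$autonomic$beat_times, x$autonomic$sai, type = "l",
                 xlab = "time (s)", ylab = "SAI (a.u.)")
  graphics::lines(x$autonomic$beat_times, x$autonomic$pai,
                  col = "grey50")
  graphics::legend("topright", c("SAI", "PAI"),
                   col = c("black", "grey50"), lty = 1, bty = "n")
  cs1 <- x$couplings[[paste("brain_to_heart", "SAI", band, channel,
                            sep = ".")]]
  graphics::plot(cs1$grid, cs1$sdg, type = "l", xlab = "time (s)",
                 ylab = sprintf("SDG %s->SAI", band))
  cs2 <- x$couplings[[paste("heart_to_brain", "SAI", band, channel,
                            sep = ".")]]
  graphics::plot(cs2$grid, cs2$sdg, type = "l", xlab = "time (s)",
                 ylab = sprintf("SDG SAI->%s", band))
  invisible(x)
}

#' Merge per-condition series into one protocol-long series
#'
#' \code{merge_rr} concatenates contiguous per-condition RR series,
#' dropping each later segment's leading beat (placed at the condition
#' onset) so the stitched intervals stay physiological.
#' \code{merge_bandpower} concatenates band-power series along time.
#'
#' @param pieces List of [rr_series()] or [band_power_series()] in
#'   protocol order.
#' @return A single merged object of the same class.
#' @export
merge_rr <- function(pieces) {
  bt <- pieces[[1]]$beat_times
  for (p in pieces[-1]) bt <- c(bt, p$beat_times[-1L])
  rr_series(bt)
}

#' @rdname merge_rr
#' @export
merge_bandpower <- function(pieces) {
  grid <- do.call(c, lapply(pieces, `[[`, "grid"))
  pow <- do.call(abind_time, lapply(pieces, `[[`, "power"))
  band_power_series(grid, pow, pieces[[1]]$channels, pieces[[1]]$bands)
}

abind_time <- function(...) {
  pieces <- list(...)
  d <- dim(pieces[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(pieces, function(p)
    dim(p)[1], numeric(1))), d[2], d[3]))
  at <- 1L
  for (p in pieces) {
    np <- dim(p)[1]
    out[at:(at + np - 1L), , ] <- p
    at <- at + np
  }
  out
}
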