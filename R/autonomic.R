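#' Fixed sympathetic and parasympathetic kernels
#'
#' The published kernel constants that map time-varying Laguerre
#' coefficients onto the cardiac sympathetic activity index (SAI) and
#' parasympathetic activity index (PAI).  The sympathetic kernel weights
#' the first two Laguerre coefficients (fast dynamics), the parasympathetic
#' kernel the remaining seven (slower, vagally mediated dynamics).
#'
#' @return Object of class \code{autonomic_kernels}: list with \code{psi_s}
#'   (length 3) and \code{psi_p} (length 8).
#' @export
autonomic_kernels <- function() {
  structure(list(
    psi_s = c(39.2343, 10.1963, -5.9242),
    psi_p = c(28.4875, -17.3627, 5.8798, 12.0628, 5.6408,
              -7.0664, -5.6779, -3.9474)),
    class = "autonomic_kernels")
}

#' Cardiac sympathetic and parasympathetic activity indices
#'
#' Combines a [kalman_estimate_coeffs()] coefficient trajectory with the
#' fixed autonomic kernels:
#' \deqn{SAI(k) = [\Psi s_0 + \Psi s_1 g_{1,0}(k) + \Psi s_2 g_{1,1}(k)]
#'   / RR(k)}
#' \deqn{PAI(k) = [\Psi p_0 + \sum_{j=1}^{7} \Psi p_j g_{1,j+1}(k)]
#'   \cdot 2\, RR(k)}
#' with RR in seconds.  SAI therefore scales inversely with the interval
#' (sympathetic activation shortens beats) and PAI proportionally
#' (vagal activation lengthens them).  Both are in arbitrary units.
#'
#' @param coeffs A \code{coeff_trajectory}.
#' @param rr Optional numeric vector of intervals aligned with
#'   \code{coeffs}; defaults to the intervals stored in the trajectory.
#' @param kernels An [autonomic_kernels()] object.
#' @return Object of class \code{autonomic_series}: list with
#'   \code{beat_times}, \code{sai}, \code{pai}.
#' @examples
#' \donttest{
#' rr <- synthesize_rr_integrate_and_fire(function(t) 0.1 * sin(0.5 * t),
#'                                        baseline_rate_hz = 1.1,
#'                                        duration = 300)
#' aut <- estimate_autonomic(rr)
#' head(aut$sai)
#' }
#' @export
compute_sai_pai <- function(coeffs, rr = NULL, kernels = autonomic_kernels()) {
  stopifnot(inherits(coeffs, "coeff_trajectory"),
            inherits(kernels, "autonomic_kernels"))
  rrv <- if (is.null(rr)) coeffs$rr else as.numeric(rr)
  if (length(rrv) != length(coeffs$g0))
    stop("rr and coefficient trajectory are not aligned")
  if (any(rrv <= 0)) stop("non-positive RR interval")
  g1 <- coeffs$g1
  ps <- kernels$psi_s
  pp <- kernels$psi_p
  sai <- (ps[1] + ps[2] * g1[, 1L] + ps[3] * g1[, 2L]) / rrv
  pai <- (pp[1] + drop(g1[, 3:9, drop = FALSE] %*% pp[2:8])) * 2 * rrv
  structure(list(beat_times = coeffs$beat_times, sai = sai, pai = pai),
            class = "autonomic_series")
}

#' @export
print.autonomic_series <- function(x, ...) {
  cat("Autonomic activity series: ", length(x$sai), " beats\n", sep = "")
  cat("  SAI median ", signif(stats::median(x$sai), 4),
      " (MAD ", signif(stats::mad(x$sai, constant = 1), 4), ")\n", sep = "")
  cat("  PAI median ", signif(stats::median(x$pai), 4),
      " (MAD ", signif(stats::mad(x$pai, constant = 1), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.autonomic_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$beat_times, x$sai, type = "l", xlab = "time (s)",
                 ylab = "SAI (a.u.)", ...)
  graphics::plot(x$beat_times, x$pai, type = "l", xlab = "time (s)",
                 ylab = "PAI (a.u.)", ...)
  invisible(x)
}

#' One-call autonomic estimation from an RR series
#'
#' Convenience wrapper running the full chain
#' [laguerre_basis()] -> [convolve_rr()] -> [kalman_estimate_coeffs()] ->
#' [compute_sai_pai()].
#'
#' @param rr An [rr_series()].
#' @param alpha Laguerre discount (default 0.2).
#' @param max_order Highest Laguerre order (default 8).
#' @param ... Passed to [kalman_estimate_coeffs()].
#' @return An \code{autonomic_series} with the \code{coeff_trajectory}
#'   attached as attribute \code{"coeffs"}.
#' @export
estimate_autonomic <- function(rr, alpha = 0.2, max_order = 8L, ...) {
  basis <- laguerre_basis(alpha, max_order,
                          max(500L, 10L * max_order))
  reg <- convolve_rr(rr, basis)
  co <- kalman_estimate_coeffs(rr, reg, ...)
  out <- compute_sai_pai(co)
  attr(out, "coeffs") <- co
  out
}

#' Write an autonomic series as delimited text
#'
#' Columns \code{t_beat_s, sai, pai}.
#'
#' @param x An \code{autonomic_series}.
#' @param path Output file path.
#' @export
write_autonomic <- function(x, path) {
  stopifnot(inherits(x, "autonomic_series"))
  utils::write.csv(data.frame(t_beat_s = x$beat_times, sai = x$sai,
                              pai = x$pai),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
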