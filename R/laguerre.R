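#' Discrete orthonormal Laguerre basis
#'
#' Builds the family of discrete-time orthonormal Laguerre functions
#' \eqn{\phi_j(n)}, \eqn{j = 0, \dots, max\_order}, with discount parameter
#' \eqn{\alpha \in (0, 1)}.  The zeroth function is
#' \eqn{\phi_0(n) = \sqrt{1 - \alpha}\,\alpha^{n/2}}; higher orders follow
#' the stable two-term recursion
#' \deqn{\phi_j(n) = \sqrt{\alpha}\,\phi_j(n-1) + \sqrt{\alpha}\,
#'   \phi_{j-1}(n) - \phi_{j-1}(n-1).}
#' The functions are orthonormal over \eqn{n \ge 0} and decay geometrically,
#' which is what lets a short vector of convolved coefficients summarise the
#' long autoregressive memory of an RR series.
#'
#' @param alpha Discount parameter in (0, 1).  Default 0.2, a common choice
#'   for heartbeat dynamics: memory concentrates over the last 10--20 beats.
#' @param max_order Highest order (default 8, giving 9 functions).
#' @param length Number of samples \eqn{n = 0, \dots, length - 1} at which
#'   the functions are tabulated; must be at least \code{10 * max_order} so
#'   that truncation error is negligible.
#' @return Object of class \code{laguerre_basis}: list with \code{alpha},
#'   \code{max_order}, \code{length} and \code{functions}, a
#'   \code{length x (max_order + 1)} matrix whose column \code{j + 1} is
#'   \eqn{\phi_j}.
#' @examples
#' b <- laguerre_basis(0.2, 8, 500)
#' crossprod(b$functions)[1:3, 1:3]   # ~ identity
#' @export
laguerre_basis <- function(alpha = 0.2, max_order = 8L, length = 500L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  max_order <- as.integer(max_order)
  length <- as.integer(length)
  if (max_order < 0L) stop("max_order must be >= 0")
  if (length < 10L * max(max_order, 1L))
    stop("length must be >= 10 * max_order for adequate decay")
  sa <- sqrt(alpha)
  phi <- matrix(0, nrow = length, ncol = max_order + 1L)
  phi[, 1L] <- sqrt(1 - alpha) * sa^(0:(length - 1L))
  if (max_order >= 1L) {
    for (j in seq_len(max_order)) {
      prev <- phi[, j]
      cur <- numeric(length)
      cur[1L] <- sa * prev[1L]
      for (n in 2:length)
        cur[n] <- sa * cur[n - 1L] + sa * prev[n] - prev[n - 1L]
      phi[, j + 1L] <- cur
    }
  }
  structure(list(alpha = alpha, max_order = max_order, length = length,
                 functions = phi),
            class = "laguerre_basis")
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat("Discrete Laguerre basis: orders 0..", x$max_order,
      ", alpha = ", x$alpha, ", tabulated over ", x$length,
      " lags\n", sep = "")
  invisible(x)
}

#' Convolve an RR series with a Laguerre basis
#'
#' Computes the causal Laguerre regressors
#' \deqn{L_j(k) = \sum_{n=0}^{k-1} \phi_j(n)\, RR(k - n - 1),}
#' i.e. each beat's regressor vector is a geometrically discounted summary
#' of all strictly earlier intervals.  \eqn{L_j(k)} is defined for
#' \eqn{k \ge 1} (1-based row \code{k} of the result corresponds to beat
#' index \eqn{k}, which uses intervals \eqn{RR(0), \dots, RR(k-1)} only).
#'
#' @param rr An [rr_series()].
#' @param basis A [laguerre_basis()].
#' @return Object of class \code{laguerre_regressors}: list with
#'   \code{values}, an \code{(n_intervals - 1) x (max_order + 1)} matrix
#'   whose row \code{k} holds \eqn{L_j(k)} for the beat following interval
#'   \code{k}, and \code{basis}.
#' @export
convolve_rr <- function(rr, basis) {
  stopifnot(inherits(rr, "rr_series"), inherits(basis, "laguerre_basis"))
  x <- rr$intervals
  nk <- length(x) - 1L            # regressors for k = 1 .. n-1
  if (nk < 1L) stop("need at least 2 intervals to form regressors")
  phi <- basis$functions
  nl <- nrow(phi)
  vals <- matrix(0, nrow = nk, ncol = ncol(phi))
  for (k in seq_len(nk)) {
    nmax <- min(k, nl)                     # truncate at available history
    hist <- x[k:(k - nmax + 1L)]           # RR(k-1), RR(k-2), ... (0-based)
    vals[k, ] <- crossprod(phi[seq_len(nmax), , drop = FALSE], hist)
  }
  structure(list(values = vals, basis = basis), class = "laguerre_regressors")
}
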