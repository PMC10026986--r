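#' Kalman estimation of time-varying Laguerre coefficients
#'
#' Tracks the coefficient vector
#' \eqn{g(k) = [g_0(k), g_{1,0}(k), \dots, g_{1,8}(k)]^T} of the
#' time-varying autoregressive heartbeat model
#' \deqn{RR(k) = g_0(k) + \sum_j g_{1,j}(k) L_j(k) + \epsilon_{RR}(k)}
#' under a random-walk state model \eqn{g(k) = g(k-1) + \epsilon_g(k)},
#' using a Kalman filter whose observation matrix
#' \eqn{[1, L_0(k), \dots, L_8(k)]} changes at every beat.
#'
#' The filter is initialised with the batch least-squares solution over the
#' first \code{warmup_beats} beats, with state covariance
#' \code{10 * r_init * I}.  The observation-noise variance is either held at
#' \code{r_init} or (default) re-estimated adaptively from a sliding window
#' of recent innovations.  Filtered (not smoothed) estimates are returned,
#' so every coefficient at beat \eqn{k} depends on intervals up to \eqn{k}
#' only — a requirement for the directional coupling claims built on top.
#'
#' @param rr An [rr_series()].
#' @param regressors Output of [convolve_rr()] for the same series.
#' @param q Random-walk state-noise variance per coefficient (default 1e-5).
#' @param r_init Initial observation-noise variance in s^2 (default 1e-4,
#'   i.e. 10 ms innovation scale).
#' @param warmup_beats Number of initial beats used for least-squares
#'   initialisation; estimates are reported from this beat on (default 50,
#'   minimum 20).
#' @param adapt_r Logical; re-estimate the observation noise from a sliding
#'   window of innovations (default TRUE).
#' @param r_window Innovation window length for the adaptive estimate
#'   (default 30 beats).
#' @param skip_beats Discard this many leading beats before the warm-up
#'   (default 0); useful when the start of a series is known not to
#'   follow the model (e.g. a simulator's seed history).
#' @param p0_scale Initial state covariance is \code{p0_scale * r_init *
#'   I} (default 10); large values give a diffuse prior under which the
#'   q = 0 filter reproduces batch least squares.
#' @return Object of class \code{coeff_trajectory}: list with
#'   \code{beat_index} (k of each reported beat, 1-based over intervals),
#'   \code{beat_times}, \code{g0}, \code{g1} (matrix, columns
#'   \eqn{g_{1,0} \dots g_{1,8}}), \code{innovation}, \code{rr} (the target
#'   intervals), \code{q}, \code{r} (per-beat observation variance used) and
#'   \code{warmup_beats}.
#' @export
kalman_estimate_coeffs <- function(rr, regressors, q = 1e-5, r_init = 1e-4,
                                   warmup_beats = 50L, adapt_r = TRUE,
                                   r_window = 30L, skip_beats = 0L,
                                   p0_scale = 10) {
  stopifnot(inherits(rr, "rr_series"),
            inherits(regressors, "laguerre_regressors"))
  if (!is.finite(q) || q < 0) stop("q must be finite and >= 0")
  if (!is.finite(r_init) || r_init <= 0) stop("r_init must be positive")
  warmup_beats <- as.integer(warmup_beats)
  skip_beats <- as.integer(skip_beats)
  if (warmup_beats < 20L) stop("warmup_beats must be >= 20")
  L <- regressors$values
  nk <- nrow(L)
  if (nk <= skip_beats + warmup_beats + 5L)
    stop("series too short for the requested warm-up")
  y <- rr$intervals[-1L]          # RR(k) for k = 1 .. nk
  p <- ncol(L) + 1L               # intercept + Laguerre orders
  X <- cbind(1, L)

  # batch least-squares initialisation over the warm-up span
  iw <- skip_beats + seq_len(warmup_beats)
  g <- qr.coef(qr(X[iw, , drop = FALSE]), y[iw])
  g[!is.finite(g)] <- 0
  P <- diag(p0_scale * r_init, p)
  Q <- diag(q, p)
  r <- r_init
  r_floor <- 1e-12

  g_hist <- matrix(NA_real_, nk, p)
  innov <- rep(NA_real_, nk)
  r_hist <- rep(NA_real_, nk)
  vwin <- numeric(0)
  swin <- numeric(0)

  for (k in (skip_beats + 1L):nk) {
    x <- X[k, ]
    P <- P + Q
    s_pred <- drop(crossprod(x, P %*% x))
    S <- s_pred + r
    if (!is.finite(S) || S <= r_floor)
      stop("numerically singular innovation variance at beat ", k)
    v <- y[k] - drop(crossprod(x, g))
    K <- drop(P %*% x) / S
    g <- g + K * v
    IKx <- diag(p) - tcrossprod(K, x)
    P <- IKx %*% P %*% t(IKx) + tcrossprod(K) * r   # Joseph form
    innov[k] <- v
    r_hist[k] <- r
    g_hist[k, ] <- g
    if (adapt_r) {
      vwin <- c(vwin, v); swin <- c(swin, s_pred)
      if (length(vwin) > r_window) {
        vwin <- vwin[-1L]; swin <- swin[-1L]
      }
      if (length(vwin) == r_window)
        r <- max(r_floor, mean(vwin^2) - mean(swin))
    }
  }

  keep <- (skip_beats + warmup_beats):nk
  structure(list(beat_index = keep,
                 beat_times = rr$beat_times[keep + 1L],
                 g0 = g_hist[keep, 1L],
                 g1 = g_hist[keep, -1L, drop = FALSE],
                 innovation = innov[keep],
                 rr = y[keep],
                 q = q, r = r_hist[keep],
                 warmup_beats = warmup_beats),
            class = "coeff_trajectory")
}

#' @export
print.coeff_trajectory <- function(x, ...) {
  cat("Time-varying Laguerre coefficient trajectory: ",
      length(x$g0), " beats (after ", x$warmup_beats, "-beat warm-up), ",
      ncol(x$g1), " Laguerre orders\n", sep = "")
  cat("innovation sd: ", signif(stats::sd(x$innovation), 4), " s\n", sep = "")
  invisible(x)
}
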