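# internal helpers

# deterministic, bounded child seed from a parent seed and stream labels;
# keeps adding subjects from perturbing existing ones
child_seed <- function(seed, subject = 0L, condition = 0L, stream = 0L) {
  h <- (as.double(seed) %% 2147483647) + 7919 * subject +
    104729 * condition + 613 * stream
  as.integer((1103515245 * (h %% 2147483647) + 12345) %% 2147483647)
}

# standardized stationary AR(1) path (mean 0, unit variance)
ar1_path <- function(n, phi = 0.9) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + innov[i + 1L]
  x
}

# standardized narrowband oscillation (resonant AR(2) at frequency f_hz
# on a 1-s grid); emulates LF / HF heart-rate rhythms
osc_path <- function(n, f_hz, r = 0.97) {
  a1 <- 2 * r * cos(2 * pi * f_hz)
  a2 <- -r^2
  e <- stats::rnorm(n + 200L)
  x <- numeric(n + 200L)
  x[1:2] <- e[1:2]
  for (i in 3:(n + 200L)) x[i] <- a1 * x[i - 1L] + a2 * x[i - 2L] + e[i]
  x <- x[-(1:200)]
  (x - mean(x)) / stats::sd(x)
}

# rolling window sum over a vector, window w, aligned to window centres;
# returns a vector of length length(x) - w + 1
roll_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

# centred running mean with edge-clipped windows
running_mean <- function(x, w) {
  n <- length(x)
  half <- as.integer(w) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear interpolation wrapper with flat extrapolation
interp_to <- function(t, v, grid) {
  stats::approx(t, v, xout = grid, rule = 2)$y
}
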