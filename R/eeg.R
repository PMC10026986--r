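#' Canonical EEG frequency bands
#'
#' Band edges in Hz: delta 1--4, theta 4--8, alpha 8--12, beta 12--30,
#' gamma 30--45.  Intervals are half-open \code{[low, high)} so each
#' boundary bin belongs to exactly one band.
#'
#' @return Named list of \code{c(low, high)} pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45))
}

#' Default 9-channel montage
#' @return Character vector of channel labels.
#' @export
eeg_channels <- function() {
  c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "POz", "P4")
}

#' Multichannel EEG recording
#'
#' @param samples Numeric matrix, samples x channels, in microvolts.
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param channels Channel labels (default the 9-channel montage).
#' @param start_time Time of the first sample in seconds (default 0).
#' @return Object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, sampling_rate = 256,
                          channels = NULL, start_time = 0) {
  samples <- as.matrix(samples)
  if (is.null(channels))
    channels <- if (ncol(samples) == 9L) eeg_channels()
                else paste0("ch", seq_len(ncol(samples)))
  if (length(channels) != ncol(samples))
    stop("channel labels do not match sample matrix")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (anyNA(samples))
    stop("missing samples; split gapped recordings before loading")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channels = channels, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording: ", nrow(x$samples), " samples x ",
      length(x$channels), " channels at ", x$sampling_rate, " Hz (",
      signif(nrow(x$samples) / x$sampling_rate, 5), " s)\n", sep = "")
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-\code{order} Butterworth band-pass (default 0.5--45 Hz,
#' order 4) forward and backward per channel, so the filter is zero-phase.
#' Zero-phase filtering avoids introducing band-power lags that would bias
#' the directional coupling estimates downstream.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order Filter order (default 4).
#' @return A filtered \code{eeg_recording}.
#' @export
bandpass_eeg <- function(rec, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("high edge ", high, " Hz at or above Nyquist (",
                        nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(rec$samples, 2L, function(ch)
    signal::filtfilt(bf, ch))
  rec$samples <- out
  rec
}

#' Short-time Fourier power spectrogram
#'
#' Hann-tapered STFT with the study geometry: window 2 s, 50% overlap,
#' giving a 1-s time step and 0.5-Hz frequency spacing at 256 Hz.  Power is
#' normalised by the window energy so the one-sided sum over frequency
#' matches the windowed-signal variance (Parseval), in microvolt^2.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 2).
#' @param overlap_frac Fractional overlap in [0, 1) (default 0.5).
#' @return Object of class \code{eeg_spectrogram}: list with \code{times}
#'   (window centres, s), \code{freqs} (Hz), \code{power} (array
#'   time x frequency x channel), \code{channels}.
#' @export
stft_power <- function(rec, window_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  nwin <- window_s * fs
  if (abs(nwin - round(nwin)) > 1e-9 || round(nwin) < 16)
    stop("window_s * sampling_rate must be an integer >= 16")
  nwin <- as.integer(round(nwin))
  hop <- as.integer(round(nwin * (1 - overlap_frac)))
  if (hop < 1L) stop("overlap too large")
  n <- nrow(rec$samples)
  if (n < nwin) stop("recording shorter than one window")
  starts <- seq(1L, n - nwin + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / nwin))  # periodic Hann
  wnorm <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nwin
  scale <- rep(2, nfreq)
  scale[1L] <- 1
  if (nwin %% 2L == 0L) scale[nfreq] <- 1
  nch <- ncol(rec$samples)
  pow <- array(0, dim = c(length(starts), nfreq, nch))
  for (ci in seq_len(nch)) {
    x <- rec$samples[, ci]
    for (si in seq_along(starts)) {
      seg <- x[starts[si]:(starts[si] + nwin - 1L)] * w
      sp <- stats::fft(seg)[seq_len(nfreq)]
      # one-sided power normalised so the sum over frequency equals
      # the window-energy-normalised variance (Parseval)
      pow[si, , ci] <- scale * (Mod(sp)^2) / (wnorm * nwin)
    }
  }
  times <- rec$start_time + (starts - 1L + nwin / 2) / fs
  structure(list(times = times, freqs = freqs, power = pow,
                 channels = rec$channels),
            class = "eeg_spectrogram")
}

#' Integrate a spectrogram within frequency bands
#'
#' Sums spectrogram power over the bins with \code{low <= f < high} for
#' each band (half-open intervals; the upper edge belongs to the next
#' band).
#'
#' @param spec An \code{eeg_spectrogram}.
#' @param band_defs Named list of \code{c(low, high)} pairs in Hz
#'   (default [eeg_bands()]).
#' @return A [band_power_series()].
#' @export
integrate_bands <- function(spec, band_defs = eeg_bands()) {
  stopifnot(inherits(spec, "eeg_spectrogram"))
  fmax <- max(spec$freqs)
  nt <- length(spec$times)
  nch <- length(spec$channels)
  pow <- array(0, dim = c(nt, nch, length(band_defs)),
               dimnames = list(NULL, spec$channels, names(band_defs)))
  for (bi in seq_along(band_defs)) {
    bd <- band_defs[[bi]]
    if (bd[2] > fmax + 1e-9)
      stop("band ", names(band_defs)[bi], " extends beyond the ",
           "spectrogram range (", fmax, " Hz)")
    sel <- spec$freqs >= bd[1] - 1e-9 & spec$freqs < bd[2] - 1e-9
    pow[, , bi] <- apply(spec$power[, sel, , drop = FALSE], c(1, 3), sum)
  }
  band_power_series(grid = spec$times, power = pow,
                    channels = spec$channels, bands = names(band_defs))
}

#' Time-resolved EEG band-power series
#'
#' @param grid Uniform time stamps in seconds (1-s step expected by the
#'   coupling stage).
#' @param power Array time x channel x band, microvolt^2, finite and >= 0.
#' @param channels,bands Dimension labels.
#' @return Object of class \code{band_power_series}.
#' @export
band_power_series <- function(grid, power, channels, bands) {
  grid <- as.numeric(grid)
  if (length(grid) > 1L) {
    steps <- diff(grid)
    if (any(abs(steps - steps[1]) > 1e-9))
      stop("band-power grid must be uniform")
  }
  if (!is.array(power) || length(dim(power)) != 3L)
    stop("power must be a time x channel x band array")
  if (dim(power)[1] != length(grid)) stop("grid/power length mismatch")
  if (any(!is.finite(power)) || any(power < 0))
    stop("band power must be finite and non-negative")
  dimnames(power) <- list(NULL, channels, bands)
  structure(list(grid = grid, power = power, channels = channels,
                 bands = bands),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat("Band-power series: ", length(x$grid), " frames x ",
      length(x$channels), " channels x ", length(x$bands), " bands\n",
      sep = "")
  invisible(x)
}

#' Full band-power extraction from a raw EEG recording
#'
#' Chains [bandpass_eeg()], [stft_power()] and [integrate_bands()] with
#' the study defaults.
#'
#' @param rec An [eeg_recording()].
#' @param low,high,order Band-pass settings (defaults 0.5--45 Hz, order 4).
#' @param window_s,overlap_frac STFT settings (defaults 2 s, 50%).
#' @param band_defs Band definitions (default [eeg_bands()]).
#' @return A [band_power_series()].
#' @export
eeg_bandpower <- function(rec, low = 0.5, high = 45, order = 4L,
                          window_s = 2, overlap_frac = 0.5,
                          band_defs = eeg_bands()) {
  integrate_bands(stft_power(bandpass_eeg(rec, low, high, order),
                             window_s, overlap_frac),
                  band_defs)
}

#' Read / write band-power series as delimited text
#'
#' Long format with header \code{t_s, channel, band, power_uv2}.
#'
#' @param path File path.
#' @param expect_bands,expect_channels Optional label sets that must all
#'   be present; a missing band or channel aborts naming it and the file.
#' @return \code{load_bandpower}: a [band_power_series()].
#' @export
load_bandpower <- function(path, expect_bands = NULL,
                           expect_channels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "channel", "band", "power_uv2")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  bad <- which(!is.finite(df$power_uv2) | df$power_uv2 < 0)
  if (length(bad))
    stop("invalid power value at line ", bad[1] + 1L, " of ", path)
  grid <- sort(unique(df$t_s))
  channels <- unique(df$channel)
  bands <- unique(df$band)
  miss <- setdiff(expect_bands, bands)
  if (length(miss))
    stop("band '", miss[1], "' missing from ", path)
  miss <- setdiff(expect_channels, channels)
  if (length(miss))
    stop("channel '", miss[1], "' missing from ", path)
  pow <- array(NA_real_, dim = c(length(grid), length(channels),
                                 length(bands)))
  ti <- match(df$t_s, grid)
  ci <- match(df$channel, channels)
  bi <- match(df$band, bands)
  pow[cbind(ti, ci, bi)] <- df$power_uv2
  if (anyNA(pow))
    stop("incomplete time x channel x band grid in ", path)
  band_power_series(grid, pow, channels, bands)
}

#' @rdname load_bandpower
#' @param x A [band_power_series()].
#' @export
write_bandpower <- function(x, path) {
  stopifnot(inherits(x, "band_power_series"))
  d <- dim(x$power)
  df <- data.frame(
    t_s = rep(x$grid, times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    band = rep(x$bands, each = d[1] * d[2]),
    power_uv2 = as.vector(x$power))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read raw EEG from delimited text
#'
#' Header \code{t_s} plus one column per channel; sampling rate inferred
#' from the (uniform) time stamps.
#'
#' @param path File path.
#' @return An [eeg_recording()].
#' @export
load_eeg <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"t_s" %in% names(df)) stop("expected a t_s column in ", path)
  t <- df$t_s
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop("non-uniform sampling in ", path)
  eeg_recording(as.matrix(df[, setdiff(names(df), "t_s"), drop = FALSE]),
                sampling_rate = 1 / dt[1],
                channels = setdiff(names(df), "t_s"),
                start_time = t[1])
}
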