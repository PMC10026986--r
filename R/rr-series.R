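#' RR-interval series
#'
#' Container for a heartbeat (R-to-R interval) series: strictly increasing
#' beat times in seconds and the corresponding inter-beat intervals
#' \code{RR(k) = beat_times[k + 1] - beat_times[k]}.
#'
#' Physiologically implausible intervals (outside 0.2--3.0 s) are rejected
#' at construction, as are beat times inconsistent with the intervals.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param intervals Optional numeric vector of intervals in seconds.  When
#'   omitted it is computed as \code{diff(beat_times)}; when supplied it must
#'   agree with the beat-time differences to within 1e-9 s.
#' @return An object of class \code{rr_series} with components
#'   \code{beat_times} (length n) and \code{intervals} (length n - 1).
#' @examples
#' rr <- rr_series(seq(0, 10, by = 0.8))
#' rr$intervals[1:3]
#' @export
rr_series <- function(beat_times, intervals = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L)
    stop("an RR series needs at least 2 beats")
  if (any(!is.finite(beat_times)))
    stop("non-finite beat times")
  d <- diff(beat_times)
  if (any(d <= 0))
    stop("beat times must be strictly increasing (first violation at beat ",
         which(d <= 0)[1] + 1L, ")")
  if (is.null(intervals)) {
    intervals <- d
  } else {
    intervals <- as.numeric(intervals)
    if (length(intervals) != length(beat_times) - 1L)
      stop("length(intervals) must equal length(beat_times) - 1")
    bad <- which(abs(intervals - d) > 1e-9)
    if (length(bad))
      stop("intervals disagree with beat-time differences by more than ",
           "1e-9 s (first at interval ", bad[1], ")")
  }
  out <- which(intervals <= 0.2 | intervals >= 3.0)
  if (length(out))
    stop("interval ", out[1], " (", signif(intervals[out[1]], 6),
         " s) outside the plausible (0.2, 3.0) s range")
  structure(list(beat_times = beat_times, intervals = intervals),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("RR series: ", length(x$intervals), " intervals over ",
      signif(diff(range(x$beat_times)), 6), " s, mean RR ",
      signif(mean(x$intervals), 4), " s\n", sep = "")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR series from delimited text
#'
#' Expects a header line \code{t_beat_s,rr_s}: beat time in seconds and the
#' interval ending at that beat (first row's interval may be NA).  Beat
#' times must be strictly increasing and consistent with the cumulative
#' intervals; malformed rows are reported with their line number.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return An \code{rr_series}.
#' @export
load_rr <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("t_beat_s", "rr_s")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  tb <- df$t_beat_s
  rr <- df$rr_s
  bad <- which(!is.finite(tb))
  if (length(bad))
    stop("non-numeric beat time at line ", bad[1] + 1L, " of ", path)
  neg <- which(is.finite(rr) & rr <= 0)
  if (length(neg))
    stop("non-positive RR interval at line ", neg[1] + 1L, " of ", path)
  ints <- rr[-1]
  if (any(!is.finite(ints)))
    stop("missing RR interval at line ",
         which(!is.finite(rr[-1]))[1] + 2L, " of ", path)
  mis <- which(abs(ints - diff(tb)) > 1e-9)
  if (length(mis))
    stop("beat times and cumulative intervals disagree by more than 1e-9 s ",
         "at line ", mis[1] + 2L, " of ", path)
  rr_series(tb, ints)
}

#' Write an RR series as delimited text
#'
#' Inverse of [load_rr()]: columns \code{t_beat_s, rr_s} with the interval
#' ending at each beat (NA for the first beat).
#'
#' @param rr An \code{rr_series}.
#' @param path Output file path.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  df <- data.frame(t_beat_s = rr$beat_times,
                   rr_s = c(NA, rr$intervals))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
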