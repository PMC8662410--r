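#' Apply recorded clock offsets to a loaded recording
#'
#' Maps each stream's raw source-clock timestamps onto the recorder's clock:
#' `corrected = raw + offset_at(series, raw)`, with the offset series
#' interpolated piecewise-linearly ([offset_at()]). Streams without any
#' recorded offsets — e.g. from a file killed before the first measurement —
#' keep their raw timestamps and are flagged `synchronized = FALSE`.
#'
#' Offsets are indexed by consumer-clock time but evaluated at the raw source
#' timestamps; since offsets change by at most a few parts per million per
#' second, the error of this substitution is second-order and far below the
#' probe noise.
#'
#' @param recording An `xdf_recording` from [read_xdf()].
#' @return The recording with, per stream, `corrected_timestamps` and a
#'   logical `synchronized` added; class `synchronized_recording` prepended.
#' @export
synchronize <- function(recording) {
  stopifnot(inherits(recording, "xdf_recording"))
  for (sid in names(recording$streams)) {
    s <- recording$streams[[sid]]
    series <- s$clock_offsets
    if ((is.null(series) || nrow(series) == 0) && !is.null(s$footer)) {
      series <- s$footer$offsets
    }
    if (is.null(series) || nrow(series) == 0) {
      s$corrected_timestamps <- s$timestamps
      s$synchronized <- FALSE
    } else {
      s$corrected_timestamps <- s$timestamps + offset_at(series, s$timestamps)
      s$synchronized <- TRUE
    }
    recording$streams[[sid]] <- s
  }
  class(recording) <- unique(c("synchronized_recording", class(recording)))
  recording
}

#' Default gap threshold for segmentation and gap detection
#'
#' Twice the nominal sampling interval or 500 ms, whichever is larger.
#'
#' @param nominal_srate Nominal sampling rate (Hz).
#' @export
gap_threshold <- function(nominal_srate) {
  if (nominal_srate <= 0) return(Inf)
  max(2 / nominal_srate, 0.5)
}

#' Dejitter timestamps by per-segment linear regression
#'
#' Splits the timestamp vector into contiguous segments wherever consecutive
#' spacing exceeds `threshold`, then replaces the timestamps of each segment
#' by the least-squares line of timestamp against sample index. This removes
#' per-sample timestamping noise while preserving the segment's span and the
#' sample count, and never moves a timestamp across a segment boundary.
#'
#' @param timestamps Numeric timestamps (s), non-decreasing, length >= 2.
#' @param nominal_srate Nominal rate (Hz); `0` (irregular) returns the input
#'   unchanged with a warning.
#' @param threshold Gap threshold (s); default [gap_threshold()].
#' @return List with `timestamps` (regularized) and `segments`, a data frame
#'   of `start_index`/`end_index` per contiguous segment.
#' @export
dejitter <- function(timestamps, nominal_srate,
                     threshold = gap_threshold(nominal_srate)) {
  n <- length(timestamps)
  stopifnot(n >= 2)
  if (nominal_srate <= 0) {
    warning("irregular stream (nominal_srate = 0): timestamps returned unchanged")
    return(list(timestamps = timestamps,
                segments = data.frame(start_index = 1L, end_index = n)))
  }
  breaks <- which(diff(timestamps) > threshold)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- timestamps
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    m <- i1 - i0 + 1L
    if (m < 2L) next
    idx <- seq_len(m) - 1
    ts <- timestamps[i0:i1]
    # closed-form least squares of ts ~ idx
    mx <- mean(idx); my <- mean(ts)
    slope <- sum((idx - mx) * (ts - my)) / sum((idx - mx)^2)
    out[i0:i1] <- my + slope * (idx - mx)
  }
  list(timestamps = out,
       segments = data.frame(start_index = starts, end_index = ends))
}

#' Effective sampling rate from timestamps or footer statistics
#'
#' `(N - 1) / (last - first)`: exact for regular sampling and the estimator
#' the recorder stores in the file footer.
#'
#' @param x Either a numeric timestamp vector (length >= 2) or a stream footer
#'   list with `sample_count`, `first_timestamp`, `last_timestamp`.
#' @return Rate in Hz, or `NA_real_` when undefined (< 2 samples).
#' @examples
#' effective_srate(seq(0, 1, length.out = 251))  # 250 Hz
#' @export
effective_srate <- function(x) {
  if (is.list(x)) {
    n <- x$sample_count
    if (is.null(n) || n < 2) return(NA_real_)
    return((n - 1) / (x$last_timestamp - x$first_timestamp))
  }
  n <- length(x)
  if (n < 2) return(NA_real_)
  (n - 1) / (x[n] - x[1])
}

#' Detect gaps (lost samples) in a stream
#'
#' Flags every inter-sample interval larger than `threshold` and estimates the
#' number of samples a regular stream would have delivered in each gap.
#'
#' @param timestamps Numeric timestamps (s), non-decreasing.
#' @param nominal_srate Nominal rate (Hz); `0` yields an empty report flagged
#'   `irregular`.
#' @param threshold Gap threshold (s); default [gap_threshold()].
#' @return A `gap_report`: data frame of `gap_start`/`gap_duration` with
#'   attributes `total_missing_expected_samples` and `irregular`.
#' @export
detect_gaps <- function(timestamps, nominal_srate,
                        threshold = gap_threshold(nominal_srate)) {
  if (nominal_srate <= 0 || length(timestamps) < 2) {
    rep <- data.frame(gap_start = numeric(), gap_duration = numeric())
    attr(rep, "total_missing_expected_samples") <- 0
    attr(rep, "irregular") <- nominal_srate <= 0
    class(rep) <- c("gap_report", "data.frame")
    return(rep)
  }
  d <- diff(timestamps)
  idx <- which(d > threshold)
  rep <- data.frame(gap_start = timestamps[idx], gap_duration = d[idx])
  attr(rep, "total_missing_expected_samples") <-
    sum(pmax(0, round(rep$gap_duration * nominal_srate - 1)))
  attr(rep, "irregular") <- FALSE
  class(rep) <- c("gap_report", "data.frame")
  rep
}

#' Resample streams onto a common time grid
#'
#' Builds a regular grid at `target_rate` over the intersection of the
#' streams' time ranges and linearly interpolates every channel of every
#' stream onto it — the numeric equivalent of plotting streams with different
#' effective rates on one time axis. Grid spacing is exactly
#' `1 / target_rate`.
#'
#' @param streams List of streams, each a list with `timestamps` (typically
#'   corrected) and `values` (samples x channels matrix).
#' @param target_rate Grid rate (Hz).
#' @return List with `grid` (times), `streams` (list of interpolated
#'   matrices) and `overlap` (`c(start, end)`).
#' @export
align_streams <- function(streams, target_rate) {
  stopifnot(length(streams) >= 2, target_rate > 0)
  firsts <- vapply(streams, function(s) s$timestamps[1], numeric(1))
  lasts <- vapply(streams, function(s) s$timestamps[length(s$timestamps)],
                  numeric(1))
  start <- max(firsts); end <- min(lasts)
  if (end <= start) {
    stop(sprintf(
      "streams do not overlap in time: ranges [%s] vs [%s]",
      paste(sprintf("%.3f-%.3f", firsts, lasts), collapse = "], ["),
      sprintf("intersection %.3f > %.3f", start, end)))
  }
  m <- floor((end - start) * target_rate)
  grid <- start + (0:m) / target_rate
  out <- lapply(streams, function(s) {
    apply(s$values, 2, function(col) {
      stats::approx(s$timestamps, col, xout = grid, ties = "ordered")$y
    })
  })
  list(grid = grid, streams = out, overlap = c(start, end))
}

#' Pearson correlation between two equal-length channels
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return Pearson product-moment correlation, or `NA_real_` if either input
#'   has zero variance (undefined).
#' @export
channel_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Per-channel correlations of two aligned streams over a trimmed window
#'
#' Drops `edge_trim` seconds at each end of the overlap before correlating, to
#' keep interpolation edge effects out of the comparison.
#'
#' @param aligned Result of [align_streams()] with exactly two streams.
#' @param edge_trim Seconds trimmed from each end (default 1).
#' @return Numeric vector of per-channel correlations.
#' @export
aligned_correlations <- function(aligned, edge_trim = 1) {
  grid <- aligned$grid
  keep <- grid >= (aligned$overlap[1] + edge_trim) &
    grid <= (aligned$overlap[2] - edge_trim)
  if (sum(keep) < 3) stop("overlap too short after edge trimming")
  a <- aligned$streams[[1]][keep, , drop = FALSE]
  b <- aligned$streams[[2]][keep, , drop = FALSE]
  stopifnot(ncol(a) == ncol(b))
  vapply(seq_len(ncol(a)), function(j) channel_correlation(a[, j], b[, j]),
         numeric(1))
}

#' One-line per-stream summary of a recording
#'
#' @param recording An `xdf_recording` (synchronized or not).
#' @return Data frame with name, type, sample count, first/last timestamp,
#'   effective rate, number of gaps and synchronization flag.
#' @export
recording_summary <- function(recording) {
  rows <- lapply(recording$streams, function(s) {
    ts <- s$corrected_timestamps %||% s$timestamps
    gaps <- detect_gaps(ts, s$info$nominal_srate)
    data.frame(
      name = s$info$name, type = s$info$stream_type,
      n_samples = s$n_samples,
      first = if (s$n_samples) ts[1] else NA_real_,
      last = if (s$n_samples) ts[length(ts)] else NA_real_,
      effective_srate = effective_srate(ts),
      n_gaps = nrow(gaps),
      footer = !is.null(s$footer),
      synchronized = isTRUE(s$synchronized))
  })
  do.call(rbind, rows)
}
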