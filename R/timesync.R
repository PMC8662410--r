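#' Raw NTP-style offset from one round-trip probe
#'
#' Given the four timestamps of a request/reply round trip — consumer send
#' `t0`, source receive `t1`, source reply `t2`, consumer receive `t3` — the
#' classical estimate of the source clock minus the consumer clock is
#' `((t1 - t0) + (t2 - t3)) / 2`, which is exact whenever the outbound and
#' return transport delays are equal.
#'
#' @param t0,t1,t2,t3 Probe timestamps in seconds (vectorized).
#' @return Estimated `source - consumer` clock difference (s).
#' @examples
#' ntp_offset(100.000, 102.005, 102.006, 100.011)  # source 2 s ahead -> 2
#' @export
ntp_offset <- function(t0, t1, t2, t3) {
  ((t1 - t0) + (t2 - t3)) / 2
}

#' Measure the clock offset between an inlet's consumer and its source
#'
#' Runs `n_probes` simulated round trips through the outlet's
#' [transport_delay()] model and combines them with a median, which discards
#' probes that hit an asymmetric delay outlier. The returned `offset` follows
#' the convention used throughout this package: consumer clock minus source
#' clock, so that `corrected = raw_source_timestamp + offset`.
#'
#' If the source has terminated, probes time out: the measurement is skipped
#' and `NULL` is returned (synchronization degrades but recording continues).
#'
#' @param inlet A [StreamInlet].
#' @param n_probes Number of round trips (default 5).
#' @param probe_spacing Time between successive probes (s).
#' @param tau True time at which the measurement starts; defaults to the
#'   registry's current simulation time.
#' @param clock_consumer,clock_source Clocks to probe; default to the inlet's
#'   consumer clock and the outlet's device clock.
#' @param delay [transport_delay()] model; defaults to the outlet's.
#' @return A list with `collection_time` (consumer clock, s) and `offset`
#'   (consumer - source, s), or `NULL` on timeout.
#' @export
measure_offset <- function(inlet, n_probes = 5, probe_spacing = 0.01,
                           tau = NULL,
                           clock_consumer = NULL, clock_source = NULL,
                           delay = NULL) {
  stopifnot(n_probes >= 1)
  if (inlet$outlet$is_terminated()) return(NULL)
  tau <- tau %||% inlet$outlet$registry$now()
  clock_consumer <- clock_consumer %||% inlet$clock
  clock_source <- clock_source %||% inlet$outlet$clock
  delay <- delay %||% inlet$outlet$delay

  theta <- numeric(n_probes)
  t3s <- numeric(n_probes)
  for (i in seq_len(n_probes)) {
    tau_i <- tau + (i - 1) * probe_spacing
    d1 <- delay$base + abs(stats::rnorm(1, 0, delay$jitter_sd))
    d2 <- delay$base + abs(stats::rnorm(1, 0, delay$jitter_sd))
    t0 <- clock_consumer$read(tau_i)
    t1 <- clock_source$read(tau_i + d1)
    t2 <- clock_source$read(tau_i + d1 + delay$proc)
    t3 <- clock_consumer$read(tau_i + d1 + delay$proc + d2)
    theta[i] <- ntp_offset(t0, t1, t2, t3)
    t3s[i] <- t3
  }
  med <- stats::median(theta)
  # consumer time at the probe realizing (or closest to) the median estimate
  collection_time <- t3s[which.min(abs(theta - med))]
  list(collection_time = collection_time, offset = -med)
}

#' Ordered series of clock-offset records for one stream
#'
#' @param collection_time Consumer-clock times (s), strictly increasing.
#' @param offset Offsets (consumer - source, s).
#' @param stream_uid Optional stream uid carried as an attribute.
#' @return A data frame of class `offset_series`.
#' @export
offset_series <- function(collection_time = numeric(),
                          offset = numeric(), stream_uid = NULL) {
  stopifnot(length(collection_time) == length(offset))
  if (length(collection_time) > 1 && any(diff(collection_time) <= 0)) {
    stop("offset records must be strictly increasing in collection_time")
  }
  structure(
    data.frame(collection_time = as.numeric(collection_time),
               offset = as.numeric(offset)),
    stream_uid = stream_uid,
    class = c("offset_series", "data.frame")
  )
}

#' Interpolate a clock-offset series at given consumer-clock times
#'
#' Piecewise-linear interpolation between bracketing records, with constant
#' extrapolation beyond the first and last record. This tracks slow,
#' not-necessarily-linear drift; a single global line can be obtained by
#' fitting the series directly if preferred.
#'
#' @param series An [offset_series()] (or data frame with `collection_time`
#'   and `offset` columns) with at least one record.
#' @param t Consumer-clock query times (s).
#' @return Offsets (s) at `t`.
#' @export
offset_at <- function(series, t) {
  if (is.null(series) || nrow(series) == 0) {
    stop("empty offset series: no synchronization possible")
  }
  if (nrow(series) == 1) {
    return(rep(series$offset[1], length(t)))
  }
  stats::approx(series$collection_time, series$offset, xout = t,
                rule = 2, ties = "ordered")$y
}
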