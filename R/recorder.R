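#' Recorder configuration
#'
#' Defaults follow the recording application being modelled: incoming samples
#' are buffered for 500 ms between file flushes, and clock offsets against the
#' recorder's (master) clock are measured every 5 s. Boundary markers are
#' written every 10 s to aid recovery of partially written files.
#'
#' @param flush_interval Buffer flush interval (s), > 0.
#' @param offset_interval Clock-offset measurement interval (s), > 0.
#' @param boundary_interval Boundary-chunk interval (s); `Inf` disables.
#' @param filename_base Base name for [make_filename()].
#' @param dir Directory for the output file.
#' @param clock Consumer (master) [VirtualClock] of the recorder.
#' @param n_probes Round trips per offset measurement.
#' @return A `recorder_config` list.
#' @export
recorder_config <- function(flush_interval = 0.5, offset_interval = 5,
                            boundary_interval = 10,
                            filename_base = "recording", dir = tempdir(),
                            clock = ideal_clock(), n_probes = 5) {
  stopifnot(flush_interval > 0, offset_interval > 0, boundary_interval > 0)
  structure(list(flush_interval = flush_interval,
                 offset_interval = offset_interval,
                 boundary_interval = boundary_interval,
                 filename_base = filename_base, dir = dir,
                 clock = clock, n_probes = n_probes),
            class = "recorder_config")
}

#' Read a recorder configuration from a key=value text file
#'
#' Recognized keys: `flush_interval`, `offset_interval`, `boundary_interval`,
#' `filename_base`, `dir`, `streams` (comma-separated name/type/source_id
#' glob patterns used by `RecordingSession$select_streams()`). Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A list with `config` (a [recorder_config()]) and `stream_patterns`.
#' @export
read_recorder_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(named[[key]])) default else as.numeric(named[[key]])
  }
  cfg <- recorder_config(
    flush_interval = num("flush_interval", 0.5),
    offset_interval = num("offset_interval", 5),
    boundary_interval = num("boundary_interval", 10),
    filename_base = named[["filename_base"]] %||% "recording",
    dir = named[["dir"]] %||% tempdir())
  patterns <- if (is.null(named[["streams"]])) "*" else {
    trimws(strsplit(named[["streams"]], ",", fixed = TRUE)[[1]])
  }
  list(config = cfg, stream_patterns = patterns)
}

#' Build a unique, timestamped recording filename
#'
#' The base name is sanitized (path separators stripped; empty bases fall back
#' to `"recording"`) and suffixed with the wall-clock date and time so an
#' existing recording is never overwritten. If the resulting name still
#' collides — two recordings started within the same second — a counter
#' (`_2`, `_3`, ...) is appended.
#'
#' @param base Recording name chosen by the user.
#' @param now Wall-clock time stamped into the name (a `POSIXct`).
#' @param dir Directory the file will live in.
#' @return Full file path ending in `.xdf` that does not yet exist.
#' @examples
#' make_filename("run", as.POSIXct("2021-11-16 13:05:00", tz = "UTC"))
#' @export
make_filename <- function(base, now = Sys.time(), dir = ".") {
  base <- gsub("[/\\\\]", "", base)
  if (!nzchar(trimws(base))) base <- "recording"
  stamp <- format(now, "%Y-%m-%d_%H-%M-%S")
  path <- file.path(dir, sprintf("%s_%s.xdf", base, stamp))
  k <- 2L
  while (file.exists(path)) {
    path <- file.path(dir, sprintf("%s_%s_%d.xdf", base, stamp, k))
    k <- k + 1L
  }
  path
}

#' Recording session: discover, select, buffer, flush, synchronize
#'
#' The recorder equivalent of the modelled mobile app: it resolves streams
#' from a [StreamRegistry], opens one inlet per selected stream, writes each
#' stream's header, then alternates two independent loops on its (simulated)
#' schedule — a flush loop that empties the per-stream buffers into Samples
#' chunks every `flush_interval`, and an offset loop that measures the
#' consumer-minus-source clock offset for every stream every
#' `offset_interval`. `stop()` writes per-stream footers (sample count,
#' first/last timestamp, measured rate, full offset series) and closes the
#' file; `kill()` emulates abnormal termination: the file is left on disk
#' without footers, losing at most one flush interval of buffered samples.
#'
#' All scheduling runs on the registry's simulated time, so timing behaviour
#' is exactly reproducible; see [simulate_session()] for the event loop.
#'
#' @export
RecordingSession <- R6::R6Class("RecordingSession",
  public = list(
    #' @field registry The [StreamRegistry] to record from.
    registry = NULL,
    #' @field config The session's [recorder_config()].
    config = NULL,
    #' @field state One of `"idle"`, `"recording"`, `"stopped"`, `"killed"`.
    state = "idle",
    #' @field path Output file path (set by `start()`).
    path = NULL,

    #' @param registry A [StreamRegistry].
    #' @param config A [recorder_config()].
    initialize = function(registry, config = recorder_config()) {
      self$registry <- registry
      self$config <- config
      private$selected <- list()
    },

    #' @description Select streams to record by glob patterns matched against
    #'   stream name, type and source_id. Default selects everything resolved.
    #' @param patterns Character vector of glob patterns.
    #' @return The selected [stream_info()] list (invisibly).
    select_streams = function(patterns = "*") {
      infos <- self$registry$resolve_streams()
      rx <- utils::glob2rx(patterns)
      keep <- vapply(infos, function(i) {
        any(vapply(rx, function(r) {
          grepl(r, i$name) || grepl(r, i$stream_type) || grepl(r, i$source_id)
        }, logical(1)))
      }, logical(1))
      private$selected <- infos[keep]
      invisible(private$selected)
    },

    #' @description Start recording: create the file, write stream headers,
    #'   take an immediate offset measurement for every stream, and schedule
    #'   the flush/offset/boundary loops.
    #' @param wall_time Wall-clock time used for the file name.
    start = function(wall_time = Sys.time()) {
      if (self$state != "idle") stop("start() called on a ", self$state, " session")
      now <- self$registry$now()
      self$path <- make_filename(self$config$filename_base, wall_time,
                                 self$config$dir)
      private$writer <- XdfWriter$new(self$path)
      private$streams <- list()
      sid <- 0L
      for (info in private$selected) {
        sid <- sid + 1L
        private$writer$write_stream_header(sid, info)
        inlet <- self$registry$open_inlet(info$uid, clock = self$config$clock)
        private$streams[[sid]] <- list(
          stream_id = sid, info = info, inlet = inlet,
          count = 0, first_ts = NA_real_, last_ts = NA_real_,
          offsets = offset_series(stream_uid = info$uid))
      }
      self$state <- "recording"
      private$t_start <- now
      private$next_flush <- now + self$config$flush_interval
      private$next_offset <- now + self$config$offset_interval
      private$next_boundary <- now + self$config$boundary_interval
      self$offset_cycle()  # immediate measurement at t = 0
      invisible(self)
    },

    #' @description Earliest pending scheduled event.
    #' @return List with `tau` and `kind`, or `NULL` when not recording.
    next_event = function() {
      if (self$state != "recording") return(NULL)
      times <- c(offset = private$next_offset, boundary = private$next_boundary,
                 flush = private$next_flush)
      kind <- names(times)[which.min(times)]
      list(tau = unname(times[[kind]]), kind = kind)
    },

    #' @description Fire all scheduled events due up to simulated time `tau`
    #'   in order (offset before flush on ties, so a flush always captures a
    #'   consistent buffer).
    #' @param tau Simulated time to advance to (s).
    process_until = function(tau) {
      while (self$state == "recording") {
        ev <- self$next_event()
        if (is.null(ev) || ev$tau > tau + 1e-12) break
        self$registry$set_time(max(ev$tau, self$registry$now()))
        switch(ev$kind,
          offset = {
            self$offset_cycle()
            private$next_offset <- private$next_offset + self$config$offset_interval
          },
          boundary = {
            private$writer$write_boundary()
            private$next_boundary <- private$next_boundary + self$config$boundary_interval
          },
          flush = {
            self$flush_cycle()
            private$next_flush <- private$next_flush + self$config$flush_interval
          })
      }
      invisible(self)
    },

    #' @description Empty every stream's inlet buffer into one Samples chunk
    #'   (streams with nothing buffered are skipped this cycle).
    #' @return Number of samples written this cycle (invisibly).
    flush_cycle = function() {
      private$assert_recording()
      written <- 0L
      for (i in seq_along(private$streams)) {
        st <- private$streams[[i]]
        chunk <- st$inlet$pull_chunk()
        if (is.null(chunk)) next
        private$writer$write_samples(st$stream_id, chunk$values, chunk$timestamps)
        n <- nrow(chunk$values)
        written <- written + n
        if (is.na(st$first_ts)) st$first_ts <- chunk$timestamps[1]
        st$last_ts <- chunk$timestamps[n]
        st$count <- st$count + n
        private$streams[[i]] <- st
      }
      private$flush_times <- c(private$flush_times, self$registry$now())
      invisible(written)
    },

    #' @description Measure the clock offset of every stream and write one
    #'   ClockOffset chunk per stream. A timed-out probe (terminated source)
    #'   is skipped; the series recorded so far is retained.
    #' @return Number of streams measured (invisibly).
    offset_cycle = function() {
      private$assert_recording()
      measured <- 0L
      for (i in seq_along(private$streams)) {
        st <- private$streams[[i]]
        rec <- measure_offset(st$inlet, n_probes = self$config$n_probes)
        if (is.null(rec)) {
          private$offset_skips <- private$offset_skips + 1L
          next
        }
        st$offsets <- offset_series(
          c(st$offsets$collection_time, rec$collection_time),
          c(st$offsets$offset, rec$offset),
          stream_uid = st$info$uid)
        private$writer$write_clock_offset(st$stream_id, rec$collection_time,
                                          rec$offset)
        private$streams[[i]] <- st
        measured <- measured + 1L
      }
      invisible(measured)
    },

    #' @description Stop regularly: final flush, per-stream footers with
    #'   `measured_srate = (N - 1) / (last - first)` (nominal rate fallback
    #'   for fewer than 2 samples), then close the file.
    #' @return The file path (invisibly).
    stop = function() {
      private$assert_recording()
      self$flush_cycle()
      footers <- lapply(private$streams, function(st) {
        srate <- if (st$count >= 2 && st$last_ts > st$first_ts) {
          (st$count - 1) / (st$last_ts - st$first_ts)
        } else st$info$nominal_srate
        list(stream_id = st$stream_id,
             first_timestamp = if (is.na(st$first_ts)) 0 else st$first_ts,
             last_timestamp = if (is.na(st$last_ts)) 0 else st$last_ts,
             sample_count = st$count,
             measured_srate = srate,
             offsets = st$offsets)
      })
      private$writer$finish(footers)
      self$state <- "stopped"
      invisible(self$path)
    },

    #' @description Abnormal termination: close the file as-is, without
    #'   footers, discarding anything still buffered in the inlets.
    #' @return The file path (invisibly).
    kill = function() {
      private$assert_recording()
      private$writer$kill()
      self$state <- "killed"
      invisible(self$path)
    },

    #' @description Simulated times at which flush cycles completed.
    flush_log = function() private$flush_times,

    #' @description Recorded offset series per stream id.
    offset_log = function() lapply(private$streams, `[[`, "offsets"),

    #' @description Samples written per stream id.
    sample_counts = function() vapply(private$streams, `[[`, numeric(1), "count"),

    #' @description Number of offset measurements skipped due to timeouts.
    n_offset_skipped = function() private$offset_skips
  ),
  private = list(
    selected = NULL, streams = NULL, writer = NULL,
    t_start = NA_real_, next_flush = Inf, next_offset = Inf,
    next_boundary = Inf, flush_times = numeric(), offset_skips = 0L,

    assert_recording = function() {
      if (self$state != "recording") {
        stop("session is ", self$state, ", not recording")
      }
    }
  )
)
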