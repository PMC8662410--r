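#' Stream metadata
#'
#' Everything a recorder needs to handle a stream without stream-specific
#' logic: identity, channel layout and the nominal sampling rate. This is the
#' in-memory equivalent of the XML stream header stored in an XDF file.
#'
#' @param name Human-readable stream name.
#' @param stream_type Content type, e.g. `"EEG"`, `"rotation"`, `"sine"`.
#' @param channel_count Number of channels (>= 1).
#' @param nominal_srate Advertised sampling rate in Hz; `0` marks an
#'   irregularly sampled stream.
#' @param channel_format One of `"float32"`, `"double64"`, `"int32"`,
#'   `"string"`.
#' @param source_id Stable identifier of the physical source (device+sensor).
#' @param uid Unique identifier of this outlet instance; generated when `NULL`.
#' @return A `stream_info` list.
#' @examples
#' stream_info("sines", "sine", 10, 250, "double64", "phone1-sine")
#' @export
stream_info <- function(name, stream_type, channel_count, nominal_srate,
                        channel_format = c("float32", "double64", "int32",
                                           "string"),
                        source_id, uid = NULL) {
  channel_format <- match.arg(channel_format)
  if (!is_scalar_string(name)) stop("'name' must be a non-empty string")
  if (!is_scalar_string(stream_type)) stop("'stream_type' must be a non-empty string")
  if (!is_scalar_number(channel_count) || channel_count < 1 ||
      channel_count != round(channel_count)) {
    stop("'channel_count' must be a positive integer")
  }
  if (!is_scalar_number(nominal_srate) || nominal_srate < 0) {
    stop("'nominal_srate' must be a non-negative number (0 = irregular)")
  }
  if (!is_scalar_string(source_id)) stop("'source_id' must be a non-empty string")
  if (is.null(uid)) {
    uid <- sprintf("%s-%s", source_id,
                   paste(format(as.hexmode(sample.int(16L, 12, replace = TRUE) - 1L)),
                         collapse = ""))
  }
  structure(
    list(name = name, stream_type = stream_type,
         channel_count = as.integer(channel_count),
         nominal_srate = as.numeric(nominal_srate),
         channel_format = channel_format,
         source_id = source_id, uid = uid),
    class = "stream_info"
  )
}

#' @export
print.stream_info <- function(x, ...) {
  cat(sprintf("<stream_info> %s (%s): %d ch, %g Hz nominal, %s [%s]\n",
              x$name, x$stream_type, x$channel_count, x$nominal_srate,
              x$channel_format, x$uid))
  invisible(x)
}

#' Transport delay model for clock probes
#'
#' One-way network delay applied to simulated clock-synchronization probes:
#' `base` plus the absolute value of Gaussian noise, independently per
#' direction, plus a fixed turn-around (processing) time at the source.
#'
#' @param base Baseline one-way delay (s).
#' @param jitter_sd Standard deviation of the delay noise (s).
#' @param proc Source-side turn-around time between receiving a probe and
#'   answering it (s).
#' @export
transport_delay <- function(base = 0.002, jitter_sd = 5e-4, proc = 1e-4) {
  stopifnot(base >= 0, jitter_sd >= 0, proc >= 0)
  list(base = base, jitter_sd = jitter_sd, proc = proc)
}

#' In-process stream registry
#'
#' The transport layer: outlets register here, inlets connect to them, and all
#' delivery is ordered and lossless (bounded only by queue capacity). A
#' registry also carries the current simulation time, which drives all
#' scheduling in simulated recordings.
#'
#' @export
StreamRegistry <- R6::R6Class("StreamRegistry",
  public = list(
    #' @description Create an empty registry at simulation time 0.
    initialize = function() {
      private$outlets <- list()
      private$tau <- 0
    },

    #' @description Current simulation (true) time in seconds.
    now = function() private$tau,

    #' @description Move simulation time forward (never backwards).
    #' @param tau New simulation time (s).
    set_time = function(tau) {
      stopifnot(is_scalar_number(tau), tau >= private$tau)
      private$tau <- tau
      invisible(self)
    },

    #' @description Register a new outlet.
    #' @param info A [stream_info()].
    #' @param clock Source device [VirtualClock].
    #' @param delay [transport_delay()] model for clock probes.
    #' @param buffer Outlet-side backlog capacity in samples.
    open_outlet = function(info, clock = ideal_clock(),
                           delay = transport_delay(), buffer = 32768L) {
      stopifnot(inherits(info, "stream_info"))
      if (info$uid %in% names(private$outlets)) {
        stop(sprintf("an outlet with uid '%s' is already registered", info$uid))
      }
      out <- StreamOutlet$new(info, clock, delay, self, buffer)
      private$outlets[[info$uid]] <- out
      out
    },

    #' @description Remove an outlet from the registry.
    #' @param uid Outlet uid.
    close_outlet = function(uid) {
      private$outlets[[uid]] <- NULL
      invisible(self)
    },

    #' @description List metadata of all registered streams.
    #' @param timeout Kept for API parity with networked resolvers; the
    #'   in-process registry answers immediately.
    #' @return List of [stream_info()] (possibly empty).
    resolve_streams = function(timeout = 0) {
      unname(lapply(private$outlets, function(o) o$info))
    },

    #' @description Fetch an outlet handle by uid.
    #' @param uid Outlet uid.
    get_outlet = function(uid) {
      out <- private$outlets[[uid]]
      if (is.null(out)) stop(sprintf("no outlet with uid '%s'", uid))
      out
    },

    #' @description Connect an inlet to the outlet with the given uid.
    #' @param uid Outlet uid.
    #' @param clock Consumer-side [VirtualClock].
    #' @param capacity Inlet queue capacity in samples.
    open_inlet = function(uid, clock = ideal_clock(), capacity = 32768L) {
      self$get_outlet(uid)$connect(clock, capacity)
    }
  ),
  private = list(outlets = NULL, tau = 0)
)

#' Stream outlet: the sending end of a stream
#'
#' Created through [StreamRegistry]`$open_outlet()`. Samples pushed here are
#' delivered, in order, to every connected inlet; a bounded backlog is kept so
#' inlets connecting late still receive recent samples.
#'
#' @export
StreamOutlet <- R6::R6Class("StreamOutlet",
  public = list(
    #' @field info The outlet's [stream_info()].
    info = NULL,
    #' @field clock Source device [VirtualClock].
    clock = NULL,
    #' @field delay [transport_delay()] model for clock probes.
    delay = NULL,
    #' @field registry Owning [StreamRegistry].
    registry = NULL,

    #' @param info,clock,delay,registry,buffer See [StreamRegistry].
    initialize = function(info, clock, delay, registry, buffer = 32768L) {
      self$info <- info
      self$clock <- clock
      self$delay <- delay
      self$registry <- registry
      private$buffer_cap <- as.integer(buffer)
      private$inlets <- list()
      private$backlog <- list()
      private$n_backlog <- 0L
      private$last_ts <- -Inf
    },

    #' @description Push a chunk of samples to all connected inlets.
    #' @param values Sample values: an `n x channel_count` matrix (numeric, or
    #'   character for string streams), or a single-sample vector of length
    #'   `channel_count`.
    #' @param timestamps Per-sample source-clock timestamps (s), non-decreasing.
    #'   When omitted, all samples are stamped with the device clock at the
    #'   registry's current time.
    #' @return Number of samples accepted (invisibly).
    push_chunk = function(values, timestamps = NULL) {
      if (private$terminated) {
        stop(sprintf("stream '%s': outlet has terminated", self$info$name))
      }
      if (is.null(dim(values))) {
        values <- matrix(values, nrow = 1L)
      }
      if (ncol(values) != self$info$channel_count) {
        stop(sprintf(
          "stream '%s': sample length %d does not match channel_count %d",
          self$info$name, ncol(values), self$info$channel_count))
      }
      n <- nrow(values)
      if (n == 0L) return(invisible(0L))
      if (is.null(timestamps)) {
        timestamps <- self$clock$read(rep(self$registry$now(), n))
      }
      if (length(timestamps) != n) {
        stop(sprintf("stream '%s': %d timestamps for %d samples",
                     self$info$name, length(timestamps), n))
      }
      if (any(diff(timestamps) < 0) || timestamps[1] < private$last_ts) {
        stop(sprintf("stream '%s': timestamps must be non-decreasing",
                     self$info$name))
      }
      private$last_ts <- timestamps[n]
      chunk <- list(values = values, timestamps = as.numeric(timestamps))
      # outlet-side backlog for late-joining inlets, trimmed to capacity
      private$backlog[[length(private$backlog) + 1L]] <- chunk
      private$n_backlog <- private$n_backlog + n
      while (private$n_backlog > private$buffer_cap && length(private$backlog) > 1L) {
        private$n_backlog <- private$n_backlog - nrow(private$backlog[[1L]]$values)
        private$backlog[[1L]] <- NULL
      }
      for (inl in private$inlets) inl$.receive(chunk)
      invisible(n)
    },

    #' @description Connect a new inlet (delivers the backlog first).
    #' @param clock Consumer [VirtualClock].
    #' @param capacity Queue capacity in samples.
    connect = function(clock = ideal_clock(), capacity = 32768L) {
      inl <- StreamInlet$new(self, clock, capacity)
      for (chunk in private$backlog) inl$.receive(chunk)
      private$inlets[[length(private$inlets) + 1L]] <- inl
      inl
    },

    #' @description Mark the source as terminated: no further samples, and
    #'   clock probes go unanswered ([measure_offset()] then reports a
    #'   timeout). A paused source, by contrast, simply pushes nothing.
    terminate = function() {
      private$terminated <- TRUE
      invisible(self)
    },

    #' @description Whether the source has terminated.
    is_terminated = function() private$terminated,

    #' @description Close the outlet and deregister it.
    close = function() {
      self$registry$close_outlet(self$info$uid)
      invisible(NULL)
    }
  ),
  private = list(
    inlets = NULL, backlog = NULL, n_backlog = 0L, buffer_cap = 32768L,
    last_ts = -Inf, terminated = FALSE
  )
)

#' Stream inlet: the receiving end of a stream
#'
#' Created through [StreamRegistry]`$open_inlet()` or `outlet$connect()`.
#' Holds a bounded FIFO queue of delivered samples.
#'
#' @export
StreamInlet <- R6::R6Class("StreamInlet",
  public = list(
    #' @field outlet The connected [StreamOutlet].
    outlet = NULL,
    #' @field clock Consumer-side [VirtualClock].
    clock = NULL,

    #' @param outlet,clock,capacity See [StreamRegistry]`$open_inlet()`.
    initialize = function(outlet, clock, capacity = 32768L) {
      self$outlet <- outlet
      self$clock <- clock
      private$capacity <- as.integer(capacity)
      private$queue <- list()
      private$n_queued <- 0L
      private$dropped_count <- 0L
    },

    #' @description Internal delivery hook used by the outlet.
    #' @param chunk List with `values` and `timestamps`.
    .receive = function(chunk) {
      n <- nrow(chunk$values)
      space <- private$capacity - private$n_queued
      if (space <= 0L) {
        private$dropped_count <- private$dropped_count + n
        return(invisible(0L))
      }
      if (n > space) {
        private$dropped_count <- private$dropped_count + (n - space)
        chunk <- list(values = chunk$values[seq_len(space), , drop = FALSE],
                      timestamps = chunk$timestamps[seq_len(space)])
        n <- space
      }
      private$queue[[length(private$queue) + 1L]] <- chunk
      private$n_queued <- private$n_queued + n
      invisible(n)
    },

    #' @description Number of samples currently queued.
    n_available = function() private$n_queued,

    #' @description Number of samples dropped due to a full queue.
    n_dropped = function() private$dropped_count,

    #' @description Pull everything queued, in push order.
    #' @return `NULL` when empty, else a list with `values` (matrix) and
    #'   `timestamps`.
    pull_chunk = function() {
      if (private$n_queued == 0L) return(NULL)
      values <- do.call(rbind, lapply(private$queue, `[[`, "values"))
      timestamps <- unlist(lapply(private$queue, `[[`, "timestamps"),
                           use.names = FALSE)
      private$queue <- list()
      private$n_queued <- 0L
      list(values = values, timestamps = timestamps)
    }
  ),
  private = list(queue = NULL, n_queued = 0L, dropped_count = 0L, capacity = 32768L)
)
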