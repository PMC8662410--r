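#' Smooth shared motion ground truth for two-device scenarios
#'
#' A band-limited 3-channel signal standing in for the physical motion two
#' phones undergo when moved together: per channel, a sum of sinusoids with
#' seeded random frequencies (default 0.2-3 Hz), amplitudes and phases. Being
#' a pure function of true time, the same motion can be sampled by any number
#' of devices at their own rates and clocks.
#'
#' @param seed Integer seed for the component draw.
#' @param channels Number of channels (3 for motion sensors).
#' @param n_components Sinusoids per channel.
#' @param freq_range Frequency range in Hz.
#' @return A function `f(t)` mapping true times to a `length(t) x channels`
#'   matrix.
#' @export
motion_signal <- function(seed = 1, channels = 3, n_components = 6,
                          freq_range = c(0.2, 3)) {
  rng <- with_seed(seed, list(
    freqs = matrix(stats::runif(channels * n_components, freq_range[1],
                                freq_range[2]), n_components, channels),
    amps = matrix(stats::runif(channels * n_components, 0.3, 1),
                  n_components, channels),
    phases = matrix(stats::runif(channels * n_components, 0, 2 * pi),
                    n_components, channels)))
  function(t) {
    out <- matrix(0, length(t), channels)
    for (c in seq_len(channels)) {
      for (k in seq_len(n_components)) {
        out[, c] <- out[, c] + rng$amps[k, c] *
          sin(2 * pi * rng$freqs[k, c] * t + rng$phases[k, c])
      }
    }
    out
  }
}

#' Multi-channel sine source
#'
#' Emulates the signal-generator app: `channels` sine waves with distinct
#' per-channel frequencies at a nominal 250 Hz. Channel `c` emits
#' `amplitude * sin(2 pi freqs[c] t_true)`; because the signal is a function
#' of true time, two sine sources with the same frequencies but different
#' clocks emit identical values at equal true time — the ground truth behind
#' cross-device correlation checks.
#'
#' @param channels Number of channels (default 10).
#' @param nominal_srate Advertised rate in Hz (default 250).
#' @param freqs Per-channel frequencies (Hz), all distinct; defaults to
#'   1..channels Hz.
#' @param amplitude Common amplitude.
#' @param name,source_id Stream identity.
#' @return A `virtual_source`: list with `info` and `signal(t)`.
#' @export
sine_source <- function(channels = 10, nominal_srate = 250,
                        freqs = seq_len(channels), amplitude = 1,
                        name = "sine-waves", source_id = "sine-app") {
  stopifnot(length(freqs) == channels)
  if (anyDuplicated(freqs)) stop("sine channel frequencies must be distinct")
  info <- stream_info(name, "sine", channels, nominal_srate, "double64",
                      source_id, uid = paste0(source_id, "-", name))
  signal <- function(t) {
    out <- sapply(freqs, function(f) amplitude * sin(2 * pi * f * t))
    if (is.null(dim(out))) out <- matrix(out, nrow = length(t))
    out
  }
  structure(list(info = info, signal = signal, kind = "sine"),
            class = "virtual_source")
}

#' Simulated phone sensor source
#'
#' Samples a shared [motion_signal()] the way a phone sensor would. Hardware
#' sensors (gravity, accelerometer) transduce the motion directly and differ
#' across devices only by independent measurement noise. Software sensors
#' (rotation) are derived quantities interpreted by each device's firmware:
#' modelled as a one-pole low-pass of the motion with a device-specific time
#' constant and gain plus a slow device-specific wander, so that two devices
#' observing the same motion report visibly different signals — the mechanism
#' behind the lower cross-device correlation of software sensors.
#'
#' @param sensor_kind `"rotation"`, `"gravity"`, `"accelerometer"`, or
#'   `"generic"`.
#' @param motion A [motion_signal()] function.
#' @param nominal_srate Advertised rate (Hz).
#' @param hardware Logical; defaults to `FALSE` for rotation, `TRUE` otherwise.
#' @param noise_sd Measurement noise SD.
#' @param lag One-pole time constant (s) for software sensors (default 50 ms).
#' @param gain Device-specific gain for software sensors; draw once per device.
#' @param wander_amp Amplitude of the slow device-specific wander added to
#'   software sensors.
#' @param device Device label used in the stream identity.
#' @param seed Seed for the device-specific wander shape.
#' @return A `virtual_source` with `info` and `signal(t)`.
#' @export
sensor_source <- function(sensor_kind = c("rotation", "gravity",
                                          "accelerometer", "generic"),
                          motion, nominal_srate = 125,
                          hardware = NULL, noise_sd = 0.02,
                          lag = 0.05, gain = 1, wander_amp = 0.35,
                          device = "phone", seed = 1) {
  sensor_kind <- match.arg(sensor_kind)
  hardware <- hardware %||% (sensor_kind != "rotation")
  info <- stream_info(paste0(device, "-", sensor_kind), sensor_kind, 3L,
                      nominal_srate, "double64",
                      source_id = paste0(device, "-", sensor_kind),
                      uid = paste0(device, "-", sensor_kind))
  wander <- if (!hardware && wander_amp > 0) {
    motion_signal(seed = seed + 7919L, channels = 3, n_components = 3,
                  freq_range = c(0.05, 0.4))
  } else NULL
  signal <- function(t) {
    x <- motion(t)
    if (!hardware) {
      # discrete one-pole low-pass along the device's own sample times
      if (length(t) > 1) {
        dt <- c(diff(t), utils::tail(diff(t), 1))
        a <- exp(-dt / lag)
        y <- x
        for (ch in seq_len(ncol(x))) {
          acc <- x[1, ch]
          for (i in 2:nrow(x)) {
            acc <- a[i - 1] * acc + (1 - a[i - 1]) * x[i, ch]
            y[i, ch] <- acc
          }
        }
        x <- y
      }
      x <- gain * x + wander_amp * wander(t)
    }
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    }
    x
  }
  structure(list(info = info, signal = signal, kind = sensor_kind,
                 hardware = hardware),
            class = "virtual_source")
}

#' Load-dependent effective sampling rates of a simulated phone
#'
#' On the modelled platform the operating system, not the application,
#' governs sensor sampling: under processing load the delivered rate drops
#' below the nominal one, and it drops for all sensors of the device alike
#' (constant-rate audio streams being the exception). `load_preset()` ships
#' measured rate tables for the two modelled handsets at 125 Hz nominal as
#' named presets; `effective_rate_for()` looks up the device-wide effective
#' rate for a number of simultaneously active sensors.
#'
#' @param name `"samsung"` or `"huawei"`.
#' @return A `load_model`: list with `nominal` and a `rates` table keyed by
#'   active-sensor count (`one`, `three`, `all`).
#' @export
load_preset <- function(name = c("samsung", "huawei")) {
  name <- match.arg(name)
  rates <- switch(name,
    samsung = c(one = 114, three = 106, all = 95),
    huawei = c(one = 118, three = 116, all = 111))
  structure(list(device = name, nominal = 125, rates = rates,
                 constant_rate_exempt = "microphone"),
            class = "load_model")
}

#' @rdname load_preset
#' @param load A `load_model`.
#' @param n_active Number of simultaneously active sensors.
#' @export
effective_rate_for <- function(load, n_active) {
  stopifnot(inherits(load, "load_model"), n_active >= 1)
  if (n_active <= 1) load$rates[["one"]]
  else if (n_active <= 3) load$rates[["three"]]
  else load$rates[["all"]]
}

#' Assemble a virtual device
#'
#' A device bundles a clock, one or more sources (all sharing the device's
#' effective sampling rate, mirroring the platform's "decreased for all
#' sensors alike" behaviour) and an emission schedule: a constant-delay
#' polling loop whose period is `1 / effective_rate`, with optional fractional
#' interval jitter.
#'
#' @param sources List of `virtual_source` objects.
#' @param clock The device [VirtualClock].
#' @param effective_rate Achieved per-sensor rate (Hz); defaults to nominal.
#' @param interval_jitter Fractional SD of the polling interval (default 2%).
#' @param delay [transport_delay()] used for this device's clock probes.
#' @return A `virtual_device` list.
#' @export
virtual_device <- function(sources, clock = ideal_clock(),
                           effective_rate = NULL, interval_jitter = 0.02,
                           delay = transport_delay()) {
  if (inherits(sources, "virtual_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1)
  effective_rate <- effective_rate %||% sources[[1]]$info$nominal_srate
  stopifnot(effective_rate > 0)
  structure(list(sources = sources, clock = clock,
                 effective_rate = effective_rate,
                 interval_jitter = interval_jitter,
                 delay = delay, faults = list()),
            class = "virtual_device")
}

#' Inject a fault into a virtual device's schedule
#'
#' `fault_pause(t_start, t_dur)` suspends sample emission for a window while
#' the device keeps answering clock probes; `fault_terminate(t)` stops both
#' samples and probe replies from `t` on. Overlapping faults are rejected.
#'
#' @param device A [virtual_device()].
#' @param fault A `fault_pause()` or `fault_terminate()`.
#' @return The device with the fault attached.
#' @export
inject_fault <- function(device, fault) {
  stopifnot(inherits(device, "virtual_device"), inherits(fault, "device_fault"))
  for (f in device$faults) {
    if (fault$start < f$end && f$start < fault$end) {
      stop("overlapping faults on device schedule")
    }
  }
  device$faults <- c(device$faults, list(fault))
  device
}

#' @rdname inject_fault
#' @param t_start Pause start (true time, s).
#' @param t_dur Pause duration (s).
#' @export
fault_pause <- function(t_start, t_dur) {
  stopifnot(t_dur > 0)
  structure(list(kind = "pause", start = t_start, end = t_start + t_dur),
            class = "device_fault")
}

#' @rdname inject_fault
#' @param t Termination time (true time, s).
#' @export
fault_terminate <- function(t) {
  structure(list(kind = "terminate", start = t, end = Inf),
            class = "device_fault")
}

#' Generate a device's full emission ledger
#'
#' Event-driven stand-in for the device's polling thread: computes every
#' emission's true time at the device's effective rate (with interval
#' jitter), reads the device clock for the timestamps, evaluates each
#' source's signal at the true emission times, and applies any injected
#' faults. The ledger is the exact record of what the device pushes, used for
#' end-to-end conservation checks; it is a pure function of (device
#' configuration, RNG state).
#'
#' @param device A [virtual_device()].
#' @param duration Simulated duration (s).
#' @param start Start time (true time, s).
#' @return List of per-source ledgers, each with `tau` (true emission times),
#'   `timestamps` (device clock) and `values`; plus attribute `terminated_at`.
#' @export
device_ledger <- function(device, duration, start = 0) {
  stopifnot(duration > 0)
  dt <- 1 / device$effective_rate
  n_max <- ceiling(duration / dt) + 1L
  ivl <- if (device$interval_jitter > 0) {
    dt * pmax(0.1, 1 + stats::rnorm(n_max, 0, device$interval_jitter))
  } else rep(dt, n_max)
  tau <- start + cumsum(c(0, ivl))
  tau <- tau[tau < start + duration]

  terminated_at <- Inf
  for (f in device$faults) {
    if (f$kind == "pause") {
      tau <- tau[tau < f$start | tau >= f$end]
    } else {
      terminated_at <- min(terminated_at, f$start)
      tau <- tau[tau < f$start]
    }
  }

  ledgers <- lapply(device$sources, function(src) {
    timestamps <- device$clock$read(tau)
    values <- src$signal(tau)
    list(info = src$info, tau = tau, timestamps = timestamps, values = values)
  })
  names(ledgers) <- vapply(device$sources, function(s) s$info$uid, character(1))
  attr(ledgers, "terminated_at") <- terminated_at
  ledgers
}
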