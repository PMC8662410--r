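#' Validation thresholds used by the scenario harness
#'
#' The pass/fail limits applied to scenario reports, encoded once: minimum
#' cross-device channel correlation 0.9, minimum cross-file (two-recorder)
#' correlation 0.96, maximum trailing loss on abnormal termination 0.5 s,
#' clock-offset cadence 5 s and buffer flush cadence 0.5 s.
#'
#' @export
xdf_thresholds <- list(
  min_channel_r = 0.9,
  cross_file_r = 0.96,
  max_kill_loss_s = 0.5,
  offset_interval_s = 5,
  flush_interval_s = 0.5
)

#' Generic signal stream source
#'
#' Wraps an arbitrary function of true time as a `virtual_source`, e.g. a
#' simulated multichannel neural signal.
#'
#' @param name,stream_type,source_id Stream identity.
#' @param channels Channel count.
#' @param nominal_srate Advertised rate (Hz).
#' @param signal Function `f(t)` returning a `length(t) x channels` matrix.
#' @return A `virtual_source`.
#' @export
signal_source <- function(name, stream_type, channels, nominal_srate, signal,
                          source_id = name) {
  info <- stream_info(name, stream_type, channels, nominal_srate, "double64",
                      source_id, uid = source_id)
  structure(list(info = info, signal = signal, kind = stream_type),
            class = "virtual_source")
}

#' Run virtual devices against one or more recorders on simulated time
#'
#' The deterministic event loop behind every scenario: generates each
#' device's emission ledger, starts every recorder session, then advances
#' simulated time event by event, pushing due samples into the outlets before
#' each recorder event fires. Recorders can be killed mid-run to emulate
#' abnormal termination. The whole run is a pure function of the seed.
#'
#' @param devices List of [virtual_device()] objects.
#' @param recorder_configs List of [recorder_config()] (one file each).
#' @param duration Simulated duration (s).
#' @param seed Integer seed for all randomness in the run.
#' @param kill_times Optional numeric vector (NA = run to completion), one
#'   entry per recorder: simulated time at which that recorder is killed.
#' @param select Stream-selection glob patterns passed to every session.
#' @return List with `sessions`, `paths`, `ledgers` (per device) and
#'   `kill_times`.
#' @export
simulate_session <- function(devices, recorder_configs, duration, seed = 1,
                             kill_times = NULL, select = "*") {
  stopifnot(length(devices) >= 1, length(recorder_configs) >= 1, duration > 0)
  if (inherits(devices, "virtual_device")) devices <- list(devices)
  if (inherits(recorder_configs, "recorder_config")) {
    recorder_configs <- list(recorder_configs)
  }
  n_rec <- length(recorder_configs)
  if (is.null(kill_times)) kill_times <- rep(NA_real_, n_rec)
  stopifnot(length(kill_times) == n_rec)
  set.seed(seed)

  registry <- StreamRegistry$new()
  outlets <- list()
  for (d in seq_along(devices)) {
    dev <- devices[[d]]
    for (src in dev$sources) {
      outlets[[src$info$uid]] <- registry$open_outlet(
        src$info, clock = dev$clock, delay = dev$delay)
    }
  }

  ledgers <- lapply(devices, device_ledger, duration = duration)
  cursors <- lapply(ledgers, function(ld) lapply(ld, function(x) 1L))

  push_until <- function(t) {
    for (d in seq_along(ledgers)) {
      term_at <- attr(ledgers[[d]], "terminated_at")
      for (uid in names(ledgers[[d]])) {
        ld <- ledgers[[d]][[uid]]
        i0 <- cursors[[d]][[uid]]
        n <- length(ld$tau)
        if (i0 > n) next
        i1 <- i0 - 1L + findInterval(t, ld$tau[i0:n])
        if (i1 >= i0) {
          outlets[[uid]]$push_chunk(ld$values[i0:i1, , drop = FALSE],
                                    ld$timestamps[i0:i1])
          cursors[[d]][[uid]] <<- i1 + 1L
        }
      }
      if (is.finite(term_at) && term_at <= t &&
          !outlets[[names(ledgers[[d]])[1]]]$is_terminated()) {
        for (uid in names(ledgers[[d]])) outlets[[uid]]$terminate()
      }
    }
  }

  sessions <- lapply(recorder_configs, function(cfg) {
    s <- RecordingSession$new(registry, cfg)
    s$select_streams(select)
    s$start()
    s
  })

  pending_kills <- kill_times
  repeat {
    taus <- vapply(sessions, function(s) {
      ev <- s$next_event()
      if (is.null(ev)) Inf else ev$tau
    }, numeric(1))
    taus <- c(taus, ifelse(is.na(pending_kills), Inf, pending_kills))
    t_next <- min(taus)
    if (t_next >= duration) break
    push_until(t_next)
    for (r in seq_len(n_rec)) {
      if (!is.na(pending_kills[r]) && pending_kills[r] <= t_next &&
          sessions[[r]]$state == "recording") {
        sessions[[r]]$process_until(pending_kills[r] - 1e-9)
        sessions[[r]]$kill()
        pending_kills[r] <- NA_real_
      }
    }
    for (s in sessions) {
      if (s$state == "recording") s$process_until(t_next)
    }
  }

  push_until(duration)
  registry$set_time(duration)
  for (s in sessions) {
    if (s$state == "recording") {
      s$process_until(duration)
      s$stop()
    }
  }

  list(sessions = sessions,
       paths = lapply(sessions, function(s) s$path),
       ledgers = ledgers,
       kill_times = kill_times,
       registry = registry)
}

# Load, synchronize and align two streams (possibly from different files),
# returning per-channel correlations over the trimmed overlap.
cross_correlate <- function(stream_a, stream_b, target_rate, edge_trim = 1) {
  aligned <- align_streams(
    list(list(timestamps = stream_a$corrected_timestamps, values = stream_a$values),
         list(timestamps = stream_b$corrected_timestamps, values = stream_b$values)),
    target_rate)
  aligned_correlations(aligned, edge_trim = edge_trim)
}

#' Scenario 1A: two sine-generator phones, one recorder
#'
#' Two virtual devices run the 10-channel 250 Hz sine generator with the
#' effective rates observed on the two modelled handsets (203 and 213 Hz) and
#' clearly diverging clocks (seconds of offset, tens of ppm of drift). One
#' recorder captures both streams; the report carries the per-channel
#' correlations of the matched sine channels after synchronization and
#' resampling onto a common grid, and the raw (index-aligned) phase drift
#' over 4 s that motivates the alignment in the first place.
#'
#' @param duration Simulated duration (s), default 60.
#' @param seed Integer seed.
#' @param effective_rates Effective rates of the two devices (Hz).
#' @param align_rate Common grid rate (Hz).
#' @return A `scenario_report` list.
#' @export
run_s1a <- function(duration = 60, seed = 1, effective_rates = c(203, 213),
                    align_rate = 100) {
  dev1 <- virtual_device(
    sine_source(name = "sine-phone1", source_id = "phone1-sine"),
    clock = VirtualClock$new(3.2, 40, 2e-4),
    effective_rate = effective_rates[1])
  dev2 <- virtual_device(
    sine_source(name = "sine-phone2", source_id = "phone2-sine"),
    clock = VirtualClock$new(-1.7, -25, 2e-4),
    effective_rate = effective_rates[2])
  cfg <- recorder_config(filename_base = "s1a",
                         clock = VirtualClock$new(5e-4, 5, 5e-6))
  run <- simulate_session(list(dev1, dev2), cfg, duration, seed)

  rec <- synchronize(read_xdf(run$paths[[1]]))
  s1 <- rec$streams[["1"]]; s2 <- rec$streams[["2"]]
  r <- cross_correlate(s1, s2, align_rate)

  # index-aligned divergence of the raw streams over their first 4 s
  k <- min(floor(4 * min(effective_rates)), s1$n_samples, s2$n_samples)
  drift <- (s1$timestamps[k] - s1$timestamps[1]) -
    (s2$timestamps[k] - s2$timestamps[1])

  structure(list(
    scenario = "s1a", seed = seed, duration = duration,
    paths = run$paths,
    summary = recording_summary(rec),
    channel_correlations = r,
    min_correlation = min(r),
    raw_phase_drift_4s = abs(drift),
    effective_srates = vapply(rec$streams, function(s)
      effective_srate(s$footer), numeric(1)),
    pass = min(r) > xdf_thresholds$min_channel_r
  ), class = "scenario_report")
}

#' Scenario 1B: two phones streaming motion sensors, one recorder
#'
#' Two virtual phones observe the same physical motion and stream rotation
#' (software sensor), gravity and accelerometer (hardware sensors), each
#' device at the effective rate its load preset gives for three active
#' sensors. Hardware channels differ across devices only by measurement
#' noise; the software sensor applies a device-specific interpretation, so
#' its cross-device correlation is markedly lower.
#'
#' @param duration Simulated duration (s), default 60.
#' @param seed Integer seed.
#' @param align_rate Common grid rate (Hz).
#' @param noise_sd Hardware sensor measurement noise SD.
#' @return A `scenario_report` list.
#' @export
run_s1b <- function(duration = 60, seed = 1, align_rate = 50,
                    noise_sd = 0.02) {
  motion <- motion_signal(seed = seed + 101L)
  sensors <- c("rotation", "gravity", "accelerometer")
  set.seed(seed)
  make_phone <- function(device, preset, clock) {
    gain <- stats::rnorm(1, 1, 0.05)
    lag <- stats::runif(1, 0.03, 0.08)
    srcs <- lapply(sensors, function(k) {
      sensor_source(k, motion, nominal_srate = load_preset(preset)$nominal,
                    noise_sd = noise_sd, gain = gain, lag = lag,
                    device = device, seed = seed + match(device, c("phone1", "phone2")))
    })
    virtual_device(srcs, clock = clock,
                   effective_rate = effective_rate_for(load_preset(preset),
                                                       length(sensors)))
  }
  dev1 <- make_phone("phone1", "samsung", VirtualClock$new(1.1, 30, 2e-4))
  dev2 <- make_phone("phone2", "huawei", VirtualClock$new(-0.6, -20, 2e-4))
  cfg <- recorder_config(filename_base = "s1b",
                         clock = VirtualClock$new(-3e-4, 8, 5e-6))
  run <- simulate_session(list(dev1, dev2), cfg, duration, seed)

  rec <- synchronize(read_xdf(run$paths[[1]]))
  by_type <- split(rec$streams, vapply(rec$streams, function(s)
    s$info$stream_type, character(1)))
  correlations <- lapply(by_type, function(pair) {
    stopifnot(length(pair) == 2)
    cross_correlate(pair[[1]], pair[[2]], align_rate)
  })
  mean_r <- vapply(correlations, mean, numeric(1))
  hardware <- c("gravity", "accelerometer")
  software <- "rotation"

  structure(list(
    scenario = "s1b", seed = seed, duration = duration,
    paths = run$paths,
    summary = recording_summary(rec),
    correlations = correlations,
    hardware_r = mean_r[hardware],
    software_r = mean_r[software],
    load_rates = c(one = effective_rate_for(load_preset("samsung"), 1),
                   three = effective_rate_for(load_preset("samsung"), 3),
                   all = effective_rate_for(load_preset("samsung"), 5)),
    pass = all(mean_r[hardware] >= xdf_thresholds$min_channel_r) &&
      mean_r[software] < min(mean_r[hardware])
  ), class = "scenario_report")
}

#' Scenario 2: one source recorded by two independent recorders
#'
#' A simulated 8-channel 100 Hz neural-like source (achieving 94 Hz
#' effective, as a scheduler-limited sender would) is recorded simultaneously
#' by two recorder instances with independent consumer clocks. Both files
#' must contain the same samples: the report compares each channel across
#' files after synchronization and alignment, checks both files for gaps, and
#' compares their effective sampling rates.
#'
#' @param duration Simulated duration (s), default 60.
#' @param seed Integer seed.
#' @param channels,nominal_srate,effective_rate Source configuration.
#' @return A `scenario_report` list.
#' @export
run_s2 <- function(duration = 60, seed = 1, channels = 8,
                   nominal_srate = 100, effective_rate = 94) {
  base <- motion_signal(seed = seed + 33L, channels = channels,
                        n_components = 5, freq_range = c(0.5, 8))
  signal <- function(t) {
    base(t) + matrix(stats::rnorm(length(t) * channels, 0, 0.01),
                     length(t), channels)
  }
  src <- signal_source("eeg-sim", "EEG", channels, nominal_srate, signal,
                       source_id = "laptop-eeg")
  dev <- virtual_device(src, clock = VirtualClock$new(1.3, 30, 2e-4),
                        effective_rate = effective_rate)
  cfg_phone <- recorder_config(filename_base = "s2-phone",
                               clock = VirtualClock$new(8e-4, 12, 5e-6))
  cfg_pc <- recorder_config(filename_base = "s2-pc",
                            clock = VirtualClock$new(-5e-4, -8, 5e-6))
  run <- simulate_session(list(dev), list(cfg_phone, cfg_pc), duration, seed)

  rec_a <- synchronize(read_xdf(run$paths[[1]]))
  rec_b <- synchronize(read_xdf(run$paths[[2]]))
  sa <- rec_a$streams[["1"]]; sb <- rec_b$streams[["1"]]
  eff_a <- effective_srate(sa$footer); eff_b <- effective_srate(sb$footer)
  r <- cross_correlate(sa, sb, target_rate = min(eff_a, eff_b))
  gaps_a <- detect_gaps(sa$corrected_timestamps, nominal_srate)
  gaps_b <- detect_gaps(sb$corrected_timestamps, nominal_srate)
  n_common <- min(sa$n_samples, sb$n_samples)
  ts_diff <- stats::median(sa$corrected_timestamps[seq_len(n_common)] -
                           sb$corrected_timestamps[seq_len(n_common)])

  structure(list(
    scenario = "s2", seed = seed, duration = duration,
    paths = run$paths,
    channel_correlations = r,
    min_correlation = min(r),
    n_gaps = c(nrow(gaps_a), nrow(gaps_b)),
    effective_srates = c(phone = eff_a, pc = eff_b),
    srates_equal = isTRUE(all.equal(eff_a, eff_b, tolerance = 1e-12)),
    corrected_ts_median_diff = ts_diff,
    pass = min(r) >= xdf_thresholds$cross_file_r &&
      nrow(gaps_a) == 0 && nrow(gaps_b) == 0
  ), class = "scenario_report")
}

#' Scenario 3: source and recorder sharing one device clock
#'
#' One virtual phone streams rotation, gravity and accelerometer sensors (all
#' at the shared device-wide effective rate, 76.5 Hz by default) and is
#' recorded twice: by a recorder sharing the phone's own clock (offsets near
#' zero throughout) and by an independent recorder on a drifting clock. All
#' sensor channels are compared across the two files after synchronization.
#'
#' @param duration Simulated duration (s), default 300.
#' @param seed Integer seed.
#' @param effective_rate Device-wide sensor rate (Hz), default 76.5.
#' @return A `scenario_report` list.
#' @export
run_s3 <- function(duration = 300, seed = 1, effective_rate = 76.5) {
  motion <- motion_signal(seed = seed + 77L)
  phone_clock <- VirtualClock$new(1.2e-3, 25, 2e-4)
  srcs <- lapply(c("rotation", "gravity", "accelerometer"), function(k) {
    sensor_source(k, motion, nominal_srate = 100, noise_sd = 0.02,
                  device = "phone", seed = seed + 5L)
  })
  dev <- virtual_device(srcs, clock = phone_clock,
                        effective_rate = effective_rate)
  cfg_local <- recorder_config(filename_base = "s3-phone", clock = phone_clock)
  cfg_remote <- recorder_config(filename_base = "s3-pc",
                                clock = VirtualClock$new(-9e-4, -15, 5e-6))
  run <- simulate_session(list(dev), list(cfg_local, cfg_remote), duration, seed)

  rec_a <- synchronize(read_xdf(run$paths[[1]]))
  rec_b <- synchronize(read_xdf(run$paths[[2]]))
  eff <- vapply(rec_a$streams, function(s) effective_srate(s$footer), numeric(1))
  correlations <- lapply(names(rec_a$streams), function(sid) {
    cross_correlate(rec_a$streams[[sid]], rec_b$streams[[sid]],
                    target_rate = min(eff))
  })
  names(correlations) <- vapply(rec_a$streams, function(s)
    s$info$stream_type, character(1))
  all_r <- unlist(correlations)
  local_offsets <- unlist(lapply(rec_a$streams, function(s)
    s$clock_offsets$offset))

  structure(list(
    scenario = "s3", seed = seed, duration = duration,
    paths = run$paths,
    correlations = correlations,
    min_correlation = min(all_r),
    effective_srates = eff,
    shared_clock_max_abs_offset = max(abs(local_offsets)),
    pass = min(all_r) > xdf_thresholds$min_channel_r
  ), class = "scenario_report")
}

#' Fault-tolerance scenarios: paused stream and killed recorder
#'
#' `kind = "pause"` suspends a 100 Hz source for `pause_dur` seconds mid-run;
#' the recorder simply writes nothing for that stream while it is silent,
#' the file finalizes normally and the loader reports one gap. `kind =
#' "kill"` terminates the recorder abruptly at `kill_time` (random within the
#' run when `NULL`): the file on disk has no footer but loads, and the
#' trailing data loss is bounded by one flush interval.
#'
#' @param kind `"pause"` or `"kill"`.
#' @param duration Simulated duration (s).
#' @param seed Integer seed.
#' @param pause_start,pause_dur Pause window (s), for `kind = "pause"`.
#' @param kill_time Kill time (s), for `kind = "kill"`.
#' @return A `scenario_report` list.
#' @export
run_fault <- function(kind = c("pause", "kill"), duration = 60, seed = 1,
                      pause_start = 20, pause_dur = 5, kill_time = NULL) {
  kind <- match.arg(kind)
  motion <- motion_signal(seed = seed + 11L)
  src <- signal_source("sensor-sim", "accelerometer", 3, 100,
                       function(t) motion(t), source_id = "phone-acc")
  dev <- virtual_device(src, clock = VirtualClock$new(0.8, 20, 2e-4),
                        effective_rate = 100)
  cfg <- recorder_config(filename_base = paste0("fault-", kind),
                         clock = VirtualClock$new(2e-4, 5, 5e-6))

  if (kind == "pause") {
    dev <- inject_fault(dev, fault_pause(pause_start, pause_dur))
    run <- simulate_session(list(dev), cfg, duration, seed)
    rec <- synchronize(read_xdf(run$paths[[1]]))
    s <- rec$streams[["1"]]
    gaps <- detect_gaps(s$corrected_timestamps, 100)
    return(structure(list(
      scenario = "fault_pause", seed = seed, duration = duration,
      paths = run$paths,
      n_gaps = nrow(gaps),
      gap_durations = gaps$gap_duration,
      footer_present = !is.null(s$footer),
      pass = nrow(gaps) == 1 && !is.null(s$footer) &&
        abs(gaps$gap_duration[1] - pause_dur) < 0.5
    ), class = "scenario_report"))
  }

  if (is.null(kill_time)) {
    kill_time <- with_seed(seed + 1L, stats::runif(1, 5, duration - 5))
  }
  run <- simulate_session(list(dev), cfg, duration, seed,
                          kill_times = kill_time)
  rec <- read_xdf(run$paths[[1]])
  s <- rec$streams[["1"]]
  ld <- run$ledgers[[1]][[1]]
  pushed <- sum(ld$tau <= kill_time)
  loss_s <- if (s$n_samples >= pushed) 0 else {
    ld$tau[pushed] - ld$tau[s$n_samples]
  }
  structure(list(
    scenario = "fault_kill", seed = seed, duration = duration,
    paths = run$paths,
    kill_time = kill_time,
    samples_pushed = pushed,
    samples_recovered = s$n_samples,
    trailing_loss_s = loss_s,
    footer_present = !is.null(s$footer),
    pass = is.null(s$footer) && loss_s <= xdf_thresholds$max_kill_loss_s
  ), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s (seed %d, %g s simulated): %s\n",
              x$scenario, x$seed, x$duration,
              if (isTRUE(x$pass)) "PASS" else "FAIL"))
  num <- vapply(x, function(v) is.numeric(v) && length(v) <= 10, logical(1))
  for (nm in names(x)[num]) {
    if (nm %in% c("seed", "duration")) next
    cat(sprintf("  %s: %s\n", nm,
                paste(signif(x[[nm]], 6), collapse = ", ")))
  }
  invisible(x)
}
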