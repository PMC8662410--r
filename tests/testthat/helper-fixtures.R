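# Shared fixture builders. Everything is generated in code at test time.

# Round a double through IEEE float32, as the file format does for
# float32-format streams.
f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

# Regular timestamp grid built by sequential accumulation, matching the
# reader's reconstruction of omitted (deduced) timestamps bit-for-bit.
regular_ts <- function(t0, dt, n) {
  Reduce(`+`, rep(dt, n - 1L), accumulate = TRUE, init = t0)
}

rand_string <- function(n) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:12, 1)
    paste(sample(c(letters, LETTERS, " ", "-"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Write a randomized multi-stream recording and return the ground truth that
# a lossless reader must reproduce exactly.
write_random_recording <- function(path, seed) {
  set.seed(seed)
  n_streams <- sample(1:3, 1)
  w <- XdfWriter$new(path)
  truth <- list()
  footers <- list()
  for (sid in seq_len(n_streams)) {
    fmt <- sample(c("float32", "double64", "int32", "string"), 1)
    ch <- sample(1:4, 1)
    srate <- sample(c(0, 50, 100, 250), 1)
    info <- stream_info(paste0("stream", sid), "test", ch, srate, fmt,
                        source_id = paste0("src", sid),
                        uid = paste0("uid", sid, "-", seed))
    w$write_stream_header(sid, info)

    n_chunks <- sample(1:4, 1)
    all_vals <- NULL
    all_ts <- numeric(0)
    t_cursor <- stats::runif(1, 0, 100)
    for (k in seq_len(n_chunks)) {
      n <- sample(1:30, 1)
      if (srate > 0 && stats::runif(1) < 0.4) {
        ts <- regular_ts(t_cursor, 1 / srate, n)
      } else {
        ts <- t_cursor + cumsum(stats::runif(n, 0.001, 0.05))
      }
      t_cursor <- ts[n] + stats::runif(1, 0.001, 0.1)
      vals <- switch(fmt,
        float32 = matrix(f32(stats::rnorm(n * ch)), n, ch),
        double64 = matrix(stats::rnorm(n * ch), n, ch),
        int32 = matrix(sample.int(100000L, n * ch, replace = TRUE) - 50000L,
                       n, ch),
        string = matrix(rand_string(n * ch), n, ch))
      w$write_samples(sid, vals, ts)
      all_vals <- rbind(all_vals, vals)
      all_ts <- c(all_ts, ts)
      if (stats::runif(1) < 0.3) w$write_boundary()
    }

    n_off <- sample(0:4, 1)
    off <- offset_series(sort(stats::runif(n_off, 0, 100)),
                         stats::rnorm(n_off, 0, 0.01))
    for (i in seq_len(nrow(off))) {
      w$write_clock_offset(sid, off$collection_time[i], off$offset[i])
    }

    n_total <- length(all_ts)
    truth[[as.character(sid)]] <- list(info = info, values = all_vals,
                                       timestamps = all_ts, offsets = off)
    footers[[sid]] <- list(
      stream_id = sid, first_timestamp = all_ts[1],
      last_timestamp = all_ts[n_total], sample_count = n_total,
      measured_srate = if (n_total >= 2) effective_srate(all_ts) else srate,
      offsets = off)
  }
  w$finish(footers)
  truth
}

# Independent byte-level encoder of a Samples chunk with explicit timestamps,
# written directly from the chunk framing definition (scalar loops, no shared
# code with the package encoder).
hand_encode_samples_chunk <- function(stream_id, values, timestamps, format) {
  le_uint <- function(x, width) {
    out <- raw(width)
    for (i in seq_len(width)) {
      out[i] <- as.raw(x %% 256)
      x <- x %/% 256
    }
    out
  }
  content <- c(le_uint(stream_id, 4), as.raw(1), as.raw(nrow(values)))
  for (i in seq_len(nrow(values))) {
    content <- c(content, as.raw(8),
                 writeBin(timestamps[i], raw(), size = 8, endian = "little"))
    for (j in seq_len(ncol(values))) {
      content <- c(content, switch(format,
        float32 = writeBin(values[i, j], raw(), size = 4, endian = "little"),
        double64 = writeBin(values[i, j], raw(), size = 8, endian = "little"),
        int32 = writeBin(as.integer(values[i, j]), raw(), size = 4,
                         endian = "little")))
    }
  }
  len <- length(content) + 2
  stopifnot(len <= 255)
  c(as.raw(1), as.raw(len), as.raw(3), as.raw(0), content)
}

# A tiny one-stream virtual setup used across recorder tests: a 100 Hz
# 2-channel source on a drifting clock plus a recorder config in tempdir().
tiny_setup <- function(offset0 = 0.5, drift_ppm = 20, jitter_sd = 1e-4,
                       srate = 100, flush = 0.5, offset_int = 5) {
  src <- signal_source("tiny", "generic", 2, srate,
                       function(t) cbind(sin(2 * pi * t), cos(2 * pi * t)),
                       source_id = "tiny-dev")
  dev <- virtual_device(src,
                        clock = VirtualClock$new(offset0, drift_ppm, jitter_sd),
                        effective_rate = srate)
  cfg <- recorder_config(flush_interval = flush, offset_interval = offset_int,
                         filename_base = "tiny", dir = tempdir(),
                         clock = VirtualClock$new(1e-4, 3, 1e-6))
  list(dev = dev, cfg = cfg)
}

oracle_script <- function() {
  system.file("tools", "xdf_read_oracle.py", package = "xdfstream")
}
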