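test_that("a constant recorded offset shifts every corrected timestamp", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "generic", 1, 100, "double64", "d", uid = "u")
  w$write_stream_header(1, info)
  ts <- seq(0, 1, by = 0.01)
  w$write_samples(1, matrix(seq_along(ts), ncol = 1), ts)
  w$write_clock_offset(1, 0, 1.0)
  w$kill()
  rec <- synchronize(read_xdf(path))
  s <- rec$streams[["1"]]
  expect_true(s$synchronized)
  expect_equal(s$corrected_timestamps, s$timestamps + 1.0)
  unlink(path)
})

test_that("synchronization undoes a simulated linear drift to within the
           probe-noise envelope", {
  setup <- tiny_setup(offset0 = 2.5, drift_ppm = 50, jitter_sd = 1e-5)
  run <- simulate_session(setup$dev, setup$cfg, duration = 60, seed = 4)
  rec <- synchronize(read_xdf(run$sessions[[1]]$path))
  s <- rec$streams[["1"]]
  ld <- run$ledgers[[1]][[1]]
  # corrected timestamps should recover the recorder's clock at emission,
  # which tracks true emission time up to the consumer clock's own tiny error
  consumer_truth <- setup$cfg$clock$true_offset(ld$tau) + ld$tau
  err <- s$corrected_timestamps - consumer_truth
  expect_lt(stats::median(abs(err)), 2e-3)
  expect_lt(max(abs(err)), 5e-3)
  unlink(run$sessions[[1]]$path)
})

test_that("streams without any offsets pass through raw and flagged", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "generic", 1, 100, "double64", "d", uid = "u")
  w$write_stream_header(1, info)
  w$write_samples(1, matrix(1:3, ncol = 1), 1:3 / 100)
  w$kill()
  rec <- synchronize(read_xdf(path))
  s <- rec$streams[["1"]]
  expect_false(s$synchronized)
  expect_identical(s$corrected_timestamps, s$timestamps)
  unlink(path)
})

test_that("dejitter is a no-op on a perfectly regular grid", {
  ts <- regular_ts(10, 1 / 250, 1000)
  out <- dejitter(ts, 250)
  expect_lt(max(abs(out$timestamps - ts)), 1e-12)
  expect_identical(nrow(out$segments), 1L)
})

test_that("dejitter shrinks uniform timestamp jitter at least tenfold", {
  set.seed(21)
  grid <- seq(0, 8, by = 1 / 250)
  noisy <- grid + runif(length(grid), -0.002, 0.002)
  noisy <- cummax(noisy)  # keep non-decreasing, as device stamps are
  out <- dejitter(noisy, 250)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$timestamps - grid) * 10, rms(noisy - grid))
  expect_identical(length(out$timestamps), length(grid))
  # monotone within the (single) segment
  expect_true(all(diff(out$timestamps) > 0))
})

test_that("dejitter splits at silences and never moves stamps across the
           boundary", {
  ts <- c(seq(0, 1, by = 0.01), seq(2.5, 3.5, by = 0.01))
  out <- dejitter(ts, 100)
  expect_identical(nrow(out$segments), 2L)
  expect_identical(out$segments$start_index, c(1L, 102L))
  expect_lt(max(out$timestamps[1:101]), 1.5)
  expect_gt(min(out$timestamps[102:202]), 2)
  expect_warning(dejitter(c(0, 1, 3), 0), "irregular")
})

test_that("effective sampling rate has its closed-form values", {
  expect_equal(effective_srate(seq(0, 1, length.out = 251)), 250)
  expect_equal(effective_srate(c(0, 0.01)), 100)
  expect_true(is.na(effective_srate(1.5)))
  expect_equal(effective_srate(list(sample_count = 251, first_timestamp = 0,
                                    last_timestamp = 1)), 250)
})

test_that("gap detection finds a constructed 50-sample dropout", {
  ts <- seq(0, 10, by = 0.01)
  drop <- 301:350  # 50 consecutive samples of a 100 Hz stream
  ts_gapped <- ts[-drop]
  rep <- detect_gaps(ts_gapped, 100)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$gap_duration, 0.51, tolerance = 1e-9)
  expect_equal(attr(rep, "total_missing_expected_samples"), 50)

  clean <- detect_gaps(ts, 100)
  expect_identical(nrow(clean), 0L)

  irr <- detect_gaps(ts, 0)
  expect_true(attr(irr, "irregular"))
})

test_that("alignment grid spacing is exact and self-alignment correlates
           perfectly", {
  set.seed(31)
  ts <- cumsum(runif(500, 0.004, 0.006))
  vals <- matrix(sin(2 * pi * 1.3 * ts) + 0.1 * rnorm(500), ncol = 1)
  s <- list(timestamps = ts, values = vals)
  aligned <- align_streams(list(s, s), target_rate = 100)
  expect_equal(unique(round(diff(aligned$grid), 12)), 0.01)
  r <- aligned_correlations(aligned, edge_trim = 0.1)
  expect_equal(r, 1.0)
})

test_that("alignment is invariant under a constant, properly synchronized
           clock shift", {
  set.seed(32)
  t_true <- cumsum(runif(2000, 0.004, 0.006))
  sig <- function(t) cbind(sin(2 * pi * 0.7 * t), cos(2 * pi * 1.9 * t))
  a <- list(timestamps = t_true, values = sig(t_true))
  t2 <- t_true[seq(1, 2000, by = 2)]
  b <- list(timestamps = t2, values = sig(t2))
  r0 <- aligned_correlations(align_streams(list(a, b), 50), edge_trim = 0.5)

  shift <- 123.456
  b_shifted <- list(timestamps = t2 + shift, values = b$values)
  a_shifted <- list(timestamps = t_true + shift, values = a$values)
  r1 <- aligned_correlations(align_streams(list(a_shifted, b_shifted), 50),
                             edge_trim = 0.5)
  expect_equal(r1, r0, tolerance = 1e-6)
})

test_that("disjoint streams are rejected with their ranges identified", {
  a <- list(timestamps = 0:10, values = matrix(0:10, ncol = 1))
  b <- list(timestamps = 20:30, values = matrix(0:10, ncol = 1))
  expect_error(align_streams(list(a, b), 10), "overlap")
})

test_that("channel correlation matches a naive two-pass formula and handles
           degenerate inputs", {
  set.seed(9)
  naive_r <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(channel_correlation(a, b), naive_r(a, b), tolerance = 1e-12)
  }
  a <- rnorm(20)
  expect_equal(channel_correlation(a, a), 1.0)
  expect_equal(channel_correlation(a, -a), -1.0)
  expect_true(is.na(channel_correlation(a, rep(2, 20))))
})

test_that("effective rate is invariant under constant shifts and
           synchronization", {
  setup <- tiny_setup(offset0 = 1.0, drift_ppm = 10)
  run <- simulate_session(setup$dev, setup$cfg, duration = 10, seed = 14)
  rec <- synchronize(read_xdf(run$sessions[[1]]$path))
  s <- rec$streams[["1"]]
  raw_rate <- effective_srate(s$timestamps)
  corr_rate <- effective_srate(s$corrected_timestamps)
  expect_equal(effective_srate(s$timestamps + 500), raw_rate)
  # synchronization rescales time by at most the drift (ppm-level)
  expect_equal(corr_rate, raw_rate, tolerance = 1e-4)
  unlink(run$sessions[[1]]$path)
})
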