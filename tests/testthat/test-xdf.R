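test_that("a new file begins with the XDF magic and refuses to overwrite", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  w$kill()
  expect_identical(rawToChar(readBin(path, raw(), 4)), "XDF:")
  expect_error(XdfWriter$new(path), "refusing to overwrite")
  expect_error(XdfWriter$new(tempdir()), "directory")
  unlink(path)
})

test_that("writer output matches an independent hand-encoding of the chunk
           layout", {
  # Boundary chunk: 1-byte length field, length = tag (2) + 16-byte payload
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  header_len <- file.size(path)
  w$write_boundary()
  w$kill()
  bytes <- readBin(path, raw(), file.size(path))
  boundary <- bytes[(header_len + 1):length(bytes)]
  expect_identical(boundary[1:2], as.raw(c(1, 18)))
  expect_identical(boundary[3:4], as.raw(c(5, 0)))
  expect_length(boundary, 2 + 2 + 16)
  unlink(path)

  # Samples chunk, 3 samples x 2 float32 channels, explicit timestamps:
  # content = 4 (stream id) + 2 (count varlen) + 3 x (1 + 8 + 2x4) = 57 bytes
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "test", 2, 0, "float32", "d", uid = "u")
  w$write_stream_header(7, info)
  before <- file.size(path)
  vals <- matrix(f32(c(1.5, -2.25, 3.125, 0, 10, -0.5)), 3, 2)
  ts <- c(0.1, 0.2, 0.35)
  w$write_samples(7, vals, ts)
  w$kill()
  bytes <- readBin(path, raw(), file.size(path))
  written <- bytes[(before + 1):length(bytes)]
  expect_identical(written, hand_encode_samples_chunk(7, vals, ts, "float32"))
  unlink(path)
})

test_that("randomized recordings roundtrip bit-exactly through write/read", {
  for (seed in 1:12) {
    path <- tempfile(fileext = ".xdf")
    truth <- write_random_recording(path, seed)
    rec <- read_xdf(path)
    expect_false(rec$truncated)
    expect_length(rec$streams, length(truth))
    for (sid in names(truth)) {
      got <- rec$streams[[sid]]
      tr <- truth[[sid]]
      expect_identical(got$info$name, tr$info$name)
      expect_identical(got$info$channel_format, tr$info$channel_format)
      expect_identical(got$values, tr$values)
      expect_identical(got$timestamps, tr$timestamps)
      expect_identical(got$clock_offsets$collection_time,
                       tr$offsets$collection_time)
      expect_identical(got$clock_offsets$offset, tr$offsets$offset)
      expect_identical(got$footer$sample_count, as.numeric(length(tr$timestamps)))
    }
    expect_true(validate_xdf(rec))
    unlink(path)
  }
})

test_that("footer sample_count mismatches are rejected at finalize time", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "test", 1, 100, "double64", "d", uid = "u")
  w$write_stream_header(1, info)
  w$write_samples(1, matrix(1:5, ncol = 1), 1:5 / 100)
  bad <- list(stream_id = 1, first_timestamp = 0.01, last_timestamp = 0.05,
              sample_count = 99, measured_srate = 100,
              offsets = offset_series())
  expect_error(w$finish(list(bad)), "sample_count")
  good <- bad; good$sample_count <- 5
  w$finish(list(good))
  expect_error(w$finish(list(good)), "closed")
  unlink(path)
})

test_that("a header-only file and a zero-stream finalize are valid", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  w$finish(list())
  rec <- read_xdf(path)
  expect_length(rec$streams, 0)
  expect_false(rec$truncated)
  unlink(path)
})

test_that("truncating a file at any point yields a readable prefix", {
  path <- tempfile(fileext = ".xdf")
  write_random_recording(path, 99)
  full <- read_xdf(path)
  sizes <- file.size(path)
  bytes <- readBin(path, raw(), sizes)
  header_end <- 4 + 2 + 2 + nchar("<?xml version=\"1.0\"?><info><version>1.0</version></info>")

  set.seed(5)
  for (cut in sort(sample(header_end:(sizes - 1), 12))) {
    tpath <- tempfile(fileext = ".xdf")
    writeBin(bytes[1:cut], tpath)
    rec <- suppressWarnings(read_xdf(tpath))
    for (sid in names(rec$streams)) {
      n <- rec$streams[[sid]]$n_samples
      if (n > 0) {
        expect_identical(rec$streams[[sid]]$timestamps,
                         full$streams[[sid]]$timestamps[seq_len(n)])
      }
    }
    unlink(tpath)
  }
  unlink(path)
})

test_that("killed-mid-chunk files load with a warning and no exception", {
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "test", 1, 0, "double64", "d", uid = "u")
  w$write_stream_header(1, info)
  ts <- cumsum(runif(1000, 0.001, 0.002))
  w$write_samples(1, matrix(rnorm(800), ncol = 1), ts[1:800])
  w$write_samples(1, matrix(rnorm(200), ncol = 1), ts[801:1000])
  w$kill()
  # chop into the middle of the last chunk
  bytes <- readBin(path, raw(), file.size(path))
  tpath <- tempfile(fileext = ".xdf")
  writeBin(bytes[1:(length(bytes) - 500)], tpath)
  expect_warning(rec <- read_xdf(tpath), "truncated")
  expect_true(rec$truncated)
  expect_null(rec$streams[["1"]]$footer)
  expect_gt(rec$streams[["1"]]$n_samples, 0)
  unlink(c(path, tpath))
})

test_that("reader rejects non-XDF files and skips unknown chunk tags", {
  path <- tempfile()
  writeBin(charToRaw("NOPE asdf"), path)
  expect_error(read_xdf(path), "magic")
  unlink(path)

  # valid file with an injected unknown-tag chunk between known chunks
  path <- tempfile(fileext = ".xdf")
  w <- XdfWriter$new(path)
  info <- stream_info("s", "test", 1, 100, "double64", "d", uid = "u")
  w$write_stream_header(1, info)
  w$write_samples(1, matrix(1:3, ncol = 1), 1:3 / 100)
  w$kill()
  bytes <- readBin(path, raw(), file.size(path))
  rogue <- c(as.raw(1), as.raw(6), as.raw(99), as.raw(0), as.raw(c(1, 2, 3, 4)))
  writeBin(c(bytes, rogue), path)
  expect_warning(rec <- read_xdf(path), "unknown chunk tag")
  expect_identical(rec$n_skipped_chunks, 1L)
  expect_identical(rec$streams[["1"]]$n_samples, 3L)
  unlink(path)
})

test_that("a hand-built file (independent byte layout, 4-byte length fields,
           deduced timestamps) loads correctly", {
  # Constructed byte-by-byte from the chunk framing definition, not via the
  # package writer: approximates a file produced by another XDF writer.
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                              x %/% 16777216 %% 256))
  chunk4 <- function(tag, content) {
    c(as.raw(4), u32(length(content) + 2), u16(tag), content)
  }
  header <- charToRaw('<?xml version="1.0"?><info><version>1.0</version></info>')
  sh_xml <- charToRaw(paste0(
    '<?xml version="1.0"?><info><name>ext</name><type>EEG</type>',
    '<channel_count>2</channel_count><nominal_srate>100</nominal_srate>',
    '<channel_format>double64</channel_format>',
    '<source_id>ext-src</source_id><uid>ext-uid</uid></info>'))
  # 3 samples: explicit ts 1.0, then two deduced (1.01, 1.02)
  samples <- c(u32(1), as.raw(1), as.raw(3),
               as.raw(8), writeBin(1.0, raw(), size = 8, endian = "little"),
               writeBin(c(10, 20), raw(), size = 8, endian = "little"),
               as.raw(0),
               writeBin(c(11, 21), raw(), size = 8, endian = "little"),
               as.raw(0),
               writeBin(c(12, 22), raw(), size = 8, endian = "little"))
  clockoff <- c(u32(1), writeBin(c(2.5, -0.25), raw(), size = 8,
                                 endian = "little"))
  path <- tempfile(fileext = ".xdf")
  writeBin(c(charToRaw("XDF:"),
             chunk4(1, header),
             chunk4(2, c(u32(1), sh_xml)),
             chunk4(3, samples),
             chunk4(4, clockoff)), path)
  rec <- read_xdf(path)
  s <- rec$streams[["1"]]
  expect_identical(s$info$name, "ext")
  expect_equal(s$values, matrix(c(10, 11, 12, 20, 21, 22), 3, 2))
  expect_equal(s$timestamps, c(1.0, 1.0 + 0.01, 1.0 + 0.01 + 0.01))
  expect_equal(s$clock_offsets$offset, -0.25)
  expect_null(s$footer)
  unlink(path)
})

test_that("files load identically in the independent Python XDF decoder", {
  paths <- character(3)
  truths <- list()
  for (i in seq_along(paths)) {
    paths[i] <- tempfile(fileext = ".xdf")
    truths[[i]] <- write_random_recording(paths[i], 200 + i)
  }
  out <- system2("python", c(oracle_script(), paths), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""),
                               simplifyVector = FALSE)
  for (i in seq_along(paths)) {
    py <- parsed[[paths[i]]]
    for (sid in names(truths[[i]])) {
      tr <- truths[[i]][[sid]]
      ps <- py[[sid]]
      expect_identical(ps$uid, tr$info$uid)
      expect_equal(unlist(ps$timestamps), tr$timestamps, tolerance = 1e-12)
      pyvals <- do.call(rbind, lapply(ps$values, function(r)
        unlist(r, use.names = FALSE)))
      if (tr$info$channel_format == "string") {
        expect_identical(matrix(as.character(pyvals), nrow(tr$values)),
                         unname(tr$values))
      } else {
        expect_equal(matrix(as.numeric(pyvals), nrow(tr$values)),
                     tr$values, tolerance = 1e-12, ignore_attr = TRUE)
      }
      expect_identical(ps$footer_sample_count, length(tr$timestamps))
    }
  }
  unlink(paths)
})
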