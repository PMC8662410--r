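parse_stream_header_xml <- function(txt) {
  doc <- xml2::read_xml(txt)
  get <- function(nm) xml2::xml_text(xml2::xml_find_first(doc, paste0("./", nm)))
  fmt <- get("channel_format")
  if (!fmt %in% names(xdf_format_size) && fmt != "string") {
    stop("unsupported channel_format in stream header: ", fmt)
  }
  stream_info(
    name = get("name"), stream_type = get("type"),
    channel_count = as.integer(get("channel_count")),
    nominal_srate = as.numeric(get("nominal_srate")),
    channel_format = fmt,
    source_id = get("source_id"), uid = get("uid"))
}

parse_stream_footer_xml <- function(txt) {
  doc <- xml2::read_xml(txt)
  get <- function(nm) xml2::xml_text(xml2::xml_find_first(doc, paste0("./", nm)))
  offs <- xml2::xml_find_all(doc, "./clock_offsets/offset")
  times <- as.numeric(vapply(offs, function(o)
    xml2::xml_text(xml2::xml_find_first(o, "./time")), character(1)))
  vals <- as.numeric(vapply(offs, function(o)
    xml2::xml_text(xml2::xml_find_first(o, "./value")), character(1)))
  list(first_timestamp = as.numeric(get("first_timestamp")),
       last_timestamp = as.numeric(get("last_timestamp")),
       sample_count = as.numeric(get("sample_count")),
       measured_srate = as.numeric(get("measured_srate")),
       offsets = offset_series(times, vals))
}

# Decode one Samples chunk content (after the stream_id) into values+timestamps.
# `state` carries channel_count, format, nominal_srate and the running last
# timestamp used to deduce omitted per-sample timestamps.
decode_samples_content <- function(bytes, state) {
  pos <- 1L
  nlb <- as.integer(bytes[pos]); pos <- pos + 1L
  n <- raw_to_uint(bytes[pos:(pos + nlb - 1L)]); pos <- pos + nlb
  n <- as.integer(n)
  ch <- state$channel_count
  fmt <- state$format
  dt <- if (state$nominal_srate > 0) 1 / state$nominal_srate else 0
  last_ts <- state$last_ts

  if (fmt != "string") {
    sz <- xdf_format_size[[fmt]]
    body <- bytes[pos:length(bytes)]
    # fast path: every sample shares the first sample's timestamp flag
    f0 <- as.integer(body[1L])
    sb <- 1L + f0 + ch * sz
    uniform <- (length(body) == n * sb) &&
      all(body[seq(1L, by = sb, length.out = n)] == as.raw(f0))
    if (uniform) {
      starts <- seq(1L, by = sb, length.out = n)
      if (f0 == 8L) {
        ts_idx <- as.vector(outer(1:8, starts, `+`))
        ts <- readBin(body[ts_idx], "double", n = n, size = 8L,
                      endian = "little")
      } else {
        # sequential double additions (prev + dt); cumsum would accumulate in
        # extended precision and not match the writer's omission rule
        ts <- Reduce(`+`, rep(dt, n), accumulate = TRUE, init = last_ts)[-1L]
      }
      val_idx <- as.vector(outer(seq_len(ch * sz), starts + f0, `+`))
      vals <- read_values(body[val_idx], fmt, n * ch)
      values <- matrix(vals, nrow = n, ncol = ch, byrow = TRUE)
      return(list(values = values, timestamps = ts, last_ts = ts[n]))
    }
    # mixed explicit/deduced timestamps
    ts <- numeric(n)
    values <- matrix(read_values(raw(0), fmt, 0), nrow = 0, ncol = ch)
    rows <- vector("list", n)
    p <- 1L
    for (i in seq_len(n)) {
      f <- as.integer(body[p]); p <- p + 1L
      if (f == 8L) {
        ts[i] <- readBin(body[p:(p + 7L)], "double", 1L, size = 8L,
                         endian = "little")
        p <- p + 8L
      } else {
        ts[i] <- last_ts + dt
      }
      rows[[i]] <- read_values(body[p:(p + ch * sz - 1L)], fmt, ch)
      p <- p + ch * sz
      last_ts <- ts[i]
    }
    values <- do.call(rbind, rows)
    return(list(values = values, timestamps = ts, last_ts = ts[n]))
  }

  # string samples: per-value varlen strings
  ts <- numeric(n)
  values <- matrix(NA_character_, nrow = n, ncol = ch)
  p <- pos
  for (i in seq_len(n)) {
    f <- as.integer(bytes[p]); p <- p + 1L
    if (f == 8L) {
      ts[i] <- readBin(bytes[p:(p + 7L)], "double", 1L, size = 8L,
                       endian = "little")
      p <- p + 8L
    } else {
      ts[i] <- last_ts + dt
    }
    for (j in seq_len(ch)) {
      w <- as.integer(bytes[p]); p <- p + 1L
      slen <- as.integer(raw_to_uint(bytes[p:(p + w - 1L)])); p <- p + w
      values[i, j] <- if (slen > 0) {
        rawToChar(bytes[p:(p + slen - 1L)])
      } else ""
      p <- p + slen
    }
    last_ts <- ts[i]
  }
  list(values = values, timestamps = ts, last_ts = ts[n])
}

read_values <- function(bytes, format, n) {
  switch(format,
    float32 = readBin(bytes, "double", n = n, size = 4L, endian = "little"),
    double64 = readBin(bytes, "double", n = n, size = 8L, endian = "little"),
    int32 = readBin(bytes, "integer", n = n, size = 4L, endian = "little"))
}

#' Read an XDF file
#'
#' Parses all complete chunks of an XDF 1.0 file into per-stream sample
#' matrices, raw (source-clock) timestamps, clock-offset series and footers.
#' Degraded files are handled the way a recording tool must: a truncated final
#' chunk (writer killed mid-write) is discarded with a warning, an unknown
#' chunk tag is skipped with a warning, and a missing footer is reported per
#' stream rather than treated as fatal.
#'
#' @param path Path to the file.
#' @return An object of class `xdf_recording`: a list with `streams` (keyed by
#'   stream id; each has `info`, `values`, `timestamps`, `clock_offsets`,
#'   `footer` or `NULL`, `n_samples`), `truncated` and `n_skipped_chunks`.
#' @export
read_xdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path)
  bytes <- readBin(path, raw(), n = sz)
  if (length(bytes) < 4L || rawToChar(bytes[1:4]) != "XDF:") {
    stop("not an XDF file (bad magic): ", path)
  }

  streams <- new.env(parent = emptyenv())
  header_xml <- NULL
  truncated <- FALSE
  n_skipped <- 0L
  pos <- 5L
  total <- length(bytes)

  while (pos <= total) {
    start <- pos
    nlb <- as.integer(bytes[pos])
    if (!nlb %in% c(1L, 4L, 8L) || pos + nlb > total) {
      warning("discarding truncated/corrupt trailing chunk at byte ", start)
      truncated <- TRUE
      break
    }
    len <- raw_to_uint(bytes[(pos + 1L):(pos + nlb)])
    pos <- pos + 1L + nlb
    if (len < 2 || pos + len - 1 > total) {
      warning("discarding truncated trailing chunk at byte ", start)
      truncated <- TRUE
      break
    }
    tag <- raw_to_uint(bytes[pos:(pos + 1L)])
    content <- if (len > 2) bytes[(pos + 2L):(pos + len - 1L)] else raw(0)
    pos <- pos + len

    if (tag == xdf_tags[["FileHeader"]]) {
      header_xml <- rawToChar(content)
    } else if (tag == xdf_tags[["StreamHeader"]]) {
      sid <- as.character(raw_to_uint(content[1:4]))
      info <- parse_stream_header_xml(rawToChar(content[-(1:4)]))
      streams[[sid]] <- list(
        info = info, chunks = list(),
        offset_time = numeric(), offset_value = numeric(),
        footer = NULL, last_ts = NA_real_)
    } else if (tag == xdf_tags[["Samples"]]) {
      sid <- as.character(raw_to_uint(content[1:4]))
      st <- streams[[sid]]
      if (is.null(st)) {
        warning("Samples chunk for unknown stream ", sid, "; skipped")
        n_skipped <- n_skipped + 1L
        next
      }
      dec <- decode_samples_content(content[-(1:4)],
        list(channel_count = st$info$channel_count,
             format = st$info$channel_format,
             nominal_srate = st$info$nominal_srate,
             last_ts = st$last_ts))
      st$chunks[[length(st$chunks) + 1L]] <- dec
      st$last_ts <- dec$last_ts
      streams[[sid]] <- st
    } else if (tag == xdf_tags[["ClockOffset"]]) {
      sid <- as.character(raw_to_uint(content[1:4]))
      st <- streams[[sid]]
      if (!is.null(st)) {
        v <- readBin(content[-(1:4)], "double", n = 2L, size = 8L,
                     endian = "little")
        st$offset_time <- c(st$offset_time, v[1])
        st$offset_value <- c(st$offset_value, v[2])
        streams[[sid]] <- st
      }
    } else if (tag == xdf_tags[["Boundary"]]) {
      # recovery marker; no content of interest
    } else if (tag == xdf_tags[["StreamFooter"]]) {
      sid <- as.character(raw_to_uint(content[1:4]))
      st <- streams[[sid]]
      if (!is.null(st)) {
        st$footer <- parse_stream_footer_xml(rawToChar(content[-(1:4)]))
        streams[[sid]] <- st
      }
    } else {
      warning("unknown chunk tag ", tag, " at byte ", start, "; skipped")
      n_skipped <- n_skipped + 1L
    }
  }

  out_streams <- list()
  for (sid in sort(as.numeric(ls(streams)))) {
    st <- streams[[as.character(sid)]]
    values <- do.call(rbind, lapply(st$chunks, `[[`, "values"))
    if (is.null(values)) {
      values <- if (st$info$channel_format == "string") {
        matrix(character(0), 0, st$info$channel_count)
      } else {
        matrix(numeric(0), 0, st$info$channel_count)
      }
    }
    timestamps <- unlist(lapply(st$chunks, `[[`, "timestamps"),
                         use.names = FALSE) %||% numeric(0)
    out_streams[[as.character(sid)]] <- list(
      stream_id = as.integer(sid),
      info = st$info,
      values = values,
      timestamps = timestamps,
      clock_offsets = offset_series(st$offset_time, st$offset_value,
                                    stream_uid = st$info$uid),
      footer = st$footer,
      n_samples = length(timestamps))
  }

  structure(
    list(header_xml = header_xml, streams = out_streams,
         truncated = truncated, n_skipped_chunks = n_skipped, path = path),
    class = "xdf_recording")
}

#' @export
print.xdf_recording <- function(x, ...) {
  cat(sprintf("<xdf_recording> %s\n", x$path %||% "<memory>"))
  for (s in x$streams) {
    rate <- if (s$n_samples >= 2) {
      sprintf("%.2f Hz effective", effective_srate(s$timestamps))
    } else "rate undefined"
    cat(sprintf(
      "  [%d] %s (%s): %d samples x %d ch, %s, %d offsets, footer %s\n",
      s$stream_id, s$info$name, s$info$stream_type, s$n_samples,
      s$info$channel_count, rate, nrow(s$clock_offsets),
      if (is.null(s$footer)) "ABSENT" else "present"))
  }
  if (x$truncated) cat("  (file was truncated; trailing chunk discarded)\n")
  invisible(x)
}

#' Validate footer statistics of a recording against its data
#'
#' Cross-checks, per stream with a footer, the footer's `sample_count`,
#' `first_timestamp` and `last_timestamp` against the samples actually loaded.
#'
#' @param recording An `xdf_recording` from [read_xdf()].
#' @return `TRUE` invisibly if consistent; otherwise stops with a message.
#' @export
validate_xdf <- function(recording) {
  stopifnot(inherits(recording, "xdf_recording"))
  for (s in recording$streams) {
    f <- s$footer
    if (is.null(f)) next
    if (f$sample_count != s$n_samples) {
      stop(sprintf("stream %d: footer sample_count %s != %s samples in file",
                   s$stream_id, format(f$sample_count), format(s$n_samples)))
    }
    if (s$n_samples > 0) {
      if (abs(f$first_timestamp - s$timestamps[1]) > 1e-6 ||
          abs(f$last_timestamp - s$timestamps[s$n_samples]) > 1e-6) {
        stop(sprintf("stream %d: footer first/last timestamps disagree with data",
                     s$stream_id))
      }
    }
  }
  invisible(TRUE)
}
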