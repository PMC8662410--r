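# XDF 1.0 chunk tags and framing constants.
xdf_tags <- c(FileHeader = 1L, StreamHeader = 2L, Samples = 3L,
              ClockOffset = 4L, Boundary = 5L, StreamFooter = 6L)

# Fixed 16-byte Boundary chunk payload from the XDF 1.0 layout.
xdf_boundary_uuid <- as.raw(c(0x43, 0xA5, 0x46, 0xDC, 0xCB, 0xF5, 0x41, 0x0F,
                              0xB3, 0x0E, 0xD5, 0x46, 0x73, 0x83, 0xCB, 0xE4))

xdf_format_size <- c(float32 = 4L, double64 = 8L, int32 = 4L)

# Writer omits a sample's 8-byte timestamp when it is deducible from the
# previous one as prev + 1/nominal_srate within this tolerance (seconds).
xdf_deduce_tol <- 1e-9

# Frame a chunk: [NumLengthBytes][Length][Tag u16][content]. Length counts the
# tag plus content.
encode_chunk <- function(tag, content) {
  len <- length(content) + 2
  c(varlen_raw(len), u16_raw(tag), content)
}

build_stream_header_xml <- function(info) {
  paste0(
    "<?xml version=\"1.0\"?><info>",
    "<name>", xml_escape(info$name), "</name>",
    "<type>", xml_escape(info$stream_type), "</type>",
    "<channel_count>", info$channel_count, "</channel_count>",
    "<nominal_srate>", fmt_num(info$nominal_srate), "</nominal_srate>",
    "<channel_format>", info$channel_format, "</channel_format>",
    "<source_id>", xml_escape(info$source_id), "</source_id>",
    "<uid>", xml_escape(info$uid), "</uid>",
    "</info>"
  )
}

build_stream_footer_xml <- function(footer) {
  off <- footer$offsets
  off_xml <- if (!is.null(off) && nrow(off) > 0) {
    paste0(vapply(seq_len(nrow(off)), function(i) {
      paste0("<offset><time>", fmt_num(off$collection_time[i]), "</time>",
             "<value>", fmt_num(off$offset[i]), "</value></offset>")
    }, character(1)), collapse = "")
  } else ""
  paste0(
    "<?xml version=\"1.0\"?><info>",
    "<first_timestamp>", fmt_num(footer$first_timestamp), "</first_timestamp>",
    "<last_timestamp>", fmt_num(footer$last_timestamp), "</last_timestamp>",
    "<sample_count>", format(footer$sample_count, scientific = FALSE),
    "</sample_count>",
    "<measured_srate>", fmt_num(footer$measured_srate), "</measured_srate>",
    "<clock_offsets>", off_xml, "</clock_offsets>",
    "</info>"
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Encode the numeric channel values of n samples (row-major) for one format.
encode_values_raw <- function(values, format) {
  v <- as.vector(t(values))
  switch(format,
    float32 = writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
    double64 = writeBin(as.numeric(v), raw(), size = 8L, endian = "little"),
    int32 = writeBin(as.integer(v), raw(), size = 4L, endian = "little"),
    stop("unsupported numeric format: ", format)
  )
}

# Samples chunk content: [stream_id u32][NumSamples varlen][samples...], each
# sample = [TimestampBytes u8 (0|8)][timestamp f64?][values].
encode_samples_content <- function(stream_id, values, timestamps, format,
                                   nominal_srate, prev_ts = NA_real_) {
  n <- nrow(values)
  ch <- ncol(values)
  expected <- c(prev_ts, timestamps[-n][seq_len(n - 1)]) +
    if (nominal_srate > 0) 1 / nominal_srate else NA_real_
  if (n >= 1 && nominal_srate > 0) {
    explicit <- is.na(expected) | abs(timestamps - expected) > xdf_deduce_tol
  } else {
    explicit <- rep(TRUE, n)
  }

  head_raw <- c(u32_raw(stream_id), varlen_raw(n))
  if (format == "string") {
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      ts_raw <- if (explicit[i]) {
        c(as.raw(8), writeBin(timestamps[i], raw(), size = 8L, endian = "little"))
      } else as.raw(0)
      vals <- lapply(seq_len(ch), function(j) {
        b <- charToRaw(enc2utf8(values[i, j]))
        c(varlen_raw(length(b)), b)
      })
      parts[[i]] <- c(ts_raw, unlist(vals))
    }
    return(c(head_raw, unlist(parts)))
  }

  sz <- xdf_format_size[[format]]
  vals_raw <- encode_values_raw(values, format)
  if (all(explicit)) {
    ts_raw <- writeBin(as.numeric(timestamps), raw(), size = 8L, endian = "little")
    body <- rbind(matrix(as.raw(8), 1L, n),
                  matrix(ts_raw, 8L, n),
                  matrix(vals_raw, ch * sz, n))
    c(head_raw, as.vector(body))
  } else if (!any(explicit)) {
    body <- rbind(matrix(as.raw(0), 1L, n), matrix(vals_raw, ch * sz, n))
    c(head_raw, as.vector(body))
  } else {
    vm <- matrix(vals_raw, ch * sz, n)
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      ts_raw <- if (explicit[i]) {
        c(as.raw(8), writeBin(timestamps[i], raw(), size = 8L, endian = "little"))
      } else as.raw(0)
      parts[[i]] <- c(ts_raw, vm[, i])
    }
    c(head_raw, unlist(parts))
  }
}

#' Chunked XDF file writer
#'
#' Writes the binary XDF 1.0 container produced by the recorder: `"XDF:"`
#' magic, an XML file header, then stream headers, sample chunks, clock-offset
#' chunks, boundary markers and per-stream footers. Every chunk is flushed to
#' the operating system as it is written, so an abrupt termination loses at
#' most the samples not yet handed to the writer.
#'
#' An existing file is never overwritten; the recorder guarantees unique names
#' via [make_filename()].
#'
#' @examples
#' path <- tempfile(fileext = ".xdf")
#' w <- XdfWriter$new(path)
#' info <- stream_info("s", "sine", 1, 100, "double64", "dev1", "u1")
#' w$write_stream_header(1, info)
#' w$write_samples(1, matrix(sin(1:10), ncol = 1), 0:9 / 100)
#' w$finish(list(list(stream_id = 1, first_timestamp = 0,
#'                      last_timestamp = 0.09, sample_count = 10,
#'                      measured_srate = 100,
#'                      offsets = offset_series())))
#' unlink(path)
#' @export
XdfWriter <- R6::R6Class("XdfWriter",
  public = list(
    #' @field path Path of the file being written.
    path = NULL,

    #' @param path Destination path; must not already exist.
    initialize = function(path) {
      if (dir.exists(path)) stop("path is a directory: ", path)
      if (file.exists(path)) {
        stop("refusing to overwrite existing file: ", path)
      }
      self$path <- path
      private$con <- file(path, open = "wb")
      private$streams <- new.env(parent = emptyenv())
      writeBin(charToRaw("XDF:"), private$con)
      private$write_chunk(xdf_tags[["FileHeader"]],
        charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>"))
    },

    #' @description Write a StreamHeader chunk and register the stream.
    #' @param stream_id Positive integer, unique within the file.
    #' @param info The stream's [stream_info()].
    write_stream_header = function(stream_id, info) {
      private$check_open()
      sid <- as.character(stream_id)
      if (!is.null(private$streams[[sid]])) {
        stop("stream_id ", stream_id, " already has a header")
      }
      private$streams[[sid]] <- list(
        format = info$channel_format, channel_count = info$channel_count,
        nominal_srate = info$nominal_srate, count = 0, last_ts = NA_real_)
      private$write_chunk(xdf_tags[["StreamHeader"]],
        c(u32_raw(stream_id), charToRaw(build_stream_header_xml(info))))
    },

    #' @description Write one Samples chunk for a stream.
    #' @param stream_id Stream id (header must exist).
    #' @param values `n x channel_count` matrix (character for string streams).
    #' @param timestamps Source-clock timestamps (s), length `n`.
    #' @return Bytes written (invisibly).
    write_samples = function(stream_id, values, timestamps) {
      private$check_open()
      st <- private$stream_state(stream_id)
      if (is.null(dim(values))) values <- matrix(values, ncol = st$channel_count)
      stopifnot(ncol(values) == st$channel_count,
                nrow(values) == length(timestamps))
      if (nrow(values) == 0L) return(invisible(0))
      content <- encode_samples_content(stream_id, values,
                                        as.numeric(timestamps), st$format,
                                        st$nominal_srate, st$last_ts)
      st$count <- st$count + nrow(values)
      st$last_ts <- timestamps[length(timestamps)]
      private$streams[[as.character(stream_id)]] <- st
      private$write_chunk(xdf_tags[["Samples"]], content)
    },

    #' @description Write a ClockOffset chunk.
    #' @param stream_id Stream id.
    #' @param collection_time Consumer-clock time (s).
    #' @param offset Consumer minus source clock (s).
    write_clock_offset = function(stream_id, collection_time, offset) {
      private$check_open()
      private$stream_state(stream_id)
      private$write_chunk(xdf_tags[["ClockOffset"]],
        c(u32_raw(stream_id),
          writeBin(as.numeric(c(collection_time, offset)), raw(),
                   size = 8L, endian = "little")))
    },

    #' @description Write a Boundary chunk (recovery marker).
    write_boundary = function() {
      private$check_open()
      private$write_chunk(xdf_tags[["Boundary"]], xdf_boundary_uuid)
    },

    #' @description Number of samples written so far for a stream.
    #' @param stream_id Stream id.
    sample_count = function(stream_id) private$stream_state(stream_id)$count,

    #' @description Write one StreamFooter per stream and close the file
    #'   (the finalize step of a regular stop).
    #' @param footers List of footers, each a list with `stream_id`,
    #'   `first_timestamp`, `last_timestamp`, `sample_count`,
    #'   `measured_srate` and `offsets` (an [offset_series()]).
    finish = function(footers) {
      private$check_open()
      if (private$finalized) stop("finish() called twice: file already finalized")
      for (f in footers) {
        st <- private$stream_state(f$stream_id)
        if (f$sample_count != st$count) {
          stop(sprintf(
            "footer sample_count %s does not match %s samples written for stream %s",
            format(f$sample_count), format(st$count), format(f$stream_id)))
        }
        private$write_chunk(xdf_tags[["StreamFooter"]],
          c(u32_raw(f$stream_id), charToRaw(build_stream_footer_xml(f))))
      }
      private$finalized <- TRUE
      close(private$con)
      private$open_flag <- FALSE
      invisible(self$path)
    },

    #' @description Close the file abruptly, without footers. Emulates the
    #'   recorder process being killed; the file stays readable.
    kill = function() {
      if (private$open_flag) {
        flush(private$con)
        close(private$con)
        private$open_flag <- FALSE
      }
      invisible(self$path)
    },

    #' @description Whether the file is still open for writing.
    is_open = function() private$open_flag
  ),
  private = list(
    con = NULL, streams = NULL, open_flag = TRUE, finalized = FALSE,

    check_open = function() {
      if (!private$open_flag) stop("writer is closed")
    },

    stream_state = function(stream_id) {
      st <- private$streams[[as.character(stream_id)]]
      if (is.null(st)) stop("no StreamHeader written for stream ", stream_id)
      st
    },

    write_chunk = function(tag, content) {
      bytes <- encode_chunk(tag, content)
      writeBin(bytes, private$con)
      flush(private$con)
      invisible(length(bytes))
    }
  )
)
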