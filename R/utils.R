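`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate expr under a temporary seed, restoring the caller's RNG state so
# that constructing seeded components never perturbs an outer simulation.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Little-endian unsigned integer encoders. R has no native unsigned types, so
# values are carried as doubles (exact below 2^53) and emitted byte-wise.
u16_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

u64_raw <- function(x) {
  x <- as.numeric(x)
  out <- numeric(8)
  for (i in 1:8) {
    out[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(out)
}

# Decode a little-endian unsigned integer from a raw vector (exact < 2^53).
raw_to_uint <- function(r) {
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

# Variable-length length field used by the XDF chunk framing: one byte giving
# the width of the length field (1, 4 or 8), then the length itself.
varlen_raw <- function(len) {
  if (len <= 255) {
    c(as.raw(1), as.raw(len))
  } else if (len <= 4294967295) {
    c(as.raw(4), u32_raw(len))
  } else {
    c(as.raw(8), u64_raw(len))
  }
}

# Shortest round-trippable decimal rendering for XML metadata fields.
fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
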