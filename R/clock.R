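#' Simulated device clock with offset, drift and read jitter
#'
#' A `VirtualClock` maps true (simulation) time `tau`, in seconds, onto the
#' time a device would report: `tau * (1 + drift_ppm * 1e-6) + offset0` plus
#' zero-mean Gaussian read noise. Every real device in a multi-sensor setup
#' carries such a clock, and the divergence between them is exactly what the
#' clock-offset machinery ([measure_offset()], [synchronize()]) must undo.
#'
#' Reads within one (ascending) `read()` call are clamped to be non-decreasing
#' so that jitter never makes a device clock run backwards. Read noise is drawn
#' from the R session RNG, so a simulation seeded once is fully reproducible.
#'
#' @examples
#' clk <- VirtualClock$new(offset0 = 2, drift_ppm = 50, jitter_sd = 0)
#' clk$read(100)  # 102.005
#' @export
VirtualClock <- R6::R6Class("VirtualClock",
  public = list(
    #' @field offset0 Initial offset from true time (s).
    offset0 = 0,
    #' @field drift_ppm Clock rate error in parts per million.
    drift_ppm = 0,
    #' @field jitter_sd Standard deviation of per-read noise (s).
    jitter_sd = 0,

    #' @param offset0 Initial offset from true time (s).
    #' @param drift_ppm Clock rate error in parts per million.
    #' @param jitter_sd Standard deviation of per-read noise (s).
    initialize = function(offset0 = 0, drift_ppm = 0, jitter_sd = 0) {
      stopifnot(is_scalar_number(offset0), is_scalar_number(drift_ppm),
                is_scalar_number(jitter_sd), jitter_sd >= 0)
      self$offset0 <- offset0
      self$drift_ppm <- drift_ppm
      self$jitter_sd <- jitter_sd
    },

    #' @description Read the device clock at true time(s) `tau`.
    #' @param tau Numeric vector of true times (s), ascending.
    #' @return Device time(s) in seconds, non-decreasing for ascending `tau`.
    read = function(tau) {
      out <- tau * (1 + self$drift_ppm * 1e-6) + self$offset0
      if (self$jitter_sd > 0) {
        out <- out + stats::rnorm(length(tau), 0, self$jitter_sd)
        out <- cummax(out)
      }
      out
    },

    #' @description True offset of this clock relative to true time at `tau`,
    #'   without read noise. Used as simulation ground truth in tests.
    #' @param tau True time(s) (s).
    true_offset = function(tau) {
      tau * self$drift_ppm * 1e-6 + self$offset0
    }
  )
)

#' Drift- and jitter-free clock reading true simulation time
#'
#' @return A [VirtualClock] with zero offset, drift and jitter.
#' @export
ideal_clock <- function() VirtualClock$new(0, 0, 0)
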