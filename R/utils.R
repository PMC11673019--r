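`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed for stage/index `i`, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647L)
}

#' Snap a frequency to the measurement grid
#'
#' VOCT spectra are sampled at 10 Hz steps, so any continuous frequency (for
#' instance one obtained by inverting the modulus calibration) must be rounded
#' to the nearest grid point before it can be used as a peak centre.
#'
#' @param frequency_hz numeric frequency (Hz).
#' @param step_hz grid step (Hz), default 10.
#' @return frequency rounded to the nearest multiple of `step_hz`.
#' @export
#' @examples
#' snap_to_grid(114.06) # 110
snap_to_grid <- function(frequency_hz, step_hz = 10) {
  stopifnot(is.numeric(frequency_hz), step_hz > 0)
  step_hz * round(frequency_hz / step_hz)
}
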