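#' Resonant-frequency to elastic-modulus calibration
#'
#' The empirical VOCT calibration relates the product of tensile elastic
#' modulus E and tissue thickness d to the resonant frequency fn:
#' \deqn{E \cdot d = a \, f_n^2 + b}
#' with default coefficients a = 0.0651 and b = 233.1.
#'
#' Unit convention: the calibration's source literature states the thickness
#' in metres, but the corneal moduli it reports (2--3 MPa for a ~500 um cornea
#' resonating near 110--150 Hz) only follow if the right-hand side is read as
#' MPa·um (equivalently Pa·m) with d in micrometres. This package therefore
#' takes d in um by default and exposes a `thickness_unit` flag; the
#' discrepancy is deliberate and documented rather than silently resolved.
#'
#' @param a quadratic coefficient (MPa·um per Hz^2), > 0.
#' @param b intercept (MPa·um), >= 0.
#' @return a `calibration_model` object.
#' @export
calibration_model <- function(a = 0.0651, b = 233.1) {
  stopifnot(a > 0, b >= 0)
  structure(list(a = a, b = b), class = "calibration_model")
}

thickness_to_um <- function(d, thickness_unit) {
  switch(thickness_unit, um = d, m = d * 1e6,
         stop("thickness_unit must be 'um' or 'm'", call. = FALSE))
}

#' Elastic modulus from a resonant frequency
#'
#' Evaluates E = (a fn^2 + b) / d and propagates the +/- 10 Hz frequency-grid
#' resolution by interval arithmetic: `E_low` and `E_high` are the moduli at
#' fn - 10 Hz (floored at 0 Hz) and fn + 10 Hz. Vectorized over `fn` (and `d`,
#' recycled).
#'
#' @param fn resonant frequency (Hz), >= 0.
#' @param d tissue thickness, > 0 (micrometres unless `thickness_unit = "m"`).
#' @param model a [calibration_model()].
#' @param band optional tissue-band label(s) carried through.
#' @param thickness_unit `"um"` (default) or `"m"`; see [calibration_model()].
#' @param grid_resolution_hz half-width of the frequency uncertainty
#'   (default 10 Hz, the measurement grid step).
#' @return data frame of class `modulus_estimate` with columns `fn`,
#'   `thickness_um`, `E`, `E_low`, `E_high`, `band` (E in MPa).
#' @export
#' @examples
#' modulus_from_resonance(150, 500) # 3.3957 MPa
modulus_from_resonance <- function(fn, d, model = calibration_model(),
                                   band = NA_character_,
                                   thickness_unit = c("um", "m"),
                                   grid_resolution_hz = 10) {
  thickness_unit <- match.arg(thickness_unit)
  d_um <- thickness_to_um(d, thickness_unit)
  if (any(fn < 0)) stop("resonant frequency must be non-negative", call. = FALSE)
  if (any(d_um <= 0)) stop("thickness must be positive", call. = FALSE)
  ev <- function(f) (model$a * f^2 + model$b) / d_um
  out <- data.frame(fn = fn,
                    thickness_um = rep_len(d_um, length(fn)),
                    E = ev(fn),
                    E_low = ev(pmax(fn - grid_resolution_hz, 0)),
                    E_high = ev(fn + grid_resolution_hz),
                    band = rep_len(band, length(fn)),
                    stringsAsFactors = FALSE)
  class(out) <- c("modulus_estimate", "data.frame")
  out
}

#' Resonant frequency from an elastic modulus
#'
#' Algebraic inverse of [modulus_from_resonance()]:
#' fn = sqrt((E d - b) / a). Requires E d >= b; E d = b gives fn = 0, and
#' below the intercept no real resonance exists.
#'
#' @param E elastic modulus (MPa).
#' @param d tissue thickness (micrometres unless `thickness_unit = "m"`).
#' @inheritParams modulus_from_resonance
#' @return resonant frequency (Hz).
#' @export
resonance_from_modulus <- function(E, d, model = calibration_model(),
                                   thickness_unit = c("um", "m")) {
  thickness_unit <- match.arg(thickness_unit)
  d_um <- thickness_to_um(d, thickness_unit)
  prod <- E * d_um
  if (any(prod < model$b)) {
    stop("E*d below the calibration intercept: no real resonance", call. = FALSE)
  }
  sqrt((prod - model$b) / model$a)
}

#' Peak-height-weighted average modulus
#'
#' The mean corneal modulus weighted by the amount of light reflected from
#' each tissue component, i.e. by the weighted-displacement peak heights:
#' sum(h_i E_i) / sum(h_i).
#'
#' @param heights peak heights, all > 0, at least one.
#' @param moduli component moduli (MPa), same length.
#' @return weighted average modulus (MPa); lies between min and max of
#'   `moduli` and is invariant to uniform rescaling of `heights`.
#' @export
weighted_average_modulus <- function(heights, moduli) {
  if (length(heights) == 0) stop("no peaks supplied", call. = FALSE)
  if (length(heights) != length(moduli)) {
    stop("`heights` and `moduli` must have the same length", call. = FALSE)
  }
  if (any(heights <= 0)) stop("peak heights must be positive", call. = FALSE)
  sum(heights * moduli) / sum(heights)
}

#' Per-eye modulus table for a cohort
#'
#' Detects resonant peaks in each spectrum, converts each peak frequency to a
#' component modulus using the eye's thickness (metadata field `thickness_um`
#' unless `default_thickness_um` overrides), and computes the per-eye
#' peak-height-weighted average modulus.
#'
#' @param spectra list of [voct_spectrum()] objects (speaker-normalized).
#' @param model a [calibration_model()].
#' @param min_prominence passed to [detect_peaks()].
#' @param default_thickness_um thickness used when an eye has none in
#'   metadata.
#' @return list with `peaks` (per-peak data frame: eye_id, group, stage,
#'   frequency_hz, height, band, E, E_low, E_high) and `eyes` (per-eye data
#'   frame: eye_id, group, stage, thickness_um, weighted_average_E).
#' @export
eye_modulus_table <- function(spectra, model = calibration_model(),
                              min_prominence = 0.05,
                              default_thickness_um = 550) {
  peak_rows <- list()
  eye_rows <- list()
  for (s in spectra) {
    md <- s$metadata
    d_um <- md$thickness_um %||% default_thickness_um
    pk <- detect_peaks(s, min_prominence = min_prominence)
    if (nrow(pk) == 0) next
    est <- modulus_from_resonance(pk$frequency_hz, d_um, model,
                                  band = pk$band)
    peak_rows[[length(peak_rows) + 1]] <- data.frame(
      eye_id = md$eye_id %||% NA_character_,
      group = md$group %||% NA_character_,
      stage = md$stage %||% NA_character_,
      frequency_hz = pk$frequency_hz, height = pk$height, band = pk$band,
      E = est$E, E_low = est$E_low, E_high = est$E_high,
      stringsAsFactors = FALSE)
    eye_rows[[length(eye_rows) + 1]] <- data.frame(
      eye_id = md$eye_id %||% NA_character_,
      group = md$group %||% NA_character_,
      stage = md$stage %||% NA_character_,
      thickness_um = d_um,
      weighted_average_E = weighted_average_modulus(pk$height, est$E),
      stringsAsFactors = FALSE)
  }
  list(peaks = do.call(rbind, peak_rows), eyes = do.call(rbind, eye_rows))
}
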