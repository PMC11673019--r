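#' Construct a vibrational spectrum
#'
#' A `voct_spectrum` holds one eye's weighted displacement versus driving
#' frequency on a uniform frequency grid (10 Hz steps by convention), together
#' with subject metadata and a record of how the displacements have been
#' normalized.
#'
#' @param frequencies numeric vector of driving frequencies (Hz), strictly
#'   ascending with constant spacing.
#' @param displacements numeric vector of weighted displacements
#'   (dimensionless), same length as `frequencies`, non-negative.
#' @param metadata named list; recognised fields are `eye_id`, `species`
#'   (`"human"` or `"porcine"`), `group` (`"control"`, `"kc"`,
#'   `"not_applicable"`), `stage` (KC stage `"I"`--`"IV"` or `NA`), `location`
#'   (`"central"` or `"inferior"`) and `thickness_um` (per-eye corneal
#'   thickness used by the calibration).
#' @param normalization_state one of `"raw"`, `"speaker_normalized"`,
#'   `"unit_max"`.
#' @return an object of class `voct_spectrum`.
#' @seealso [normalize_by_speaker()], [normalize_unit_max()], [detect_peaks()]
#' @export
voct_spectrum <- function(frequencies, displacements, metadata = list(),
                          normalization_state = c("raw", "speaker_normalized",
                                                  "unit_max")) {
  normalization_state <- match.arg(normalization_state)
  frequencies <- as.numeric(frequencies)
  displacements <- as.numeric(displacements)
  if (length(frequencies) != length(displacements)) {
    stop("`frequencies` and `displacements` must have the same length", call. = FALSE)
  }
  if (length(frequencies) < 2) {
    stop("a spectrum needs at least two grid frequencies", call. = FALSE)
  }
  steps <- diff(frequencies)
  if (any(steps <= 0)) {
    stop("invalid grid: frequencies must be strictly ascending with positive step",
         call. = FALSE)
  }
  if (max(abs(steps - steps[1])) > 1e-9) {
    stop("invalid grid: frequency step must be constant", call. = FALSE)
  }
  if (any(!is.finite(displacements))) {
    stop("displacements must be finite", call. = FALSE)
  }
  if (normalization_state != "raw" && any(displacements < 0)) {
    stop("normalized displacements must be non-negative", call. = FALSE)
  }
  if (normalization_state == "unit_max" &&
      abs(max(displacements) - 1) > 1e-9) {
    stop("unit_max state requires max(displacements) == 1", call. = FALSE)
  }
  structure(
    list(frequencies = frequencies,
         displacements = displacements,
         metadata = metadata,
         normalization_state = normalization_state),
    class = "voct_spectrum"
  )
}

#' @export
print.voct_spectrum <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<voct_spectrum> %s%s: %d frequencies %g-%g Hz (step %g), state=%s\n",
              md$eye_id %||% "(unnamed)",
              if (!is.null(md$species)) paste0(" [", md$species, "]") else "",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1], x$normalization_state))
  invisible(x)
}

#' Grid of a spectrum
#'
#' @param s a [voct_spectrum()].
#' @return list with elements `start`, `stop`, `step` (Hz).
#' @export
spectrum_grid <- function(s) {
  stopifnot(inherits(s, "voct_spectrum"))
  list(start = s$frequencies[1],
       stop = s$frequencies[length(s$frequencies)],
       step = s$frequencies[2] - s$frequencies[1])
}

same_grid <- function(a, b) {
  length(a$frequencies) == length(b$frequencies) &&
    max(abs(a$frequencies - b$frequencies)) < 1e-9
}

#' Normalize a raw spectrum by the speaker baseline
#'
#' Divides the raw displacement at every frequency by the speaker displacement
#' measured at the same frequency in the absence of the sample, yielding the
#' weighted displacement spectrum.
#'
#' @param raw a [voct_spectrum()] in any state (typically `"raw"`).
#' @param baseline speaker baseline spectrum on the identical grid, strictly
#'   positive everywhere.
#' @return a `voct_spectrum` in state `"speaker_normalized"`.
#' @export
normalize_by_speaker <- function(raw, baseline) {
  stopifnot(inherits(raw, "voct_spectrum"), inherits(baseline, "voct_spectrum"))
  if (!same_grid(raw, baseline)) {
    stop("grid mismatch between raw spectrum and speaker baseline", call. = FALSE)
  }
  bad <- which(baseline$displacements <= 0)
  if (length(bad) > 0) {
    stop(sprintf("speaker baseline is not strictly positive at %g Hz",
                 baseline$frequencies[bad[1]]), call. = FALSE)
  }
  voct_spectrum(raw$frequencies,
                raw$displacements / baseline$displacements,
                metadata = raw$metadata,
                normalization_state = "speaker_normalized")
}

#' Normalize a spectrum to unit maximum
#'
#' Divides by the largest displacement so values lie in \[0, 1\] with the peak
#' at exactly 1. This is the per-spectrum rescaling applied before the
#' machine-learning localization, making displacement values comparable across
#' eyes. Idempotent.
#'
#' @param s a [voct_spectrum()] with positive maximum displacement.
#' @return a `voct_spectrum` in state `"unit_max"`.
#' @export
normalize_unit_max <- function(s) {
  stopifnot(inherits(s, "voct_spectrum"))
  if (s$normalization_state == "unit_max") {
    return(s)
  }
  m <- max(s$displacements)
  if (m <= 0) {
    stop("cannot unit-max normalize: spectrum has no positive displacement",
         call. = FALSE)
  }
  voct_spectrum(s$frequencies, s$displacements / m, metadata = s$metadata,
                normalization_state = "unit_max")
}

#' Tissue-component frequency bands
#'
#' Default band windows for assigning detected resonance peaks to corneal
#' tissue components. The cellular band is widened to 70--90 Hz because the
#' epithelial-cell/keratocyte resonance is variously reported at 60--80 Hz and
#' at 80 Hz; the window is configurable.
#'
#' @return named list of `c(lower, upper)` frequency windows (Hz).
#' @export
default_bands <- function() {
  list(cells_80 = c(70, 90),
       anterior_110_120 = c(110, 120),
       posterior_140_150 = c(140, 150),
       limbus_240_250 = c(240, 250))
}

#' Assign a frequency to a tissue-component band
#'
#' @param frequency_hz numeric vector of grid frequencies (Hz).
#' @param bands band windows as produced by [default_bands()].
#' @return character vector: the band name, or `"unassigned"`.
#' @export
#' @examples
#' assign_band(c(80, 110, 150, 200, 250))
assign_band <- function(frequency_hz, bands = default_bands()) {
  vapply(frequency_hz, function(f) {
    for (nm in names(bands)) {
      w <- bands[[nm]]
      if (f >= w[1] && f <= w[2]) return(nm)
    }
    "unassigned"
  }, character(1))
}

#' Detect resonant peaks in a spectrum
#'
#' A resonant peak is a strict local maximum over the 3-point neighbourhood on
#' the frequency grid. Plateaus of equal values flanked by lower values are
#' reported once, at their lowest frequency (the documented tie-break);
#' boundary grid points count as peaks when strictly greater than their single
#' interior neighbour. Peaks below `min_prominence` times the spectrum maximum
#' are discarded, so detection is invariant under unit-max rescaling.
#'
#' @param s a [voct_spectrum()] in state `"speaker_normalized"` or
#'   `"unit_max"`.
#' @param min_prominence minimum peak height relative to the spectrum maximum
#'   (default 0.05).
#' @param bands band windows for [assign_band()].
#' @return data frame with columns `frequency_hz`, `height`, `band`, sorted by
#'   frequency (zero rows if no peak qualifies).
#' @export
detect_peaks <- function(s, min_prominence = 0.05, bands = default_bands()) {
  stopifnot(inherits(s, "voct_spectrum"))
  if (!s$normalization_state %in% c("speaker_normalized", "unit_max")) {
    stop("detect_peaks expects a speaker-normalized or unit-max spectrum",
         call. = FALSE)
  }
  x <- s$displacements
  runs <- rle(x)
  n_runs <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peak_idx <- integer(0)
  if (n_runs >= 2) {
    for (k in seq_len(n_runs)) {
      v <- runs$values[k]
      left_ok <- k > 1 && runs$values[k - 1] < v
      right_ok <- k < n_runs && runs$values[k + 1] < v
      # interior runs need both flanks lower; boundary runs need the one
      # interior flank lower
      is_peak <- if (k == 1) right_ok
      else if (k == n_runs) left_ok
      else left_ok && right_ok
      if (is_peak) peak_idx <- c(peak_idx, starts[k])
    }
  }
  thresh <- min_prominence * max(x)
  peak_idx <- peak_idx[x[peak_idx] >= thresh & x[peak_idx] > 0]
  data.frame(frequency_hz = s$frequencies[peak_idx],
             height = x[peak_idx],
             band = assign_band(s$frequencies[peak_idx], bands),
             stringsAsFactors = FALSE)
}

#' Write / read cohort spectra as CSV
#'
#' Long-format interchange: one row per (eye, frequency) measurement plus a
#' sidecar table of per-eye labels.
#'
#' @param spectra list of [voct_spectrum()] objects.
#' @param measurements_path CSV path for columns
#'   (`eye_id`, `frequency_hz`, `weighted_displacement`).
#' @param labels_path CSV path for columns
#'   (`eye_id`, `species`, `group`, `stage`, `location`, `thickness_um`).
#' @return `write_spectra_csv()` returns the paths invisibly;
#'   `read_spectra_csv()` returns a list of `voct_spectrum` objects.
#' @export
write_spectra_csv <- function(spectra, measurements_path, labels_path) {
  stopifnot(length(spectra) > 0)
  meas <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(eye_id = s$metadata$eye_id %||% NA_character_,
               frequency_hz = s$frequencies,
               weighted_displacement = s$displacements)
  }))
  labs <- do.call(rbind, lapply(spectra, function(s) {
    md <- s$metadata
    data.frame(eye_id = md$eye_id %||% NA_character_,
               species = md$species %||% NA_character_,
               group = md$group %||% NA_character_,
               stage = md$stage %||% NA_character_,
               location = md$location %||% NA_character_,
               thickness_um = md$thickness_um %||% NA_real_,
               normalization_state = s$normalization_state)
  }))
  write.csv(meas, measurements_path, row.names = FALSE)
  write.csv(labs, labels_path, row.names = FALSE)
  invisible(c(measurements = measurements_path, labels = labels_path))
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(measurements_path, labels_path) {
  meas <- read.csv(measurements_path, stringsAsFactors = FALSE)
  labs <- read.csv(labels_path, stringsAsFactors = FALSE)
  lapply(labs$eye_id, function(id) {
    m <- meas[meas$eye_id == id, ]
    m <- m[order(m$frequency_hz), ]
    l <- labs[labs$eye_id == id, ][1, ]
    voct_spectrum(m$frequency_hz, m$weighted_displacement,
                  metadata = list(eye_id = id,
                                  species = if (is.na(l$species)) NULL else l$species,
                                  group = if (is.na(l$group)) NULL else l$group,
                                  stage = if (is.na(l$stage)) NULL else l$stage,
                                  location = if (is.na(l$location)) NULL else l$location,
                                  thickness_um = if (is.na(l$thickness_um)) NULL else l$thickness_um),
                  normalization_state = l$normalization_state)
  })
}
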