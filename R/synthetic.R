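#' Resonance peak specification
#'
#' One programmed resonance in a synthetic spectrum profile, rendered as a
#' Lorentzian (damped-resonance) line shape
#' \eqn{h \, \gamma^2 / (\gamma^2 + (f - f_0)^2)} with centre \eqn{f_0},
#' height \eqn{h} and half-width at half-maximum \eqn{\gamma}.
#'
#' The default half-width of 10 Hz keeps the four corneal bands (80, 110, 150,
#' 250 Hz) mutually resolvable as local maxima on the 10 Hz measurement grid.
#'
#' @param center_frequency peak centre (Hz), positive.
#' @param height peak height (dimensionless weighted displacement), >= 0.
#' @param width resonance half-width at half-maximum (Hz), positive.
#' @return a `peak_spec` object.
#' @export
peak_spec <- function(center_frequency, height, width = 10) {
  stopifnot(center_frequency > 0, height >= 0, width > 0)
  structure(list(center_frequency = center_frequency, height = height,
                 width = width), class = "peak_spec")
}

lorentzian <- function(f, peak) {
  g2 <- peak$width^2
  peak$height * g2 / (g2 + (f - peak$center_frequency)^2)
}

#' Spectrum profile for the synthetic generator
#'
#' Describes the population a synthetic eye is drawn from: species, cohort
#' group, measurement location, the programmed resonance peaks, the additive
#' noise level, and the frequency grid (human eyes are driven at 50--250 Hz,
#' porcine at 50--300 Hz, both in 10 Hz steps).
#'
#' @param species `"human"` or `"porcine"`.
#' @param group `"control"`, `"kc"` or `"not_applicable"`.
#' @param location `"central"` or `"inferior"`.
#' @param peaks list of [peak_spec()] objects.
#' @param noise_sd standard deviation of additive Gaussian displacement noise
#'   (truncated at zero); default 0.05, i.e. 5% of the tallest default peak.
#' @param grid `c(start, stop, step)` in Hz; defaults to the species grid.
#' @return a `spectrum_profile` object.
#' @export
spectrum_profile <- function(species = c("human", "porcine"),
                             group = c("control", "kc", "not_applicable"),
                             location = c("central", "inferior"),
                             peaks = list(), noise_sd = 0.05, grid = NULL) {
  species <- match.arg(species)
  group <- match.arg(group)
  location <- match.arg(location)
  if (is.null(grid)) {
    grid <- if (species == "human") c(50, 250, 10) else c(50, 300, 10)
  }
  stopifnot(length(grid) == 3, noise_sd >= 0)
  if (grid[3] <= 0) stop("invalid grid: step must be positive", call. = FALSE)
  stopifnot(all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(species = species, group = group, location = location,
                 peaks = peaks, noise_sd = noise_sd, grid = grid),
            class = "spectrum_profile")
}

grid_frequencies <- function(grid) seq(grid[1], grid[2], by = grid[3])

# Base peak set shared by the default profiles. The limbus band is tallest so
# that per-spectrum unit-max normalization divides every eye by the (species-
# independent) limbus peak rather than by the species-contrasted 110 Hz band.
base_corneal_peaks <- function(width = 10) {
  list(peak_spec(80, 0.60, width),
       peak_spec(110, 0.80, width),
       peak_spec(150, 0.75, width),
       peak_spec(250, 1.10, width))
}

#' Default species profiles
#'
#' Human control profile with resonances at 80, 110, 150 and 250 Hz; the
#' porcine profile carries the same peak set except that the 110 Hz resonance
#' height is scaled by `porcine_110_scale` (default 0.3), emulating the
#' diminished 110 Hz peak of corneas lacking Bowman's layer, and extends to
#' the 300 Hz porcine grid.
#'
#' @param noise_sd additive noise standard deviation.
#' @param width Lorentzian half-width (Hz).
#' @param porcine_110_scale height scale of the porcine 110 Hz resonance.
#' @return a [spectrum_profile()].
#' @export
default_human_profile <- function(noise_sd = 0.05, width = 10) {
  spectrum_profile("human", "control", "central",
                   peaks = base_corneal_peaks(width), noise_sd = noise_sd)
}

#' @rdname default_human_profile
#' @export
default_porcine_profile <- function(noise_sd = 0.05, width = 10,
                                    porcine_110_scale = 0.3) {
  peaks <- base_corneal_peaks(width)
  peaks[[2]] <- peak_spec(110, peaks[[2]]$height * porcine_110_scale, width)
  spectrum_profile("porcine", "not_applicable", "central",
                   peaks = peaks, noise_sd = noise_sd)
}

#' Noiseless expected spectrum of a profile
#'
#' Sum of the programmed Lorentzian peaks on the profile grid, with no noise
#' and no per-eye variation; useful as a generator oracle.
#'
#' @param profile a [spectrum_profile()].
#' @return a [voct_spectrum()] in state `"speaker_normalized"`.
#' @export
expected_spectrum <- function(profile) {
  f <- grid_frequencies(profile$grid)
  disp <- clean_displacement(f, profile$peaks)
  voct_spectrum(f, disp,
                metadata = list(species = profile$species,
                                group = profile$group,
                                location = profile$location),
                normalization_state = "speaker_normalized")
}

clean_displacement <- function(f, peaks, warn_outside = FALSE) {
  disp <- numeric(length(f))
  for (p in peaks) {
    if (warn_outside &&
        (p$center_frequency < min(f) || p$center_frequency > max(f))) {
      warning(sprintf(
        "peak centre %g Hz lies outside the %g-%g Hz grid; only its tail contributes",
        p$center_frequency, min(f), max(f)), call. = FALSE)
    }
    disp <- disp + lorentzian(f, p)
  }
  disp
}

#' Generate a speaker displacement baseline
#'
#' The speaker baseline is the displacement measured with no sample present;
#' raw spectra are divided by it ([normalize_by_speaker()]). The synthetic
#' baseline is a smooth, slowly varying, strictly positive curve plus small
#' Gaussian noise.
#'
#' @param grid `c(start, stop, step)` in Hz; step must be positive.
#' @param seed integer RNG seed.
#' @param level mean baseline displacement.
#' @param noise_sd additive noise standard deviation; with `noise_sd = 0` the
#'   baseline equals its smooth component exactly.
#' @return a [voct_spectrum()] in state `"raw"`, all values > 0.
#' @export
generate_speaker_baseline <- function(grid = c(50, 250, 10), seed = 1L,
                                      level = 2, noise_sd = 0.02) {
  stopifnot(length(grid) == 3)
  if (grid[3] <= 0) stop("invalid grid: step must be positive", call. = FALSE)
  f <- grid_frequencies(grid)
  smooth <- speaker_baseline_shape(f, level)
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(f), 0, noise_sd))
  } else {
    numeric(length(f))
  }
  disp <- pmax(smooth + noise, .Machine$double.eps)
  voct_spectrum(f, disp, metadata = list(eye_id = "speaker_baseline"),
                normalization_state = "raw")
}

#' @rdname generate_speaker_baseline
#' @param frequencies frequency vector (Hz) at which to evaluate the smooth
#'   component.
#' @export
speaker_baseline_shape <- function(frequencies, level = 2) {
  span <- max(frequencies) - min(frequencies)
  level * (1 + 0.25 * cos(pi * (frequencies - min(frequencies)) / span))
}

#' Generate one synthetic VOCT spectrum
#'
#' Evaluates the profile's Lorentzian peaks on its grid, adds seeded Gaussian
#' noise truncated at zero, and attaches the profile metadata. When a speaker
#' `baseline` is supplied the returned spectrum is the corresponding raw
#' measurement (normalized signal times baseline, state `"raw"`), so that
#' [normalize_by_speaker()] recovers the weighted displacement exactly.
#'
#' @param profile a [spectrum_profile()].
#' @param seed integer RNG seed.
#' @param eye_id optional subject identifier stored in metadata.
#' @param baseline optional speaker baseline on the identical grid.
#' @param height_scales optional numeric vector multiplying each programmed
#'   peak height (per-eye variability; used by the cohort generators).
#' @return a [voct_spectrum()].
#' @export
generate_spectrum <- function(profile, seed = 1L, eye_id = NULL,
                              baseline = NULL, height_scales = NULL) {
  stopifnot(inherits(profile, "spectrum_profile"))
  f <- grid_frequencies(profile$grid)
  peaks <- profile$peaks
  if (!is.null(height_scales)) {
    stopifnot(length(height_scales) == length(peaks))
    peaks <- Map(function(p, s) peak_spec(p$center_frequency,
                                          p$height * s, p$width),
                 peaks, height_scales)
  }
  clean <- clean_displacement(f, peaks, warn_outside = TRUE)
  noise <- if (profile$noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(f), 0, profile$noise_sd))
  } else {
    numeric(length(f))
  }
  disp <- pmax(clean + noise, 0)
  md <- list(eye_id = eye_id, species = profile$species,
             group = profile$group, stage = NULL,
             location = profile$location)
  if (is.null(baseline)) {
    return(voct_spectrum(f, disp, metadata = md,
                         normalization_state = "speaker_normalized"))
  }
  stopifnot(inherits(baseline, "voct_spectrum"))
  if (length(baseline$frequencies) != length(f) ||
      max(abs(baseline$frequencies - f)) > 1e-9) {
    stop("grid mismatch between profile and speaker baseline", call. = FALSE)
  }
  voct_spectrum(f, disp * baseline$displacements, metadata = md,
                normalization_state = "raw")
}

#' Cohort design: control and keratoconus counts
#'
#' Defaults mirror the clinical cohort the analyses assume: 41 normal control
#' eyes and 22 keratoconus eyes staged I (2), II (9), III (3), IV (8).
#'
#' @param n_control number of control eyes.
#' @param n_kc_by_stage counts for KC stages I--IV (length 4).
#' @param seed integer RNG seed driving all per-eye randomness.
#' @return a `cohort_design` object.
#' @export
cohort_design <- function(n_control = 41, n_kc_by_stage = c(2, 9, 3, 8),
                          seed = 1L) {
  stopifnot(length(n_kc_by_stage) == 4, n_control >= 0,
            all(n_kc_by_stage >= 0))
  structure(list(n_control = as.integer(n_control),
                 n_kc_by_stage = as.integer(n_kc_by_stage),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Contrast parameters for the control/KC cohort
#'
#' The keratoconus contrast is encoded physically through the calibration
#' inverse: the central-stroma resonance of a control eye sits at
#' \eqn{f_n = \sqrt{(E d - b)/a}} for the healthy central modulus and
#' thickness (3.1 MPa, 550 um -> 150 Hz), while the thinner, softer KC cornea
#' (2.4 MPa, 450 um) resonates near 114 Hz, snapped to the 110 Hz grid point.
#'
#' @param healthy_modulus_mpa,kc_modulus_mpa central corneal moduli (MPa).
#' @param healthy_thickness_um,kc_thickness_um central corneal thickness (um).
#' @param model a [calibration_model()].
#' @param height_jitter_sd per-eye multiplicative peak-height jitter sd.
#' @param noise_sd additive spectrum noise sd.
#' @param peak_width Lorentzian half-width (Hz).
#' @return named list of contrast parameters.
#' @export
cohort_contrast <- function(healthy_modulus_mpa = 3.1, kc_modulus_mpa = 2.4,
                            healthy_thickness_um = 550,
                            kc_thickness_um = 450,
                            model = calibration_model(),
                            height_jitter_sd = 0.05, noise_sd = 0.05,
                            peak_width = 10) {
  list(healthy_modulus_mpa = healthy_modulus_mpa,
       kc_modulus_mpa = kc_modulus_mpa,
       healthy_thickness_um = healthy_thickness_um,
       kc_thickness_um = kc_thickness_um,
       model = model,
       height_jitter_sd = height_jitter_sd,
       noise_sd = noise_sd,
       peak_width = peak_width)
}

cohort_profile <- function(group, contrast) {
  w <- contrast$peak_width
  if (group == "control") {
    E <- contrast$healthy_modulus_mpa
    d <- contrast$healthy_thickness_um
  } else {
    E <- contrast$kc_modulus_mpa
    d <- contrast$kc_thickness_um
  }
  central_fn <- snap_to_grid(resonance_from_modulus(E, d, contrast$model))
  peaks <- list(peak_spec(80, 0.60, w),
                peak_spec(110, 0.80, w),
                peak_spec(central_fn, 0.75, w),
                peak_spec(250, 1.10, w))
  spectrum_profile("human", group, "central", peaks = peaks,
                   noise_sd = contrast$noise_sd)
}

#' Generate a labelled control/keratoconus cohort
#'
#' Draws `n_control` control eyes and the staged KC eyes from profiles whose
#' central-stroma resonance encodes the group's central modulus and thickness
#' (see [cohort_contrast()]). Per-eye peak heights are jittered
#' multiplicatively; all randomness flows from `design$seed`.
#'
#' @param design a [cohort_design()].
#' @param contrast a [cohort_contrast()].
#' @return list of [voct_spectrum()] objects with `eye_id`, `group`, `stage`
#'   and `thickness_um` metadata; length `n_control + sum(n_kc_by_stage)`.
#' @export
generate_cohort <- function(design = cohort_design(),
                            contrast = cohort_contrast()) {
  stopifnot(inherits(design, "cohort_design"))
  stages <- c("I", "II", "III", "IV")
  plan <- data.frame(
    group = c(rep("control", design$n_control),
              rep("kc", sum(design$n_kc_by_stage))),
    stage = c(rep(NA_character_, design$n_control),
              rep(stages, times = design$n_kc_by_stage)),
    stringsAsFactors = FALSE)
  if (nrow(plan) == 0) return(list())
  profiles <- list(control = cohort_profile("control", contrast),
                   kc = cohort_profile("kc", contrast))
  lapply(seq_len(nrow(plan)), function(i) {
    grp <- plan$group[i]
    prof <- profiles[[grp]]
    eye_seed <- derive_seed(design$seed, i)
    scales <- if (contrast$height_jitter_sd > 0) {
      withr::with_seed(eye_seed,
                       pmax(rnorm(length(prof$peaks), 1,
                                  contrast$height_jitter_sd), 0.1))
    } else {
      rep(1, length(prof$peaks))
    }
    s <- generate_spectrum(prof, seed = derive_seed(eye_seed, 1),
                           eye_id = sprintf("%s%02d",
                                            if (grp == "control") "C" else "K", i),
                           height_scales = scales)
    s$metadata$stage <- plan$stage[i]
    s$metadata$thickness_um <- if (grp == "control") {
      contrast$healthy_thickness_um
    } else {
      contrast$kc_thickness_um
    }
    s
  })
}

#' Generate a human/porcine species cohort on the common grid
#'
#' Both species are drawn from the same peak-height distributions on the
#' common 50--250 Hz grid; the only systematic difference is the 110 Hz bin,
#' whose clean amplitude is scaled by `porcine_110_scale` for porcine eyes
#' (emulating the absence of Bowman's layer). Confinement of the contrast to
#' the single 110 Hz grid bin makes the localization problem exactly posed:
#' in the noiseless limit the species means agree at every other frequency.
#'
#' @param n_human,n_porcine eyes per species (>= 1).
#' @param seed integer RNG seed.
#' @param porcine_110_scale multiplicative reduction of the porcine 110 Hz
#'   amplitude (default 0.3).
#' @param contrast_frequency_hz the contrasted grid bin (default 110 Hz).
#' @param noise_sd additive noise sd; `0` gives the noiseless limit.
#' @param height_jitter_sd per-eye multiplicative peak-height jitter sd.
#' @param peak_width Lorentzian half-width (Hz).
#' @return list of `n_human + n_porcine` [voct_spectrum()] objects with
#'   `species` metadata, all on the identical 21-point grid.
#' @export
generate_species_cohort <- function(n_human = 20, n_porcine = 20, seed = 1L,
                                    porcine_110_scale = 0.3,
                                    contrast_frequency_hz = 110,
                                    noise_sd = 0.05, height_jitter_sd = 0.05,
                                    peak_width = 10) {
  stopifnot(n_human >= 1, n_porcine >= 1)
  grid <- c(50, 250, 10)
  f <- grid_frequencies(grid)
  base <- base_corneal_peaks(peak_width)
  species <- c(rep("human", n_human), rep("porcine", n_porcine))
  lapply(seq_along(species), function(i) {
    sp <- species[i]
    eye_seed <- derive_seed(seed, i)
    scales <- if (height_jitter_sd > 0) {
      withr::with_seed(eye_seed,
                       pmax(rnorm(length(base), 1, height_jitter_sd), 0.1))
    } else {
      rep(1, length(base))
    }
    peaks <- Map(function(p, s) peak_spec(p$center_frequency, p$height * s,
                                          p$width), base, scales)
    clean <- clean_displacement(f, peaks)
    if (sp == "porcine") {
      clean[f == contrast_frequency_hz] <-
        clean[f == contrast_frequency_hz] * porcine_110_scale
    }
    noise <- if (noise_sd > 0) {
      withr::with_seed(derive_seed(eye_seed, 1), rnorm(length(f), 0, noise_sd))
    } else {
      numeric(length(f))
    }
    voct_spectrum(f, pmax(clean + noise, 0),
                  metadata = list(eye_id = sprintf("%s%02d",
                                                   toupper(substr(sp, 1, 1)), i),
                                  species = sp, group = "not_applicable",
                                  location = "central"),
                  normalization_state = "speaker_normalized")
  })
}

#' Expected species spectrum (noiseless, no jitter)
#'
#' The generator mean for one species in [generate_species_cohort()]: base
#' peaks on the common grid with the porcine 110 Hz bin reduction applied.
#'
#' @inheritParams generate_species_cohort
#' @param species `"human"` or `"porcine"`.
#' @return a [voct_spectrum()].
#' @export
expected_species_spectrum <- function(species = c("human", "porcine"),
                                      porcine_110_scale = 0.3,
                                      contrast_frequency_hz = 110,
                                      peak_width = 10) {
  species <- match.arg(species)
  f <- grid_frequencies(c(50, 250, 10))
  clean <- clean_displacement(f, base_corneal_peaks(peak_width))
  if (species == "porcine") {
    clean[f == contrast_frequency_hz] <-
      clean[f == contrast_frequency_hz] * porcine_110_scale
  }
  voct_spectrum(f, clean, metadata = list(species = species),
                normalization_state = "speaker_normalized")
}

#' Stack a cohort into an eyes-by-frequency matrix
#'
#' Unit-max normalizes each spectrum (idempotent) and binds displacements into
#' a matrix with one row per eye and one column per grid frequency; all
#' spectra must share the grid.
#'
#' @param spectra list of [voct_spectrum()] objects.
#' @param normalize apply [normalize_unit_max()] per spectrum (default TRUE).
#' @return numeric matrix; rownames are eye ids, colnames frequencies in Hz.
#' @export
cohort_matrix <- function(spectra, normalize = TRUE) {
  stopifnot(length(spectra) > 0)
  ref <- spectra[[1]]
  for (s in spectra) {
    if (!same_grid(ref, s)) stop("cohort spectra do not share a grid", call. = FALSE)
  }
  rows <- lapply(spectra, function(s) {
    if (normalize) s <- normalize_unit_max(s)
    s$displacements
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(seq_along(spectra), function(i) {
    spectra[[i]]$metadata$eye_id %||% sprintf("eye%02d", i)
  }, character(1))
  colnames(m) <- ref$frequencies
  m
}

#' Extract a metadata label vector from a cohort
#'
#' @param spectra list of [voct_spectrum()] objects.
#' @param field metadata field name (default `"species"`).
#' @return character vector, `NA` where the field is absent.
#' @export
cohort_labels <- function(spectra, field = "species") {
  vapply(spectra, function(s) {
    v <- s$metadata[[field]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
}
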