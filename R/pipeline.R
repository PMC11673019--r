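#' Default pipeline configuration
#'
#' Nested list of per-stage settings driving [run_pipeline()]: cohort design
#' (41 control + 22 staged KC eyes), species cohort (20 + 20 eyes), generator
#' noise and jitter, calibration coefficients, machine-learning settings, and
#' the paired FEM cases (healthy E = 3.1 MPa vs keratoconic E = 2.4 MPa,
#' nu = 0.42, 2000 Pa, ~1024 elements). Every stochastic stage derives its
#' seed from the single top-level `seed`. The configuration round-trips
#' losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param seed integer master seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 101L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_control = 41L, n_kc_by_stage = c(2L, 9L, 3L, 8L)),
    species_cohort = list(n_human = 20L, n_porcine = 20L,
                          porcine_110_scale = 0.3),
    generator = list(noise_sd = 0.05, height_jitter_sd = 0.05,
                     peak_width_hz = 10, baseline_level = 2,
                     baseline_noise_sd = 0.02),
    calibration = list(a = 0.0651, b = 233.1, thickness_unit = "um",
                       min_prominence = 0.05),
    ml = list(n_folds = 5L, n_repeats_svc = 20L, n_repeats_vbgmm = 1L,
              cost = 1),
    fem = list(enabled = TRUE, n_elements = 1024L, iop_pa = 2000,
               poisson_ratio = 0.42, density_g_cm3 = 1.038,
               healthy = list(elastic_modulus_mpa = 3.1,
                              central_thickness_um = 550,
                              peripheral_thickness_um = 700),
               kc = list(elastic_modulus_mpa = 2.4,
                         central_thickness_um = 450,
                         peripheral_thickness_um = 750),
               corneal_diameter_mm = 11.5, anterior_radius_mm = 7.8)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list (see [default_pipeline_config()]).
#' @return `read_pipeline_config()` returns the configuration list;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_log <- function(quiet, stage, t0) {
  if (!quiet) {
    message(sprintf("[%s] done in %.2f s", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
}

#' Run the end-to-end VOCT analysis pipeline
#'
#' Orchestrates simulate -> normalize/peaks -> calibrate -> localize -> FEM
#' from one configuration, writing stage artefacts (cohort and peak CSVs,
#' accuracy curves, FEM summaries, VTK fields) under `out_dir` plus one
#' aggregate `report.json`. Deterministic: identical configuration (including
#' its seed) gives a byte-identical report.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("simulate", "spectra", "calibrate", "localize", "fem")`; the report is
#'   always written. Stages build on the artefacts of earlier ones, which
#'   must then be included (or already present from a previous run's files is
#'   not supported: stages recompute in-memory).
#' @param quiet suppress per-stage timing messages.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("corneavoct_run_"),
                         stages = c("simulate", "spectra", "calibrate",
                                    "localize", "fem"),
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  model <- calibration_model(config$calibration$a, config$calibration$b)
  report <- list(seed = seed)

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_log(quiet, name, t0)
    out
  }

  # -- simulate ---------------------------------------------------------
  cohort <- species <- baseline <- NULL
  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", {
      gen <- config$generator
      contrast <- cohort_contrast(model = model,
                                  height_jitter_sd = gen$height_jitter_sd,
                                  noise_sd = gen$noise_sd,
                                  peak_width = gen$peak_width_hz)
      cohort <- generate_cohort(
        cohort_design(config$cohort$n_control,
                      config$cohort$n_kc_by_stage,
                      seed = derive_seed(seed, 1)),
        contrast)
      species <- generate_species_cohort(
        config$species_cohort$n_human, config$species_cohort$n_porcine,
        seed = derive_seed(seed, 2),
        porcine_110_scale = config$species_cohort$porcine_110_scale,
        noise_sd = gen$noise_sd,
        height_jitter_sd = gen$height_jitter_sd,
        peak_width = gen$peak_width_hz)
      baseline <- generate_speaker_baseline(
        c(50, 250, 10), seed = derive_seed(seed, 3),
        level = gen$baseline_level, noise_sd = gen$baseline_noise_sd)
      write_spectra_csv(cohort, file.path(out_dir, "cohort_spectra.csv"),
                        file.path(out_dir, "cohort_labels.csv"))
      write_spectra_csv(species, file.path(out_dir, "species_spectra.csv"),
                        file.path(out_dir, "species_labels.csv"))
      write_spectra_csv(list(baseline),
                        file.path(out_dir, "speaker_baseline.csv"),
                        file.path(out_dir, "speaker_baseline_labels.csv"))
      list(cohort = cohort, species = species, baseline = baseline)
    })
    cohort <- sim$cohort; species <- sim$species; baseline <- sim$baseline
    report$cohort <- list(n_control = config$cohort$n_control,
                          n_kc = sum(config$cohort$n_kc_by_stage))
  }

  # -- spectra: peak tables --------------------------------------------
  if ("spectra" %in% stages && !is.null(cohort)) {
    run_stage("spectra", {
      peaks <- do.call(rbind, lapply(cohort, function(s) {
        pk <- detect_peaks(s, config$calibration$min_prominence)
        if (nrow(pk) == 0) return(NULL)
        cbind(eye_id = s$metadata$eye_id, pk)
      }))
      write.csv(peaks, file.path(out_dir, "cohort_peaks.csv"),
                row.names = FALSE)
    })
  }

  # -- calibrate --------------------------------------------------------
  if ("calibrate" %in% stages && !is.null(cohort)) {
    moduli <- run_stage("calibrate", {
      tab <- eye_modulus_table(cohort, model,
                               min_prominence = config$calibration$min_prominence)
      write.csv(tab$peaks, file.path(out_dir, "moduli_per_peak.csv"),
                row.names = FALSE)
      write.csv(tab$eyes, file.path(out_dir, "moduli_per_eye.csv"),
                row.names = FALSE)
      tab
    })
    band_mean <- stats::aggregate(E ~ band + group, data = moduli$peaks, FUN = mean)
    eye_mean <- stats::aggregate(weighted_average_E ~ group, data = moduli$eyes,
                                 FUN = mean)
    report$moduli <- list(
      per_band_mean_E_mpa = stats::setNames(
        lapply(split(band_mean, band_mean$group),
               function(d) as.list(stats::setNames(round(d$E, 6), d$band))),
        unique(band_mean$group)),
      weighted_average_E_mpa = as.list(
        stats::setNames(round(eye_mean$weighted_average_E, 6), eye_mean$group)))
  }

  # -- localize ---------------------------------------------------------
  if ("localize" %in% stages && !is.null(species)) {
    loc <- run_stage("localize", {
      scan <- vbgmm_frequency_scan(species,
                                   n_repeats = config$ml$n_repeats_vbgmm,
                                   seed = derive_seed(seed, 4))
      abl <- svc_leave_one_frequency_out(species,
                                         n_folds = config$ml$n_folds,
                                         n_repeats = config$ml$n_repeats_svc,
                                         seed = derive_seed(seed, 5),
                                         cost = config$ml$cost)
      write.csv(rbind(scan, abl), file.path(out_dir, "accuracy_curves.csv"),
                row.names = FALSE)
      list(scan = locate_distinguishing_frequency(scan),
           abl = locate_distinguishing_frequency(abl))
    })
    report$localization <- list(
      vbgmm_scan_frequency_hz = loc$scan$distinguishing_frequency_hz,
      svc_ablation_frequency_hz = loc$abl$distinguishing_frequency_hz)
    jsonlite::write_json(report$localization,
                         file.path(out_dir, "localization.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # -- fem --------------------------------------------------------------
  if ("fem" %in% stages && isTRUE(config$fem$enabled)) {
    fem <- run_stage("fem", {
      fc <- config$fem
      healthy_geom <- cornea_geometry(fc$healthy$central_thickness_um,
                                      fc$healthy$peripheral_thickness_um,
                                      fc$corneal_diameter_mm,
                                      fc$anterior_radius_mm, "healthy")
      kc_geom <- cornea_geometry(fc$kc$central_thickness_um,
                                 fc$kc$peripheral_thickness_um,
                                 fc$corneal_diameter_mm,
                                 fc$anterior_radius_mm, "keratoconic",
                                 reference = healthy_geom)
      cmp <- cornea_deflection_comparison(
        healthy_geom, kc_geom,
        material_properties(fc$healthy$elastic_modulus_mpa,
                            fc$poisson_ratio, fc$density_g_cm3),
        material_properties(fc$kc$elastic_modulus_mpa,
                            fc$poisson_ratio, fc$density_g_cm3),
        load_case(fc$iop_pa), n_elements = fc$n_elements)
      write_vtk(cmp$healthy, file.path(out_dir, "deflection_healthy.vtk"))
      write_vtk(cmp$kc, file.path(out_dir, "deflection_kc.vtk"))
      write_deflection_csv(cmp$healthy,
                           file.path(out_dir, "deflection_healthy.csv"))
      write_deflection_csv(cmp$kc, file.path(out_dir, "deflection_kc.csv"))
      cmp$summary
    })
    report$fem <- list(
      healthy_central_deflection_um = fem$healthy_central_deflection_um,
      kc_central_deflection_um = fem$kc_central_deflection_um,
      kc_to_healthy_ratio = fem$kc_to_healthy_ratio)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
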