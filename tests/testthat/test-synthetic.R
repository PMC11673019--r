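test_that("speaker baseline is positive, seeded, and exactly smooth when noiseless", {
  b <- generate_speaker_baseline(c(50, 250, 10), seed = 11)
  expect_length(b$displacements, 21)
  expect_true(all(b$displacements > 0))

  # seeded determinism
  expect_identical(generate_speaker_baseline(c(50, 250, 10), seed = 11), b)
  expect_false(identical(generate_speaker_baseline(c(50, 250, 10), seed = 12), b))

  # degenerate noise: baseline equals its smooth component
  b0 <- generate_speaker_baseline(c(50, 250, 10), seed = 11, noise_sd = 0)
  expect_equal(b0$displacements, speaker_baseline_shape(b0$frequencies, 2))

  expect_error(generate_speaker_baseline(c(50, 250, 0)), "invalid grid")
  expect_error(generate_speaker_baseline(c(50, 250, -10)), "invalid grid")
})

test_that("spectrum generation renders Lorentzian peaks with truncated noise", {
  # zero peaks, zero noise -> all-zero spectrum
  empty <- spectrum_profile("human", peaks = list(), noise_sd = 0)
  expect_equal(generate_spectrum(empty, seed = 1)$displacements, rep(0, 21))

  # porcine default has a diminished 110 Hz resonance (noiseless)
  h <- expected_spectrum(default_human_profile(noise_sd = 0))
  p <- expected_spectrum(default_porcine_profile(noise_sd = 0))
  at110 <- function(s) s$displacements[s$frequencies == 110]
  expect_lt(at110(p), at110(h))

  # seeded determinism
  prof <- default_human_profile()
  expect_identical(generate_spectrum(prof, seed = 5),
                   generate_spectrum(prof, seed = 5))

  # off-grid peak centre warns but still contributes tail mass
  far <- spectrum_profile("human", peaks = list(peak_spec(300, 1, 10)),
                          noise_sd = 0)
  expect_warning(s <- generate_spectrum(far, seed = 1), "outside")
  expect_true(all(s$displacements > 0))

  # raw generation round-trips through speaker normalization
  base <- generate_speaker_baseline(c(50, 250, 10), seed = 2)
  raw <- generate_spectrum(prof, seed = 9, baseline = base)
  expect_identical(raw$normalization_state, "raw")
  norm <- normalize_by_speaker(raw, base)
  direct <- generate_spectrum(prof, seed = 9)
  expect_equal(norm$displacements, direct$displacements, tolerance = 1e-12)
})

test_that("control/KC cohort matches the design counts and labels exactly", {
  coh <- generate_cohort(cohort_design(seed = 21))
  expect_length(coh, 63)
  groups <- cohort_labels(coh, "group")
  expect_equal(sum(groups == "control"), 41)
  expect_equal(sum(groups == "kc"), 22)
  stages <- cohort_labels(coh, "stage")
  expect_equal(unname(table(stages)[c("I", "II", "III", "IV")]),
               c(2L, 9L, 3L, 8L), ignore_attr = TRUE)

  # KC eyes carry the thinner central cornea in metadata
  th <- vapply(coh, function(s) s$metadata$thickness_um, numeric(1))
  expect_true(all(th[groups == "control"] == 550))
  expect_true(all(th[groups == "kc"] == 450))

  # empty design -> empty cohort
  expect_length(generate_cohort(cohort_design(0, c(0, 0, 0, 0))), 0)

  # byte-identical under the same design seed
  expect_identical(generate_cohort(cohort_design(seed = 21)), coh)
})

test_that("KC profile shifts the central-stroma resonance via the calibration inverse", {
  contrast <- cohort_contrast(noise_sd = 0, height_jitter_sd = 0)
  coh <- generate_cohort(cohort_design(1, c(1, 0, 0, 0), seed = 2), contrast)
  pk_control <- detect_peaks(coh[[1]])
  pk_kc <- detect_peaks(coh[[2]])
  # healthy central band resonates at 150 Hz (3.1 MPa, 550 um)
  expect_true(150 %in% pk_control$frequency_hz)
  # KC central band collapses onto the 110 Hz point (2.4 MPa, 450 um)
  expect_false(150 %in% pk_kc$frequency_hz)
  expect_true(110 %in% pk_kc$frequency_hz)
})

test_that("species cohort confines the systematic contrast to the 110 Hz bin", {
  coh <- generate_species_cohort(20, 20, seed = 8)
  expect_length(coh, 40)
  expect_true(all(vapply(coh, function(s) length(s$frequencies), numeric(1)) == 21))
  expect_equal(unname(table(cohort_labels(coh))), c(20L, 20L), ignore_attr = TRUE)

  tiny <- generate_species_cohort(1, 1, seed = 8)
  expect_equal(tiny[[1]]$frequencies, tiny[[2]]$frequencies)

  # noiseless, jitter-free limit: species means differ only at 110 Hz
  h <- generate_species_cohort(1, 1, seed = 1, noise_sd = 0,
                               height_jitter_sd = 0)
  f <- h[[1]]$frequencies
  diff_mask <- abs(h[[1]]$displacements - h[[2]]$displacements) > 1e-12
  expect_equal(f[diff_mask], 110)
  expect_gt(h[[1]]$displacements[f == 110], h[[2]]$displacements[f == 110])

  # generator means match the closed-form expected spectra
  expect_equal(h[[1]]$displacements,
               expected_species_spectrum("human")$displacements)
  expect_equal(h[[2]]$displacements,
               expected_species_spectrum("porcine")$displacements)
})

test_that("generated spectra always satisfy the grid and sign invariants", {
  for (seed in 1:5) {
    coh <- c(generate_species_cohort(3, 3, seed = seed),
             generate_cohort(cohort_design(2, c(1, 1, 0, 0), seed = seed)))
    for (s in coh) {
      expect_s3_class(s, "voct_spectrum")
      expect_equal(unique(diff(s$frequencies)), 10)
      expect_true(all(s$displacements >= 0))
      # reconstruction through the validating constructor succeeds
      expect_silent(voct_spectrum(s$frequencies, s$displacements,
                                  s$metadata, s$normalization_state))
    }
  }
})
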