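test_that("speaker normalization is the pointwise ratio with strict contracts", {
  f <- seq(50, 250, 10)
  raw <- voct_spectrum(f, rep(1, 21), normalization_state = "raw")
  base2 <- voct_spectrum(f, rep(2, 21), normalization_state = "raw")

  # raw == baseline -> all ones
  expect_equal(normalize_by_speaker(raw, raw)$displacements, rep(1, 21))
  # raw all 1, baseline all 2 -> all 0.5
  out <- normalize_by_speaker(raw, base2)
  expect_equal(out$displacements, rep(0.5, 21))
  expect_identical(out$normalization_state, "speaker_normalized")

  # mismatched grids rejected
  base_long <- voct_spectrum(seq(50, 300, 10), rep(2, 26),
                             normalization_state = "raw")
  expect_error(normalize_by_speaker(raw, base_long), "grid mismatch")

  # non-positive baseline rejected, naming the offending frequency
  bad <- voct_spectrum(f, c(rep(2, 5), 0, rep(2, 15)),
                       normalization_state = "raw")
  expect_error(normalize_by_speaker(raw, bad), "100 Hz")
})

test_that("unit-max normalization maps to [0,1] with max exactly 1 and is idempotent", {
  s <- flat_spectrum(c(2, 4, 1))
  out <- normalize_unit_max(s)
  expect_equal(out$displacements, c(0.5, 1, 0.25))
  expect_identical(out$normalization_state, "unit_max")
  expect_identical(normalize_unit_max(out), out)

  expect_error(normalize_unit_max(flat_spectrum(c(0, 0, 0))),
               "no positive displacement")
})

test_that("peak detection recovers programmed resonances and honours tie-breaks", {
  # generator round trip: noiseless default human profile
  clean <- expected_spectrum(default_human_profile(noise_sd = 0))
  pk <- detect_peaks(clean)
  expect_equal(pk$frequency_hz, c(80, 110, 150, 250))
  expect_equal(pk$band, c("cells_80", "anterior_110_120",
                          "posterior_140_150", "limbus_240_250"))

  # constant spectrum has no peaks
  expect_equal(nrow(detect_peaks(flat_spectrum(rep(1, 10)))), 0)

  # two equal adjacent maxima: the lower frequency is reported once
  plateau <- flat_spectrum(c(0.1, 1, 1, 0.1, 0.1))
  expect_equal(detect_peaks(plateau)$frequency_hz, 60)

  # boundary point is a peak when strictly above its interior neighbour
  ramp <- flat_spectrum(c(0.1, 0.2, 0.5, 0.8, 1))
  expect_equal(detect_peaks(ramp)$frequency_hz, 90)

  # detection invariant under unit-max rescaling (relative prominence)
  s <- flat_spectrum(c(0.2, 2, 0.3, 5, 0.1, 1, 0.2))
  expect_equal(detect_peaks(normalize_unit_max(s))$frequency_hz,
               detect_peaks(s)$frequency_hz)

  # prominence threshold removes small bumps
  weak <- flat_spectrum(c(0.1, 0.102, 0.1, 10, 0.1))
  expect_equal(detect_peaks(weak, min_prominence = 0.05)$frequency_hz, 80)

  # raw spectra must be normalized before peak picking
  expect_error(detect_peaks(flat_spectrum(1:5, state = "raw")),
               "speaker-normalized or unit-max")
})

test_that("band assignment follows the tissue-component windows", {
  expect_equal(assign_band(c(70, 80, 90, 110, 120, 140, 150, 240, 250)),
               c("cells_80", "cells_80", "cells_80",
                 "anterior_110_120", "anterior_110_120",
                 "posterior_140_150", "posterior_140_150",
                 "limbus_240_250", "limbus_240_250"))
  expect_equal(assign_band(c(50, 100, 130, 200, 300)),
               rep("unassigned", 5))
})

test_that("spectrum constructor enforces the uniform ascending grid", {
  expect_error(voct_spectrum(c(50, 60, 80), c(1, 1, 1)), "constant")
  expect_error(voct_spectrum(c(50, 50, 60), c(1, 1, 1)), "ascending")
  expect_error(voct_spectrum(c(50, 60), c(1, 1, 1)), "same length")
  expect_error(voct_spectrum(seq(50, 70, 10), c(1, -1, 1),
                             normalization_state = "speaker_normalized"),
               "non-negative")
})

test_that("cohort CSV round trip preserves spectra and labels", {
  coh <- generate_cohort(cohort_design(2, c(1, 0, 0, 0), seed = 3))
  m <- tempfile(fileext = ".csv"); l <- tempfile(fileext = ".csv")
  write_spectra_csv(coh, m, l)
  back <- read_spectra_csv(m, l)
  expect_equal(length(back), 3)
  expect_equal(back[[1]]$displacements, coh[[1]]$displacements)
  expect_equal(back[[3]]$metadata$stage, "I")
  expect_equal(back[[3]]$metadata$thickness_um, 450)
  unlink(c(m, l))
})
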