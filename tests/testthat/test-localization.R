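test_that("cluster-to-class accuracy is permutation-invariant and matches the chance oracle", {
  truth <- rep(c("a", "b"), each = 20)
  expect_equal(clustering_accuracy(rep(1:2, each = 20), truth), 1)
  # inverted cluster ids score identically (label symmetry)
  expect_equal(clustering_accuracy(rep(2:1, each = 20), truth), 1)
  expect_error(clustering_accuracy(1:3, c("a", "b")), "same length")
  expect_error(clustering_accuracy(c(1, 2, 3, 1), truth[1:4]), "two distinct")

  # random assignments: Monte-Carlo mean equals the folded-binomial closed
  # form E[max(m, n - m)] / n with m ~ Binomial(n, 1/2)
  n <- 40
  closed_form <- sum(vapply(0:n, function(k) {
    stats::dbinom(k, n, 0.5) * max(k, n - k) / n
  }, numeric(1)))
  mc <- withr::with_seed(123, {
    mean(replicate(4000, clustering_accuracy(sample(0:1, n, TRUE), truth)))
  })
  expect_equal(mc, closed_form, tolerance = 0.01)
  expect_gt(closed_form, 0.5) # permutation-max bias above chance
})

test_that("per-frequency mixture scan pinpoints the contrasted 110 Hz bin", {
  coh <- quick_species_cohort(10, seed = 31)
  scan <- vbgmm_frequency_scan(coh, seed = 2)
  expect_equal(nrow(scan), 21)
  expect_true(all(scan$mean_accuracy >= 0.5 & scan$mean_accuracy <= 1))
  expect_identical(unique(scan$method), "vbgmm_scan")

  rep_ <- locate_distinguishing_frequency(scan)
  expect_equal(rep_$distinguishing_frequency_hz, 110)
  expect_identical(rep_$rule, "argmax")
  # the contrasted bin separates essentially perfectly at this noise level
  expect_gt(scan$mean_accuracy[scan$frequency_hz == 110], 0.9)

  # seeded determinism of the full curve
  expect_identical(vbgmm_frequency_scan(coh, seed = 2), scan)

  # degenerate (all-identical) frequency values are flagged at chance level
  flat <- lapply(1:6, function(i) {
    voct_spectrum(seq(50, 70, 10), c(1, 1, 1),
                  metadata = list(eye_id = paste0("e", i),
                                  species = c("human", "porcine")[1 + i %% 2]),
                  normalization_state = "speaker_normalized")
  })
  fs <- vbgmm_frequency_scan(flat, seed = 1)
  expect_true(all(fs$degenerate))
  expect_true(all(fs$mean_accuracy == 0.5))
})

test_that("scan curves are invariant to per-spectrum rescaling", {
  coh <- quick_species_cohort(8, seed = 17)
  scaled <- lapply(coh, function(s) {
    voct_spectrum(s$frequencies, s$displacements * 7.5, s$metadata,
                  normalization_state = "speaker_normalized")
  })
  expect_equal(vbgmm_frequency_scan(scaled, seed = 3),
               vbgmm_frequency_scan(coh, seed = 3))
})

test_that("leave-one-frequency-out ablation is costliest at the informative bin", {
  coh <- quick_species_cohort(10, seed = 57)
  abl <- svc_leave_one_frequency_out(coh, n_repeats = 3, seed = 4)
  expect_equal(nrow(abl), 21)
  rep_ <- locate_distinguishing_frequency(abl)
  expect_equal(rep_$distinguishing_frequency_hz, 110)
  expect_identical(rep_$rule, "argmin")

  # ablating an uninformative frequency leaves accuracy at the full-model level
  full <- svc_cv_accuracy(coh, n_repeats = 3, seed = 4)
  without_200 <- svc_cv_accuracy(coh, n_repeats = 3, seed = 4,
                                 exclude_frequency_hz = 200)
  expect_lt(abs(without_200$mean_accuracy - full$mean_accuracy), 0.1)
  # while ablating the informative one collapses it
  expect_lt(abl$mean_accuracy[abl$frequency_hz == 110],
            full$mean_accuracy - 0.2)

  # determinism under a fixed seed
  expect_identical(svc_leave_one_frequency_out(coh, n_repeats = 3, seed = 4),
                   abl)
})

test_that("ablation accuracy stays near chance when the classes are exchangeable", {
  same <- quick_species_cohort(8, seed = 71, porcine_110_scale = 1)
  abl <- svc_leave_one_frequency_out(same, n_repeats = 3, seed = 9)
  expect_lt(mean(abl$mean_accuracy), 0.75)
})

test_that("classifier contracts reject unusable inputs", {
  coh <- quick_species_cohort(2, seed = 1)
  expect_error(svc_cv_accuracy(coh, n_folds = 5), "fewer samples than folds")
  one_class <- generate_species_cohort(4, 1, seed = 1)[1:4]
  expect_error(svc_cv_accuracy(one_class), "two classes")
  expect_error(svc_leave_one_frequency_out(quick_species_cohort(6, seed = 1),
                                           train_fraction = 0.7),
               "train_fraction")
})

test_that("distinguishing-frequency rules follow argmax/argmin with low-frequency ties", {
  curve <- data.frame(frequency_hz = c(50, 110, 200),
                      mean_accuracy = c(0.6, 0.95, 0.6),
                      accuracy_sd = 0, method = "vbgmm_scan",
                      degenerate = FALSE)
  expect_equal(locate_distinguishing_frequency(curve)$distinguishing_frequency_hz,
               110)

  const <- transform(curve, mean_accuracy = 0.7)
  res <- locate_distinguishing_frequency(const)
  expect_equal(res$distinguishing_frequency_hz, 50)
  expect_true(res$tie)

  two <- data.frame(frequency_hz = c(60, 70), mean_accuracy = c(0.9, 0.7),
                    accuracy_sd = 0, method = "vbgmm_scan", degenerate = FALSE)
  expect_equal(locate_distinguishing_frequency(two)$distinguishing_frequency_hz,
               60)
  # the same curve under the ablation rule selects the minimum instead
  expect_equal(locate_distinguishing_frequency(two, "svc_ablation")$distinguishing_frequency_hz,
               70)
})
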