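# Shared fixtures, built in code at test time.

flat_spectrum <- function(displacements, state = "speaker_normalized",
                          start = 50, step = 10) {
  voct_spectrum(seq(start, by = step, length.out = length(displacements)),
                displacements, normalization_state = state)
}

quick_species_cohort <- function(n = 10, seed = 1L, ...) {
  generate_species_cohort(n, n, seed = seed, ...)
}

# Scaled-down pipeline configuration used by pipeline tests.
test_pipeline_config <- function(seed = 7L) {
  cfg <- default_pipeline_config(seed)
  cfg$cohort$n_control <- 6L
  cfg$cohort$n_kc_by_stage <- c(1L, 2L, 1L, 2L)
  cfg$species_cohort$n_human <- 10L
  cfg$species_cohort$n_porcine <- 10L
  cfg$ml$n_repeats_svc <- 3L
  cfg$fem$n_elements <- 256L
  cfg
}
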