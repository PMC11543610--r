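# Scaled end-to-end experiment shared by the acceptance-property tests.
# Training runs are expensive, so each configuration is computed once per
# test session and the property blocks assert on the cached result.
# Conditions (32^3, K = 4, amplitude 3, sigma 13, 8 pairs, seeds 0..7,
# reduced widths/epochs) are the package's scaled study conditions,
# documented in the methods vignette.

acceptance_spec <- function() {
  phantom_spec(shape = c(32, 32, 32), n_regions = 4,
               deform_amplitude = 3, deform_smoothness = 13)
}

acceptance_cache <- new.env(parent = emptyenv())

acceptance_full <- function() {
  if (is.null(acceptance_cache$full)) {
    acceptance_cache$full <- run_coupled_experiment(
      n_pairs = 8, spec_template = acceptance_spec(), seed = 0,
      epochs_g = 20, epochs_s = 60, epochs_r = 100, epochs_ft = 8,
      g_channels = c(8, 16, 32, 64, 128), r_channels = c(8, 16, 16, 16),
      s_channels = c(4, 8, 16, 32), n_holdout = 2)
  }
  acceptance_cache$full
}

acceptance_ablation <- function(mode) {
  key <- paste0("abl_", mode)
  if (is.null(acceptance_cache[[key]])) {
    acceptance_cache[[key]] <- run_coupled_experiment(
      n_pairs = 8, spec_template = acceptance_spec(), seed = 0,
      epochs_g = 6, epochs_s = 14, epochs_r = 60, epochs_ft = 3,
      cold_ft_factor = 3, mode = mode,
      g_channels = c(8, 16, 32, 64, 128), r_channels = c(8, 16, 16, 16),
      s_channels = c(4, 8, 16, 32), n_holdout = 1)
  }
  acceptance_cache[[key]]
}
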