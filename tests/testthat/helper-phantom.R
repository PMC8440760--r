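# Small, fast phantom configurations shared across test files.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(height = 160L, width = 128L,
               n_old_benign = 3L, n_new_benign = 1L, n_new_suspicious = 3L,
               mc_radius_px = c(1.5, 3),
               deformation_amplitude_px = 3,
               deformation_sigma_px = 20,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_spec, args)
}

# Fully degenerate pair: no deformation, no noise, no drift.
frozen_spec <- function(seed = 1L, ...) {
  tiny_spec(seed = seed, deformation_amplitude_px = 0, noise_sigma = 0,
            intensity_drift = 0, ...)
}

fast_demons <- function() {
  demons_params(levels = c(4, 2), iterations = c(60, 30))
}
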