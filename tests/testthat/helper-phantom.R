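# Desk-scale phantom spec used across tests: a coarser grid than the default
# keeps each study ~0.1 s to generate while preserving gland geometry.
tiny_spec <- function(...) {
  phantom_spec(shape = c(64L, 48L, 32L), spacing = c(3, 3, 4.5), ...)
}

# Noise-free, variance-free study conditions for exact-recovery checks.
exact_spec <- function(...) {
  tiny_spec(gland_volume_sd = c(0, 0), pid20_sd = c(0, 0), ef_sd = c(0, 0),
            hu_noise_sd = 0, noiseless = TRUE,
            misalign_trans_mm = 0, misalign_rot_deg = 0, ...)
}

# Small uniform volume helper.
flat_volume <- function(value, dim = c(8L, 8L, 8L), spacing = c(2, 2, 2),
                        modality = "CT", time_min = NA_real_) {
  sq_volume(array(value, dim = dim), spacing = spacing, modality = modality,
            time_min = time_min)
}
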