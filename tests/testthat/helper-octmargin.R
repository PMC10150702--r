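# Shared fixtures, all generated in code.

# Texture-free tissue: exact forward model, no speckle-independent
# randomness, for machine-precision recovery checks.
zero_texture_params <- function(label = "WM0", mu = 4, intensity_db = 60) {
  tissue_params(label, mu, intensity_db,
                heterogeneity = 0, surface_roughness_um = 0,
                microstructure_rate = 0)
}

small_flat_system <- function(depth_pixels = 120L) {
  oct_system_flat(depth_pixels = depth_pixels)
}

# One noiseless patch through the real chain: simulate a B-scan, compensate,
# flatten, extract.
make_noiseless_patch <- function(params, system, patch_size = c(64L, 100L),
                                 surface_mean_px = 10L) {
  bs <- simulate_bscan(params, system, n_lateral = patch_size[1],
                       surface_mean_px = surface_mean_px, noise = FALSE)
  vol <- oct_volume(array(bs$image, c(1L, dim(bs$image))), system,
                    label = params$label)
  pre <- preprocess_scan(vol, qc = FALSE)
  extract_patches(pre$volume, patch_size = patch_size,
                  min_valid_frac = 0)[[1]]
}

# Small patient-structured two-class patch set for classifier tests.
make_two_class_patches <- function(n_per_class = 40L, n_patients = 5L,
                                   seed = 1L) {
  sys <- oct_system(depth_pixels = 140L)
  pa <- default_tissue_params()$WM0
  pb <- default_tissue_params()$WM60plus
  ids <- sprintf("p%02d", rep_len(seq_len(n_patients), n_per_class))
  a <- simulate_labeled_patches(pa, n_per_class, sys,
                                patch_size = c(64L, 112L),
                                patient_ids = ids, seed = seed)
  b <- simulate_labeled_patches(pb, n_per_class, sys,
                                patch_size = c(64L, 112L),
                                patient_ids = ids, seed = seed + 1L)
  list(
    patches = c(a, b),
    positive = rep(c(FALSE, TRUE), c(length(a), length(b))),
    patient_ids = c(vapply(a, `[[`, "", "patient_id"),
                    vapply(b, `[[`, "", "patient_id"))
  )
}
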