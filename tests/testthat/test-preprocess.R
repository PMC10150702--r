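test_that("depth compensation inverts the system sensitivity exactly", {
  sys <- oct_system(depth_pixels = 120L)   # curved roll-off and focus
  p <- zero_texture_params(mu = 3, intensity_db = 58)
  s <- 10L
  bs <- simulate_bscan(p, sys, n_lateral = 20L, surface_mean_px = s,
                       noise = FALSE)
  vol <- oct_volume(array(bs$image, c(1L, dim(bs$image))), sys)
  comp <- compensate_depth(vol)
  z <- (seq_len(sys$depth_pixels) - 1L - s) * sys$axial_spacing_um * 1e-3
  below <- z >= 0
  model <- db_to_linear(58) * exp(-2 * 3 * z[below])
  got <- db_to_linear(comp$data[1, 7, below])
  expect_lt(max(abs(got - model) / model), 1e-9)
})

test_that("flat unit profiles make compensation the identity", {
  sys <- small_flat_system()
  vol <- simulate_scan(zero_texture_params(), sys, n_bscans = 2L,
                       n_lateral = 20L, seed = 1)
  expect_equal(compensate_depth(vol)$data, vol$data)
  # and idempotence: a second pass after profile reset changes nothing
  comp <- compensate_depth(simulate_scan(zero_texture_params(),
                                         oct_system(), n_bscans = 2L,
                                         n_lateral = 20L, seed = 1))
  expect_equal(compensate_depth(comp)$data, comp$data)
})

test_that("degenerate sensitivity profiles are rejected", {
  sys <- small_flat_system()
  vol <- simulate_scan(zero_texture_params(), sys, n_bscans = 1L,
                       n_lateral = 10L, seed = 1)
  bad <- sys
  bad$rolloff[5] <- 0
  expect_error(compensate_depth(vol, bad), "strictly positive")
  short <- sys
  short$rolloff <- short$rolloff[-1]
  expect_error(compensate_depth(vol, short), "length")
})

test_that("surface detection finds a constructed surface and flags
           all-floor columns missing", {
  sys <- small_flat_system()
  p <- zero_texture_params(mu = 2, intensity_db = 60)
  bs <- simulate_bscan(p, sys, n_lateral = 30L, surface_mean_px = 30L,
                       noise = FALSE)
  img <- bs$image
  img[5:9, ] <- sys$noise_floor_db   # dead column block
  vol <- oct_volume(array(img, c(1L, dim(img))), sys)
  sm <- detect_surface(vol)
  expect_true(all(is.na(sm[1, 6:8])))  # interior of the dead block
  expect_true(all(sm[1, c(1:3, 12:30)] == 30L))
})

test_that("surface normalization flattens, conserves and flags", {
  set.seed(4)
  sys <- small_flat_system()
  p <- tissue_params("WM0", 5, 65, surface_roughness_um = 20)
  vol <- simulate_scan(p, sys, n_bscans = 3L, n_lateral = 40L, seed = 4,
                       noise = FALSE)
  sm <- detect_surface(vol)
  expect_gt(length(unique(as.vector(sm))), 1L)  # rough surface varies
  norm <- normalize_surface(vol, sm)
  # re-detection is flat to within the lateral smoothing resolution
  sm_after <- detect_surface(norm)
  expect_identical(median(sm_after), 0)
  expect_lte(max(sm_after), 3L)
  # with a laterally constant surface the flattening is exact
  cvol <- simulate_scan(zero_texture_params(mu = 5, intensity_db = 65),
                        sys, n_bscans = 2L, n_lateral = 30L,
                        surface_mean_px = 12L, seed = 1, noise = FALSE)
  cnorm <- normalize_surface(cvol, detect_surface(cvol))
  expect_true(all(detect_surface(cnorm) == 0L))
  # shifting preserves the below-surface samples of each column
  b <- 2L; l <- 7L; s <- sm[b, l]
  before <- sum(db_to_linear(vol$data[b, l, (s + 1L):dim(vol$data)[3]]))
  after <- sum(db_to_linear(
    norm$data[b, l, 1:(dim(vol$data)[3] - s)]))
  expect_equal(after, before, tolerance = 1e-12)
  # an already-flat surface at row 0 is untouched
  flat <- simulate_scan(zero_texture_params(), sys, n_bscans = 2L,
                        n_lateral = 20L, surface_mean_px = 0L, seed = 1)
  flat_sm <- detect_surface(flat)
  expect_true(all(flat_sm == 0L))
  expect_equal(normalize_surface(flat, flat_sm)$data, flat$data)
})

test_that("normalization refuses scans with too few detected surfaces", {
  sys <- small_flat_system()
  img <- matrix(sys$noise_floor_db, 20L, sys$depth_pixels)
  vol <- oct_volume(array(img, c(1L, dim(img))), sys)
  expect_error(normalize_surface(vol), "QC failure")
})

test_that("en-face projection averages the requested band", {
  sys <- small_flat_system(depth_pixels = 50L)
  data <- array(47, c(3, 8, 50))
  vol <- oct_volume(data, sys)
  expect_equal(enface_projection(vol), matrix(47, 3, 8))
  # one-pixel band at the surface equals the surface plane
  data[2, 3, 1] <- 60
  vol <- oct_volume(data, sys)
  ef1 <- enface_projection(vol, band_um = c(0, 4))
  expect_equal(ef1, data[, , 1])
  expect_error(enface_projection(vol, band_um = c(400, 401)), "band")
  # brighter tissue projects brighter
  sys2 <- small_flat_system()
  bright <- simulate_scan(zero_texture_params(mu = 3, intensity_db = 65),
                          sys2, n_bscans = 2L, n_lateral = 20L, seed = 1)
  dim_ <- simulate_scan(zero_texture_params(mu = 3, intensity_db = 50),
                        sys2, n_bscans = 2L, n_lateral = 20L, seed = 1)
  expect_gt(mean(enface_projection(bright, c(60, 160))),
            mean(enface_projection(dim_, c(60, 160))))
})

test_that("subvolume extraction restricts the ROI and validates bounds", {
  sys <- small_flat_system()
  vol <- simulate_scan(zero_texture_params(), sys, n_bscans = 6L,
                       n_lateral = 30L, seed = 2)
  expect_equal(extract_subvolume(vol)$data, vol$data)
  sub <- extract_subvolume(vol, bscan_range = c(2, 4),
                           lateral_range = c(5, 24))
  expect_identical(dim(sub$data), c(3L, 20L, sys$depth_pixels))
  expect_identical(sub$patient_id, vol$patient_id)
  expect_error(extract_subvolume(vol, bscan_range = c(4, 2)), "bounds")
  expect_error(extract_subvolume(vol, lateral_range = c(0, 10)), "bounds")
})

test_that("patch extraction tiles clean data and skips invalid columns", {
  sys <- small_flat_system()
  vol <- simulate_scan(zero_texture_params(mu = 3, intensity_db = 62), sys,
                       n_bscans = 4L, n_lateral = 70L,
                       surface_mean_px = 5L, seed = 3)
  pre <- preprocess_scan(vol, qc = FALSE)
  patches <- extract_patches(pre$volume, patch_size = c(32L, 56L))
  expect_length(patches, 4L * 2L)  # 2 lateral tiles per B-scan
  expect_true(all(vapply(patches, function(p) all(dim(p$data) == c(32, 56)),
                         TRUE)))
  # flag a column invalid: every patch containing it must disappear
  nv <- pre$volume
  nv$valid_mask[, 10L] <- FALSE
  patches2 <- extract_patches(nv, patch_size = c(32L, 56L))
  expect_length(patches2, 4L)
  expect_true(all(vapply(patches2, function(p) p$lateral_offset >= 32L,
                         TRUE)))
})

test_that("patch standardization z-scores and rejects constants", {
  set.seed(1)
  m <- matrix(rnorm(200, 50, 4), 20, 10)
  z <- normalize_patch(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(normalize_patch(z), z, tolerance = 1e-10)
  expect_error(normalize_patch(matrix(3, 5, 5)), "zero-variance")
})

test_that("QC distinguishes clean, fold-over and dropout scans", {
  sys <- oct_system()
  p <- default_tissue_params()$WM0
  clean <- simulate_scan(p, sys, n_bscans = 6L, n_lateral = 80L, seed = 8)
  expect_identical(qc_scan(clean), "ok")
  expect_identical(qc_scan(inject_fold_over(
    simulate_scan(p, sys, n_bscans = 6L, n_lateral = 80L, seed = 8))),
    "fold_over")
  set.seed(2)
  expect_identical(qc_scan(inject_dropout(
    simulate_scan(p, sys, n_bscans = 6L, n_lateral = 80L, seed = 8))),
    "dropout")
})
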