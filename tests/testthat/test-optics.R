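make_patch_from_matrix <- function(db, spacing = 4, floor_db = 40) {
  structure(
    list(data = db, patient_id = "p", scan_id = "s", bscan = 1L,
         lateral_offset = 0L, label = "WM0", axial_spacing_um = spacing,
         refractive_index = 1, noise_floor_db = floor_db),
    class = "oct_patch"
  )
}

test_that("patch averaging is the lateral mean in linear units", {
  set.seed(7)
  db <- matrix(rnorm(60 * 30, 55, 5), 60, 30)
  prof <- average_patch_to_ascan(make_patch_from_matrix(db))
  # brute-force oracle: average each depth's linear values one by one
  oracle <- vapply(seq_len(30), function(j) {
    mean(10^(db[, j] / 10))
  }, 0)
  expect_equal(prof$y, log(oracle), tolerance = 1e-12)
  expect_equal(diff(prof$z_mm), rep(0.004, 29), tolerance = 1e-12)

  # constant patch value v maps to ln(10^(v/10))
  cst <- average_patch_to_ascan(make_patch_from_matrix(matrix(50, 10, 8)))
  expect_equal(cst$y, rep(log(10^5), 8))

  # a single-column patch is that column
  one <- matrix(db[3, ], 1, 30)
  expect_equal(average_patch_to_ascan(make_patch_from_matrix(one))$y,
               log(10^(db[3, ] / 10)), tolerance = 1e-12)
})

test_that("fit window starts 20 um after the maximum and spans 300 um", {
  y <- c(seq(1, 3, length.out = 11), seq(2.99, -8, length.out = 109))
  prof <- structure(
    list(z_mm = (0:119) * 0.004, y = y, axial_spacing_um = 4,
         refractive_index = 1),
    class = "ascan_profile"
  )
  w <- select_fit_window(prof)
  expect_identical(w$start_index, 15L)   # max at 0-based 10, +ceil(20/4)
  expect_identical(w$n_samples, 75L)     # floor(300/4)
  expect_identical(range(w$idx), c(16L, 90L))

  # maximum at the last sample leaves no room
  prof_bad <- prof
  prof_bad$y <- seq_along(y)
  expect_error(select_fit_window(prof_bad), "too short")

  # ties take the shallowest maximum
  prof_tie <- prof
  prof_tie$y[3] <- 3
  prof_tie$y[11] <- 3
  expect_identical(select_fit_window(prof_tie)$start_index, 7L)
})

test_that("exact log-linear profiles are recovered to machine precision", {
  i0 <- 2.5e5
  z <- (0:119) * 0.004
  prof <- structure(
    list(z_mm = z, y = log(i0) - 2 * 4 * z, axial_spacing_um = 4,
         refractive_index = 1, patient_id = "p", scan_id = "s",
         label = "WM0"),
    class = "ascan_profile"
  )
  fit <- fit_optical_properties(prof)
  expect_equal(fit$mu, 4, tolerance = 1e-9)
  expect_equal(fit$I_lin, i0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant profile: undefined r2, zero attenuation
  cst <- prof
  cst$y <- rep(3.3, 120)
  fitc <- fit_optical_properties(cst)
  expect_identical(fitc$r2_defined, FALSE)
  expect_true(is.na(fitc$r2))
  expect_identical(fitc$mu, 0)
  expect_equal(fitc$I_lin, exp(3.3))
})

test_that("slope, intercept and r2 agree with an independent OLS oracle", {
  set.seed(42)
  for (k in 1:100) {
    n <- sample(10:60, 1)
    z <- sort(runif(n, 0, 0.5))
    y <- rnorm(1, 10, 2) - 2 * runif(1, 0.5, 8) * z + rnorm(n, 0, 0.3)
    prof <- structure(
      list(z_mm = z, y = y, axial_spacing_um = 4, refractive_index = 1,
           patient_id = "p", scan_id = "s", label = "x"),
      class = "ascan_profile"
    )
    win <- structure(list(start_index = 0L, n_samples = n,
                          idx = seq_len(n)),
                     class = "fit_window")
    fit <- fit_optical_properties(prof, win)
    ref <- stats::lm(y ~ z)
    expect_equal(fit$mu, -unname(coef(ref)[2]) / 2, tolerance = 1e-9)
    expect_equal(fit$I_lin, exp(unname(coef(ref)[1])), tolerance = 1e-9)
    expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-12)
  }
})

test_that("the fit is scale-equivariant in linear intensity", {
  sys <- small_flat_system()
  patch <- make_noiseless_patch(zero_texture_params(mu = 3,
                                                    intensity_db = 58),
                                sys)
  f1 <- fit_patches(list(patch), subtract_floor = FALSE)
  patch2 <- patch
  patch2$data <- patch$data + 10 * log10(7)   # linear scale by 7
  f2 <- fit_patches(list(patch2), subtract_floor = FALSE)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-9)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  expect_equal(f2$I_lin, 7 * f1$I_lin, tolerance = 1e-9)
})

test_that("r2 falls as injected heterogeneity rises", {
  sys <- oct_system()
  r2_med <- vapply(c(0.05, 0.2, 0.4), function(h) {
    p <- tissue_params("x", 4, 60, heterogeneity = h,
                       surface_roughness_um = 10)
    ps <- simulate_labeled_patches(p, 30, sys, seed = 400 + round(100 * h))
    median(fit_patches(ps)$r2)
  }, 0)
  expect_true(all(diff(r2_med) < 0))
})

test_that("group statistics behave at the boundaries", {
  set.seed(10)
  same <- rnorm(40)
  res <- compare_groups(c(same, same), rep(c("a", "b"), each = 40))
  expect_gt(res$pairwise$wilcoxon_p, 0.99)

  sep <- compare_groups(c(rnorm(50), rnorm(50, 5)),
                        rep(c("a", "b"), each = 50))
  expect_lt(sep$pairwise$wilcoxon_p, 0.001)
  expect_identical(sep$pairwise$stars, "***")
  expect_true(all(c("a", "b") %in% sep$shapiro$label))

  tiny <- compare_groups(c(rnorm(50), 1, 2), rep(c("a", "b"), c(50, 2)))
  expect_true(is.na(tiny$pairwise$wilcoxon_p))

  # star coding: exactly 0.05 earns no star
  expect_identical(significance_stars(c(0.05, 0.049, 0.01, 0.0099,
                                        0.001, 5e-4)),
                   c("", "*", "*", "**", "**", "***"))
  expect_error(compare_groups(1:5, rep("a", 5)), "2 groups")
})
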