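test_that("high intensity always classifies as white matter", {
  combos <- expand.grid(
    homogeneity = c("homogeneous", "heterogeneous"),
    penetration = c("high", "low"),
    uniformity = c("uniform", "non_uniform"),
    microstructures = c("present", "absent"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(combos))) {
    a <- criteria_assessment("high", combos$homogeneity[i],
                             combos$penetration[i], combos$uniformity[i],
                             combos$microstructures[i])
    expect_identical(classify_visual(a), "white_matter")
  }
})

test_that("the low-intensity special combinations export their classes", {
  expect_identical(
    classify_visual(criteria_assessment("low", "homogeneous", "low",
                                        "uniform", "absent")),
    "rather_not_tumorous"
  )
  expect_identical(
    classify_visual(criteria_assessment("low", "homogeneous", "high",
                                        "uniform", "absent")),
    "rather_tumorous_gray_matter"
  )
  expect_identical(
    classify_visual(criteria_assessment("low", "heterogeneous", "high",
                                        "non_uniform", "present")),
    "tumorous"
  )
  # any other deviation exports "rather tumorous"
  expect_identical(
    classify_visual(criteria_assessment("low", "heterogeneous", "low",
                                        "uniform", "absent")),
    "rather_tumorous"
  )
})

test_that("exhaustive enumeration gives the fixed class multiset", {
  grid <- enumerate_visual_classifier()
  expect_identical(nrow(grid), 32L)
  counts <- table(grid$visual_class)
  expect_identical(counts[["white_matter"]], 16L)
  expect_identical(counts[["rather_not_tumorous"]], 1L)
  expect_identical(counts[["rather_tumorous_gray_matter"]], 1L)
  expect_identical(counts[["tumorous"]], 1L)
  expect_identical(counts[["rather_tumorous"]], 13L)
  # determinism: the enumeration is fixed
  expect_identical(enumerate_visual_classifier(), grid)
})

test_that("binarization maps benign classes to non-tumor", {
  expect_identical(binarize_visual("white_matter"), "non_tumor")
  expect_identical(binarize_visual("rather_not_tumorous"), "non_tumor")
  expect_identical(binarize_visual("tumorous"), "tumor")
  expect_identical(binarize_visual("rather_tumorous"), "tumor")
  expect_identical(binarize_visual("rather_tumorous_gray_matter"), "tumor")
  expect_identical(
    binarize_visual("rather_tumorous_gray_matter",
                    gray_matter_tumor = FALSE),
    "non_tumor"
  )
  expect_error(binarize_visual("nonsense"))
})

test_that("automated grading reproduces the archetypal tissue pictures", {
  sys <- oct_system()
  pw <- default_tissue_params()

  wm <- preprocess_scan(simulate_scan(pw$WM0, sys, n_bscans = 15L,
                                      seed = 21))$volume
  expect_identical(classify_visual(grade_criteria(wm)), "white_matter")

  wme <- preprocess_scan(simulate_scan(pw$WME, sys, n_bscans = 15L,
                                       seed = 22))$volume
  g_wme <- grade_criteria(wme)
  expect_identical(g_wme$intensity, "low")
  expect_identical(classify_visual(g_wme), "rather_not_tumorous")

  # deep-penetration, heterogeneous, shadowed tumor archetype
  dsys <- oct_system(depth_pixels = 260L)
  tp <- tissue_params("tumor", mu = 1.5, intensity_db = 54,
                      heterogeneity = 0.5, surface_roughness_um = 30,
                      microstructure_rate = 5)
  tum <- preprocess_scan(simulate_scan(tp, dsys, n_bscans = 15L,
                                       seed = 23))$volume
  expect_identical(classify_visual(grade_criteria(tum)), "tumorous")

  # grading identical data twice is bit-stable
  expect_identical(unlist(grade_criteria(wm)),
                   unlist(grade_criteria(wm)))
})

test_that("grading refuses QC-failed and unnormalized input", {
  sys <- oct_system()
  vol <- simulate_scan(default_tissue_params()$WM0, sys, n_bscans = 4L,
                       seed = 2)
  expect_error(grade_criteria(vol), "surface-normalized")
  norm <- preprocess_scan(vol)$volume
  norm$qc_flags <- "fold_over"
  expect_error(grade_criteria(norm), "QC-failed")
})

test_that("observer agreement and kappa behave at the boundaries", {
  x <- sample(visual_classes(), 200, replace = TRUE)
  same <- observer_agreement(x, x)
  expect_equal(same$kappa, 1)
  expect_equal(same$observed_agreement, 1)

  set.seed(31)
  a <- sample(visual_classes(), 3000, replace = TRUE)
  b <- sample(visual_classes(), 3000, replace = TRUE)
  indep <- observer_agreement(a, b)
  expect_lt(abs(indep$kappa), 0.05)

  single <- observer_agreement(rep("tumorous", 5), rep("tumorous", 5))
  expect_true(is.na(single$kappa))

  expect_error(observer_agreement(a, b[-1]), "length")
})

test_that("kappa matches the e1071 cross-check on random tables", {
  set.seed(77)
  for (k in 1:5) {
    a <- sample(letters[1:4], 150, replace = TRUE)
    b <- ifelse(runif(150) < 0.5, a, sample(letters[1:4], 150,
                                            replace = TRUE))
    ours <- observer_agreement(a, b)
    ref <- e1071::classAgreement(table(a, b))
    expect_equal(ours$kappa, ref$kappa, tolerance = 1e-12)
    expect_equal(ours$observed_agreement, ref$diag, tolerance = 1e-12)
  }
})
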