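#' Five-criterion qualitative assessment
#'
#' The qualitative grading of an OCT subvolume: (1) signal intensity
#' (high/low; the display archetypes are deep red 70 dB vs deep blue
#' 40 dB), (2) homogeneity of the intensity, (3) penetration depth of the
#' signal (high when the signal depth exceeds 500 um), (4) uniformity of
#' the penetration depth across the subvolume, and (5) increase in
#' microstructures (signal shadowing cast by calcifications, cysts or
#' hypervascularization).
#'
#' @param intensity `"high"` or `"low"`.
#' @param homogeneity `"homogeneous"` or `"heterogeneous"`.
#' @param penetration `"high"` or `"low"`.
#' @param uniformity `"uniform"` or `"non_uniform"`.
#' @param microstructures `"present"` or `"absent"`.
#' @return An object of class `criteria_assessment`.
#' @export
criteria_assessment <- function(intensity, homogeneity, penetration,
                                uniformity, microstructures) {
  check <- function(x, levels, name) {
    if (length(x) != 1L || !x %in% levels) {
      stopf("'%s' must be one of: %s", name, paste(levels, collapse = ", "))
    }
    x
  }
  structure(
    list(
      intensity = check(intensity, c("high", "low"), "intensity"),
      homogeneity = check(homogeneity, c("homogeneous", "heterogeneous"),
                          "homogeneity"),
      penetration = check(penetration, c("high", "low"), "penetration"),
      uniformity = check(uniformity, c("uniform", "non_uniform"),
                         "uniformity"),
      microstructures = check(microstructures, c("present", "absent"),
                              "microstructures")
    ),
    class = "criteria_assessment"
  )
}

#' Visual classifier output levels
#'
#' The five flowchart classes, ordered benign to malignant.
#'
#' @return Character vector of the five class names.
#' @export
visual_classes <- function() {
  c("white_matter", "rather_not_tumorous", "rather_tumorous_gray_matter",
    "rather_tumorous", "tumorous")
}

#' Rule-based visual classifier
#'
#' Signal intensity is the major criterion: high intensity is
#' representative of myelinated white matter and classifies the scan as
#' `white_matter` outright. When intensity is low, the four additional
#' criteria decide: all-benign gradings (homogeneous, low penetration,
#' uniform, no microstructures) export `rather_not_tumorous`; the single
#' combination (homogeneous, high penetration, uniform, no microstructures)
#' exports `rather_tumorous_gray_matter`; the all-malignant combination
#' (heterogeneous, high penetration, non-uniform, microstructures present)
#' exports `tumorous`; every other combination exports `rather_tumorous`.
#' The classifier is a total function on the 32-point criteria domain.
#'
#' @param assessment A [criteria_assessment()].
#' @return One of [visual_classes()].
#' @export
classify_visual <- function(assessment) {
  stopifnot(inherits(assessment, "criteria_assessment"))
  a <- assessment
  if (a$intensity == "high") return("white_matter")
  key <- paste(a$homogeneity, a$penetration, a$uniformity,
               a$microstructures)
  switch(key,
         "homogeneous low uniform absent" = "rather_not_tumorous",
         "homogeneous high uniform absent" = "rather_tumorous_gray_matter",
         "heterogeneous high non_uniform present" = "tumorous",
         "rather_tumorous")
}

#' Enumerate the classifier over its full domain
#'
#' Applies [classify_visual()] to all 32 criteria combinations.
#'
#' @return data.frame of the 32 combinations with their `visual_class`.
#' @export
enumerate_visual_classifier <- function() {
  grid <- expand.grid(
    intensity = c("high", "low"),
    homogeneity = c("homogeneous", "heterogeneous"),
    penetration = c("high", "low"),
    uniformity = c("uniform", "non_uniform"),
    microstructures = c("present", "absent"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$visual_class <- vapply(seq_len(nrow(grid)), function(i) {
    classify_visual(do.call(criteria_assessment, as.list(grid[i, ])))
  }, character(1))
  grid
}

#' Binarize a visual class
#'
#' Collapses the five-level output to tumor / non-tumor for diagnostic
#' metrics: `white_matter` and `rather_not_tumorous` are non-tumor; the
#' remaining classes are tumor. Whether `rather_tumorous_gray_matter`
#' counts as tumor is configurable (default yes, following its "rather
#' tumorous" prefix).
#'
#' @param visual_class Character vector of [visual_classes()] values.
#' @param gray_matter_tumor Treat `rather_tumorous_gray_matter` as tumor?
#' @return Character vector, `"tumor"` or `"non_tumor"`.
#' @export
binarize_visual <- function(visual_class, gray_matter_tumor = TRUE) {
  stopifnot(all(visual_class %in% visual_classes()))
  non_tumor <- c("white_matter", "rather_not_tumorous")
  if (!gray_matter_tumor) {
    non_tumor <- c(non_tumor, "rather_tumorous_gray_matter")
  }
  ifelse(visual_class %in% non_tumor, "non_tumor", "tumor")
}

#' Automated criteria grading
#'
#' Deterministic surrogate for the human grading of the five criteria on a
#' surface-normalized, QC-passed subvolume, making the flowchart classifier
#' testable end-to-end:
#' * intensity: mean dB over the near-surface band vs `intensity_db`
#'   (default 55 dB, midpoint of the 70/40 dB display archetypes);
#' * penetration: median per-column depth at which the axially smoothed
#'   signal falls to within 3 dB of the floor, vs `penetration_um`
#'   (500 um);
#' * homogeneity: sd of the natural-log en-face intensity over coarse
#'   tiles vs `homogeneity_cv` (a coefficient-of-variation scale);
#' * uniformity: sd of the per-column penetration depth vs
#'   `uniformity_sd_um`;
#' * microstructures: present when any column's mid-depth mean intensity
#'   drops `shadow_drop_db` below the column median (shadowing).
#'
#' All thresholds are pure configuration; re-running with identical
#' configuration and data is bit-stable.
#'
#' @param volume A surface-normalized, QC-ok [oct_volume()].
#' @param intensity_db,penetration_um,homogeneity_cv,uniformity_sd_um,
#'   shadow_drop_db Decision thresholds (units in the description).
#' @param intensity_band_um Near-surface band for the intensity criterion.
#' @param shadow_band_um Depth band for shadow detection.
#' @param tile `c(b-scans, columns)` tile size for the homogeneity metric.
#' @return A [criteria_assessment()] with attribute `measures` holding the
#'   underlying continuous measurements.
#' @export
grade_criteria <- function(volume,
                           intensity_db = 55,
                           penetration_um = 500,
                           homogeneity_cv = 0.15,
                           uniformity_sd_um = 100,
                           shadow_drop_db = 4,
                           intensity_band_um = c(0, 100),
                           shadow_band_um = c(100, 300),
                           tile = c(5L, 20L)) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!isTRUE(attr(volume, "normalized"))) {
    stopf("grade_criteria() expects a surface-normalized volume")
  }
  if (any(c("fold_over", "dropout") %in% volume$qc_flags)) {
    stopf("QC-failed volume (%s) cannot be graded",
          paste(volume$qc_flags, collapse = ","))
  }
  sp <- volume$system$axial_spacing_um
  floor_db <- volume$system$noise_floor_db

  # (1) intensity: mean dB in the near-surface band, valid columns only
  ef_near <- enface_projection(volume, band_um = intensity_band_um)
  mean_near_db <- mean(ef_near[volume$valid_mask])

  # (3)/(4) penetration: per-column first axially smoothed drop to the floor
  nd <- n_depth(volume)
  pen_px <- matrix(NA_real_, n_bscans(volume), n_lateral(volume))
  for (b in seq_len(n_bscans(volume))) {
    img <- volume$data[b, , ]
    # smooth laterally then axially before the floor crossing; raw speckle
    # makes single-pixel crossings meaninglessly jittery
    sm <- if (n_lateral(volume) >= 5L) apply(img, 2, stats::runmed, k = 5)
          else img
    sm <- t(apply(sm, 1, stats::runmed, k = 11))
    below <- sm < (floor_db + 3)
    below[, 1L] <- FALSE   # the surface row itself never terminates signal
    first <- first_true_index(below)
    first[is.na(first)] <- nd + 1L
    pen_px[b, ] <- first - 1L
  }
  pen_um <- pen_px[volume$valid_mask] * sp
  median_pen_um <- stats::median(pen_um)
  sd_pen_um <- stats::sd(pen_um)

  # (2) homogeneity: sd of log en-face intensity over coarse tiles
  ef <- enface_projection(volume, band_um = c(50, 250))
  bi <- (seq_len(nrow(ef)) - 1L) %/% tile[1]
  li <- (seq_len(ncol(ef)) - 1L) %/% tile[2]
  tiles <- tapply(as.vector(ef), list(bi[row(ef)], li[col(ef)]), mean)
  cv_log <- stats::sd(as.vector(tiles)) * log(10) / 10

  # (5) microstructures: shadowed columns in the mid-depth band
  band <- (floor(shadow_band_um[1] / sp) + 1L):
    min(nd, ceiling(shadow_band_um[2] / sp))
  col_db <- apply(volume$data[, , band, drop = FALSE], c(1, 2), mean)
  shadow_cols <- sum(col_db < stats::median(col_db[volume$valid_mask]) -
                       shadow_drop_db, na.rm = TRUE)

  out <- criteria_assessment(
    intensity = if (mean_near_db >= intensity_db) "high" else "low",
    homogeneity = if (cv_log > homogeneity_cv) "heterogeneous"
                  else "homogeneous",
    penetration = if (median_pen_um > penetration_um) "high" else "low",
    uniformity = if (sd_pen_um > uniformity_sd_um) "non_uniform"
                 else "uniform",
    microstructures = if (shadow_cols > 0L) "present" else "absent"
  )
  attr(out, "measures") <- list(
    mean_near_db = mean_near_db, cv_log = cv_log,
    median_pen_um = median_pen_um, sd_pen_um = sd_pen_um,
    shadow_cols = shadow_cols
  )
  out
}

#' Inter-observer agreement
#'
#' Cross-tabulates two observers' visual classifications and computes
#' Cohen's kappa. When both observers use a single identical class the
#' expected agreement is 1 and kappa is undefined (`NA`).
#'
#' @param class_a,class_b Equal-length vectors of [visual_classes()]
#'   values (or any categorical labels).
#' @return List with `table` (cross-tabulation), `observed_agreement`,
#'   `expected_agreement` and `kappa`.
#' @export
observer_agreement <- function(class_a, class_b) {
  if (length(class_a) != length(class_b)) {
    stopf("observer classification lists differ in length")
  }
  levels <- union(unique(class_a), unique(class_b))
  a <- factor(class_a, levels = levels)
  b <- factor(class_b, levels = levels)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  list(table = tab, observed_agreement = po, expected_agreement = pe,
       kappa = kappa)
}
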