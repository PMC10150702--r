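#' Preprocess one scan
#'
#' The per-scan preprocessing chain: depth-sensitivity compensation, QC,
#' and (for QC-passed scans) surface detection and flattening. Returns the
#' normalized volume with its QC flags attached, or the flags alone for
#' rejected scans.
#'
#' After flattening, the expected dB profile of the (compensated, shifted)
#' noise floor is attached to the volume as `floor_db_profile`, using the
#' median detected surface shift: the additive detection floor is not
#' subject to the system sensitivity, so after the division it varies with
#' depth and must be known to the optical-property fit, which removes it
#' from the patch-averaged profile.
#'
#' @param volume An [oct_volume()].
#' @param qc Apply [qc_scan()] and stop early on failure?
#' @return List with `volume` (normalized [oct_volume()] or `NULL` when
#'   rejected) and `qc_flags`.
#' @export
preprocess_scan <- function(volume, qc = TRUE) {
  corr_db <- linear_to_db(volume$system$rolloff * volume$system$focus)
  vol <- compensate_depth(volume)
  surface <- detect_surface(vol)
  flags <- if (qc) qc_scan(vol, surface = surface) else "ok"
  if (!identical(flags, "ok")) {
    return(list(volume = NULL, qc_flags = flags))
  }
  vol <- normalize_surface(vol, surface)
  shift <- as.integer(round(stats::median(surface, na.rm = TRUE)))
  nd <- n_depth(vol)
  rows <- pmin(seq_len(nd) + shift, nd)
  vol$floor_db_profile <- vol$system$noise_floor_db - corr_db[rows]
  vol$qc_flags <- flags
  list(volume = vol, qc_flags = flags)
}

#' Simulate ready-to-fit labeled patches
#'
#' Generates single-B-scan patches of one tissue class through the full
#' chain (simulate, compensate, flatten, extract), for parameter-recovery
#' studies and classifier tests without building whole cohorts.
#'
#' @param params A [tissue_params()].
#' @param n Number of patches.
#' @param system An [oct_system()].
#' @param patch_size `c(lateral, axial)` pixels.
#' @param noise Simulate with speckle?
#' @param patient_ids Optional patient id per patch (recycled).
#' @param seed Optional seed.
#' @return List of `oct_patch` objects (may be shorter than `n` if a patch
#'   fails validity).
#' @export
simulate_labeled_patches <- function(params, n, system = oct_system(),
                                     patch_size = c(144L, 112L),
                                     noise = TRUE, patient_ids = "p01",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  patient_ids <- rep_len(patient_ids, n)
  out <- list()
  for (i in seq_len(n)) {
    bs <- simulate_bscan(params, system, n_lateral = patch_size[1],
                         surface_mean_px = 15L, noise = noise)
    vol <- oct_volume(array(bs$image, c(1L, dim(bs$image))), system,
                      patient_id = patient_ids[i],
                      scan_id = sprintf("patch%04d", i),
                      label = params$label)
    pre <- preprocess_scan(vol, qc = FALSE)
    patches <- extract_patches(pre$volume, patch_size = patch_size,
                               min_valid_frac = 0.5)
    if (length(patches)) out[[length(out) + 1L]] <- patches[[1L]]
  }
  out
}

#' Run the synthetic cohort through the full analysis
#'
#' Streams the cohort plan scan by scan (simulate, compensate, QC, flatten),
#' extracts patches from QC-passed scans at the counting footprint
#' (144 x 56) and at an axially extended footprint for the attenuation fit,
#' fits the optical properties per patch, grades the five visual criteria
#' per scan, and evaluates the classification tasks with the
#' leave-one-patient-out linear SVM.
#'
#' @param spec A [cohort_spec()].
#' @param class_params Named list of [tissue_params()].
#' @param system An [oct_system()].
#' @param tasks Character vector of tasks to evaluate.
#' @param count_patch_size Patch footprint used for the patch count.
#' @param fit_patch_size Axially extended footprint used for the fit (deep
#'   enough to host the 20 um + 300 um fit window past the profile
#'   maximum).
#' @param bscan_stride B-scan sampling stride for patch extraction.
#' @param grade_visual Run the automated criteria grading per scan?
#' @return List of class `cohort_analysis`: `qc` (per-scan table),
#'   `properties` (per-patch fit table), `patch_count`, `visual` (per-scan
#'   visual classes, if graded) and `reports` (per-task `eval_report`).
#' @export
run_cohort_analysis <- function(spec,
                                class_params = default_tissue_params(),
                                system = oct_system(),
                                tasks = c("I", "II", "III"),
                                count_patch_size = c(144L, 56L),
                                fit_patch_size = c(144L, 112L),
                                bscan_stride = 2L,
                                grade_visual = TRUE) {
  plan <- cohort_plan(spec, class_params)
  qc_rows <- list(); prop_rows <- list(); visual_rows <- list()
  patch_count <- 0L
  for (i in seq_len(nrow(plan))) {
    vol <- materialize_scan(plan[i, ], spec, class_params, system)
    pre <- preprocess_scan(vol)
    qc_rows[[i]] <- data.frame(
      patient_id = plan$patient_id[i], scan_id = plan$scan_id[i],
      label = plan$label[i], artifact = plan$artifact[i],
      qc = paste(pre$qc_flags, collapse = "+"),
      accepted = identical(pre$qc_flags, "ok")
    )
    if (is.null(pre$volume)) next
    patch_count <- patch_count +
      length(extract_patches(pre$volume, patch_size = count_patch_size,
                             bscan_stride = bscan_stride))
    fitp <- extract_patches(pre$volume, patch_size = fit_patch_size,
                            bscan_stride = bscan_stride,
                            min_valid_frac = 0.5)
    if (length(fitp)) {
      prop_rows[[length(prop_rows) + 1L]] <-
        fit_patches(fitp, subtract_floor = TRUE, skip_short = TRUE)
    }
    if (grade_visual) {
      crit <- grade_criteria(pre$volume)
      visual_rows[[length(visual_rows) + 1L]] <- data.frame(
        patient_id = plan$patient_id[i], scan_id = plan$scan_id[i],
        label = plan$label[i],
        visual_class = classify_visual(crit)
      )
    }
  }
  qc <- do.call(rbind, qc_rows)
  properties <- if (length(prop_rows)) do.call(rbind, prop_rows) else NULL
  visual <- if (length(visual_rows)) do.call(rbind, visual_rows) else NULL
  reports <- list()
  if (!is.null(properties)) {
    for (t in tasks) {
      ts <- task_spec(t)
      masked <- try(assign_task_labels(properties$label, ts),
                    silent = TRUE)
      if (inherits(masked, "try-error")) next
      sub <- properties[masked$included, ]
      reports[[t]] <- suppressWarnings(loo_svm_evaluate(
        sub[, c("mu", "I_db", "r2")], masked$positive, sub$patient_id
      ))
    }
  }
  structure(
    list(qc = qc, properties = properties, patch_count = patch_count,
         visual = visual, reports = reports, spec = spec),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf(
    "<cohort_analysis> %d scans (%.0f%% QC-rejected), %d patches, %d task reports\n",
    nrow(x$qc), 100 * mean(!x$qc$accepted), x$patch_count,
    length(x$reports)
  ))
  invisible(x)
}

#' Reported operating points and patient contingencies bundled with the
#' package
#'
#' Loads the bundled CSV tables of published operating points (observer and
#' classifier sensitivity/specificity pairs) and patient-level contingency
#' counts (fluorescein-sodium guidance; early post-operative MRI), used by
#' the worked-example arithmetic.
#'
#' @param which `"operating_points"` or `"contingency_counts"`.
#' @return data.frame.
#' @export
reference_tables <- function(which = c("operating_points",
                                       "contingency_counts")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"),
                      package = "octmargin")
  if (!nzchar(path)) stopf("bundled table '%s' not found", which)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Worked-example diagnostic arithmetic
#'
#' Recomputes every diagnostic metric that follows from the bundled count
#' tables: sensitivity/accuracy of fluorescein-sodium guidance and early
#' post-operative MRI from patient-level contingencies, and balanced
#' accuracies from the published sensitivity/specificity operating points.
#'
#' @return List with `contingency` (one [compute_metrics()] per study) and
#'   `operating_points` (data.frame with computed balanced accuracy).
#' @export
worked_examples <- function() {
  counts <- reference_tables("contingency_counts")
  contingency <- lapply(seq_len(nrow(counts)), function(i) {
    compute_metrics(counts$tp[i], counts$fp[i], counts$tn[i], counts$fn[i])
  })
  names(contingency) <- counts$study
  op <- reference_tables("operating_points")
  op$balanced_accuracy <- as.numeric(
    balanced_accuracy(op$sensitivity_pct, op$specificity_pct))
  list(contingency = contingency, operating_points = op)
}
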