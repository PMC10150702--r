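#' Simulate a single A-scan
#'
#' Forward model of one depth profile under the single-scattering
#' approximation: below the tissue surface the expected linear intensity is
#' `I * exp(-2 mu z)` (z in mm from the surface) scaled by the system's
#' roll-off and focus sensitivity; above the surface only the noise floor is
#' present. With `noise = TRUE`, fully developed speckle is applied as
#' multiplicative unit-mean exponential intensity noise and an additive
#' fluctuating noise floor; with `noise = FALSE` the profile is the exact
#' noiseless model (and the noise floor above the surface only), so that
#' downstream compensation and fitting can be verified to machine precision.
#'
#' @param params A [tissue_params()].
#' @param system An [oct_system()].
#' @param surface_px 0-based depth index of the tissue surface.
#' @param noise Apply speckle and noise floor fluctuation?
#' @param log_offset Additive offset on the natural-log intensity of this
#'   A-scan (per-A-scan heterogeneity; used by [simulate_bscan()]).
#' @return Numeric vector of length `depth_pixels`, dB.
#' @export
simulate_ascan <- function(params, system, surface_px = 0L, noise = TRUE,
                           log_offset = 0) {
  stopifnot(inherits(params, "tissue_params"), inherits(system, "oct_system"))
  d <- system$depth_pixels
  surface_px <- as.integer(surface_px)
  if (surface_px < 0L || surface_px >= d) {
    stopf("'surface_px' must lie in [0, %d)", d)
  }
  assert_scalar_finite(log_offset, "log_offset")
  idx <- seq_len(d) - 1L
  below <- idx >= surface_px
  z_mm <- pmax(idx - surface_px, 0) * system$axial_spacing_um * 1e-3 /
    system$refractive_index
  i_lin <- db_to_linear(params$intensity_db) * exp(log_offset)
  sig <- ifelse(below,
                i_lin * exp(-2 * params$mu * z_mm) *
                  system$rolloff * system$focus,
                0)
  floor_lin <- db_to_linear(system$noise_floor_db)
  if (noise) {
    meas <- sig * stats::rexp(d) + floor_lin * stats::rexp(d)
  } else {
    meas <- sig
    meas[!below] <- floor_lin
  }
  linear_to_db(meas)
}

#' Simulate a B-scan
#'
#' Assembles a cross-sectional image of `n_lateral` A-scans with per-column
#' surface jitter (Gaussian, sd `surface_roughness_um`), structural
#' heterogeneity, and Poisson-placed microstructure shadows: narrow column
#' groups whose signal is strongly attenuated below a random depth,
#' emulating the signal shadowing cast by cysts, calcifications or vessels.
#'
#' Heterogeneity enters in two spatially coherent forms, splitting the
#' class's log-intensity fluctuation sd between a lateral amplitude field
#' (shared across the B-scans of one scan; what an en-face view shows) and
#' a 2-D lateral-by-depth texture field (what curves individual A-scan
#' decays and lowers the fit determination coefficient).
#'
#' @inheritParams simulate_ascan
#' @param n_lateral Number of A-scans (columns).
#' @param surface_mean_px Mean 0-based surface depth index.
#' @param lateral_field Optional length-`n_lateral` log-intensity field
#'   shared across B-scans of one scan; defaults to a fresh smooth field.
#' @param shadow_width_cols Width of each shadow, columns.
#' @return List with `image` (matrix `n_lateral x depth_pixels`, dB),
#'   `surface_px` (0-based per-column surface), `shadow_count` and
#'   `shadow_columns`.
#' @export
simulate_bscan <- function(params, system, n_lateral = 160L,
                           surface_mean_px = 15L, noise = TRUE,
                           lateral_field = NULL, shadow_width_cols = 3L) {
  stopifnot(inherits(params, "tissue_params"), inherits(system, "oct_system"))
  n_lateral <- as.integer(n_lateral)
  d <- system$depth_pixels
  dz_mm <- system$axial_spacing_um * 1e-3 / system$refractive_index

  if (is.null(lateral_field)) {
    lateral_field <- smooth_field(n_lateral, 0.7 * params$heterogeneity)
  }
  stopifnot(length(lateral_field) == n_lateral)
  offs <- lateral_field +
    stats::rnorm(n_lateral, 0, 0.15 * params$heterogeneity)

  surf <- round(surface_mean_px +
                  stats::rnorm(n_lateral) *
                    params$surface_roughness_um / system$axial_spacing_um)
  surf <- pmin(pmax(as.integer(surf), 0L), d - 2L)

  idx <- seq_len(d) - 1L
  decay <- exp(-2 * params$mu * idx * dz_mm) * system$rolloff * system$focus
  i_col <- db_to_linear(params$intensity_db) * exp(offs) *
    exp(2 * params$mu * surf * dz_mm)
  sig <- outer(i_col, decay) *
    exp(smooth_field_2d(n_lateral, d, 0.7 * params$heterogeneity))
  sig[outer(surf, idx, ">")] <- 0

  shadow_count <- stats::rpois(1L, params$microstructure_rate)
  shadow_columns <- integer(0)
  if (shadow_count > 0L) {
    centers <- sample.int(n_lateral, shadow_count, replace = TRUE)
    half <- (shadow_width_cols - 1L) %/% 2L
    start_px <- surface_mean_px +
      round(stats::runif(shadow_count, 40, 240) / system$axial_spacing_um)
    for (j in seq_len(shadow_count)) {
      cols <- pmin(pmax(centers[j] + (-half:half), 1L), n_lateral)
      rows <- which(idx >= start_px[j])
      sig[cols, rows] <- sig[cols, rows] * 1e-3
      shadow_columns <- union(shadow_columns, cols)
    }
  }

  floor_lin <- db_to_linear(system$noise_floor_db)
  if (noise) {
    meas <- sig * matrix(stats::rexp(n_lateral * d), n_lateral, d) +
      floor_lin * matrix(stats::rexp(n_lateral * d), n_lateral, d)
  } else {
    meas <- sig
    meas[meas == 0] <- floor_lin
  }
  list(
    image = linear_to_db(meas),
    surface_px = surf,
    shadow_count = shadow_count,
    shadow_columns = sort(shadow_columns)
  )
}

#' Simulate one OCT scan (subvolume)
#'
#' Stacks B-scans of one tissue class into an [oct_volume()]. The
#' heterogeneity field is drawn once per scan and shared across B-scans
#' (tissue texture persists between adjacent sections). Ground truth
#' (class parameters, per-column surface, shadow counts) is attached.
#'
#' @inheritParams simulate_bscan
#' @param n_bscans Number of B-scans in the subvolume.
#' @param patient_id,scan_id Identity strings.
#' @param seed Optional RNG seed for this scan.
#' @return An [oct_volume()] with a `truth` list.
#' @export
simulate_scan <- function(params, system, n_bscans = 40L, n_lateral = 160L,
                          patient_id = "p01", scan_id = "s1",
                          surface_mean_px = 15L, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  field <- smooth_field(n_lateral, 0.7 * params$heterogeneity)
  data <- array(NA_real_, c(n_bscans, n_lateral, system$depth_pixels))
  surface <- matrix(NA_integer_, n_bscans, n_lateral)
  shadow_counts <- integer(n_bscans)
  for (b in seq_len(n_bscans)) {
    bs <- simulate_bscan(params, system, n_lateral = n_lateral,
                         surface_mean_px = surface_mean_px, noise = noise,
                         lateral_field = field)
    data[b, , ] <- bs$image
    surface[b, ] <- bs$surface_px
    shadow_counts[b] <- bs$shadow_count
  }
  oct_volume(
    data, system, patient_id = patient_id, scan_id = scan_id,
    label = params$label,
    truth = list(
      mu = params$mu, intensity_db = params$intensity_db,
      heterogeneity = params$heterogeneity,
      surface_px = surface, shadow_counts = shadow_counts,
      artifact = "none"
    )
  )
}

#' Inject a fold-over artifact
#'
#' Emulates the wrap-around of out-of-range signal into the shallow image
#' rows that spectral-domain OCT produces when tissue crosses the zero-delay
#' line: the bright near-surface band is copied, wrapped, into the top rows
#' of every B-scan.
#'
#' @param volume An [oct_volume()].
#' @param n_rows Number of shallow depth rows overwritten.
#' @return The modified volume, with `truth$artifact = "fold_over"`.
#' @export
inject_fold_over <- function(volume, n_rows = 8L) {
  stopifnot(inherits(volume, "oct_volume"))
  prof <- apply(volume$data, 3, mean)
  s0 <- which.max(prof)
  s0 <- min(s0, n_depth(volume) - n_rows)
  volume$data[, , seq_len(n_rows)] <-
    volume$data[, , s0 + seq_len(n_rows) - 1L]
  volume$truth$artifact <- "fold_over"
  volume
}

#' Inject a signal-dropout artifact
#'
#' Replaces a contiguous block of lateral columns (all B-scans) with
#' noise-floor-level signal, emulating loss of signal over part of the
#' scanned field (poor beam angle or shadowing by the cavity wall).
#'
#' @param volume An [oct_volume()].
#' @param column_fraction Fraction of lateral columns dropped.
#' @return The modified volume, with `truth$artifact = "dropout"`.
#' @export
inject_dropout <- function(volume, column_fraction = 0.4) {
  stopifnot(inherits(volume, "oct_volume"))
  nl <- n_lateral(volume)
  width <- max(1L, round(column_fraction * nl))
  start <- sample.int(nl - width + 1L, 1L)
  cols <- start:(start + width - 1L)
  floor_lin <- db_to_linear(volume$system$noise_floor_db)
  nb <- n_bscans(volume); nd <- n_depth(volume)
  volume$data[, cols, ] <- linear_to_db(
    floor_lin * array(stats::rexp(nb * length(cols) * nd),
                      c(nb, length(cols), nd)))
  volume$truth$artifact <- "dropout"
  volume$truth$dropout_columns <- sort(cols)
  volume
}

#' Cohort specification
#'
#' Study-structure parameters of a synthetic cohort: 21 patients with 5
#' scanned resection-margin locations each (subvolumes of 40 B-scans), a
#' label mix over the six histology classes, and the fraction of scans
#' carrying an injected fold-over or dropout artifact (default 0.6, the
#' drop-out rate observed when in vivo scans were screened for quality).
#' `tumor_surface_scan = TRUE` adds one additional tumor-surface scan per
#' patient.
#'
#' @param n_patients,scans_per_patient,bscans_per_subvolume,n_lateral Counts.
#' @param label_mix Named proportions over tissue labels, summing to 1.
#' @param artifact_fraction Fraction of scans given an artifact.
#' @param tumor_surface_scan Add one tumor-surface scan per patient?
#' @param surface_mean_px Mean 0-based surface depth index.
#' @param seed RNG seed making the cohort fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 21L, scans_per_patient = 5L,
                        bscans_per_subvolume = 40L, n_lateral = 160L,
                        label_mix = c(GM0 = 0.15, WM0 = 0.30, WM0_30 = 0.15,
                                      WM30_60 = 0.10, WM60plus = 0.15,
                                      WME = 0.15),
                        artifact_fraction = 0.6,
                        tumor_surface_scan = FALSE,
                        surface_mean_px = 15L,
                        seed = 1L) {
  counts <- c(n_patients, scans_per_patient, bscans_per_subvolume, n_lateral)
  if (any(counts < 1L)) stopf("cohort counts must be >= 1")
  if (is.null(names(label_mix)) || any(!nzchar(names(label_mix)))) {
    stopf("'label_mix' must be a named vector of proportions")
  }
  if (abs(sum(label_mix) - 1) > 1e-8) stopf("'label_mix' must sum to 1")
  if (any(label_mix < 0)) stopf("'label_mix' proportions must be >= 0")
  if (artifact_fraction < 0 || artifact_fraction > 1) {
    stopf("'artifact_fraction' must lie in [0, 1]")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      scans_per_patient = as.integer(scans_per_patient),
      bscans_per_subvolume = as.integer(bscans_per_subvolume),
      n_lateral = as.integer(n_lateral),
      label_mix = label_mix,
      artifact_fraction = artifact_fraction,
      tumor_surface_scan = isTRUE(tumor_surface_scan),
      surface_mean_px = as.integer(surface_mean_px),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Deterministic per-scan plan for a cohort
#'
#' Expands a [cohort_spec()] into one row per scan with patient/scan ids,
#' assigned tissue label, artifact type (`none`, `fold_over` or `dropout`;
#' exactly `round(artifact_fraction * n_scans)` scans are affected) and a
#' per-scan RNG seed. The plan is a pure function of the spec seed, so a
#' cohort can be materialized scan-by-scan without holding all volumes in
#' memory.
#'
#' @param spec A [cohort_spec()].
#' @param class_params Named list of [tissue_params()]; must cover every
#'   label in `label_mix`.
#' @return A data.frame with one row per scan.
#' @export
cohort_plan <- function(spec, class_params = default_tissue_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  missing <- setdiff(names(spec$label_mix), names(class_params))
  if (length(missing)) {
    stopf("class_params missing parameters for label(s): %s",
          paste(missing, collapse = ", "))
  }
  set.seed(spec$seed)
  patients <- sprintf("p%02d", seq_len(spec$n_patients))
  plan <- expand.grid(
    scan_id = sprintf("s%d", seq_len(spec$scans_per_patient)),
    patient_id = patients,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("patient_id", "scan_id")]
  if (spec$tumor_surface_scan) {
    plan <- rbind(plan, data.frame(patient_id = patients,
                                   scan_id = "surface"))
  }
  n <- nrow(plan)
  plan$label <- sample(names(spec$label_mix), n, replace = TRUE,
                       prob = spec$label_mix)
  plan$label[plan$scan_id == "surface"] <- "WM60plus"
  plan$artifact <- "none"
  n_art <- round(spec$artifact_fraction * n)
  if (n_art > 0L) {
    rows <- sample.int(n, n_art)
    plan$artifact[rows] <- sample(c("fold_over", "dropout"), n_art,
                                  replace = TRUE)
  }
  plan$seed <- sample.int(.Machine$integer.max - 1L, n)
  plan$mu <- vapply(plan$label, function(l) class_params[[l]]$mu, 0)
  plan$intensity_db <- vapply(plan$label,
                              function(l) class_params[[l]]$intensity_db, 0)
  plan
}

#' Materialize one scan of a cohort plan
#'
#' @param plan_row One row of [cohort_plan()].
#' @param spec The [cohort_spec()] the plan came from.
#' @param class_params Named list of [tissue_params()].
#' @param system An [oct_system()].
#' @return An [oct_volume()], with any planned artifact injected.
#' @export
materialize_scan <- function(plan_row, spec, class_params, system) {
  set.seed(plan_row$seed)
  vol <- simulate_scan(
    class_params[[plan_row$label]], system,
    n_bscans = spec$bscans_per_subvolume, n_lateral = spec$n_lateral,
    patient_id = plan_row$patient_id, scan_id = plan_row$scan_id,
    surface_mean_px = spec$surface_mean_px
  )
  switch(plan_row$artifact,
         fold_over = inject_fold_over(vol),
         dropout = inject_dropout(vol),
         vol)
}

#' Simulate a full labeled cohort
#'
#' Materializes every scan of [cohort_plan()] and returns the volumes
#' together with the label table and ground-truth table. Deterministic for
#' a fixed spec seed. For large cohorts prefer streaming over the plan with
#' [materialize_scan()] (as the pipeline does) to bound memory.
#'
#' @inheritParams cohort_plan
#' @param system An [oct_system()].
#' @return List with `volumes` (list of [oct_volume()]), `labels`
#'   (data.frame: patient_id, scan_id, label, artifact) and `truth`
#'   (data.frame adding the true mu and intensity).
#' @export
simulate_cohort <- function(spec, class_params = default_tissue_params(),
                            system = oct_system()) {
  plan <- cohort_plan(spec, class_params)
  volumes <- lapply(seq_len(nrow(plan)), function(i) {
    materialize_scan(plan[i, ], spec, class_params, system)
  })
  list(
    volumes = volumes,
    labels = plan[, c("patient_id", "scan_id", "label", "artifact")],
    truth = plan[, c("patient_id", "scan_id", "label", "mu",
                     "intensity_db", "artifact")]
  )
}
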