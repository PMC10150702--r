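#' Compensate depth-dependent system sensitivity
#'
#' Every A-scan is attenuated by the spectrometer roll-off and the confocal
#' focus function of the system. Compensation divides the linear intensity
#' at each depth pixel by `rolloff * focus` (equivalently, subtracts their
#' dB contribution), leaving the pure tissue signal; it is the exact inverse
#' of the sensitivity applied by the simulator and is idempotent when the
#' profiles are flat.
#'
#' With `subtract_floor = TRUE` the mean noise-floor intensity is removed
#' in linear units before the division. The additive detection floor is not
#' subject to the system sensitivity, so dividing it along with the signal
#' would amplify it at depth; subtracting it first leaves the pure
#' attenuation decay that the optical-property fit assumes. Pixels at or
#' below the floor are clamped 30 dB under it to keep the dB image finite.
#' Keep `FALSE` (the plain division of the definition) for noiseless or
#' already floor-free data.
#'
#' @param volume An [oct_volume()].
#' @param system The [oct_system()] whose profiles are removed; defaults to
#'   the volume's own system.
#' @param subtract_floor Remove the mean noise floor before dividing?
#' @return The compensated volume (its system's profiles are reset to 1 so
#'   compensation is not applied twice).
#' @export
compensate_depth <- function(volume, system = volume$system,
                             subtract_floor = FALSE) {
  stopifnot(inherits(volume, "oct_volume"))
  if (length(system$rolloff) != n_depth(volume) ||
      length(system$focus) != n_depth(volume)) {
    stopf("sensitivity profiles must have length %d", n_depth(volume))
  }
  if (any(system$rolloff <= 0) || any(system$focus <= 0)) {
    stopf("sensitivity profiles must be strictly positive")
  }
  if (subtract_floor) {
    floor_lin <- db_to_linear(system$noise_floor_db)
    volume$data <- linear_to_db(
      pmax(db_to_linear(volume$data) - floor_lin, floor_lin * 1e-3))
  }
  corr_db <- linear_to_db(system$rolloff * system$focus)
  volume$data <- sweep(volume$data, 3, corr_db, "-")
  volume$system$rolloff <- rep(1, n_depth(volume))
  volume$system$focus <- rep(1, n_depth(volume))
  volume
}

#' Detect the tissue surface
#'
#' For each A-scan, the surface is the first depth pixel whose laterally
#' median-smoothed intensity (running median over `smooth_cols` neighboring
#' columns) exceeds the noise floor by `threshold_db`. Columns that never
#' exceed the threshold are marked missing (`NA`).
#'
#' @param volume An [oct_volume()].
#' @param threshold_db Detection threshold above the noise floor, dB.
#' @param smooth_cols Lateral running-median window (odd).
#' @return A `surface_map`: integer matrix `(n_bscan, n_lateral)` of 0-based
#'   surface depth indices, `NA` where no surface was found.
#' @export
detect_surface <- function(volume, threshold_db = 6, smooth_cols = 5L) {
  stopifnot(inherits(volume, "oct_volume"))
  if (threshold_db <= 0) stopf("'threshold_db' must be > 0")
  thr <- volume$system$noise_floor_db + threshold_db
  nb <- n_bscans(volume)
  out <- matrix(NA_integer_, nb, n_lateral(volume))
  for (b in seq_len(nb)) {
    img <- volume$data[b, , ]
    sm <- if (n_lateral(volume) >= smooth_cols) {
      apply(img, 2, stats::runmed, k = smooth_cols)
    } else {
      img
    }
    out[b, ] <- first_true_index(sm > thr) - 1L
  }
  structure(out, class = c("surface_map", "matrix", "array"))
}

#' Flatten the tissue surface
#'
#' Shifts each A-scan so that its detected surface sits at depth row 0;
#' vacated deep rows are padded with the noise floor. Columns with no
#' detected surface are flagged invalid in the volume's validity mask and
#' set to the noise floor. Errors when fewer than `min_fraction` of columns
#' have a detected surface (a quality-control failure, as for dropout
#' scans).
#'
#' @param volume An [oct_volume()].
#' @param surface A surface map from [detect_surface()].
#' @param min_fraction Minimum fraction of columns with a surface.
#' @return The surface-normalized volume (attribute `normalized` set).
#' @export
normalize_surface <- function(volume, surface = detect_surface(volume),
                              min_fraction = 0.5) {
  stopifnot(inherits(volume, "oct_volume"))
  stopifnot(identical(dim(surface)[1:2], dim(volume$data)[1:2]))
  frac <- mean(!is.na(surface))
  if (frac < min_fraction) {
    stopf("surface detected on only %.0f%% of columns (< %.0f%%): QC failure",
          100 * frac, 100 * min_fraction)
  }
  nd <- n_depth(volume)
  floor_db <- volume$system$noise_floor_db
  for (b in seq_len(n_bscans(volume))) {
    for (l in seq_len(n_lateral(volume))) {
      s <- surface[b, l]
      if (is.na(s)) {
        volume$data[b, l, ] <- floor_db
        volume$valid_mask[b, l] <- FALSE
      } else if (s > 0L) {
        keep <- (s + 1L):nd
        volume$data[b, l, ] <- c(volume$data[b, l, keep],
                                 rep(floor_db, s))
      }
    }
  }
  attr(volume, "normalized") <- TRUE
  volume
}

#' En-face projection
#'
#' Collapses a volume to a top-down 2-D image by averaging the dB intensity
#' over a depth band. On surface-normalized volumes the band is measured
#' from the surface (row 0).
#'
#' @param volume An [oct_volume()].
#' @param band_um Depth band `c(from, to)` below the surface, um; half-open
#'   in pixels.
#' @return Matrix `(n_bscan, n_lateral)` of mean dB intensity.
#' @export
enface_projection <- function(volume, band_um = c(0, 200)) {
  stopifnot(inherits(volume, "oct_volume"))
  sp <- volume$system$axial_spacing_um
  from <- floor(band_um[1] / sp) + 1L
  to <- max(from, ceiling(band_um[2] / sp))
  to <- min(to, n_depth(volume))
  if (from > to || from > n_depth(volume)) stopf("empty depth band")
  rows <- from:to
  apply(volume$data[, , rows, drop = FALSE], c(1, 2), mean)
}

#' Extract image patches
#'
#' Tiles surface-normalized B-scans into candidate patches of
#' `patch_size = c(lateral, axial)` pixels (the study's patch footprint is
#' 144 x 56) anchored at the surface, then keeps only patches with valid
#' OCT data: no invalid-flagged columns and at least `min_valid_frac` of
#' pixels above the noise floor (+ `floor_margin_db`).
#'
#' @param volume A surface-normalized [oct_volume()].
#' @param patch_size `c(lateral, axial)` pixels.
#' @param bscan_stride Take every `bscan_stride`-th B-scan.
#' @param lateral_stride Lateral tiling stride; defaults to the patch width
#'   (non-overlapping).
#' @param min_valid_frac Minimum fraction of pixels above the floor.
#' @param floor_margin_db Margin above the noise floor for pixel validity.
#' @return List of `oct_patch` objects: `data` (matrix lateral x axial, dB)
#'   plus provenance (`patient_id`, `scan_id`, `bscan`, `lateral_offset`),
#'   `label`, `axial_spacing_um`, `refractive_index` and `noise_floor_db`.
#' @export
extract_patches <- function(volume, patch_size = c(144L, 56L),
                            bscan_stride = 1L, lateral_stride = NULL,
                            min_valid_frac = 0.6, floor_margin_db = 0) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!isTRUE(attr(volume, "normalized"))) {
    stopf("patches are extracted from surface-normalized volumes")
  }
  w <- as.integer(patch_size[1]); h <- as.integer(patch_size[2])
  if (is.null(lateral_stride)) lateral_stride <- w
  if (w > n_lateral(volume) || h > n_depth(volume)) {
    return(list())
  }
  thr <- volume$system$noise_floor_db + floor_margin_db
  patches <- list()
  for (b in seq.int(1L, n_bscans(volume), by = bscan_stride)) {
    for (off in seq.int(1L, n_lateral(volume) - w + 1L,
                        by = lateral_stride)) {
      cols <- off:(off + w - 1L)
      if (!all(volume$valid_mask[b, cols])) next
      patch <- volume$data[b, cols, seq_len(h)]
      if (mean(patch > thr) < min_valid_frac) next
      patches[[length(patches) + 1L]] <- structure(
        list(
          data = patch,
          floor_db_profile = volume$floor_db_profile[seq_len(h)],
          patient_id = volume$patient_id, scan_id = volume$scan_id,
          bscan = b, lateral_offset = off - 1L,
          label = volume$label,
          axial_spacing_um = volume$system$axial_spacing_um,
          refractive_index = volume$system$refractive_index,
          noise_floor_db = volume$system$noise_floor_db
        ),
        class = "oct_patch"
      )
    }
  }
  patches
}

#' Standardize a patch
#'
#' Z-scores a patch (subtract the mean image value, divide by the standard
#' deviation), the normalization applied before classifier training.
#'
#' @param patch An `oct_patch` or a numeric matrix.
#' @return Same shape, mean 0 and sd 1.
#' @export
normalize_patch <- function(patch) {
  m <- if (inherits(patch, "oct_patch")) patch$data else patch
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) stopf("zero-variance patch cannot be standardized")
  out <- (m - mean(m)) / s
  if (inherits(patch, "oct_patch")) {
    patch$data <- out
    patch
  } else {
    out
  }
}

#' Scan quality control
#'
#' Flags the two artifact modes seen in intraoperative volumes:
#' `fold_over` when an excessive fraction of columns have their detected
#' surface in the shallowest rows (wrapped signal sits on top of the image),
#' and `dropout` when too many columns have no detectable surface at all.
#' Clean scans are flagged `ok`.
#'
#' @param volume An [oct_volume()].
#' @param surface Optional precomputed [detect_surface()] map.
#' @param fold_over_max_frac Max tolerated fraction of near-zero surfaces.
#' @param dropout_max_frac Max tolerated fraction of missing surfaces.
#' @param surface_min_px Surfaces below this 0-based row count as wrapped.
#' @param threshold_db Surface-detection threshold, dB above floor.
#' @return Character vector of flags (`"ok"`, or any of `"fold_over"`,
#'   `"dropout"`).
#' @export
qc_scan <- function(volume, surface = NULL, fold_over_max_frac = 0.1,
                    dropout_max_frac = 0.2, surface_min_px = 3L,
                    threshold_db = 6) {
  stopifnot(inherits(volume, "oct_volume"))
  if (is.null(surface)) {
    surface <- detect_surface(volume, threshold_db = threshold_db)
  }
  flags <- character()
  if (mean(is.na(surface)) > dropout_max_frac) flags <- c(flags, "dropout")
  if (mean(surface < surface_min_px, na.rm = TRUE) > fold_over_max_frac) {
    flags <- c(flags, "fold_over")
  }
  if (!length(flags)) flags <- "ok"
  flags
}
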