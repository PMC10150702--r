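#' OCT volume container
#'
#' A 3-D OCT intensity volume in dB with dimensions
#' `(B-scan, lateral, depth)`, its [oct_system()] metadata, patient/scan
#' identity, an optional histology label, per-column validity mask and QC
#' flags. Ground-truth forward-model parameters travel with simulated
#' volumes for downstream verification.
#'
#' @param data Numeric 3-D array `(n_bscan, n_lateral, n_depth)`, dB.
#' @param system An [oct_system()]; `depth_pixels` must match `dim(data)[3]`.
#' @param patient_id,scan_id Identity strings.
#' @param label Optional tissue label.
#' @param truth Optional list of ground-truth parameters (simulated data).
#' @param valid_mask Logical `(n_bscan, n_lateral)` matrix; columns flagged
#'   `FALSE` carry no usable signal.
#' @param qc_flags Character vector of QC flags (`"ok"`, `"fold_over"`,
#'   `"dropout"`); empty until [qc_scan()] is run.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(data, system, patient_id = NA_character_,
                       scan_id = NA_character_, label = NA_character_,
                       truth = NULL, valid_mask = NULL,
                       qc_flags = character()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("'data' must be a 3-D array (bscan x lateral x depth)")
  }
  if (!all(is.finite(data))) stopf("'data' must be finite")
  if (!inherits(system, "oct_system")) stopf("'system' must be an oct_system")
  if (dim(data)[3] != system$depth_pixels) {
    stopf("depth dimension (%d) does not match system depth_pixels (%d)",
          dim(data)[3], system$depth_pixels)
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  }
  stopifnot(identical(dim(valid_mask), dim(data)[1:2]))
  structure(
    list(
      data = data, system = system,
      patient_id = as.character(patient_id), scan_id = as.character(scan_id),
      label = as.character(label), truth = truth,
      valid_mask = valid_mask, qc_flags = qc_flags
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %s/%s label=%s  %d B-scans x %d lateral x %d depth  [%s]\n",
    x$patient_id, x$scan_id, x$label, d[1], d[2], d[3],
    if (length(x$qc_flags)) paste(x$qc_flags, collapse = ",") else "no QC"
  ))
  invisible(x)
}

n_bscans <- function(volume) dim(volume$data)[1]
n_lateral <- function(volume) dim(volume$data)[2]
n_depth <- function(volume) dim(volume$data)[3]

#' Extract a rectangular subvolume
#'
#' Restricts a volume to a region of interest given as B-scan and lateral
#' index ranges (the stand-in for the study's manual white-light / en-face
#' ROI matching). Provenance, system metadata and the validity mask are
#' retained.
#'
#' @param volume An [oct_volume()].
#' @param bscan_range,lateral_range Integer vectors `c(first, last)`,
#'   1-based inclusive; `NULL` keeps the full extent.
#' @return The restricted `oct_volume`.
#' @export
extract_subvolume <- function(volume, bscan_range = NULL,
                              lateral_range = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  if (is.null(bscan_range)) bscan_range <- c(1L, d[1])
  if (is.null(lateral_range)) lateral_range <- c(1L, d[2])
  check_range <- function(r, n, name) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < 1L || r[2] > n) {
      stopf("'%s' = [%s] is empty or out of bounds (1..%d)",
            name, paste(r, collapse = ", "), n)
    }
  }
  check_range(bscan_range, d[1], "bscan_range")
  check_range(lateral_range, d[2], "lateral_range")
  bi <- seq.int(bscan_range[1], bscan_range[2])
  li <- seq.int(lateral_range[1], lateral_range[2])
  out <- volume
  out$data <- volume$data[bi, li, , drop = FALSE]
  out$valid_mask <- volume$valid_mask[bi, li, drop = FALSE]
  out
}
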