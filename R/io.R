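#' Write / read an OCT volume (multi-page TIFF + JSON sidecar)
#'
#' Volumes are stored as one 32-bit-float TIFF page per B-scan plus a JSON
#' sidecar with the spatial metadata and identity. TIFF float samples are
#' kept in `[0, 1]`, so dB values are stored affinely as
#' `(dB - db_offset) / db_scale` with the mapping recorded in the sidecar;
#' the default mapping covers -60..140 dB at float32 resolution.
#'
#' @param volume An [oct_volume()].
#' @param stem Path stem; `<stem>.tiff` and `<stem>.json` are written.
#' @param db_offset,db_scale Affine dB storage mapping.
#' @return `stem`, invisibly.
#' @export
write_oct_volume <- function(volume, stem, db_offset = -60,
                             db_scale = 200) {
  stopifnot(inherits(volume, "oct_volume"))
  pages <- lapply(seq_len(n_bscans(volume)), function(b) {
    (volume$data[b, , ] - db_offset) / db_scale
  })
  tiff::writeTIFF(pages, paste0(stem, ".tiff"), bits.per.sample = 32,
                  reduce = FALSE)
  sys <- volume$system
  meta <- list(
    patient_id = volume$patient_id, scan_id = volume$scan_id,
    label = volume$label,
    axial_spacing_um = sys$axial_spacing_um,
    lateral_spacing_um = sys$lateral_spacing_um,
    depth_pixels = sys$depth_pixels,
    noise_floor_db = sys$noise_floor_db,
    central_wavelength_nm = sys$central_wavelength_nm,
    axial_resolution_um = sys$axial_resolution_um,
    lateral_resolution_um = sys$lateral_resolution_um,
    refractive_index = sys$refractive_index,
    rolloff = sys$rolloff, focus = sys$focus,
    db_offset = db_offset, db_scale = db_scale,
    qc_flags = volume$qc_flags
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(stem, ".tiff"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nb <- length(pages)
  d1 <- dim(pages[[1]])
  data <- array(NA_real_, c(nb, d1[1], d1[2]))
  for (b in seq_len(nb)) {
    data[b, , ] <- pages[[b]] * meta$db_scale + meta$db_offset
  }
  sys <- oct_system(
    axial_spacing_um = meta$axial_spacing_um,
    lateral_spacing_um = meta$lateral_spacing_um,
    depth_pixels = meta$depth_pixels,
    rolloff = meta$rolloff, focus = meta$focus,
    noise_floor_db = meta$noise_floor_db,
    central_wavelength_nm = meta$central_wavelength_nm,
    axial_resolution_um = meta$axial_resolution_um,
    lateral_resolution_um = meta$lateral_resolution_um,
    refractive_index = meta$refractive_index
  )
  oct_volume(data, sys, patient_id = meta$patient_id,
             scan_id = meta$scan_id, label = meta$label,
             qc_flags = unlist(meta$qc_flags))
}

#' Write / read a label or ground-truth table (CSV)
#'
#' Plain CSV with a header row; numeric columns keep full precision so the
#' tables round-trip without loss.
#'
#' @param table A data.frame.
#' @param path CSV path.
#' @return The path (write) or the data.frame (read).
#' @export
write_label_table <- function(table, path) {
  utils::write.csv(format(table, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export patches as a TIFF stack with a CSV manifest
#'
#' @param patches List of `oct_patch` objects (all one size).
#' @param stem Path stem; `<stem>.tiff` and `<stem>.csv` are written.
#' @inheritParams write_oct_volume
#' @return `stem`, invisibly.
#' @export
write_patches <- function(patches, stem, db_offset = -60, db_scale = 200) {
  stopifnot(length(patches) > 0)
  pages <- lapply(patches, function(p) (p$data - db_offset) / db_scale)
  tiff::writeTIFF(pages, paste0(stem, ".tiff"), bits.per.sample = 32,
                  reduce = FALSE)
  manifest <- do.call(rbind, lapply(patches, function(p) {
    data.frame(patient_id = p$patient_id, scan_id = p$scan_id,
               bscan = p$bscan, lateral_offset = p$lateral_offset,
               label = p$label, axial_spacing_um = p$axial_spacing_um,
               refractive_index = p$refractive_index,
               noise_floor_db = p$noise_floor_db,
               db_offset = db_offset, db_scale = db_scale)
  }))
  utils::write.csv(manifest, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_patches
#' @export
read_patches <- function(stem) {
  manifest <- utils::read.csv(paste0(stem, ".csv"),
                              stringsAsFactors = FALSE)
  pages <- tiff::readTIFF(paste0(stem, ".tiff"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    m <- manifest[i, ]
    structure(
      list(data = pages[[i]] * m$db_scale + m$db_offset,
           patient_id = m$patient_id, scan_id = m$scan_id,
           bscan = m$bscan, lateral_offset = m$lateral_offset,
           label = m$label, axial_spacing_um = m$axial_spacing_um,
           refractive_index = m$refractive_index,
           noise_floor_db = m$noise_floor_db),
      class = "oct_patch"
    )
  })
}
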