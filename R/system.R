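#' OCT system model
#'
#' Describes the imaging geometry and depth-dependent sensitivity of a
#' spectral-domain OCT system: pixel spacings, depth range, per-depth-pixel
#' roll-off and focus sensitivity profiles, and the noise floor. Metadata
#' defaults follow a microscope-integrated 830 nm system (8 um axial /
#' 23 um lateral resolution, FWHM in air).
#'
#' The axial pixel pitch defaults to 4 um/pixel so that a 56-pixel axial
#' patch spans about 224 um. `refractive_index` converts pixel depth to
#' physical depth in tissue; the default of 1 reports depths on the in-air
#' scale.
#'
#' @param axial_spacing_um Axial pixel pitch, um/pixel.
#' @param lateral_spacing_um Lateral pixel pitch, um/pixel.
#' @param depth_pixels Number of depth pixels per A-scan.
#' @param rolloff Per-depth-pixel multiplicative sensitivity (length
#'   `depth_pixels`, strictly positive). Default: exponential decay.
#' @param focus Per-depth-pixel multiplicative focus sensitivity (length
#'   `depth_pixels`, strictly positive). Default: Gaussian confocal profile
#'   centred mid-depth.
#' @param noise_floor_db System noise floor, dB.
#' @param central_wavelength_nm,axial_resolution_um,lateral_resolution_um
#'   Descriptive metadata.
#' @param refractive_index Scalar group refractive index used when
#'   converting pixel depth to physical depth.
#' @return An object of class `oct_system`.
#' @export
oct_system <- function(axial_spacing_um = 4,
                       lateral_spacing_um = 12,
                       depth_pixels = 140L,
                       rolloff = NULL,
                       focus = NULL,
                       noise_floor_db = 40,
                       central_wavelength_nm = 830,
                       axial_resolution_um = 8,
                       lateral_resolution_um = 23,
                       refractive_index = 1) {
  assert_scalar_finite(axial_spacing_um, "axial_spacing_um")
  assert_scalar_finite(lateral_spacing_um, "lateral_spacing_um")
  if (axial_spacing_um <= 0 || lateral_spacing_um <= 0) {
    stopf("pixel spacings must be > 0")
  }
  depth_pixels <- as.integer(depth_pixels)
  if (depth_pixels < 2L) stopf("'depth_pixels' must be >= 2")
  z_mm <- (seq_len(depth_pixels) - 1L) * axial_spacing_um * 1e-3
  if (is.null(rolloff)) rolloff <- exp(-z_mm / 1.2)
  if (is.null(focus)) {
    zf <- max(z_mm) / 2
    focus <- exp(-((z_mm - zf)^2) / (2 * 0.5^2))
  }
  for (nm in c("rolloff", "focus")) {
    p <- get(nm)
    if (length(p) != depth_pixels) {
      stopf("'%s' must have length depth_pixels (%d)", nm, depth_pixels)
    }
    if (!all(is.finite(p)) || any(p <= 0)) {
      stopf("'%s' must be strictly positive and finite", nm)
    }
  }
  assert_scalar_finite(noise_floor_db, "noise_floor_db")
  assert_scalar_finite(refractive_index, "refractive_index")
  structure(
    list(
      axial_spacing_um = axial_spacing_um,
      lateral_spacing_um = lateral_spacing_um,
      depth_pixels = depth_pixels,
      rolloff = as.numeric(rolloff),
      focus = as.numeric(focus),
      noise_floor_db = noise_floor_db,
      central_wavelength_nm = central_wavelength_nm,
      axial_resolution_um = axial_resolution_um,
      lateral_resolution_um = lateral_resolution_um,
      refractive_index = refractive_index
    ),
    class = "oct_system"
  )
}

#' Flat-sensitivity variant of an OCT system
#'
#' Convenience constructor with unit roll-off and focus profiles, useful for
#' tests and for data already compensated upstream.
#'
#' @param ... Passed to [oct_system()].
#' @return An `oct_system` with flat sensitivity profiles.
#' @export
oct_system_flat <- function(...) {
  sys <- oct_system(...)
  sys$rolloff <- rep(1, sys$depth_pixels)
  sys$focus <- rep(1, sys$depth_pixels)
  sys
}

#' @export
print.oct_system <- function(x, ...) {
  cat(sprintf(
    "<oct_system> %d depth px @ %.3g um, noise floor %.3g dB, lambda %g nm\n",
    x$depth_pixels, x$axial_spacing_um, x$noise_floor_db,
    x$central_wavelength_nm
  ))
  invisible(x)
}

#' Optical tissue class parameters
#'
#' Per-class parameters of the single-scattering forward model: the
#' attenuation coefficient `mu` (mm^-1) and peak backscattered intensity
#' `intensity_db` of `I * exp(-2 mu z)`, plus the statistical texture of the
#' class: `heterogeneity` (sd of per-A-scan natural-log intensity
#' fluctuation), `surface_roughness_um` (sd of per-A-scan surface depth) and
#' `microstructure_rate` (expected signal-shadowing artifacts per B-scan,
#' emulating cysts/calcifications/vessels).
#'
#' @param label Tissue class label (one of [tissue_labels()] or custom).
#' @param mu Attenuation coefficient, mm^-1, >= 0.
#' @param intensity_db Peak backscattered intensity, dB; the display-range
#'   archetypes are 70 dB (deep red) vs 40 dB (deep blue).
#' @param heterogeneity Sd of per-A-scan log-intensity fluctuation, >= 0.
#' @param surface_roughness_um Sd of the surface depth across A-scans, um.
#' @param microstructure_rate Expected shadow artifacts per B-scan, >= 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(label, mu, intensity_db,
                          heterogeneity = 0,
                          surface_roughness_um = 0,
                          microstructure_rate = 0) {
  assert_scalar_finite(mu, "mu")
  assert_scalar_finite(intensity_db, "intensity_db")
  assert_scalar_finite(heterogeneity, "heterogeneity")
  assert_scalar_finite(surface_roughness_um, "surface_roughness_um")
  assert_scalar_finite(microstructure_rate, "microstructure_rate")
  if (mu < 0) stopf("'mu' must be >= 0")
  if (heterogeneity < 0 || surface_roughness_um < 0) {
    stopf("texture parameters must be >= 0")
  }
  if (microstructure_rate < 0) stopf("'microstructure_rate' must be >= 0")
  structure(
    list(
      label = as.character(label), mu = mu, intensity_db = intensity_db,
      heterogeneity = heterogeneity,
      surface_roughness_um = surface_roughness_um,
      microstructure_rate = microstructure_rate
    ),
    class = "tissue_params"
  )
}

#' Histology class labels
#'
#' The six histopathological classes: gray matter, healthy white matter,
#' three grades of tumor-infiltrated white matter, and edematous white
#' matter, ordered by infiltration grade within white matter.
#'
#' @return Character vector of the six labels.
#' @export
tissue_labels <- function() {
  c("GM0", "WM0", "WM0_30", "WM30_60", "WM60plus", "WME")
}

#' Default tissue-class parameter set
#'
#' Class parameters for the six histology classes. Only relative attenuation
#' differences at 830 nm are anchored: gray matter at 44% of healthy white
#' matter (56% lower) and edematous white matter at 60% (40% lower); the
#' absolute healthy-white-matter value `wm0_mu` is configuration (literature
#' values at longer wavelengths are around 3.5 mm^-1 and scattering grows
#' toward shorter wavelengths). Attenuation, intensity and homogeneity all
#' decrease with increasing infiltration grade; microstructure shadowing
#' increases with grade.
#'
#' @param wm0_mu Absolute attenuation of healthy white matter, mm^-1.
#' @return Named list of [tissue_params()], one per label.
#' @export
default_tissue_params <- function(wm0_mu = 6.0) {
  list(
    GM0 = tissue_params("GM0", 0.44 * wm0_mu, 50, 0.30, 20, 0.2),
    WM0 = tissue_params("WM0", wm0_mu, 68, 0.05, 10, 0),
    WM0_30 = tissue_params("WM0_30", 0.57 * wm0_mu, 55, 0.20, 15, 0.5),
    WM30_60 = tissue_params("WM30_60", 0.50 * wm0_mu, 52, 0.28, 15, 1),
    WM60plus = tissue_params("WM60plus", 0.42 * wm0_mu, 49, 0.35, 20, 2),
    WME = tissue_params("WME", 0.60 * wm0_mu, 52, 0.10, 15, 0)
  )
}
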