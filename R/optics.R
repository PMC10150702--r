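#' Average a patch to one A-scan profile
#'
#' Each B-scan patch is collapsed to a single depth profile by averaging
#' its A-scans laterally in linear intensity units, optionally subtracting
#' the (known) mean noise floor, and taking the natural logarithm. The
#' depth axis starts at the patch's top row (the flattened tissue surface)
#' and is expressed in mm, so the single-scattering model
#' `I * exp(-2 mu z)` becomes the straight line `ln I - 2 mu z`.
#'
#' @param patch An `oct_patch` from [extract_patches()].
#' @param subtract_floor Subtract the expected noise-floor intensity (the
#'   patch's per-depth `floor_db_profile` when present, else the constant
#'   floor) from the lateral mean before taking the log. Recommended for
#'   noisy data, where the additive floor flattens the decay at depth; keep
#'   `FALSE` for noiseless/idealized profiles without floor contribution.
#' @return An `ascan_profile`: list with `z_mm` (strictly increasing),
#'   `y` (log linear intensity), `axial_spacing_um` and provenance.
#' @export
average_patch_to_ascan <- function(patch, subtract_floor = FALSE) {
  stopifnot(inherits(patch, "oct_patch"))
  lin <- db_to_linear(patch$data)
  prof <- if (is.matrix(lin)) colMeans(lin) else as.numeric(lin)
  if (subtract_floor) {
    floor_db <- patch$floor_db_profile
    if (is.null(floor_db)) floor_db <- patch$noise_floor_db
    prof <- prof - db_to_linear(floor_db)
    prof <- pmax(prof, max(prof) * 1e-9)
  }
  dz_mm <- patch$axial_spacing_um * 1e-3 / patch$refractive_index
  structure(
    list(
      z_mm = (seq_along(prof) - 1L) * dz_mm,
      y = log(prof),
      axial_spacing_um = patch$axial_spacing_um,
      refractive_index = patch$refractive_index,
      patient_id = patch$patient_id, scan_id = patch$scan_id,
      label = patch$label
    ),
    class = "ascan_profile"
  )
}

#' Select the fit window on an A-scan profile
#'
#' The attenuation fit is applied to a fixed region of interest: a window
#' `length_um` (300 um) long that starts `start_after_um` (20 um) after the
#' maximum measured intensity of the A-scan. The start is rounded up to the
#' next sample, the window holds `floor(length_um / spacing)` samples and is
#' half-open; ties in the maximum take the shallowest sample.
#'
#' @param profile An `ascan_profile`.
#' @param start_after_um Gap between the intensity maximum and the window
#'   start, um.
#' @param length_um Window length, um.
#' @return A `fit_window`: list with `start_index` (0-based), `n_samples`
#'   and the 1-based sample `idx` vector.
#' @export
select_fit_window <- function(profile, start_after_um = 20,
                              length_um = 300) {
  stopifnot(inherits(profile, "ascan_profile"))
  sp <- profile$axial_spacing_um / profile$refractive_index
  imax <- which.max(profile$y)
  start <- imax + as.integer(ceiling(start_after_um / sp))
  n <- as.integer(floor(length_um / sp))
  if (n < 3L) stopf("fit window holds fewer than 3 samples")
  if (start + n - 1L > length(profile$y)) {
    stopf(paste0(
      "profile too short for the fit window: needs %d samples past the ",
      "maximum (%s um), has %d"),
      start + n - 1L - imax, start_after_um + length_um,
      length(profile$y) - imax)
  }
  structure(
    list(start_index = start - 1L, n_samples = n,
         idx = start:(start + n - 1L)),
    class = "fit_window"
  )
}

#' Fit the single-scattering model to an A-scan window
#'
#' Ordinary least squares of the log intensity `y` on depth `z` within the
#' fit window. With slope `b` and intercept `a`, the optical properties are
#' the attenuation coefficient `mu = -b / 2` (mm^-1) and the peak
#' backscattered intensity `I = exp(a)` (linear; also returned in dB). Fit
#' quality is the coefficient of determination
#' `r2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`, used downstream as a
#' proxy for A-scan homogeneity. A zero-variance window yields `mu = 0`,
#' `I = exp(mean(y))` and an undefined (`NA`) `r2`.
#'
#' @param profile An `ascan_profile`.
#' @param window A `fit_window`; defaults to [select_fit_window()].
#' @return An `optical_properties` list: `mu`, `I_lin`, `I_db`, `r2`,
#'   `r2_defined`, `n` and provenance.
#' @export
fit_optical_properties <- function(profile,
                                   window = select_fit_window(profile)) {
  stopifnot(inherits(profile, "ascan_profile"),
            inherits(window, "fit_window"))
  z <- profile$z_mm[window$idx]
  y <- profile$y[window$idx]
  if (!all(is.finite(y))) stopf("non-finite log-intensity in fit window")
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  if (sst == 0) {
    props <- list(mu = 0, I_lin = exp(ybar), I_db = linear_to_db(exp(ybar)),
                  r2 = NA_real_, r2_defined = FALSE)
  } else {
    zbar <- mean(z)
    slope <- sum((z - zbar) * (y - ybar)) / sum((z - zbar)^2)
    intercept <- ybar - slope * zbar
    f <- intercept + slope * z
    props <- list(
      mu = -slope / 2,
      I_lin = exp(intercept),
      I_db = linear_to_db(exp(intercept)),
      r2 = 1 - sum((y - f)^2) / sst,
      r2_defined = TRUE
    )
  }
  structure(
    c(props,
      list(n = window$n_samples, patient_id = profile$patient_id,
           scan_id = profile$scan_id, label = profile$label)),
    class = "optical_properties"
  )
}

#' Fit optical properties for a list of patches
#'
#' Convenience wrapper running patch averaging, window selection and the
#' log-linear fit over a patch list, returning one row per patch.
#'
#' @param patches List of `oct_patch` objects.
#' @param subtract_floor Passed to [average_patch_to_ascan()].
#' @param skip_short Skip (rather than stop on) patches too shallow for
#'   the fit window.
#' @param ... Passed to [select_fit_window()].
#' @return data.frame with columns `patient_id`, `scan_id`, `label`, `mu`,
#'   `I_lin`, `I_db`, `r2`.
#' @export
fit_patches <- function(patches, subtract_floor = TRUE,
                        skip_short = FALSE, ...) {
  rows <- lapply(patches, function(p) {
    prof <- average_patch_to_ascan(p, subtract_floor = subtract_floor)
    win <- if (skip_short) {
      tryCatch(select_fit_window(prof, ...), error = function(e) NULL)
    } else {
      select_fit_window(prof, ...)
    }
    if (is.null(win)) return(NULL)
    props <- fit_optical_properties(prof, win)
    data.frame(
      patient_id = props$patient_id, scan_id = props$scan_id,
      label = props$label, mu = props$mu, I_lin = props$I_lin,
      I_db = props$I_db, r2 = props$r2
    )
  })
  do.call(rbind, rows)
}

#' Group statistics over optical properties
#'
#' For one optical property tabulated by tissue label: per-group
#' Shapiro-Wilk normality tests and pairwise two-sample Wilcoxon rank-sum
#' location tests over all label pairs, with significance stars at
#' p < 0.05 (*), < 0.01 (**) and < 0.001 (***); a p-value of exactly 0.05
#' earns no star. Groups smaller than 3 are marked not computable.
#'
#' @param values Numeric vector of one property (e.g. `mu`).
#' @param groups Tissue label per value.
#' @return List with `shapiro` and `pairwise` data.frames.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  labs <- unique(groups)
  if (length(labs) < 2L) stopf("need at least 2 groups")
  shapiro <- do.call(rbind, lapply(labs, function(g) {
    x <- values[groups == g]
    p <- if (length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0) {
      stats::shapiro.test(x)$p.value
    } else {
      NA_real_
    }
    data.frame(label = g, n = length(x), shapiro_p = p)
  }))
  pairs <- utils::combn(labs, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- values[groups == pairs[1, k]]
    b <- values[groups == pairs[2, k]]
    p <- if (length(a) >= 3L && length(b) >= 3L) {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    } else {
      NA_real_
    }
    data.frame(label_a = pairs[1, k], label_b = pairs[2, k],
               wilcoxon_p = p, stars = significance_stars(p))
  }))
  list(shapiro = shapiro, pairwise = pairwise)
}

#' Significance star coding
#'
#' @param p P-value (may be `NA`).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}
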