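#' Decibel / linear intensity conversions
#'
#' OCT intensities are handled on the decibel scale for display and storage
#' and on the linear scale for all physical computation (compensation,
#' averaging, model fitting). The convention throughout is
#' `dB = 10 * log10(linear)`.
#'
#' @param db,linear Numeric vectors.
#' @return Numeric vector of the converted values.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(linear) 10 * log10(linear)

#' Round half away from zero to integer
#'
#' Percentage metrics are reported as integers, rounding halves away from
#' zero (so 81.5 -> 82), matching the usual clinical-reporting style.
#' Raw unrounded values are kept alongside wherever this is applied.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)

# Smooth random lateral field with given marginal sd (moving-average of
# white noise, rescaled). Used to give per-A-scan log-intensity fluctuation
# lateral spatial correlation, as tissue heterogeneity is not pixel-iid.
smooth_field <- function(n, sd, span = 31L) {
  if (sd <= 0) return(rep(0, n))
  span <- min(span, max(3L, n - (1L - n %% 2L)))
  if (span %% 2L == 0L) span <- span - 1L
  x <- stats::rnorm(n + 2L * span)
  x <- stats::filter(x, rep(1 / span, span), sides = 2)
  x <- as.numeric(x[(span + 1L):(span + n)])
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, n))
  x * (sd / s)
}

# Smooth random 2-D log-intensity texture (lateral x depth), marginal sd
# `sd`, with separate lateral and axial correlation spans. Models the
# spatially coherent structural inhomogeneity (cysts, vessels, hemorrhage)
# that curves A-scan decays, unlike pure per-column amplitude variation.
smooth_field_2d <- function(n_lat, n_depth, sd, span_lat = 31L,
                            span_ax = 15L) {
  if (sd <= 0) return(matrix(0, n_lat, n_depth))
  ma <- function(v, span) {
    span <- max(3L, min(span, length(v)))
    pad <- c(rev(v[seq_len(span)]), v, rev(v[length(v) - seq_len(span) + 1L]))
    sm <- stats::filter(pad, rep(1 / span, span), sides = 2)
    as.numeric(sm[(span + 1L):(span + length(v))])
  }
  m <- matrix(stats::rnorm(n_lat * n_depth), n_lat, n_depth)
  m <- apply(m, 2, ma, span = span_lat)
  m <- t(apply(m, 1, ma, span = span_ax))
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) return(matrix(0, n_lat, n_depth))
  m * (sd / s)
}

# First TRUE index per row of a logical matrix, NA when a row has none.
first_true_index <- function(m) {
  idx <- max.col(m * 1L, ties.method = "first")
  idx[!m[cbind(seq_len(nrow(m)), idx)]] <- NA_integer_
  idx
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a finite numeric scalar", name)
  }
  invisible(x)
}
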