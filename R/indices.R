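#' Inclusive spectral band window
#'
#' @param low_nm,high_nm Window limits in nm, inclusive; `low_nm < high_nm`.
#' @return A `band_window` object.
#' @export
band_window <- function(low_nm, high_nm) {
  if (!is.numeric(low_nm) || !is.numeric(high_nm) || low_nm >= high_nm)
    lhsi_stop("band window requires low_nm < high_nm", "lhsi_parameter_error")
  structure(list(low_nm = low_nm, high_nm = high_nm), class = "band_window")
}

as_band_window <- function(x) {
  if (inherits(x, "band_window")) return(x)
  if (is.numeric(x) && length(x) == 2) return(band_window(x[1], x[2]))
  lhsi_stop("cannot interpret band window", "lhsi_parameter_error")
}

window_bands <- function(grid, win) {
  win <- as_band_window(win)
  wl <- wavelengths(grid)
  if (win$low_nm < min(wl) - 1e-9 || win$high_nm > max(wl) + 1e-9)
    lhsi_stop(sprintf("window %g-%g nm lies outside the %g-%g nm grid",
                      win$low_nm, win$high_nm, min(wl), max(wl)),
              "lhsi_parameter_error")
  idx <- which(wl >= win$low_nm - 1e-9 & wl <= win$high_nm + 1e-9)
  if (length(idx) == 0)
    lhsi_stop("band window contains no grid bands", "lhsi_parameter_error")
  idx
}

#' Smoothed second derivative of an absorbance spectrum
#'
#' Savitzky-Golay polynomial smoothing followed by a central second
#' difference with respect to wavelength. The result is expressed per nm^2
#' (the band-index difference is divided by `step_nm^2`); the two boundary
#' samples replicate their nearest interior value. Smoothing and
#' differentiation are both linear, so the whole operator is a single
#' band-by-band matrix, exposed via [second_derivative_operator()] for
#' cube-scale work.
#'
#' @param spectrum Numeric vector of per-band absorbance.
#' @param step_nm Band spacing in nm (default 5, the package grid).
#' @param window_len Odd smoothing window length in bands; must be at least
#'   `polyorder + 2`. Default 9.
#' @param polyorder Polynomial order of the smoother. Default 4.
#' @return Numeric vector, same length as `spectrum`.
#' @export
second_derivative <- function(spectrum, step_nm = 5, window_len = 9,
                              polyorder = 4) {
  check_sg_params(length(spectrum), window_len, polyorder)
  sm <- signal::sgolayfilt(spectrum, p = polyorder, n = window_len)
  central_second_diff(sm, step_nm)
}

check_sg_params <- function(len, window_len, polyorder) {
  if (window_len %% 2 == 0 || window_len < polyorder + 2)
    lhsi_stop("window_len must be odd and >= polyorder + 2",
              "lhsi_parameter_error")
  if (len < window_len)
    lhsi_stop(sprintf("spectrum too short (%d bands) for window_len %d",
                      len, window_len), "lhsi_parameter_error")
  invisible(TRUE)
}

central_second_diff <- function(x, step_nm) {
  n <- length(x)
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (x[1:(n - 2)] - 2 * x[2:(n - 1)] + x[3:n]) / step_nm^2
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  d2
}

#' @rdname second_derivative
#' @param n_bands Number of bands of the operator.
#' @return `second_derivative_operator()` returns the `n_bands` x `n_bands`
#'   matrix `D` such that `D %*% spectrum == second_derivative(spectrum)`.
#' @export
second_derivative_operator <- function(n_bands, step_nm = 5, window_len = 9,
                                       polyorder = 4) {
  check_sg_params(n_bands, window_len, polyorder)
  vapply(seq_len(n_bands), function(j) {
    e <- numeric(n_bands); e[j] <- 1
    second_derivative(e, step_nm, window_len, polyorder)
  }, numeric(n_bands))
}

new_index_map <- function(values, kind) {
  structure(list(values = values, index_kind = kind), class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<index_map:%s> %d x %d, mean %.3f\n", x$index_kind,
              nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Tissue oxygen saturation (StO2) map
#'
#' Estimates superficial (~1 mm) microcirculatory oxygen saturation from the
#' curvature of the absorbance spectrum. An absorption band centred inside a
#' window makes the absorbance locally concave there, so the rectified
#' negative second derivative ("concavity") detects band presence: the
#' oxyhaemoglobin 577 nm peak lights up the 570-590 nm window and the
#' deoxyhaemoglobin 760 nm band the 740-780 nm window. The index is the
#' normalized concavity ratio `D_vis / (D_vis + D_nir)` with each `D` the
#' mean rectified negative smoothed second derivative over its window. For
#' any linear mixture of an oxygenated and a deoxygenated chromophore the
#' ratio is monotone in the oxygen fraction: `D_vis` can only grow and
#' `D_nir` only shrink with it. Values lie in `[0, 1]`; spectrally flat
#' pixels (no concavity in either window) yield `NaN`.
#'
#' The ratio is exactly invariant to a positive uniform rescaling of the
#' reflectance: rescaling shifts absorbance by a constant, which the second
#' derivative annihilates.
#'
#' @param acube An `absorbance_cube` from [to_absorbance()].
#' @param vis_window,nir_window Band windows in nm (defaults 570-590 and
#'   740-780).
#' @param window_len,polyorder Savitzky-Golay parameters, see
#'   [second_derivative()].
#' @return An `index_map` with `index_kind = "sto2"`.
#' @export
sto2_map <- function(acube, vis_window = c(570, 590),
                     nir_window = c(740, 780),
                     window_len = 9, polyorder = 4) {
  stopifnot(inherits(acube, "absorbance_cube"))
  grid <- acube$grid
  vis_idx <- window_bands(grid, vis_window)
  nir_idx <- window_bands(grid, nir_window)
  d <- dim(acube$absorbance)
  D <- second_derivative_operator(d[3], grid$step_nm, window_len, polyorder)
  flat <- matrix(acube$absorbance, d[1] * d[2], d[3])
  d2 <- pmax(-(flat %*% t(D)), 0)            # rectified concavity
  dvis <- rowMeans(d2[, vis_idx, drop = FALSE])
  dnir <- rowMeans(d2[, nir_idx, drop = FALSE])
  denom <- dvis + dnir
  vals <- ifelse(denom > 1e-12, dvis / denom, NaN)
  new_index_map(matrix(pmin(pmax(vals, 0), 1), d[1], d[2]), "sto2")
}

#' Near-infrared (NIR) perfusion index map
#'
#' Deeper-layer (3-5 mm) perfusion surrogate: per pixel, the mean absorbance
#' over the upper NIR window minus the mean over the lower window, rescaled
#' over the image to `[0, 1]`. The rescale uses the 1st-99th percentile of the
#' raw difference so that a handful of specular outliers cannot compress the
#' dynamic range; a degenerate image (constant raw difference) maps to all
#' zeros by convention.
#'
#' @param acube An `absorbance_cube`.
#' @param lower_window,upper_window Band windows in nm (defaults 655-735 and
#'   825-925).
#' @return An `index_map` with `index_kind = "nir"`.
#' @export
nir_map <- function(acube, lower_window = c(655, 735),
                    upper_window = c(825, 925)) {
  stopifnot(inherits(acube, "absorbance_cube"))
  lo_idx <- window_bands(acube$grid, lower_window)
  hi_idx <- window_bands(acube$grid, upper_window)
  d <- dim(acube$absorbance)
  flat <- matrix(acube$absorbance, d[1] * d[2], d[3])
  raw <- rowMeans(flat[, hi_idx, drop = FALSE]) -
    rowMeans(flat[, lo_idx, drop = FALSE])
  qs <- quantile(raw, c(0.01, 0.99), names = FALSE, na.rm = TRUE)
  if (qs[2] - qs[1] <= 0) {
    vals <- rep(0, length(raw))
  } else {
    vals <- pmin(pmax((raw - qs[1]) / (qs[2] - qs[1]), 0), 1)
  }
  new_index_map(matrix(vals, d[1], d[2]), "nir")
}

#' Export an index map as a greyscale PNG
#'
#' Values in `[0, 1]` are written as grey levels; `NaN` pixels are written
#' as 0. For lossless float export store the map inside the native archive
#' instead.
#'
#' @param map An `index_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_index_map <- function(map, path) {
  stopifnot(inherits(map, "index_map"))
  v <- map$values
  v[!is.finite(v)] <- 0
  png::writePNG(v, path, dpi = NULL)
  invisible(path)
}
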