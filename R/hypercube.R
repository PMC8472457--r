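#' Wavelength grid of a hyperspectral cube
#'
#' A regular spectral sampling: band `k` (1-based) sits at
#' `start_nm + (k - 1) * step_nm`. The default grid is the 100-band
#' visible/near-infrared grid used throughout the package: 500 nm to 995 nm in
#' 5 nm steps.
#'
#' @param start_nm Wavelength of the first band, in nm.
#' @param step_nm Band spacing, in nm; must be positive.
#' @param n_bands Number of bands; must be at least 1.
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' range(wavelengths(g))  # 500 995
#' @export
wavelength_grid <- function(start_nm = 500, step_nm = 5, n_bands = 100) {
  if (!is.numeric(step_nm) || length(step_nm) != 1 || step_nm <= 0)
    lhsi_stop("step_nm must be a positive scalar", "lhsi_parameter_error")
  if (!is.numeric(n_bands) || length(n_bands) != 1 || n_bands < 1)
    lhsi_stop("n_bands must be >= 1", "lhsi_parameter_error")
  structure(
    list(start_nm = as.numeric(start_nm), step_nm = as.numeric(step_nm),
         n_bands = as.integer(n_bands)),
    class = "wavelength_grid"
  )
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @return `wavelengths()` returns the numeric vector of band centres in nm.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n_bands) - 1)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %g-%g nm, step %g nm\n",
              x$n_bands, x$start_nm,
              x$start_nm + x$step_nm * (x$n_bands - 1), x$step_nm))
  invisible(x)
}

#' Hyperspectral reflectance cube
#'
#' A three-axis array of relative reflectance I/I0 (rows x cols x bands),
#' dimensionless and non-negative, together with its wavelength grid and
#' acquisition metadata. Values above 1 are permitted: specular highlights
#' routinely exceed the white-reference level.
#'
#' @param reflectance Numeric array with `dim` of length 3 (H, W, B); all
#'   values must be finite and non-negative.
#' @param grid A [wavelength_grid()]; its `n_bands` must equal `dim()[3]`.
#' @param subject_id Optional subject identifier (string).
#' @param timepoint Optional acquisition label, e.g. `"T0"`, `"isch30"`,
#'   `"rep1h"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(reflectance, grid = wavelength_grid(),
                      subject_id = NA_character_, timepoint = NA_character_) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3)
    lhsi_stop("reflectance must be a 3-axis array (H x W x B)",
              "lhsi_validation_error")
  if (dim(reflectance)[3] != grid$n_bands)
    lhsi_stop(sprintf("band axis (%d) does not match grid (%d bands)",
                      dim(reflectance)[3], grid$n_bands),
              "lhsi_validation_error")
  if (!all(is.finite(reflectance)))
    lhsi_stop("reflectance contains non-finite values", "lhsi_validation_error")
  if (any(reflectance < 0))
    lhsi_stop("reflectance must be non-negative", "lhsi_validation_error")
  structure(
    list(reflectance = reflectance, grid = grid,
         subject_id = as.character(subject_id),
         timepoint = as.character(timepoint)),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%g-%g nm)",
              d[1], d[2], d[3], x$grid$start_nm,
              x$grid$start_nm + x$grid$step_nm * (d[3] - 1)))
  if (!is.na(x$subject_id)) cat(" subject:", x$subject_id)
  if (!is.na(x$timepoint)) cat(" @", x$timepoint)
  cat("\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$reflectance)

#' Per-pixel label mask
#'
#' Integer H x W image with values in {+1, -1, 0}. For organ segmentation, +1
#' marks liver, -1 non-liver, and 0 the annulus at the organ border where
#' optical blurring makes the label undecidable; 0-labelled pixels are never
#' used for training. For tissue characterisation, +1 marks ischemic liver,
#' -1 perfused liver, and 0 everything else.
#'
#' @param labels Integer matrix with entries in {-1, 0, 1}.
#' @return An object of class `label_mask` (an integer matrix subclass).
#' @export
label_mask <- function(labels) {
  if (!is.matrix(labels))
    lhsi_stop("labels must be a matrix", "lhsi_validation_error")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(-1L, 0L, 1L)))
    lhsi_stop("labels must take values in {-1, 0, +1}", "lhsi_validation_error")
  structure(labels, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = c(-1, 0, 1)))
  cat(sprintf("<label_mask> %d x %d  (-1: %d, 0: %d, +1: %d)\n",
              nrow(x), ncol(x), tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}
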