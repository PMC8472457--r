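#' Convert relative reflectance to relative absorbance
#'
#' Applies the Beer-Lambert style log transform `A = -ln(max(I/I0, floor))`
#' elementwise. The floor clip keeps the map finite where the reflectance is
#' zero (shadow pixels, dead sensor elements); reflectance equal to 1 maps to
#' absorbance 0 exactly.
#'
#' @param cube A [hypercube()].
#' @param floor Lower clip applied to reflectance before the log; must be
#'   strictly positive. Default `1e-6`.
#' @return An object of class `absorbance_cube`: a list with `absorbance`
#'   (array, same shape as the input reflectance) and `grid`.
#' @examples
#' cu <- hypercube(array(exp(-2), c(2, 2, 100)))
#' a <- to_absorbance(cu)
#' a$absorbance[1, 1, 1]  # 2
#' @export
to_absorbance <- function(cube, floor = 1e-6) {
  if (!inherits(cube, "hypercube"))
    lhsi_stop("cube must be a hypercube", "lhsi_validation_error")
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    lhsi_stop("floor must be a strictly positive scalar", "lhsi_parameter_error")
  a <- -log(pmax(cube$reflectance, floor))
  structure(list(absorbance = a, grid = cube$grid), class = "absorbance_cube")
}

#' @export
print.absorbance_cube <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf("<absorbance_cube> %d x %d px, %d bands\n", d[1], d[2], d[3]))
  invisible(x)
}
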