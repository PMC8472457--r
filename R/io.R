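#' Write a hypercube to disk
#'
#' Two on-disk representations are supported:
#' \describe{
#'   \item{`"envi"`}{A plain-text ENVI header (`<path>.hdr`) plus a raw binary
#'     data file at `path`. Data are written band-sequential (BSQ) as float32,
#'     little-endian, with the wavelength list in nm carried in the header.
#'     Round trips are exact to float32 precision.}
#'   \item{`"archive"`}{The package-native archive: a versioned serialized
#'     container holding the reflectance array at full double precision, the
#'     wavelength vector, an optional label mask, and metadata. Round trips
#'     are bit-exact.}
#' }
#'
#' @param cube A [hypercube()].
#' @param path Output file path (the ENVI header is written to `<path>.hdr`).
#' @param format `"envi"` or `"archive"`.
#' @param labels Optional [label_mask()] stored alongside the cube
#'   (archive format only).
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path, format = c("archive", "envi"), labels = NULL) {
  format <- match.arg(format)
  if (!inherits(cube, "hypercube"))
    lhsi_stop("cube must be a hypercube", "lhsi_validation_error")
  if (!is.null(labels) && !inherits(labels, "label_mask"))
    lhsi_stop("labels must be a label_mask", "lhsi_validation_error")
  d <- dim(cube$reflectance)
  if (!is.null(labels) && !all(dim(labels) == d[1:2]))
    lhsi_stop("label mask shape does not match cube", "lhsi_validation_error")
  if (format == "archive") {
    obj <- list(
      format = "liverhsi-archive", version = 1L,
      reflectance = cube$reflectance,
      wavelength = wavelengths(cube$grid),
      labels = if (is.null(labels)) NULL else unclass(labels),
      metadata = list(subject_id = cube$subject_id, timepoint = cube$timepoint,
                      label_coding = "int {-1,0,+1}")
    )
    ok <- tryCatch({ saveRDS(obj, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) lhsi_stop(paste("cannot write archive:", path), "lhsi_io_error")
  } else {
    hdr <- c(
      "ENVI",
      "description = {liverhsi hyperspectral reflectance cube}",
      sprintf("samples = %d", d[2]),
      sprintf("lines = %d", d[1]),
      sprintf("bands = %d", d[3]),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 4",
      "interleave = bsq",
      "byte order = 0",
      "wavelength units = Nanometers",
      sprintf("wavelength = {%s}",
              paste(format(wavelengths(cube$grid), trim = TRUE), collapse = ", "))
    )
    ok <- tryCatch({
      con <- file(path, "wb")
      on.exit(close(con), add = TRUE)
      # BSQ: sample (column) fastest, then line, then band
      writeBin(as.vector(aperm(cube$reflectance, c(2, 1, 3))), con,
               size = 4, endian = "little")
      writeLines(hdr, paste0(path, ".hdr"))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) lhsi_stop(paste("cannot write ENVI file:", path), "lhsi_io_error")
  }
  invisible(path)
}

#' Read a hypercube from disk
#'
#' Reads either the package-native archive or an ENVI file (BSQ, BIL, and BIP
#' interleaves; float32 or float64 samples). The wavelength grid is taken from
#' the ENVI header when present (it must be regularly spaced); if the header
#' carries no wavelength list, the default 500-995 nm / 5 nm grid is assumed.
#' A header whose declared dimensions contradict the data size is a format
#' error.
#'
#' @param path File written by [write_cube()] (or by any ENVI writer).
#' @param format `"envi"` or `"archive"`; `"auto"` sniffs the file.
#' @return A [hypercube()]. For archives carrying a label mask, the mask is
#'   attached as attribute `"labels"`.
#' @export
read_cube <- function(path, format = c("auto", "archive", "envi")) {
  format <- match.arg(format)
  if (!file.exists(path))
    lhsi_stop(paste("no such file:", path), "lhsi_io_error")
  if (format == "auto")
    format <- if (file.exists(paste0(path, ".hdr"))) "envi" else "archive"
  if (format == "archive") {
    obj <- tryCatch(readRDS(path), error = function(e) NULL)
    if (!is.list(obj) || !identical(obj$format, "liverhsi-archive"))
      lhsi_stop(paste("not a liverhsi archive:", path), "lhsi_format_error")
    wl <- obj$wavelength
    grid <- wavelength_grid(wl[1], if (length(wl) > 1) wl[2] - wl[1] else 5,
                            length(wl))
    cube <- hypercube(obj$reflectance, grid,
                      subject_id = obj$metadata$subject_id,
                      timepoint = obj$metadata$timepoint)
    if (!is.null(obj$labels)) attr(cube, "labels") <- label_mask(obj$labels)
    return(cube)
  }
  read_envi_cube(path)
}

# -- ENVI plumbing ------------------------------------------------------------

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || toupper(trimws(lines[1])) != "ENVI")
    lhsi_stop("missing ENVI magic line", "lhsi_format_error")
  entries <- list()
  # accumulate physical lines until braces balance, then split key = value
  buf <- ""
  for (ln in lines[-1]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    if (lengths(regmatches(buf, gregexpr("\\{", buf))) ==
        lengths(regmatches(buf, gregexpr("\\}", buf)))) {
      kv <- regmatches(buf, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", buf))[[1]]
      if (length(kv) == 3) entries[[tolower(kv[2])]] <- trimws(kv[3])
      buf <- ""
    }
  }
  entries
}

read_envi_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    alt <- sub("\\.[^.]+$", ".hdr", path)
    if (file.exists(alt)) hdr_path <- alt
    else lhsi_stop(paste("missing ENVI header for", path), "lhsi_format_error")
  }
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands")
  if (!all(need %in% names(h)))
    lhsi_stop("ENVI header lacks samples/lines/bands", "lhsi_format_error")
  W <- as.integer(h$samples); H <- as.integer(h$lines); B <- as.integer(h$bands)
  dtype <- as.integer(if (is.null(h$`data type`)) 4 else h$`data type`)
  offset <- as.integer(if (is.null(h$`header offset`)) 0 else h$`header offset`)
  interleave <- tolower(if (is.null(h$interleave)) "bsq" else h$interleave)
  endian <- if (!is.null(h$`byte order`) && as.integer(h$`byte order`) == 1)
    "big" else "little"
  bytes <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                  lhsi_stop(sprintf("unsupported ENVI data type %d", dtype),
                            "lhsi_format_error"))
  n <- as.numeric(H) * W * B
  if (file.info(path)$size - offset != n * bytes)
    lhsi_stop(sprintf(
      "ENVI header declares %d x %d x %d (%g bytes) but file holds %g bytes",
      H, W, B, n * bytes, file.info(path)$size - offset), "lhsi_format_error")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, "double", n = n, size = bytes, endian = endian)
  ref <- switch(interleave,
    bsq = aperm(array(v, dim = c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(B, W, H)), c(3, 2, 1)),
    lhsi_stop(paste("unknown interleave:", interleave), "lhsi_format_error"))
  grid <- if (!is.null(h$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
    if (length(wl) != B)
      lhsi_stop(sprintf("header lists %d wavelengths for %d bands",
                        length(wl), B), "lhsi_format_error")
    steps <- diff(wl)
    if (length(steps) && max(abs(steps - steps[1])) > 1e-6 * abs(steps[1]))
      lhsi_stop("irregular wavelength spacing in ENVI header",
                "lhsi_format_error")
    wavelength_grid(wl[1], if (length(wl) > 1) steps[1] else 5, B)
  } else {
    wavelength_grid(500, 5, B)
  }
  if (!all(is.finite(ref)))
    lhsi_stop("ENVI data contain non-finite values", "lhsi_validation_error")
  hypercube(ref, grid)
}

# -- label mask PNG -----------------------------------------------------------

#' Read and write label masks as 8-bit PNG
#'
#' Labels are coded as grey levels: +1 -> 255, -1 -> 0, 0 (undecided) -> 128.
#'
#' @param mask A [label_mask()].
#' @param path PNG file path.
#' @return `write_label_mask()` returns `path` invisibly; `read_label_mask()`
#'   returns a [label_mask()].
#' @export
write_label_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask"))
    lhsi_stop("mask must be a label_mask", "lhsi_validation_error")
  grey <- matrix(0, nrow(mask), ncol(mask))
  grey[mask == 1L] <- 255
  grey[mask == 0L] <- 128
  png::writePNG(grey / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path))
    lhsi_stop(paste("no such file:", path), "lhsi_io_error")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  grey <- round(img * 255)
  out <- matrix(NA_integer_, nrow(grey), ncol(grey))
  out[grey == 255] <- 1L
  out[grey == 0] <- -1L
  out[grey == 128] <- 0L
  if (anyNA(out))
    lhsi_stop("PNG contains grey levels outside the {0,128,255} label coding",
              "lhsi_format_error")
  label_mask(out)
}
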