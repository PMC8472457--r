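test_that("wavelength grid maps band index to nm and validates its fields", {
  g <- wavelength_grid()
  expect_equal(g$n_bands, 100L)
  wl <- wavelengths(g)
  expect_equal(wl[1], 500)
  expect_equal(wl[100], 995)
  expect_equal(unique(diff(wl)), 5)
  expect_error(wavelength_grid(step_nm = 0), class = "lhsi_parameter_error")
  expect_error(wavelength_grid(n_bands = 0), class = "lhsi_parameter_error")
})

test_that("hypercube constructor enforces its invariants", {
  ok <- hypercube(array(runif(4 * 3 * 100), c(4, 3, 100)))
  expect_s3_class(ok, "hypercube")
  expect_error(hypercube(matrix(1, 2, 2)), class = "lhsi_validation_error")
  expect_error(hypercube(array(1, c(2, 2, 50))),
               class = "lhsi_validation_error")  # band/grid mismatch
  bad <- array(1, c(2, 2, 100)); bad[1] <- NaN
  expect_error(hypercube(bad), class = "lhsi_validation_error")
  neg <- array(1, c(2, 2, 100)); neg[1] <- -0.1
  expect_error(hypercube(neg), class = "lhsi_validation_error")
})

test_that("label masks admit only {-1, 0, +1}", {
  m <- label_mask(matrix(c(-1L, 0L, 1L, 1L), 2))
  expect_s3_class(m, "label_mask")
  expect_error(label_mask(matrix(2L, 2, 2)), class = "lhsi_validation_error")
})

test_that("native archive round trip is bit exact across random shapes", {
  set.seed(11)
  for (dims in list(c(8, 8, 100), c(5, 9, 60), c(12, 4, 31))) {
    cu <- hypercube(array(runif(prod(dims)), dims),
                    wavelength_grid(500, 5, dims[3]),
                    subject_id = "S9", timepoint = "isch30")
    lab <- label_mask(matrix(sample(c(-1L, 0L, 1L), prod(dims[1:2]),
                                    replace = TRUE), dims[1]))
    p <- withr::local_tempfile(fileext = ".lhsi")
    write_cube(cu, p, "archive", labels = lab)
    back <- read_cube(p)
    expect_identical(back$reflectance, cu$reflectance)
    expect_identical(wavelengths(back$grid), wavelengths(cu$grid))
    expect_identical(back$subject_id, "S9")
    expect_identical(unclass(attr(back, "labels")), unclass(lab))
  }
})

test_that("ENVI round trip preserves data to float32 and the header grid", {
  set.seed(2)
  cu <- hypercube(array(runif(8 * 8 * 100), c(8, 8, 100)))
  p <- withr::local_tempfile(fileext = ".raw")
  write_cube(cu, p, "envi")
  back <- read_cube(p)
  expect_lt(max(abs(back$reflectance - cu$reflectance)), 1e-6)
  expect_equal(wavelengths(back$grid), wavelengths(cu$grid))
})

test_that("the written ENVI header carries the standard keys", {
  cu <- hypercube(array(0.5, c(4, 6, 100)))
  p <- withr::local_tempfile(fileext = ".raw")
  write_cube(cu, p, "envi")
  hdr <- readLines(paste0(p, ".hdr"))
  expect_identical(hdr[1], "ENVI")
  # independent minimal parse of 'key = value' lines
  kv <- regmatches(hdr, regexec("^([a-z ]+?) = (.*)$", hdr))
  keys <- vapply(kv[lengths(kv) == 3], `[`, character(1), 2)
  expect_true(all(c("samples", "lines", "bands", "wavelength") %in% keys))
  expect_equal(as.integer(sub(".* = ", "", hdr[grep("^samples", hdr)])), 6L)
  expect_equal(as.integer(sub(".* = ", "", hdr[grep("^lines", hdr)])), 4L)
})

test_that("ENVI interleaves BIL and BIP are read back equivalently", {
  set.seed(5)
  cu <- hypercube(array(runif(6 * 7 * 20), c(6, 7, 20)),
                  wavelength_grid(500, 5, 20))
  p <- withr::local_tempfile(fileext = ".raw")
  write_cube(cu, p, "envi")
  hdr <- readLines(paste0(p, ".hdr"))
  # rewrite the payload in each interleave and patch the header
  for (il in c("bil", "bip")) {
    perm <- switch(il, bil = c(2, 3, 1), bip = c(3, 2, 1))
    con <- file(p, "wb")
    writeBin(as.vector(aperm(cu$reflectance, perm)), con, size = 4,
             endian = "little")
    close(con)
    writeLines(sub("interleave = bsq", paste("interleave =", il), hdr),
               paste0(p, ".hdr"))
    back <- read_cube(p, format = "envi")
    expect_lt(max(abs(back$reflectance - cu$reflectance)), 1e-6)
  }
})

test_that("contradictory or broken ENVI headers are format errors", {
  cu <- hypercube(array(0.5, c(4, 4, 100)))
  p <- withr::local_tempfile(fileext = ".raw")
  write_cube(cu, p, "envi")
  hdr <- readLines(paste0(p, ".hdr"))
  bad <- hdr[-grep("^wavelength =", hdr)]
  bad[grep("^bands", bad)] <- "bands = 50"
  writeLines(bad, paste0(p, ".hdr"))
  expect_error(read_cube(p, format = "envi"), class = "lhsi_format_error")
  # wavelength count disagreeing with the band count
  bad2 <- hdr
  bad2[grep("^wavelength =", bad2)] <- "wavelength = {500, 505, 510}"
  writeLines(bad2, paste0(p, ".hdr"))
  expect_error(read_cube(p, format = "envi"), class = "lhsi_format_error")
  expect_error(read_cube(tempfile()), class = "lhsi_io_error")
})

test_that("label masks survive the PNG grey coding", {
  set.seed(3)
  lab <- label_mask(matrix(sample(c(-1L, 0L, 1L), 60, TRUE), 6))
  p <- withr::local_tempfile(fileext = ".png")
  write_label_mask(lab, p)
  expect_identical(unclass(read_label_mask(p)), unclass(lab))
})

test_that("absorbance conversion matches -ln with a floor clip", {
  cu <- hypercube(array(1, c(2, 2, 100)))
  expect_equal(to_absorbance(cu)$absorbance, array(0, c(2, 2, 100)))
  cu2 <- hypercube(array(exp(-2), c(1, 1, 100)))
  expect_equal(to_absorbance(cu2)$absorbance[1, 1, ], rep(2, 100))
  cu3 <- hypercube(array(0, c(1, 1, 100)))
  expect_equal(to_absorbance(cu3)$absorbance[1, 1, 1], -log(1e-6),
               tolerance = 1e-12)
  expect_equal(round(to_absorbance(cu3)$absorbance[1, 1, 1], 4), 13.8155)
  expect_error(to_absorbance(cu3, floor = 0), class = "lhsi_parameter_error")
})

test_that("absorbance is monotone decreasing in reflectance and invertible", {
  set.seed(7)
  r <- sort(runif(50, 0.01, 1.4))
  cu <- hypercube(array(rep(r, each = 1), c(1, 50, 1)),
                  wavelength_grid(500, 5, 1))
  a <- to_absorbance(cu)$absorbance[1, , 1]
  expect_true(all(diff(a) < 0))
  expect_equal(exp(-a), pmax(r, 1e-6), tolerance = 1e-12)
})
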