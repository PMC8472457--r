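test_that("scenes are bit-reproducible given a seed", {
  a <- make_scene(seed = 5, shape = c(48, 48))
  b <- make_scene(seed = 5, shape = c(48, 48))
  expect_identical(a, b)
  c <- make_scene(seed = 6, shape = c(48, 48))
  expect_false(identical(a$cube$reflectance, c$cube$reflectance))
})

test_that("the labelled organ fraction tracks the requested fraction", {
  for (s in 1:5) {
    sc <- make_scene(seed = s, shape = c(96, 96), liver_fraction = 0.30)
    expect_lt(abs(mean(unclass(sc$liver_mask) == 1L) - 0.30), 0.05)
  }
  sc2 <- make_scene(seed = 1, shape = c(96, 96), liver_fraction = 0.15)
  expect_lt(abs(mean(unclass(sc2$liver_mask) == 1L) - 0.15), 0.05)
  expect_error(make_scene(liver_fraction = 0.95),
               class = "lhsi_parameter_error")
  expect_error(make_scene(shape = c(16, 16)), class = "lhsi_parameter_error")
})

test_that("masks carry the border ring, and specular discs sit both sides", {
  sc <- make_scene(seed = 9, shape = c(64, 64))
  lab <- unclass(sc$liver_mask)
  expect_setequal(unique(as.vector(lab)), c(-1L, 0L, 1L))
  expect_gt(sum(lab == 0L), 50)          # a real ring, not stray pixels
  # specular pixels: reflectance saturated above 1 at every band
  spec <- apply(sc$cube$reflectance, c(1, 2), min) > 1.2
  expect_gt(sum(spec & lab == 1L), 0)
  expect_gt(sum(spec & lab == -1L), 0)
  # tissue truth only defined inside the organ
  expect_true(all(unclass(sc$tissue_mask)[lab != 1L] %in% c(0L)))
})

test_that("control livers are perfused and late-ischemia livers ischemic", {
  ctrl <- make_scene(seed = 2, state = "control", shape = c(48, 48))
  isch <- make_scene(seed = 2, state = "isch90", shape = c(48, 48))
  tc <- unclass(ctrl$tissue_mask); ti <- unclass(isch$tissue_mask)
  expect_true(all(tc[tc != 0L] == -1L))
  expect_true(all(ti[ti != 0L] == 1L))
})

test_that("mean StO2 orders control above isch90 for every seed", {
  for (s in 1:20) {
    ctrl <- make_scene(seed = s, state = "control", shape = c(32, 32))
    isch <- make_scene(seed = s, state = "isch90", shape = c(32, 32))
    mc <- mean(sto2_map(to_absorbance(ctrl$cube))$values[
      unclass(ctrl$liver_mask) == 1L], na.rm = TRUE)
    mi <- mean(sto2_map(to_absorbance(isch$cube))$values[
      unclass(isch$liver_mask) == 1L], na.rm = TRUE)
    expect_gt(mc, mi)
  }
})

test_that("single spectra are separable but not trivially so", {
  # nearest-centroid accuracy on raw single-pixel spectra must be high but
  # imperfect: the phantom forces the classifier to use spatial context
  accs <- vapply(1:5, function(s) {
    sc <- make_scene(seed = s, shape = c(96, 96))
    ref <- matrix(sc$cube$reflectance, 96 * 96, 100)
    lab <- as.vector(unclass(sc$liver_mask))
    keep <- lab != 0
    X <- ref[keep, ]; y <- lab[keep]
    c1 <- colMeans(X[y == 1, ]); c2 <- colMeans(X[y == -1, ])
    d1 <- rowSums(sweep(X, 2, c1)^2); d2 <- rowSums(sweep(X, 2, c2)^2)
    mean(ifelse(d1 < d2, 1, -1) == y)
  }, numeric(1))
  expect_true(all(accs > 0.80))
  expect_true(all(accs < 0.999))
})

test_that("biomarkers follow the stated linear models", {
  st <- perfusion_state("control")
  st$oxygen_fraction <- 1
  expect_equal(biomarkers(st, noise_sd = 0, seed = 1)$lactate, 1.0)
  st$oxygen_fraction <- 0
  expect_equal(biomarkers(st, noise_sd = 0, seed = 1)$lactate, 8.0)
  for (f in seq(0, 1, by = 0.1)) {
    st$oxygen_fraction <- f
    z <- biomarkers(st, noise_sd = 2, seed = round(10 * f))
    expect_gte(z$suzuki, 0L); expect_lte(z$suzuki, 4L)
    expect_gte(z$lactate, 0.5)
  }
  expect_error(biomarkers(st, noise_sd = -1), class = "lhsi_parameter_error")
})

test_that("oxygen fraction decreases monotonically through ischemia", {
  fr <- vapply(c("isch30", "isch60", "isch90"),
               function(n) perfusion_state(n)$oxygen_fraction, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_gt(perfusion_state("control")$oxygen_fraction, fr[1])
  # recovery trajectory stays perfused at late reperfusion
  expect_gt(perfusion_state("rep5h", "recovery")$oxygen_fraction,
            perfusion_state("rep5h", "injury")$oxygen_fraction)
  expect_error(perfusion_state("isch120"), class = "lhsi_parameter_error")
})

test_that("cohorts have the requested structure and distinct subjects", {
  co <- make_cohort(5, seed = 3, shape = c(32, 32))
  expect_length(co$subjects, 5)
  expect_equal(sum(lengths(lapply(co$subjects, `[[`, "scenes"))), 20)
  expect_equal(co$subjects[[5]]$trajectory, "recovery")
  gains <- vapply(co$subjects, `[[`, numeric(1), "gain")
  expect_equal(length(unique(gains)), 5)
  expect_error(make_cohort(1), class = "lhsi_parameter_error")
})

test_that("true oxygenation and surrogate lactate are negatively coupled", {
  for (s in 1:6) {
    co <- make_cohort(3, timepoints = c("control", "isch30", "isch90",
                                        "rep1h", "rep5h"),
                      seed = s, shape = c(32, 32))
    f <- c(); lac <- c()
    for (subj in co$subjects)
      for (sc in subj$scenes) {
        f <- c(f, sc$state$oxygen_fraction); lac <- c(lac, sc$lactate)
      }
    expect_lt(cor(f, lac, method = "spearman"), 0)
  }
})

test_that("label subsampling keeps at most n per class and zeroes the rest", {
  sc <- make_scene(seed = 1, shape = c(48, 48))
  sub <- label_subsample(sc$liver_mask, 40, seed = 2)
  expect_lte(sum(sub == 1L), 40)
  expect_lte(sum(sub == -1L), 40)
  expect_true(all(unclass(sc$liver_mask)[sub != 0L] == sub[sub != 0L]))
})
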