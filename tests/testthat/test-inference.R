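test_that("batched dense prediction equals the naive per-pixel loop", {
  set.seed(12)
  cu <- hypercube(array(runif(16 * 16 * 100), c(16, 16, 100)))
  m <- build_model(architecture_spec(), seed = 2)
  dense <- predict_dense(m, cu, batch_px = 37)     # awkward batch size
  naive <- matrix(NA_integer_, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    x <- liverhsi:::cc_extract_subvols(cu$reflectance, r, c, 5)
    naive[r, c] <- predict_classes(forward(m, x))
  }
  expect_identical(bare(dense), naive)
  # and the scores agree too
  d2 <- predict_dense(m, cu, batch_px = 256, return_scores = TRUE)
  for (r in c(1, 7, 16)) for (c in c(1, 9, 16)) {
    x <- liverhsi:::cc_extract_subvols(cu$reflectance, r, c, 5)
    expect_equal(d2$score_pos[r, c], unname(forward(m, x)[1, 1]),
                 tolerance = 1e-12)
  }
})

test_that("restriction masks and constant models behave as documented", {
  set.seed(13)
  cu <- hypercube(array(runif(12 * 12 * 100), c(12, 12, 100)))
  m <- build_model(architecture_spec(), seed = 2)
  none <- predict_dense(m, cu, restrict_to = matrix(0L, 12, 12))
  expect_true(all(is.na(none)))
  some <- matrix(0L, 12, 12); some[3:5, 3:5] <- 1L
  part <- predict_dense(m, cu, restrict_to = some)
  expect_true(all(!is.na(part[3:5, 3:5])))
  expect_true(all(is.na(part[some == 0L])))
  # zeroed model predicts the tie-break class everywhere
  mz <- m
  for (i in seq_along(mz$params))
    mz$params[[i]] <- lapply(mz$params[[i]], function(p) p * 0)
  expect_true(all(predict_dense(mz, cu) == -1L))
  wrong <- hypercube(array(1, c(8, 8, 50)), wavelength_grid(500, 5, 50))
  expect_error(predict_dense(m, wrong), class = "lhsi_input_error")
})

test_that("postfilter keeps the largest component and fills its holes", {
  m <- matrix(0L, 20, 20)
  m[2:12, 2:12] <- 1L          # big blob, area 121
  m[6:8, 6:8] <- 0L            # interior hole
  m[16:17, 16:18] <- 1L        # small island (area 6)
  out <- postfilter(m)
  expect_equal(sum(out[16:17, 16:18]), 0)       # island removed
  expect_true(all(out[6:8, 6:8] == 1L))         # hole filled
  expect_equal(sum(out), 121)
  # a solid ring is closed up
  ring <- matrix(0L, 15, 15); ring[4:11, 4:11] <- 1L; ring[6:9, 6:9] <- 0L
  expect_true(all(postfilter(ring)[6:9, 6:9] == 1L))
  expect_warning(ez <- postfilter(matrix(0L, 5, 5)))
  expect_true(isTRUE(attr(ez, "empty")))
})

test_that("postfilter matches the BFS oracle and is idempotent (200 masks)", {
  set.seed(77)
  for (i in 1:200) {
    m <- matrix(rbinom(18 * 18, 1, runif(1, 0.25, 0.7)), 18, 18)
    got <- postfilter(m)
    expect_identical(bare(got), bare(oracle_postfilter(m)))
    again <- suppressWarnings(postfilter(got))
    expect_identical(bare(again), bare(got))
    # filtering never grows the mask except by interior fill
    lab <- oracle_components(m, 8)
    expect_lte(sum(got), 18 * 18)
  }
})

test_that("connectivity choice changes which diagonal bridges survive", {
  m <- matrix(0L, 9, 9)
  m[2:4, 2:4] <- 1L
  m[5, 5] <- 1L; m[6:8, 6:8] <- 1L   # diagonal chain
  expect_equal(sum(postfilter(m, connectivity = 8)), 19)  # one 8-component
  expect_equal(sum(postfilter(m, connectivity = 4)), 9)   # splits under 4
})

test_that("the viability score is the perfused fraction of the organ", {
  seg <- segmentation_mask(matrix(c(rep(1L, 40), rep(0L, 60)), 10))
  all_perf <- matrix(-1L, 10, 10)
  all_isch <- matrix(1L, 10, 10)
  expect_equal(as.numeric(ai_score(all_perf, seg)), 1.0)
  expect_equal(as.numeric(ai_score(all_isch, seg)), 0.0)
  mixed <- all_isch; mixed[1:30] <- -1L       # 30 of 40 organ px perfused
  s <- ai_score(mixed, seg)
  expect_equal(as.numeric(s), 0.75)
  expect_equal(attr(s, "ischemic_proportion"), 0.25)
  expect_equal(attr(s, "n_liver"), 40)
  expect_error(ai_score(all_perf, segmentation_mask(matrix(0L, 10, 10))),
               class = "lhsi_empty_segmentation_error")
})

test_that("the score is invariant to joint transposition", {
  set.seed(5)
  seg <- matrix(rbinom(100, 1, 0.5), 10)
  tis <- matrix(sample(c(1L, -1L), 100, TRUE), 10)
  if (sum(seg) == 0) seg[1] <- 1L
  a <- as.numeric(ai_score(tis, segmentation_mask(seg)))
  b <- as.numeric(ai_score(t(tis), segmentation_mask(t(seg))))
  expect_equal(a, b)
})

test_that("score tables are tidy and complete", {
  scored <- list(
    list(subject = "S1", timepoint = "control", ai_score = 0.97),
    list(subject = "S1", timepoint = "rep5h", ai_score = 0.10),
    list(subject = "S2", timepoint = "control", ai_score = 0.95),
    list(subject = "S2", timepoint = "rep5h", ai_score = 0.88))
  tab <- score_timeseries(scored)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("subject", "timepoint", "ai_score"))
  p <- withr::local_tempfile(fileext = ".png")
  grDevices::png(p, width = 300, height = 300)
  expect_silent(plot_score_timeseries(tab, flip_y = TRUE))
  grDevices::dev.off()
})
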