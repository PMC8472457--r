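# Dense per-pixel prediction, post-segmentation morphology, and the
# per-image viability score.

#' Binary segmentation mask
#'
#' @param mask Matrix of 0/1 (or logical) values; 1 = organ.
#' @return A `segmentation_mask` (integer matrix subclass).
#' @export
segmentation_mask <- function(mask) {
  if (!is.matrix(mask))
    lhsi_stop("mask must be a matrix", "lhsi_validation_error")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  structure(m, class = c("segmentation_mask", "matrix", "array"))
}

#' Dense per-pixel classification of a cube
#'
#' Classifies every pixel of the (optionally strided) spatial lattice by
#' running the model on its mirror-padded `win x win x B` subvolume.
#' Batching over row strips is purely an engineering knob: results are
#' identical to a naive per-pixel loop. With `stride > 1` the returned map
#' covers the subsampled lattice `seq(1, H, stride)` x `seq(1, W, stride)`
#' (an unbiased coarse map used for desk-scale scoring).
#'
#' @param model A trained `classifier_model`.
#' @param cube A [hypercube()] with matching band count.
#' @param restrict_to Optional binary matrix on the output lattice; pixels
#'   with 0 are skipped (returned as `NA`).
#' @param stride Lattice stride (default 1 = every pixel).
#' @param batch_px Pixels classified per internal batch.
#' @param return_scores Also return the positive-class sigmoid score.
#' @return An integer matrix of +1/-1 labels (`NA` where skipped) with
#'   attributes `rows`, `cols`, `stride`; or a list with `classes` and
#'   `score_pos` when `return_scores = TRUE`.
#' @export
predict_dense <- function(model, cube, restrict_to = NULL, stride = 1,
                          batch_px = 4096, return_scores = FALSE) {
  stopifnot(inherits(model, "classifier_model"), inherits(cube, "hypercube"))
  if (cube$grid$n_bands != model$spec$input_bands)
    lhsi_stop(sprintf("cube has %d bands, model expects %d",
                      cube$grid$n_bands, model$spec$input_bands),
              "lhsi_input_error")
  if (identical(model$preproc, "band_standardize"))
    cube <- standardize_cube(cube)
  d <- dim(cube$reflectance)
  rows <- seq(1, d[1], by = stride)
  cols <- seq(1, d[2], by = stride)
  out <- matrix(NA_integer_, length(rows), length(cols))
  sc_out <- matrix(NA_real_, length(rows), length(cols))
  sel <- matrix(TRUE, length(rows), length(cols))
  if (!is.null(restrict_to)) {
    if (!all(dim(restrict_to) == dim(out)))
      lhsi_stop("restrict_to must match the output lattice",
                "lhsi_input_error")
    sel <- unclass(restrict_to) != 0
  }
  todo <- which(sel)
  win <- model$spec$input_window
  i <- 1L
  while (i <= length(todo)) {
    take <- todo[i:min(length(todo), i + batch_px - 1L)]
    pos <- arrayInd(take, dim(out))
    X <- cc_extract_subvols(cube$reflectance,
                            rows[pos[, 1]], cols[pos[, 2]], win)
    sco <- forward(model, X)
    out[take] <- predict_classes(sco)
    sc_out[take] <- sco[, 1]
    i <- i + batch_px
  }
  attr(out, "rows") <- rows; attr(out, "cols") <- cols
  attr(out, "stride") <- stride
  if (return_scores) list(classes = out, score_pos = sc_out) else out
}

#' Post-segmentation filtering
#'
#' Removes spurious positive islands (typically specular reflections) by
#' keeping only the largest connected positive component, then fills
#' interior holes: background components that do not touch the image border
#' become foreground. Foreground uses 8-connectivity by default, background
#' the complementary 4-connectivity. The operation is idempotent.
#'
#' @param mask A [segmentation_mask()] or binary matrix.
#' @param connectivity Foreground connectivity, 4 or 8 (default 8).
#' @return A filtered `segmentation_mask`; an all-zero input is returned
#'   unchanged with attribute `empty = TRUE` and a warning.
#' @export
postfilter <- function(mask, connectivity = 8) {
  m <- unclass(segmentation_mask(mask))
  if (!any(m != 0L)) {
    warning("postfilter: empty segmentation mask")
    out <- segmentation_mask(m)
    attr(out, "empty") <- TRUE
    return(out)
  }
  lab <- cc_label_components(m, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m2 <- matrix(as.integer(lab == keep), nrow(m), ncol(m))
  # hole fill: background components not touching the border
  bg_conn <- if (connectivity == 8) 4 else 8
  bg <- cc_label_components(1L - m2, bg_conn)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labs <- border_labs[border_labs > 0]
  hole <- bg > 0 & !(bg %in% border_labs)
  m2[hole] <- 1L
  segmentation_mask(m2)
}

#' Per-image viability (AI) score
#'
#' The proportion of organ pixels classified as perfused:
#' `score = #(tissue == -1) / #(seg == 1)`. A score of 0 indicates total
#' ischemia, 1 total perfusion. The complementary ischemic proportion is
#' returned alongside.
#'
#' @param tissue_map Matrix of +1 (ischemic) / -1 (perfused) labels over the
#'   segmentation-positive pixels (`NA` elsewhere is fine).
#' @param seg A [segmentation_mask()] on the same lattice.
#' @return Numeric score in `[0, 1]`, with attributes `n_liver`,
#'   `n_perfused`, `n_ischemic`, `ischemic_proportion`.
#' @export
ai_score <- function(tissue_map, seg) {
  seg <- segmentation_mask(seg)
  if (!all(dim(tissue_map) == dim(seg)))
    lhsi_stop("tissue map and segmentation differ in shape",
              "lhsi_input_error")
  liver <- unclass(seg) == 1L
  n_liver <- sum(liver)
  if (n_liver == 0)
    lhsi_stop("empty segmentation: the viability score is undefined",
              "lhsi_empty_segmentation_error")
  n_perf <- sum(tissue_map[liver] == -1L, na.rm = TRUE)
  n_isch <- sum(tissue_map[liver] == 1L, na.rm = TRUE)
  score <- n_perf / n_liver
  structure(score, n_liver = n_liver, n_perfused = n_perf,
            n_ischemic = n_isch, ischemic_proportion = n_isch / n_liver)
}

#' Full two-stage scoring of one image
#'
#' Runs the organ-segmentation model densely, post-filters the mask, runs
#' the tissue-characterization model on the segmentation-positive pixels
#' only, and computes the viability score.
#'
#' @param cube A [hypercube()].
#' @param seg_model,tissue_model Trained classifiers for the two stages.
#' @param stride Lattice stride for desk-scale scoring (default 1).
#' @param connectivity Passed to [postfilter()].
#' @return A `viability_result`: `seg` (filtered mask), `tissue` (class map
#'   over organ pixels), `ai_score`, `ischemic_proportion`, and pixel counts.
#' @export
score_image <- function(cube, seg_model, tissue_model, stride = 1,
                        connectivity = 8) {
  seg_raw <- predict_dense(seg_model, cube, stride = stride)
  seg <- postfilter(matrix(as.integer(seg_raw == 1L),
                           nrow(seg_raw), ncol(seg_raw)),
                    connectivity = connectivity)
  if (isTRUE(attr(seg, "empty")))
    lhsi_stop("segmentation found no organ pixels",
              "lhsi_empty_segmentation_error")
  tissue <- predict_dense(tissue_model, cube, restrict_to = seg,
                          stride = stride)
  sc <- ai_score(tissue, seg)
  structure(list(seg = seg, tissue = tissue,
                 ai_score = as.numeric(sc),
                 ischemic_proportion = attr(sc, "ischemic_proportion"),
                 n_liver = attr(sc, "n_liver"),
                 n_perfused = attr(sc, "n_perfused"),
                 n_ischemic = attr(sc, "n_ischemic"),
                 stride = stride),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf(
    "<viability_result> AI score %.3f (%d/%d organ px perfused, stride %d)\n",
    x$ai_score, x$n_perfused, x$n_liver, x$stride))
  invisible(x)
}

#' Score-versus-time table and plot
#'
#' Collects per-image viability scores into a tidy (subject, timepoint,
#' ai_score) table.
#'
#' @param scored List of entries, each with `subject`, `timepoint`, and
#'   either a `viability_result` under `result` or a numeric `ai_score`.
#' @return A data.frame with columns `subject`, `timepoint`, `ai_score`.
#' @export
score_timeseries <- function(scored) {
  stopifnot(length(scored) >= 1)
  do.call(rbind, lapply(scored, function(e) {
    sc <- if (!is.null(e$result)) e$result$ai_score else e$ai_score
    data.frame(subject = e$subject, timepoint = e$timepoint,
               ai_score = as.numeric(sc))
  }))
}

#' @rdname score_timeseries
#' @param tab A table from `score_timeseries()`.
#' @param flip_y Flip the y axis (viability plotted downwards, matching the
#'   convention of plotting injury severity upwards).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_score_timeseries <- function(tab, flip_y = FALSE, ...) {
  tps <- unique(tab$timepoint)
  subs <- unique(tab$subject)
  m <- sapply(subs, function(s) {
    sub <- tab[tab$subject == s, ]
    sub$ai_score[match(tps, sub$timepoint)]
  })
  ylim <- if (flip_y) c(1, 0) else c(0, 1)
  graphics::matplot(seq_along(tps), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "timepoint", ylab = "AI score",
                    ylim = ylim, ...)
  graphics::axis(1, at = seq_along(tps), labels = tps)
  graphics::legend("bottomleft", legend = subs, col = seq_along(subs),
                   lty = 1, cex = 0.8)
  invisible(m)
}
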