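# Supervised training protocol: vertical concatenation of training images,
# class-balanced binary cross-entropy with inverse-median-frequency weights,
# plain SGD with L2 weight decay, without-replacement subvolume epochs, and
# the leave-one-subject-out cross-validation harness.

#' Concatenate training scenes vertically
#'
#' Stacks the training images along the row axis into a single cube with an
#' aligned label image, recording per-row provenance. All scenes must share
#' width and band count.
#'
#' @param scenes List; each element needs `cube` (a [hypercube()]) and
#'   `labels` (a [label_mask()] aligned with it).
#' @return A `training_set`: `cube`, `labels`, and `provenance`
#'   (data.frame with `subject`, `timepoint`, `row_start`, `row_end`).
#' @export
concat_training_set <- function(scenes) {
  stopifnot(length(scenes) >= 1)
  dims <- lapply(scenes, function(s) dim(s$cube$reflectance))
  W <- dims[[1]][2]; B <- dims[[1]][3]
  for (d in dims)
    if (d[2] != W || d[3] != B)
      lhsi_stop("scenes differ in width or band count", "lhsi_validation_error")
  for (s in scenes)
    if (!all(dim(s$labels) == dim(s$cube$reflectance)[1:2]))
      lhsi_stop("label mask misaligned with cube", "lhsi_validation_error")
  Htot <- sum(vapply(dims, `[`, numeric(1), 1))
  ref <- array(0, c(Htot, W, B))
  lab <- matrix(0L, Htot, W)
  prov <- data.frame(subject = character(), timepoint = character(),
                     row_start = integer(), row_end = integer())
  at <- 1L
  for (s in scenes) {
    h <- dim(s$cube$reflectance)[1]
    ref[at:(at + h - 1), , ] <- s$cube$reflectance
    lab[at:(at + h - 1), ] <- unclass(s$labels)
    prov <- rbind(prov, data.frame(
      subject = s$cube$subject_id, timepoint = s$cube$timepoint,
      row_start = at, row_end = at + h - 1L))
    at <- at + h
  }
  cube <- structure(list(reflectance = ref, grid = scenes[[1]]$cube$grid,
                         subject_id = NA_character_,
                         timepoint = NA_character_),
                    class = "hypercube")
  # standardized inputs carry negatives, so the strict reflectance
  # constructor is bypassed; propagate the flag instead
  if (any(vapply(scenes, function(s)
    isTRUE(attr(s$cube, "standardized")), logical(1))))
    attr(cube, "standardized") <- TRUE
  structure(list(
    cube = cube,
    labels = label_mask(lab),
    provenance = prov
  ), class = "training_set")
}

#' @rdname concat_training_set
#' @param set A `training_set`.
#' @param row Row index into the concatenated cube.
#' @return `provenance_of()` returns the provenance record owning `row`.
#' @export
provenance_of <- function(set, row) {
  p <- set$provenance
  hit <- which(p$row_start <= row & row <= p$row_end)
  if (length(hit) != 1)
    lhsi_stop("row outside the concatenated set", "lhsi_input_error")
  p[hit, ]
}

#' Inverse-median-frequency class weights
#'
#' Over the labelled (non-zero) pixels, let `f_i` be the proportion of class
#' `i` and `m = (f_pos + f_neg) / 2 = 1/2`. The loss weight of class `i` is
#' `w_i = m / f_i`, so `w_pos * f_pos + w_neg * f_neg = 2m = 1` identically:
#' the weighted loss of a perfectly class-balanced batch equals the
#' unweighted one.
#'
#' @param labels A [label_mask()].
#' @return A `class_weights` list: `w_pos`, `w_neg`, `f_pos`, `f_neg`, `m`.
#' @export
compute_class_weights <- function(labels) {
  stopifnot(inherits(labels, "label_mask"))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == -1L)
  if (n_pos == 0 || n_neg == 0)
    lhsi_stop("both classes must occur among labelled pixels",
              "lhsi_degenerate_labels_error")
  f_pos <- n_pos / (n_pos + n_neg)
  f_neg <- 1 - f_pos
  m <- (f_pos + f_neg) / 2
  structure(list(w_pos = m / f_pos, w_neg = m / f_neg,
                 f_pos = f_pos, f_neg = f_neg, m = m),
            class = "class_weights")
}

#' Without-replacement epoch sampling of labelled subvolumes
#'
#' `init_epoch()` permutes all pixels labelled +1 or -1; successive
#' `sample_batch()` calls walk the permutation, so over one epoch every
#' labelled pixel is drawn exactly once. Subvolumes are centred on the drawn
#' pixel; centres near the border use mirror (reflect) padding of the cube.
#' The final batch of an epoch may be smaller than `batch_size`.
#'
#' @param set A [concat_training_set()] result.
#' @param seed Seed of the epoch permutation.
#' @return `init_epoch()` returns an `epoch_state`.
#' @export
init_epoch <- function(set, seed = 1) {
  centers <- which(unclass(set$labels) != 0L, arr.ind = TRUE)
  if (nrow(centers) == 0)
    lhsi_stop("no labelled pixels", "lhsi_degenerate_labels_error")
  ord <- with_local_seed(seed, sample.int(nrow(centers)))
  structure(list(centers = centers[ord, , drop = FALSE], cursor = 1L),
            class = "epoch_state")
}

#' @rdname init_epoch
#' @param state An `epoch_state`.
#' @param batch_size Number of subvolumes to draw.
#' @param window Spatial window (must match the model spec; default 5).
#' @return `sample_batch()` returns `NULL` when the epoch is exhausted, else
#'   a list with `X` (features x n matrix), `y` (+1/-1), `centers`, and the
#'   advanced `state`.
#' @export
sample_batch <- function(set, state, batch_size, window = 5) {
  n <- nrow(state$centers)
  if (state$cursor > n) return(NULL)
  take <- state$cursor:min(n, state$cursor + batch_size - 1L)
  ctr <- state$centers[take, , drop = FALSE]
  X <- cc_extract_subvols(set$cube$reflectance, ctr[, 1], ctr[, 2], window)
  y <- unclass(set$labels)[ctr]
  state$cursor <- max(take) + 1L
  list(X = X, y = as.integer(y), centers = ctr, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference protocol (learning rate 0.01, weight decay
#' 5e-4) with desk-scale batch and epoch counts; the protocol-scale values
#' (batch 8192, 2000 epochs) are reachable by argument.
#'
#' @param learning_rate SGD step size.
#' @param weight_decay L2 penalty applied to weights (not biases).
#' @param batch_size Subvolumes per SGD step.
#' @param epochs Passes over the labelled pixels.
#' @param seed Seed governing epoch permutations.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, weight_decay = 5e-4,
                         batch_size = 512, epochs = 3, seed = 1) {
  if (learning_rate < 0 || weight_decay < 0 || batch_size < 1 || epochs < 1)
    lhsi_stop("invalid training configuration", "lhsi_parameter_error")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# Weighted binary cross-entropy on the two sigmoid outputs. The positive
# output is trained towards {+1 -> 1, -1 -> 0} and the negative output to the
# complementary target; per-sample class weights follow compute_class_weights.
weighted_bce <- function(scores, y, cw) {
  eps <- 1e-12
  p <- t(pmin(pmax(scores, eps), 1 - eps))    # 2 x N
  tpos <- as.numeric(y == 1L)
  tt <- rbind(tpos, 1 - tpos)
  wgt <- ifelse(y == 1L, cw$w_pos, cw$w_neg)
  ll <- -(tt * log(p) + (1 - tt) * log(1 - p))
  loss <- mean(colSums(ll) / 2 * wgt)
  dZ <- sweep(p - tt, 2, wgt, `*`) / (2 * length(y))
  dimnames(dZ) <- NULL
  list(loss = loss, dZ = dZ)
}

#' Train a classifier on a concatenated set
#'
#' Class-balanced binary cross-entropy on the sigmoid outputs, minimized by
#' plain stochastic gradient descent (no momentum) with L2 weight decay on
#' the weight tensors. Within each epoch, batches of subvolumes centred on
#' labelled pixels are drawn without replacement. Deterministic given
#' `cfg$seed`.
#'
#' @param model A [build_model()] result.
#' @param set A [concat_training_set()] result.
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `trace` (mean loss per epoch).
#' @export
train <- function(model, set, cfg = train_config()) {
  stopifnot(inherits(model, "classifier_model"),
            inherits(set, "training_set"))
  cw <- compute_class_weights(set$labels)
  n_lab <- sum(unclass(set$labels) != 0L)
  if (cfg$batch_size > n_lab)
    lhsi_stop("batch_size exceeds the number of labelled pixels",
              "lhsi_parameter_error")
  if (is.null(model$norm) && is.null(model$preproc)) {
    d <- dim(set$cube$reflectance)
    flat <- matrix(set$cube$reflectance, d[1] * d[2], d[3])
    model <- set_input_norm(model, colMeans(flat),
                            apply(flat, 2, sd))
  }
  win <- model$spec$input_window
  nl <- length(model$spec$layers)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    st <- init_epoch(set, seed = cfg$seed + 7919L * ep)
    losses <- c()
    repeat {
      b <- sample_batch(set, st, cfg$batch_size, window = win)
      if (is.null(b)) break
      st <- b$state
      fw <- forward(model, b$X, return_acts = TRUE)
      lb <- weighted_bce(fw$scores, b$y, cw)
      if (!is.finite(lb$loss))
        lhsi_stop(sprintf(
          "non-finite loss at epoch %d (lr %.3g); training diverged",
          ep, cfg$learning_rate), "lhsi_divergence_error")
      losses <- c(losses, lb$loss)
      model <- sgd_step(model, fw, lb$dZ, cfg)
    }
    trace[ep] <- mean(losses)
  }
  list(model = model, trace = trace)
}

# One SGD update from the batch gradients (backprop through the stored
# activations). Weight decay hits W tensors only.
sgd_step <- function(model, fw, dZ, cfg) {
  nl <- length(model$spec$layers)
  lr <- cfg$learning_rate; wd <- cfg$weight_decay
  p <- model$params[[nl]]
  H1 <- fw$acts[[nl + 1]]
  A6 <- fw$acts[[nl]]
  dW2 <- dZ %*% t(H1)
  db2 <- rowSums(dZ)
  dH1 <- t(p$W2) %*% dZ
  dH1[H1 <= 0] <- 0
  dW1 <- dH1 %*% t(A6)
  db1 <- rowSums(dH1)
  dA <- t(p$W1) %*% dH1
  if (model$trainable[nl]) {
    p$W2 <- p$W2 - lr * (dW2 + wd * p$W2); p$b2 <- p$b2 - lr * db2
    p$W1 <- p$W1 - lr * (dW1 + wd * p$W1); p$b1 <- p$b1 - lr * db1
    model$params[[nl]] <- p
  }
  for (i in rev(seq_len(nl - 1))) {
    l <- model$spec$layers[[i]]
    if (l$relu) dA[fw$acts[[i + 1]] <= 0] <- 0
    g <- cc_conv_backward(fw$gathers[[i]], model$params[[i]]$W,
                          model$idx[[i]]$off, model$idx[[i]]$base, dA,
                          nrow(fw$acts[[i]]))
    dA <- g$dX
    if (model$trainable[i]) {
      model$params[[i]]$W <- model$params[[i]]$W -
        lr * (g$dW + wd * model$params[[i]]$W)
      model$params[[i]]$b <- model$params[[i]]$b - lr * as.vector(g$db)
    }
  }
  model
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains a classifier on the vertically concatenated
#' scenes of all *other* subjects and evaluates it on the held-out subject
#' only; held-out predictions are pooled across folds for global metrics.
#' Training labels come from the scene's segmentation or tissue ground-truth
#' mask, optionally thinned to `n_train_px` pixels per class per image
#' (desk-scale control); evaluation draws up to `n_eval_px` labelled pixels
#' per class per held-out image.
#'
#' @param cohort A [make_cohort()] result.
#' @param stage `"segmentation"` or `"characterization"`.
#' @param cfg A [train_config()].
#' @param n_train_px,n_eval_px Per-class per-image pixel budgets (`Inf` uses
#'   every labelled pixel).
#' @param timepoints Timepoints used; default: all in the cohort.
#' @return An `lopocv_result`: `models` (one per fold), `pooled`
#'   (data.frame of held-out `truth`, `pred`, `score_pos`, `subject`,
#'   `timepoint`), and `folds` (audit log of train/test subject sets).
#' @export
lopocv <- function(cohort, stage = c("segmentation", "characterization"),
                   cfg = train_config(), n_train_px = 150, n_eval_px = 300,
                   timepoints = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(cohort, "phantom_cohort"))
  n_sub <- length(cohort$subjects)
  if (n_sub < 2)
    lhsi_stop("LOPOCV needs at least 2 subjects", "lhsi_parameter_error")
  if (is.null(timepoints)) timepoints <- cohort$timepoints
  mask_of <- function(scene)
    if (stage == "segmentation") scene$liver_mask else scene$tissue_mask
  models <- list(); folds <- list(); pooled <- list()
  for (s in seq_len(n_sub)) {
    train_subj <- setdiff(seq_len(n_sub), s)
    scenes <- list()
    for (j in train_subj)
      for (tp in timepoints) {
        sc <- cohort$subjects[[j]]$scenes[[tp]]
        lab <- mask_of(sc)
        if (is.finite(n_train_px))
          lab <- label_subsample(lab, n_train_px,
                                 seed = cfg$seed + 97L * j + nchar(tp))
        scenes[[length(scenes) + 1]] <- list(cube = standardize_cube(sc$cube),
                                             labels = lab)
      }
    set <- concat_training_set(scenes)
    model <- build_model(architecture_spec(
      input_bands = cohort$subjects[[1]]$scenes[[1]]$cube$grid$n_bands),
      seed = cfg$seed + s)
    model$preproc <- "band_standardize"
    # a fold whose optimization fails for this draw - divergence, or a
    # collapse where the loss never leaves its chance level (~log 2) - is
    # reinitialized and retrained at half the learning rate, at most twice
    lr <- cfg$learning_rate
    fit <- NULL
    for (attempt in 0:2) {
      model_a <- build_model(model$spec, seed = cfg$seed + s + 101L * attempt)
      model_a$preproc <- model$preproc
      fit <- tryCatch(
        train(model_a, set, train_config(
          learning_rate = lr, weight_decay = cfg$weight_decay,
          batch_size = min(cfg$batch_size,
                           sum(unclass(set$labels) != 0L)),
          epochs = cfg$epochs, seed = cfg$seed + 1000L * s)),
        lhsi_divergence_error = function(e) NULL)
      if (!is.null(fit) && tail(fit$trace, 1) < 0.55) break
      fit <- NULL
      lr <- lr / 2
    }
    if (is.null(fit))
      lhsi_stop("fold training failed (divergence or collapse) even after
learning-rate reduction", "lhsi_divergence_error")
    models[[s]] <- fit$model
    # held-out evaluation
    for (tp in timepoints) {
      sc <- cohort$subjects[[s]]$scenes[[tp]]
      lab <- unclass(mask_of(sc))
      ev <- with_local_seed(cfg$seed + 13L * s + nchar(tp), {
        idx <- c()
        for (cl in c(1L, -1L)) {
          cand <- which(lab == cl)
          if (length(cand) > n_eval_px) cand <- sample(cand, n_eval_px)
          idx <- c(idx, cand)
        }
        idx
      })
      if (!length(ev)) next
      ctr <- arrayInd(ev, dim(lab))
      scube <- standardize_cube(sc$cube)
      X <- cc_extract_subvols(scube$reflectance, ctr[, 1], ctr[, 2],
                              model$spec$input_window)
      sco <- forward(fit$model, X)
      pooled[[length(pooled) + 1]] <- data.frame(
        truth = lab[ev], pred = predict_classes(sco),
        score_pos = sco[, 1],
        subject = sc$cube$subject_id, timepoint = tp)
    }
    folds[[s]] <- list(held_out = cohort$subjects[[s]]$subject_id,
                       trained_on = vapply(train_subj, function(j)
                         cohort$subjects[[j]]$subject_id, character(1)),
                       final_loss = fit$trace[length(fit$trace)])
  }
  structure(list(stage = stage, models = models, folds = folds,
                 pooled = do.call(rbind, pooled)),
            class = "lopocv_result")
}
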