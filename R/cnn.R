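# The spatio-spectral pixel classifier.
#
# Both pipeline stages (organ segmentation, tissue characterisation) use the
# identical small 3D CNN operating on a 5 x 5 x B subvolume centred at the
# pixel under consideration. Early layers build 3D spatio-spectral feature
# maps; 1D spectral convolutions with stride 2 play the role of pooling and
# progressively collapse the spectral axis; the head is a small fully
# connected block ending in two sigmoid class scores.

#' Architecture of the spatio-spectral classifier
#'
#' The default configuration is the 7-layer network used throughout the
#' package, with exactly 32,444 trainable parameters for a 5 x 5 x 100 input:
#'
#' | layer | operation                              | output (H,W,B,C) |
#' |-------|----------------------------------------|------------------|
#' | 1     | 3D conv 3x3x3, 1 -> 20, ReLU           | 3,3,98,20        |
#' | 2     | spectral conv k=3, stride 2            | 3,3,48,20        |
#' | 3     | 3D conv 3x3x3, 20 -> 35, ReLU          | 1,1,46,35        |
#' | 4     | spectral conv k=2, stride 2            | 1,1,23,35        |
#' | 5     | spectral conv k=2, stride 2, ReLU      | 1,1,11,35        |
#' | 6     | spectral conv k=2, stride 2, ReLU      | 1,1,5,35         |
#' | 7     | FC 175 -> 24 (ReLU) -> 2, sigmoid      | 2                |
#'
#' All convolutions use valid padding. The strided spectral convolutions are
#' the learned pooling stage; layer 7 is a fully connected block whose final
#' two neurons are the class scores. The kernel extents and the hidden width
#' were fixed by a discrete search over small extents constrained to
#' reproduce the 32,444-parameter budget exactly (see the methods vignette
#' for the search space and an impossibility argument that forces the hidden
#' fully connected layer).
#'
#' @param input_window Spatial window (pixels) of the input subvolume.
#' @param input_bands Number of spectral bands of the input.
#' @param stage1_channels,stage2_channels Channel counts of the two 3D
#'   convolution stages (defaults 20 and 35).
#' @param spatial_kernel Length-3 kernel `(k_h, k_w, k_b)` of the 3D
#'   convolutions.
#' @param pool_kernels Spectral kernel extents of the four strided 1D
#'   convolutions (layers 2, 4, 5, 6).
#' @param spectral_stride Stride of the spectral pooling convolutions.
#' @param hidden_units Width of the penultimate fully connected layer.
#' @param n_classes Number of output classes; the two-class case is the only
#'   supported one.
#' @return An `architecture_spec`: layer descriptors with input/output
#'   shapes, kernels, and activation flags.
#' @export
architecture_spec <- function(input_window = 5, input_bands = 100,
                              stage1_channels = 20, stage2_channels = 35,
                              spatial_kernel = c(3, 3, 3),
                              pool_kernels = c(3, 2, 2, 2),
                              spectral_stride = 2,
                              hidden_units = 24, n_classes = 2) {
  if (n_classes != 2)
    lhsi_stop("only the two-class head is supported", "lhsi_parameter_error")
  if (any(c(spatial_kernel, pool_kernels) < 1) || spectral_stride < 1)
    lhsi_stop("kernel extents and stride must be >= 1", "lhsi_parameter_error")
  kh <- spatial_kernel[1]; kw <- spatial_kernel[2]; kb <- spatial_kernel[3]
  mk <- function(type, kernel, stride_b, cin, cout, relu, indim) {
    H <- indim[1] - kernel[1] + 1
    W <- indim[2] - kernel[2] + 1
    B <- floor((indim[3] - kernel[3]) / stride_b) + 1
    if (H < 1 || W < 1 || B < 1)
      lhsi_stop(sprintf(
        "kernel %s incompatible with input %s",
        paste(kernel, collapse = "x"), paste(indim, collapse = "x")),
        "lhsi_construction_error")
    list(type = type, kernel = kernel, stride_b = stride_b,
         cin = cin, cout = cout, relu = relu,
         indim = indim, outdim = c(H, W, B))
  }
  layers <- list()
  d <- c(input_window, input_window, input_bands)
  layers[[1]] <- mk("conv", c(kh, kw, kb), 1, 1, stage1_channels, TRUE, d)
  d <- layers[[1]]$outdim
  layers[[2]] <- mk("conv", c(1, 1, pool_kernels[1]), spectral_stride,
                    stage1_channels, stage1_channels, FALSE, d)
  d <- layers[[2]]$outdim
  layers[[3]] <- mk("conv", c(kh, kw, kb), 1, stage1_channels,
                    stage2_channels, TRUE, d)
  d <- layers[[3]]$outdim
  layers[[4]] <- mk("conv", c(1, 1, pool_kernels[2]), spectral_stride,
                    stage2_channels, stage2_channels, FALSE, d)
  d <- layers[[4]]$outdim
  layers[[5]] <- mk("conv", c(1, 1, pool_kernels[3]), spectral_stride,
                    stage2_channels, stage2_channels, TRUE, d)
  d <- layers[[5]]$outdim
  layers[[6]] <- mk("conv", c(1, 1, pool_kernels[4]), spectral_stride,
                    stage2_channels, stage2_channels, TRUE, d)
  d <- layers[[6]]$outdim
  flat <- prod(d) * stage2_channels
  layers[[7]] <- list(type = "fc", n_in = flat, hidden = hidden_units,
                      n_out = n_classes)
  structure(list(input_window = input_window, input_bands = input_bands,
                 layers = layers),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> input %dx%dx%d\n",
              x$input_window, x$input_window, x$input_bands))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    if (l$type == "conv")
      cat(sprintf("  L%d conv %s s=%d  %d->%d ch  out %s%s\n", i,
                  paste(l$kernel, collapse = "x"), l$stride_b, l$cin, l$cout,
                  paste(l$outdim, collapse = "x"),
                  if (l$relu) " relu" else ""))
    else
      cat(sprintf("  L%d fc %d -> %d -> %d (sigmoid)\n", i,
                  l$n_in, l$hidden, l$n_out))
  }
  cat(sprintf("  trainable parameters: %d\n", spec_parameter_count(x)))
  invisible(x)
}

# Analytic per-layer parameter ledger: out*(in*kernel_volume)+out for
# convolutions, in*out+out for dense maps.
#' @rdname architecture_spec
#' @param spec An `architecture_spec`.
#' @return `spec_parameter_count()` returns the analytic total parameter
#'   count implied by the layer shapes.
#' @export
spec_parameter_count <- function(spec) {
  tot <- 0
  for (l in spec$layers) {
    if (l$type == "conv")
      tot <- tot + l$cout * (l$cin * prod(l$kernel)) + l$cout
    else
      tot <- tot + l$n_in * l$hidden + l$hidden + l$hidden * l$n_out + l$n_out
  }
  tot
}

# Factorized im2col gather table for a conv layer (0-based): input feature
# feeding kernel element e of output position p is off[e] + base[p].
conv_index_table <- function(l) {
  H <- l$indim[1]; W <- l$indim[2]; B <- l$indim[3]; C <- l$cin
  kh <- l$kernel[1]; kw <- l$kernel[2]; kb <- l$kernel[3]; s <- l$stride_b
  Ho <- l$outdim[1]; Wo <- l$outdim[2]; Bo <- l$outdim[3]
  off <- as.vector(outer(
    as.vector(outer(0:(kh - 1), H * (0:(kw - 1)), `+`)),
    H * W * (0:(kb - 1)), `+`))
  off <- as.vector(outer(off, H * W * B * (0:(C - 1)), `+`))
  base <- as.vector(outer(
    as.vector(outer(0:(Ho - 1), H * (0:(Wo - 1)), `+`)),
    H * W * s * (0:(Bo - 1)), `+`))
  list(off = as.integer(off), base = as.integer(base))
}

#' Build a classifier with Kaiming-initialized weights
#'
#' Weights are drawn from `N(0, sqrt(2 / fan_in))` with `fan_in` the number
#' of inputs feeding one output unit; all biases start at zero. The draw is
#' deterministic given `seed` and leaves the caller's RNG stream untouched.
#'
#' @param spec An [architecture_spec()].
#' @param seed RNG seed for the initialization.
#' @return A `classifier_model`: the spec, per-layer parameter tensors, the
#'   im2col index tables, and a trainability flag per layer.
#' @export
build_model <- function(spec = architecture_spec(), seed = 1) {
  stopifnot(inherits(spec, "architecture_spec"))
  params <- vector("list", length(spec$layers))
  idx <- vector("list", length(spec$layers))
  with_local_seed(seed, {
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      if (l$type == "conv") {
        E <- l$cin * prod(l$kernel)
        params[[i]] <- list(
          W = matrix(rnorm(l$cout * E, 0, sqrt(2 / E)), l$cout, E),
          b = rep(0, l$cout))
        idx[[i]] <- conv_index_table(l)
      } else {
        params[[i]] <- list(
          W1 = matrix(rnorm(l$hidden * l$n_in, 0, sqrt(2 / l$n_in)),
                      l$hidden, l$n_in),
          b1 = rep(0, l$hidden),
          W2 = matrix(rnorm(l$n_out * l$hidden, 0, sqrt(2 / l$hidden)),
                      l$n_out, l$hidden),
          b2 = rep(0, l$n_out))
      }
    }
  })
  structure(list(spec = spec, params = params, idx = idx,
                 trainable = rep(TRUE, length(spec$layers)),
                 seed = seed),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model> %d layers, %d trainable parameters\n",
              length(x$spec$layers), count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' Sums element counts over all parameter tensors of layers whose
#' `trainable` flag is set.
#'
#' @param model A [build_model()] result.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "classifier_model"))
  tot <- 0
  for (i in seq_along(model$params)) {
    if (!model$trainable[i]) next
    tot <- tot + sum(vapply(model$params[[i]], length, numeric(1)))
  }
  as.integer(tot)
}

#' @rdname count_parameters
#' @param value Logical, recycled over layers.
#' @return `set_trainable()` returns the modified model.
#' @export
set_trainable <- function(model, value) {
  model$trainable <- rep_len(as.logical(value), length(model$params))
  model
}

#' Forward pass
#'
#' Maps a batch of subvolumes to two per-class sigmoid scores. Column order
#' of the result is `positive` (class +1) then `negative` (class -1);
#' predictions take the larger score, with ties broken towards the negative
#' class. The network is purely feed-forward (no batch statistics), so
#' results are independent of batch composition and order.
#'
#' @param model A `classifier_model`.
#' @param X Either a matrix (`win*win*B` x N, one subvolume per column,
#'   column-major (h, w, band) order) or an array `win x win x B x N`.
#' @param return_acts Keep intermediate activations (training use).
#' @return N x 2 matrix of scores in (0, 1); with `return_acts`, a list with
#'   `scores` and `acts`.
#' @export
forward <- function(model, X, return_acts = FALSE) {
  stopifnot(inherits(model, "classifier_model"))
  spec <- model$spec
  if (is.array(X) && length(dim(X)) == 4)
    X <- matrix(X, prod(dim(X)[1:3]), dim(X)[4])
  need <- spec$input_window^2 * spec$input_bands
  if (nrow(X) != need)
    lhsi_stop(sprintf("subvolume length %d does not match spec (%d)",
                      nrow(X), need), "lhsi_input_error")
  if (!is.null(model$norm))
    X <- (X - model$norm$center) * model$norm$inv_scale
  acts <- list(X)
  gathers <- list()
  A <- X
  nl <- length(spec$layers)
  for (i in seq_len(nl - 1)) {
    l <- spec$layers[[i]]
    fwd <- cc_conv_forward(A, model$params[[i]]$W, model$params[[i]]$b,
                           model$idx[[i]]$off, model$idx[[i]]$base, l$relu)
    A <- fwd$Y
    if (return_acts) { acts[[i + 1]] <- A; gathers[[i]] <- fwd$Mt }
  }
  p <- model$params[[nl]]
  H1 <- p$W1 %*% A
  H1 <- sweep(H1, 1, p$b1, `+`)
  H1[H1 < 0] <- 0
  Z <- sweep(p$W2 %*% H1, 1, p$b2, `+`)
  S <- 1 / (1 + exp(-Z))                     # 2 x N
  scores <- t(S)
  colnames(scores) <- c("positive", "negative")
  if (!return_acts) return(scores)
  acts[[nl + 1]] <- H1
  list(scores = scores, acts = acts, gathers = gathers, logits = Z)
}

#' @rdname forward
#' @param scores An N x 2 score matrix from `forward()`.
#' @return `predict_classes()` returns an integer vector of +1 / -1 labels.
#' @export
predict_classes <- function(scores) {
  ifelse(scores[, 1] > scores[, 2], 1L, -1L)
}

#' Save / load a trained classifier
#'
#' Checkpoints are versioned serialized containers holding the architecture
#' and the parameter tensors; index tables are rebuilt on load.
#'
#' @param model A `classifier_model`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the restored `classifier_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  saveRDS(list(format = "liverhsi-model", version = 1L,
               spec = model$spec, params = model$params,
               trainable = model$trainable, norm = model$norm,
               preproc = model$preproc, seed = model$seed), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) NULL)
  if (!is.list(obj) || !identical(obj$format, "liverhsi-model"))
    lhsi_stop(paste("not a liverhsi model checkpoint:", path),
              "lhsi_format_error")
  m <- build_model(obj$spec, seed = obj$seed %||% 1)
  m$params <- obj$params
  m$trainable <- obj$trainable
  m$norm <- obj$norm
  m$preproc <- obj$preproc
  m
}

#' Per-acquisition band standardization
#'
#' Z-scores every band of a cube against that image's own per-band mean and
#' standard deviation. Global multiplicative effects - per-subject camera
#' gain, optical path differences - shift and scale whole bands, so
#' standardizing each acquisition against itself removes them before the
#' classifier ever sees the data. The same transform is applied when
#' training and when predicting, always from the statistics of the image at
#' hand, so no information crosses subjects. This is the spectral-imaging
#' analogue of the standard-normal-variate correction used throughout
#' chemometrics.
#'
#' @param cube A [hypercube()].
#' @return A `hypercube` whose array holds standardized values (no longer
#'   reflectance; flagged via attribute `standardized`).
#' @export
standardize_cube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  if (isTRUE(attr(cube, "standardized"))) return(cube)
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  mu <- colMeans(flat)
  sg <- pmax(apply(flat, 2, sd), 1e-6)
  flat <- sweep(sweep(flat, 2, mu), 2, sg, `/`)
  out <- cube
  out$reflectance <- array(flat, d)
  attr(out, "standardized") <- TRUE
  out
}

# hypercube() validation rejects negatives; standardized cubes bypass the
# constructor on purpose (they are internal model inputs, not reflectance).

#' Per-band input standardization of a model
#'
#' Fixes an affine per-band transform `(x - center) / scale` applied to
#' every subvolume before the first convolution. Because the first layer is
#' affine, this is a pure reparameterization - the representable function
#' class is unchanged - but it conditions stochastic gradient descent far
#' better than raw reflectance, whose bands are all-positive and strongly
#' correlated. [train()] installs the training-set statistics automatically
#' when the model has none.
#'
#' @param model A `classifier_model`.
#' @param center,scale Per-band center and scale (length `input_bands`).
#' @return The model with the normalization installed.
#' @export
set_input_norm <- function(model, center, scale) {
  stopifnot(inherits(model, "classifier_model"))
  B <- model$spec$input_bands
  if (length(center) != B || length(scale) != B)
    lhsi_stop("center and scale must have one entry per band",
              "lhsi_parameter_error")
  scale <- pmax(scale, 1e-6)
  w2 <- model$spec$input_window^2
  model$norm <- list(center = rep(center, each = w2),
                     inv_scale = rep(1 / scale, each = w2),
                     band_center = center, band_scale = scale)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
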