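# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: plain loops, textbook formulas.

# Naive direct convolution of one sample through the conv stack of a model.
# A: array (H, W, B, C). Returns the post-activation output array.
naive_conv_stack <- function(model, A) {
  spec <- model$spec
  for (i in seq_len(length(spec$layers) - 1)) {
    l <- spec$layers[[i]]
    W <- model$params[[i]]$W; b <- model$params[[i]]$b
    k <- l$kernel; s <- l$stride_b
    Ho <- dim(A)[1] - k[1] + 1
    Wo <- dim(A)[2] - k[2] + 1
    Bo <- floor((dim(A)[3] - k[3]) / s) + 1
    out <- array(0, c(Ho, Wo, Bo, l$cout))
    for (c2 in seq_len(l$cout))
      for (oh in seq_len(Ho)) for (ow in seq_len(Wo)) for (ob in seq_len(Bo)) {
        acc <- b[c2]
        for (c1 in seq_len(l$cin))
          for (db in seq_len(k[3])) for (dw in seq_len(k[2]))
            for (dh in seq_len(k[1])) {
              e <- dh + k[1] * (dw - 1) + k[1] * k[2] * (db - 1) +
                prod(k) * (c1 - 1)
              acc <- acc + W[c2, e] *
                A[oh + dh - 1, ow + dw - 1, (ob - 1) * s + db, c1]
            }
        out[oh, ow, ob, c2] <- acc
      }
    if (l$relu) out[out < 0] <- 0
    A <- out
  }
  A
}

# Full naive forward (conv stack + dense head) for a feature-vector input.
naive_forward_one <- function(model, x) {
  spec <- model$spec
  if (!is.null(model$norm))
    x <- (x - model$norm$center) * model$norm$inv_scale
  A <- array(x, c(spec$input_window, spec$input_window, spec$input_bands, 1))
  A <- naive_conv_stack(model, A)
  p <- model$params[[length(spec$layers)]]
  h1 <- pmax(as.vector(p$W1 %*% as.vector(A)) + p$b1, 0)
  z <- as.vector(p$W2 %*% h1) + p$b2
  1 / (1 + exp(-z))
}

# Local least-squares polynomial smoother replicating the documented
# Savitzky-Golay transient handling (fit first/last window, evaluate in
# place), followed by explicit central second differences.
oracle_second_derivative <- function(x, step_nm = 5, n = 9, p = 4) {
  N <- length(x); k <- (n - 1) / 2
  fitval <- function(idx, at) {
    X <- outer(idx - mean(idx), 0:p, `^`)
    cf <- qr.solve(X, x[idx])
    sum(cf * (at - mean(idx))^(0:p))
  }
  sm <- numeric(N)
  for (i in seq_len(N)) {
    sm[i] <- if (i <= k) fitval(1:n, i)
    else if (i > N - k) fitval((N - n + 1):N, i)
    else fitval((i - k):(i + k), i)
  }
  d2 <- numeric(N)
  d2[2:(N - 1)] <- (sm[1:(N - 2)] - 2 * sm[2:(N - 1)] + sm[3:N]) / step_nm^2
  d2[1] <- d2[2]; d2[N] <- d2[N - 1]
  d2
}

# Breadth-first connected components in plain R (queue over a logical mask).
oracle_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); nxt <- 0L
  nbr <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      qr <- (q - 1) %% H + 1; qc <- (q - 1) %/% H + 1
      for (j in seq_len(nrow(nbr))) {
        rr <- qr + nbr[j, 1]; cc <- qc + nbr[j, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        i <- rr + (cc - 1) * H
        if (mask[i] != 0 && lab[i] == 0L) { lab[i] <- nxt; queue <- c(queue, i) }
      }
    }
  }
  lab
}

# Reference post-filter built on the BFS labelling only.
oracle_postfilter <- function(mask, connectivity = 8) {
  lab <- oracle_components(mask, connectivity)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
  bg <- oracle_components(1L - m, if (connectivity == 8) 4 else 8)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  m[bg > 0 & !(bg %in% border)] <- 1L
  m
}

# Textbook Spearman: Pearson product-moment formula on average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Tiny deterministic cohort reused by training/inference tests.
tiny_cohort <- function(n = 2, size = 48, seed = 42)
  make_cohort(n, seed = seed, shape = c(size, size))

# Drop every attribute except dim (compare bare matrices).
bare <- function(m) { attributes(m) <- list(dim = dim(m)); m }
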