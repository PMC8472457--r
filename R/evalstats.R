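# Evaluation metrics and correlation statistics: pooled normalized confusion
# matrices, ROC curves, and Spearman/Pearson correlations with one- or
# two-tailed p-values.

#' Pooled normalized confusion matrix
#'
#' Counts are pooled over all provided prediction/truth pairs before row
#' normalization; pixels with truth label 0 are excluded. The positive class
#' is +1: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param pred Predicted +1/-1 labels: vector, matrix, or list of them.
#' @param truth Ground-truth labels in {+1, -1, 0}, matching `pred`'s
#'   structure.
#' @return A `normalized_confusion`: `counts` (2x2, rows = truth),
#'   `rates` (row-normalized), `sensitivity`, `specificity`, `n`.
#' @export
confusion <- function(pred, truth) {
  if (!is.list(pred)) { pred <- list(pred); truth <- list(truth) }
  stopifnot(length(pred) == length(truth))
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(pred)) {
    p <- as.vector(pred[[i]]); t <- as.vector(unclass(truth[[i]]))
    if (length(p) != length(t))
      lhsi_stop("prediction and truth differ in length", "lhsi_input_error")
    keep <- t != 0 & !is.na(p)
    p <- p[keep]; t <- t[keep]
    tp <- tp + sum(t == 1 & p == 1)
    fn <- fn + sum(t == 1 & p != 1)
    tn <- tn + sum(t == -1 & p != 1)
    fp <- fp + sum(t == -1 & p == 1)
  }
  if (tp + fn + tn + fp == 0)
    lhsi_stop("no labelled pixels to evaluate", "lhsi_input_error")
  counts <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                   dimnames = list(truth = c("+1", "-1"),
                                   pred = c("+1", "-1")))
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs > 0, rs, NA)
  structure(list(counts = counts, rates = rates,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 n = tp + fn + tn + fp),
            class = "normalized_confusion")
}

#' @export
print.normalized_confusion <- function(x, ...) {
  cat(sprintf("<normalized_confusion> n=%d  sens=%.3f  spec=%.3f\n",
              x$n, x$sensitivity, x$specificity))
  print(round(x$rates, 3))
  invisible(x)
}

#' ROC curve and area for per-pixel scores
#'
#' @param scores Continuous positive-class scores.
#' @param truth Labels in {+1, -1, 0}; 0 excluded. Both classes must occur.
#' @return List with `fpr`, `tpr` (monotone curve from (0,0) to (1,1)),
#'   `auc`, and `n`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.vector(unclass(truth)); scores <- as.vector(scores)
  keep <- truth != 0 & is.finite(scores)
  truth <- truth[keep]; scores <- scores[keep]
  if (length(unique(truth)) < 2)
    lhsi_stop("ROC needs both classes in the truth", "lhsi_input_error")
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(-1, 1), direction = "<", quiet = TRUE)
  list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
       auc = as.numeric(r$auc), n = length(truth))
}

#' Correlation with directional p-values
#'
#' Pearson or Spearman correlation. One-tailed tests require a stated
#' expected direction (physiological prior); the one-tailed p equals half
#' the two-tailed p when the observed sign matches that direction. Pearson
#' p-values use the t distribution with n-2 df; Spearman uses the same
#' approximation (with average ranks for ties), adequate for the n ~ 20-40
#' regime this package targets. An exact permutation p-value is available
#' for n <= 8.
#'
#' @param x,y Numeric series of equal length, n >= 3, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @param tails `"two"` or `"one"`.
#' @param direction Expected sign for one-tailed tests: `"negative"` or
#'   `"positive"`.
#' @param exact_perm Use the exact permutation distribution (n <= 8 only).
#' @return A `correlation_report`: `r`, `p_value`, `method`, `tails`,
#'   `direction`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      tails = c("two", "one"), direction = c("negative",
                                                             "positive"),
                      exact_perm = FALSE) {
  method <- match.arg(method); tails <- match.arg(tails)
  direction <- match.arg(direction)
  if (length(x) != length(y) || length(x) < 3)
    lhsi_stop("need at least 3 paired values", "lhsi_input_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    lhsi_stop("non-finite values in the series", "lhsi_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    lhsi_stop("correlation undefined for a constant series",
              "lhsi_undefined_correlation_error")
  n <- length(x)
  if (exact_perm) {
    if (n > 8)
      lhsi_stop("exact permutation p-value supported for n <= 8 only",
                "lhsi_parameter_error")
    r <- cor(x, y, method = method)
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(pm) cor(x, y[pm], method = method))
    p2 <- mean(abs(rs) >= abs(r) - 1e-12)
    p <- if (tails == "two") p2 else {
      want <- if (direction == "negative") rs <= r + 1e-12 else rs >= r - 1e-12
      # one-tailed: mass at least as extreme in the stated direction
      if ((direction == "negative" && r <= 0) ||
          (direction == "positive" && r >= 0)) mean(want) else 1 - mean(want)
    }
  } else {
    alt <- if (tails == "two") "two.sided"
           else if (direction == "negative") "less" else "greater"
    ct <- suppressWarnings(cor.test(x, y, method = method, alternative = alt,
                                    exact = FALSE))
    r <- as.numeric(ct$estimate)
    p <- ct$p.value
  }
  structure(list(r = r, p_value = p, method = method, tails = tails,
                 direction = if (tails == "one") direction else NA_character_,
                 n = n),
            class = "correlation_report")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation> %s r = %.3f, %s-tailed p = %.4g (n = %d)\n",
              x$method, x$r, x$tails, x$p_value, x$n))
  invisible(x)
}

#' Pairwise correlation matrix
#'
#' Symmetric grid of pairwise correlations over the complete cases of a
#' numeric table (e.g. AI score, capillary lactate, histology score).
#'
#' @param table Data.frame of numeric columns.
#' @param method,tails,direction Passed to [correlate()] for every pair.
#' @return A `correlation_grid`: matrices `r` and `p` (diagonal r = 1,
#'   p = NA) plus `n`, the number of complete rows.
#' @export
correlation_matrix <- function(table, method = "spearman", tails = "two",
                               direction = "negative") {
  stopifnot(is.data.frame(table))
  tab <- table[stats::complete.cases(table), , drop = FALSE]
  if (nrow(tab) < 3)
    lhsi_stop("need at least 3 complete rows", "lhsi_input_error")
  k <- ncol(tab)
  R <- diag(1, k); P <- matrix(NA_real_, k, k)
  dimnames(R) <- dimnames(P) <- list(names(tab), names(tab))
  for (i in seq_len(k - 1))
    for (j in (i + 1):k) {
      rep_ <- correlate(tab[[i]], tab[[j]], method = method, tails = tails,
                        direction = direction)
      R[i, j] <- R[j, i] <- rep_$r
      P[i, j] <- P[j, i] <- rep_$p_value
    }
  structure(list(r = R, p = P, n = nrow(tab), method = method),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("<correlation_grid> %s, n = %d complete cases\n",
              x$method, x$n))
  print(round(x$r, 3))
  invisible(x)
}
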