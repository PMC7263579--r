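## stratified, seeded fold assignment; each fold's class proportions are
## within one sample of the global proportions. Folds are identical for a
## given (y, folds, seed) regardless of the feature set evaluated.
stratified_folds <- function(y, folds = 10L, seed = 1L) {
  y <- as.factor(y)
  counts <- table(y)
  small <- names(counts)[counts < folds]
  if (length(small))
    stop("class '", small[1], "' has fewer members (", counts[small[1]],
         ") than folds (", folds, ")", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

## z-score normalization fit on the training rows only (default), or on the
## whole table when global_norm = TRUE (global mean/variance normalization)
.fit_scale <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
.apply_scale <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

## cross-validated accuracy of a linear maximum-margin classifier on the
## given feature columns, with fixed fold assignment
.cv_accuracy_linear <- function(X, y, fold, folds, global_norm = FALSE) {
  correct <- 0L
  gsc <- if (global_norm) .fit_scale(X) else NULL
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    sc <- if (global_norm) gsc else .fit_scale(X[tr, , drop = FALSE])
    Xtr <- .apply_scale(X[tr, , drop = FALSE], sc)
    Xte <- .apply_scale(X[te, , drop = FALSE], sc)
    m <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1, scale = FALSE)
    correct <- correct + sum(predict(m, Xte) == y[te])
  }
  correct / length(y)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' inclusion maximizes stratified k-fold cross-validated accuracy of a linear
#' maximum-margin classifier (soft-margin SVM, cost 1) is added, ties broken
#' by the lowest feature index. The same seeded fold assignment is reused for
#' every candidate evaluation in every step, so results are deterministic
#' given the seed. Selection stops after `k` features (default 7), or earlier
#' when no candidate improves the accuracy if `early_stop = TRUE`.
#'
#' @param X numeric matrix, subjects x features.
#' @param y class labels (factor or coercible), >= `folds` members per class.
#' @param k number of features to select.
#' @param folds cross-validation folds (default 10).
#' @param seed seed for the fold assignment.
#' @param global_norm if TRUE, mean/variance normalization is fit on the whole
#'   table before cross-validation (the global-normalization convention);
#'   default FALSE fits normalization on training folds only to avoid
#'   leakage.
#' @param early_stop stop when no candidate improves CV accuracy.
#' @return object of class `sfs_result`: list with `ordered_indices`,
#'   `ordered_names`, `step_accuracies`, `k`, `folds`, `seed`.
#' @export
sfs <- function(X, y, k = 7L, folds = 10L, seed = 1L, global_norm = FALSE,
                early_stop = FALSE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  stopifnot(nrow(X) == length(y), k >= 0, k <= ncol(X))
  fold <- stratified_folds(y, folds, seed)
  selected <- integer(0)
  accs <- numeric(0)
  best_prev <- -Inf
  while (length(selected) < k) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    cand_acc <- vapply(cand, function(j) {
      .cv_accuracy_linear(X[, c(selected, j), drop = FALSE], y, fold, folds,
                          global_norm)
    }, 0)
    best <- which.max(cand_acc)   # first maximum = lowest feature index
    if (early_stop && cand_acc[best] <= best_prev) break
    selected <- c(selected, cand[best])
    accs <- c(accs, cand_acc[best])
    best_prev <- cand_acc[best]
  }
  structure(list(ordered_indices = selected,
                 ordered_names = colnames(X)[selected],
                 step_accuracies = accs, k = length(selected),
                 folds = folds, seed = seed, global_norm = global_norm),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("Sequential forward selection: %d features (%d-fold CV)\n",
              x$k, x$folds))
  nm <- if (is.null(x$ordered_names)) x$ordered_indices else x$ordered_names
  for (i in seq_len(x$k))
    cat(sprintf("  %d. %s  (CV accuracy %.3f)\n", i, nm[i],
                x$step_accuracies[i]))
  invisible(x)
}
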