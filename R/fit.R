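#' Fit the texture-pattern classifier
#'
#' The package's central model: sequential forward selection of texture
#' features (wrapper = linear maximum-margin classifier under stratified
#' k-fold cross-validation), followed by cross-validated evaluation of the
#' chosen classifier on the selected features, and a final model trained on
#' all subjects for prediction on new data.
#'
#' @param X numeric matrix, subjects x features (e.g. the 152-feature table
#'   from [extract_features()]), with column names.
#' @param labels cohort labels (factor or coercible).
#' @param k number of features to select (default 7).
#' @param classifier `"linear-svm"` (default), `"rbf-svm"`, `"knn"`, or
#'   `"ensemble-trees"`.
#' @param folds cross-validation folds (default 10).
#' @param seed seed for fold assignment.
#' @param global_norm fit the mean/variance normalization globally instead of
#'   per training fold.
#' @return object of class `texture_fit`: list with `selection`
#'   (an `sfs_result`), `evaluation` (an `eval_report` on the selected
#'   features), `scale`, `model` (final classifier on all subjects),
#'   `levels`, and the call parameters.
#' @seealso [sfs()], [cross_validated_eval()], [texture_index()]
#' @export
texture_fit <- function(X, labels, k = 7L, classifier = "linear-svm",
                        folds = 10L, seed = 1L, global_norm = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.factor(labels)
  sel <- sfs(X, y, k = k, folds = folds, seed = seed, global_norm = global_norm)
  Xs <- X[, sel$ordered_indices, drop = FALSE]
  ev <- cross_validated_eval(Xs, y, classifier = classifier, folds = folds,
                             seed = seed, global_norm = global_norm)
  sc <- .fit_scale(Xs)
  Xn <- .apply_scale(Xs, sc)
  model <- if (classifier == "ensemble-trees") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    randomForest::randomForest(Xn, y, ntree = 200)
  } else if (classifier == "knn") {
    list(Xtr = Xn, ytr = y)   # lazy learner: keep the training table
  } else {
    e1071::svm(Xn, y, kernel = if (classifier == "linear-svm") "linear"
               else "radial", cost = 1, scale = FALSE)
  }
  structure(list(selection = sel, evaluation = ev, scale = sc, model = model,
                 classifier = classifier, k = sel$k, folds = folds,
                 seed = seed, global_norm = global_norm, levels = levels(y),
                 feature_names = sel$ordered_names),
            class = "texture_fit")
}

#' @export
print.texture_fit <- function(x, ...) {
  cat("Texture-pattern classifier\n")
  cat(sprintf("  classifier: %s, %d-fold CV, %d selected features\n",
              x$classifier, x$folds, x$k))
  cat("  selected:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  CV accuracy: %.1f%%\n", 100 * x$evaluation$accuracy))
  invisible(x)
}

#' @export
summary.texture_fit <- function(object, ...) {
  x <- object
  cat("Texture-pattern classifier --", x$classifier, "\n\n")
  cat("Selected features (in inclusion order):\n")
  for (i in seq_len(x$k))
    cat(sprintf("  %d. %-18s step CV accuracy %.3f\n", i,
                x$feature_names[i], x$selection$step_accuracies[i]))
  cat(sprintf("\nCross-validated accuracy: %.1f%% (%d-fold)\n",
              100 * x$evaluation$accuracy, x$folds))
  cat("\nPer-class performance (one-vs-all):\n")
  tab <- cbind(sensitivity = x$evaluation$sensitivity,
               specificity = x$evaluation$specificity,
               AUC = x$evaluation$auc,
               x$evaluation$auc_ci)
  print(round(tab, 3))
  cat("\nConfusion matrix (pooled out-of-fold):\n")
  print(x$evaluation$confusion)
  invisible(x)
}

#' @rdname texture_fit
#' @param object a `texture_fit`.
#' @param newdata matrix with either the full original feature columns or
#'   exactly the selected ones.
#' @param ... unused.
#' @export
predict.texture_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  stopifnot(ncol(newdata) == object$k)
  Xn <- .apply_scale(newdata, object$scale)
  if (object$classifier == "knn") {
    lev <- levels(object$model$ytr)
    k <- min(5L, nrow(object$model$Xtr))
    d2 <- outer(rowSums(Xn^2), rowSums(object$model$Xtr^2), "+") -
      2 * Xn %*% t(object$model$Xtr)
    pred <- factor(vapply(seq_len(nrow(Xn)), function(i) {
      nb <- object$model$ytr[order(d2[i, ])[seq_len(k)]]
      lev[which.max(table(nb)[lev])]
    }, ""), levels = lev)
    return(pred)
  }
  predict(object$model, Xn)
}

#' @rdname texture_fit
#' @param x a `texture_fit`.
#' @param which_class classes whose ROC curves to draw (default all).
#' @export
plot.texture_fit <- function(x, which_class = NULL, ...) {
  ev <- x$evaluation
  lev <- names(ev$roc)
  if (is.null(which_class)) which_class <- lev
  cols <- c("forestgreen", "steelblue", "firebrick", "orange", "purple")
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("One-vs-all ROC (%s)", x$classifier), ...)
  for (i in seq_along(which_class)) {
    r <- ev$roc[[which_class[i]]]
    lines(r$fpr, r$tpr, col = cols[(i - 1) %% length(cols) + 1], lwd = 2)
  }
  legend("bottomright", bty = "n", lwd = 2,
         col = cols[seq_along(which_class)],
         legend = sprintf("%s (AUC %.2f)", which_class,
                          ev$auc[which_class]))
  invisible(x)
}
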