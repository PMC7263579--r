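## classifier backends ------------------------------------------------------
##
## Each backend takes scaled training/test tables and returns predicted
## labels plus an n_test x n_class matrix of one-vs-all decision scores
## (larger = more that class). SVM class labels come from the usual
## one-vs-one vote; ROC scores come from per-class one-vs-all margins.

.fit_predict <- function(classifier, Xtr, ytr, Xte, seed = 1L) {
  lev <- levels(ytr)
  scores <- matrix(NA_real_, nrow(Xte), length(lev),
                   dimnames = list(NULL, lev))
  if (classifier %in% c("linear-svm", "rbf-svm")) {
    kern <- if (classifier == "linear-svm") "linear" else "radial"
    m <- e1071::svm(Xtr, ytr, kernel = kern, cost = 1, scale = FALSE)
    pred <- predict(m, Xte)
    for (cl in lev) {
      yb <- factor(ifelse(ytr == cl, "pos", "neg"), levels = c("pos", "neg"))
      mb <- e1071::svm(Xtr, yb, kernel = kern, cost = 1, scale = FALSE)
      dv <- attr(predict(mb, Xte, decision.values = TRUE), "decision.values")
      ## orient so larger = 'pos' regardless of internal label order
      sgn <- if (colnames(dv)[1] == "pos/neg") 1 else -1
      scores[, cl] <- sgn * dv[, 1]
    }
  } else if (classifier == "knn") {
    ## deterministic KNN (k = 5): per-class neighbor fractions as scores,
    ## argmax with lowest-class-index tie-break as the label
    k <- min(5L, nrow(Xtr))
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
    for (i in seq_len(nrow(Xte))) {
      nb <- ytr[order(d2[i, ])[seq_len(k)]]
      scores[i, ] <- as.numeric(table(nb)[lev]) / k
    }
    scores[is.na(scores)] <- 0
    pred <- factor(lev[apply(scores, 1, which.max)], levels = lev)
  } else if (classifier == "ensemble-trees") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    m <- randomForest::randomForest(Xtr, ytr, ntree = 200)
    pred <- predict(m, Xte)
    scores[, ] <- predict(m, Xte, type = "vote")[, lev]
  } else {
    stop("unknown classifier: '", classifier, "'", call. = FALSE)
  }
  list(pred = pred, scores = scores)
}

## ROC curve with descending score thresholds; trapezoidal AUC
.roc_curve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  ## keep one point per distinct threshold (ties grouped)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[keep] / sum(positive))
  fpr <- c(0, fp[keep] / sum(!positive))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Cross-validated multiclass evaluation
#'
#' Stratified k-fold cross-validation of one classifier. Mean/variance
#' normalization is fit on the training folds of each split (or globally with
#' `global_norm = TRUE`). Out-of-fold predictions are pooled into a confusion
#' matrix; one-vs-all ROC curves are computed from pooled decision scores,
#' with AUC confidence intervals from the DeLong variance.
#'
#' @param X numeric matrix, subjects x features (finite).
#' @param y class labels.
#' @param classifier one of `"linear-svm"`, `"rbf-svm"`, `"knn"`,
#'   `"ensemble-trees"`.
#' @param folds number of CV folds (default 10).
#' @param seed seed controlling fold assignment (and tree bagging).
#' @param global_norm global instead of per-fold normalization.
#' @return object of class `eval_report`: accuracy, confusion matrix,
#'   per-class sensitivity/specificity, ROC curves, AUCs with 95% CIs,
#'   pooled out-of-fold scores and predictions.
#' @export
cross_validated_eval <- function(X, y, classifier = "linear-svm", folds = 10L,
                                 seed = 1L, global_norm = FALSE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  y <- as.factor(y)
  lev <- levels(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- factor(rep(lev[1], length(y)), levels = lev)
  scores <- matrix(NA_real_, length(y), length(lev),
                   dimnames = list(NULL, lev))
  gsc <- if (global_norm) .fit_scale(X) else NULL
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    sc <- if (global_norm) gsc else .fit_scale(X[tr, , drop = FALSE])
    fp <- .fit_predict(classifier,
                       .apply_scale(X[tr, , drop = FALSE], sc), y[tr],
                       .apply_scale(X[te, , drop = FALSE], sc),
                       seed = seed + f)
    pred[te] <- fp$pred
    scores[te, ] <- fp$scores
  }
  confusion <- table(truth = y, predicted = pred)
  accuracy <- sum(diag(confusion)) / length(y)
  sens <- spec <- auc <- numeric(length(lev))
  auc_ci <- matrix(NA_real_, length(lev), 2,
                   dimnames = list(lev, c("lower", "upper")))
  roc <- vector("list", length(lev)); names(roc) <- names(sens) <-
    names(spec) <- names(auc) <- lev
  for (i in seq_along(lev)) {
    pos <- y == lev[i]
    tp <- sum(pred == lev[i] & pos); fn <- sum(pred != lev[i] & pos)
    fp_ <- sum(pred == lev[i] & !pos); tn <- sum(pred != lev[i] & !pos)
    sens[i] <- tp / (tp + fn)
    spec[i] <- tn / (tn + fp_)
    roc[[i]] <- .roc_curve(scores[, i], pos)
    auc[i] <- roc[[i]]$auc
    v <- .delong_auc_var(scores[, i], pos)
    auc_ci[i, ] <- pmin(1, pmax(0, auc[i] + c(-1, 1) * 1.96 * sqrt(v)))
  }
  structure(list(classifier = classifier, folds = folds, seed = seed,
                 accuracy = accuracy, confusion = confusion,
                 sensitivity = sens, specificity = spec,
                 roc = roc, auc = auc, auc_ci = auc_ci,
                 scores = scores, predictions = pred, labels = y),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s, %d-fold CV: accuracy %d/%d (%.1f%%)\n", x$classifier,
              x$folds, sum(diag(x$confusion)), length(x$labels),
              100 * x$accuracy))
  tab <- rbind(sensitivity = x$sensitivity, specificity = x$specificity,
               AUC = x$auc)
  print(round(tab, 3))
  invisible(x)
}

## DeLong structural components (placement values) --------------------------

.delong_components <- function(scores, positive) {
  xs <- scores[positive]; ys <- scores[!positive]
  m <- length(xs); n <- length(ys)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  ## midranks handle ties
  r_all <- rank(c(xs, ys), ties.method = "average")
  r_x <- rank(xs, ties.method = "average")
  r_y <- rank(ys, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n               # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m       # per-negative placements
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

.delong_auc_var <- function(scores, positive) {
  cp <- .delong_components(scores, positive)
  s10 <- stats::var(cp$v10); s01 <- stats::var(cp$v01)
  if (cp$m < 2) s10 <- 0
  if (cp$n < 2) s01 <- 0
  s10 / cp$m + s01 / cp$n
}

#' DeLong comparison of two correlated AUCs
#'
#' Both score vectors are evaluated on the same subjects, so their AUC
#' estimates are correlated; the covariance is estimated from DeLong's
#' structural components (per-positive and per-negative placement values,
#' midranks for ties) and a two-sided normal test is applied to the AUC
#' difference. The AUCs themselves are the Mann-Whitney estimators.
#'
#' @param scores_a,scores_b numeric score vectors on the same subjects.
#' @param y binary truth: logical, or a 2-level factor whose second level is
#'   taken as positive, or 0/1.
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, y) {
  positive <- .as_positive(y)
  stopifnot(length(scores_a) == length(positive),
            length(scores_b) == length(positive))
  if (all(positive) || !any(positive))
    stop("both classes must be present", call. = FALSE)
  a <- .delong_components(scores_a, positive)
  b <- .delong_components(scores_b, positive)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / a$m + s01 / a$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- a$auc - b$auc
  if (v <= 0 || !is.finite(v)) {
    z <- if (abs(delta) < .Machine$double.eps^0.5) 0 else Inf * sign(delta)
  } else z <- delta / sqrt(v)
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, z = z, p_value = p)
}

.as_positive <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must be binary", call. = FALSE)
    return(y == levels(y)[2])
  }
  u <- sort(unique(y))
  if (length(u) == 1) stop("y has a single class", call. = FALSE)
  if (length(u) != 2) stop("y must be binary", call. = FALSE)
  y == u[2]
}
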