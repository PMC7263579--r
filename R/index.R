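#' Texture index: linear regression combination of selected features
#'
#' Combines the selected texture features into one scalar index
#' `Tx = b0 + b1*x1 + ... + bn*xn` by ordinary least squares against binary
#' cohort coding: +1 for the first-listed cohort, -1 for the second. A
#' positive index therefore indicates the first cohort. When the design is
#' rank-deficient (n <= p) the minimum-norm least-squares solution is used.
#'
#' @param X numeric matrix, subjects x selected features.
#' @param group binary cohort labels: a 2-level factor (first level coded
#'   +1), or a vector coercible to one.
#' @return object of class `texture_index`: list with `beta0`, `beta`,
#'   `feature_names`, `groups` (the two cohort names, +1 first), `fitted`.
#' @export
texture_index <- function(X, group) {
  X <- as.matrix(X)
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("single-class group: need two cohorts",
                               call. = FALSE)
  if (nlevels(group) > 2) stop("texture index is a binary comparison",
                               call. = FALSE)
  stopifnot(nrow(X) == length(group))
  yy <- ifelse(group == levels(group)[1], 1, -1)
  A <- cbind(`(Intercept)` = 1, X)
  if (nrow(A) > ncol(A) && qr(A)$rank == ncol(A)) {
    beta <- solve(crossprod(A), crossprod(A, yy))[, 1]
  } else {
    beta <- (MASS::ginv(A) %*% yy)[, 1]   # minimum-norm solution
    names(beta) <- colnames(A)
  }
  structure(list(beta0 = beta[1], beta = beta[-1],
                 feature_names = colnames(X),
                 groups = levels(group),
                 fitted = as.vector(A %*% beta)),
            class = "texture_index")
}

#' @export
coef.texture_index <- function(object, ...) {
  c("(Intercept)" = unname(object$beta0), object$beta)
}

#' @rdname texture_index
#' @param object,x a `texture_index` model.
#' @param newdata matrix of the same selected features.
#' @param ... unused.
#' @export
predict.texture_index <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$beta))
  as.vector(object$beta0 + newdata %*% object$beta)
}

#' @rdname texture_index
#' @export
print.texture_index <- function(x, ...) {
  cat(sprintf("Texture index (Tx): %s (+1) vs %s (-1), %d features\n",
              x$groups[1], x$groups[2], length(x$beta)))
  print(round(coef(x), 4))
  invisible(x)
}
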