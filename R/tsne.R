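#' 2-D embedding for cohort visualization (exact t-SNE)
#'
#' Embeds the feature table on a 2-D plane with t-distributed stochastic
#' neighbor embedding, used to visualize how well the selected features
#' cluster the cohorts. This is an exact (O(n^2)) implementation suitable for
#' cohort-sized tables: Gaussian input affinities calibrated per point to a
#' target perplexity by bisection, Student-t output affinities, gradient
#' descent with early exaggeration and momentum. Deterministic given `seed`.
#'
#' @param X numeric matrix, subjects x features (finite values).
#' @param seed integer seed for the random initialization.
#' @param perplexity effective neighbor count (default 15, reduced
#'   automatically if n is small).
#' @param n_iter gradient-descent iterations (default 500).
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_2d <- function(X, seed = 1L, perplexity = 15, n_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects to embed", call. = FALSE)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)

  ## squared Euclidean distances
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  diag(D2) <- Inf

  ## per-point precision by bisection to match log-perplexity
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- 0; hi <- Inf
    di <- D2[i, ]
    for (iter in 1:50) {
      w <- exp(-di * beta); w[i] <- 0
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; hi <- beta * 2; next }
      H <- log(sw) + beta * sum(di[w > 0] * w[w > 0]) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, ] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1      # early exaggeration
    ssy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(ssy, ssy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    mom <- if (it < 250) 0.5 else 0.8
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(X), c("dim1", "dim2"))
  Y
}
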