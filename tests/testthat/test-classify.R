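blobs <- function(n_per = 20, gap = 10, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b", "c"), each = n_per))
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, gap), ncol = 2),
             cbind(rnorm(n_per, -gap), rnorm(n_per, gap)))
  colnames(X) <- c("u", "v")
  list(X = X, y = y)
}

test_that("well-separated blobs are classified perfectly by all classifiers", {
  d <- blobs()
  for (clf in c("linear-svm", "rbf-svm", "knn", "ensemble-trees")) {
    ev <- cross_validated_eval(d$X, d$y, classifier = clf, seed = 4)
    expect_equal(ev$accuracy, 1, label = clf)
    expect_equal(unname(ev$auc), rep(1, 3), label = clf)
    expect_equal(unname(ev$sensitivity), rep(1, 3))
    expect_equal(unname(ev$specificity), rep(1, 3))
  }
  expect_error(cross_validated_eval(d$X, d$y, classifier = "mlp"), "unknown")
})

test_that("permuted labels give chance accuracy and null AUCs", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 4), n)
  y <- factor(rep(c("a", "b", "c"), each = 100))
  ev <- cross_validated_eval(X, y, classifier = "linear-svm", seed = 9)
  se_acc <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(ev$accuracy - 1 / 3), 3 * se_acc)
  # null AUC ~ 0.5 with SE ~ sqrt((n1+n2+1)/(12 n1 n2))
  se_auc <- sqrt((100 + 200 + 1) / (12 * 100 * 200))
  expect_true(all(abs(ev$auc - 0.5) < 3 * se_auc))
})

test_that("folds are stratified within one sample of global proportions", {
  y <- factor(rep(c("a", "b", "c"), times = c(23, 31, 46)))
  fold <- stratified_folds(y, folds = 10, seed = 7)
  for (f in 1:10) {
    tab <- table(y[fold == f])
    for (cl in levels(y)) {
      expected <- sum(y == cl) / 10
      expect_lte(abs(tab[cl] - expected), 1)
    }
  }
})

test_that("accuracy and sensitivity/specificity re-derive from the confusion matrix", {
  d <- blobs(gap = 2, seed = 12)   # overlapping blobs: non-trivial errors
  ev <- cross_validated_eval(d$X, d$y, classifier = "knn", seed = 2)
  cm <- ev$confusion
  expect_equal(ev$accuracy, sum(diag(cm)) / sum(cm))
  for (cl in levels(d$y)) {
    tp <- cm[cl, cl]
    expect_equal(unname(ev$sensitivity[cl]), tp / sum(cm[cl, ]))
    tn <- sum(cm[rownames(cm) != cl, colnames(cm) != cl])
    fp <- sum(cm[rownames(cm) != cl, cl])
    expect_equal(unname(ev$specificity[cl]), tn / (tn + fp))
  }
  expect_true(all(ev$sensitivity >= 0 & ev$sensitivity <= 1))
  expect_true(all(ev$specificity >= 0 & ev$specificity <= 1))
})

test_that("AUC of a score vector and of its negation sum to one", {
  set.seed(21)
  s <- rnorm(60)
  y <- rep(c(TRUE, FALSE), 30)
  a1 <- delong_test(s, s, y)$auc_a
  a2 <- delong_test(-s, -s, y)$auc_a
  expect_equal(a1 + a2, 1)
})

test_that("DeLong AUC equals exhaustive Mann-Whitney pair counting", {
  set.seed(33)
  y <- c(rep(TRUE, 18), rep(FALSE, 22))
  s_a <- rnorm(40) + y * 0.8
  s_b <- round(rnorm(40) + y * 0.5, 1)    # rounding forces ties
  dt <- delong_test(s_a, s_b, y)
  expect_equal(dt$auc_a, oracle_auc(s_a, y), tolerance = 1e-12)
  expect_equal(dt$auc_b, oracle_auc(s_b, y), tolerance = 1e-12)
  expect_equal(dt$delta, dt$auc_a - dt$auc_b)
})

test_that("identical scores compare with zero difference and p = 1", {
  set.seed(2)
  y <- rep(c(TRUE, FALSE), each = 15)
  s <- rnorm(30)
  dt <- delong_test(s, s, y)
  expect_equal(dt$delta, 0)
  expect_equal(dt$p_value, 1)
  expect_error(delong_test(s, s, rep(TRUE, 30)), "both classes")
})

test_that("perfect separation yields AUC exactly 1", {
  y <- rep(c(TRUE, FALSE), each = 10)
  s <- c(rnorm(10, 10), rnorm(10, -10))
  expect_equal(delong_test(s, s, y)$auc_a, 1)
})

test_that("DeLong p-value agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rep(c(TRUE, FALSE), each = 25)
  s_a <- rnorm(50) + y
  s_b <- rnorm(50) + 0.5 * y
  dt <- delong_test(s_a, s_b, y)
  ref <- pROC::roc.test(pROC::roc(y, s_a, quiet = TRUE),
                        pROC::roc(y, s_b, quiet = TRUE), method = "delong")
  expect_equal(dt$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("texture index interpolates, matches OLS, and codes groups +1/-1", {
  # two subjects, one feature: exact interpolation
  ti <- texture_index(matrix(c(0, 1), ncol = 1), factor(c("g1", "g2")))
  expect_equal(predict(ti, matrix(c(0, 1), ncol = 1)), c(1, -1))
  # closed-form OLS on three points
  X <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  yy <- c(1, 1, -1)
  g <- factor(c("a", "a", "b"), levels = c("a", "b"))
  ti2 <- texture_index(X, g)
  b <- coef(ti2)
  # normal equations oracle
  A <- cbind(1, X)
  bo <- solve(t(A) %*% A, t(A) %*% yy)[, 1]
  expect_equal(unname(b), unname(bo), tolerance = 1e-10)
  expect_error(texture_index(X, factor(rep("a", 3))), "single-class")
})

test_that("the 2-D embedding is deterministic and separates distinct blobs", {
  skip_if_not_installed("cluster")
  d <- blobs(n_per = 15, gap = 12, seed = 6)
  e1 <- embed_2d(d$X, seed = 8)
  e2 <- embed_2d(d$X, seed = 8)
  expect_equal(dim(e1), c(45, 2))
  expect_identical(e1, e2)
  sil <- cluster::silhouette(as.integer(d$y), dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_2d(matrix(c(NA, rnorm(19)), 5, 4)), "finite")
})
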