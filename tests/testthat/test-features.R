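test_that("quantization matches the per-pixel binning formula", {
  m <- matrix(0:31, 4, 8)
  expect_identical(quantize(m, 32), matrix(0:31, 4, 8))
  expect_identical(quantize(matrix(7, 3, 3), 32), matrix(0L, 3, 3))
  set.seed(1)
  r <- matrix(runif(64, 900, 1300), 8, 8)
  q <- quantize(r, 13)
  oracle <- pmin(floor(13 * (r - min(r)) / (max(r) - min(r))), 12)
  expect_identical(q, matrix(as.integer(oracle), 8, 8))
})

test_that("histogram moments match direct summation", {
  expect_equal(unname(histogram_features(matrix(5, 4, 4))),
               c(5, rep(0, 9)))
  two_pt <- matrix(c(0, 2), 4, 4)
  hf <- histogram_features(two_pt)
  expect_equal(unname(hf[1:4]), c(1, 1, 0, 1))
  set.seed(42)
  m <- matrix(rnorm(100, 1100, 40), 10, 10)
  expect_equal(unname(histogram_features(m)), oracle_moments(m),
               tolerance = 1e-12)
})

test_that("GLCM features: degenerate and forced-by-construction cases", {
  qc <- matrix(3L, 16, 16)
  g <- glcm_features(qc, n_levels = 32)
  for (d in 1:10) {
    expect_equal(unname(g[sprintf("ASM(%d)", d)]), 1)
    expect_equal(unname(g[sprintf("Contrast(%d)", d)]), 0)
    expect_equal(unname(g[sprintf("Homogeneity2(%d)", d)]), 1)
    expect_equal(unname(g[sprintf("Entropy(%d)", d)]), 0)
    expect_equal(unname(g[sprintf("SumOfSquares(%d)", d)]), 0)
  }
  # two-level checkerboard, d = 1, 0-degree direction only:
  # all horizontal pairs alternate, p(0,1) = p(1,0) = 0.5
  cb <- outer(1:8, 1:8, function(i, j) as.integer((i + j) %% 2))
  g1 <- glcm_features(cb, n_levels = 2, displacements = 1, directions = "0")
  expect_equal(unname(g1["Contrast(1)"]), 1)
  expect_equal(unname(g1["ASM(1)"]), 0.5)
})

test_that("all 60 GLCM features equal the brute-force pair enumeration", {
  set.seed(7)
  q <- matrix(sample(0:3, 256, replace = TRUE), 16, 16)
  g <- glcm_features(q, n_levels = 4, displacements = 1:10)
  for (d in 1:10) {
    o <- oracle_glcm(q, d, K = 4)
    got <- g[sprintf("%s(%d)", names(o), d)]
    expect_equal(unname(got), unname(o), tolerance = 1e-10,
                 label = sprintf("GLCM d=%d", d))
  }
})

test_that("GLRLM features: single-run algebra and all-runs-length-1 maps", {
  row8 <- matrix(2L, 1, 8)
  g <- glrlm_features(row8, n_levels = 4)
  expect_equal(unname(g["SRE(0)"]), 1 / 64)
  expect_equal(unname(g["LRE(0)"]), 64)
  expect_equal(unname(g["RP(0)"]), 1 / 8)
  expect_equal(unname(g["RLN(0)"]), 1)
  expect_equal(unname(g["GLN(0)"]), 1)
  # no two adjacent pixels share a level in any direction
  alt <- outer(1:6, 1:6, function(i, j) as.integer((i + 2 * j) %% 4))
  ga <- glrlm_features(alt, n_levels = 4)
  for (dir in c("0", "45", "90", "135")) {
    expect_equal(unname(ga[sprintf("SRE(%s)", dir)]), 1)
    expect_equal(unname(ga[sprintf("LRE(%s)", dir)]), 1)
    expect_equal(unname(ga[sprintf("RP(%s)", dir)]), 1)
  }
  expect_error(glrlm_features(matrix(integer(0), 0, 0)), "empty")
})

test_that("all 44 GLRLM features equal the exhaustive run enumeration", {
  set.seed(11)
  q <- matrix(sample(0:3, 64, replace = TRUE, prob = c(4, 2, 1, 1)), 8, 8)
  g <- glrlm_features(q, n_levels = 4)
  for (dir in c("0", "45", "90", "135")) {
    o <- oracle_glrlm(q, dir, K = 4)
    got <- g[sprintf("%s(%s)", names(o), dir)]
    expect_equal(unname(got), unname(o), tolerance = 1e-10,
                 label = sprintf("GLRLM %s deg", dir))
  }
})

test_that("LBP histogram behaves on constant maps and normalizes", {
  h <- lbp_features(matrix(7, 16, 16))
  expect_length(h, 38)
  expect_equal(sum(h), 1)
  # ties count as 1: all-ones word, uniform, code P = 36 -> bin 37
  expect_equal(unname(h["LBP(37)"]), 1)
  set.seed(3)
  h2 <- lbp_features(matrix(rnorm(400), 20, 20))
  expect_equal(sum(h2), 1)
  expect_error(lbp_features(matrix(1, 4, 4)), "smaller")
})

test_that("LBP histogram equals the naive rotate-and-threshold oracle (P=8)", {
  set.seed(19)
  m <- matrix(rnorm(256, 1000, 50), 16, 16)
  got <- lbp_features(m, P = 8, R = 1)
  expect_equal(unname(got), oracle_lbp(m, P = 8, R = 1), tolerance = 1e-10)
})

test_that("the extractor emits exactly the 152 documented features", {
  s <- generate_subject("DCM", seed = 13)
  fv <- extract_features(unwrap_subject(s))
  expect_length(fv, 152)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())
  nm <- names(fv)
  expect_length(grep("^(Mean|Variance|Skewness|Kurtosis|Moment)", nm), 10)
  expect_length(grep("^(SRE|LRE|GLN|RLN|RP|LGRE|HGRE|SRLGE|SRHGE|LRLGE|LRHGE)\\(", nm), 44)
  expect_length(grep("^(ASM|Contrast|Homogeneity2|Entropy|Correlation|SumOfSquares)\\(", nm), 60)
  expect_length(grep("^LBP\\(", nm), 38)
  # a constant stacked map exercises every degenerate convention
  fc <- extract_features(structure(matrix(1100, 160, 192),
                                   class = c("stacked_map", "matrix")))
  expect_length(fc, 152)
  expect_true(all(is.finite(fc)))
})

test_that("intensity shifts move only the histogram mean", {
  s <- generate_subject("HCM", seed = 29)
  st <- unwrap_subject(s)
  f1 <- extract_features(st)
  st2 <- st; st2[] <- st[] + 137
  f2 <- extract_features(st2)
  expect_equal(unname(f2["Mean"] - f1["Mean"]), 137)
  keep <- setdiff(names(f1), "Mean")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-9)
})

test_that("landmark column cycling barely moves LBP bins on smooth phantoms", {
  sl <- make_annulus_slice(n = 96, r_endo = 14, r_epi = 24,
    value_fun = function(r, th) 1100 + 15 * sin(3 * th) + 2 * r)
  u <- unwrap_slice(sl)
  st <- stack_subject(rep(list(u), 5))
  f1 <- extract_features(st)
  st2 <- st[, c(49:192, 1:48)]
  class(st2) <- c("stacked_map", "matrix")
  f2 <- extract_features(st2)
  # tolerance reflects the changed interior support at the map's side edges
  lbp <- grep("^LBP\\(", names(f1))
  expect_lt(max(abs(f1[lbp] - f2[lbp])), 0.05)
})
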