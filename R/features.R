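#' Quantize a map to discrete gray levels
#'
#' Equal-width binning of the `[min, max]` range of this map into `n_levels`
#' levels `0..n_levels-1`; the maximum maps to the top level. A constant map
#' quantizes to level 0 everywhere (by convention, not an error). Because the
#' binning is min-max relative, co-occurrence and run-length features are
#' invariant to adding a constant to the map.
#'
#' @param map numeric matrix (finite values).
#' @param n_levels number of gray levels (default 32).
#' @return integer matrix of levels in `0..n_levels-1`.
#' @export
quantize <- function(map, n_levels = 32L) {
  stopifnot(n_levels >= 2L, all(is.finite(map)))
  lo <- min(map); hi <- max(map)
  if (hi == lo) return(matrix(0L, nrow(map), ncol(map)))
  q <- floor(n_levels * (map - lo) / (hi - lo))
  q[q >= n_levels] <- n_levels - 1L
  matrix(as.integer(q), nrow(map), ncol(map))
}

#' First-order histogram features
#'
#' Mean, population variance (1/N), skewness and kurtosis as standardized
#' 3rd/4th central moments, and standardized central moments of orders 5-10
#' (m_k / sigma^k). On a zero-variance map all standardized moments are
#' defined as 0.
#'
#' @param map numeric matrix (or vector) of pixel values, >= 2 pixels.
#' @return named numeric of length 10.
#' @export
histogram_features <- function(map) {
  v <- as.numeric(map)
  stopifnot(length(v) >= 2, all(is.finite(v)))
  m <- mean(v)
  d <- v - m
  var_p <- mean(d^2)
  out <- c(Mean = m, Variance = var_p)
  if (var_p == 0) {
    out <- c(out, Skewness = 0, Kurtosis = 0,
             structure(rep(0, 6), names = paste0("Moment", 5:10)))
  } else {
    s <- sqrt(var_p)
    std_mom <- vapply(3:10, function(k) mean(d^k) / s^k, 0)
    names(std_mom) <- c("Skewness", "Kurtosis", paste0("Moment", 5:10))
    out <- c(out, std_mom)
  }
  out
}

## the 4 standard direction offsets as (drow, dcol) per unit displacement;
## image convention, row index increasing downwards
.tex_directions <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

#' Gray-level co-occurrence features
#'
#' For each displacement d in `displacements`, symmetric co-occurrence counts
#' are accumulated over the four directions (0, 45, 90, 135 degrees) at
#' offset d and normalized to a joint probability p(i, j); six Haralick-type
#' statistics are emitted per displacement: angular second moment, contrast,
#' homogeneity (inverse difference moment, sum of p/(1+(i-j)^2)), entropy
#' (bits, 0 log 0 = 0), correlation, and sum of squares (variance about the
#' marginal mean). Pooling counts across directions (rather than averaging
#' per-direction feature values) is the package's convention; it yields
#' 6 x 10 = 60 features.
#'
#' @param qmap integer matrix of quantized levels `0..n_levels-1`.
#' @param n_levels number of gray levels of the quantization.
#' @param displacements integer pixel offsets (default 1:10).
#' @param directions subset of `c("0", "45", "90", "135")` to pool over
#'   (default all four).
#' @return named numeric of length `6 * length(displacements)`, feature-major
#'   (`ASM(1)..ASM(10), Contrast(1)..`). Degenerate marginals (sd 0) give
#'   correlation 0.
#' @export
glcm_features <- function(qmap, n_levels = max(qmap) + 1L,
                          displacements = 1:10,
                          directions = c("0", "45", "90", "135")) {
  K <- as.integer(n_levels)
  nr <- nrow(qmap); nc <- ncol(qmap)
  feats <- c("ASM", "Contrast", "Homogeneity2", "Entropy", "Correlation",
             "SumOfSquares")
  res <- matrix(NA_real_, length(feats), length(displacements),
                dimnames = list(feats, displacements))
  lev <- 0:(K - 1)
  for (di in seq_along(displacements)) {
    d <- displacements[di]
    counts <- numeric(K * K)
    for (off in .tex_directions()[match.arg(directions, several.ok = TRUE)]) {
      dr <- off[1] * d; dc <- off[2] * d
      r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
      c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
      if (r1 > r2 || c1 > c2) next
      a <- qmap[r1:r2, c1:c2, drop = FALSE]
      b <- qmap[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
      idx <- as.vector(a) * K + as.vector(b) + 1L
      tc <- tabulate(idx, nbins = K * K)
      counts <- counts + tc
      ## symmetric: count the reversed pair as well
      idx_t <- as.vector(b) * K + as.vector(a) + 1L
      counts <- counts + tabulate(idx_t, nbins = K * K)
    }
    if (sum(counts) == 0) stop("no valid pixel pairs at displacement ", d,
                               call. = FALSE)
    p <- matrix(counts / sum(counts), K, K)
    i <- matrix(lev, K, K); j <- t(i)
    px <- rowSums(p)
    mux <- sum(lev * px)
    sdx <- sqrt(sum((lev - mux)^2 * px))
    res["ASM", di] <- sum(p^2)
    res["Contrast", di] <- sum((i - j)^2 * p)
    res["Homogeneity2", di] <- sum(p / (1 + (i - j)^2))
    res["Entropy", di] <- -sum(ifelse(p > 0, p * log2(p), 0))
    res["Correlation", di] <- if (sdx == 0) 0 else
      (sum(i * j * p) - mux^2) / sdx^2   # symmetric p: mu_x = mu_y
    res["SumOfSquares", di] <- sum((i - mux)^2 * p)
  }
  structure(as.vector(t(res)),
            names = as.vector(vapply(feats, function(f)
              sprintf("%s(%d)", f, displacements), character(length(displacements)))))
}

## split a matrix into directional lines for run extraction
.dir_lines <- function(qmap, dir_name) {
  nr <- nrow(qmap); nc <- ncol(qmap)
  switch(dir_name,
    `0` = lapply(seq_len(nr), function(r) qmap[r, ]),
    `90` = lapply(seq_len(nc), function(c) qmap[, c]),
    ## 45 deg: lines along (-1,+1); traverse anti-diagonals (r+c constant)
    `45` = {
      rr <- as.vector(row(qmap)); cc <- as.vector(col(qmap))
      s <- rr + cc
      ord <- order(s, -rr)   # within a line, increasing column = decreasing row
      split(as.vector(qmap)[ord], s[ord])
    },
    ## 135 deg: lines along (-1,-1); traverse main diagonals (r-c constant)
    `135` = {
      rr <- as.vector(row(qmap)); cc <- as.vector(col(qmap))
      s <- rr - cc
      ord <- order(s, -rr)
      split(as.vector(qmap)[ord], s[ord])
    })
}

#' Gray-level run-length features
#'
#' For each of the four directions a run-length matrix p(i, j) counts maximal
#' runs of level i with length j; eleven statistics are emitted per direction:
#' SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE. Gray-level
#' weights use (i + 1) with levels indexed from 0, so low-gray-level emphasis
#' features are finite at level 0. 11 x 4 = 44 features.
#'
#' @inheritParams glcm_features
#' @return named numeric of length 44, feature-major
#'   (`SRE(0), SRE(45), ..., LRHGE(135)`).
#' @export
glrlm_features <- function(qmap, n_levels = max(qmap) + 1L) {
  if (length(qmap) == 0) stop("empty map", call. = FALSE)
  K <- as.integer(n_levels)
  n_p <- length(qmap)
  dirs <- names(.tex_directions())
  feats <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
             "SRLGE", "SRHGE", "LRLGE", "LRHGE")
  res <- matrix(NA_real_, length(feats), length(dirs),
                dimnames = list(feats, dirs))
  for (dn in dirs) {
    lines <- .dir_lines(qmap, dn)
    lv <- integer(0); ln <- integer(0)
    for (line in lines) {
      r <- rle(as.integer(line))
      lv <- c(lv, r$values); ln <- c(ln, r$lengths)
    }
    n_r <- length(lv)
    i1 <- lv + 1      # gray-level weight, levels indexed from 0
    j <- ln
    res["SRE", dn] <- sum(1 / j^2) / n_r
    res["LRE", dn] <- sum(j^2) / n_r
    res["GLN", dn] <- sum(tapply(rep(1, n_r), lv, sum)^2) / n_r
    res["RLN", dn] <- sum(tapply(rep(1, n_r), j, sum)^2) / n_r
    res["RP", dn] <- n_r / n_p
    res["LGRE", dn] <- sum(1 / i1^2) / n_r
    res["HGRE", dn] <- sum(i1^2) / n_r
    res["SRLGE", dn] <- sum(1 / (j^2 * i1^2)) / n_r
    res["SRHGE", dn] <- sum(i1^2 / j^2) / n_r
    res["LRLGE", dn] <- sum(j^2 / i1^2) / n_r
    res["LRHGE", dn] <- sum(j^2 * i1^2) / n_r
  }
  structure(as.vector(t(res)),
            names = as.vector(vapply(feats, function(f)
              sprintf("%s(%s)", f, dirs), character(length(dirs)))))
}

## rotation-invariant uniform (riu2) LBP code map; neighbors sampled
## bilinearly on a circle of radius R; tie (neighbor == center) counts as 1.
## Returns an integer matrix of codes 0..P+1 for interior pixels (NA at the
## margin where the neighborhood leaves the map).
lbp_code_map <- function(map, P = 36L, R = 2) {
  nr <- nrow(map); nc <- ncol(map)
  M <- floor(R) + 1L      # margin so every bilinear corner stays inside
  if (nr <= 2 * M || nc <= 2 * M)
    stop("map smaller than the LBP neighborhood", call. = FALSE)
  ri <- (M + 1):(nr - M); ci <- (M + 1):(nc - M)
  center <- map[ri, ci, drop = FALSE]
  npix <- length(center)
  ## ties (neighbor == center) count as 1; the tolerance absorbs bilinear
  ## round-off so exact ties are not broken by floating-point noise
  tol <- 1e-9 * max(abs(map), 1)
  bits <- matrix(FALSE, npix, P)
  for (p in seq_len(P)) {
    a <- 2 * pi * (p - 1) / P
    dx <- R * cos(a); dy <- R * sin(a)
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0; fy <- dy - y0
    nb <- (1 - fx) * (1 - fy) * map[ri + y0, ci + x0, drop = FALSE] +
          fx * (1 - fy) * map[ri + y0, ci + x0 + 1, drop = FALSE] +
          (1 - fx) * fy * map[ri + y0 + 1, ci + x0, drop = FALSE] +
          fx * fy * map[ri + y0 + 1, ci + x0 + 1, drop = FALSE]
    bits[, p] <- as.vector(nb) >= as.vector(center) - tol
  }
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  ones <- rowSums(bits)
  codes <- ifelse(trans <= 2, ones, P + 1)
  out <- matrix(NA_integer_, nr, nc)
  out[ri, ci] <- as.integer(codes)
  out
}

#' Rotation-invariant uniform LBP histogram
#'
#' Local binary pattern codes with `P` circular neighbors at radius `R`
#' (bilinear neighbor sampling; neighbor >= center sets the bit). The
#' rotation-invariant uniform (riu2) mapping assigns uniform patterns (at
#' most two 0/1 transitions around the circle) the count of set bits (0..P)
#' and all non-uniform patterns one extra code, giving P + 2 possible codes.
#' With the default P = 36 this is 38 histogram bins, reported normalized
#' over all pixels whose full neighborhood lies inside the map. Bins are
#' named `LBP(1)..LBP(P+2)`: bin b holds code b - 1.
#'
#' @param map numeric matrix.
#' @param P number of circular neighbors (default 36).
#' @param R neighborhood radius in pixels (default 2).
#' @return named numeric of length `P + 2` summing to 1.
#' @export
lbp_features <- function(map, P = 36L, R = 2) {
  codes <- lbp_code_map(map, P = P, R = R)
  codes <- codes[!is.na(codes)]
  h <- tabulate(codes + 1L, nbins = P + 2L)
  structure(h / sum(h), names = sprintf("LBP(%d)", seq_len(P + 2L)))
}

#' Feature extraction configuration
#'
#' @param n_levels gray levels for the min-max quantization feeding GLCM and
#'   GLRLM (default 32).
#' @param displacements GLCM pixel displacements (default 1:10).
#' @param lbp_P,lbp_R LBP neighbor count and radius.
#' @return a list of extraction parameters.
#' @export
feature_config <- function(n_levels = 32L, displacements = 1:10,
                           lbp_P = 36L, lbp_R = 2) {
  stopifnot(n_levels >= 2, length(displacements) >= 1, lbp_P >= 4, lbp_R > 0)
  list(n_levels = as.integer(n_levels), displacements = as.integer(displacements),
       lbp_P = as.integer(lbp_P), lbp_R = lbp_R)
}

#' Extract the full 152-feature texture vector from a stacked map
#'
#' Emits, in a fixed documented order: 10 histogram moments, 44 run-length
#' features (11 statistics x 4 directions), 60 co-occurrence features
#' (6 statistics x 10 displacements, direction-pooled), and 38 riu2 LBP
#' histogram bins — 152 features per subject. The stacked 5-slice map is
#' treated as one image.
#'
#' @param stacked a `stacked_map` (or any numeric matrix).
#' @param cfg a [feature_config()].
#' @return named numeric of length 152.
#' @export
extract_features <- function(stacked, cfg = feature_config()) {
  m <- unclass(stacked)
  attributes(m) <- list(dim = dim(stacked))
  q <- quantize(m, cfg$n_levels)
  c(histogram_features(m),
    glrlm_features(q, cfg$n_levels),
    glcm_features(q, cfg$n_levels, cfg$displacements),
    lbp_features(m, cfg$lbp_P, cfg$lbp_R))
}

#' Canonical names of the 152 texture features
#'
#' @param cfg a [feature_config()].
#' @return character vector of length 152.
#' @export
feature_names <- function(cfg = feature_config()) {
  dirs <- c("0", "45", "90", "135")
  glrlm <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
             "SRLGE", "SRHGE", "LRLGE", "LRHGE")
  glcm <- c("ASM", "Contrast", "Homogeneity2", "Entropy", "Correlation",
            "SumOfSquares")
  c(c("Mean", "Variance", "Skewness", "Kurtosis", paste0("Moment", 5:10)),
    as.vector(vapply(glrlm, function(f) sprintf("%s(%s)", f, dirs),
                     character(4))),
    as.vector(vapply(glcm, function(f) sprintf("%s(%d)", f, cfg$displacements),
                     character(length(cfg$displacements)))),
    sprintf("LBP(%d)", seq_len(cfg$lbp_P + 2L)))
}
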