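# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, closed forms), sharing no
# code with the package implementation.

oracle_moments <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  m <- sum(v) / n
  cm <- function(k) sum((v - m)^k) / n
  var_p <- cm(2)
  if (var_p == 0) return(c(m, 0, rep(0, 8)))
  s <- sqrt(var_p)
  c(m, var_p, cm(3) / s^3, cm(4) / s^4, cm(5) / s^5, cm(6) / s^6,
    cm(7) / s^7, cm(8) / s^8, cm(9) / s^9, cm(10) / s^10)
}

# explicit pixel-pair enumeration; dirs as (drow, dcol) unit offsets
oracle_glcm <- function(qmap, d, K,
                        dirs = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
  nr <- nrow(qmap); nc <- ncol(qmap)
  p <- matrix(0, K, K)
  for (off in dirs) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + off[1] * d; c2 <- c + off[2] * d
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- qmap[r, c] + 1; j <- qmap[r2, c2] + 1
        p[i, j] <- p[i, j] + 1
        p[j, i] <- p[j, i] + 1
      }
    }
  }
  p <- p / sum(p)
  lev <- 0:(K - 1)
  asm <- sum(p^2)
  contrast <- 0; hom <- 0; ent <- 0
  for (i in 1:K) for (j in 1:K) {
    contrast <- contrast + (lev[i] - lev[j])^2 * p[i, j]
    hom <- hom + p[i, j] / (1 + (lev[i] - lev[j])^2)
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  }
  px <- rowSums(p)
  mux <- sum(lev * px)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  corr <- if (sdx == 0) 0 else
    (sum(outer(lev, lev) * p) - mux^2) / sdx^2
  sos <- sum(outer((lev - mux)^2, rep(1, K)) * p)
  c(ASM = asm, Contrast = contrast, Homogeneity2 = hom, Entropy = ent,
    Correlation = corr, SumOfSquares = sos)
}

# scan each directional line, list maximal runs, accumulate the run-length
# matrix, compute the 11 statistics directly
oracle_glrlm <- function(qmap, dir_name, K) {
  nr <- nrow(qmap); nc <- ncol(qmap)
  step <- switch(dir_name, `0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                 `135` = c(-1, -1))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  maxlen <- max(nr, nc)
  p <- matrix(0, K, maxlen)
  for (st in starts) {
    r <- st[1]; c <- st[2]
    line <- integer(0)
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      line <- c(line, qmap[r, c])
      r <- r + step[1]; c <- c + step[2]
    }
    k <- 1
    while (k <= length(line)) {
      len <- 1
      while (k + len <= length(line) && line[k + len] == line[k]) len <- len + 1
      p[line[k] + 1, len] <- p[line[k] + 1, len] + 1
      k <- k + len
    }
  }
  n_r <- sum(p)
  n_p <- nr * nc
  iw <- (1:K)          # (i + 1) with levels from 0
  jw <- seq_len(maxlen)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in 1:K) for (j in jw) if (p[i, j] > 0) {
    sre <- sre + p[i, j] / j^2;      lre <- lre + p[i, j] * j^2
    lgre <- lgre + p[i, j] / iw[i]^2; hgre <- hgre + p[i, j] * iw[i]^2
    srlge <- srlge + p[i, j] / (j^2 * iw[i]^2)
    srhge <- srhge + p[i, j] * iw[i]^2 / j^2
    lrlge <- lrlge + p[i, j] * j^2 / iw[i]^2
    lrhge <- lrhge + p[i, j] * j^2 * iw[i]^2
  }
  c(SRE = sre / n_r, LRE = lre / n_r,
    GLN = sum(rowSums(p)^2) / n_r, RLN = sum(colSums(p)^2) / n_r,
    RP = n_r / n_p, LGRE = lgre / n_r, HGRE = hgre / n_r,
    SRLGE = srlge / n_r, SRHGE = srhge / n_r, LRLGE = lrlge / n_r,
    LRHGE = lrhge / n_r)
}

# naive per-pixel LBP with explicit rotation handling: threshold the P
# neighbors (own bilinear sampling), check uniformity by counting transitions
# over all rotations of the word, riu2 code = popcount or P+1
oracle_lbp <- function(map, P, R) {
  nr <- nrow(map); nc <- ncol(map)
  M <- floor(R) + 1
  bil <- function(x, y) {           # 0-based coords
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    v00 <- map[y0 + 1, x0 + 1]; v10 <- map[y0 + 1, x0 + 2]
    v01 <- map[y0 + 2, x0 + 1]; v11 <- map[y0 + 2, x0 + 2]
    (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
  }
  hist <- numeric(P + 2)
  tol <- 1e-9 * max(abs(map), 1)   # shared documented tie convention
  for (r in (M + 1):(nr - M)) for (c in (M + 1):(nc - M)) {
    ctr <- map[r, c]
    bits <- integer(P)
    for (p in 1:P) {
      a <- 2 * pi * (p - 1) / P
      bits[p] <- as.integer(bil((c - 1) + R * cos(a), (r - 1) + R * sin(a)) >= ctr - tol)
    }
    # rotation sweep: word is uniform iff some rotation sorts all ones together
    words <- vapply(0:(P - 1), function(k) {
      b <- bits[((seq_len(P) - 1 + k) %% P) + 1]
      sum(b * 2^(seq_len(P) - 1))
    }, 0)
    ones <- sum(bits)
    uniform_words <- vapply(0:P, function(m)
      if (m == 0) 0 else sum(2^(0:(m - 1))), 0)
    code <- if (min(words) %in% uniform_words) ones else P + 1
    hist[code + 1] <- hist[code + 1] + 1
  }
  hist / sum(hist)
}

# exhaustive Mann-Whitney pair counting
oracle_auc <- function(scores, positive) {
  xs <- scores[positive]; ys <- scores[!positive]
  total <- 0
  for (x in xs) for (y in ys)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(xs) * length(ys))
}

# ICC(3,1) via explicit ANOVA sums of squares on the long-format table
oracle_icc31 <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- anova(stats::aov(y ~ subj + rater, data = df))
  msr <- av["subj", "Mean Sq"]; mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}

# connected components (4-connectivity) by flood fill
oracle_cc_count <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c)); lab[r, c] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          rr <- q[1] + d[1]; cc <- q[2] + d[2]
          if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  cur
}
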