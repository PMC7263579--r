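#' Unwrapping configuration
#'
#' The myocardium of each slice is resampled onto a standardized rectangle of
#' `rows` radial x `cols` angular samples. The default 32 x 192 preserves six
#' 32 x 32 angular segments per slice; the constraint `cols == 6 * rows`
#' keeps that property at every preset (`R16` = 16 x 96, `R32` = 32 x 192,
#' `R64` = 64 x 384).
#'
#' @param rows radial samples (row 0 = endocardial border).
#' @param preset one of `"R16"`, `"R32"`, `"R64"`; overrides `rows` if given.
#' @return list with `rows`, `cols`, `interpolation`, `direction`.
#' @export
unwrap_config <- function(rows = 32L, preset = NULL) {
  if (!is.null(preset)) {
    rows <- switch(match.arg(preset, c("R16", "R32", "R64")),
                   R16 = 16L, R32 = 32L, R64 = 64L)
  }
  rows <- as.integer(rows)
  stopifnot(rows >= 2L)
  list(rows = rows, cols = 6L * rows,
       interpolation = "linear", direction = "clockwise")
}

#' Rasterize the myocardial annulus to a binary mask
#'
#' Marks pixels whose centres lie inside the epicardial contour and outside
#' the endocardial contour (point-in-polygon on pixel centres). Contours are
#' 0-based (x, y) coordinate matrices.
#'
#' @param endo,epi closed contour polygons, n x 2 matrices of (x, y).
#' @param grid_shape c(nrow, ncol) of the target grid.
#' @return logical matrix of `grid_shape`.
#' @export
rasterize_myocardium <- function(endo, epi, grid_shape) {
  .check_contour(endo); .check_contour(epi)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  xg <- rep(0:(nc - 1), each = nr)
  yg <- rep(0:(nr - 1), times = nc)
  in_epi <- pracma::inpolygon(xg, yg, epi[, 1], epi[, 2], boundary = TRUE)
  in_endo <- pracma::inpolygon(xg, yg, endo[, 1], endo[, 2], boundary = FALSE)
  if (!all(in_epi[in_endo]))
    stop("contours cross: endocardial contour not enclosed by epicardial",
         call. = FALSE)
  matrix(in_epi & !in_endo, nr, nc)
}

.check_contour <- function(p) {
  if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 8)
    stop("contour must be an n x 2 matrix with n >= 8", call. = FALSE)
  if (any(!is.finite(p))) stop("contour has non-finite points", call. = FALSE)
  invisible(p)
}

## distance from `center` to the (first) intersection of the ray at angle
## `theta` (y-down frame) with a closed polygon; piecewise-linear contour
.ray_radius <- function(center, theta, poly) {
  dx <- cos(theta); dy <- sin(theta)
  p1 <- poly
  p2 <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ## solve center + t*d = p1 + u*(p2-p1), t>0, 0<=u<1
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  wx <- p1[, 1] - center[1]; wy <- p1[, 2] - center[2]
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-12
  u <- (wx * dy - wy * dx) / den
  t <- (wx * ey - wy * ex) / den
  hit <- ok & u >= 0 & u < 1 & t > 0
  if (!any(hit)) return(NA_real_)
  min(t[hit])
}

## mask-aware bilinear interpolation of grid values at 0-based (x, y) points;
## pixels that are non-finite or exactly 0 count as background and are
## excluded with weight renormalization
.bilinear <- function(values, x, y) {
  nr <- nrow(values); nc <- ncol(values)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  wsum <- numeric(length(x))
  for (k in 1:4) {
    xi <- x0 + (k == 2 | k == 4)   # 1:(0,0) 2:(1,0) 3:(0,1) 4:(1,1)
    yi <- y0 + (k >= 3)
    w <- (if (k %in% c(2, 4)) fx else 1 - fx) *
         (if (k >= 3) fy else 1 - fy)
    inside <- xi >= 0 & xi < nc & yi >= 0 & yi < nr
    v <- rep(NA_real_, length(x))
    v[inside] <- values[cbind(yi[inside] + 1, xi[inside] + 1)]
    valid <- inside & is.finite(v) & v != 0
    w[!valid] <- 0
    v[!valid] <- 0
    out <- out + w * v
    wsum <- wsum + w
  }
  res <- ifelse(wsum > 0, out / wsum, NA_real_)
  ## samples whose whole 2x2 support is background (possible when contours
  ## were drawn loosely, e.g. re-contoured by another observer): take the
  ## nearest foreground pixel within a 4-pixel radius
  for (i in which(is.na(res))) {
    rc <- round(y[i]); cc <- round(x[i])
    rr <- max(0, rc - 4):min(nr - 1, rc + 4)
    cs <- max(0, cc - 4):min(nc - 1, cc + 4)
    win <- values[rr + 1, cs + 1, drop = FALSE]
    ok <- which(is.finite(win) & win != 0, arr.ind = TRUE)
    if (nrow(ok) == 0) next
    d2 <- (rr[ok[, 1]] - y[i])^2 + (cs[ok[, 2]] - x[i])^2
    res[i] <- win[ok[which.min(d2), , drop = FALSE]]
  }
  res
}

#' Unwrap one slice to a standardized rectangular map
#'
#' For each of `cols` angular positions, starting at the landmark angle and
#' proceeding clockwise in displayed-image orientation (y axis down), `rows`
#' samples are taken at equal fractional depths between the endocardial and
#' epicardial border radii along the ray from the cavity centre (the
#' endocardial contour centroid). Angles are sampled at column centres
#' ((c + 0.5) / cols of a turn) and depths at ((r + 0.5) / rows) of the local
#' wall, so all samples are strictly interior. T1 values are obtained by
#' bilinear interpolation; background pixels (0 or non-finite) are excluded
#' with weight renormalization so border samples are not diluted.
#'
#' @param slice a `t1_slice` (or any list with `values`, `endo`, `epi`,
#'   `landmark`).
#' @param cfg an [unwrap_config()].
#' @return object of class `rect_map`: `rows` x `cols` matrix of ms values
#'   with attribute `slice_index`; row 1 is the endocardial border, the
#'   bottom-left entry sits at the landmark.
#' @export
unwrap_slice <- function(slice, cfg = unwrap_config()) {
  .check_contour(slice$endo); .check_contour(slice$epi)
  stopifnot(length(slice$landmark) == 2, all(is.finite(slice$landmark)))
  center <- colMeans(slice$endo)
  lm <- as.numeric(slice$landmark)
  theta0 <- atan2(lm[2] - center[2], lm[1] - center[1])

  rows <- cfg$rows; cols <- cfg$cols
  ## y-down frame: increasing atan2 angle appears clockwise on screen
  thetas <- theta0 + 2 * pi * (seq_len(cols) - 0.5) / cols

  r_endo <- vapply(thetas, function(t) .ray_radius(center, t, slice$endo), 0)
  r_epi <- vapply(thetas, function(t) .ray_radius(center, t, slice$epi), 0)
  bad <- !is.finite(r_endo) | !is.finite(r_epi) | r_epi <= r_endo
  if (any(bad))
    stop(sprintf("ray at %.1f deg from landmark fails to cross both contours",
                 360 * (which(bad)[1] - 0.5) / cols), call. = FALSE)

  depth <- (seq_len(rows) - 0.5) / rows
  rad <- outer(depth, r_epi - r_endo) + matrix(r_endo, rows, cols, byrow = TRUE)
  thm <- matrix(thetas, rows, cols, byrow = TRUE)
  xs <- center[1] + rad * cos(thm)
  ys <- center[2] + rad * sin(thm)
  vals <- .bilinear(slice$values, as.vector(xs), as.vector(ys))
  if (anyNA(vals))
    stop("unwrapped sample fell entirely on background; check contours",
         call. = FALSE)
  structure(matrix(vals, rows, cols),
            slice_index = slice$slice_index, class = c("rect_map", "matrix"))
}

#' Stack five rectangular maps into one subject-level map
#'
#' Vertical concatenation in slice order, base at the top, apex at the
#' bottom; values are untouched.
#'
#' @param maps list of 5 `rect_map`s with identical dimensions.
#' @return `(5*rows) x cols` matrix of class `stacked_map`.
#' @export
stack_subject <- function(maps) {
  if (length(maps) != 5L) stop("expected 5 maps, got ", length(maps),
                               call. = FALSE)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps have mixed shapes", call. = FALSE)
  structure(do.call(rbind, lapply(maps, unclass)),
            rows_per_slice = dims[1, 1], class = c("stacked_map", "matrix"))
}

#' Unwrap and stack one subject
#'
#' @param subject a `t1_subject`.
#' @param cfg an [unwrap_config()].
#' @return a `stacked_map`.
#' @export
unwrap_subject <- function(subject, cfg = unwrap_config()) {
  stack_subject(lapply(subject$slices, unwrap_slice, cfg = cfg))
}

#' Global and segmental myocardial T1
#'
#' Global native T1 is the mean over all myocardial pixels of the 5 slices
#' (myocardium rasterized from the contours). Segmental values are the means
#' of 6 contiguous angular blocks per unwrapped slice (block 1 starting at
#' the landmark column), 30 values per subject — the standard 6-segments-per-
#' slice reading used as the pattern-independent baseline.
#'
#' @param subject a `t1_subject`.
#' @param cfg an [unwrap_config()].
#' @return list with `global` (ms) and `segmental` (numeric length 30, named
#'   `s<slice>_seg<block>`).
#' @export
global_segmental_t1 <- function(subject, cfg = unwrap_config()) {
  vals <- numeric(0)
  seg <- numeric(0)
  block <- cfg$cols / 6L
  for (s in seq_along(subject$slices)) {
    sl <- subject$slices[[s]]
    mask <- rasterize_myocardium(sl$endo, sl$epi, dim(sl$values))
    v <- sl$values[mask]
    vals <- c(vals, v[is.finite(v) & v != 0])
    m <- unwrap_slice(sl, cfg)
    for (b in 1:6) {
      cols_b <- ((b - 1) * block + 1):(b * block)
      seg <- c(seg, structure(mean(m[, cols_b]),
                              names = sprintf("s%d_seg%d", s, b)))
    }
  }
  list(global = mean(vals), segmental = seg)
}
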