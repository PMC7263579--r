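#' Intraclass correlation from a two-way mixed-effects model
#'
#' Agreement of repeated feature measurements (subjects x raters) from the
#' two-way ANOVA decomposition. The default is the single-measure consistency
#' form ICC(3,1) = (MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error);
#' `type = "agreement"` gives the absolute-agreement variant, which also
#' charges the rater mean-square to the denominator.
#'
#' @param table numeric matrix, n subjects x k raters (n >= 3, k >= 2, no
#'   missing values).
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return the ICC value (scalar).
#' @export
icc_two_way_mixed <- function(table, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  if (any(!is.finite(table))) stop("missing entries in rating table",
                                   call. = FALSE)
  row_m <- rowMeans(table); col_m <- colMeans(table); g <- mean(table)
  ss_rows <- k * sum((row_m - g)^2)
  ss_cols <- n * sum((col_m - g)^2)
  ss_err <- sum((table - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + g)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * abs(g + 1)) {
    warning("zero between-subject variance; ICC defined as 0")
    return(0)
  }
  den <- switch(type,
    consistency = msr + (k - 1) * mse,
    agreement = msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (den <= 0) { warning("degenerate denominator; ICC defined as 0"); return(0) }
  (msr - mse) / den
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement between two paired measurement series:
#' bias = mean(a - b), limits = bias +/- 1.96 SD(a - b) (sample SD, n - 1).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `bias`, `loa_lower`, `loa_upper`, `sd`, `differences`,
#'   `means` (the per-pair means, for plotting).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd = s, differences = d, means = (a + b) / 2)
}

## radially jitter a closed contour: smooth per-vertex radial noise (circular
## moving average) emulating a re-drawn contour
.jitter_contour <- function(pts, center, sd, window = 9L) {
  n <- nrow(pts)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
  noise <- stats::rnorm(n, 0, sd)
  half <- window %/% 2
  sm <- vapply(seq_len(n), function(i) {
    idx <- ((i - half - 1):(i + half - 1)) %% n + 1
    mean(noise[idx])
  }, 0)
  ## smoothing shrinks the SD; rescale back to the requested magnitude
  if (stats::sd(sm) > 0) sm <- sm * sd / stats::sd(sm)
  r2 <- pmax(r + sm, 0.5)
  cbind(x = center[1] + r2 * cos(th), y = center[2] + r2 * sin(th))
}

#' Emulate re-contouring of a subject
#'
#' Returns a copy of the subject whose endo- and epicardial contours have
#' been perturbed by smooth seeded radial jitter (default SD 1 pixel),
#' emulating an observer re-drawing the delineation. The epicardial contour
#' is kept at least 2 pixels outside the endocardial one so the slice remains
#' unwrappable. Pixel values are untouched.
#'
#' @param subject a `t1_subject`.
#' @param sd radial jitter SD in pixels.
#' @param seed integer seed.
#' @return a `t1_subject` with perturbed contours.
#' @export
perturb_contours <- function(subject, sd = 1, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- subject
  for (s in seq_along(out$slices)) {
    sl <- out$slices[[s]]
    center <- colMeans(sl$endo)
    endo2 <- .jitter_contour(sl$endo, center, sd)
    epi2 <- .jitter_contour(sl$epi, center, sd)
    ## enforce a minimal wall: push epi out where it comes too close
    re <- sqrt(rowSums(sweep(endo2, 2, center)^2))
    rp <- sqrt(rowSums(sweep(epi2, 2, center)^2))
    rp <- pmax(rp, re + 2)
    th <- atan2(epi2[, 2] - center[2], epi2[, 1] - center[1])
    out$slices[[s]]$endo <- endo2
    out$slices[[s]]$epi <- cbind(x = center[1] + rp * cos(th),
                                 y = center[2] + rp * sin(th))
  }
  out
}

#' Observer-variability study on phantoms
#'
#' Emulates the intra-/inter-observer experiment: each "rater" is one
#' re-contouring of every subject (rater 1 = the original contours, raters
#' 2..k = seeded contour jitter), after which the full unwrap + feature
#' extraction pipeline is re-run. The result is one n_subjects x n_raters
#' rating table per feature, ready for [icc_two_way_mixed()] and
#' [bland_altman()].
#'
#' @param subjects list of `t1_subject`s.
#' @param features character vector of feature names to tabulate (default:
#'   all 152).
#' @param n_raters number of raters including the original (>= 2).
#' @param jitter_sd contour jitter SD in pixels.
#' @param seed master seed.
#' @param ucfg an [unwrap_config()].
#' @param fcfg a [feature_config()].
#' @return named list of n x n_raters matrices, one per feature.
#' @export
observer_study <- function(subjects, features = NULL, n_raters = 2L,
                           jitter_sd = 1, seed = 1L,
                           ucfg = unwrap_config(), fcfg = feature_config()) {
  stopifnot(n_raters >= 2)
  if (is.null(features)) features <- feature_names(fcfg)
  n <- length(subjects)
  vals <- array(NA_real_, c(n, n_raters, length(features)),
                dimnames = list(NULL, NULL, features))
  for (i in seq_len(n)) {
    for (r in seq_len(n_raters)) {
      sub <- if (r == 1) subjects[[i]] else
        perturb_contours(subjects[[i]], sd = jitter_sd,
                         seed = seed + 1000L * r + i)
      fv <- extract_features(unwrap_subject(sub, ucfg), fcfg)
      vals[i, r, ] <- fv[features]
    }
  }
  out <- lapply(seq_along(features), function(j) vals[, , j, drop = TRUE])
  names(out) <- features
  out
}
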