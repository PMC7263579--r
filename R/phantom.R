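#' Phantom geometry parameters
#'
#' Geometry of the synthetic short-axis phantom: an annular myocardium with
#' mild eccentricity, wall thickness and cavity radius decreasing from base
#' to apex. The defaults give a 96 x 96 grid at 2.1 x 2.1 mm pixels, the
#' in-plane resolution typical of native T1 mapping.
#'
#' @param grid_size image size in pixels (square grid).
#' @param pixel_size pixel edge length in mm.
#' @param endo_radius_mm endocardial radius per slice, base to apex (length 5).
#' @param eccentricity relative flattening of the annulus (0 = circular).
#' @param n_contour_points number of vertices per contour polygon.
#' @return a list of geometry parameters.
#' @export
geometry_defaults <- function(grid_size = 96L, pixel_size = 2.1,
                              endo_radius_mm = seq(23, 16, length.out = 5),
                              eccentricity = 0.08,
                              n_contour_points = 96L) {
  stopifnot(grid_size >= 32L, pixel_size > 0, length(endo_radius_mm) == 5L,
            all(endo_radius_mm > 0), eccentricity >= 0, eccentricity < 0.5,
            n_contour_points >= 8L)
  list(grid_size = as.integer(grid_size), pixel_size = pixel_size,
       endo_radius_mm = endo_radius_mm, eccentricity = eccentricity,
       n_contour_points = as.integer(n_contour_points))
}

## radius of the (mildly elliptical) endocardial border at polar angle theta,
## in pixels; a = semi-major (x), b = a*(1-ecc)
.ellipse_radius <- function(theta, a, ecc) {
  b <- a * (1 - ecc)
  (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

## smallest signed circular distance between angles (radians)
.ang_diff <- function(t1, t2) {
  d <- (t1 - t2) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Simulate one subject (5 short-axis T1 slices with contours and landmark)
#'
#' Renders five annular myocardial T1 slices, base to apex, for one synthetic
#' subject. The myocardial T1 field is the sum of a subject-level global mean
#' (drawn from the cohort spec), a cohort-specific texture component, and
#' i.i.d. Gaussian pixel noise. Texture archetypes: controls are homogeneous;
#' HCM receives 2-5 elliptical patches of elevated T1 inside a thickened
#' septal sector (patch angles shared across slices, emulating spatially
#' coherent regional fibrosis); DCM receives scattered small high-T1 clusters
#' throughout the wall (diffuse interstitial fibrosis). Background pixels are
#' 0. Each slice carries closed endo-/epicardial contour polygons (0-based
#' (x, y) pixel coordinates, x = column, y = row down) and one landmark on the
#' epicardial border at the inferior junction of the annulus, emulating the
#' inferior right-ventricular insertion point.
#'
#' @param spec a [cohort_defaults()] object (or cohort name).
#' @param geometry a [geometry_defaults()] list.
#' @param seed integer seed; output is deterministic in (spec, geometry, seed).
#' @param subject_id identifier string stored on the subject.
#' @return an object of class `t1_subject`: list with `subject_id`, `cohort`,
#'   `seed`, `global_mean` (the subject-level mean actually drawn), and
#'   `slices`, a list of 5 `t1_slice` objects (fields `values`, `pixel_size`,
#'   `endo`, `epi`, `landmark`, `patch_mask`, `myo_mask`, `slice_index`).
#' @export
generate_subject <- function(spec, geometry = geometry_defaults(), seed = 1L,
                             subject_id = NULL) {
  if (is.character(spec)) spec <- cohort_defaults(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed)
  if (is.null(subject_id)) subject_id <- sprintf("%s_%06d", spec$name, seed)

  g <- geometry
  px <- g$pixel_size
  n <- g$grid_size
  ctr0 <- (n - 1) / 2

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  mu <- rnorm(1, spec$t1_mean, spec$t1_sd_between_subjects)

  ## per-slice baseline wall thickness (mm), thinning base -> apex
  wr <- spec$wall_thickness_range
  w_base_mm <- switch(spec$texture_kind,
    patchy = seq(wr[1] + 3, wr[1], length.out = 5),
    seq(wr[2], wr[1], length.out = 5))
  theta_sept <- pi            # septal sector centre (left of the cavity)
  sept_sd <- 0.55             # angular width (rad) of the thickened sector

  ## HCM: patch count and angles drawn once per subject, shared across slices
  n_patch <- 0L; patch_angles <- numeric(0)
  if (spec$texture_kind == "patchy") {
    pr <- spec$patch_count_range
    n_patch <- sample(seq.int(pr[1], pr[2]), 1L)
    ## candidate angles spaced so patches stay disjoint at every slice radius
    cand <- theta_sept + seq(-1.1, 1.1, length.out = 5L)
    patch_angles <- sort(sample(cand, n_patch)) + runif(n_patch, -0.04, 0.04)
    patch_depth <- runif(n_patch, 0.3, 0.7)   # fractional depth in the wall
  }

  ## pixel coordinate grids (0-based x = column, y = row)
  xg <- matrix(rep(0:(n - 1), each = n), n, n)   # x varies by column
  yg <- matrix(rep(0:(n - 1), times = n), n, n)  # y varies by row

  slices <- vector("list", 5L)
  for (s in 1:5) {
    a_px <- g$endo_radius_mm[s] / px
    w_px0 <- w_base_mm[s] / px
    cx <- ctr0 + c(0, 0.8, -0.6, 0.4, -0.3)[s]
    cy <- ctr0 + c(0, -0.5, 0.7, -0.4, 0.2)[s]

    wall_at <- function(theta) {
      w <- rep(w_px0, length(theta))
      if (spec$texture_kind == "patchy") {
        extra <- (wr[2] - w_base_mm[s]) / px
        w <- w + pmax(0, extra) * exp(-(.ang_diff(theta, theta_sept) / sept_sd)^2)
      }
      w
    }
    endo_at <- function(theta) .ellipse_radius(theta, a_px, g$eccentricity)
    epi_at <- function(theta) endo_at(theta) + wall_at(theta)

    if (min(wall_at(seq(0, 2 * pi, length.out = 720))) < 2)
      stop("wall thickness below 2 pixels at slice ", s,
           "; unwrappable at this grid", call. = FALSE)

    dx <- xg - cx; dy <- yg - cy
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    re <- endo_at(th); rp <- epi_at(th)
    myo <- r >= re & r <= rp

    vals <- matrix(0, n, n)
    noise <- matrix(rnorm(n * n, 0, spec$diffuse_noise_sd), n, n)
    field <- mu + noise

    patch_mask <- matrix(FALSE, n, n)
    if (spec$texture_kind == "patchy") {
      for (k in seq_len(n_patch)) {
        thk <- patch_angles[k]
        rk <- endo_at(thk) + patch_depth[k] * wall_at(thk)
        pcx <- cx + rk * cos(thk); pcy <- cy + rk * sin(thk)
        ## ellipse elongated along the wall (tangential axis)
        ux <- -sin(thk); uy <- cos(thk)              # tangential unit vector
        vx <- cos(thk);  vy <- sin(thk)              # radial unit vector
        t_len <- 1.7; r_len <- 1.2
        et <- ((xg - pcx) * ux + (yg - pcy) * uy) / t_len
        er <- ((xg - pcx) * vx + (yg - pcy) * vy) / r_len
        patch_mask <- patch_mask | (et^2 + er^2 <= 1)
      }
      patch_mask <- patch_mask & myo
      ## centre the texture component so the subject's global mean stays at
      ## the drawn cohort-level value (effect size lives in the mean, texture
      ## in the spatial pattern)
      field <- field + spec$patch_t1_elevation *
        (patch_mask - mean(patch_mask[myo]))
    } else if (spec$texture_kind == "diffuse") {
      idx <- which(myo)
      n_clust <- max(1L, round(0.035 * length(idx)))
      centers <- sample(idx, n_clust)
      ccx <- xg[centers]; ccy <- yg[centers]
      for (k in seq_len(n_clust)) {
        d2 <- (xg - ccx[k])^2 + (yg - ccy[k])^2
        patch_mask <- patch_mask | (d2 <= 1.3^2)
      }
      patch_mask <- patch_mask & myo
      field <- field + spec$patch_t1_elevation *
        (patch_mask - mean(patch_mask[myo]))
    }

    vals[myo] <- field[myo]
    if (any(vals[myo] <= 0))
      vals[myo] <- pmax(vals[myo], 1)   # T1 strictly positive

    thc <- 2 * pi * (seq_len(g$n_contour_points) - 1) / g$n_contour_points
    endo_pts <- cbind(x = cx + endo_at(thc) * cos(thc),
                      y = cy + endo_at(thc) * sin(thc))
    epi_pts <- cbind(x = cx + epi_at(thc) * cos(thc),
                     y = cy + epi_at(thc) * sin(thc))
    ## inferior point of the annulus: y-down frame, +y is inferior
    lm_theta <- pi / 2
    landmark <- c(x = cx + epi_at(lm_theta) * cos(lm_theta),
                  y = cy + epi_at(lm_theta) * sin(lm_theta))

    slices[[s]] <- structure(list(
      values = vals, pixel_size = px, endo = endo_pts, epi = epi_pts,
      landmark = landmark, patch_mask = patch_mask, myo_mask = myo,
      slice_index = s - 1L), class = "t1_slice")
  }

  structure(list(subject_id = subject_id, cohort = spec$name, seed = seed,
                 global_mean = mu, slices = slices),
            class = "t1_subject")
}

#' @export
print.t1_subject <- function(x, ...) {
  n <- nrow(x$slices[[1]]$values)
  cat(sprintf("t1_subject '%s' (%s): 5 slices, %dx%d grid, seed %d\n",
              x$subject_id, x$cohort, n, n, x$seed))
  invisible(x)
}

#' Simulate a three-cohort phantom dataset
#'
#' Generates `sizes["control"]` + `sizes["HCM"]` + `sizes["DCM"]` subjects.
#' Each subject receives its own seed derived from the master seed by a fixed
#' counter scheme, so any subject is reproducible independently of generation
#' order.
#'
#' @param sizes named or positional integer vector of length 3:
#'   (control, HCM, DCM) subject counts, each >= 0, not all 0.
#' @param seed master seed.
#' @param geometry a [geometry_defaults()] list.
#' @return list with `subjects` (list of `t1_subject`) and `labels` (factor
#'   with levels control, HCM, DCM, aligned with `subjects`).
#' @export
generate_dataset <- function(sizes, seed = 1L, geometry = geometry_defaults()) {
  stopifnot(length(sizes) == 3L, all(sizes >= 0))
  if (sum(sizes) == 0) stop("all cohort sizes are zero", call. = FALSE)
  cohorts <- c("control", "HCM", "DCM")
  if (!is.null(names(sizes))) sizes <- sizes[cohorts]
  seed <- as.integer(seed)
  labels <- factor(rep(cohorts, times = sizes), levels = cohorts)
  subjects <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sub_seed <- (seed %% 19777L) * 100000L + i   # counter substream, < 2^31
    subjects[[i]] <- generate_subject(
      cohort_defaults(as.character(labels[i])), geometry, seed = sub_seed,
      subject_id = sprintf("S%03d_%s", i, labels[i]))
  }
  list(subjects = subjects, labels = labels)
}

## save/restore the global RNG state so simulators do not clobber it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
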