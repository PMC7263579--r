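#' Default cohort specification
#'
#' Returns the parameters used to simulate subjects of one cohort. Global
#' native T1 means and between-subject SDs follow the reference clinical
#' values for healthy controls (1071 +/- 32 ms), hypertrophic cardiomyopathy
#' (HCM, 1096 +/- 38 ms) and dilated cardiomyopathy (DCM, 1123 +/- 38 ms).
#' The spatial texture archetype differs per cohort: controls are
#' homogeneous; HCM carries a small number of patchy T1 elevations co-located
#' with a thickened septal sector; DCM carries diffuse scattered small-scale
#' elevations.
#'
#' @param name cohort name, one of `"control"`, `"HCM"`, `"DCM"`.
#' @return an object of class `cohort_spec`: a list with fields `name`,
#'   `t1_mean` (ms), `t1_sd_between_subjects` (ms), `texture_kind`,
#'   `patch_count_range` (HCM only), `patch_t1_elevation` (ms),
#'   `diffuse_noise_sd` (ms, pixel noise), `wall_thickness_range` (mm).
#' @export
#' @examples
#' cohort_defaults("control")$t1_mean  # 1071
cohort_defaults <- function(name) {
  specs <- list(
    control = list(
      name = "control", t1_mean = 1071, t1_sd_between_subjects = 32,
      texture_kind = "homogeneous", patch_count_range = NULL,
      patch_t1_elevation = 0, diffuse_noise_sd = 25,
      wall_thickness_range = c(8, 11)),
    HCM = list(
      name = "HCM", t1_mean = 1096, t1_sd_between_subjects = 38,
      texture_kind = "patchy", patch_count_range = c(2L, 5L),
      patch_t1_elevation = 90, diffuse_noise_sd = 25,
      wall_thickness_range = c(9, 19)),
    DCM = list(
      name = "DCM", t1_mean = 1123, t1_sd_between_subjects = 38,
      texture_kind = "diffuse", patch_count_range = NULL,
      patch_t1_elevation = 60, diffuse_noise_sd = 25,
      wall_thickness_range = c(8, 12))
  )
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(specs))))
    stop("unknown cohort name: ", deparse(substitute(name)),
         " (expected one of 'control', 'HCM', 'DCM')", call. = FALSE)
  structure(specs[[name]], class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec:", x$name, "\n")
  cat(sprintf("  global T1: %g +/- %g ms (between subjects)\n",
              x$t1_mean, x$t1_sd_between_subjects))
  cat("  texture:", x$texture_kind, "\n")
  if (!is.null(x$patch_count_range))
    cat(sprintf("  patches: %d-%d, +%g ms\n", x$patch_count_range[1],
                x$patch_count_range[2], x$patch_t1_elevation))
  invisible(x)
}
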