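#' Write a subject to disk (per-slice NIfTI + JSON sidecar)
#'
#' Writes the 5 T1 slices as float32 NIfTI files `slice_1.nii` ..
#' `slice_5.nii` (values in ms) and a sidecar `subject.json` holding, per
#' slice, the contours as ordered (x, y) pixel-coordinate lists (0-based,
#' x = column), the landmark, plus cohort label and seed.
#'
#' @param subject a `t1_subject`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(subject$slices)) {
    sl <- subject$slices[[s]]
    img <- RNifti::asNifti(sl$values, datatype = "float")
    RNifti::writeNifti(img, file.path(dir, sprintf("slice_%d.nii", s)))
  }
  sidecar <- list(
    subject_id = subject$subject_id,
    cohort = subject$cohort,
    seed = subject$seed,
    pixel_size = subject$slices[[1]]$pixel_size,
    slices = lapply(subject$slices, function(sl) list(
      endo = unname(as.matrix(sl$endo)),
      epi = unname(as.matrix(sl$epi)),
      landmark = unname(as.numeric(sl$landmark)))))
  jsonlite::write_json(sidecar, file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject written by [write_subject()]
#'
#' Validates the on-disk record: exactly 5 slices, closed contours with at
#' least 8 points each, and a landmark inside the image.
#'
#' @param dir directory holding `slice_1.nii..slice_5.nii` + `subject.json`.
#' @return a `t1_subject` (without generator-only fields such as the patch
#'   mask).
#' @export
read_subject <- function(dir) {
  sc_path <- file.path(dir, "subject.json")
  if (!file.exists(sc_path)) stop("missing sidecar: ", sc_path, call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (length(sc$slices$endo) != 5 && (is.null(nrow(sc$slices)) ||
      length(sc$slices$landmark) != 5))
    {} # structure checked below via slice count
  nii <- file.path(dir, sprintf("slice_%d.nii", 1:5))
  missing <- nii[!file.exists(nii)]
  if (length(missing))
    stop("expected 5 slices; missing ", basename(missing[1]), call. = FALSE)
  get_slice <- function(field, s) {
    if (is.data.frame(sc$slices)) sc$slices[[field]][[s]]
    else sc$slices[[s]][[field]]
  }
  n_sl <- if (is.data.frame(sc$slices)) nrow(sc$slices) else length(sc$slices)
  if (n_sl != 5) stop("expected 5 slices in sidecar, found ", n_sl,
                      call. = FALSE)
  slices <- vector("list", 5L)
  for (s in 1:5) {
    vals <- matrix(as.numeric(RNifti::readNifti(nii[s])),
                   nrow = dim(RNifti::readNifti(nii[s]))[1])
    endo <- as.matrix(get_slice("endo", s))
    epi <- as.matrix(get_slice("epi", s))
    lm <- as.numeric(get_slice("landmark", s))
    .check_contour(endo); .check_contour(epi)
    if (lm[1] < 0 || lm[1] > ncol(vals) - 1 || lm[2] < 0 ||
        lm[2] > nrow(vals) - 1)
      stop("landmark outside image at slice ", s, call. = FALSE)
    colnames(endo) <- colnames(epi) <- c("x", "y")
    slices[[s]] <- structure(list(
      values = vals, pixel_size = sc$pixel_size, endo = endo, epi = epi,
      landmark = c(x = lm[1], y = lm[2]), slice_index = s - 1L),
      class = "t1_slice")
  }
  structure(list(subject_id = sc$subject_id, cohort = sc$cohort,
                 seed = sc$seed, slices = slices), class = "t1_subject")
}

#' Write a feature table to CSV
#'
#' One row per subject: `subject_id`, `label`, then the 152 canonical feature
#' columns in their documented order.
#'
#' @param X numeric matrix, subjects x features, with column names.
#' @param subject_ids character vector of unique ids.
#' @param labels cohort labels aligned with rows.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_features <- function(X, subject_ids, labels, path) {
  stopifnot(nrow(X) == length(subject_ids), nrow(X) == length(labels))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids", call. = FALSE)
  df <- data.frame(subject_id = subject_ids, label = as.character(labels),
                   X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return list with `X` (numeric matrix), `subject_ids`, `labels`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, !(names(df) %in% c("subject_id", "label")),
                    drop = FALSE])
  list(X = X, subject_ids = df$subject_id,
       labels = factor(df$label, levels = c("control", "HCM", "DCM")))
}

#' Pipeline configuration
#'
#' Bundles the knobs of the full pipeline into one serializable object.
#'
#' @param preset unwrap resolution preset (`"R16"`, `"R32"`, `"R64"`).
#' @param n_levels quantization levels.
#' @param lbp_R LBP radius in pixels.
#' @param classifier classifier name.
#' @param folds CV folds.
#' @param k number of features to select.
#' @param seed master seed.
#' @param global_norm global-normalization flag.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "R32", n_levels = 32L, lbp_R = 2,
                            classifier = "linear-svm", folds = 10L, k = 7L,
                            seed = 1L, global_norm = FALSE) {
  structure(list(preset = preset, n_levels = as.integer(n_levels),
                 lbp_R = lbp_R, classifier = classifier,
                 folds = as.integer(folds), k = as.integer(k),
                 seed = as.integer(seed), global_norm = global_norm),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}
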