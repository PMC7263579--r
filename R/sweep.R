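#' Extract the feature table of a whole dataset
#'
#' Unwraps, stacks and extracts features for every subject.
#'
#' @param dataset a [generate_dataset()] result (or a list with `subjects`
#'   and `labels`).
#' @param ucfg an [unwrap_config()].
#' @param fcfg a [feature_config()].
#' @return numeric matrix, subjects x 152, with canonical column names and
#'   subject ids as row names.
#' @export
extract_dataset <- function(dataset, ucfg = unwrap_config(),
                            fcfg = feature_config()) {
  X <- t(vapply(dataset$subjects, function(s)
    extract_features(unwrap_subject(s, ucfg), fcfg),
    numeric(length(feature_names(fcfg)))))
  rownames(X) <- vapply(dataset$subjects, `[[`, "", "subject_id")
  X
}

#' Baseline global / segmental T1 tables for a dataset
#'
#' The pattern-independent comparators: per-subject global native T1 (one
#' feature) and the 30 segmental means (6 segments x 5 slices).
#'
#' @inheritParams extract_dataset
#' @return list with `global` (n x 1 matrix) and `segmental` (n x 30 matrix).
#' @export
baseline_t1 <- function(dataset, ucfg = unwrap_config()) {
  gs <- lapply(dataset$subjects, global_segmental_t1, cfg = ucfg)
  g <- matrix(vapply(gs, `[[`, 0, "global"), ncol = 1,
              dimnames = list(NULL, "GlobalT1"))
  seg <- t(vapply(gs, `[[`, numeric(30), "segmental"))
  list(global = g, segmental = seg)
}

#' Resolution sweep of the full pipeline
#'
#' Re-runs unwrap, feature extraction, forward selection, and cross-validated
#' evaluation at each rectangular-map resolution preset (16 x 96, 32 x 192,
#' 64 x 384 per slice by default), with a shared seed, and tabulates the
#' resulting accuracies.
#'
#' @param dataset a [generate_dataset()] result.
#' @param presets character vector of [unwrap_config()] presets.
#' @param k,classifier,folds,seed,global_norm passed to [texture_fit()].
#' @param fcfg a [feature_config()].
#' @return object of class `resolution_sweep`: list with `table` (data frame
#'   preset/rows/cols/accuracy) and `fits` (per-preset `texture_fit`s).
#' @export
resolution_sweep <- function(dataset, presets = c("R16", "R32", "R64"),
                             k = 7L, classifier = "linear-svm", folds = 10L,
                             seed = 1L, global_norm = FALSE,
                             fcfg = feature_config()) {
  fits <- vector("list", length(presets)); names(fits) <- presets
  rows <- cols <- acc <- numeric(length(presets))
  for (i in seq_along(presets)) {
    ucfg <- unwrap_config(preset = presets[i])
    X <- extract_dataset(dataset, ucfg, fcfg)
    fits[[i]] <- texture_fit(X, dataset$labels, k = k,
                             classifier = classifier, folds = folds,
                             seed = seed, global_norm = global_norm)
    rows[i] <- ucfg$rows; cols[i] <- ucfg$cols
    acc[i] <- fits[[i]]$evaluation$accuracy
  }
  structure(list(table = data.frame(preset = presets, rows = rows,
                                    cols = cols, accuracy = acc),
                 fits = fits),
            class = "resolution_sweep")
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat("Resolution sweep (per-slice map size vs CV accuracy):\n")
  tab <- x$table
  tab$accuracy <- sprintf("%.1f%%", 100 * tab$accuracy)
  print(tab, row.names = FALSE)
  invisible(x)
}
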