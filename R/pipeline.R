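# End-to-end orchestration: dataset construction -> encoding -> mRMR ->
# IFS with jackknife NNA -> final grid-searched SVM.

#' Run the full site-prediction pipeline
#'
#' Chains every stage on in-memory inputs: dataset filters and redundancy
#' reduction, window extraction and negative subsampling, 646-feature
#' encoding, mRMR ranking, incremental feature selection under jackknife
#' nearest-neighbour evaluation, and (optionally) the final grid-searched
#' RBF-SVM refit on the optimal feature subset. Deterministic given `seed`.
#'
#' @param proteins Protein tibble with a filled `sites` list-column.
#' @param annotations Named list of [residue_annotations] (or `NULL` to use
#'   [fallback_annotations()] throughout).
#' @param flank Window flank (default 10).
#' @param neg_ratio Negatives per positive (default 3).
#' @param min_length Minimum protein length retained (default 50).
#' @param identity_threshold Redundancy-reduction cutoff (default 0.40);
#'   `NULL` skips the reduction.
#' @param seed Integer seed driving negative sampling and SVM folds.
#' @param ifs_k_max Truncate the IFS scan to the top `ifs_k_max` ranked
#'   features (default: all).
#' @param svm `TRUE` to grid-search and refit the final SVM on the optimal
#'   subset.
#' @param C_grid,gamma_grid SVM grids (default [default_grid()]).
#' @return List with `windows`, `features`, `ranked_maxrel`, `ranked_mrmr`,
#'   `ifs`, `optimum`, and when `svm = TRUE` also `model` and `predictions`
#'   (decision scores of the refit model on the training windows).
#' @export
run_pipeline <- function(proteins, annotations = NULL, flank = 10,
                         neg_ratio = 3, min_length = 50,
                         identity_threshold = 0.40, seed = 1,
                         ifs_k_max = NULL, svm = TRUE,
                         C_grid = default_grid(),
                         gamma_grid = default_grid()) {
  proteins <- filter_proteins(proteins, min_length = min_length)
  if (!is.null(identity_threshold)) {
    proteins <- reduce_redundancy(proteins, identity_threshold)
  }
  if (is.null(annotations)) {
    annotations <- stats::setNames(
      purrr::map(proteins$sequence, fallback_annotations, quiet = TRUE),
      proteins$id)
  }
  windows <- extract_windows(proteins, flank = flank) |>
    sample_negatives(ratio = neg_ratio, seed = seed)
  features <- encode_dataset(windows, annotations, flank = flank)
  D <- discretize(features$X)
  ranked_maxrel <- maxrel_rank(D, features$labels)
  ranked_mrmr <- mrmr_rank(D, features$labels)
  k_max <- ifs_k_max %||% nrow(ranked_mrmr)
  ifs <- run_ifs(features$X, features$labels, ranked_mrmr, k_max = k_max)
  optimum <- find_optimum(ifs)
  out <- list(windows = windows, features = features,
              ranked_maxrel = ranked_maxrel, ranked_mrmr = ranked_mrmr,
              ifs = ifs, optimum = optimum)
  if (svm) {
    sel <- ranked_mrmr$feature_index[seq_len(optimum$k)]
    Xsel <- features$X[, sel, drop = FALSE]
    model <- grid_search_train(Xsel, features$labels, C_grid = C_grid,
                               gamma_grid = gamma_grid, seed = seed,
                               selected_feature_indices = sel,
                               descriptors = features$descriptors)
    preds <- predict(model, Xsel)
    out$model <- model
    out$predictions <- dplyr::bind_cols(
      windows[, c("protein_id", "center")], preds)
  }
  out
}
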