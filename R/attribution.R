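# Feature-set attribution: tabulating a selected feature set by family,
# window site, or family-specific subtype.

#' Tabulate a selected feature set
#'
#' Counts the selected descriptors by `family`, by window `site`, or by
#' `subtype`; `family` can restrict the tabulation to one feature family
#' first (e.g. PSSM features by target residue, or by site). Groups with
#' zero selected features are reported with count 0, so site tables always
#' span 1..2*flank+1.
#'
#' @param selected Integer vector of descriptor indices.
#' @param descriptors Descriptor table from [descriptor_table()].
#' @param grouping `"family"`, `"site"` or `"subtype"`.
#' @param family Optional family filter (`AAF`, `PSSM`, `DIS`, `SS`, `SA`).
#' @return An `attribution_table` tibble: `group`, `count`, with the
#'   grouping, filter and selected-set size as attributes.
#' @export
tabulate_features <- function(selected, descriptors,
                              grouping = c("family", "site", "subtype"),
                              family = NULL) {
  grouping <- match.arg(grouping)
  if (length(selected) > 0 &&
      !all(selected %in% descriptors$index)) {
    stop("selected contains indices outside the descriptor table",
         call. = FALSE)
  }
  pool <- descriptors
  if (!is.null(family)) {
    stopifnot(family %in% c("AAF", "PSSM", "DIS", "SS", "SA"))
    pool <- dplyr::filter(pool, .data$family == !!family)
  }
  levels <- switch(grouping,
    family = c("AAF", "PSSM", "DIS", "SS", "SA"),
    site = sort(unique(descriptors$site)),
    subtype = unique(pool$subtype))
  hit <- pool[pool$index %in% selected, , drop = FALSE]
  key <- switch(grouping, family = hit$family, site = hit$site,
                subtype = hit$subtype)
  counts <- table(factor(key, levels = levels))
  out <- tibble::tibble(group = as.character(levels),
                        count = as.integer(counts))
  structure(out, grouping = grouping, family = family,
            total = length(unique(selected)),
            class = c("attribution_table", class(tibble::tibble())))
}

#' Report the top-ranked features with their addresses
#'
#' @param ranked A `ranked_list`.
#' @param k Number of leading features to report.
#' @param descriptors Descriptor table.
#' @return Tibble `rank`, `feature_index`, `score`, `site`, `family`,
#'   `subtype`.
#' @export
top_features_report <- function(ranked, k, descriptors) {
  stopifnot(k >= 0, k <= nrow(ranked))
  head_k <- ranked[seq_len(k), , drop = FALSE]
  dplyr::left_join(
    head_k[, c("rank", "feature_index", "score")],
    descriptors, by = c(feature_index = "index"))
}

#' Plot an attribution table
#'
#' Bar chart of selected-feature counts per group.
#'
#' @param object An `attribution_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- factor(df$group, levels = df$group)
  lab <- attr(object, "grouping")
  if (!is.null(attr(object, "family"))) {
    lab <- paste0(attr(object, "family"), " features by ", lab)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = lab, y = "selected features") +
    ggplot2::theme_minimal()
}

#' Plot an IFS curve
#'
#' MCC against the number of top-ranked features, with the optimum marked.
#'
#' @param object An `ifs_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifs_curve <- function(object, ...) {
  opt <- find_optimum(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$MCC)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = opt$k, linetype = "dashed") +
    ggplot2::labs(x = "number of top-ranked features", y = "jackknife MCC") +
    ggplot2::theme_minimal()
}

#' Summarise an IFS curve at its optimum
#'
#' @param x An `ifs_curve`.
#' @param ... Unused.
#' @return One-row tibble: `k_opt`, `Sn`, `Sp`, `Ac`, `MCC`.
#' @export
glance.ifs_curve <- function(x, ...) {
  opt <- find_optimum(x)
  dplyr::bind_cols(tibble::tibble(k_opt = opt$k), opt$metrics)
}

#' Plot a ROC curve
#'
#' @param scores Decision scores.
#' @param y Labels.
#' @return A ggplot object annotated with the AUC.
#' @export
plot_roc <- function(scores, y) {
  pts <- roc_points(scores, y)
  auc <- roc_auc(scores, y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(title = sprintf("AUC = %.3f", auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Write an attribution table
#'
#' TSV `group`, `count`.
#'
#' @param tab An `attribution_table`.
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_attribution <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
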