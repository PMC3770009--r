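# Nearest-neighbour classification, jackknife evaluation, performance
# metrics, incremental feature selection, and ROC/AUC.

#' Nearest-neighbour prediction
#'
#' A query inherits the label of the training row at minimum Euclidean
#' distance; ties break to the lowest training-row index.
#'
#' @param train_X Numeric training matrix.
#' @param train_y Labels, one per training row.
#' @param query Numeric vector, or a matrix of queries (one per row).
#' @return Predicted label(s).
#' @export
nna_predict <- function(train_X, train_y, query) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  stopifnot(ncol(query) == ncol(train_X))
  preds <- vapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(train_X) - query[i, ])^2)
    train_y[which.min(d2)]
  }, train_y[1])
  if (nrow(query) == 1L) preds[1] else preds
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# internal: counts from truth/prediction label vectors
counts_from_labels <- function(truth, pred) {
  confusion_counts(
    TP = sum(truth == "positive" & pred == "positive"),
    FP = sum(truth == "negative" & pred == "positive"),
    TN = sum(truth == "negative" & pred == "negative"),
    FN = sum(truth == "positive" & pred == "negative"))
}

# internal: normalise labels to "positive"/"negative"
norm_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y) || is.logical(y)) y <- ifelse(y != 0, "positive", "negative")
  if (!all(y %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative' (or coercible)", call. = FALSE)
  }
  y
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sample is predicted by a classifier trained on the remaining N-1;
#' with `groups` given, all samples sharing the held-out sample's group
#' (e.g. its source protein) are removed from the training side, giving a
#' leave-one-protein-out evaluation.
#'
#' @param X Numeric matrix.
#' @param y Labels.
#' @param classifier `"nna"` (fast path) or a function
#'   `(train_X, train_y, query_matrix) -> labels`.
#' @param groups Optional grouping vector for grouped jackknife.
#' @return A [confusion_counts] object.
#' @export
jackknife_evaluate <- function(X, y, classifier = "nna", groups = NULL) {
  X <- as.matrix(X)
  y <- norm_labels(y)
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y))
  if (length(unique(y)) < 2L) {
    stop("jackknife requires both classes present", call. = FALSE)
  }
  n <- nrow(X)
  if (identical(classifier, "nna") && is.null(groups)) {
    D <- squared_distances(X)
    diag(D) <- Inf
    nn <- max.col(-D, ties.method = "first")
    return(counts_from_labels(y, y[nn]))
  }
  fn <- if (identical(classifier, "nna")) {
    function(tx, ty, q) nna_predict(tx, ty, q)
  } else classifier
  pred <- character(n)
  for (i in seq_len(n)) {
    out <- if (is.null(groups)) i else which(groups == groups[i])
    pred[i] <- fn(X[-out, , drop = FALSE], y[-out],
                  X[i, , drop = FALSE])
  }
  counts_from_labels(y, pred)
}

# internal: full pairwise squared Euclidean distance matrix
squared_distances <- function(X) {
  G <- tcrossprod(X)
  q <- diag(G)
  D <- outer(q, q, "+") - 2 * G
  D[D < 0] <- 0
  D
}

#' Performance metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Ac = (TP+TN)/N and the Matthews
#' correlation coefficient. A zero factor in the MCC denominator yields
#' MCC = 0; Sn or Sp with an empty truth class is reported as `NA`.
#'
#' @param counts A [confusion_counts] object.
#' @return Tibble with one row: `Sn`, `Sp`, `Ac`, `MCC`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0L) stop("no evaluated samples", call. = FALSE)
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  tibble::tibble(Sn = sn, Sp = sp, Ac = (TP + TN) / total, MCC = mcc)
}

#' Incremental feature selection curve
#'
#' For each k along the ranked list, restricts the matrix to the top-k
#' features and jackknife-evaluates a nearest-neighbour classifier. The
#' squared-distance matrix is grown one feature at a time, so the whole
#' curve costs one pass over the ranked features.
#'
#' @param X Numeric matrix (windows x features).
#' @param y Labels.
#' @param ranked A `ranked_list` covering the columns of `X`.
#' @param k_max Evaluate k = 1..k_max (default: full list).
#' @return An `ifs_curve` tibble: `k`, `Sn`, `Sp`, `Ac`, `MCC`.
#' @export
run_ifs <- function(X, y, ranked, k_max = nrow(ranked)) {
  X <- as.matrix(X)
  y <- norm_labels(y)
  ord <- ranked$feature_index
  stopifnot(all(ord %in% seq_len(ncol(X))), k_max <= length(ord))
  n <- nrow(X)
  D <- matrix(0, n, n)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    xk <- X[, ord[k]]
    D <- D + (outer(xk, xk, "-"))^2
    Dk <- D
    diag(Dk) <- Inf
    nn <- max.col(-Dk, ties.method = "first")
    rows[[k]] <- metrics(counts_from_labels(y, y[nn]))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, k = seq_len(k_max), .before = 1)
  structure(out, class = c("ifs_curve", class(tibble::tibble())))
}

#' Locate the IFS optimum
#'
#' @param curve An `ifs_curve` tibble.
#' @return List with `k` (smallest k maximizing MCC) and `metrics`
#'   (the corresponding one-row tibble).
#' @export
find_optimum <- function(curve) {
  stopifnot(nrow(curve) > 0L)
  k_star <- which.max(curve$MCC)  # first max = smallest k on a plateau
  list(k = curve$k[k_star],
       metrics = curve[k_star, c("Sn", "Sp", "Ac", "MCC")])
}

#' Jackknife nearest-neighbour decision scores
#'
#' Signed margin per sample: distance to the nearest negative minus the
#' distance to the nearest positive (self excluded), so larger scores mean
#' more confidently positive. Used to draw ROC curves for the NNA stage.
#'
#' @param X Numeric matrix.
#' @param y Labels.
#' @return Numeric score vector.
#' @export
nna_scores <- function(X, y) {
  y <- norm_labels(y)
  D <- squared_distances(as.matrix(X))
  diag(D) <- Inf
  pos <- y == "positive"
  dpos <- apply(D[, pos, drop = FALSE], 1, min)
  dneg <- apply(D[, !pos, drop = FALSE], 1, min)
  sqrt(dneg) - sqrt(dpos)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate with the midrank convention for tied
#' scores; equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores Real-valued decision scores (larger = more positive).
#' @param y Labels.
#' @return AUC fraction in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  y <- norm_labels(y)
  npos <- sum(y == "positive")
  nneg <- sum(y == "negative")
  if (npos == 0L || nneg == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "positive"]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble `threshold`, `FPR`, `TPR`, one row per distinct score
#'   (prediction positive iff score >= threshold) plus the all-negative
#'   endpoint.
#' @export
roc_points <- function(scores, y) {
  y <- norm_labels(y)
  thr <- c(sort(unique(scores), decreasing = TRUE), Inf)
  thr <- sort(thr, decreasing = TRUE)
  purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(
      threshold = t,
      FPR = sum(pred & y == "negative") / sum(y == "negative"),
      TPR = sum(pred & y == "positive") / sum(y == "positive"))
  })
}

#' Write / read an IFS curve
#'
#' TSV with columns `k`, `Sn`, `Sp`, `Ac`, `MCC`.
#'
#' @param curve An `ifs_curve` tibble.
#' @param path TSV path.
#' @return `path` invisibly, or the curve.
#' @export
write_ifs_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  raw <- utils::read.delim(path, sep = "\t")
  structure(tibble::as_tibble(raw),
            class = c("ifs_curve", class(tibble::tibble())))
}
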