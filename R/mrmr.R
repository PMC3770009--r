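# MaxRel and mRMR feature ranking on discretized mutual information.
#
# Continuous features are discretized into three states at mean +/- one
# standard deviation (the classical treatment of continuous variables in
# the mRMR literature); mutual information is the plug-in estimate in bits;
# the mRMR criterion is the greedy difference (MID) form
#   argmax_f [ I(f; y) - (1/|S|) sum_{s in S} I(f; s) ].

#' Discretize a feature matrix into three states
#'
#' Per feature with mean mu and (population) standard deviation sigma:
#' values below mu - sigma map to state 0, above mu + sigma to state 2,
#' otherwise 1. Constant features map entirely to state 1.
#'
#' @param X Numeric matrix (rows = samples).
#' @return Integer matrix of the same shape with entries in `0:2`.
#' @export
discretize <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values",
                               call. = FALSE)
  mu <- colMeans(X)
  sdev <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  D <- matrix(1L, nrow(X), ncol(X), dimnames = dimnames(X))
  lo <- sweep(X, 2, mu - sdev, "<")
  hi <- sweep(X, 2, mu + sdev, ">")
  ok <- rep(sdev > 0, each = nrow(X))
  D[lo & ok] <- 0L
  D[hi & ok] <- 2L
  D
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate over the observed joint distribution, in bits.
#'
#' @param a,b Vectors of equal length (any discrete coding).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  mi_from_counts(table(a, b))
}

# internal: MI in bits from a joint count table
mi_from_counts <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# internal: fast MI for integer-coded vectors with small known state counts
mi_fast <- function(a, b, na, nb) {
  counts <- tabulate(a * nb + b + 1L, nbins = na * nb)
  mi_from_counts(matrix(counts, nrow = na, byrow = TRUE))
}

# internal: coerce labels to integer codes 0/1 (positive = 1)
label_codes <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    code <- as.integer(y == "positive")
  } else {
    code <- as.integer(y != 0)
  }
  if (length(unique(code)) < 2L) {
    stop("labels are single-class; ranking requires both classes",
         call. = FALSE)
  }
  code
}

new_ranked_list <- function(order, scores, criterion) {
  structure(
    tibble::tibble(rank = seq_along(order), feature_index = order,
                   score = scores, criterion = criterion),
    class = c("ranked_list", class(tibble::tibble())))
}

#' Rank features by relevance to the class (MaxRel)
#'
#' Features sorted by decreasing mutual information with the label; ties
#' break by ascending feature index.
#'
#' @param D Discretized matrix from [discretize()] (states `0:2`).
#' @param y Binary labels (`"positive"`/`"negative"`, factor, or 0/1).
#' @return A `ranked_list` tibble: `rank`, `feature_index`, `score`
#'   (MI in bits), `criterion = "MaxRel"`.
#' @export
maxrel_rank <- function(D, y) {
  yc <- label_codes(y)
  stopifnot(nrow(D) == length(yc))
  rel <- apply(D, 2, function(f) mi_fast(as.integer(f), yc, 3L, 2L))
  ord <- order(-rel, seq_along(rel))
  new_ranked_list(ord, rel[ord], "MaxRel")
}

#' Rank features by maximum relevance, minimum redundancy (mRMR)
#'
#' Greedy difference (MID) form: the first feature maximizes relevance
#' I(f; y); each subsequent pick maximizes relevance minus the mean mutual
#' information with the already-selected set. Ties break by ascending
#' feature index. The recorded score is the criterion value at selection
#' time (so it equals relevance for the first feature).
#'
#' @inheritParams maxrel_rank
#' @param n_select Length of the returned list (default: all features).
#' @return A `ranked_list` tibble with `criterion = "mRMR"`.
#' @export
mrmr_rank <- function(D, y, n_select = ncol(D)) {
  yc <- label_codes(y)
  stopifnot(nrow(D) == length(yc), n_select >= 1L, n_select <= ncol(D))
  p <- ncol(D)
  Di <- matrix(as.integer(D), nrow(D), p)
  rel <- vapply(seq_len(p), function(j) mi_fast(Di[, j], yc, 3L, 2L),
                numeric(1))
  selected <- integer(n_select)
  scores <- numeric(n_select)
  redsum <- numeric(p)
  candidate <- rep(TRUE, p)
  for (t in seq_len(n_select)) {
    crit <- if (t == 1L) rel else rel - redsum / (t - 1L)
    crit[!candidate] <- -Inf
    pick <- which.max(crit)  # which.max takes the lowest index on ties
    selected[t] <- pick
    scores[t] <- crit[pick]
    candidate[pick] <- FALSE
    if (t < n_select) {
      xs <- Di[, pick]
      upd <- which(candidate)
      redsum[upd] <- redsum[upd] + vapply(upd, function(j) {
        mi_fast(Di[, j], xs, 3L, 3L)
      }, numeric(1))
    }
  }
  new_ranked_list(selected, scores, "mRMR")
}

#' Write / read a ranked feature list
#'
#' TSV with columns `rank`, `feature_index`, `score`, `criterion`.
#'
#' @param ranked A `ranked_list` tibble.
#' @param path TSV path.
#' @return `path` invisibly, or the ranked list.
#' @export
write_ranked <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked
#' @export
read_ranked <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = c(
    rank = "integer", feature_index = "integer",
    score = "numeric", criterion = "character"))
  structure(tibble::as_tibble(raw),
            class = c("ranked_list", class(tibble::tibble())))
}
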