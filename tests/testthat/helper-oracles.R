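# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately re-derive each quantity with the plainest
# possible code (explicit loops, no shared helpers with the implementation).

# --- fixtures ---------------------------------------------------------------

make_proteins <- function(seqs, sites = NULL, ids = NULL) {
  ids <- ids %||% sprintf("p%d", seq_along(seqs))
  sites <- sites %||% rep(list(integer()), length(seqs))
  tibble::tibble(id = ids, sequence = seqs,
                 sites = lapply(sites, as.integer))
}

# a protein whose annotations are small integers, easy to hand-assemble
make_fixture_annotations <- function(sequence, seed = 99) {
  withr::with_seed(seed, {
    L <- nchar(sequence)
    residue_annotations(
      pssm = matrix(sample(-5:9, L * 20, replace = TRUE), L, 20),
      disorder = round(stats::runif(L), 3),
      ss = sample(c("C", "H", "E"), L, replace = TRUE),
      sa = sample(c("buried", "exposed"), L, replace = TRUE))
  })
}

random_small_instance <- function(seed, n_feat_max = 30, n_samp_max = 50) {
  withr::with_seed(seed, {
    p <- sample(3:n_feat_max, 1)
    n <- sample(12:n_samp_max, 1)
    X <- matrix(stats::rnorm(n * p), n, p)
    # a couple of informative columns so rankings are non-trivial
    y <- rep(c("positive", "negative"), length.out = n)
    X[, 1] <- X[, 1] + 1.5 * (y == "positive")
    list(X = X, y = y, n = n, p = p)
  })
}

# --- oracles ----------------------------------------------------------------

# plug-in MI in bits by explicit summation over observed category pairs
oracle_mi <- function(a, b) {
  n <- length(a)
  total <- 0
  for (va in unique(a)) for (vb in unique(b)) {
    pxy <- sum(a == va & b == vb) / n
    if (pxy == 0) next
    px <- sum(a == va) / n
    py <- sum(b == vb) / n
    total <- total + pxy * log2(pxy / (px * py))
  }
  total
}

oracle_maxrel <- function(D, y01) {
  rel <- sapply(seq_len(ncol(D)), function(j) oracle_mi(D[, j], y01))
  order(-rel, seq_len(ncol(D)))
}

# validates a MaxRel ranking against independently recomputed relevance:
# the order must be a permutation sorted by the oracle's MI (analytic ties
# are equal only up to floating-point noise, hence the tolerance) and the
# reported scores must equal the oracle's values
oracle_check_maxrel <- function(D, y01, ranked, tol = 1e-9) {
  p <- ncol(D)
  rel <- sapply(seq_len(p), function(j) oracle_mi(D[, j], y01))
  ord <- ranked$feature_index
  setequal(ord, seq_len(p)) &&
    max(abs(ranked$score - rel[ord])) < tol &&
    all(diff(rel[ord]) <= tol)
}

# validates an mRMR ranking stepwise: each selected feature must attain the
# maximum of the independently recomputed greedy criterion over the features
# still available at that step, with the reported score agreeing
oracle_check_mrmr <- function(D, y01, ranked, tol = 1e-9) {
  p <- ncol(D)
  rel <- sapply(seq_len(p), function(j) oracle_mi(D[, j], y01))
  ord <- ranked$feature_index
  if (!setequal(ord, seq_len(p))) return(FALSE)
  chosen <- integer()
  for (t in seq_along(ord)) {
    remaining <- setdiff(seq_len(p), chosen)
    crit <- sapply(remaining, function(f) {
      if (length(chosen) == 0) return(rel[f])
      rel[f] - mean(sapply(chosen, function(s) oracle_mi(D[, f], D[, s])))
    })
    pick_crit <- crit[match(ord[t], remaining)]
    if (pick_crit < max(crit) - tol) return(FALSE)
    if (abs(pick_crit - ranked$score[t]) > tol) return(FALSE)
    chosen <- c(chosen, ord[t])
  }
  TRUE
}

# leave-one-out NNA by a verbatim distance scan
oracle_jackknife_nna <- function(X, y) {
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    best_d <- Inf; best_j <- NA
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    pred[i] <- y[best_j]
  }
  c(TP = sum(y == "positive" & pred == "positive"),
    FP = sum(y == "negative" & pred == "positive"),
    TN = sum(y == "negative" & pred == "negative"),
    FN = sum(y == "positive" & pred == "negative"))
}

# AUC as the fraction of concordant positive/negative pairs (ties = 1/2)
oracle_auc <- function(scores, y) {
  pos <- scores[y == "positive"]
  neg <- scores[y == "negative"]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# per-descriptor scan for attribution counts
oracle_attribution <- function(selected, descriptors, key) {
  counts <- list()
  for (i in selected) {
    row <- descriptors[descriptors$index == i, ]
    k <- as.character(row[[key]])
    counts[[k]] <- (counts[[k]] %||% 0) + 1
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
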