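# Synthetic proteome generator with planted pupylation motifs and
# class-coupled annotation tracks, so every pipeline stage is testable
# without any external database or prediction tool.

#' Specification of the planted motif and annotation couplings
#'
#' Planted (positive) lysine sites receive position-specific residue
#' enrichment around the central K and annotation tracks whose distribution
#' differs between classes at the informative window sites:
#' * sequence: the residue at each enriched site is replaced by the
#'   enriched letter with probability `enrich_prob` (default: `E` at window
#'   sites 7 and 10, probability 0.6);
#' * conservation: the profile column of the site's signal residue (the
#'   enriched letter at flanking sites, `K` at the centre) is raised by
#'   `pssm_coupling` score units;
#' * disorder: the site-10 residue's disorder score is raised by
#'   `disorder_coupling`;
#' * secondary structure / accessibility: with probability `ss_coupling`
#'   (resp. `sa_coupling`) the central residue is forced to coil
#'   (resp. exposed) instead of a background draw.
#'
#' Setting `enrich_prob` to the background frequency and all couplings to 0
#' gives the exchangeable null construction.
#'
#' @param informative_sites Window sites carrying signal (default 7, 10, 11;
#'   site 11 is the centre and always K).
#' @param enriched_residues Named list mapping flanking informative sites to
#'   their enriched residue.
#' @param enrich_prob Probability that an enriched site carries its residue
#'   in a positive window (default 0.6).
#' @param background Residue frequencies for background positions (default
#'   uniform over the 20 letters).
#' @param pssm_coupling Conservation-score shift (log-odds units, default 4).
#' @param disorder_coupling Disorder-score shift (default 0.3).
#' @param ss_coupling,sa_coupling Forcing probabilities in \[0, 1\]
#'   (default 0.3 each).
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(informative_sites = c(7L, 10L, 11L),
                       enriched_residues = list(`7` = "E", `10` = "E"),
                       enrich_prob = 0.6,
                       background = stats::setNames(rep(1 / 20, 20),
                                                    AA_ALPHABET),
                       pssm_coupling = 4,
                       disorder_coupling = 0.3,
                       ss_coupling = 0.3,
                       sa_coupling = 0.3) {
  stopifnot(all(informative_sites %in% 1:21),
            enrich_prob >= 0, enrich_prob <= 1,
            abs(sum(background) - 1) < 1e-8,
            ss_coupling >= 0, ss_coupling <= 1,
            sa_coupling >= 0, sa_coupling <= 1)
  structure(list(informative_sites = as.integer(informative_sites),
                 enriched_residues = enriched_residues,
                 enrich_prob = enrich_prob, background = background,
                 pssm_coupling = pssm_coupling,
                 disorder_coupling = disorder_coupling,
                 ss_coupling = ss_coupling, sa_coupling = sa_coupling),
            class = "motif_spec")
}

#' The null motif: no class signal anywhere
#'
#' Enrichment probability equals the background frequency of the enriched
#' residue and every annotation coupling is zero, so positive and negative
#' windows are exchangeable.
#'
#' @return A `motif_spec` object.
#' @export
null_motif_spec <- function() {
  motif_spec(enrich_prob = 1 / 20, pssm_coupling = 0,
             disorder_coupling = 0, ss_coupling = 0, sa_coupling = 0)
}

#' Generate a synthetic annotated proteome with planted pupylation sites
#'
#' Background sequences are i.i.d. draws from the background residue
#' distribution. `n_positive_sites` lysines are planted across the proteins
#' (sequence motif and annotation couplings per the [motif_spec()]);
#' all remaining lysines are unlabelled and serve as negatives. Annotation
#' tracks mimic the external-tool outputs: the conservation profile of a
#' residue is its substitution-table row plus rounded Gaussian noise, the
#' disorder track is uniform background noise, secondary structure and
#' accessibility are categorical draws.
#'
#' @param n_proteins Number of proteins (default 120).
#' @param length_range Protein length interval (default 80..160).
#' @param n_positive_sites Planted sites in total (default 200).
#' @param motif A [motif_spec()].
#' @param flank Window flank (default 10; lengths must be >= 2*flank+1).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the arguments and the seed.
#' @return A `synthetic_dataset`: list with `proteins` (tibble with sites),
#'   `annotations` (named list of [residue_annotations]), `ground_truth`
#'   (informative sites, planted positions, informative descriptor
#'   addresses), `motif`, `flank`, `seed`.
#' @export
generate_dataset <- function(n_proteins = 120, length_range = c(80, 160),
                             n_positive_sites = 200, motif = motif_spec(),
                             flank = 10, seed = 1) {
  stopifnot(length_range[1] >= 2 * flank + 1,
            n_positive_sites >= 1)
  per_protein <- ceiling(n_positive_sites / n_proteins)
  if (per_protein * n_proteins < n_positive_sites ||
      length_range[1] < per_protein) {
    stop("infeasible configuration: cannot place the requested sites",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    n_planted <- diff_round(n_positive_sites, n_proteins)
    proteins <- vector("list", n_proteins)
    annotations <- vector("list", n_proteins)
    planted_tbl <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      g <- generate_protein(lens[i], n_planted[i], motif, flank)
      id <- sprintf("syn%03d", i)
      proteins[[i]] <- tibble::tibble(id = id, sequence = g$sequence,
                                      sites = list(g$sites))
      annotations[[i]] <- g$annotations
      planted_tbl[[i]] <- tibble::tibble(protein_id = id, position = g$sites)
    }
    proteins <- dplyr::bind_rows(proteins)
    names(annotations) <- proteins$id
    descriptors <- descriptor_table(flank)
    structure(list(
      proteins = proteins,
      annotations = annotations,
      ground_truth = list(
        informative_sites = motif$informative_sites,
        planted = dplyr::bind_rows(planted_tbl),
        informative_indices =
          descriptors$index[descriptors$site %in% motif$informative_sites]),
      motif = motif, flank = flank, seed = seed
    ), class = "synthetic_dataset")
  })
}

# internal: spread n sites over k proteins as evenly as possible
diff_round <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

# internal: one protein with planted sites and coupled annotations
generate_protein <- function(len, n_sites, motif, flank) {
  centre <- flank + 1L
  chars <- sample(names(motif$background), len, replace = TRUE,
                  prob = motif$background)
  sites <- integer()
  if (n_sites > 0L) {
    sites <- sort(sample(seq_len(len), n_sites))
    chars[sites] <- "K"
    for (s in sites) {
      for (ws in names(motif$enriched_residues)) {
        pos <- s + as.integer(ws) - centre
        if (pos >= 1L && pos <= len && !(pos %in% sites) &&
            stats::runif(1) < motif$enrich_prob) {
          chars[pos] <- motif$enriched_residues[[ws]]
        }
      }
    }
  }
  sequence <- paste(chars, collapse = "")

  # background annotation tracks
  pssm <- SUBSTITUTION_TABLE[chars, , drop = FALSE] +
    matrix(stats::rnorm(len * 20), len, 20)
  disorder <- stats::runif(len, 0.1, 0.7)
  ss <- sample(SS_LABELS, len, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  sa <- sample(SA_LABELS, len, replace = TRUE)

  # class-coupled shifts at the informative sites of planted windows
  for (s in sites) {
    for (ws in motif$informative_sites) {
      pos <- s + ws - centre
      if (pos < 1L || pos > len) next
      signal_res <- if (ws == centre) "K" else
        motif$enriched_residues[[as.character(ws)]]
      if (!is.null(signal_res)) {
        pssm[pos, signal_res] <- pssm[pos, signal_res] + motif$pssm_coupling
      }
      if (ws == 10L) {
        disorder[pos] <- min(1, disorder[pos] + motif$disorder_coupling)
      }
      if (ws == centre) {
        if (stats::runif(1) < motif$ss_coupling) ss[pos] <- "C"
        if (stats::runif(1) < motif$sa_coupling) sa[pos] <- "exposed"
      }
    }
  }
  rownames(pssm) <- NULL
  list(sequence = sequence, sites = sites,
       annotations = residue_annotations(
         pssm = round(pssm), disorder = round(disorder, 6),
         ss = ss, sa = sa))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d proteins, %d planted sites (seed %d)\n",
    nrow(x$proteins), nrow(x$ground_truth$planted), x$seed))
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's on-disk layout
#'
#' Emits `proteins.fasta`, `sites.tsv`, an `annotations/` directory in the
#' external-tool dialects, and `ground_truth.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$proteins, file.path(outdir, "proteins.fasta"))
  utils::write.table(dataset$ground_truth$planted,
                     file.path(outdir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  adir <- file.path(outdir, "annotations")
  for (i in seq_len(nrow(dataset$proteins))) {
    write_annotations(dataset$annotations[[dataset$proteins$id[i]]],
                      dataset$proteins$sequence[i],
                      dataset$proteins$id[i], adir)
  }
  jsonlite::write_json(
    list(informative_sites = dataset$ground_truth$informative_sites,
         informative_indices = dataset$ground_truth$informative_indices,
         seed = dataset$seed),
    file.path(outdir, "ground_truth.json"))
  invisible(outdir)
}

#' Encode a synthetic dataset end to end
#'
#' Window extraction, negative subsampling and feature encoding in one call
#' (no redundancy reduction: synthetic backgrounds are already unrelated).
#'
#' @param dataset A `synthetic_dataset`.
#' @param neg_ratio Negatives per positive (default 3).
#' @param seed Seed for the negative draw (default: the dataset's seed).
#' @return A `pup_features` object.
#' @export
encode_synthetic <- function(dataset, neg_ratio = 3, seed = dataset$seed) {
  windows <- extract_windows(dataset$proteins, flank = dataset$flank)
  windows <- sample_negatives(windows, ratio = neg_ratio, seed = seed)
  encode_dataset(windows, dataset$annotations, flank = dataset$flank)
}

#' Fraction of top-ranked features at the planted informative sites
#'
#' @param dataset A `synthetic_dataset` (source of the ground truth).
#' @param ranked A `ranked_list` computed on the dataset's encoded matrix.
#' @param k Number of leading features to assess.
#' @return List with `fraction` (in \[0, 1\]) and `report`, a tibble of the
#'   top-k features flagged `hit`/`miss`.
#' @export
recovery_report <- function(dataset, ranked, k) {
  descriptors <- descriptor_table(dataset$flank)
  top <- top_features_report(ranked, k, descriptors)
  top$hit <- top$site %in% dataset$ground_truth$informative_sites
  list(fraction = mean(top$hit), report = top)
}
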