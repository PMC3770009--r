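# Sequence and site-annotation I/O, dataset filters, redundancy reduction,
# window extraction and negative subsampling.

#' Read protein sequences from a FASTA file
#'
#' Returns one row per FASTA entry with an empty site list; merge annotated
#' pupylation positions afterwards with [merge_sites()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `sequence` (uppercase
#'   character) and `sites` (list of integer vectors, empty until merged).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKTAYIAKQR"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(tibble::tibble(id = character(), sequence = character(),
                          sites = list()))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a '>' header",
                 nonblank[1]), call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  tibble::tibble(
    id = unname(ids),
    sequence = unname(toupper(as.character(seqs))),
    sites = rep(list(integer()), length(ids))
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Expects a tab-separated file with header columns `protein_id` and
#' `position` (1-based). Duplicate rows collapse; positions sort ascending
#' within protein.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `protein_id` and `position` (integer).
#' @export
read_sites <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (nrow(raw) == 0L) {
    return(tibble::tibble(protein_id = character(), position = integer()))
  }
  if (!all(c("protein_id", "position") %in% names(raw))) {
    stop("sites file must have columns 'protein_id' and 'position'",
         call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- is.na(pos) | pos != floor(pos)
  if (any(bad)) {
    stop(sprintf("non-integer position '%s' for protein '%s'",
                 raw$position[bad][1], raw$protein_id[bad][1]), call. = FALSE)
  }
  tibble::tibble(protein_id = raw$protein_id, position = as.integer(pos)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_id, .data$position)
}

#' Attach annotated sites to protein records
#'
#' Validates that each annotated position falls inside its protein and lands
#' on a lysine.
#'
#' @param proteins Tibble from [read_fasta()].
#' @param sites Tibble from [read_sites()] (or any tibble with `protein_id`
#'   and `position`).
#' @return `proteins` with the `sites` list-column filled in.
#' @export
merge_sites <- function(proteins, sites) {
  unknown <- setdiff(unique(sites$protein_id), proteins$id)
  if (length(unknown) > 0L) {
    stop(sprintf("site annotations refer to unknown protein(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  by_id <- split(sites$position, sites$protein_id)
  proteins$sites <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    pos <- sort(unique(by_id[[id]]))
    if (is.null(pos)) return(integer())
    if (any(pos < 1L | pos > nchar(seq))) {
      stop(sprintf("site position %d outside protein '%s' (length %d)",
                   pos[pos < 1L | pos > nchar(seq)][1], id, nchar(seq)),
           call. = FALSE)
    }
    res <- substring(seq, pos, pos)
    if (any(res != "K")) {
      stop(sprintf("annotated site %d of protein '%s' is '%s', not 'K'",
                   pos[res != "K"][1], id, res[res != "K"][1]), call. = FALSE)
    }
    as.integer(pos)
  })
  proteins
}

#' Apply the dataset inclusion filters
#'
#' Drops proteins shorter than `min_length` residues (likely fragments) and
#' proteins containing any non-standard amino-acid letter (B, J, O, U, X, Z
#' or anything else outside the 20-letter alphabet).
#'
#' @param proteins Protein tibble.
#' @param min_length Minimum sequence length retained (default 50).
#' @return Filtered tibble, relative order preserved.
#' @export
filter_proteins <- function(proteins, min_length = 50) {
  standard <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]*$")
  dplyr::filter(proteins,
                nchar(.data$sequence) >= min_length,
                grepl(standard, .data$sequence))
}

#' Pairwise sequence identity
#'
#' Global ends-free alignment (match +1, mismatch 0, gap open 5 / extend 1)
#' via [Biostrings::pairwiseAlignment()]; identity is exact matches divided
#' by alignment columns.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  subm <- diag(1, 20)
  dimnames(subm) <- list(AA_ALPHABET, AA_ALPHABET)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = subm,
    gapOpening = 5, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0L) return(0)
  Biostrings::nmatch(aln) / cols
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Orders records longest-first (ties by id), then keeps a record iff its
#' identity to every already-kept record is below `identity_threshold`.
#' A transparent, deterministic stand-in for binary clustering tools;
#' precomputed cluster representatives can be supplied instead via `keep_ids`.
#'
#' @param proteins Protein tibble (already filtered).
#' @param identity_threshold Records at or above this identity to a kept
#'   record are discarded (default 0.40).
#' @param keep_ids Optional character vector of representative ids from an
#'   external clustering; when given, the identity computation is skipped.
#' @return Tibble of retained records in the original row order.
#' @export
reduce_redundancy <- function(proteins, identity_threshold = 0.40,
                              keep_ids = NULL) {
  if (!is.null(keep_ids)) {
    return(dplyr::filter(proteins, .data$id %in% keep_ids))
  }
  if (nrow(proteins) <= 1L) return(proteins)
  ord <- order(-nchar(proteins$sequence), proteins$id)
  kept <- integer()
  for (i in ord) {
    redundant <- FALSE
    for (j in kept) {
      if (pairwise_identity(proteins$sequence[i],
                            proteins$sequence[j]) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  proteins[sort(kept), , drop = FALSE]
}

#' Extract lysine-centred peptide windows
#'
#' One window per lysine in each protein: `flank` residues either side of
#' the K, positions beyond the sequence ends padded with `-`. A window is
#' labelled positive iff its centre is an annotated site.
#'
#' @param proteins Protein tibble with a filled `sites` list-column.
#' @param flank Residues on each side of the centre (default 10, i.e.
#'   21-residue windows).
#' @return Tibble with columns `protein_id`, `center` (1-based), `peptide`
#'   and `label` (`"positive"`/`"negative"`), ordered by protein row then
#'   ascending position.
#' @export
extract_windows <- function(proteins, flank = 10) {
  purrr::pmap_dfr(proteins[, c("id", "sequence", "sites")],
                  function(id, sequence, sites) {
    chars <- strsplit(sequence, "")[[1]]
    ks <- which(chars == "K")
    if (length(ks) == 0L) {
      return(tibble::tibble(protein_id = character(), center = integer(),
                            peptide = character(), label = character()))
    }
    padded <- c(rep(PAD_CHAR, flank), chars, rep(PAD_CHAR, flank))
    peptides <- vapply(ks, function(p) {
      paste(padded[p:(p + 2 * flank)], collapse = "")
    }, character(1))
    tibble::tibble(
      protein_id = id,
      center = as.integer(ks),
      peptide = peptides,
      label = ifelse(ks %in% sites, "positive", "negative")
    )
  })
}

#' Subsample negative windows to a fixed class ratio
#'
#' Keeps every positive window and draws `ratio` negatives per positive
#' uniformly without replacement (capped at the number available).
#'
#' @param windows Window tibble from [extract_windows()].
#' @param ratio Negatives kept per positive (default 3).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return Window tibble (positives first in original order, then the
#'   sampled negatives in original order).
#' @export
sample_negatives <- function(windows, ratio = 3, seed) {
  pos <- which(windows$label == "positive")
  neg <- which(windows$label == "negative")
  if (length(pos) == 0L) {
    stop("no positive windows: cannot define the sampling ratio",
         call. = FALSE)
  }
  n_draw <- min(ratio * length(pos), length(neg))
  drawn <- withr::with_seed(seed, sample(neg, n_draw))
  windows[c(pos, sort(drawn)), , drop = FALSE]
}

#' Write / read a window table
#'
#' TSV with columns `protein_id`, `center`, `peptide`, `label`.
#'
#' @param windows Window tibble.
#' @param path Output path.
#' @return `path` invisibly (`write_windows`); a window tibble
#'   (`read_windows`).
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = c(
    protein_id = "character", center = "integer",
    peptide = "character", label = "character"))
  tibble::as_tibble(raw)
}
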