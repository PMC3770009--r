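# The 646-dimensional window encoding and its feature-address scheme.
#
# Each 21-residue window is encoded site-by-site (site 1..21, centre 11):
# a flanking site contributes 5 amino-acid-factor values, 20 conservation
# scores, 1 disorder score, a 3-bit secondary-structure one-hot and a 2-bit
# accessibility one-hot (31 features); the centre, always lysine, omits the
# amino-acid factors (26 features). 20 x 31 + 26 = 646.

#' Atchley factor scores for a residue
#'
#' @param residue Single residue letter, or `-` (padding), vectorised.
#' @return Numeric vector of the five factor scores (a matrix for vector
#'   input); all zeros for padding.
#' @export
atchley_factors <- function(residue) {
  check_residues(residue, allow_pad = TRUE)
  out <- matrix(0, nrow = length(residue), ncol = 5,
                dimnames = list(NULL, colnames(ATCHLEY_FACTORS)))
  real <- residue != PAD_CHAR
  out[real, ] <- ATCHLEY_FACTORS[residue[real], , drop = FALSE]
  if (length(residue) == 1L) out[1, ] else out
}

#' The feature descriptor table
#'
#' Deterministic addressing of the encoded feature space: site-major order
#' (site 1 to 2*flank+1); within each site amino-acid factors (5, omitted at
#' the centre), conservation scores (20, [AA_ALPHABET] order), disorder (1),
#' secondary structure (C, H, E), accessibility (buried, exposed).
#'
#' @param flank Residues per side (default 10 gives 646 descriptors).
#' @return Tibble with columns `index`, `site`, `family` (one of `AAF`,
#'   `PSSM`, `DIS`, `SS`, `SA`) and `subtype`.
#' @export
descriptor_table <- function(flank = 10) {
  stopifnot(flank >= 1)
  centre <- flank + 1L
  per_site <- function(site) {
    fam <- c(if (site != centre) rep("AAF", 5), rep("PSSM", 20),
             "DIS", rep("SS", 3), rep("SA", 2))
    sub <- c(if (site != centre) colnames(ATCHLEY_FACTORS), AA_ALPHABET,
             "score", SS_LABELS, SA_LABELS)
    tibble::tibble(site = site, family = fam, subtype = sub)
  }
  out <- purrr::map_dfr(seq_len(2L * flank + 1L), per_site)
  dplyr::mutate(out, index = dplyr::row_number(), .before = 1)
}

#' Encode one peptide window as a feature vector
#'
#' @param peptide Window string of length 2*flank+1 (padding `-` allowed at
#'   the ends only), centre residue `K`.
#' @param center 1-based position of the centre lysine in its protein.
#' @param annotations [residue_annotations] of the source protein.
#' @param descriptors Descriptor table (recomputed from the window length if
#'   omitted).
#' @return Numeric feature vector aligned to the descriptor table; padding
#'   sites contribute zeros in every family.
#' @export
encode_window <- function(peptide, center, annotations, descriptors = NULL) {
  chars <- strsplit(peptide, "")[[1]]
  w <- length(chars)
  stopifnot(w %% 2L == 1L)
  flank <- (w - 1L) %/% 2L
  if (chars[flank + 1L] != "K") {
    stop("window centre must be 'K'", call. = FALSE)
  }
  if (is.null(descriptors)) descriptors <- descriptor_table(flank)
  vals <- numeric(nrow(descriptors))
  L <- length(annotations)
  for (site in seq_len(w)) {
    res <- chars[site]
    if (res == PAD_CHAR) next
    pos <- center - flank - 1L + site
    if (pos < 1L || pos > L) {
      stop(sprintf("window site %d maps outside the annotated protein", site),
           call. = FALSE)
    }
    idx <- descriptors$index[descriptors$site == site]
    fam <- descriptors$family[descriptors$site == site]
    vals[idx[fam == "AAF"]] <- atchley_factors(res)
    vals[idx[fam == "PSSM"]] <- annotations$pssm[pos, ]
    vals[idx[fam == "DIS"]] <- annotations$disorder[pos]
    vals[idx[fam == "SS"]] <- as.numeric(SS_LABELS == annotations$ss[pos])
    vals[idx[fam == "SA"]] <- as.numeric(SA_LABELS == annotations$sa[pos])
  }
  vals
}

#' Encode a window table into the feature matrix
#'
#' @param windows Window tibble (`protein_id`, `center`, `peptide`, `label`).
#' @param annotations Named list of [residue_annotations], one per protein id
#'   occurring in `windows`.
#' @param flank Residues per side (default 10).
#' @return A `pup_features` object: list with the numeric matrix `X`
#'   (rows = windows, columns = descriptor indices), character `labels`,
#'   the `windows` tibble and the `descriptors` table.
#' @export
encode_dataset <- function(windows, annotations, flank = 10) {
  missing <- setdiff(unique(windows$protein_id), names(annotations))
  if (length(missing) > 0L) {
    stop(sprintf("no annotations for protein(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  descriptors <- descriptor_table(flank)
  X <- matrix(0, nrow = nrow(windows), ncol = nrow(descriptors))
  if (nrow(windows) > 0L) {
    for (i in seq_len(nrow(windows))) {
      X[i, ] <- encode_window(windows$peptide[i], windows$center[i],
                              annotations[[windows$protein_id[i]]],
                              descriptors)
    }
  }
  colnames(X) <- sprintf("f%03d", descriptors$index)
  structure(list(X = X, labels = windows$label, windows = windows,
                 descriptors = descriptors),
            class = "pup_features")
}

#' @export
print.pup_features <- function(x, ...) {
  cat(sprintf("<pup_features> %d windows x %d features (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$labels == "positive"),
              sum(x$labels == "negative")))
  invisible(x)
}

#' Tidy a feature matrix into long form
#'
#' @param x A `pup_features` object.
#' @param ... Unused.
#' @return Tibble with one row per (window, feature): window identity,
#'   label, descriptor address and value.
#' @export
tidy.pup_features <- function(x, ...) {
  wide <- tibble::as_tibble(x$X)
  wide$.row <- seq_len(nrow(x$X))
  long <- tidyr::pivot_longer(wide, -".row", names_to = "feature",
                              values_to = "value")
  long$index <- as.integer(sub("^f", "", long$feature))
  long <- dplyr::left_join(long, x$descriptors, by = "index")
  dplyr::bind_cols(
    x$windows[long$.row, c("protein_id", "center", "label")],
    long[, c("index", "site", "family", "subtype", "value")]
  )
}

#' Write / read the descriptor table
#'
#' @param descriptors Descriptor tibble.
#' @param path TSV path.
#' @return `path` invisibly, or the descriptor tibble.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.table(descriptors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", colClasses = c(
    index = "integer", site = "integer",
    family = "character", subtype = "character")))
}

# internal: stable checksum of the descriptor table (model portability guard)
descriptor_checksum <- function(descriptors) {
  txt <- paste(descriptors$index, descriptors$site, descriptors$family,
               descriptors$subtype, collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
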