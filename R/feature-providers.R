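# Per-residue annotation tracks: parsers for the standard external-tool
# output dialects (PSI-BLAST ASCII PSSM, PSIPRED .ss2, VSL2 disorder tables,
# two-state accessibility) plus a deterministic fallback provider.

#' Construct a residue-annotation container
#'
#' Bundles the four per-residue tracks used by the encoder. Lengths must
#' agree with each other (and with the protein sequence at encoding time).
#'
#' @param pssm Numeric L x 20 matrix of conservation scores, columns in
#'   [AA_ALPHABET] order.
#' @param disorder Numeric vector of disorder scores in \[0, 1\].
#' @param ss Character vector of secondary-structure labels in `C`/`H`/`E`.
#' @param sa Character vector of accessibility labels `buried`/`exposed`.
#' @return An object of class `residue_annotations`.
#' @export
residue_annotations <- function(pssm, disorder, ss, sa) {
  L <- nrow(pssm)
  stopifnot(ncol(pssm) == 20L, length(disorder) == L,
            length(ss) == L, length(sa) == L)
  if (any(disorder < 0 | disorder > 1)) {
    stop("disorder scores must lie in [0, 1]", call. = FALSE)
  }
  if (!all(ss %in% SS_LABELS)) {
    stop("secondary-structure labels must be C, H or E", call. = FALSE)
  }
  if (!all(sa %in% SA_LABELS)) {
    stop("accessibility labels must be 'buried' or 'exposed'", call. = FALSE)
  }
  colnames(pssm) <- AA_ALPHABET
  structure(list(pssm = pssm, disorder = disorder, ss = ss, sa = sa),
            class = "residue_annotations")
}

#' @export
length.residue_annotations <- function(x) nrow(x$pssm)

#' @export
print.residue_annotations <- function(x, ...) {
  cat(sprintf("<residue_annotations> %d residues\n", length(x)))
  invisible(x)
}

# internal: split file content (path or character scalar/vector) into lines
as_lines <- function(text) {
  if (length(text) == 1L && file.exists(text)) return(readLines(text))
  unlist(strsplit(text, "\n", fixed = TRUE))
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the query-profile dialect written by `blastpgp`/`psiblast
#' -out_ascii_pssm`: header lines, then one row per residue carrying the
#' residue index, the residue letter, 20 log-odds integers, 20 weighted
#' percentage columns and two trailing statistics. Only the 20 log-odds
#' columns are returned.
#'
#' @param text Path to a `.pssm` file, or its content as a character scalar.
#' @param sequence Optional expected amino-acid sequence; residue letters in
#'   the file are checked against it.
#' @return Numeric L x 20 matrix (columns named by [AA_ALPHABET]).
#' @export
parse_pssm <- function(text, sequence = NULL) {
  lines <- as_lines(text)
  is_row <- grepl("^\\s*\\d+\\s+[A-Z](\\s+-?\\d)", lines)
  if (!any(is_row)) stop("no PSSM matrix rows found", call. = FALSE)
  rows <- lines[is_row]
  row_no <- which(is_row)
  parsed <- lapply(seq_along(rows), function(i) {
    toks <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (!length(vals) %in% c(40L, 42L)) {
      stop(sprintf(
        "PSSM row at line %d has %d numeric columns (expected 40 + optional 2)",
        row_no[i], length(vals)), call. = FALSE)
    }
    list(residue = toks[2], scores = vals[1:20])
  })
  residues <- vapply(parsed, `[[`, character(1), "residue")
  if (!is.null(sequence)) {
    expect <- strsplit(sequence, "")[[1]]
    if (length(expect) != length(residues) || any(expect != residues)) {
      bad <- which(expect[seq_along(residues)] != residues)[1]
      stop(sprintf("PSSM residue mismatch at position %d ('%s' vs '%s')",
                   bad, residues[bad], expect[bad]), call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(parsed, `[[`, "scores"))
  colnames(m) <- AA_ALPHABET
  m
}

#' Parse PSIPRED vertical-format (.ss2) secondary-structure output
#'
#' Comment lines (starting with `#`) and blank lines are skipped; each data
#' row is `index residue label pC pH pE` and only the label is kept.
#'
#' @param text Path or character content.
#' @return Character vector of labels in `C`/`H`/`E`.
#' @export
parse_psipred_ss2 <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(character())
  labs <- vapply(strsplit(trimws(lines), "\\s+"), `[`, character(1), 3)
  bad <- which(!labs %in% SS_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown secondary-structure label '%s' at row %d",
                 labs[bad[1]], bad[1]), call. = FALSE)
  }
  labs
}

#' Parse VSL2-style per-residue disorder output
#'
#' Data rows are `index residue score [label]`; header/comment lines are
#' skipped. Scores must lie in \[0, 1\] up to a rounding tolerance of 1e-6
#' (values inside the tolerance are clipped).
#'
#' @param text Path or character content.
#' @return Numeric vector of disorder scores in \[0, 1\].
#' @export
parse_disorder <- function(text) {
  lines <- as_lines(text)
  keep <- grepl("^\\s*\\d+\\s+[A-Z]\\s+-?[0-9.]", lines)
  if (!any(keep)) return(numeric())
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  scores <- vapply(toks, function(t) suppressWarnings(as.numeric(t[3])),
                   numeric(1))
  if (anyNA(scores)) {
    stop(sprintf("non-numeric disorder score at row %d", which(is.na(scores))[1]),
         call. = FALSE)
  }
  tol <- 1e-6
  out <- which(scores < -tol | scores > 1 + tol)
  if (length(out) > 0L) {
    stop(sprintf("disorder score %g at row %d outside [0, 1]",
                 scores[out[1]], out[1]), call. = FALSE)
  }
  pmin(pmax(scores, 0), 1)
}

#' Parse two-state solvent-accessibility output
#'
#' Accepts either a single string of `b`/`e` characters (one per residue) or
#' rows whose last field is a two-state label (`b`/`e`/`buried`/`exposed`).
#'
#' @param text Path or character content.
#' @return Character vector of `buried`/`exposed` labels.
#' @export
parse_acc <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*[#>]", lines)]
  if (length(lines) == 0L) return(character())
  map1 <- c(b = "buried", e = "exposed")
  if (length(lines) == 1L && grepl("^[a-zA-Z]+$", trimws(lines))) {
    chars <- tolower(strsplit(trimws(lines), "")[[1]])
    bad <- which(!chars %in% names(map1))
    if (length(bad) > 0L) {
      stop(sprintf("unknown accessibility state '%s' at position %d",
                   chars[bad[1]], bad[1]), call. = FALSE)
    }
    return(unname(map1[chars]))
  }
  labs <- tolower(vapply(strsplit(trimws(lines), "\\s+"),
                         function(t) t[length(t)], character(1)))
  full <- c(map1, buried = "buried", exposed = "exposed")
  bad <- which(!labs %in% names(full))
  if (length(bad) > 0L) {
    stop(sprintf("unknown accessibility state '%s' at row %d",
                 labs[bad[1]], bad[1]), call. = FALSE)
  }
  unname(full[labs])
}

#' Deterministic fallback annotations
#'
#' A stand-in annotation provider for pipeline testing when no external-tool
#' output is available: the conservation profile of each residue is its row
#' of a fixed substitution-score table shipped with the package (BLOSUM62),
#' disorder is 0.5, secondary structure coil, accessibility exposed. Values
#' depend only on residue identity, never on position.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param quiet Suppress the one-line fallback notice (default FALSE).
#' @return A [residue_annotations] object.
#' @export
fallback_annotations <- function(sequence, quiet = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  check_residues(chars)
  if (!quiet) message("using fallback substitution-table annotations")
  residue_annotations(
    pssm = SUBSTITUTION_TABLE[chars, , drop = FALSE],
    disorder = rep(0.5, length(chars)),
    ss = rep("C", length(chars)),
    sa = rep("exposed", length(chars))
  )
}

#' Load annotation tracks for a protein from a directory
#'
#' Looks for `<id>.pssm`, `<id>.ss2`, `<id>.dis` and `<id>.acc` under
#' `annot_dir`. With `fallback = "substitution"` a missing directory or file
#' set is replaced by [fallback_annotations()]; with `"none"` it is an error.
#'
#' @param annot_dir Directory of per-protein annotation files (or `NULL`).
#' @param id Protein identifier.
#' @param sequence The protein sequence (used for validation and fallback).
#' @param fallback `"none"` or `"substitution"`.
#' @param quiet Passed to [fallback_annotations()].
#' @return A [residue_annotations] object.
#' @export
read_annotations <- function(annot_dir, id, sequence,
                             fallback = c("none", "substitution"),
                             quiet = FALSE) {
  fallback <- match.arg(fallback)
  paths <- file.path(annot_dir %||% "", paste0(id, c(".pssm", ".ss2", ".dis", ".acc")))
  if (is.null(annot_dir) || !all(file.exists(paths))) {
    if (fallback == "substitution") {
      return(fallback_annotations(sequence, quiet = quiet))
    }
    stop(sprintf("missing annotation files for protein '%s'", id),
         call. = FALSE)
  }
  ann <- residue_annotations(
    pssm = parse_pssm(paths[1], sequence = sequence),
    ss = parse_psipred_ss2(paths[2]),
    disorder = parse_disorder(paths[3]),
    sa = parse_acc(paths[4])
  )
  if (length(ann) != nchar(sequence)) {
    stop(sprintf("annotation length %d != sequence length %d for '%s'",
                 length(ann), nchar(sequence), id), call. = FALSE)
  }
  ann
}

#' Write annotation tracks in the external-tool dialects
#'
#' Emits `<id>.pssm`, `<id>.ss2`, `<id>.dis` and `<id>.acc` under `dir`,
#' round-trippable through the corresponding parsers. Used by the synthetic
#' generator and for fixture construction.
#'
#' @param ann A [residue_annotations] object.
#' @param sequence The protein sequence.
#' @param id Protein identifier (file stem).
#' @param dir Output directory (created if needed).
#' @return The four file paths, invisibly.
#' @export
write_annotations <- function(ann, sequence, id, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  stopifnot(length(ann) == L)

  pssm_path <- file.path(dir, paste0(id, ".pssm"))
  header <- c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down",
    paste0("            ", paste(sprintf("%3s", AA_ALPHABET), collapse = ""),
           "   ", paste(sprintf("%3s", AA_ALPHABET), collapse = "")))
  body <- vapply(seq_len(L), function(i) {
    lo <- sprintf("%3.0f", round(ann$pssm[i, ]))
    pct <- sprintf("%3d", rep(0L, 20))
    sprintf("%5d %s %s   %s  %.2f %.2f", i, chars[i],
            paste(lo, collapse = ""), paste(pct, collapse = ""), 0, 0)
  }, character(1))
  writeLines(c(header, body), pssm_path)

  ss2_path <- file.path(dir, paste0(id, ".ss2"))
  p <- function(lab, want) ifelse(ann$ss == want, 1, 0)
  ss_body <- sprintf("%4d %s %s  %5.3f %5.3f %5.3f", seq_len(L), chars,
                     ann$ss, p(ann$ss, "C"), p(ann$ss, "H"), p(ann$ss, "E"))
  writeLines(c("# PSIPRED VFORMAT", "", ss_body), ss2_path)

  dis_path <- file.path(dir, paste0(id, ".dis"))
  dis_body <- sprintf("%d\t%s\t%.6f\t%s", seq_len(L), chars, ann$disorder,
                      ifelse(ann$disorder >= 0.5, "D", "O"))
  writeLines(c("# residue disorder", dis_body), dis_path)

  acc_path <- file.path(dir, paste0(id, ".acc"))
  writeLines(paste(substr(ann$sa, 1, 1), collapse = ""), acc_path)

  invisible(c(pssm_path, ss2_path, dis_path, acc_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
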