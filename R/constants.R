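# Shared alphabets and embedded numeric tables.

#' Amino-acid alphabet in PSI-BLAST profile column order
#'
#' The 20 standard amino acids in the column order of a PSI-BLAST
#' position-specific scoring matrix (`ARNDCQEGHILKMFPSTWYV`). All PSSM-style
#' feature blocks use this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Atchley amino-acid factor scores
#'
#' Five multivariate summary scores per residue obtained by factor analysis
#' of the AAindex physicochemical property collection: polarity/accessibility
#' (often glossed as "polarity"), secondary-structure propensity, molecular
#' volume, codon diversity, and electrostatic charge. Values transcribed from
#' the published factor-score table; rows follow [AA_ALPHABET].
#'
#' @format Numeric 20 x 5 matrix, rownames = residues, colnames = factor
#'   labels `polarity`, `secondary.structure`, `molecular.volume`,
#'   `codon.diversity`, `electrostatic.charge`.
#' @export
ATCHLEY_FACTORS <- local({
  vals <- c(
    # pol    ss      vol     codon   charge
    -0.591, -1.302, -0.733,  1.570, -0.146, # A
     1.538, -0.055,  1.502,  0.440,  2.897, # R
     0.945,  0.828,  1.299, -0.169,  0.933, # N
     1.050,  0.302, -3.656, -0.259, -3.242, # D
    -1.343,  0.465, -0.862, -1.020, -0.255, # C
     0.931, -0.179, -3.005, -0.503, -1.853, # Q
     1.357, -1.453,  1.477,  0.113, -0.837, # E
    -0.384,  1.652,  1.330,  1.045,  2.064, # G
     0.336, -0.417, -1.673, -1.474, -0.078, # H
    -1.239, -0.547,  2.131,  0.393,  0.816, # I
    -1.019, -0.987, -1.505,  1.266, -0.912, # L
     1.831, -0.561,  0.533, -0.277,  1.648, # K
    -0.663, -1.524,  2.219, -1.005,  1.212, # M
    -1.006, -0.590,  1.891, -0.397,  0.412, # F
     0.189,  2.081, -1.628,  0.421, -1.392, # P
    -0.228,  1.399, -4.760,  0.670, -2.647, # S
    -0.032,  0.326,  2.213,  0.908,  1.313, # T
    -0.595,  0.009,  0.672, -2.128, -0.184, # W
     0.260,  0.830,  3.097, -0.838,  1.512, # Y
    -1.337, -0.279, -0.544,  1.242, -1.262  # V
  )
  m <- matrix(vals, nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET,
                              c("polarity", "secondary.structure",
                                "molecular.volume", "codon.diversity",
                                "electrostatic.charge")))
  m
})

# BLOSUM62 restricted to the 20 standard residues, AA_ALPHABET order.
# Used as the deterministic stand-in conservation profile by
# fallback_annotations() and as the base profile of the synthetic generator.
SUBSTITUTION_TABLE <- local({
  vals <- c(
  4, -1, -2, -2, 0, -1, -1, 0, -2, -1, -1, -1, -1, -2, -1, 1, 0, -3, -2, 0,
  -1, 5, 0, -2, -3, 1, 0, -2, 0, -3, -2, 2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2, 0, 6, 1, -3, 0, 0, 0, 1, -3, -3, 0, -2, -3, -2, 1, 0, -4, -2, -3,
  -2, -2, 1, 6, -3, 0, 2, -1, -1, -3, -4, -1, -3, -3, -1, 0, -1, -4, -3, -3,
  0, -3, -3, -3, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1, 1, 0, 0, -3, 5, 2, -2, 0, -3, -2, 1, 0, -3, -1, 0, -1, -2, -1, -2,
  -1, 0, 0, 2, -4, 2, 5, -2, 0, -3, -3, 1, -2, -3, -1, 0, -1, -3, -2, -2,
  0, -2, 0, -1, -3, -2, -2, 6, -2, -4, -4, -2, -3, -3, -2, 0, -2, -2, -3, -3,
  -2, 0, 1, -1, -3, 0, 0, -2, 8, -3, -3, -1, -2, -1, -2, -1, -2, -2, 2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3, 4, 2, -3, 1, 0, -3, -2, -1, -3, -1, 3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1,
  -1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 5, 0, -2, -1, -1, -1, -1, 1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1, 0, 0, -3, 0, 6, -4, -2, -2, 1, 3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4, 7, -1, -1, -4, -3, -2,
  1, -1, 1, 0, -1, 0, 0, 0, -1, -2, -2, 0, -1, -2, -1, 4, 1, -3, -2, -2,
  0, -1, 0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1, 1, 5, -2, -2, 0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1, 1, -4, -3, -2, 11, 2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3, 2, -1, -1, -2, -1, 3, -3, -2, -2, 2, 7, -1,
  0, -3, -3, -3, -1, -2, -2, -3, -3, 3, 1, -2, 1, -1, -2, -2, 0, -3, -1, 4)
  matrix(vals, nrow = 20, byrow = TRUE,
         dimnames = list(AA_ALPHABET, AA_ALPHABET))
})

SS_LABELS <- c("C", "H", "E")
SA_LABELS <- c("buried", "exposed")
PAD_CHAR  <- "-"

# internal: validate a vector of residues against the 20-letter alphabet
check_residues <- function(x, allow_pad = FALSE, what = "residue") {
  ok <- x %in% AA_ALPHABET | (allow_pad & x == PAD_CHAR)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("unknown %s '%s' at position %d", what, x[bad], bad),
         call. = FALSE)
  }
  invisible(x)
}
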