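Package: pupsite
Title: Pupylation-Site Prediction from Sequence-Derived Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts pupylation sites (attachment of the prokaryotic
    ubiquitin-like protein Pup to substrate lysines) from protein sequence.
    Candidate lysines are represented as 21-residue peptide windows encoded
    into 646 features spanning five families: Atchley amino-acid factors,
    position-specific scoring matrix conservation scores, structural
    disorder, secondary structure and solvent accessibility. Features are
    ranked by minimum-redundancy maximum-relevance (mRMR) mutual
    information, an optimal subset is selected incrementally under
    jackknife nearest-neighbour evaluation, and the final classifier is a
    grid-searched radial-kernel support vector machine. Includes parsers
    for the standard annotation-tool output formats, feature-attribution
    tables, and a seeded synthetic proteome generator with planted motifs
    for offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
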