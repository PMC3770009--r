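---
title: "Predicting pupylation sites: model, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pupylation sites: model, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupsite)
```

## The problem

Pupylation is the covalent attachment of the prokaryotic ubiquitin-like
protein (Pup) to a substrate lysine, catalysed by the ligase PafA; in
actinobacteria such as *Mycobacterium tuberculosis* it marks proteins for
proteasomal degradation. Experimentally mapping which lysine carries the
modification is slow, so sequence-based prediction of pupylation sites is a
useful triage tool. `pupsite` implements a classical and transparent
machine-learning pipeline for this task: fixed-width peptide windows around
candidate lysines, an interpretable feature encoding, information-theoretic
feature selection, and a kernel SVM as the final classifier.

## From proteins to samples

Every lysine in a protein defines one candidate. A window of `flank = 10`
residues on each side (21 residues total) is cut around it; positions beyond
the sequence ends are filled with the placeholder `-`. Windows centred on an
annotated site are positive samples; all other lysine windows are negative.
Because non-modified lysines vastly outnumber modified ones, negatives are
subsampled uniformly at random to a 3:1 negative:positive ratio (seeded, so
datasets are reproducible). Before window extraction the dataset is cleaned
the way curated benchmark sets are built: proteins shorter than 50 residues
(likely fragments) or containing non-standard letters (B, J, O, U, X, Z) are
removed, and near-duplicate proteins are reduced with a greedy longest-first
clustering that discards any protein with ≥ 40% identity to an
already-retained one. Identity is computed from an ends-free global
alignment (match +1, mismatch 0, gap open 5 / extend 1, via `Biostrings`)
as exact matches over alignment columns. This in-package clusterer is a
deliberate, fully specified replacement for external clustering binaries;
representatives computed elsewhere can be supplied with `keep_ids`.

Window sites are numbered 1–21 left to right; the central lysine is site 11.

## The 646-feature encoding

Each window is encoded site by site with five feature families:

| family | per site | meaning |
|--------|----------|---------|
| AAF    | 5        | Atchley amino-acid factors (polarity, secondary-structure propensity, molecular volume, codon diversity, electrostatic charge) |
| PSSM   | 20       | conservation scores of the residue against each of the 20 amino acids, `ARNDCQEGHILKMFPSTWYV` order |
| DIS    | 1        | structural disorder score in [0, 1] |
| SS     | 3        | secondary-structure one-hot over coil/helix/strand |
| SA     | 2        | two-state solvent accessibility one-hot (buried/exposed) |

A flanking site therefore carries 31 features. The centre is always lysine,
so its five amino-acid factors are constant and are omitted: 26 features.
The total is 20 × 31 + 26 = 646. Padding sites contribute zeros in every
family (so their one-hot blocks sum to 0 instead of 1) — the neutral choice
for positions that do not exist. Within a site the order is
AAF → PSSM → DIS → SS → SA; the full address table (`descriptor_table()`)
is serialisable and checksummed into trained models so that saved models
refuse to run against a different layout.

Conservation, disorder, secondary structure and accessibility are
per-residue tracks normally produced by external tools (PSI-BLAST profiles,
VSL2, PSIPRED, SSPro). The package parses those tools' standard output
dialects (`parse_pssm()`, `parse_disorder()`, `parse_psipred_ss2()`,
`parse_acc()`); PSSM values are used as raw log-odds, the native PSI-BLAST
output (a logistic rescaling is easy to add downstream but is not applied by
default because none is standard). When no tool output is available,
`fallback_annotations()` supplies a deterministic stand-in — each residue's
BLOSUM62 row as its profile, disorder 0.5, coil, exposed — which keeps the
pipeline runnable and testable but carries no position-specific information;
it is flagged in logs and intended for plumbing tests, not for production
predictions.

## Feature selection

Features are ranked by mutual information after a three-state
discretization: per feature, values below mean − σ, within one σ, and above
mean + σ map to states 0/1/2 (population σ; constant features collapse to
state 1). This is the classical treatment of continuous variables in the
mRMR literature. Two rankings are produced:

* **MaxRel** — decreasing I(feature; class), ties broken by feature index;
* **mRMR** — greedy difference form (MID): after seeding with the most
  relevant feature, each step selects
  argmax over the candidates of I(f; y) − (1/|S|) Σ I(f; s) for the
  already-selected set S. The quotient (MIQ) variant is not implemented;
  MID is the common default of the reference implementations.

Mutual information is the plug-in estimate in bits; the base only rescales
scores and never reorders.

**Incremental feature selection (IFS)** then walks the mRMR list: for every
k, the matrix restricted to the top-k features is evaluated by jackknife
(leave-one-out) nearest-neighbour classification, and the k maximizing the
Matthews correlation coefficient (smallest k on ties) defines the optimal
subset. The implementation grows the pairwise squared-distance matrix one
feature at a time, so the full 646-point curve costs one pass over the
features rather than 646 independent evaluations; a test verifies the fast
path agrees bit-for-bit with naive truncation. The jackknife unit is the
peptide window; a grouped variant (`groups =` the source protein) is
available for leave-one-protein-out evaluation, since with windows cut from
the same protein the two readings genuinely differ. The nearest-neighbour
distance is Euclidean on the raw features; no standardization is applied
before ranking or NNA (one-hot and PSSM scales are part of the encoding
definition), and the SVM stage exposes `scale` as an option, default off.

Metrics: Sn = TP/(TP+FN), Sp = TN/(TN+FP), Ac = (TP+TN)/N, and MCC with the
convention that a zero factor in the denominator yields MCC = 0. ROC/AUC
use the midrank (Mann–Whitney) convention; NNA decision scores for ROC are
signed margins (nearest-negative minus nearest-positive distance).

## The final classifier

The optimal subset feeds a radial-basis-function SVM (LIBSVM via `e1071`).
Both the cost C and kernel width γ are searched over
{2⁻⁷, 2⁻⁶, …, 2⁸} — 16 × 16 = 256 pairs — by stratified 5-fold
cross-validation with accuracy as the selection metric (MCC selectable);
ties resolve to the smaller C, then the smaller γ. Fold assignment is a
deterministic function of the seed, and trained models persist with an
integrity checksum.

## What the synthetic generator emulates

Real annotations (PSI-BLAST against a large reference database, disorder
and structure predictors) cannot be produced offline, so the package ships
a generator (`generate_dataset()`) that emulates the statistical structure
the pipeline exploits, with ground truth attached:

* background sequences are i.i.d. uniform over the 20 residues
  (a natural-frequency table can be supplied via `motif_spec(background=)`);
* planted positive sites place a K and enrich window sites 7 and 10 with
  glutamate at probability 0.6 — an acidic upstream context of the kind
  reported for pupylation substrates — while site 11 is the centre itself;
* annotation tracks are coupled to the class at those same sites: the
  profile column of the signal residue is raised by 4 score units (one
  substitution-matrix step, comparable to the BLOSUM62 dynamic range),
  disorder at site 10 by 0.3, and the centre is forced to coil/exposed with
  probability 0.3. Each coupling is an independent knob so family-specific
  contributions can be ablated; setting all couplings to zero and the
  enrichment to the background frequency gives an exchangeable null.

The default study condition is 120 proteins of length 80–160 with 200
planted sites, encoded with 3:1 negative sampling into 800 windows. Those
sizes keep a full mRMR ranking plus the complete 646-point IFS curve and a
256-pair grid search in the low tens of seconds on one CPU while leaving
class counts large enough for stable binomial checks.

What passing on synthetic data does **not** show: real conservation
profiles are strongly autocorrelated along the sequence, real motifs are
degenerate, and real negatives share proteome composition biases with
positives. Synthetic recovery rates and MCC values are therefore upper
bounds on the difficulty of the construction, not estimates of real-data
performance; reproducing published real-data numbers requires the original
curated dataset and the external annotation tools.

## Numerical and degenerate-input conventions

* Ties: nearest-neighbour ties take the lowest training-row index; ranking
  ties take the ascending feature index; IFS plateaus take the smallest k;
  grid-search ties take the smallest C then γ.
* Empty classes: metrics report Sn/Sp as `NA` rather than 0; single-class
  inputs are errors for ranking, jackknife, ROC and training.
* Disorder scores are accepted within 1e-6 of [0, 1] and clipped; anything
  further out is an error, since it indicates a malformed file rather than
  rounding.
* Windows at sequence ends are padded, never dropped, so every lysine is a
  candidate.
* All randomness (negative subsampling, fold assignment, the generator)
  flows through explicit integer seeds; two runs with equal seeds produce
  byte-identical artifacts.

## A small end-to-end run

```{r pipeline, fig.width = 6, fig.height = 3.5}
ds <- generate_dataset(n_proteins = 20, length_range = c(60, 100),
                       n_positive_sites = 30, seed = 7)
res <- run_pipeline(ds$proteins, ds$annotations, identity_threshold = NULL,
                    seed = 7, ifs_k_max = 60,
                    C_grid = 2^(-2:4), gamma_grid = 2^(-6:0))
glance(res$ifs)
autoplot(res$ifs)
```

```{r attribution}
sel <- res$ranked_mrmr$feature_index[seq_len(res$optimum$k)]
tabulate_features(sel, res$features$descriptors, grouping = "site")
```

## Known limitations

* The greedy identity clusterer is O(n²) pairwise alignments; for thousands
  of proteins an external clustering should be imported via `keep_ids`.
* The fallback annotation provider is intentionally information-poor;
  predictions made with it reflect sequence composition only.
* Only binary two-state accessibility and three-state secondary structure
  are supported, matching the encoding definition.
* k-nearest-neighbour with k > 1, MIQ-form mRMR and probability-calibrated
  SVM outputs are out of scope.
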