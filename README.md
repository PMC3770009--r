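# pupsite

Prediction of **pupylation sites** — the attachment of the prokaryotic
ubiquitin-like protein Pup to substrate lysines by the ligase PafA, the
degradation tag of the mycobacterial proteasome — from protein sequence.
It is aimed at computational biologists who want a transparent,
fully reproducible implementation of the classical peptide-window +
feature-selection + SVM architecture for lysine-modification prediction,
with every stage exposed as a composable, pipe-friendly function.

## The method

Every lysine defines a 21-residue window (10 residues each side, `-`-padded
at sequence ends; window sites numbered 1–21 with the K at site 11).
Each window is encoded into **646 features**:

- 5 Atchley amino-acid factors per flanking site (omitted at the centre,
  which is always K),
- 20 PSSM conservation scores per site (`ARNDCQEGHILKMFPSTWYV`-ordered
  log-odds from PSI-BLAST profiles, or a deterministic fallback),
- 1 structural disorder score per site,
- a 3-bit coil/helix/strand one-hot and a 2-bit buried/exposed one-hot per
  site,

giving 20 × 31 + 26 = 646. Features are discretized at μ ± σ and ranked by
**mRMR** (greedy difference form,
argmax<sub>f</sub> [ I(f; y) − (1/|S|) Σ<sub>s∈S</sub> I(f; s) ]);
**incremental feature selection** walks the ranked list and picks the
subset size maximizing the Matthews correlation coefficient under
jackknife (leave-one-out) nearest-neighbour evaluation; the final model is
an RBF-kernel SVM with C, γ ∈ {2⁻⁷…2⁸} (256 pairs) chosen by stratified
5-fold cross-validation. Attribution tables count the selected features by
family, window site or subtype. A seeded synthetic-proteome generator with
planted motifs (acidic enrichment upstream of the modified K, coupled
annotation tracks) makes the whole pipeline testable offline with known
ground truth.

Dataset hygiene follows standard benchmark practice: proteins < 50 residues
or containing non-standard letters are dropped, proteins with ≥ 40%
pairwise identity are greedily reduced, and negatives are subsampled 3:1.

## Worked example

```r
library(pupsite)

ds  <- generate_dataset(n_proteins = 20, length_range = c(60, 100),
                        n_positive_sites = 30, seed = 7)
res <- run_pipeline(ds$proteins, ds$annotations, identity_threshold = NULL,
                    seed = 7, ifs_k_max = 60,
                    C_grid = 2^(-2:4), gamma_grid = 2^(-6:0))

res$features
#> <pup_features> 104 windows x 646 features (30 positive, 74 negative)

glance(res$ifs)
#> # A tibble: 1 × 5
#>   k_opt    Sn    Sp    Ac   MCC
#>   <int> <dbl> <dbl> <dbl> <dbl>
#> 1     2 0.967 0.986 0.981 0.953

top_features_report(res$ranked_mrmr, 5, res$features$descriptors)
#> # A tibble: 5 × 6
#>    rank feature_index  score  site family subtype
#>   <int>         <int>  <dbl> <int> <chr>  <chr>
#> 1     1           322 0.602     11 PSSM   K
#> 2     2           305 0.191     10 DIS    score
#> 3     3           291 0.0725    10 PSSM   E
#> 4     4           198 0.0577     7 PSSM   E
#> 5     5           145 0.0350     5 PSSM   S
```

Reading the output: the IFS curve peaks at two features with a jackknife
MCC of 0.953 — the generator plants a strong, low-dimensional signal, so a
small optimal subset is expected. The top of the mRMR list recovers the
planted feature addresses: conservation of the central lysine (site 11,
PSSM/K), the elevated disorder and glutamate conservation at site 10, and
glutamate conservation at site 7. `autoplot(res$ifs)` draws the IFS curve,
`tabulate_features()` + `autoplot()` the attribution bar charts, and
`predict(res$model, ...)` scores new windows.

A thin command-line front end over the same functions ships in
`inst/scripts/pupsite` (subcommands `simulate`, `dataset`, `encode`,
`rank`, `ifs`, `train`, `predict`, `attribute`).

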