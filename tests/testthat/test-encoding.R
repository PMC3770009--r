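# The 646-feature encoding and its descriptor addressing.

test_that("Atchley factor lookup matches the published table", {
  expect_equal(unname(atchley_factors("-")), rep(0, 5))
  expect_identical(atchley_factors("W"), atchley_factors("W"))
  expect_error(atchley_factors("B"), "unknown residue")

  # transcription anchors from the published factor-score table
  expect_equal(unname(atchley_factors("A")),
               c(-0.591, -1.302, -0.733, 1.570, -0.146))
  expect_equal(unname(atchley_factors("K")),
               c(1.831, -0.561, 0.533, -0.277, 1.648))
  # factor scores are centred over the 20 residues: column means ~0
  expect_true(all(abs(colMeans(ATCHLEY_FACTORS)) < 0.01))
  expect_equal(unname(ATCHLEY_FACTORS["S", "molecular.volume"]), -4.760)
  expect_equal(unname(ATCHLEY_FACTORS["R", "electrostatic.charge"]), 2.897)
})

test_that("descriptor table has the documented layout", {
  d <- descriptor_table(10)
  expect_equal(nrow(d), 646L)
  expect_equal(d$index, 1:646)                       # bijection
  expect_equal(sum(d$site == 11), 26L)
  for (s in setdiff(1:21, 11)) expect_equal(sum(d$site == s), 31L)
  expect_equal(d$family[1], "AAF")
  expect_equal(d$site[1], 1L)
  expect_equal(sum(d$family == "AAF" & d$site == 11), 0L)
  # per-site family composition
  comp <- table(d$family[d$site == 3])
  expect_equal(as.integer(comp[c("AAF", "PSSM", "DIS", "SS", "SA")]),
               c(5L, 20L, 1L, 3L, 2L))
  # generic flank: 2*flank*31 + 26
  expect_equal(nrow(descriptor_table(3)), 2 * 3 * 31 + 26)
  # stable across calls and through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors(d, path)
  expect_equal(read_descriptors(path), tibble::as_tibble(d))
})

test_that("window encoding matches an independent slot-by-slot assembly", {
  seq <- paste(rep(AA_ALPHABET, 2), collapse = "")  # 40 residues
  centre <- 22L
  seq <- paste0(substr(seq, 1, centre - 1), "K", substr(seq, centre + 1, 40))
  ann <- make_fixture_annotations(seq)
  win <- substr(seq, centre - 10, centre + 10)
  v <- encode_window(win, centre, ann)
  expect_length(v, 646L)

  # hand assembly, walking the documented order site by site
  d <- descriptor_table(10)
  expected <- numeric(646)
  chars <- strsplit(win, "")[[1]]
  for (site in 1:21) {
    pos <- centre - 11L + site
    res <- chars[site]
    idx <- which(d$site == site)
    block <- c(
      if (site != 11) ATCHLEY_FACTORS[res, ],
      ann$pssm[pos, ],
      ann$disorder[pos],
      c(C = 0, H = 0, E = 0) + (c("C", "H", "E") == ann$ss[pos]),
      c(buried = 0, exposed = 0) + (c("buried", "exposed") == ann$sa[pos]))
    expected[idx] <- block
  }
  expect_equal(v, expected)

  # one-hot blocks per real site sum to 1 (SS) and 1 (SA)
  for (site in 1:21) {
    expect_equal(sum(v[d$index[d$site == site & d$family == "SS"]]), 1)
    expect_equal(sum(v[d$index[d$site == site & d$family == "SA"]]), 1)
  }
})

test_that("padding sites contribute zeros in every family", {
  seq <- paste0("K", strrep("A", 29))
  ann <- fallback_annotations(seq, quiet = TRUE)
  win <- paste0(strrep("-", 10), substr(seq, 1, 11))
  v <- encode_window(win, 1L, ann)
  d <- descriptor_table(10)
  pad_idx <- d$index[d$site <= 10]
  expect_true(all(v[pad_idx] == 0))
  expect_true(any(v[d$index[d$site > 10]] != 0))
  # exactly the padded sites are all-zero blocks
  for (site in 11:21) {
    expect_true(any(v[d$index[d$site == site]] != 0))
  }
})

test_that("dataset encoding preserves row order and addresses correctly", {
  ds <- generate_dataset(n_proteins = 6, length_range = c(60, 80),
                         n_positive_sites = 10, seed = 3)
  windows <- extract_windows(ds$proteins)
  feats <- encode_dataset(windows, ds$annotations)
  expect_equal(nrow(feats$X), nrow(windows))
  expect_equal(ncol(feats$X), 646L)

  # direct lookup oracle: the (site 11, PSSM, K) column equals the centre
  # residue's K-column profile entry
  d <- feats$descriptors
  colK <- d$index[d$site == 11 & d$family == "PSSM" & d$subtype == "K"]
  for (i in seq_len(min(5, nrow(windows)))) {
    ann <- ds$annotations[[windows$protein_id[i]]]
    expect_equal(unname(feats$X[i, colK]),
                 unname(ann$pssm[windows$center[i], "K"]))
  }

  # duplicated windows produce identical rows; empty input, empty matrix
  dup <- windows[c(1, 1), ]
  Xdup <- encode_dataset(dup, ds$annotations)$X
  expect_equal(Xdup[1, ], Xdup[2, ])
  expect_equal(nrow(encode_dataset(windows[0, ], ds$annotations)$X), 0L)

  # shuffling window order permutes rows identically
  perm <- withr::with_seed(1, sample(nrow(windows)))
  Xp <- encode_dataset(windows[perm, ], ds$annotations)$X
  expect_equal(unname(Xp), unname(feats$X[perm, ]))

  expect_error(encode_dataset(windows, ds$annotations[-1]),
               ds$proteins$id[1])
})

test_that("tidy() exposes the long descriptor-addressed view", {
  ds <- generate_dataset(n_proteins = 3, length_range = c(60, 70),
                         n_positive_sites = 3, seed = 5)
  feats <- encode_synthetic(ds, seed = 5)
  long <- tidy(feats)
  expect_equal(nrow(long), nrow(feats$X) * 646L)
  expect_setequal(unique(long$family), c("AAF", "PSSM", "DIS", "SS", "SA"))
  one <- long[long$index == 1, ]
  expect_equal(one$value, unname(feats$X[, 1]))
})
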