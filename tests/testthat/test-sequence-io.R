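# Sequence I/O, dataset filters, redundancy reduction, window extraction
# and negative subsampling.

test_that("FASTA read/write round-trips and rejects malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKT"), fa)
  rec <- read_fasta(fa)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "MKT")
  expect_equal(rec$sites[[1]], integer())

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  two <- make_proteins(c("MKTAYIAKQR", "GGKLMNPQRS"))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(two, out)
  back <- read_fasta(out)
  expect_equal(back$id, two$id)
  expect_equal(back$sequence, two$sequence)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKT", ">p1"), bad)
  expect_error(read_fasta(bad), "line 1")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKT", ">p1", "MKA"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("site tables parse, deduplicate and validate on merge", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition", "p1\t5", "p1\t5", "p2\t3", "p1\t2"), f)
  sites <- read_sites(f)
  expect_equal(split(sites$position, sites$protein_id),
               list(p1 = c(2L, 5L), p2 = 3L))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_id\tposition", empty)
  expect_equal(nrow(read_sites(empty)), 0L)

  badf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tposition", "p1\tfive"), badf)
  expect_error(read_sites(badf), "non-integer")

  prot <- make_proteins("MAKTA")  # K at 3
  expect_equal(
    merge_sites(prot, tibble::tibble(protein_id = "p1", position = 3L))$sites[[1]],
    3L)
  expect_error(
    merge_sites(prot, tibble::tibble(protein_id = "p1", position = 2L)),
    "not 'K'")
  expect_error(
    merge_sites(prot, tibble::tibble(protein_id = "p1", position = 99L)),
    "outside")
})

test_that("length and alphabet filters use the documented boundaries", {
  seq49 <- strrep("A", 48) |> paste0("K")
  seq50 <- strrep("A", 49) |> paste0("K")
  seqX <- paste0(strrep("A", 49), "X")
  prot <- make_proteins(c(seq49, seq50, seqX))
  kept <- filter_proteins(prot)
  expect_equal(kept$id, "p2")
  expect_equal(nrow(filter_proteins(prot[0, ])), 0L)
})

test_that("greedy redundancy reduction matches an all-pairs oracle", {
  s <- c(a = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
         b = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",  # ~97% identical to a
         c = "GGGGGPPPPPWWWWWCCCCCHHHHHNNNNNYYY",
         d = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIE",   # prefix of a
         e = "DDDDDEEEEEDDDDDEEEEEDDDDDEEEEEDDD")
  prot <- make_proteins(unname(s), ids = names(s))

  # oracle: all-pairs identity, then the same longest-first greedy rule
  n <- length(s)
  idm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    idm[i, j] <- pairwise_identity(s[i], s[j])
  }
  ord <- order(-nchar(s), names(s))
  kept <- integer()
  for (i in ord) {
    if (all(idm[i, kept] < 0.40) || length(kept) == 0) kept <- c(kept, i)
  }
  expected_ids <- sort(names(s)[kept])

  red <- reduce_redundancy(prot)
  expect_equal(sort(red$id), expected_ids)

  # identical pair: only one survives; disjoint pair: both survive
  twin <- make_proteins(c("MKTAYIAKQR", "MKTAYIAKQR"))
  expect_equal(nrow(reduce_redundancy(twin)), 1L)
  disjoint <- make_proteins(c("MKMKMKMKMK", "ACDEFGHIST"))
  expect_equal(nrow(reduce_redundancy(disjoint)), 2L)

  # idempotence
  expect_equal(reduce_redundancy(red), red)
})

test_that("window extraction pads ends, labels sites and covers every K", {
  seq30 <- paste0("K", strrep("A", 29))
  w <- extract_windows(make_proteins(seq30, sites = list(1L)))
  expect_equal(nrow(w), 1L)
  expect_equal(w$peptide, paste0(strrep("-", 10), "K", substr(seq30, 2, 11)))
  expect_equal(w$label, "positive")

  seq21 <- paste0(strrep("A", 10), "K", strrep("C", 10))
  w21 <- extract_windows(make_proteins(seq21))
  expect_equal(w21$peptide, seq21)

  seq3k <- "AKAAKAAAKA"
  w3 <- extract_windows(make_proteins(seq3k, sites = list(5L)))
  expect_equal(nrow(w3), 3L)
  expect_equal(sum(w3$label == "positive"), 1L)
  expect_equal(w3$center, c(2L, 5L, 9L))

  # property: window count equals K count; de-padded residues match source
  withr::with_seed(42, {
    for (rep in 1:5) {
      seq <- paste(sample(AA_ALPHABET, 40, replace = TRUE), collapse = "")
      w <- extract_windows(make_proteins(seq))
      expect_equal(nrow(w), sum(strsplit(seq, "")[[1]] == "K"))
      for (i in seq_len(nrow(w))) {
        depad <- gsub("-", "", w$peptide[i])
        lo <- max(1, w$center[i] - 10)
        hi <- min(nchar(seq), w$center[i] + 10)
        expect_equal(depad, substr(seq, lo, hi))
      }
    }
  })
})

test_that("negative subsampling keeps positives, caps, and is seeded", {
  w <- tibble::tibble(
    protein_id = "p", center = 1:110,
    peptide = strrep("K", 21),
    label = c(rep("positive", 10), rep("negative", 100)))
  s <- sample_negatives(w, ratio = 3, seed = 5)
  expect_equal(sum(s$label == "positive"), 10L)
  expect_equal(sum(s$label == "negative"), 30L)
  expect_false(any(duplicated(s$center)))

  capped <- sample_negatives(w[1:30, ], ratio = 3, seed = 5)
  expect_equal(sum(capped$label == "negative"), 20L)

  expect_identical(sample_negatives(w, 3, seed = 7),
                   sample_negatives(w, 3, seed = 7))
  expect_error(sample_negatives(w[w$label == "negative", ], 3, seed = 1),
               "no positive")
})

test_that("window tables round-trip through TSV", {
  w <- extract_windows(make_proteins("AKAAKAAAKA", sites = list(5L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windows(w, path)
  expect_equal(read_windows(path), w)
})
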