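test_that("FASTA reading enforces the alignment contract", {
  p <- write_fasta(c("a", "b", "c"),
                   c("ACGTACGTAC", "ACGTACGTAT", "ACGTTCGTAC"))
  aln <- read_alignment(p)
  expect_s3_class(aln, "dna_alignment")
  expect_equal(aln$L, 10)
  expect_equal(length(aln$ids), 3)

  ragged <- write_fasta(c("a", "b"), c("ACGTACGTAC", "ACGTACGTA"))
  expect_error(read_alignment(ragged), "alignment length")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty), "empty")

  expect_error(alignment(c("a", "b"), c("ACGJ", "ACGT")), "non-IUPAC")
})

test_that("complete deletion masks any column containing missing data", {
  p <- write_fasta(c("a", "b", "c"),
                   c("ACGTACGTAC", "ACGNACGTAT", "ACGTACGTAC"))
  aln <- read_alignment(p)
  pm <- toy_popmap(c("a", "b", "c"), rep("X", 3))
  spec <- collapse_haplotypes(aln, pm)
  expect_equal(spec$usable_sites, 9L)  # the N column is dropped for everyone
  # site 10 differs between a/c and b, site 4 is masked: 2 haplotypes remain
  expect_equal(ncol(spec$counts), 2L)
})

test_that("haplotype collapsing matches hand enumeration", {
  spec <- toy_spectrum(c("ACGT", "ACGT", "ACTT"), rep("P1", 3))
  expect_equal(ncol(spec$counts), 2L)
  expect_equal(unname(spec$counts[1, ]), c(2L, 1L))
  expect_equal(unname(spec$diffs), rbind(c(0L, 1L), c(1L, 0L)))

  mono <- toy_spectrum(rep("ACGT", 4), rep("P1", 4))
  expect_equal(ncol(mono$counts), 1L)
  expect_equal(unname(mono$diffs), matrix(0L, 1, 1))

  two <- toy_spectrum(c("ACGT", "ACGT"), c("P1", "P2"))
  expect_equal(unname(two$counts), rbind(1L, 1L))

  aln <- alignment(c("x", "y"), c("ACGT", "ACGT"))
  pm <- toy_popmap("x", "A")
  expect_error(collapse_haplotypes(aln, pm), "unmapped")
})

test_that("collapsing preserves the sequence multiset and diffs are a metric", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    seqs <- replicate(n, paste0(sample(c("A", "C", "T"), 8, replace = TRUE),
                                collapse = ""))
    spec <- toy_spectrum(seqs, rep("P", n))
    # expansion by counts reconstructs the multiset of input sequences
    rebuilt <- rep(unname(apply(spec$haplotypes, 1, paste0, collapse = "")),
                   unname(colSums(spec$counts)))
    expect_equal(sort(rebuilt), sort(seqs))
    # L1 distance over sites: triangle inequality
    D <- spec$diffs
    H <- nrow(D)
    if (H >= 3)
      for (i in 1:H) for (j in 1:H) for (k in 1:H)
        expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})

test_that("site grouping follows single linkage under haversine distance", {
  # ~10 km apart -> one group; ~100 km apart -> two groups
  pm_close <- toy_popmap(c("a", "b"), c("s1", "s2"),
                         lat = c(0, 0.09), lon = c(0, 0))
  g <- group_sites(pm_close, 50)
  expect_equal(length(unique(g$group)), 1L)

  pm_far <- toy_popmap(c("a", "b"), c("s1", "s2"),
                       lat = c(0, 0.9), lon = c(0, 0))
  g <- group_sites(pm_far, 50)
  expect_equal(length(unique(g$group)), 2L)

  # chain at ~40/40/75 km: single linkage joins all three through the middle
  pm3 <- toy_popmap(c("a", "b", "c"), c("s1", "s2", "s3"),
                    lat = c(0, 0.3597, 0.6316), lon = c(0, 0, 0.2344))
  g <- group_sites(pm3, 50)
  expect_equal(length(unique(g$group)), 1L)
})

test_that("site grouping is idempotent and invariant to row order", {
  set.seed(7)
  df <- data.frame(sample_id = sprintf("s%d", 1:6),
                   site = sprintf("site%d", 1:6),
                   latitude = runif(6, -10, 10),
                   longitude = runif(6, 30, 45))
  pm <- popmap(df)
  g1 <- group_sites(pm, 200)
  g2 <- group_sites(g1, 200)
  expect_equal(g1$group, g2$group)
  shuf <- popmap(df[sample(nrow(df)), ])
  g3 <- group_sites(shuf, 200)
  m1 <- stats::setNames(g1$group, g1$site)
  m3 <- stats::setNames(g3$group, g3$site)
  expect_equal(m1[sort(names(m1))], m3[sort(names(m3))])

  expect_error(group_sites(popmap(data.frame(
    sample_id = "a", site = "x", latitude = NA, longitude = 1))),
    "coordinates")
})
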