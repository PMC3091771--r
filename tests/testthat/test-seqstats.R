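test_that("dinucleotide windows overlap and skip Ns", {
  d <- dinucleotide_counts("ACGT")
  expect_equal(unname(d[c("AC", "CG", "GT")]), c(1L, 1L, 1L))
  expect_equal(sum(d), 3L)
  d2 <- dinucleotide_counts("ACNGT")
  expect_equal(unname(d2[c("AC", "GT")]), c(1L, 1L))
  expect_equal(sum(d2), 2L)
  expect_equal(sum(dinucleotide_counts("AAAAAAAAAA")), 9L)
})

test_that("invalid characters are rejected with their position", {
  expect_error(dinucleotide_counts("ACGXA"), "position 4")
  expect_error(composition("acgu"), "position 4")
})

test_that("composition reproduces hand-derived values", {
  c1 <- composition("ACGT")
  expect_equal(c1$gc, 0.5)
  expect_equal(c1$cpg_oe, 4)            # 1 * 4 / (1 * 1)
  expect_equal(c1$deamination_index, 0) # (0 + 0) / (2 * 1)
  expect_true(c1$has_cpg)

  c2 <- composition("CGCG")
  expect_equal(c2$n_CpG, 2L)
  expect_equal(c2$cpg_oe, 2)            # 2 * 4 / (2 * 2)
  expect_equal(c2$deamination_index, 0)

  c3 <- composition("TGCA")
  expect_equal(c3$n_CpG, 0L)
  expect_false(c3$has_cpg)
  expect_true(is.na(c3$deamination_index))
})

test_that("empty or all-N sequences are flagged invalid", {
  c0 <- composition("NNNN")
  expect_false(c0$valid)
  expect_true(is.na(c0$gc))
  expect_equal(c0$length_effective, 0L)
  expect_false(composition("")$valid)
})

test_that("soft-masked lowercase can be folded or masked to N", {
  expect_equal(composition("acgt")$n_CpG, 1L)
  expect_equal(composition("acgt", mask_lowercase = TRUE)$length_effective, 0L)
  expect_equal(dinucleotide_counts("ACgt", mask_lowercase = TRUE)[["AC"]], 1L)
})

test_that("no dinucleotide window spans an interval boundary", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  split2 <- composition_of_intervals(
    tibble::tibble(chrom = "chr1", start = c(0L, 2L), end = c(2L, 4L)), genome)
  whole <- composition_of_intervals(
    tibble::tibble(chrom = "chr1", start = 0L, end = 4L), genome)
  expect_equal(split2$n_CpG, 0L)   # CG straddles the boundary
  expect_equal(whole$n_CpG, 1L)
  expect_equal(split2$length_effective, whole$length_effective)

  empty <- composition_of_intervals(
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    genome)
  expect_false(empty$valid)
})

test_that("intervals outside the chromosome are rejected", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(composition_of_intervals(
    tibble::tibble(chrom = "chr1", start = 5L, end = 12L), genome), "bounds")
  expect_error(composition_of_intervals(
    tibble::tibble(chrom = "chrX", start = 0L, end = 2L), genome), "chromosome")
})

test_that("TpG+CpA is invariant under reverse complement", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    cf <- composition(s); cr <- composition(rc)
    expect_equal(cf$n_TpG + cf$n_CpA, cr$n_TpG + cr$n_CpA)
    expect_equal(cf$n_CpG, cr$n_CpG)  # CpG is its own reverse complement
  }
})

test_that("uniform sequence has near-uniform dinucleotides and cpg_oe near 1", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE), collapse = "")
  d <- dinucleotide_counts(s)
  n_win <- sum(d)
  p <- 1 / 16
  sigma <- sqrt(n_win * p * (1 - p))
  expect_true(all(abs(d - n_win * p) < 4 * sigma))
  expect_equal(composition(s)$cpg_oe, 1, tolerance = 0.05)
})

test_that("deamination simulator honors its limiting cases", {
  r0 <- deamination_simulator(0.03, 0, 5000, seed = 11)
  expect_identical(r0$ancestral, r0$evolved)
  r1 <- deamination_simulator(0.03, 1, 5000, seed = 11)
  expect_equal(composition(r1$evolved)$n_CpG, 0L)
  expect_true(is.na(composition(r1$evolved)$deamination_index))
  expect_error(deamination_simulator(1.5, 0.5, 100), "\\[0, 1\\]")
  expect_error(deamination_simulator(0.1, -0.1, 100), "\\[0, 1\\]")
})

test_that("deamination simulator is deterministic and index/cpg_oe are monotone in d", {
  a <- deamination_simulator(0.05, 0.4, 2000, seed = 3)
  b <- deamination_simulator(0.05, 0.4, 2000, seed = 3)
  expect_identical(a$evolved, b$evolved)

  ds <- seq(0.1, 0.9, by = 0.2)
  idx <- vapply(ds, function(d) {
    composition(deamination_simulator(0.05, d, 3e4, seed = 5)$evolved)$deamination_index
  }, numeric(1))
  oe <- vapply(ds, function(d) {
    composition(deamination_simulator(0.05, d, 3e4, seed = 5)$evolved)$cpg_oe
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
  expect_true(all(diff(oe) < 0))
})
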