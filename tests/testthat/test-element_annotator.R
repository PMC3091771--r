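# One small hand-built locus used across the classification tests:
# gene gA on chr1 with exons [100,200) [400,500) (intron [200,400)... see
# below), CDS inside, and gene gB downstream.
locus <- function() {
  tx <- tibble::tibble(
    gene_id = c(rep("gA", 5), rep("gB", 2)),
    transcript_id = c(rep("gA.t", 5), rep("gB.t", 2)),
    chrom = "chr1", strand = "+",
    feature = c("exon", "exon", "CDS", "CDS", "transcript", "exon", "transcript"),
    start = c(100L, 400L, 150L, 400L, 100L, 800L, 800L),
    end = c(250L, 500L, 250L, 450L, 500L, 900L, 900L)
  )
  genes <- dplyr::arrange(merge_transcripts(tx), start)
  ig <- partition_intergenic(genes, c(chr1 = 1200L))
  list(genes = genes, ig = ig)
}

test_that("short elements are removed with the retention fraction reported", {
  el <- tibble::tibble(chrom = "chr1", start = c(0L, 30L, 60L),
                       end = c(19L, 50L, 81L), score = 1)
  kept <- filter_elements(el)
  expect_equal(kept$end - kept$start, c(20L, 21L))
  expect_equal(attr(kept, "retention"), 2 / 3)
  all_long <- filter_elements(el[2:3, ])
  expect_equal(nrow(all_long), 2)
  expect_equal(attr(all_long, "retention"), 1)
})

test_that("elements are classified coding > UTR > intronic > intergenic", {
  lc <- locus()
  el <- tibble::tibble(
    chrom = "chr1",
    start = c(300L, 390L, 120L, 110L, 1150L, 600L),
    end = c(340L, 430L, 145L, 160L, 1190L, 640L),
    score = 1
  )
  out <- classify_elements(el, lc$genes, lc$ig)
  # [300,340) inside intron [250,400)
  expect_equal(out$element_class[1], "intronic")
  # [390,430) overlaps intron and coding exon [400,450)
  expect_equal(out$element_class[2], "coding")
  expect_false(out$fully_coding[2])
  # [120,145) inside UTR part of exon [100,150)
  expect_equal(out$element_class[3], "UTR")
  # [110,160) spans UTR and CDS -> coding
  expect_equal(out$element_class[4], "coding")
  # [1150,1190) in gB's downstream flank
  expect_equal(out$element_class[5], "intergenic")
  expect_equal(out$gene_id[5], "gB")
  # [600,640) in left half of gap [500,800) (midpoint 650) -> gA
  expect_equal(out$element_class[6], "intergenic")
  expect_equal(out$gene_id[6], "gA")
  expect_true(all(out$gene_id[1:4] == "gA"))
})

test_that("fully coding flags elements wholly inside the coding cover", {
  lc <- locus()
  el <- tibble::tibble(chrom = "chr1", start = c(160L, 140L),
                       end = c(200L, 200L), score = 1)
  out <- classify_elements(el, lc$genes, lc$ig)
  expect_true(out$fully_coding[1])    # inside CDS [150,250)
  expect_false(out$fully_coding[2])   # starts in UTR
})

test_that("elements on a gene-free chromosome stay unassigned", {
  lc <- locus()
  el <- tibble::tibble(chrom = "chr9", start = 0L, end = 50L, score = 1)
  out <- classify_elements(el, lc$genes, lc$ig)
  expect_equal(out$element_class, "intergenic")
  expect_true(is.na(out$gene_id))
})

test_that("overlap flags require at least one shared base", {
  el <- tibble::tibble(chrom = "chr1", start = 10L, end = 30L)
  touching <- tibble::tibble(chrom = "chr1", start = 29L, end = 60L)
  adjacent <- tibble::tibble(chrom = "chr1", start = 30L, end = 60L)
  out <- annotate_overlaps(el, list(cpg_island = touching, repeat_x = adjacent))
  expect_true(out$overlaps_cpg_island)   # 1 bp shared
  expect_false(out$overlaps_repeat_x)    # half-open adjacency
})

test_that("first overlapping repeat is the one with the smallest start", {
  el <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  reps <- tibble::tibble(
    chrom = "chr1", start = c(60L, 5L), end = c(80L, 50L),
    name = c("AluY", "L1M4"),
    category = c("SINE_Alu", "L1"), is_L1M = c(FALSE, TRUE)
  )
  expect_equal(first_repeat_category(el, reps), "L1")
  expect_equal(first_repeat_category(el, reps[1, ]), "SINE_Alu")
  none <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
  expect_true(is.na(first_repeat_category(none, reps)))
})

test_that("repeat names map deterministically onto categories", {
  expect_equal(
    repeat_category(c("AluY", "MIR3", "L1M4", "L1PA3", "L2a", "MLT1A",
                      "MER20", "(TA)n", "Foo")),
    c("SINE_Alu", "MIR", "L1", "L1", "L2", "LTR", "MER",
      "low_complexity_simple", "other")
  )
  expect_equal(repeat_category("Unknown", "SINE/Alu"), "SINE_Alu")
  expect_equal(repeat_category("Unknown", "Simple_repeat"),
               "low_complexity_simple")
})

test_that("unique elements overlap no exon, repeat, or CpG island", {
  el <- tibble::tibble(
    element_class = c("intronic", "intergenic", "coding", "intronic"),
    overlaps_repeat = c(FALSE, TRUE, FALSE, FALSE),
    overlaps_cpg_island = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_equal(classify_unique(el)$unique, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_unique(el[, 1:2]), "needs column")
})

test_that("exon distances are signed and measured to the closest boundary", {
  lc <- locus()
  el <- tibble::tibble(
    chrom = "chr1",
    start = c(300L, 250L, 160L, 390L),
    end = c(340L, 290L, 200L, 430L),
    score = 1
  )
  out <- classify_elements(el, lc$genes, lc$ig)
  d <- imprintcons:::exon_distances(out, lc$genes)
  expect_equal(d[1], 50)   # min(300-250, 400-340)
  expect_equal(d[2], 0)    # abuts the exon boundary at 250
  expect_equal(d[3], -50)  # inside exon [100,250): -min(160-100, 250-200)
  expect_equal(d[4], -30)  # penetrates exon [400,500) by 430-400
})

test_that("the exon-distance profile bins counts and normalizes by introns", {
  lc <- locus()
  el <- tibble::tibble(
    chrom = "chr1",
    start = c(260L, 300L, 390L), end = c(280L, 340L, 430L), score = 1
  )
  cls <- classify_elements(el, lc$genes, lc$ig)
  prof <- exon_distance_profile(cls, lc$genes, bin_width = 100)
  expect_s3_class(prof, "exon_distance_profile")
  expect_equal(sum(prof$n), attr(prof, "n_profiled"))
  expect_equal(sum(prof$n), 3)
  # gA has one intron, so densities are counts / 1 within gA's group
  expect_equal(prof$density, prof$n / 1)
})

test_that("coverage summary matches the worked 10 kb example", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 0L, end = 10400L,
    group = "autosomal",
    exons = list(data.frame(start = c(0L, 10200L), end = c(200L, 10400L))),
    coding = list(data.frame(start = 50L, end = 150L)),
    introns = list(data.frame(start = 200L, end = 10200L)),
    n_introns = 1L, is_intronless = FALSE
  )
  el <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1074L, score = 1,
                       gene_id = "g1", element_class = "intronic")
  cov <- coverage_summary(genes, el, "intronic")
  expect_equal(cov$region_bp, 10000)
  expect_equal(cov$coverage, 0.0074)
  expect_equal(cov$per_10kb, 1)
  # no elements -> zero coverage
  cov0 <- coverage_summary(genes, el[0, ], "intronic")
  expect_equal(cov0$coverage, 0)
  expect_equal(cov0$n_elements, 0L)
})

test_that("CpG island conservation summary covers the limiting cases", {
  islands <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                            end = c(50L, 150L))
  el <- tibble::tibble(chrom = "chr1", start = 0L, end = 60L, score = 1)
  out <- cgi_conservation_summary(islands, el)
  expect_equal(out$overlaps_element, c(TRUE, FALSE))
  expect_equal(out$covered_fraction, c(1, 0))
})

test_that("L1 summaries report coverage, conserved fraction, and L1M share", {
  ig <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                       gene_id = "g1", side = "upstream")
  genes <- tibble::tibble(gene_id = "g1", group = "maternal")
  reps <- tibble::tibble(
    chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L),
    name = c("L1M4", "L1PA3"), category = "L1", is_L1M = c(TRUE, FALSE)
  )
  el <- tibble::tibble(chrom = "chr1", start = 50L, end = 80L, score = 1)
  out <- l1_summary(ig, reps, el, genes)
  expect_equal(out$frac_l1m, 0.5)
  expect_equal(out$frac_l1_with_pcs, 0.5)
  expect_equal(out$median_l1_coverage, 200 / 1000)
})

test_that("binding-site association flags regions and co-occurrence", {
  # gB far downstream so its promoter cannot reach gA's neighbourhood
  tx <- tibble::tibble(
    gene_id = c("gA", "gA", "gA", "gB"),
    transcript_id = c("gA.t", "gA.t", "gA.t", "gB.t"),
    chrom = "chr1", strand = "+", feature = "exon",
    start = c(100L, 400L, 100L, 9000L), end = c(250L, 500L, 250L, 9100L)
  )
  genes <- dplyr::arrange(merge_transcripts(tx), start)
  ig <- partition_intergenic(genes, c(chr1 = 12000L))
  prom <- promoter_of(genes, c(chr1 = 12000L))
  tracks <- list(
    ctcf = tibble::tibble(chrom = "chr1", start = 300L, end = 316L),  # gA intron
    yy1 = tibble::tibble(chrom = "chr1", start = 540L, end = 556L)    # gA intergenic
  )
  out <- gene_site_association(genes, tracks, ig, prom)
  gA <- out[out$gene_id == "gA", ]
  expect_true(gA$has_ctcf_intronic)
  expect_false(gA$has_ctcf_intergenic)
  expect_true(gA$has_yy1_intergenic)
  expect_true(gA$co_occurrence)
  gB <- out[out$gene_id == "gB", ]
  expect_false(any(unlist(gB[, grepl("^has_", names(gB))])))
  expect_false(gB$co_occurrence)
})

test_that("classification, flags and coverage match the per-base oracle", {
  for (seed in 101:130) {
    fx <- random_fixture(seed)
    genes <- dplyr::arrange(merge_transcripts(fx$transcripts), start)
    ig <- partition_intergenic(genes, c(chrT = fx$chrom_len))
    el <- classify_elements(fx$elements, genes, ig)
    labels <- oracle_base_labels(fx$transcripts, fx$chrom_len)
    want <- oracle_classify(fx$elements, labels)
    expect_identical(el$element_class, want$element_class)
    expect_identical(el$gene_id, want$gene_id)
    flagged <- annotate_overlaps(el, list(t = fx$feature_track))
    expect_identical(flagged$overlaps_t,
                     oracle_overlap(el, fx$feature_track, fx$chrom_len))
  }
})
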