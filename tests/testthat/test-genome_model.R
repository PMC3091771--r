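make_tx <- function(gene_id, exons, chrom = "chr1", strand = "+", cds = NULL,
                    tx_id = paste0(gene_id, ".t1")) {
  rows <- tibble::tibble(
    gene_id = gene_id, transcript_id = tx_id, chrom = chrom, strand = strand,
    feature = "exon", start = exons[, 1], end = exons[, 2]
  )
  if (!is.null(cds)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chrom = chrom, strand = strand,
      feature = "CDS", start = cds[, 1], end = cds[, 2]))
  }
  rows
}

test_that("transcript merging takes extreme TSS/TTS and unions exons", {
  tx <- dplyr::bind_rows(
    make_tx("g1", rbind(c(100, 200), c(400, 500)), tx_id = "t1"),
    make_tx("g1", rbind(c(150, 250), c(450, 600)), tx_id = "t2")
  )
  gm <- merge_transcripts(tx)
  expect_equal(nrow(gm), 1)
  expect_equal(c(gm$start, gm$end), c(100, 600))
  expect_equal(gm$exons[[1]]$start, c(100, 400))
  expect_equal(gm$exons[[1]]$end, c(250, 600))
  expect_equal(gm$introns[[1]]$start, 250)
  expect_equal(gm$introns[[1]]$end, 400)

  # brute-force per-base check of the union/complement
  covered <- rep(FALSE, 600)
  ex_in <- tx[tx$feature == "exon", ]
  for (r in seq_len(nrow(ex_in))) covered[(ex_in$start[r] + 1):ex_in$end[r]] <- TRUE
  merged_cov <- rep(FALSE, 600)
  ex <- gm$exons[[1]]
  for (r in seq_len(nrow(ex))) merged_cov[(ex$start[r] + 1):ex$end[r]] <- TRUE
  expect_identical(merged_cov, covered)
})

test_that("single one-exon transcript yields an intronless model", {
  gm <- merge_transcripts(make_tx("g1", rbind(c(10, 110))))
  expect_equal(nrow(gm$introns[[1]]), 0)
  expect_true(gm$is_intronless)
  expect_equal(gm$n_introns, 0L)
})

test_that("mixed strand or chromosome within a gene is rejected", {
  tx <- dplyr::bind_rows(
    make_tx("g1", rbind(c(0, 100)), strand = "+", tx_id = "t1"),
    make_tx("g1", rbind(c(200, 300)), strand = "-", tx_id = "t2")
  )
  expect_error(merge_transcripts(tx), "mixed")
  tx2 <- dplyr::bind_rows(
    make_tx("g1", rbind(c(0, 100)), chrom = "chr1", tx_id = "t1"),
    make_tx("g1", rbind(c(0, 100)), chrom = "chr2", tx_id = "t2")
  )
  expect_error(merge_transcripts(tx2), "mixed")
})

test_that("merging is idempotent", {
  tx <- dplyr::bind_rows(
    make_tx("g1", rbind(c(100, 200), c(400, 500)),
            cds = rbind(c(150, 200), c(400, 450)), tx_id = "t1"),
    make_tx("g1", rbind(c(150, 250), c(450, 600)), tx_id = "t2")
  )
  gm <- merge_transcripts(tx)
  as_tx <- function(g) {
    dplyr::bind_rows(
      tibble::tibble(gene_id = g$gene_id, transcript_id = "m", chrom = g$chrom,
                     strand = g$strand, feature = "transcript",
                     start = g$start, end = g$end),
      tibble::tibble(gene_id = g$gene_id, transcript_id = "m", chrom = g$chrom,
                     strand = g$strand, feature = "exon",
                     start = g$exons[[1]]$start, end = g$exons[[1]]$end),
      tibble::tibble(gene_id = g$gene_id, transcript_id = "m", chrom = g$chrom,
                     strand = g$strand, feature = "CDS",
                     start = g$coding[[1]]$start, end = g$coding[[1]]$end)
    )
  }
  gm2 <- merge_transcripts(as_tx(gm))
  expect_equal(gm2$start, gm$start)
  expect_equal(gm2$end, gm$end)
  expect_equal(gm2$exons[[1]], gm$exons[[1]], ignore_attr = TRUE)
  expect_equal(gm2$coding[[1]], gm$coding[[1]], ignore_attr = TRUE)
  expect_equal(gm2$introns[[1]], gm$introns[[1]], ignore_attr = TRUE)
})

test_that("intergenic DNA is halved at the floor midpoint", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(0L, 200L), end = c(100L, 300L)
  )
  ig <- partition_intergenic(genes, c(chr1 = 400L))
  expect_equal(ig$start, c(100, 150, 300))
  expect_equal(ig$end, c(150, 200, 400))
  expect_equal(ig$gene_id, c("g1", "g2", "g2"))
  # partition conservation
  expect_equal(sum(ig$end - ig$start) + sum(genes$end - genes$start), 400)
})

test_that("adjacent genes emit no intergenic region between them", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          strand = "+", start = c(0L, 100L), end = c(100L, 200L))
  ig <- partition_intergenic(genes, c(chr1 = 200L))
  expect_equal(nrow(ig), 0)
})

test_that("a single gene receives both flanks", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 100L, end = 200L)
  ig <- partition_intergenic(genes, c(chr1 = 500L))
  expect_equal(ig$start, c(0, 200))
  expect_equal(ig$end, c(100, 500))
  expect_equal(unique(ig$gene_id), "g1")
  expect_setequal(ig$side, c("upstream", "downstream"))
})

test_that("unsorted gene input is rejected", {
  genes <- tibble::tibble(gene_id = c("g2", "g1"), chrom = "chr1",
                          strand = "+", start = c(200L, 0L), end = c(300L, 100L))
  expect_error(partition_intergenic(genes, c(chr1 = 400L)), "sorted")
})

test_that("promoters are strand-aware and clipped only at chromosome bounds", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm", "gc"), chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(5000L, 2000L, 300L), end = c(7000L, 5000L, 800L)
  )
  pr <- promoter_of(genes, c(chr1 = 10000L))
  expect_equal(pr$start, c(4000, 5000, 0))
  expect_equal(pr$end, c(5000, 6000, 300))
  expect_equal(pr$clipped, c(FALSE, FALSE, TRUE))
})

test_that("intronless genes are counted per group with empty groups flagged", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"), group = "autosomal",
    is_intronless = c(TRUE, FALSE, FALSE)
  )
  ct <- count_intronless(genes)
  expect_equal(ct$n_intronless, 1L)
  expect_equal(ct$fraction, 1 / 3)
  ct2 <- count_intronless(genes, groups = c("autosomal", "maternal"))
  expect_true(is.na(ct2$fraction[ct2$group == "maternal"]))
  expect_equal(ct2$n_genes[ct2$group == "maternal"], 0L)
})

test_that("gene models and partition match the per-base oracle on random fixtures", {
  for (seed in 1:25) {
    fx <- random_fixture(seed)
    genes <- dplyr::arrange(merge_transcripts(fx$transcripts), start)
    ig <- partition_intergenic(genes, c(chrT = fx$chrom_len))
    # partition conservation, exact
    expect_equal(sum(ig$end - ig$start) + sum(genes$end - genes$start),
                 fx$chrom_len)
    # intron tiling per gene
    for (i in seq_len(nrow(genes))) {
      expect_equal(sum(genes$exons[[i]]$end - genes$exons[[i]]$start) +
                     sum(genes$introns[[i]]$end - genes$introns[[i]]$start),
                   genes$end[i] - genes$start[i])
    }
    # per-base assignment equivalence
    labels <- oracle_base_labels(fx$transcripts, fx$chrom_len)
    got <- rep(NA_character_, fx$chrom_len)
    for (i in seq_len(nrow(genes))) {
      got[(genes$start[i] + 1):genes$end[i]] <- genes$gene_id[i]
    }
    for (r in seq_len(nrow(ig))) {
      got[(ig$start[r] + 1):ig$end[r]] <- ig$gene_id[r]
    }
    expect_identical(got, labels$gene_at)
  }
})
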