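#' Merge transcripts into one gene model per gene
#'
#' Collapses all transcripts of each gene into a single model: the span
#' runs from the most 5' annotated start to the most 3' annotated
#' termination site, exons of all splice variants are merged into the
#' largest possible exon set, and CDS intervals are merged into the
#' largest possible coding region. Introns are exactly the span minus the
#' merged exons.
#'
#' @param transcripts Long-format transcript table (one row per feature
#'   interval) with columns `gene_id`, `chrom`, `strand`, `feature`
#'   (`"exon"`, `"CDS"`, optionally `"transcript"`), `start`, `end` in
#'   0-based half-open coordinates, as produced by [read_gtf()] or
#'   [read_bed12()].
#' @param groups Optional tibble `gene_id`, `group` (see
#'   [read_gene_groups()]). Genes absent from it get group `"autosomal"`.
#' @return A gene-model tibble with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `group`, list-columns `exons`, `coding`,
#'   `introns` (each a tibble of `start`, `end`), `n_introns` and
#'   `is_intronless`.
#' @examples
#' tx <- tibble::tibble(
#'   gene_id = "g1", transcript_id = c("t1", "t1", "t2", "t2"),
#'   chrom = "chr1", strand = "+", feature = "exon",
#'   start = c(100L, 400L, 150L, 450L), end = c(200L, 500L, 250L, 600L)
#' )
#' merge_transcripts(tx)
#' @export
merge_transcripts <- function(transcripts, groups = NULL) {
  check_intervals(transcripts, "transcript table")
  bad <- transcripts |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad) > 0) {
    stop("gene(s) with transcripts on mixed chromosomes or strands: ",
         paste(bad$gene_id, collapse = ", "), call. = FALSE)
  }

  span <- transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")

  merged_set <- function(feat) {
    sub <- dplyr::filter(transcripts, .data$feature == feat)
    ids <- factor(sub$gene_id, levels = span$gene_id)
    grl <- GenomicRanges::reduce(S4Vectors::split(as_granges0(sub), ids))
    flat <- unlist(grl, use.names = FALSE)
    df <- data.frame(start = GenomicRanges::start(flat) - 1L,
                     end = GenomicRanges::end(flat))
    f <- factor(rep(names(grl), S4Vectors::elementNROWS(grl)),
                levels = span$gene_id)
    split(df, f)
  }
  exons <- merged_set("exon")
  coding <- merged_set("CDS")
  introns <- purrr::pmap(list(span$start, span$end, exons), function(s, e, ex) {
    if (nrow(ex) == 0) return(data.frame(start = s, end = e))
    st <- c(s, ex$end); en <- c(ex$start, e)
    keep <- en > st
    data.frame(start = st[keep], end = en[keep])
  })

  out <- span |>
    dplyr::mutate(
      exons = unname(exons[.data$gene_id]),
      coding = unname(coding[.data$gene_id]),
      introns = introns,
      n_introns = purrr::map_int(introns, nrow),
      is_intronless = .data$n_introns == 0L
    )
  out$group <- "autosomal"
  if (!is.null(groups)) {
    idx <- match(out$gene_id, groups$gene_id)
    out$group[!is.na(idx)] <- groups$group[idx[!is.na(idx)]]
  }
  out
}

#' Halve intergenic DNA between consecutive genes
#'
#' The sequence between two gene spans is cut into two halves at the
#' midpoint `m = floor((a + b) / 2)`; each half is assigned to the nearest
#' gene. For odd-length gaps the extra base therefore goes to the
#' downstream (higher-coordinate) gene.
#' Terminal segments before the first and after the last gene go entirely
#' to that gene. When gene spans overlap the gap between them is empty and
#' nothing is emitted. The emitted regions tile the chromosome minus the
#' union of gene spans exactly.
#'
#' @param genes Gene-model tibble ([merge_transcripts()]); must be sorted
#'   by `start` within each chromosome.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Tibble of intergenic regions: `chrom`, `start`, `end`,
#'   `gene_id` (assigned gene), `side` (`"upstream"`/`"downstream"`
#'   relative to the assigned gene's orientation).
#' @export
partition_intergenic <- function(genes, chrom_lengths) {
  check_intervals(genes, "gene table")
  one_chrom <- function(g) {
    if (is.unsorted(g$start)) {
      stop("genes must be sorted by start within each chromosome", call. = FALSE)
    }
    len <- chrom_lengths[[g$chrom[1]]]
    if (is.null(len)) stop("no length for chromosome ", g$chrom[1], call. = FALSE)
    frontier <- cummax(g$end)
    # index of the gene currently holding the rightmost end (first on ties)
    holder <- match(frontier, g$end)
    n <- nrow(g)
    segs <- list()
    if (g$start[1] > 0) {
      segs[[length(segs) + 1]] <- tibble::tibble(
        start = 0L, end = g$start[1], gene = 1L)
    }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        a <- frontier[i]
        b <- g$start[i + 1]
        if (b > a) {
          m <- as.integer(floor((a + b) / 2))
          if (m > a) segs[[length(segs) + 1]] <- tibble::tibble(
            start = a, end = m, gene = holder[i])
          if (b > m) segs[[length(segs) + 1]] <- tibble::tibble(
            start = m, end = b, gene = i + 1L)
        }
      }
    }
    if (frontier[n] < len) {
      segs[[length(segs) + 1]] <- tibble::tibble(
        start = frontier[n], end = as.integer(len), gene = holder[n])
    }
    if (length(segs) == 0) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), gene_id = character(),
                            side = character()))
    }
    seg <- dplyr::bind_rows(segs)
    left_of_gene <- seg$end <= g$start[seg$gene]
    plus <- g$strand[seg$gene] == "+"
    tibble::tibble(
      chrom = g$chrom[1], start = seg$start, end = seg$end,
      gene_id = g$gene_id[seg$gene],
      side = ifelse(left_of_gene == plus, "upstream", "downstream")
    )
  }
  genes |>
    dplyr::group_split(.data$chrom) |>
    purrr::map(one_chrom) |>
    dplyr::bind_rows()
}

#' Promoter regions upstream of the most upstream TSS
#'
#' The promoter is the 1000 bp immediately upstream (strand-aware) of the
#' merged span's transcriptional start: `[start - 1000, start)` for `+`
#' strand genes and `[end, end + 1000)` for `-` strand genes. Promoters are
#' clipped only at chromosome bounds, never by neighbouring genes.
#'
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Promoter width in bp (default 1000).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
promoter_of <- function(genes, chrom_lengths, width = 1000L) {
  len <- unname(chrom_lengths[genes$chrom])
  plus <- genes$strand == "+"
  raw_start <- ifelse(plus, genes$start - width, genes$end)
  raw_end <- ifelse(plus, genes$start, genes$end + width)
  start <- pmax(raw_start, 0L)
  end <- pmin(raw_end, len)
  tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(start), end = as.integer(end),
    clipped = start != raw_start | end != raw_end
  )
}

#' Count intronless genes per group
#'
#' Single-exon genes are tallied per gene group; the resulting counts feed
#' Fisher's exact comparisons of intronless-gene proportions between
#' groups.
#'
#' @param genes Gene-model tibble.
#' @param groups Optional character vector of group levels to report even
#'   when empty.
#' @return Tibble `group`, `n_genes`, `n_intronless`, `fraction`
#'   (`NA` for empty groups).
#' @export
count_intronless <- function(genes, groups = NULL) {
  levels <- groups %||% sort(unique(genes$group))
  out <- genes |>
    dplyr::group_by(group = factor(.data$group, levels = levels)) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_intronless = sum(.data$is_intronless), .groups = "drop") |>
    tidyr::complete(group = factor(levels, levels = levels),
                    fill = list(n_genes = 0L, n_intronless = 0L)) |>
    dplyr::mutate(group = as.character(.data$group),
                  fraction = ifelse(.data$n_genes > 0,
                                    .data$n_intronless / .data$n_genes, NA_real_))
  out
}
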