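# End-to-end analysis of a genome bundle: gene models, region partition,
# element classification and annotation, gene-level features, the report
# tables, the exon-distance profile, repeat attribution, CpG-island / L1
# / binding-site summaries, and motif enrichment.

#' Gene-level sequence features
#'
#' Per gene: span length, summed exon/intron/intergenic length, intron
#' count, and composition of the transcribed sequence (G+C,
#' CpG_obs/CpG_exp, deamination index).
#'
#' @param genes Gene-model tibble.
#' @param intergenic Intergenic partition.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Tibble with one row per gene.
#' @export
gene_features <- function(genes, intergenic, genome) {
  ig_len <- intergenic |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(intergenic_bp = sum(.data$end - .data$start),
                     .groups = "drop")
  span_comp <- composition_per_interval(
    dplyr::select(genes, "gene_id", "chrom", "start", "end"), genome)
  genes |>
    dplyr::mutate(
      gene_length = .data$end - .data$start,
      exon_bp = purrr::map_int(.data$exons, ~ sum(.x$end - .x$start)),
      intron_bp = purrr::map_int(.data$introns, ~ sum(.x$end - .x$start))
    ) |>
    dplyr::left_join(ig_len, by = "gene_id") |>
    dplyr::mutate(intergenic_bp = dplyr::coalesce(.data$intergenic_bp, 0L)) |>
    dplyr::left_join(
      dplyr::select(span_comp, "gene_id", "gc", "cpg_oe", "deamination_index"),
      by = "gene_id") |>
    dplyr::select("gene_id", "group", "gene_length", "exon_bp", "intron_bp",
                  "n_introns", "intergenic_bp", "gc", "cpg_oe",
                  "deamination_index")
}

# Add an "imprinted" pseudo-group pooling maternal and paternal genes.
add_imprinted_group <- function(df, labeled = c("maternal", "paternal")) {
  dplyr::bind_rows(df, df |>
    dplyr::filter(.data$group %in% labeled) |>
    dplyr::mutate(group = "imprinted"))
}

#' Run the full conservation analysis on a genome bundle
#'
#' Builds gene models, partitions intergenic DNA, filters and classifies
#' the conserved elements, annotates track overlaps, and assembles all
#' group-level reports. The `imprinted` group pools maternal and paternal
#' genes.
#'
#' @param bundle A `synth_bundle` from [synth_genome()] or a list with
#'   the same track fields (e.g. [read_genome_bundle()] output).
#' @param min_element_len Element length filter (default 20).
#' @param motif_k,motif_threshold Parameters of the motif scan.
#' @return An `imprintcons_analysis` list: `genes`, `intergenic`,
#'   `promoters`, `elements` (annotated), `gene_features`, `table1`,
#'   `table2`, `intronless`, `profile`, `repeat_attribution`,
#'   `cgi`, `l1`, `sites`, `motifs`.
#' @export
analyze_bundle <- function(bundle, min_element_len = 20L, motif_k = 6L,
                           motif_threshold = 3.5) {
  chrom_lengths <- bundle$chrom_lengths %||%
    stats::setNames(Biostrings::width(bundle$genome), names(bundle$genome))
  genes <- merge_transcripts(bundle$transcripts, bundle$groups) |>
    dplyr::arrange(.data$chrom, .data$start)
  ig <- partition_intergenic(genes, chrom_lengths)
  prom <- promoter_of(genes, chrom_lengths)

  el <- filter_elements(bundle$elements, min_element_len) |>
    classify_elements(genes, ig) |>
    annotate_overlaps(list(
      cpg_island = bundle$cpg_islands, "repeat" = bundle$repeats,
      tfbs_ctcf = bundle$tfbs$ctcf, tfbs_yy1 = bundle$tfbs$yy1
    )) |>
    classify_unique()
  el$first_repeat_category <- first_repeat_category(el, bundle$repeats)

  gf <- gene_features(genes, ig, bundle$genome)
  gf_ext <- add_imprinted_group(gf)
  table1 <- table1_report(gf_ext)
  el_ext <- add_imprinted_group(el)
  table2 <- table2_report(el_ext, bundle$genome)

  intronless <- count_intronless(add_imprinted_group(
    dplyr::select(genes, "gene_id", "group", "is_intronless")))

  profile <- exon_distance_profile(el, genes)
  rep_attr <- el_ext |>
    dplyr::filter(!is.na(.data$first_repeat_category)) |>
    dplyr::count(.data$group, .data$first_repeat_category, name = "n")

  cgi <- cgi_conservation_summary(bundle$cpg_islands, el, bundle$genome)
  l1 <- l1_summary(ig, bundle$repeats, el, genes)
  sites <- gene_site_association(genes, bundle$tfbs, ig, prom)

  labeled <- unique(genes$group[genes$group != "autosomal"])
  target_el <- dplyr::filter(el, .data$element_class == "intronic",
                             .data$group %in% labeled)
  comp_el <- dplyr::filter(el, .data$element_class == "intronic",
                           .data$group == "autosomal")
  motifs <- NULL
  if (nrow(target_el) > 0 && nrow(comp_el) > 0) {
    target_seq <- concatenate_by_gene(target_el, bundle$genome)$seq
    comp_seq <- concatenate_by_gene(comp_el, bundle$genome)$seq
    motifs <- enriched_motifs(target_seq,
                              background = as.character(bundle$genome),
                              comparison = comp_seq,
                              k = motif_k, threshold = motif_threshold)
  }

  structure(list(
    genes = genes, intergenic = ig, promoters = prom, elements = el,
    gene_features = gf, table1 = table1, table2 = table2,
    intronless = intronless, profile = profile,
    repeat_attribution = rep_attr, cgi = cgi, l1 = l1, sites = sites,
    motifs = motifs
  ), class = "imprintcons_analysis")
}

#' @export
print.imprintcons_analysis <- function(x, ...) {
  cat("<imprintcons_analysis>\n")
  cat("  genes:", nrow(x$genes), "| elements:", nrow(x$elements), "\n")
  cat("  groups:", paste(sort(unique(x$genes$group)), collapse = ", "), "\n")
  if (!is.null(x$motifs)) {
    top <- dplyr::filter(x$motifs, .data$passes)
    cat("  passing motifs:", nrow(top),
        if (nrow(top) > 0) paste0("(top: ", top$kmer[1], ")") else "", "\n")
  }
  invisible(x)
}

#' Write the analysis reports as TSV files
#'
#' Writes `table1.tsv`, `table2.tsv`, `intronless.tsv`, `profile.tsv`,
#' `repeat_attribution.tsv`, `l1.tsv`, `motifs.tsv` to `dir`. Output is
#' deterministic: rerunning on the same bundle reproduces the files
#' byte-identically.
#'
#' @param analysis An `imprintcons_analysis`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_report(analysis$table1, p("table1.tsv"))
  write_report(analysis$table2, p("table2.tsv"))
  write_report(analysis$intronless, p("intronless.tsv"))
  write_report(tibble::as_tibble(analysis$profile), p("profile.tsv"))
  write_report(analysis$repeat_attribution, p("repeat_attribution.tsv"))
  write_report(analysis$l1, p("l1.tsv"))
  if (!is.null(analysis$motifs)) write_report(analysis$motifs, p("motifs.tsv"))
  invisible(dir)
}
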