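# Classification and annotation of conserved elements (PCSs) against gene
# models and feature tracks, plus the per-class / per-gene summaries the
# group comparisons consume.

#' Map repeat names to broad categories
#'
#' Deterministic mapping from RepeatMasker family names (and, when
#' available, class strings) to the categories used in repeat-overlap
#' attribution: `SINE_Alu`, `MIR`, `L1`, `L2`, `LTR`, `MER`,
#' `low_complexity_simple`, `other`. Names beginning with `L1M` mark the
#' ancient mammalian-wide LINE-1 subgroup.
#'
#' @param name Character vector of repeat family names (e.g. `L1M4`, `AluY`).
#' @param rm_class Optional RepeatMasker class/family strings
#'   (e.g. `SINE/Alu`, `Simple_repeat`).
#' @return Character vector of categories.
#' @export
repeat_category <- function(name, rm_class = NULL) {
  cat <- rep("other", length(name))
  if (!is.null(rm_class)) {
    cls <- tolower(ifelse(is.na(rm_class), "", rm_class))
    cat[grepl("^sine/alu", cls)] <- "SINE_Alu"
    cat[grepl("low_complexity|simple_repeat", cls)] <- "low_complexity_simple"
    cat[grepl("^ltr", cls)] <- "LTR"
  }
  cat[startsWith(name, "Alu")] <- "SINE_Alu"
  cat[startsWith(name, "MIR")] <- "MIR"
  cat[startsWith(name, "L1")] <- "L1"
  cat[startsWith(name, "L2")] <- "L2"
  cat[grepl("^(MLT|MST|LTR|ERV|THE1)", name)] <- "LTR"
  cat[startsWith(name, "MER")] <- "MER"
  cat[grepl("^\\(|-rich$|^GC_rich$", name)] <- "low_complexity_simple"
  cat
}

#' Drop conserved elements below a minimum length
#'
#' Conserved-element tracks contain fragments anchored to just a few
#' reference bases; elements shorter than `min_len` (default 20 bp) are
#' removed. The retained fraction is attached as attribute `retention`.
#'
#' @param elements Element tibble (`chrom`, `start`, `end`, `score`, ...).
#' @param min_len Minimum element length in bp.
#' @return Filtered tibble with attribute `retention`.
#' @export
filter_elements <- function(elements, min_len = 20L) {
  check_intervals(elements, "element table")
  keep <- (elements$end - elements$start) >= min_len
  out <- elements[keep, ]
  attr(out, "retention") <- if (nrow(elements) > 0) mean(keep) else NA_real_
  out
}

flatten_gene_intervals <- function(genes, col) {
  tidyr::unnest(
    dplyr::select(genes, "gene_id", "chrom", dplyr::all_of(col)),
    dplyr::all_of(col)
  )
}

#' Classify conserved elements against gene models
#'
#' An element overlapping a gene span is `coding` if it overlaps the
#' merged coding region by at least 1 bp, `UTR` if it overlaps merged
#' exons but not the coding region, and `intronic` otherwise. Elements
#' outside every gene span are `intergenic` and inherit the gene of the
#' intergenic region they overlap most. Elements overlapping several gene
#' spans go to the gene with the larger overlap (ties to the
#' lower-coordinate gene). `fully_coding` marks elements wholly inside the
#' merged coding cover.
#'
#' @param elements Element tibble (already length-filtered).
#' @param genes Gene-model tibble from [merge_transcripts()].
#' @param intergenic Intergenic partition from [partition_intergenic()].
#' @return `elements` with `gene_id`, `element_class`, `fully_coding`,
#'   `group` columns added. Elements on chromosomes without genes or
#'   intergenic regions keep `gene_id = NA`.
#' @export
classify_elements <- function(elements, genes, intergenic) {
  check_intervals(elements, "element table")
  n <- nrow(elements)
  gene_id <- rep(NA_character_, n)
  klass <- rep("intergenic", n)
  fully <- rep(FALSE, n)

  if (nrow(genes) > 0 && n > 0) {
    hits <- iv_hits(elements, genes) |>
      dplyr::mutate(gene_start = genes$start[.data$s]) |>
      dplyr::arrange(.data$q, dplyr::desc(.data$width), .data$gene_start) |>
      dplyr::distinct(.data$q, .keep_all = TRUE)
    gene_id[hits$q] <- genes$gene_id[hits$s]

    exons <- flatten_gene_intervals(genes, "exons")
    coding <- flatten_gene_intervals(genes, "coding")
    overlap_with <- function(feat) {
      if (nrow(feat) == 0 || nrow(hits) == 0) {
        return(tibble::tibble(q = integer(), w = integer(), cov = integer()))
      }
      fh <- iv_hits(elements[hits$q, c("chrom", "start", "end")], feat)
      fh$gene_of_feat <- feat$gene_id[fh$s]
      fh$q_orig <- hits$q[fh$q]
      fh <- dplyr::filter(fh, .data$gene_of_feat == gene_id[.data$q_orig])
      dplyr::summarise(dplyr::group_by(fh, q = .data$q_orig),
                       w = sum(.data$width), .groups = "drop")
    }
    cod_w <- overlap_with(coding)
    exo_w <- overlap_with(exons)
    genic <- hits$q
    klass[genic] <- "intronic"
    klass[exo_w$q[exo_w$w > 0]] <- "UTR"
    klass[cod_w$q[cod_w$w > 0]] <- "coding"
    # fully coding: element length entirely covered by the coding cover
    elen <- elements$end - elements$start
    cov_idx <- cod_w$q[cod_w$w >= elen[cod_w$q]]
    # summed per-exon overlap can only equal the element length when the
    # element never leaves the (disjoint, merged) coding intervals
    fully[cov_idx] <- klass[cov_idx] == "coding"
  }

  needs_ig <- which(is.na(gene_id))
  if (length(needs_ig) > 0 && nrow(intergenic) > 0) {
    igh <- iv_hits(elements[needs_ig, c("chrom", "start", "end")], intergenic) |>
      dplyr::mutate(ig_start = intergenic$start[.data$s]) |>
      dplyr::arrange(.data$q, dplyr::desc(.data$width), .data$ig_start) |>
      dplyr::distinct(.data$q, .keep_all = TRUE)
    gene_id[needs_ig[igh$q]] <- intergenic$gene_id[igh$s]
  }

  out <- dplyr::mutate(elements, gene_id = gene_id, element_class = klass,
                       fully_coding = fully)
  if ("group" %in% names(genes)) {
    grp <- genes$group[match(out$gene_id, genes$gene_id)]
    out$group <- ifelse(is.na(grp), "autosomal", grp)
    out$group[is.na(out$gene_id)] <- NA_character_
  }
  out
}

#' Flag overlaps with annotation tracks
#'
#' An element possesses a feature when it overlaps the feature's
#' annotation by at least 1 bp (half-open adjacency does not count).
#'
#' @param elements Element tibble.
#' @param tracks Named list of interval tibbles (e.g.
#'   `list(cpg_island = ..., repeat_ = ..., tfbs_ctcf = ...)`).
#' @return `elements` with one logical `overlaps_<name>` column per track.
#' @export
annotate_overlaps <- function(elements, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  for (nm in names(tracks)) {
    elements[[paste0("overlaps_", nm)]] <- iv_overlap_any(elements, tracks[[nm]])
  }
  elements
}

#' Category of the first overlapping repeat
#'
#' Repeat-overlap attribution uses the first overlapping repeat: the one
#' with the smallest start coordinate, ties broken by longer overlap and
#' then by name.
#'
#' @param elements Element tibble.
#' @param repeats Repeat tibble from [read_repeats()] (needs `category`).
#' @return Character vector (one per element): first overlapping repeat's
#'   category, `NA` where no repeat overlaps.
#' @export
first_repeat_category <- function(elements, repeats) {
  out <- rep(NA_character_, nrow(elements))
  h <- iv_hits(elements, repeats)
  if (nrow(h) == 0) return(out)
  h <- h |>
    dplyr::mutate(rep_start = repeats$start[.data$s],
                  rep_name = repeats$name[.data$s]) |>
    dplyr::arrange(.data$q, .data$rep_start, dplyr::desc(.data$width),
                   .data$rep_name) |>
    dplyr::distinct(.data$q, .keep_all = TRUE)
  out[h$q] <- repeats$category[h$s]
  out
}

#' Flag unique conserved elements
#'
#' Unique elements overlap no exon (they are intronic or intergenic), no
#' repetitive element, and no CpG island — candidate distal regulatory
#' elements.
#'
#' @param elements Element tibble carrying `element_class` and the
#'   `overlaps_repeat`, `overlaps_cpg_island` flags
#'   (see [classify_elements()], [annotate_overlaps()]).
#' @return `elements` with a logical `unique` column added.
#' @export
classify_unique <- function(elements) {
  need <- c("element_class", "overlaps_repeat", "overlaps_cpg_island")
  miss <- setdiff(need, names(elements))
  if (length(miss) > 0) {
    stop("classify_unique needs column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(elements,
    unique = .data$element_class %in% c("intronic", "intergenic") &
      !.data$overlaps_repeat & !.data$overlaps_cpg_island)
}

# Signed distance of each element from the closest exon boundary of its
# host gene. Positive: purely intronic element, gap to the nearest exon.
# Negative: exon-overlapping element; fully inside an exon it is the gap
# to the nearer boundary, across a boundary it is the penetration depth
# into the nearest overlapped exon.
exon_distances <- function(elements, genes) {
  exons <- flatten_gene_intervals(genes, "exons")
  ex_by_gene <- split(as.data.frame(exons[, c("start", "end")]),
                      factor(exons$gene_id))
  dist_one <- function(s, e, ex) {
    if (nrow(ex) == 0) return(NA_real_)
    ov <- pmin(e, ex$end) - pmax(s, ex$start)
    if (all(ov <= 0)) {           # purely intronic: gap to nearest exon
      gap <- ifelse(ex$end <= s, s - ex$end, ex$start - e)
      return(min(gap[gap >= 0]))
    }
    hit <- which(ov > 0)
    inside <- hit[s >= ex$start[hit] & e <= ex$end[hit]]
    if (length(inside) > 0) {
      return(-min(pmin(s - ex$start[inside], ex$end[inside] - e)))
    }
    pen <- c(
      ifelse(s < ex$start[hit], pmin(e, ex$end[hit]) - ex$start[hit], Inf),
      ifelse(e > ex$end[hit], ex$end[hit] - pmax(s, ex$start[hit]), Inf)
    )
    -min(pen[is.finite(pen) & pen > 0])
  }
  purrr::pmap_dbl(
    list(elements$start, elements$end, elements$gene_id),
    function(s, e, g) {
      if (is.na(g) || is.null(ex_by_gene[[g]])) return(NA_real_)
      dist_one(s, e, ex = ex_by_gene[[g]])
    }
  )
}

#' Exon-distance profile of conserved elements
#'
#' Bins intronic and exon-overlapping elements by their distance from the
#' closest exon boundary (positive distances inside introns, negative
#' inside exons) and normalizes each bin count by the number of introns of
#' the gene group, yielding a per-intron density profile.
#'
#' @param elements Classified element tibble (`element_class`, `gene_id`,
#'   `group`).
#' @param genes Gene-model tibble.
#' @param bin_width Bin width in bp (default 100).
#' @param max_dist Elements farther than this from any exon boundary are
#'   dropped from the profile (default 10000).
#' @return Tibble `group`, `bin_start` (signed lower edge), `n`, `density`
#'   of class `"exon_distance_profile"`. Attribute `n_profiled` gives the
#'   number of elements in the profile.
#' @export
exon_distance_profile <- function(elements, genes, bin_width = 100L,
                                  max_dist = 10000L) {
  el <- dplyr::filter(elements, .data$element_class %in% c("intronic", "coding", "UTR"),
                      !is.na(.data$gene_id))
  el$distance <- exon_distances(el, genes)
  el <- dplyr::filter(el, !is.na(.data$distance), abs(.data$distance) <= max_dist)
  introns_per_group <- genes |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_introns = sum(.data$n_introns), .groups = "drop")
  prof <- el |>
    dplyr::mutate(bin_start = floor(.data$distance / bin_width) * bin_width) |>
    dplyr::count(.data$group, .data$bin_start, name = "n") |>
    dplyr::left_join(introns_per_group, by = "group") |>
    dplyr::mutate(density = ifelse(.data$n_introns > 0,
                                   .data$n / .data$n_introns, NA_real_)) |>
    dplyr::select("group", "bin_start", "n", "density")
  attr(prof, "n_profiled") <- nrow(el)
  attr(prof, "bin_width") <- bin_width
  class(prof) <- c("exon_distance_profile", class(prof))
  prof
}

#' Per-gene coverage and density of conserved elements in a region class
#'
#' For each gene: the fraction of the region class (introns or assigned
#' intergenic DNA) covered by elements of that class, and the element
#' count per 10 kb of region. Region length differences between genes are
#' normalized away by dividing counts by the summed region length per
#' gene. Genes with zero-length regions are excluded.
#'
#' @param genes Gene-model tibble.
#' @param elements Classified element tibble.
#' @param region_class `"intronic"` or `"intergenic"`.
#' @param intergenic Intergenic partition (required for
#'   `region_class = "intergenic"`).
#' @return Per-gene tibble `gene_id`, `group`, `region_bp`, `n_elements`,
#'   `covered_bp`, `coverage`, `per_10kb`.
#' @export
coverage_summary <- function(genes, elements, region_class = c("intronic", "intergenic"),
                             intergenic = NULL) {
  region_class <- match.arg(region_class)
  if (region_class == "intronic") {
    regions <- flatten_gene_intervals(genes, "introns")
  } else {
    if (is.null(intergenic)) stop("intergenic partition required", call. = FALSE)
    regions <- dplyr::select(intergenic, "gene_id", "chrom", "start", "end")
  }
  el <- dplyr::filter(elements, .data$element_class == region_class,
                      !is.na(.data$gene_id))
  per_gene_len <- regions |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(region_bp = sum(.data$end - .data$start), .groups = "drop")
  excluded <- per_gene_len$gene_id[per_gene_len$region_bp == 0]
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " gene(s) with zero-length ",
            region_class, " region")
  }
  # covered bases: union of the gene's own elements clipped to its regions.
  # Re-keying intervals by gene id (one gene = one chromosome) lets a
  # single overlap pass handle every gene at once.
  genes_with_el <- intersect(unique(el$gene_id), per_gene_len$gene_id)
  reg2 <- regions[regions$gene_id %in% genes_with_el, , drop = FALSE]
  el2 <- el[el$gene_id %in% genes_with_el, , drop = FALSE]
  covered <- iv_covered_width(
    tibble::tibble(chrom = reg2$gene_id, start = reg2$start, end = reg2$end),
    tibble::tibble(chrom = el2$gene_id, start = el2$start, end = el2$end)
  )
  cov_gene <- tibble::tibble(gene_id = reg2$gene_id, covered_bp = covered) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(covered_bp = sum(.data$covered_bp), .groups = "drop")
  n_el <- el |>
    dplyr::count(.data$gene_id, name = "n_elements")
  per_gene_len |>
    dplyr::filter(.data$region_bp > 0) |>
    dplyr::left_join(cov_gene, by = "gene_id") |>
    dplyr::left_join(n_el, by = "gene_id") |>
    dplyr::mutate(
      covered_bp = dplyr::coalesce(.data$covered_bp, 0L),
      n_elements = dplyr::coalesce(.data$n_elements, 0L),
      coverage = .data$covered_bp / .data$region_bp,
      per_10kb = .data$n_elements * 1e4 / .data$region_bp,
      group = genes$group[match(.data$gene_id, genes$gene_id)]
    ) |>
    dplyr::relocate("group", .after = "gene_id")
}

#' CpG-island conservation summary
#'
#' Per island: whether it overlaps at least one conserved element, the
#' fraction of its bases covered by elements, and (when a genome is given)
#' its deamination index.
#'
#' @param islands CpG-island tibble (`chrom`, `start`, `end`).
#' @param elements Element tibble.
#' @param genome Optional [Biostrings::DNAStringSet] for per-island
#'   composition.
#' @return Island tibble with `overlaps_element`, `covered_fraction` and,
#'   with a genome, the [composition()] columns.
#' @export
cgi_conservation_summary <- function(islands, elements, genome = NULL) {
  out <- islands
  out$overlaps_element <- iv_overlap_any(islands, elements)
  out$covered_fraction <- iv_covered_width(islands, elements) /
    (islands$end - islands$start)
  if (!is.null(genome)) {
    out <- composition_per_interval(out, genome)
  }
  out
}

#' LINE-1 summaries per gene group
#'
#' Reports, per gene group: the median fraction of assigned intergenic
#' sequence covered by L1 repeats, the fraction of the group's L1 repeats
#' that contain at least one conserved element, and the fraction of those
#' L1 repeats belonging to the ancient L1M subgroup.
#'
#' @param intergenic Intergenic partition.
#' @param repeats Repeat tibble with `category`, `is_L1M`.
#' @param elements Element tibble.
#' @param genes Gene-model tibble (for group labels).
#' @return Tibble `group`, `n_l1`, `median_l1_coverage`, `frac_l1_with_pcs`,
#'   `frac_l1m`.
#' @export
l1_summary <- function(intergenic, repeats, elements, genes) {
  l1 <- dplyr::filter(repeats, .data$category == "L1")
  ig <- dplyr::mutate(intergenic,
    group = genes$group[match(.data$gene_id, genes$gene_id)],
    l1_cov = iv_covered_width(intergenic, l1) / (.data$end - .data$start))
  # assign each L1 to the intergenic region it overlaps most
  h <- iv_hits(l1, ig)
  l1_grp <- h |>
    dplyr::arrange(.data$q, dplyr::desc(.data$width)) |>
    dplyr::distinct(.data$q, .keep_all = TRUE)
  l1$group <- NA_character_
  l1$group[l1_grp$q] <- ig$group[l1_grp$s]
  l1$has_pcs <- iv_overlap_any(l1, elements)
  cov_sum <- ig |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_l1_coverage = stats::median(.data$l1_cov),
                     .groups = "drop")
  l1_sum <- l1 |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_l1 = dplyr::n(),
                     frac_l1_with_pcs = mean(.data$has_pcs),
                     frac_l1m = mean(.data$is_L1M), .groups = "drop")
  dplyr::full_join(cov_sum, l1_sum, by = "group")
}

#' Per-gene binding-site association and co-occurrence
#'
#' Flags, per gene and per site track, whether a site falls in the gene's
#' introns, assigned intergenic DNA, promoter, or any of these; reports
#' the co-occurrence of the first two tracks. Optionally only sites that
#' themselves overlap a conserved element are counted.
#'
#' @param genes Gene-model tibble.
#' @param site_tracks Named list of site tibbles (e.g.
#'   `list(ctcf = ..., yy1 = ...)`).
#' @param intergenic Intergenic partition.
#' @param promoters Promoter tibble from [promoter_of()].
#' @param elements Optional element tibble; with
#'   `require_element_overlap = TRUE` sites must overlap an element.
#' @param require_element_overlap Restrict to element-overlapping sites.
#' @return Per-gene tibble with `has_<track>_intronic`,
#'   `has_<track>_intergenic`, `has_<track>_promoter`, `has_<track>_any`
#'   flags and, for two tracks, `co_occurrence`.
#' @export
gene_site_association <- function(genes, site_tracks, intergenic, promoters,
                                  elements = NULL,
                                  require_element_overlap = FALSE) {
  introns <- flatten_gene_intervals(genes, "introns")
  region_sets <- list(
    intronic = introns,
    intergenic = dplyr::select(intergenic, "gene_id", "chrom", "start", "end"),
    promoter = dplyr::select(promoters, "gene_id", "chrom", "start", "end")
  )
  out <- dplyr::select(genes, "gene_id", "group")
  for (nm in names(site_tracks)) {
    sites <- site_tracks[[nm]]
    if (require_element_overlap) {
      if (is.null(elements)) stop("elements required", call. = FALSE)
      sites <- sites[iv_overlap_any(sites, elements), , drop = FALSE]
    }
    any_flag <- rep(FALSE, nrow(genes))
    for (rc in names(region_sets)) {
      reg <- region_sets[[rc]]
      hit_genes <- unique(reg$gene_id[iv_overlap_any(reg, sites)])
      flag <- out$gene_id %in% hit_genes
      out[[paste0("has_", nm, "_", rc)]] <- flag
      any_flag <- any_flag | flag
    }
    out[[paste0("has_", nm, "_any")]] <- any_flag
  }
  if (length(site_tracks) == 2) {
    nms <- names(site_tracks)
    out$co_occurrence <- out[[paste0("has_", nms[1], "_any")]] &
      out[[paste0("has_", nms[2], "_any")]]
  }
  out
}

#' Per-class summary of conserved elements
#'
#' For each element class (optionally within each gene group): element
#' count, median conservation score, median length, median G+C, the
#' percentage of elements containing at least one CpG, median
#' CpG_obs/CpG_exp and median deamination index.
#'
#' @param elements Classified element tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param by_group Also split by gene group.
#' @return Summary tibble, one row per class (and group).
#' @export
pcs_class_summary <- function(elements, genome, by_group = FALSE) {
  el <- composition_per_interval(elements, genome)
  keys <- if (by_group) c("group", "element_class") else "element_class"
  el |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_score = stats::median(.data$score),
      median_length = stats::median(.data$end - .data$start),
      median_gc = stats::median(.data$gc, na.rm = TRUE),
      pct_with_cpg = 100 * mean(.data$has_cpg),
      median_cpg_oe = stats::median(.data$cpg_oe, na.rm = TRUE),
      median_deamination = stats::median(.data$deamination_index, na.rm = TRUE),
      .groups = "drop"
    )
}
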