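# Synthetic genome bundles: internally consistent toy genomes (sequence +
# gene annotation + conserved-element, CpG-island, repeat and TFBS tracks
# + gene-group file) with controllable planted group effects, so that
# every pipeline stage can be checked against ground truth.

BASE_LETTERS <- c("A", "C", "G", "T")
BASE_RAW <- as.raw(c(65L, 67L, 71L, 84L))

iid_base_ints <- function(n, gc) {
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Plant non-overlapping CpG dinucleotides at roughly `density` per base.
plant_cpg_ints <- function(v, density) {
  n <- length(v)
  if (n < 2 || density <= 0) return(v)
  k <- round(density * n)
  if (k < 1) return(v)
  pos <- sort(sample.int(n - 1L, min(k, n - 1L)))
  pos <- pos[c(TRUE, diff(pos) >= 2L)]
  v[pos] <- 2L
  v[pos + 1L] <- 3L
  v
}

ints_to_string <- function(v) rawToChar(BASE_RAW[v])

# Cheap row accumulator: scalar records collected in a list, turned into
# a tibble in one pass at the end (tibble() per row is too slow in the
# placement loops).
row_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}
acc_add <- function(acc, ...) {
  acc$rows[[length(acc$rows) + 1L]] <- list(...)
  invisible(acc)
}
acc_tbl <- function(acc, proto) {
  if (length(acc$rows) == 0) return(proto)
  cols <- names(acc$rows[[1]])
  tibble::as_tibble(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(acc$rows, `[[`, cn), use.names = FALSE)
  }))
}

# Per-group parameter lookup: scalars recycle, named vectors must cover
# the group.
grp_param <- function(x, group) {
  if (length(x) == 1 && is.null(names(x))) return(rep(unname(x), length(group)))
  out <- unname(x[group])
  if (any(is.na(out))) {
    stop("parameter has no value for group(s): ",
         paste(unique(group[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Configuration for the synthetic genome generator
#'
#' Defaults encode the contrasts under study: imprinted (maternal and
#' paternal) genes sit in longer intergenic regions, carry denser
#' conserved noncoding elements that crowd closer to exon boundaries,
#' experience less CpG deamination, have more intronic CpG islands, a
#' larger ancient-L1M share among their L1 repeats, more CTCF/YY1 sites,
#' and a CpG-containing 6-mer planted into their intronic conserved
#' elements at 5-fold enrichment. Per-group parameters are named vectors
#' over the group labels; scalars apply to every group.
#'
#' @param group_sizes Named integer vector of genes per group.
#' @param n_chromosomes Number of chromosomes to spread genes over.
#' @param p_intronless Probability a gene has a single exon.
#' @param intron_lambda Poisson mean of the intron count (when not
#'   intronless; zero draws are bumped to one).
#' @param exon_meanlog,exon_sdlog Log-normal exon length (bp).
#' @param intron_meanlog,intron_sdlog Log-normal intron length (bp).
#' @param intron_mult Per-group intron length multiplier.
#' @param intergenic_meanlog,intergenic_sdlog Log-normal per-gene flank
#'   allowance (bp); consecutive flank allowances average into the gap.
#' @param intergenic_mult Per-group flank multiplier.
#' @param gc Background G+C fraction.
#' @param p_island_promoter Probability of a CpG island at the TSS.
#' @param p_island_intronic Per-group probability of an intronic CpG
#'   island.
#' @param island_len_range Island length range (bp).
#' @param island_gc,island_cpg_density Island G+C and planted CpG density.
#' @param d Per-group CpG deamination probability outside islands (the
#'   germline-methylation surrogate).
#' @param d_island Per-group deamination probability inside islands.
#' @param elements_per_kb List with per-region element densities
#'   (`coding`, `utr`, `intronic`, `intergenic`; the latter two may be
#'   per-group).
#' @param element_meanlog,element_sdlog Log-normal element length.
#' @param min_element_len Minimum emitted element length (20 bp).
#' @param frac_short Extra fraction of deliberately short (< 20 bp)
#'   elements, for exercising the length filter.
#' @param exon_decay Per-group mean distance (bp, exponential) of
#'   intronic elements from the nearest exon boundary.
#' @param score_shape Named gamma shapes of conservation scores per true
#'   class; `score_scale` scales them. Absolute scale is arbitrary.
#' @param score_scale Gamma scale of conservation scores.
#' @param repeats_per_kb Repeat density in introns and intergenic DNA.
#' @param repeat_meanlog,repeat_sdlog Log-normal repeat length.
#' @param repeat_cat_probs Category probabilities for placed repeats.
#' @param l1m_frac Per-group fraction of L1 repeats from the ancient L1M
#'   subgroup.
#' @param tfbs_prob List `ctcf`/`yy1` of per-group per-region-class site
#'   probabilities.
#' @param motif List `kmer`, `fold`, `target_groups`, `region` for the
#'   planted motif, or `NULL` for none.
#' @return A `synth_config` list.
#' @export
synth_config <- function(
    group_sizes = c(maternal = 29L, paternal = 29L, autosomal = 242L),
    n_chromosomes = 1L,
    p_intronless = 0.08,
    intron_lambda = 3,
    exon_meanlog = log(140), exon_sdlog = 0.3,
    intron_meanlog = log(500), intron_sdlog = 0.5,
    intron_mult = 1,
    intergenic_meanlog = log(2500), intergenic_sdlog = 0.5,
    intergenic_mult = c(maternal = 2, paternal = 2, autosomal = 1),
    gc = 0.42,
    p_island_promoter = 0.7,
    p_island_intronic = c(maternal = 0.5, paternal = 0.5, autosomal = 0.15),
    island_len_range = c(300L, 700L),
    island_gc = 0.65, island_cpg_density = 0.06,
    d = c(maternal = 0.25, paternal = 0.2, autosomal = 0.5),
    d_island = c(maternal = 0.05, paternal = 0.05, autosomal = 0.1),
    elements_per_kb = list(
      coding = 1.5, utr = 0.4,
      intronic = c(maternal = 1.2, paternal = 1.2, autosomal = 0.6),
      intergenic = c(maternal = 0.8, paternal = 0.8, autosomal = 0.4)
    ),
    element_meanlog = log(70), element_sdlog = 0.4,
    min_element_len = 20L,
    frac_short = 0,
    exon_decay = c(maternal = 300, paternal = 300, autosomal = 800),
    score_shape = c(coding = 8, utr = 5, intronic = 4, intergenic = 3, short = 2),
    score_scale = 30,
    repeats_per_kb = 0.4,
    repeat_meanlog = log(250), repeat_sdlog = 0.6,
    repeat_cat_probs = c(SINE_Alu = 0.25, MIR = 0.15, L1 = 0.25, L2 = 0.1,
                         LTR = 0.15, MER = 0.05, low_complexity_simple = 0.05),
    l1m_frac = c(maternal = 0.8, paternal = 0.8, autosomal = 0.4),
    tfbs_prob = list(
      ctcf = c(maternal = 0.5, paternal = 0.5, autosomal = 0.25),
      yy1 = c(maternal = 0.4, paternal = 0.4, autosomal = 0.2)
    ),
    motif = list(kmer = "TGCGTA", fold = 5,
                 target_groups = c("maternal", "paternal"),
                 region = "intronic")) {
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' Null configuration: no group differences
#'
#' Every per-group knob is flattened to the autosomal baseline and no
#' motif is planted, so all downstream group comparisons hold under the
#' null.
#'
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config` list.
#' @export
synth_config_null <- function(...) {
  synth_config(
    intergenic_mult = 1,
    p_island_intronic = 0.15,
    d = 0.4, d_island = 0.1,
    elements_per_kb = list(coding = 1.5, utr = 0.4, intronic = 0.6,
                           intergenic = 0.4),
    exon_decay = 800,
    l1m_frac = 0.4,
    tfbs_prob = list(ctcf = 0.25, yy1 = 0.2),
    motif = NULL,
    ...
  )
}

# Draw one gene's structure (relative coordinates within its span).
draw_gene_structure <- function(cfg, group) {
  n_int <- if (stats::runif(1) < cfg$p_intronless) 0L else
    max(1L, stats::rpois(1, cfg$intron_lambda))
  n_ex <- n_int + 1L
  ex_len <- pmax(40L, round(stats::rlnorm(n_ex, cfg$exon_meanlog, cfg$exon_sdlog)))
  in_len <- if (n_int > 0) {
    pmax(60L, round(stats::rlnorm(n_int, cfg$intron_meanlog, cfg$intron_sdlog) *
                      grp_param(cfg$intron_mult, group)))
  } else integer(0)
  lens <- integer(2 * n_ex - 1)
  lens[seq(1, by = 2, length.out = n_ex)] <- ex_len
  if (n_int > 0) lens[seq(2, by = 2, length.out = n_int)] <- in_len
  starts <- cumsum(c(0L, lens[-length(lens)]))
  ends <- starts + lens
  is_exon <- seq_along(lens) %% 2 == 1
  span_len <- sum(lens)
  cds_s <- max(1L, ex_len[1] %/% 3)
  cds_e <- span_len - max(1L, ex_len[n_ex] %/% 3)
  list(span_len = span_len,
       exons = cbind(starts[is_exon], ends[is_exon]),
       introns = if (n_int > 0) cbind(starts[!is_exon], ends[!is_exon])
                 else matrix(integer(0), ncol = 2),
       cds = c(cds_s, cds_e))
}

place_in_interval <- function(n, start, end, len_fun) {
  if (n <= 0 || end - start <= 0) {
    return(matrix(integer(0), ncol = 2))
  }
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    len <- min(len_fun(), end - start)
    if (len < 1) next
    s <- start + sample.int(end - start - len + 1L, 1) - 1L
    out <- rbind(out, c(s, s + len))
  }
  out
}

#' Generate a synthetic genome bundle
#'
#' Builds one or more chromosomes of i.i.d. background sequence carrying
#' the configured gene structures, overlays CpG islands, applies per-group
#' CpG deamination (a different, lower rate inside islands, emulating
#' regions hypomethylated only at their islands), places scored conserved
#' elements with an exon-proximity decay, repeats and binding sites, and
#' finally injects the planted motif into the target group's elements.
#' Everything is deterministic given the seed.
#'
#' @param config A [synth_config()] list.
#' @param seed Integer seed.
#' @return A `synth_bundle` list: `genome` (DNAStringSet),
#'   `chrom_lengths`, `transcripts`, `groups`, `elements` (raw track),
#'   `cpg_islands`, `repeats`, `tfbs` (list `ctcf`, `yy1`), `truth`
#'   (per-gene and per-element ground truth, planted parameters),
#'   `config`, `seed`.
#' @export
synth_genome <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  with_seed(seed, {
    n_genes <- sum(cfg$group_sizes)
    groups_shuffled <- sample(rep(names(cfg$group_sizes), cfg$group_sizes))
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    chrom_of <- paste0("chr", rep(seq_len(cfg$n_chromosomes),
                                  length.out = n_genes))
    chrom_of <- sort(chrom_of)

    gene_rows <- list(); tx_rows <- list()
    isl_acc <- row_acc(); el_acc <- row_acc(); rep_acc <- row_acc()
    ctcf_acc <- row_acc(); yy1_acc <- row_acc()
    chrom_lengths <- integer(0)
    genome_ints <- list()

    el_len <- function() max(cfg$min_element_len,
                             round(stats::rlnorm(1, cfg$element_meanlog,
                                                 cfg$element_sdlog)))
    rep_len <- function() max(30L, round(stats::rlnorm(1, cfg$repeat_meanlog,
                                                       cfg$repeat_sdlog)))
    n_for <- function(len, per_kb) stats::rpois(1, max(0, len) / 1000 * per_kb)

    gi <- 0L
    for (ch in unique(chrom_of)) {
      idx <- which(chrom_of == ch)
      k <- length(idx)
      grp <- groups_shuffled[idx]
      flank <- round(stats::rlnorm(k, cfg$intergenic_meanlog, cfg$intergenic_sdlog) *
                       grp_param(cfg$intergenic_mult, grp))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      structs <- lapply(grp, function(g) draw_gene_structure(cfg, g))

      # place genes left to right; interior gaps average the two flanks
      span_start <- integer(k); span_end <- integer(k)
      cursor <- flank[1]
      for (j in seq_len(k)) {
        if (j > 1) cursor <- cursor + round((flank[j - 1] + flank[j]) / 2)
        span_start[j] <- cursor
        span_end[j] <- cursor + structs[[j]]$span_len
        cursor <- span_end[j]
      }
      chrom_len <- span_end[k] + flank[k]
      chrom_lengths[ch] <- chrom_len
      # gap segments: (left bound, right bound, left gene idx, right gene idx)
      gap_tbl <- tibble::tibble(
        a = c(0L, span_end), b = c(span_start, chrom_len),
        left = c(NA_integer_, seq_len(k)), right = c(seq_len(k), NA_integer_)
      )
      gap_tbl <- gap_tbl[gap_tbl$b > gap_tbl$a, ]

      v <- iid_base_ints(chrom_len, cfg$gc)
      chrom_islands <- list()   # island intervals on this chromosome

      for (j in seq_len(k)) {
        gi <- gi + 1L
        id <- gene_ids[gi]
        st <- structs[[j]]
        exons <- st$exons + span_start[j]
        introns <- st$introns + span_start[j]
        cds <- st$cds + span_start[j]
        cds_iv <- cbind(pmax(exons[, 1], cds[1]), pmin(exons[, 2], cds[2]))
        cds_iv <- cds_iv[cds_iv[, 2] > cds_iv[, 1], , drop = FALSE]
        utr_parts <- rbind(
          if (exons[1, 1] < cds[1]) c(exons[1, 1], min(cds[1], exons[1, 2])),
          if (exons[nrow(exons), 2] > cds[2])
            c(max(cds[2], exons[nrow(exons), 1]), exons[nrow(exons), 2])
        )

        gene_rows[[gi]] <- tibble::tibble(
          gene_id = id, chrom = ch, strand = strand[j], group = grp[j],
          start = span_start[j], end = span_end[j], flank = flank[j],
          n_introns = nrow(introns)
        )
        tx_rows[[gi]] <- tibble::tibble(
          gene_id = id, transcript_id = paste0(id, ".t1"), chrom = ch,
          strand = strand[j],
          feature = c("transcript", rep("exon", nrow(exons)),
                      rep("CDS", nrow(cds_iv))),
          start = c(span_start[j], exons[, 1], cds_iv[, 1]),
          end = c(span_end[j], exons[, 2], cds_iv[, 2])
        )

        # CpG islands: promoter (straddling the strand-aware TSS), intronic
        gene_islands <- list()
        if (stats::runif(1) < cfg$p_island_promoter) {
          len <- sample(seq(cfg$island_len_range[1], cfg$island_len_range[2]), 1)
          tss <- if (strand[j] == "+") span_start[j] else span_end[j]
          isl <- c(max(0L, tss - len %/% 2), min(chrom_len, tss + len %/% 2))
          gene_islands[[length(gene_islands) + 1]] <- isl
        }
        if (nrow(introns) > 0 &&
            stats::runif(1) < grp_param(cfg$p_island_intronic, grp[j])) {
          iv <- introns[sample.int(nrow(introns), 1), ]
          len <- min(sample(seq(cfg$island_len_range[1], cfg$island_len_range[2]), 1),
                     iv[2] - iv[1])
          if (len >= 100) {
            s <- iv[1] + sample.int(iv[2] - iv[1] - len + 1L, 1) - 1L
            gene_islands[[length(gene_islands) + 1]] <- c(s, s + len)
          }
        }
        for (isl in gene_islands) {
          acc_add(isl_acc, chrom = ch, start = isl[1], end = isl[2],
                  gene_id = id)
          chrom_islands[[length(chrom_islands) + 1]] <- isl
          w <- isl[2] - isl[1]
          vi <- iid_base_ints(w, cfg$island_gc)
          v[(isl[1] + 1):isl[2]] <- plant_cpg_ints(vi, cfg$island_cpg_density)
        }

        add_elements <- function(iv_mat, klass, per_kb) {
          for (r in seq_len(nrow(iv_mat))) {
            n <- n_for(iv_mat[r, 2] - iv_mat[r, 1], per_kb)
            pos <- place_in_interval(n, iv_mat[r, 1], iv_mat[r, 2], el_len)
            for (p in seq_len(nrow(pos))) {
              acc_add(el_acc, chrom = ch, start = pos[p, 1], end = pos[p, 2],
                      true_class = klass, true_gene = id, true_group = grp[j])
            }
          }
        }
        add_elements(cds_iv, "coding", cfg$elements_per_kb$coding)
        if (!is.null(utr_parts) && nrow(utr_parts) > 0) {
          add_elements(utr_parts, "utr", cfg$elements_per_kb$utr)
        }
        # intronic elements: exponential decay from a random exon boundary
        if (nrow(introns) > 0) {
          rate_kb <- grp_param(cfg$elements_per_kb$intronic, grp[j])
          decay <- grp_param(cfg$exon_decay, grp[j])
          total_intron <- sum(introns[, 2] - introns[, 1])
          n <- n_for(total_intron, rate_kb)
          for (e in seq_len(n)) {
            r <- sample.int(nrow(introns), 1,
                            prob = introns[, 2] - introns[, 1])
            ilen <- introns[r, 2] - introns[r, 1]
            len <- el_len()
            if (ilen < len + 1) next
            dist <- min(round(stats::rexp(1, 1 / decay)), ilen - len)
            from_left <- stats::runif(1) < 0.5
            s <- if (from_left) introns[r, 1] + dist
                 else introns[r, 2] - dist - len
            acc_add(el_acc, chrom = ch, start = s, end = s + len,
                    true_class = "intronic", true_gene = id,
                    true_group = grp[j])
          }
        }

        # repeats and TFBS need the gene's intergenic halves; collected below
      }

      # intergenic halves, with owning gene and group
      halves <- list()
      for (r in seq_len(nrow(gap_tbl))) {
        a <- gap_tbl$a[r]; b <- gap_tbl$b[r]
        lg <- gap_tbl$left[r]; rg <- gap_tbl$right[r]
        if (is.na(lg)) {
          halves[[length(halves) + 1]] <- c(a, b, rg)
        } else if (is.na(rg)) {
          halves[[length(halves) + 1]] <- c(a, b, lg)
        } else {
          m <- (a + b) %/% 2
          if (m > a) halves[[length(halves) + 1]] <- c(a, m, lg)
          if (b > m) halves[[length(halves) + 1]] <- c(m, b, rg)
        }
      }
      gidx0 <- gi - k   # offset of this chromosome's first gene - 1
      for (h in halves) {
        g <- h[3]
        id <- gene_ids[gidx0 + g]
        hgrp <- grp[g]
        n <- n_for(h[2] - h[1], grp_param(cfg$elements_per_kb$intergenic, hgrp))
        pos <- place_in_interval(n, h[1], h[2], el_len)
        for (p in seq_len(nrow(pos))) {
          acc_add(el_acc, chrom = ch, start = pos[p, 1], end = pos[p, 2],
                  true_class = "intergenic", true_gene = id, true_group = hgrp)
        }
      }

      # repeats in introns and intergenic halves
      rep_regions <- c(
        lapply(halves, function(h) list(iv = h[1:2], grp = grp[h[3]])),
        unlist(lapply(seq_len(k), function(j) {
          ints <- structs[[j]]$introns + span_start[j]
          lapply(seq_len(nrow(ints)),
                 function(r) list(iv = ints[r, ], grp = grp[j]))
        }), recursive = FALSE)
      )
      for (rr in rep_regions) {
        n <- n_for(rr$iv[2] - rr$iv[1], cfg$repeats_per_kb)
        pos <- place_in_interval(n, rr$iv[1], rr$iv[2], rep_len)
        for (p in seq_len(nrow(pos))) {
          cat_p <- sample(names(cfg$repeat_cat_probs), 1,
                          prob = cfg$repeat_cat_probs)
          name <- switch(cat_p,
            SINE_Alu = "AluY", MIR = "MIR3", L2 = "L2a", LTR = "MLT1A",
            MER = "MER20", low_complexity_simple = "(TA)n",
            L1 = if (stats::runif(1) < grp_param(cfg$l1m_frac, rr$grp))
              "L1M4" else "L1PA3")
          acc_add(rep_acc, chrom = ch, start = pos[p, 1], end = pos[p, 2],
                  name = name)
        }
      }

      # CTCF / YY1 sites per gene and region class
      for (j in seq_len(k)) {
        id <- gene_ids[gidx0 + j]
        ints <- structs[[j]]$introns + span_start[j]
        my_halves <- Filter(function(h) h[3] == j, halves)
        prom <- if (strand[j] == "+") {
          c(max(0L, span_start[j] - 1000L), span_start[j])
        } else c(span_end[j], min(chrom_len, span_end[j] + 1000L))
        for (track in names(cfg$tfbs_prob)) {
          p_site <- grp_param(cfg$tfbs_prob[[track]], grp[j])
          regions <- list()
          if (nrow(ints) > 0) {
            regions$intronic <- ints[sample.int(nrow(ints), 1), ]
          }
          if (length(my_halves) > 0) {
            hh <- my_halves[[sample.int(length(my_halves), 1)]]
            regions$intergenic <- hh[1:2]
          }
          regions$promoter <- prom
          for (rc in names(regions)) {
            if (stats::runif(1) >= p_site) next
            iv <- regions[[rc]]
            if (iv[2] - iv[1] < 16) next
            s <- iv[1] + sample.int(iv[2] - iv[1] - 15L, 1) - 1L
            acc <- if (track == "ctcf") ctcf_acc else yy1_acc
            acc_add(acc, chrom = ch, start = s, end = s + 15L, name = track)
          }
        }
      }

      # deamination: per-base group territory (gap midpoints) and islands
      terr_group <- character(k)
      terr_group <- grp
      bounds <- c(0L, span_end[-k] + (span_start[-1] - span_end[-k]) %/% 2,
                  chrom_len)
      group_code <- integer(chrom_len)
      for (j in seq_len(k)) {
        group_code[(bounds[j] + 1):bounds[j + 1]] <-
          match(terr_group[j], names(cfg$group_sizes))
      }
      in_island <- logical(chrom_len)
      for (isl in chrom_islands) {
        in_island[(isl[1] + 1):isl[2]] <- TRUE
      }
      cpg_pos <- which(v[-chrom_len] == 2L & v[-1] == 3L)
      if (length(cpg_pos) > 0) {
        d_out <- grp_param(cfg$d, names(cfg$group_sizes))
        d_in <- grp_param(cfg$d_island, names(cfg$group_sizes))
        d_eff <- ifelse(in_island[cpg_pos],
                        d_in[group_code[cpg_pos]], d_out[group_code[cpg_pos]])
        hit <- cpg_pos[stats::runif(length(cpg_pos)) < d_eff]
        if (length(hit) > 0) {
          top <- stats::runif(length(hit)) < 0.5
          v[hit[top]] <- 4L        # CpG -> TpG
          v[hit[!top] + 1L] <- 1L  # CpG -> CpA
        }
      }
      genome_ints[[ch]] <- v
    }

    genes_truth <- dplyr::bind_rows(gene_rows)
    elements <- acc_tbl(el_acc, tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      true_class = character(), true_gene = character(),
      true_group = character()))

    # deliberately short fragments, exercising the >= 20 bp filter
    if (cfg$frac_short > 0 && nrow(elements) > 0) {
      n_short <- round(cfg$frac_short * nrow(elements) / (1 - cfg$frac_short))
      ch_pick <- sample(names(chrom_lengths), n_short, replace = TRUE)
      len <- sample(5:19, n_short, replace = TRUE)
      s <- vapply(seq_len(n_short), function(i) {
        sample.int(chrom_lengths[[ch_pick[i]]] - len[i], 1) - 1L
      }, integer(1))
      elements <- dplyr::bind_rows(elements, tibble::tibble(
        chrom = ch_pick, start = s, end = s + len,
        true_class = "short", true_gene = NA_character_,
        true_group = NA_character_))
    }

    # plant the motif into target-group elements, rewriting the genome
    motif_truth <- NULL
    if (!is.null(cfg$motif) && !is.null(cfg$motif$fold) && cfg$motif$fold > 1) {
      m <- cfg$motif
      kint <- match(strsplit(m$kmer, "")[[1]], BASE_LETTERS)
      klen <- length(kint)
      tgt <- which(elements$true_class == m$region &
                     elements$true_group %in% m$target_groups)
      if (length(tgt) > 0) {
        windows <- pmax(0, elements$end[tgt] - elements$start[tgt] - klen + 1)
        base_freq <- tabulate(unlist(genome_ints, use.names = FALSE), nbins = 4L)
        p_base <- base_freq / sum(base_freq)
        p0 <- prod(p_base[kint])
        n_insert <- round((m$fold - 1) * p0 * sum(windows))
        if (n_insert > 0 && sum(windows > 0) > 0) {
          pick <- sample(tgt, n_insert, replace = TRUE, prob = windows)
          for (i in pick) {
            s <- elements$start[i] +
              sample.int(elements$end[i] - elements$start[i] - klen + 1L, 1) - 1L
            genome_ints[[elements$chrom[i]]][(s + 1):(s + klen)] <- kint
          }
        }
        motif_truth <- list(kmer = m$kmer, fold = m$fold, n_inserted =
                              if (n_insert > 0) n_insert else 0L,
                            target_groups = m$target_groups, region = m$region)
      }
    }

    genome <- Biostrings::DNAStringSet(vapply(genome_ints, ints_to_string,
                                              character(1)))
    names(genome) <- names(genome_ints)

    elements <- dplyr::mutate(elements,
      name = sprintf("pcs%05d", dplyr::row_number()),
      score = round(stats::rgamma(dplyr::n(),
                                  shape = cfg$score_shape[.data$true_class]) *
                      cfg$score_scale, 1)
    )
    empty_bed <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), name = character())
    cpg_islands <- acc_tbl(isl_acc, tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      gene_id = character()))
    repeats <- acc_tbl(rep_acc, empty_bed) |>
      dplyr::mutate(category = repeat_category(.data$name),
                    is_L1M = startsWith(.data$name, "L1M"))
    tfbs <- list(ctcf = acc_tbl(ctcf_acc, empty_bed),
                 yy1 = acc_tbl(yy1_acc, empty_bed))
    groups <- dplyr::select(genes_truth, "gene_id", "group")

    structure(list(
      genome = genome,
      chrom_lengths = chrom_lengths,
      transcripts = dplyr::bind_rows(tx_rows),
      groups = groups,
      elements = dplyr::select(elements, "chrom", "start", "end", "name", "score"),
      cpg_islands = dplyr::select(cpg_islands, "chrom", "start", "end"),
      repeats = repeats,
      tfbs = tfbs,
      truth = list(
        genes = genes_truth,
        elements = dplyr::select(elements, "name", "true_class", "true_gene",
                                 "true_group"),
        d = cfg$d, d_island = cfg$d_island,
        motif = motif_truth
      ),
      config = cfg,
      seed = seed
    ), class = "synth_bundle")
  })
}

#' Small fixed study-shaped bundle
#'
#' A deterministic fixture shaped like the study design: 58 labeled genes
#' (29 maternally, 29 paternally expressed) embedded among autosomal
#' genes, with every planted contrast of the default [synth_config()].
#' Runs the full pipeline in well under a minute.
#'
#' @param seed Integer seed (default 1).
#' @param n_autosomal Number of background autosomal genes (default 942,
#'   for 1000 genes total).
#' @return A `synth_bundle`.
#' @export
paper_shaped_fixture <- function(seed = 1L, n_autosomal = 942L) {
  cfg <- synth_config(group_sizes = c(maternal = 29L, paternal = 29L,
                                      autosomal = as.integer(n_autosomal)))
  synth_genome(cfg, seed = seed)
}

#' Write a synthetic bundle to standard flat files
#'
#' Emits `genome.fa`, `genes.gtf`, `elements.bed` (BED5 with the
#' conservation score), `cpg_islands.bed`, `repeats.bed`,
#' `tfbs_ctcf.bed`, `tfbs_yy1.bed`, `groups.tsv` and a `truth.json`
#' sidecar.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_gtf(bundle$transcripts, p("genes.gtf"))
  readr::write_tsv(bundle$elements, p("elements.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(bundle$cpg_islands, p("cpg_islands.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(dplyr::select(bundle$repeats, "chrom", "start", "end", "name"),
                   p("repeats.bed"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(bundle$tfbs$ctcf, p("tfbs_ctcf.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(bundle$tfbs$yy1, p("tfbs_yy1.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(bundle$groups, p("groups.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(genes = bundle$truth$genes, elements = bundle$truth$elements,
         d = as.list(bundle$truth$d), d_island = as.list(bundle$truth$d_island),
         motif = bundle$truth$motif, seed = bundle$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle back from [write_genome_bundle()] output
#'
#' @param dir Directory written by [write_genome_bundle()].
#' @return A list with `genome`, `chrom_lengths`, `transcripts`, `groups`,
#'   `elements`, `cpg_islands`, `repeats`, `tfbs`.
#' @export
read_genome_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  genome <- read_genome(p("genome.fa"))
  list(
    genome = genome,
    chrom_lengths = stats::setNames(Biostrings::width(genome), names(genome)),
    transcripts = read_gtf(p("genes.gtf")),
    groups = read_gene_groups(p("groups.tsv")),
    elements = read_elements(p("elements.bed")),
    cpg_islands = read_bed(p("cpg_islands.bed")),
    repeats = read_repeats(p("repeats.bed"), format = "bed"),
    tfbs = list(ctcf = read_bed(p("tfbs_ctcf.bed")),
                yy1 = read_bed(p("tfbs_yy1.bed")))
  )
}
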