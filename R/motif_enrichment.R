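# k-mer enrichment of conserved-element collections against a genomic
# background and a comparison collection. Counting is strand-specific
# (reported motifs are oriented) and N-containing windows never count, so
# the 6-N separators used in per-gene concatenation cannot create
# artificial k-mers.

#' Concatenate element sequences per gene
#'
#' Extracts each element's sequence and concatenates the elements of one
#' gene into a single string, separated by six `N`s to prevent artificial
#' sequence combinations at the junctions. Optionally, bases overlapping
#' repeats are converted to `N` first to exclude motifs in repeats.
#'
#' @param elements Element tibble with `gene_id` (and `chrom`, `start`,
#'   `end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param mask Optional interval tibble (e.g. repeats); overlapping bases
#'   become `N`.
#' @param sep Separator (default `"NNNNNN"`).
#' @return Tibble `gene_id`, `seq`.
#' @export
concatenate_by_gene <- function(elements, genome, mask = NULL, sep = "NNNNNN") {
  el <- dplyr::filter(elements, !is.na(.data$gene_id))
  if (nrow(el) == 0) return(tibble::tibble(gene_id = character(), seq = character()))
  seqs <- as.character(extract_interval_seqs(el, genome))
  if (!is.null(mask) && nrow(mask) > 0) {
    h <- iv_hits(el, mask)
    if (nrow(h) > 0) {
      clip <- h |>
        dplyr::mutate(
          from = pmax(el$start[.data$q], mask$start[.data$s]) - el$start[.data$q] + 1L,
          to = pmin(el$end[.data$q], mask$end[.data$s]) - el$start[.data$q]
        )
      for (i in seq_len(nrow(clip))) {
        q <- clip$q[i]
        substr(seqs[q], clip$from[i], clip$to[i]) <-
          strrep("N", clip$to[i] - clip$from[i] + 1L)
      }
    }
  }
  el |>
    dplyr::mutate(seq = seqs) |>
    dplyr::arrange(.data$gene_id, .data$chrom, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(seq = paste(.data$seq, collapse = sep), .groups = "drop")
}

#' Count overlapping k-mers
#'
#' Strand-specific overlapping window counts over the 4^k standard k-mers;
#' windows containing `N` are skipped.
#'
#' @param seqs Character vector of sequences (pooled) or a
#'   [Biostrings::DNAStringSet].
#' @param k Word length (default 6).
#' @return Named integer vector of length `4^k`.
#' @export
kmer_counts <- function(seqs, k = 6L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(
      vapply(as.character(seqs), normalize_seq, character(1), USE.NAMES = FALSE))
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  stats::setNames(as.integer(counts), names(counts))
}

n_valid_windows <- function(counts) sum(counts)

#' Binomial z-score for k-mer enrichment
#'
#' With reference k-mer frequency `p = count_ref / windows_ref`, the
#' expected target count is `p * windows_target` and the score is the
#' binomial z-score `(observed - expected) / sqrt(expected * (1 - p))`.
#' A reference count of zero with a nonzero observation yields `Inf`
#' unless a pseudocount is supplied.
#'
#' @param count_target,count_ref Observed k-mer counts (vectors allowed).
#' @param windows_target,windows_ref Numbers of valid windows in the two
#'   collections (must be positive).
#' @param pseudocount Added to the reference counts (and reference
#'   windows) before computing `p`; default 0.
#' @return Numeric vector of scores (0 where observed equals expected).
#' @export
enrichment_score <- function(count_target, windows_target, count_ref,
                             windows_ref, pseudocount = 0) {
  if (windows_target <= 0 || windows_ref <= 0) {
    stop("window counts must be positive", call. = FALSE)
  }
  p <- (count_ref + pseudocount) / (windows_ref + pseudocount)
  expected <- p * windows_target
  score <- ifelse(count_target == expected, 0,
                  (count_target - expected) / sqrt(expected * (1 - p)))
  score[p == 0 & count_target > 0] <- Inf
  score
}

#' Find k-mers enriched over background and a comparison collection
#'
#' Counts k-mers in the target collection and scores each against (i) a
#' genomic background collection and (ii) a comparison collection; motifs
#' pass when both scores reach the threshold. Passing motifs are sorted
#' by the smaller of the two scores, descending.
#'
#' @param target,background,comparison Character vectors of sequences
#'   (e.g. the `seq` column of [concatenate_by_gene()]).
#' @param k Word length (default 6).
#' @param threshold Score threshold both scores must reach (default 3.5).
#' @param pseudocount Passed to [enrichment_score()].
#' @return Tibble of `MotifResult` rows: `kmer`, `count_target`,
#'   `count_background`, `count_comparison`, `score_vs_genome`,
#'   `score_vs_comparison`, `contains_cpg`, `passes`; all 4^k k-mers are
#'   returned, sorted with passing motifs first.
#' @export
enriched_motifs <- function(target, background, comparison = NULL, k = 6L,
                            threshold = 3.5, pseudocount = 0) {
  if (length(target) == 0 || length(background) == 0) {
    stop("target and background collections must be nonempty", call. = FALSE)
  }
  ct <- kmer_counts(target, k)
  cb <- kmer_counts(background, k)
  sc_genome <- enrichment_score(ct, n_valid_windows(ct), cb,
                                n_valid_windows(cb), pseudocount)
  if (is.null(comparison)) {
    cc <- rep(NA_integer_, length(ct))
    sc_comp <- rep(NA_real_, length(ct))
    passes <- sc_genome >= threshold
  } else {
    cc <- kmer_counts(comparison, k)
    sc_comp <- enrichment_score(ct, n_valid_windows(ct), cc,
                                n_valid_windows(cc), pseudocount)
    passes <- sc_genome >= threshold & sc_comp >= threshold
  }
  min_score <- if (is.null(comparison)) sc_genome else pmin(sc_genome, sc_comp)
  tibble::tibble(
    kmer = names(ct), count_target = ct, count_background = cb,
    count_comparison = cc,
    score_vs_genome = sc_genome, score_vs_comparison = sc_comp,
    contains_cpg = grepl("CG", names(ct), fixed = TRUE),
    passes = passes, min_score = min_score
  ) |>
    dplyr::arrange(dplyr::desc(.data$passes), dplyr::desc(.data$min_score)) |>
    dplyr::select(-"min_score")
}

#' Motifs shared between two enrichment runs
#'
#' The cross-species intersection logic: k-mers passing both thresholds
#' in both runs (e.g. the human and mouse genomes).
#'
#' @param result_a,result_b Tibbles from [enriched_motifs()].
#' @return Tibble of shared passing k-mers with both runs' scores.
#' @export
shared_motifs <- function(result_a, result_b) {
  a <- dplyr::filter(result_a, .data$passes)
  b <- dplyr::filter(result_b, .data$passes)
  dplyr::inner_join(
    dplyr::select(a, "kmer", "contains_cpg",
                  score_vs_genome_a = "score_vs_genome",
                  score_vs_comparison_a = "score_vs_comparison"),
    dplyr::select(b, score_vs_genome_b = "score_vs_genome",
                  score_vs_comparison_b = "score_vs_comparison", "kmer"),
    by = "kmer"
  )
}
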