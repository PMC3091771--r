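# Composition statistics centred on CpG dinucleotides: G+C content,
# normalized CpG content (CpG_obs/CpG_exp, Gardiner-Garden convention) and
# the (TpG+CpA)/(2*CpG) deamination index. Methylated CpG deaminates to
# TpG (CpA on the opposite strand), so a high index marks accumulated CpG
# decay and a low index CpG maintenance.

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Normalize input to an uppercase ACGTN character string, with position
# diagnostics for anything else. Lowercase letters either fold to upper
# case (default) or become N (mask_lowercase, mirroring repeat-to-N
# masking of soft-masked sequence).
normalize_seq <- function(seq, mask_lowercase = FALSE) {
  s <- as.character(seq)
  if (length(s) != 1) stop("expected a single sequence", call. = FALSE)
  if (mask_lowercase) s <- gsub("[a-z]", "N", s)
  s <- toupper(s)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0) {
    stop("invalid character '", substr(s, bad, bad), "' at position ", bad,
         call. = FALSE)
  }
  s
}

#' Overlapping dinucleotide counts
#'
#' Counts all 16 dinucleotides in overlapping windows on the given strand
#' (no reverse-complement folding). Windows containing `N` are skipped.
#'
#' @param seq A nucleotide string (`A`/`C`/`G`/`T`/`N`, case-insensitive)
#'   or a [Biostrings::DNAString].
#' @param mask_lowercase Convert soft-masked (lowercase) letters to `N`
#'   before counting.
#' @return Named integer vector of length 16 (`AA`, `AC`, ..., `TT`).
#' @examples
#' dinucleotide_counts("ACGT")
#' @export
dinucleotide_counts <- function(seq, mask_lowercase = FALSE) {
  s <- normalize_seq(seq, mask_lowercase)
  Biostrings::dinucleotideFrequency(Biostrings::DNAString(s))
}

composition_from_counts <- function(mono, di) {
  len_eff <- sum(mono[c("A", "C", "G", "T")])
  n_c <- unname(mono[["C"]]); n_g <- unname(mono[["G"]])
  n_cpg <- unname(di[["CG"]]); n_tpg <- unname(di[["TG"]]); n_cpa <- unname(di[["CA"]])
  valid <- len_eff > 0
  tibble::tibble(
    length_effective = as.integer(len_eff),
    n_C = as.integer(n_c), n_G = as.integer(n_g),
    n_CpG = as.integer(n_cpg), n_TpG = as.integer(n_tpg), n_CpA = as.integer(n_cpa),
    gc = if (valid) (n_c + n_g) / len_eff else NA_real_,
    cpg_oe = if (valid && n_c * n_g > 0) n_cpg * len_eff / (n_c * n_g) else NA_real_,
    deamination_index = if (n_cpg > 0) (n_tpg + n_cpa) / (2 * n_cpg) else NA_real_,
    has_cpg = n_cpg >= 1,
    valid = valid
  )
}

#' Sequence composition statistics
#'
#' Computes G+C content, the normalized CpG content CpG_obs/CpG_exp
#' (`n_CpG * L / (n_C * n_G)`, the Gardiner-Garden convention also
#' underlying the UCSC CpG-island track) and the deamination index
#' `(n_TpG + n_CpA) / (2 * n_CpG)`. `N` bases are excluded from the
#' effective length and `N`-containing windows from all dinucleotide
#' counts, so masked repeats do not dilute the ratios. Ratios whose
#' denominator is zero are `NA`; an empty or all-`N` sequence yields a row
#' with `valid = FALSE`.
#'
#' @inheritParams dinucleotide_counts
#' @return A one-row tibble of `CompositionStats` fields:
#'   `length_effective`, `n_C`, `n_G`, `n_CpG`, `n_TpG`, `n_CpA`, `gc`,
#'   `cpg_oe`, `deamination_index`, `has_cpg`, `valid`.
#' @examples
#' composition("ACGT")   # gc 0.5, cpg_oe 4, deamination index 0
#' composition("TGCA")   # no CpG: deamination index NA
#' @export
composition <- function(seq, mask_lowercase = FALSE) {
  s <- normalize_seq(seq, mask_lowercase)
  x <- Biostrings::DNAString(s)
  mono <- Biostrings::alphabetFrequency(x)[c("A", "C", "G", "T")]
  di <- Biostrings::dinucleotideFrequency(x)
  composition_from_counts(mono, di)
}

extract_interval_seqs <- function(intervals, genome, mask_lowercase = FALSE) {
  check_intervals(intervals)
  if (!methods::is(genome, "DNAStringSet")) {
    if (mask_lowercase) genome <- vapply(genome, function(s) gsub("[a-z]", "N", s),
                                         character(1))
    genome <- Biostrings::DNAStringSet(genome)
  }
  missing <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- Biostrings::width(genome)[match(intervals$chrom, names(genome))]
  if (any(intervals$start < 0 | intervals$end > lens)) {
    stop("interval outside chromosome bounds", call. = FALSE)
  }
  chs <- unique(intervals$chrom)
  pieces <- lapply(chs, function(ch) {
    i <- which(intervals$chrom == ch)
    at <- IRanges::IRanges(start = intervals$start[i] + 1L,
                           end = intervals$end[i])
    list(i = i, seqs = Biostrings::extractAt(genome[[ch]], at))
  })
  dss <- do.call(c, lapply(pieces, `[[`, "seqs"))
  dss[order(unlist(lapply(pieces, `[[`, "i")))]
}

#' Pooled composition of an interval set
#'
#' Counts are accumulated per interval and pooled before the ratios are
#' computed; no dinucleotide window spans an interval boundary, because
#' pooled intervals are biologically discontiguous (e.g. the introns of a
#' gene).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named [Biostrings::DNAStringSet] covering the intervals'
#'   chromosomes.
#' @param mask_lowercase Convert soft-masked letters to `N` first.
#' @return A one-row `CompositionStats` tibble as in [composition()].
#' @export
composition_of_intervals <- function(intervals, genome, mask_lowercase = FALSE) {
  if (nrow(intervals) == 0) {
    return(composition_from_counts(
      c(A = 0L, C = 0L, G = 0L, T = 0L),
      stats::setNames(rep(0L, 16), Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2))
    ))
  }
  dss <- extract_interval_seqs(intervals, genome, mask_lowercase)
  mono <- colSums(Biostrings::alphabetFrequency(dss)[, c("A", "C", "G", "T"), drop = FALSE])
  di <- colSums(Biostrings::dinucleotideFrequency(dss))
  composition_from_counts(mono, di)
}

#' Per-interval composition statistics
#'
#' Row-wise variant of [composition_of_intervals()]: one
#' `CompositionStats` row per input interval, column-bound to the input.
#'
#' @inheritParams composition_of_intervals
#' @return The input tibble with the [composition()] columns appended.
#' @export
composition_per_interval <- function(intervals, genome, mask_lowercase = FALSE) {
  if (nrow(intervals) == 0) {
    return(dplyr::bind_cols(intervals, composition("ACGT")[0, ]))
  }
  dss <- extract_interval_seqs(intervals, genome, mask_lowercase)
  mono <- Biostrings::alphabetFrequency(dss)[, c("A", "C", "G", "T"), drop = FALSE]
  di <- Biostrings::dinucleotideFrequency(dss)
  len_eff <- rowSums(mono)
  n_c <- mono[, "C"]; n_g <- mono[, "G"]
  n_cpg <- di[, "CG"]; n_tpg <- di[, "TG"]; n_cpa <- di[, "CA"]
  valid <- len_eff > 0
  stats <- tibble::tibble(
    length_effective = as.integer(len_eff),
    n_C = as.integer(n_c), n_G = as.integer(n_g),
    n_CpG = as.integer(n_cpg), n_TpG = as.integer(n_tpg),
    n_CpA = as.integer(n_cpa),
    gc = ifelse(valid, (n_c + n_g) / len_eff, NA_real_),
    cpg_oe = ifelse(valid & n_c * n_g > 0,
                    n_cpg * len_eff / (n_c * n_g), NA_real_),
    deamination_index = ifelse(n_cpg > 0,
                               (n_tpg + n_cpa) / (2 * n_cpg), NA_real_),
    has_cpg = n_cpg >= 1,
    valid = valid
  )
  dplyr::bind_cols(intervals, stats)
}

#' Simulate CpG deamination
#'
#' Generates an ancestral i.i.d. sequence with CpG dinucleotides planted
#' at a given density, then lets each ancestral CpG deaminate
#' independently with probability `d`: the transition converts CpG to TpG
#' on the counted strand or to CpA (deamination on the template strand),
#' each with probability 1/2. This is the validation oracle for the
#' deamination index: the measured `(TpG+CpA)/(2*CpG)` must increase
#' monotonically in `d`, and CpG_obs/CpG_exp must decrease.
#'
#' @param ancestral_cpg_density Target fraction of positions starting a
#'   planted CpG (in addition to the i.i.d. background), in `[0, 1]`.
#' @param d Per-CpG deamination probability, in `[0, 1]`.
#' @param length Sequence length in bp.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List with `ancestral` and `evolved` sequence strings and
#'   `n_cpg_ancestral`, the CpG count before deamination.
#' @export
deamination_simulator <- function(ancestral_cpg_density, d, length, seed = 1L) {
  if (ancestral_cpg_density < 0 || ancestral_cpg_density > 1) {
    stop("ancestral_cpg_density must be in [0, 1]", call. = FALSE)
  }
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    n_plant <- round(ancestral_cpg_density * length)
    if (n_plant > 0 && length >= 2) {
      pos <- sort(sample.int(length - 1L, min(n_plant, length - 1L)))
      # drop positions that would overwrite the G of the previous CpG
      keep <- c(TRUE, diff(pos) >= 2L)
      pos <- pos[keep]
      base[pos] <- "C"
      base[pos + 1L] <- "G"
    }
    ancestral <- base
    is_cpg <- which(base[-length] == "C" & base[-1] == "G")
    n_cpg <- length(is_cpg)
    if (n_cpg > 0 && d > 0) {
      hit <- is_cpg[stats::runif(n_cpg) < d]
      if (length(hit) > 0) {
        top_strand <- stats::runif(length(hit)) < 0.5
        base[hit[top_strand]] <- "T"              # CpG -> TpG
        base[hit[!top_strand] + 1L] <- "A"        # CpG -> CpA
      }
    }
    list(ancestral = paste(ancestral, collapse = ""),
         evolved = paste(base, collapse = ""),
         n_cpg_ancestral = n_cpg)
  })
}
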