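# Two-group comparisons with the study's significance-tier convention and
# the random-gene-set background calibration. Raw p values are reported;
# the tiers encode a Bonferroni-style interpretation instead of adjusting
# the p values themselves.

TIER_LEVELS <- c("ns", "trend", "moderate", "highly")

#' Significance tier of a raw p value
#'
#' `highly` for p < 0.005, `moderate` for 0.005 <= p < 0.01, `trend` for
#' 0.01 <= p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    p < 0.005 ~ "highly",
    p < 0.01 ~ "moderate",
    p < 0.05 ~ "trend",
    TRUE ~ "ns"
  )
}

tier_rank <- function(tier) match(tier, TIER_LEVELS)

#' Map tiers to star annotations
#'
#' @param tier Character vector of tiers.
#' @param mapping Named character vector tier -> stars.
#' @return Character vector of star strings.
#' @export
tier_stars <- function(tier, mapping = c(highly = "***", moderate = "**",
                                         trend = "*", ns = "")) {
  unname(mapping[tier])
}

new_group_comparison <- function(feature, test, statistic, p, n_a, n_b,
                                 summary_a, summary_b) {
  structure(list(
    feature = feature, test = test, statistic = unname(statistic),
    p_raw = p, n_a = n_a, n_b = n_b,
    summary_a = summary_a, summary_b = summary_b,
    direction = sign(summary_a - summary_b),
    tier = significance_tier(p)
  ), class = "group_comparison")
}

#' Compare a continuous feature between two groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test: exact enumeration
#' when both groups have at most 20 observations and no ties, the
#' tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param values_a,values_b Numeric vectors for the two groups (each
#'   nonempty).
#' @param feature Feature label carried into reports.
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @examples
#' compare_continuous(c(1, 2, 3), c(10, 11, 12))  # exact two-sided p = 0.1
#' @export
compare_continuous <- function(values_a, values_b, feature = "feature") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  no_ties <- !any(duplicated(c(values_a, values_b)))
  exact <- length(values_a) <= 20 && length(values_b) <= 20 && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = !exact)
  )
  new_group_comparison(feature, "wilcoxon_rank_sum", wt$statistic,
                       min(wt$p.value, 1), length(values_a), length(values_b),
                       stats::median(values_a), stats::median(values_b))
}

#' Compare feature proportions between two groups
#'
#' Builds the 2x2 table of carriers/non-carriers and applies the
#' chi-square test (no continuity correction), falling back to Fisher's
#' exact test whenever any expected cell is below 5.
#'
#' @param k_a,k_b Feature-carrier counts in groups a and b.
#' @param n_a,n_b Group sizes (`k <= n`, `n > 0`).
#' @param feature Feature label.
#' @return A `group_comparison` object; `summary_a`/`summary_b` hold the
#'   two proportions.
#' @export
compare_counts <- function(k_a, n_a, k_b, n_b, feature = "feature") {
  if (n_a == 0 || n_b == 0) stop("group sizes must be positive", call. = FALSE)
  if (k_a > n_a || k_b > n_b) stop("k must not exceed n", call. = FALSE)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    res <- new_group_comparison(feature, "fisher_exact", ft$estimate,
                                ft$p.value, n_a, n_b, k_a / n_a, k_b / n_b)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- new_group_comparison(feature, "chi_square", ct$statistic,
                                ct$p.value, n_a, n_b, k_a / n_a, k_b / n_b)
  }
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, p = %.4g (%s)\n",
              x$feature, x$test, x$p_raw, x$tier))
  cat(sprintf("  group a: n = %d, summary = %.4g\n", x$n_a, x$summary_a))
  cat(sprintf("  group b: n = %d, summary = %.4g\n", x$n_b, x$summary_b))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with `feature`, `test`, `statistic`, `p_raw`,
#'   `tier`, `n_a`, `n_b`, `summary_a`, `summary_b`, `direction`.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, test = x$test, statistic = as.numeric(x$statistic),
    p_raw = x$p_raw, tier = x$tier, n_a = x$n_a, n_b = x$n_b,
    summary_a = x$summary_a, summary_b = x$summary_b, direction = x$direction
  )
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = as.numeric(x$statistic),
                 p_raw = x$p_raw, tier = x$tier)
}

#' Background calibration with random gene sets
#'
#' Draws random subsets of the autosomal pool of the same size as the
#' labeled (imprinted) set, repeats the Wilcoxon comparison of subset
#' versus the remaining pool, and counts how often the random sets reach
#' (or exceed) the tier observed for the labeled set. Subsets are drawn
#' without replacement and excluded from their comparison pool.
#'
#' @param pool_values Numeric vector of the feature over the autosomal
#'   pool (one value per gene).
#' @param observed Either a `group_comparison` object or a tier string;
#'   the tier random sets must reach.
#' @param set_size Number of genes per random set (default 58, the size
#'   of the labeled imprinted set).
#' @param n_resamples Number of random sets (default 100).
#' @param seed Integer seed; resampling is deterministic given it.
#' @return A `calibration_result` object with fields `feature`,
#'   `observed_tier`, `n_resamples`, `set_size`,
#'   `frequency_reaching_tier`, `tiers` (per-resample), `seed`.
#' @export
calibrate_with_random_sets <- function(pool_values, observed, set_size = 58L,
                                       n_resamples = 100L, seed = 1L) {
  pool_values <- pool_values[!is.na(pool_values)]
  if (length(pool_values) <= set_size) {
    stop("pool must be larger than set_size", call. = FALSE)
  }
  observed_tier <- if (inherits(observed, "group_comparison")) observed$tier
                   else match.arg(observed, TIER_LEVELS)
  feature <- if (inherits(observed, "group_comparison")) observed$feature else "feature"
  tiers <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(length(pool_values), set_size)
      compare_continuous(pool_values[idx], pool_values[-idx])$tier
    }, character(1))
  })
  structure(list(
    feature = feature, observed_tier = observed_tier,
    n_resamples = n_resamples, set_size = set_size,
    frequency_reaching_tier = mean(tier_rank(tiers) >= tier_rank(observed_tier)),
    tiers = tiers, seed = seed
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %s: %d random sets of %d genes\n  observed tier '%s' reached by %.0f%% of random sets\n",
    x$feature, x$n_resamples, x$set_size, x$observed_tier,
    100 * x$frequency_reaching_tier))
  invisible(x)
}

#' Tidy a calibration result
#'
#' @param x A `calibration_result` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, observed_tier = x$observed_tier,
    n_resamples = x$n_resamples, set_size = x$set_size,
    frequency_reaching_tier = x$frequency_reaching_tier, seed = x$seed
  )
}

#' @rdname tidy.calibration_result
#' @export
glance.calibration_result <- function(x, ...) tidy(x)

#' Gene-level feature report with group comparisons
#'
#' For each feature column: the per-group median and, for every group
#' other than the reference, the Wilcoxon comparison against the
#' reference group with tier and star annotation.
#'
#' @param gene_features Tibble with `gene_id`, `group` and numeric feature
#'   columns.
#' @param reference Reference group (default `"autosomal"`).
#' @param features Feature columns to report (default: all numeric).
#' @return Long tibble: `feature`, `group`, `n`, `median`, `p_raw`,
#'   `tier`, `stars` (comparison columns `NA` for the reference group).
#' @export
table1_report <- function(gene_features, reference = "autosomal",
                          features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(gene_features)[vapply(gene_features, is.numeric,
                                                    logical(1))],
                        c("start", "end"))
  }
  groups <- unique(gene_features$group)
  ref <- dplyr::filter(gene_features, .data$group == reference)
  rows <- purrr::map(features, function(f) {
    purrr::map(groups, function(g) {
      vals <- gene_features[[f]][gene_features$group == g]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        return(tibble::tibble(feature = f, group = g, n = 0L,
                              median = NA_real_, p_raw = NA_real_,
                              tier = NA_character_, stars = NA_character_))
      }
      if (g == reference) {
        tibble::tibble(feature = f, group = g, n = length(vals),
                       median = stats::median(vals), p_raw = NA_real_,
                       tier = NA_character_, stars = NA_character_)
      } else {
        ref_vals <- ref[[f]][!is.na(ref[[f]])]
        cmp <- compare_continuous(vals, ref_vals, feature = f)
        tibble::tibble(feature = f, group = g, n = length(vals),
                       median = stats::median(vals), p_raw = cmp$p_raw,
                       tier = cmp$tier, stars = tier_stars(cmp$tier))
      }
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Per-class element report with group comparisons
#'
#' The per-class summary of [pcs_class_summary()] split by gene group,
#' with element-level Wilcoxon comparisons (score, length, G+C,
#' CpG_obs/CpG_exp, deamination index) and a chi-square/Fisher comparison
#' of the CpG-containing proportion for each non-reference group against
#' the reference within the same element class.
#'
#' @param elements Classified element tibble (with `group`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param reference Reference group (default `"autosomal"`).
#' @return Long tibble: `element_class`, `feature`, `group`, `n`, `value`,
#'   `p_raw`, `tier`, `stars`.
#' @export
table2_report <- function(elements, genome, reference = "autosomal") {
  el <- composition_per_interval(elements, genome)
  el$length <- el$end - el$start
  cont_features <- c("score", "length", "gc", "cpg_oe", "deamination_index")
  # fixed, locale-independent class order
  classes <- intersect(c("coding", "UTR", "intronic", "intergenic"),
                       unique(el$element_class))
  groups <- unique(el$group[!is.na(el$group)])
  rows <- list()
  for (cl in classes) {
    ecl <- dplyr::filter(el, .data$element_class == cl)
    ref <- dplyr::filter(ecl, .data$group == reference)
    for (g in groups) {
      eg <- dplyr::filter(ecl, .data$group == g)
      if (nrow(eg) == 0) next
      for (f in cont_features) {
        vals <- eg[[f]][!is.na(eg[[f]])]
        med <- if (length(vals)) stats::median(vals) else NA_real_
        if (g == reference || length(vals) == 0 ||
            length(ref[[f]][!is.na(ref[[f]])]) == 0) {
          cmp <- NULL
        } else {
          cmp <- compare_continuous(vals, ref[[f]][!is.na(ref[[f]])], feature = f)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          element_class = cl, feature = f, group = g, n = nrow(eg), value = med,
          p_raw = if (is.null(cmp)) NA_real_ else cmp$p_raw,
          tier = if (is.null(cmp)) NA_character_ else cmp$tier,
          stars = if (is.null(cmp)) NA_character_ else tier_stars(cmp$tier)
        )
      }
      # proportion of elements containing >= 1 CpG
      if (g == reference || nrow(ref) == 0) {
        cmp <- NULL
      } else {
        cmp <- compare_counts(sum(eg$has_cpg), nrow(eg),
                              sum(ref$has_cpg), nrow(ref),
                              feature = "pct_with_cpg")
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        element_class = cl, feature = "pct_with_cpg", group = g, n = nrow(eg),
        value = 100 * mean(eg$has_cpg),
        p_raw = if (is.null(cmp)) NA_real_ else cmp$p_raw,
        tier = if (is.null(cmp)) NA_character_ else cmp$tier,
        stars = if (is.null(cmp)) NA_character_ else tier_stars(cmp$tier)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a report tibble as TSV
#'
#' @param report A report tibble ([table1_report()], [table2_report()], ...).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
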