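test_that("tier mapping matches the threshold convention on a dense grid", {
  p <- c(seq(0, 1, by = 0.001), 0.0049999, 0.005, 0.0099999, 0.01,
         0.049999, 0.05)
  tiers <- significance_tier(p)
  want <- ifelse(p < 0.005, "highly",
          ifelse(p < 0.01, "moderate",
          ifelse(p < 0.05, "trend", "ns")))
  expect_identical(tiers, want)
  expect_equal(significance_tier(c(0.005, 0.01, 0.05)),
               c("moderate", "trend", "ns"))
  expect_error(significance_tier(1.2))
})

test_that("star annotation follows the tier", {
  expect_equal(tier_stars(c("highly", "moderate", "trend", "ns")),
               c("***", "**", "*", ""))
})

test_that("rank-sum comparison uses exact enumeration for small untied groups", {
  cmp <- compare_continuous(c(1, 2, 3), c(10, 11, 12))
  expect_equal(cmp$p_raw, 0.1)   # 2 / choose(6, 3), two-sided
  expect_equal(cmp$test, "wilcoxon_rank_sum")
  expect_equal(cmp$tier, "ns")
  expect_equal(cmp$direction, -1)
})

test_that("identical groups are clearly nonsignificant", {
  x <- rep(c(1, 2, 3, 4), 5)
  cmp <- compare_continuous(x, x)
  expect_gt(cmp$p_raw, 0.9)
  expect_equal(cmp$tier, "ns")
  expect_error(compare_continuous(numeric(0), x), "nonempty")
})

test_that("count comparison falls back to Fisher below expected cell 5", {
  cmp <- compare_counts(8, 10, 1, 10)
  expect_equal(cmp$test, "fisher_exact")
  # frozen from the hypergeometric enumeration of the 2x2 margins
  expect_equal(cmp$p_raw, 0.005477495, tolerance = 1e-6)
  expect_equal(cmp$tier, "moderate")

  big <- compare_counts(5, 100, 5, 100)
  expect_equal(big$test, "chi_square")
  expect_equal(big$p_raw, 1)
  expect_equal(big$tier, "ns")

  expect_error(compare_counts(1, 0, 1, 10), "positive")
  expect_error(compare_counts(11, 10, 1, 10), "exceed")
})

test_that("comparison objects tidy into one-row tibbles", {
  cmp <- compare_continuous(c(1, 2, 3), c(10, 11, 12), feature = "len")
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$feature, "len")
  expect_equal(td$p_raw, 0.1)
  gl <- glance(cmp)
  expect_equal(gl$tier, "ns")
  expect_output(print(cmp), "wilcoxon_rank_sum")
})

test_that("random-set calibration is deterministic and handles the trivial tier", {
  set.seed(1)
  pool <- rnorm(300)
  r1 <- calibrate_with_random_sets(pool, "trend", set_size = 20,
                                   n_resamples = 30, seed = 9)
  r2 <- calibrate_with_random_sets(pool, "trend", set_size = 20,
                                   n_resamples = 30, seed = 9)
  expect_identical(r1$tiers, r2$tiers)
  expect_true(r1$frequency_reaching_tier >= 0 &&
                r1$frequency_reaching_tier <= 1)
  # every random set trivially reaches "ns"
  r3 <- calibrate_with_random_sets(pool, "ns", set_size = 20,
                                   n_resamples = 20, seed = 2)
  expect_equal(r3$frequency_reaching_tier, 1)
  expect_error(calibrate_with_random_sets(rnorm(10), "ns", set_size = 58),
               "larger")
  expect_s3_class(tidy(r1), "tbl_df")
})

test_that("a strong labeled-set effect is rarely matched by random sets", {
  set.seed(4)
  pool <- rnorm(500)
  labeled <- rnorm(58, mean = 2)
  obs <- compare_continuous(labeled, pool)
  expect_equal(obs$tier, "highly")
  cal <- calibrate_with_random_sets(pool, obs, set_size = 58,
                                    n_resamples = 100, seed = 5)
  expect_lt(cal$frequency_reaching_tier, 0.05)
})

test_that("gene-level report compares every group against the reference", {
  set.seed(11)
  gf <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:120),
    group = rep(c("maternal", "autosomal"), c(20, 100)),
    len = c(rnorm(20, 10), rnorm(100, 5))
  )
  rep1 <- table1_report(gf, features = "len")
  expect_setequal(rep1$group, c("maternal", "autosomal"))
  mat <- rep1[rep1$group == "maternal", ]
  expect_equal(mat$median, median(gf$len[gf$group == "maternal"]))
  expect_equal(mat$tier, "highly")
  expect_true(is.na(rep1$p_raw[rep1$group == "autosomal"]))
  # empty group columns are absent rather than crashing
  rep2 <- table1_report(gf[gf$group == "autosomal", ], features = "len")
  expect_equal(nrow(rep2), 1)
})

test_that("reports are reproducible byte for byte", {
  set.seed(3)
  gf <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:60),
    group = rep(c("maternal", "autosomal"), c(10, 50)),
    len = rnorm(60)
  )
  f1 <- tempfile(); f2 <- tempfile()
  write_report(table1_report(gf, features = "len"), f1)
  write_report(table1_report(gf, features = "len"), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})
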