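test_that("allele counting honours ploidy and missingness", {
  d <- matrix(c(2L, 0L, NA,    # v1, three pseudo-haploid samples
                2L, 2L, 0L),   # v2
              nrow = 3)
  g <- make_geno(d, variant_ids = c("v1", "v2"))
  meta <- make_meta(paste0("s", 1:3), age_bp = c(7000, 7000, 3000),
                    period = c("Neolithic", "Neolithic", "PostNeolithic"),
                    is_ancient = TRUE)
  cnt <- allele_counts_by_period(g, meta, c("Neolithic", "PostNeolithic"))
  expect_equal(cnt$n_eff_1[cnt$variant_id == "v1"], 1)   # (2,0) -> 1 of 2
  expect_equal(cnt$n_called_1[cnt$variant_id == "v1"], 2)
  expect_equal(cnt$n_eff_2[cnt$variant_id == "v1"], 0)   # NA -> 0 of 0
  expect_equal(cnt$n_called_2[cnt$variant_id == "v1"], 0)

  # diploid samples contribute two alleles per call
  meta_dip <- make_meta(paste0("s", 1:3), age_bp = c(0, 0, 0),
                        period = "Modern", is_ancient = FALSE)
  meta_dip$period[3] <- "PostNeolithic"
  g2 <- make_geno(matrix(c(1L, 2L, 0L), nrow = 3), variant_ids = "v1")
  cnt2 <- allele_counts_by_period(g2, meta_dip,
                                  c("Modern", "PostNeolithic"))
  expect_equal(cnt2$n_eff_1, 3)     # dosages (1, 2) -> 3 of 4
  expect_equal(cnt2$n_called_1, 4)

  # an ancient dosage of 1 violates the pseudo-haploid contract
  g_bad <- make_geno(matrix(c(1L, 0L, 2L), nrow = 3), variant_ids = "v1")
  expect_error(allele_counts_by_period(g_bad, meta,
                                       c("Neolithic", "PostNeolithic")),
               "pseudo-haploid violation")
})

test_that("Hudson F_st matches its closed forms", {
  # reciprocal fixation
  expect_equal(hudson_fst(10, 10, 0, 10), 1.0)
  # p1 = p2 = 0.5 with n = 10 alleles each: the finite-sample correction
  # makes the estimate negative: (0 - 0.25/9 - 0.25/9) / 0.5 = -1/9
  expect_equal(hudson_fst(5, 10, 5, 10), -1 / 9, tolerance = 1e-10)
  # both fixed for the same allele: undefined
  expect_true(is.na(hudson_fst(10, 10, 10, 10)))
  expect_true(is.na(hudson_fst(0, 10, 0, 10)))
  expect_error(hudson_fst(1, 1, 5, 10), "at least 2 called alleles")
  # allele-label flip invariance
  e1 <- c(3, 7, 12); n1 <- c(10, 14, 20)
  e2 <- c(5, 2, 18); n2 <- c(12, 10, 22)
  expect_equal(hudson_fst(e1, n1, e2, n2),
               hudson_fst(n1 - e1, n1, n2 - e2, n2))
})

test_that("mean trait F_st averages defined values and reports skips", {
  m <- mean_trait_fst(c(0.1, 0.3))
  expect_equal(as.numeric(m), 0.2)
  expect_equal(attr(m, "n_skipped"), 0)
  m2 <- mean_trait_fst(c(0.4, NA, NA))
  expect_equal(as.numeric(m2), 0.4)
  expect_equal(attr(m2, "n_skipped"), 2)
  expect_error(mean_trait_fst(c(NA_real_, NA_real_)), "undefined")
})

test_that("empirical two-tailed p follows the add-one formula", {
  null <- seq_len(10000) / 10000
  expect_equal(empirical_two_tailed_p(2, null), 2 / 10001)
  expect_equal(empirical_two_tailed_p(stats::median(null), null), 1)
  expect_equal(empirical_two_tailed_p(5, 10), 1)   # B = 1, capped
  p <- empirical_two_tailed_p(0.9, null)
  expect_equal(p, 2 * (sum(null >= 0.9) + 1) / 10001)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 30), 0.03)
  expect_equal(bonferroni_adjust(0.2, 10), 1)
  expect_equal(bonferroni_adjust(0.37, 1), 0.37)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "family_size")
})

test_that("LD scores count in-window correlated background neighbours", {
  set.seed(6)
  x <- sample(c(0L, 2L), 80, replace = TRUE)
  y <- sample(c(0L, 2L), 80, replace = TRUE)
  # v1 and v2 duplicated (r2 = 1) 100 kb apart; v3 independent in window;
  # v4 duplicates v1 but 1 Mb away (outside the window)
  d <- cbind(x, x, y, x)
  g <- make_geno(d, pos = c(1e5, 2e5, 3e5, 1.2e6),
                 variant_ids = paste0("v", 1:4))
  ld <- snp_ld_scores(g, window_bp = 250000)
  expect_equal(unname(ld["v1"]), 1)
  expect_equal(unname(ld["v2"]), 1)
  expect_lt(cor(x, y)^2, 0.2)
  expect_equal(unname(ld["v3"]), 0)
  expect_equal(unname(ld["v4"]), 0)
  # restricting the background pool drops non-background neighbours
  ld2 <- snp_ld_scores(g, background_ids = c("v3", "v4"),
                       window_bp = 250000)
  expect_equal(unname(ld2["v1"]), 0)
})

test_that("matched null is deterministic, sized, and never samples trait SNPs", {
  set.seed(10)
  n_bg <- 400
  ids <- c(paste0("t", 1:20), paste0("b", seq_len(n_bg)))
  fst <- c(rep(100, 20), runif(n_bg, -0.05, 0.1))
  names(fst) <- ids
  maf <- setNames(runif(length(ids), 0.05, 0.5), ids)
  ld <- setNames(sample(0:6, length(ids), replace = TRUE), ids)
  trait <- paste0("t", 1:20)
  null1 <- suppressWarnings(
    build_matched_null(fst, maf, ld, trait, n_sets = 200, seed = 99))
  null2 <- suppressWarnings(
    build_matched_null(fst, maf, ld, trait, n_sets = 200, seed = 99))
  expect_identical(as.numeric(null1), as.numeric(null2))
  expect_length(null1, 200)
  # trait SNPs carry fst = 100; if any were sampled a null mean would
  # exceed 1 by orders of magnitude
  expect_true(all(null1 < 1))

  expect_error(build_matched_null(fst[1:40], maf[1:40], ld[1:40], trait,
                                  n_sets = 10),
               "at least 10x")
})

test_that("matched sampling respects MAF strata", {
  # all trait SNPs in one extreme MAF bin; matched nulls must come from the
  # background SNPs in that bin, which carry a distinctive F_st level
  ids <- c(paste0("t", 1:5), paste0("lo", 1:80), paste0("hi", 1:80))
  fst <- setNames(c(rep(0.5, 5), rep(0, 80), rep(1, 80)), ids)
  maf <- setNames(c(rep(0.07, 5), rep(0.32, 80), rep(0.07, 80)), ids)
  ld <- setNames(rep(0, length(ids)), ids)
  null <- build_matched_null(fst, maf, ld, paste0("t", 1:5),
                             n_sets = 50, seed = 1)
  expect_true(all(null == 1))   # only "hi" SNPs share the trait MAF bin
})

test_that("the full selection test detects a programmed shift and not its absence", {
  fx <- sim_qc_dataset(seed = 31, shift = 0.15, n_variants = 1200,
                       n_trait = 40,
                       periods = c(Neolithic = 80, PostNeolithic = 80))
  trait <- intersect(fx$trait_ids, fx$ds$stats$variant_id)
  ft <- suppressMessages(fst_selection_test(
    fx$ds$genotypes, fx$ds$meta, trait, c("Neolithic", "PostNeolithic"),
    n_sets = 500, seed = 1))
  expect_s3_class(ft, "fst_test_result")
  expect_lt(ft$empirical_p, 0.05)
  expect_gt(ft$observed_mean_fst, ft$null_mean)
  expect_equal(ft$n_null, 500)
  # fixed seed reproduces the null vector exactly
  ft2 <- suppressMessages(fst_selection_test(
    fx$ds$genotypes, fx$ds$meta, trait, c("Neolithic", "PostNeolithic"),
    n_sets = 500, seed = 1))
  expect_identical(ft$null_values, ft2$null_values)

  # the ratio-of-averages estimator agrees directionally
  fta <- suppressMessages(fst_selection_test(
    fx$ds$genotypes, fx$ds$meta, trait, c("Neolithic", "PostNeolithic"),
    n_sets = 300, seed = 2, estimator = "hudson_ratio_of_averages"))
  expect_lt(fta$empirical_p, 0.05)

  fx0 <- sim_qc_dataset(seed = 32, shift = 0, n_variants = 1200,
                        n_trait = 40,
                        periods = c(Neolithic = 80, PostNeolithic = 80))
  trait0 <- intersect(fx0$trait_ids, fx0$ds$stats$variant_id)
  ft0 <- suppressMessages(fst_selection_test(
    fx0$ds$genotypes, fx0$ds$meta, trait0, c("Neolithic", "PostNeolithic"),
    n_sets = 500, seed = 1))
  expect_gt(ft0$empirical_p, 0.05)
})
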