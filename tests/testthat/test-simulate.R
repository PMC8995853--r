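test_that("summary-stat simulation enforces programmed counts and layout", {
  cfg <- sim_config(n_variants = 1000, n_trait_variants = 50, seed = 7)
  st <- simulate_summary_stats(cfg)
  expect_equal(nrow(st), 1000)
  expect_equal(sum(st$p_value < 1e-6), 50)
  expect_setequal(st$variant_id[st$p_value < 1e-6],
                  attr(st, "trait_variant_ids"))
  expect_true(all(st$beta[st$p_value < 1e-6] != 0))
  expect_gte(length(unique(st$chrom)), 2)
  # positions strictly increasing within each chromosome
  for (ch in unique(st$chrom)) {
    expect_true(all(diff(st$pos[st$chrom == ch]) > 0))
  }
  cfg0 <- sim_config(n_variants = 200, n_trait_variants = 0, seed = 7)
  st0 <- simulate_summary_stats(cfg0)
  expect_equal(sum(st0$p_value < 1e-6), 0)
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  cfg7 <- sim_config(n_variants = 150, n_trait_variants = 10, seed = 7)
  cfg8 <- sim_config(n_variants = 150, n_trait_variants = 10, seed = 8)
  expect_identical(simulate_summary_stats(cfg7), simulate_summary_stats(cfg7))
  expect_false(identical(simulate_summary_stats(cfg7)$beta,
                         simulate_summary_stats(cfg8)$beta))
  st <- simulate_summary_stats(cfg7)
  expect_identical(simulate_cohort(cfg7, st), simulate_cohort(cfg7, st))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(n_trait_variants = 10, n_variants = 5),
               "configuration error: n_trait_variants")
  expect_error(sim_config(maf_range = c(0.1, 0.7)),
               "configuration error: maf_range")
  expect_error(sim_config(missing_rate_range = c(0.5, 1)),
               "configuration error: missing_rate_range")
  expect_error(sim_config(n_samples_per_period = c(Atlantis = 5)),
               "configuration error: n_samples_per_period")
})

test_that("ancient samples are pseudo-haploid, modern samples diploid age 0", {
  fx <- sim_qc_dataset(seed = 3, shift = 0)
  dos <- fx$cohort$genotypes$dosage
  meta <- fx$cohort$metadata
  anc <- meta$is_ancient[match(rownames(dos), meta$sample_id)]
  expect_false(any(dos[anc, ] == 1L, na.rm = TRUE))
  expect_true(all(meta$age_bp[meta$period == "Modern"] == 0))
  expect_true(all(meta$age_bp[meta$is_ancient] > 0))
  # modern samples carry no missingness
  expect_false(anyNA(dos[!anc, ]))
  # ancient missingness lands inside the configured band (pooled)
  miss <- rowMeans(is.na(dos[anc, ]))
  expect_gt(mean(miss), fx$config$missing_rate_range[1] - 0.05)
  expect_lt(mean(miss), fx$config$missing_rate_range[2] + 0.05)
})

test_that("programmed shift moves trait-allele frequencies as computed analytically", {
  # start all frequencies at 0.3; +0.1 per transition over 3 transitions
  # moves beta-positive trait alleles to ~0.6 (drift adds only ~0.006 sd)
  cfg <- sim_config(n_variants = 400, n_trait_variants = 30,
                    n_samples_per_period = c(Mesolithic = 150,
                                             Neolithic = 150,
                                             PostNeolithic = 150,
                                             Modern = 150),
                    maf_range = c(0.3, 0.3), selection_shift = 0.1,
                    missing_rate_range = c(0.1, 0.3), seed = 11)
  st <- simulate_summary_stats(cfg)
  coh <- simulate_cohort(cfg, st)
  truth <- coh$truth
  beta <- st$beta[match(truth$trait_variant_ids, st$variant_id)]
  final <- truth$frequencies[, "Modern"]
  expect_equal(mean(final[beta > 0]), 0.6, tolerance = 0.02)
  expect_equal(mean(final[beta < 0]), 0.0, tolerance = 0.02)
  # all three transitions here are Neolithic or later, so the programmed
  # trend lives entirely in the post segment
  expect_identical(truth$programmed_trend_sign, c(pre = 0L, post = 1L))

  cfg_pre <- sim_config(n_variants = 100, n_trait_variants = 10,
                        n_samples_per_period = c(EUP = 10, LUP = 10,
                                                 Mesolithic = 10),
                        selection_shift = -0.05, seed = 3)
  st_pre <- simulate_summary_stats(cfg_pre)
  truth_pre <- simulate_cohort(cfg_pre, st_pre)$truth
  expect_identical(truth_pre$programmed_trend_sign, c(pre = -1L, post = 0L))

  cfg0 <- sim_config(n_variants = 100, n_trait_variants = 10,
                     n_samples_per_period = c(Neolithic = 20, Modern = 20),
                     selection_shift = 0, seed = 2)
  st0 <- simulate_summary_stats(cfg0)
  truth0 <- simulate_cohort(cfg0, st0)$truth
  expect_identical(truth0$programmed_trend_sign, c(pre = 0L, post = 0L))
})

test_that("pooled per-period sample frequencies recover the truth", {
  fx <- sim_qc_dataset(seed = 5, shift = 0.1,
                       periods = c(Mesolithic = 150, Neolithic = 150,
                                   PostNeolithic = 150, Modern = 150),
                       missing_rate_range = c(0.1, 0.3))
  ds <- fx$ds
  truth <- fx$cohort$truth
  trait <- intersect(truth$trait_variant_ids, ds$stats$variant_id)
  dev_se <- c()
  for (per in colnames(truth$frequencies)) {
    cnt <- allele_counts_by_period(ds$genotypes, ds$meta,
                                   c(per, "Modern"))
    idx <- match(trait, cnt$variant_id)
    phat <- cnt$n_eff_1[idx] / cnt$n_called_1[idx]
    f <- truth$frequencies[match(trait, truth$trait_variant_ids), per]
    se <- sqrt(f * (1 - f) / cnt$n_called_1[idx])
    expect_true(all(cnt$n_called_1[idx] >= 100))
    dev_se <- c(dev_se, abs(phat - f) / se)
  }
  expect_gte(mean(dev_se <= 3), 0.97)
  expect_true(all(dev_se < 6))
})

test_that("zero-sample period alongside a selection shift is refused", {
  cfg <- sim_config(n_variants = 50, n_trait_variants = 5,
                    n_samples_per_period = c(Mesolithic = 10, Neolithic = 0,
                                             Modern = 10),
                    selection_shift = 0.1, seed = 1)
  st <- simulate_summary_stats(cfg)
  expect_error(simulate_cohort(cfg, st), "zero samples")
})

test_that("fixture bundles round-trip exactly and checksums track content", {
  fx <- sim_qc_dataset(seed = 9, shift = 0.05, n_variants = 120, n_trait = 8,
                       periods = c(Neolithic = 15, Modern = 10))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- write_fixture_bundle(dir1, fx$stats, fx$cohort$genotypes,
                               fx$cohort$metadata, fx$cohort$truth)
  man2 <- write_fixture_bundle(dir2, fx$stats, fx$cohort$genotypes,
                               fx$cohort$metadata, fx$cohort$truth)
  # identical inputs give byte-identical bundles
  expect_identical(man1$files, man2$files)

  g <- read_eigenstrat(file.path(dir1, "cohort.geno"),
                       file.path(dir1, "cohort.snp"),
                       file.path(dir1, "cohort.ind"))
  expect_identical(g$dosage, fx$cohort$genotypes$dosage)
  expect_identical(g$snp$ref, fx$cohort$genotypes$snp$ref)
  st2 <- read_summary_stats(file.path(dir1, "sumstats.tsv"))
  expect_equal(st2$beta, fx$stats$beta)
  expect_equal(st2$p_value, fx$stats$p_value)
  meta2 <- read_metadata(file.path(dir1, "metadata.tsv"))
  expect_equal(meta2$age_bp, fx$cohort$metadata$age_bp)
  expect_identical(meta2$period, fx$cohort$metadata$period)

  # checksum changes iff content changes
  fx2 <- sim_qc_dataset(seed = 10, shift = 0.05, n_variants = 120,
                        n_trait = 8, periods = c(Neolithic = 15, Modern = 10))
  dir3 <- withr::local_tempdir()
  man3 <- write_fixture_bundle(dir3, fx2$stats, fx2$cohort$genotypes,
                               fx2$cohort$metadata, fx2$cohort$truth)
  expect_false(identical(man1$files[["cohort.geno"]],
                         man3$files[["cohort.geno"]]))

  expect_error(write_fixture_bundle(dir1, fx$stats, fx$cohort$genotypes,
                                    fx$cohort$metadata),
               "overwrite")
  empty_stats <- fx$stats[0, , drop = FALSE]
  expect_error(write_fixture_bundle(withr::local_tempdir(), empty_stats,
                                    fx$cohort$genotypes,
                                    fx$cohort$metadata),
               "empty dataset|0 variants")
})
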