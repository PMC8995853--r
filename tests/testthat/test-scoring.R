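test_that("distance clumping reproduces the worked three-variant example", {
  st <- make_stats(c("a", "b", "c"), chrom = "1",
                   pos = c(100000, 200000, 400000),
                   beta = c(0.1, 0.1, 0.1),
                   p_value = c(1e-9, 1e-7, 1e-8))
  cl <- clump_by_distance(st, p_threshold = 1e-6, window_bp = 250000)
  # greedy: a (1e-9) leads; b is 100 kb away -> excluded by a; c is 300 kb
  # from a -> second lead
  expect_identical(cl$lead_variant_ids, c("a", "c"))
  expect_identical(cl$excluded, c(b = "a"))
})

test_that("clumping breaks p-value ties deterministically and respects bounds", {
  st <- make_stats(c("v1", "v2"), chrom = "1", pos = c(5000, 1000),
                   beta = c(0.1, 0.1), p_value = c(1e-8, 1e-8))
  cl <- clump_by_distance(st, window_bp = 250000)
  # equal p: lower position wins
  expect_identical(cl$lead_variant_ids, "v2")
  expect_identical(names(cl$excluded), "v1")

  # window bound is inclusive; cross-chromosome pairs never exclude
  st2 <- make_stats(c("w1", "w2", "w3"), chrom = c("1", "1", "2"),
                    pos = c(0, 250000, 100), beta = 0.1,
                    p_value = c(1e-9, 1e-8, 1e-8))
  cl2 <- clump_by_distance(st2, window_bp = 250000)
  expect_identical(sort(cl2$lead_variant_ids), c("w1", "w3"))

  expect_warning(cl3 <- clump_by_distance(st, p_threshold = 1e-12),
                 "no variant passes")
  expect_length(cl3$lead_variant_ids, 0)
})

test_that("distance clumping matches the brute-force greedy oracle", {
  set.seed(42)
  for (i in 1:60) {
    st <- random_clump_instance(n = sample(10:60, 1))
    got <- suppressWarnings(clump_by_distance(st, p_threshold = 1e-6,
                                              window_bp = 250000))
    want <- brute_force_clump(st, 1e-6, 250000)
    expect_identical(got$lead_variant_ids, want)
  }
})

test_that("LD clumping excludes only correlated in-window candidates", {
  set.seed(1)
  n <- 60
  x <- sample(c(0L, 2L), n, replace = TRUE)
  y_indep <- sample(c(0L, 2L), n, replace = TRUE)
  d <- cbind(x, x, y_indep, x)
  g <- make_geno(d, pos = c(1e5, 2e5, 3e5, 9e5),
                 variant_ids = c("lead", "dup", "indep", "far"))
  st <- make_stats(c("lead", "dup", "indep", "far"), "1",
                   c(1e5, 2e5, 3e5, 9e5), beta = 0.1,
                   p_value = c(1e-10, 1e-8, 1e-8, 1e-8))
  cl <- clump_by_ld(st, g, r2_threshold = 0.2, min_joint_calls = 20)
  r2_indep <- cor(x, y_indep)^2
  expect_lt(r2_indep, 0.2)   # construction check for the retained case
  expect_setequal(cl$lead_variant_ids, c("lead", "indep", "far"))
  expect_identical(cl$excluded[["dup"]], "lead")

  # too few joint calls is treated as excluded (conservative)
  d2 <- d
  d2[11:60, 2] <- NA
  g2 <- make_geno(d2, pos = c(1e5, 2e5, 3e5, 9e5),
                  variant_ids = c("lead", "dup", "indep", "far"))
  cl2 <- clump_by_ld(st, g2, r2_threshold = 0.2, min_joint_calls = 20)
  expect_true("dup" %in% names(cl2$excluded))
})

test_that("PRS arithmetic, imputation and degenerate cases follow the rules", {
  st <- make_stats(c("v1", "v2"), "1", c(1e6, 2e6),
                   beta = c(0.5, -0.2), p_value = c(1e-8, 1e-8))
  d <- matrix(c(2L, NA, NA,
                0L, 0L, NA), nrow = 3)
  g <- make_geno(d, variant_ids = c("v1", "v2"))
  sc <- compute_prs(g, st, c("v1", "v2"))
  # sample 1: 2*0.5 + 0*(-0.2) = 1.0
  expect_equal(sc$raw_score[1], 1.0)
  # sample 2: v1 imputed with mean(2) = 2 -> 2*0.5 + 0*(-0.2) = 1.0
  expect_equal(sc$raw_score[2], 1.0)
  # fully-missing sample gets the dataset-average score sum(mean_d * beta)
  md <- attr(sc, "mean_dosage")
  expect_equal(sc$raw_score[3], sum(md * c(0.5, -0.2)))

  # documented worked value: missing dosage with population mean 1.2
  # contributes 1.2 * 0.5 = 0.6
  d2 <- matrix(c(2L, 1L, 1L, NA), ncol = 1)
  g2 <- make_geno(d2, variant_ids = "v1")
  sc2 <- compute_prs(g2, st, "v1")
  expect_equal(attr(sc2, "mean_dosage")[["v1"]], 4 / 3)
  expect_equal(sc2$raw_score[4], (4 / 3) * 0.5)

  # lead observed in no sample is dropped with a warning
  d3 <- matrix(c(2L, 0L, NA, NA), nrow = 2)
  g3 <- make_geno(d3, variant_ids = c("v1", "v2"))
  expect_warning(sc3 <- compute_prs(g3, st, c("v1", "v2")),
                 "no observed dosage")
  expect_equal(attr(sc3, "n_variants_used"), 1)
})

test_that("PRS matches the brute-force oracle on random instances", {
  set.seed(7)
  for (k in 1:10) {
    inst <- random_prs_instance(n_samples = 30, n_variants = 60)
    ids <- paste0("v", seq_len(ncol(inst$dosage)))
    st <- make_stats(ids, "1", seq_along(ids) * 1000, inst$beta,
                     rep(1e-8, length(ids)))
    g <- make_geno(inst$dosage, variant_ids = ids)
    got <- compute_prs(g, st, ids)$raw_score
    want <- brute_force_prs(inst$dosage, inst$beta)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("appending a fully-missing sample perturbs no other score", {
  set.seed(8)
  inst <- random_prs_instance(n_samples = 25, n_variants = 40)
  ids <- paste0("v", seq_len(ncol(inst$dosage)))
  st <- make_stats(ids, "1", seq_along(ids) * 1000, inst$beta,
                   rep(1e-8, length(ids)))
  g1 <- make_geno(inst$dosage, variant_ids = ids)
  d2 <- rbind(inst$dosage, NA)
  g2 <- make_geno(d2, variant_ids = ids,
                  sample_ids = c(rownames(g1$dosage), "ghost"))
  s1 <- compute_prs(g1, st, ids)$raw_score
  s2 <- compute_prs(g2, st, ids)$raw_score
  expect_equal(s2[seq_along(s1)], s1)
})

test_that("scores collapse toward the dataset mean as missingness grows", {
  set.seed(9)
  inst <- random_prs_instance(n_samples = 80, n_variants = 50, miss = 0)
  ids <- paste0("v", seq_len(ncol(inst$dosage)))
  st <- make_stats(ids, "1", seq_along(ids) * 1000, inst$beta,
                   rep(1e-8, length(ids)))
  spread <- sapply(c(0, 0.6, 0.95), function(m) {
    d <- inst$dosage
    mask <- matrix(runif(length(d)) < m, nrow(d), ncol(d))
    d[mask] <- NA
    d[1, colSums(!is.na(d)) == 0] <- 1L   # keep every variant observed
    sd(compute_prs(make_geno(d, variant_ids = ids), st, ids)$raw_score)
  })
  expect_true(all(diff(spread) < 0))
})

test_that("min-max scaling spans [-1, 1], preserves ranks, zeroes constants", {
  st <- make_stats("v1", "1", 1000, 1, 1e-8)
  g <- make_geno(matrix(c(0L, 1L, 2L), ncol = 1), variant_ids = "v1")
  sc <- scale_scores(compute_prs(g, st, "v1"))
  expect_equal(sc$scaled_score, c(-1, 0, 1))
  expect_equal(range(sc$scaled_score), c(-1, 1))
  expect_identical(order(sc$scaled_score), order(sc$raw_score))

  gc <- make_geno(matrix(c(1L, 1L, 1L), ncol = 1), variant_ids = "v1")
  scc <- scale_scores(compute_prs(gc, st, "v1"))
  expect_equal(scc$scaled_score, c(0, 0, 0))
})
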