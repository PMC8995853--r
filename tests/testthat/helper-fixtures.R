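# Builders for small hand-specified fixtures, and independent brute-force
# oracles the implementation is checked against.

make_stats <- function(variant_id, chrom, pos, beta, p_value,
                       effect_allele = "A", other_allele = "G",
                       trait_name = "toy") {
  n <- length(variant_id)
  structure(
    data.frame(variant_id = variant_id, chrom = as.character(chrom),
               pos = as.integer(pos),
               effect_allele = rep_len(effect_allele, n),
               other_allele = rep_len(other_allele, n),
               beta = beta, p_value = p_value, stringsAsFactors = FALSE),
    class = c("sumstats", "data.frame"), trait_name = trait_name)
}

make_geno <- function(dosage, chrom = "1", pos = NULL,
                      ref = "A", alt = "G",
                      sample_ids = NULL, variant_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  nv <- ncol(dosage)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(nv))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosage)))
  if (is.null(pos)) pos <- seq_len(nv) * 1000000L
  rownames(dosage) <- sample_ids
  snp <- data.frame(variant_id = variant_ids,
                    chrom = rep_len(as.character(chrom), nv),
                    pos = as.integer(pos),
                    ref = rep_len(ref, nv), alt = rep_len(alt, nv),
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, snp)
}

make_meta <- function(sample_ids, age_bp, latitude = 50, longitude = 10,
                      period = NULL, is_ancient = NULL) {
  n <- length(sample_ids)
  if (is.null(period)) {
    period <- ifelse(!is.na(age_bp) & age_bp == 0, "Modern", "Neolithic")
  }
  if (is.null(is_ancient)) is_ancient <- period != "Modern"
  data.frame(sample_id = sample_ids, age_bp = age_bp,
             latitude = rep_len(latitude, n),
             longitude = rep_len(longitude, n),
             period = rep_len(period, n),
             is_ancient = rep_len(is_ancient, n),
             stringsAsFactors = FALSE)
}

# Independent PRS oracle: explicit per-sample, per-variant loop with mean
# imputation over all samples.
brute_force_prs <- function(dosage, beta) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  means <- numeric(m)
  for (j in seq_len(m)) {
    v <- dosage[, j]
    means[j] <- mean(v[!is.na(v)])
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- dosage[i, j]
      if (is.na(d)) d <- means[j]
      s[i] <- s[i] + d * beta[j]
    }
  }
  s
}

# Independent greedy clumping oracle: straightforward quadratic scan in
# ascending (p, chrom, pos) order.
brute_force_clump <- function(stats, p_threshold, window_bp) {
  cand <- stats[stats$p_value <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$p_value, cand$chrom, cand$pos), , drop = FALSE]
  lead_chrom <- character(0)
  lead_pos <- numeric(0)
  lead_id <- character(0)
  for (i in seq_len(nrow(cand))) {
    excluded <- FALSE
    for (k in seq_along(lead_id)) {
      if (lead_chrom[k] == cand$chrom[i] &&
          abs(lead_pos[k] - cand$pos[i]) <= window_bp) {
        excluded <- TRUE
        break
      }
    }
    if (!excluded) {
      lead_id <- c(lead_id, cand$variant_id[i])
      lead_chrom <- c(lead_chrom, cand$chrom[i])
      lead_pos <- c(lead_pos, cand$pos[i])
    }
  }
  lead_id
}

# Random clumping instance with deliberate p-value ties and multiple
# chromosomes, some positions clustered inside the window.
random_clump_instance <- function(n = 40) {
  chrom <- sample(c("1", "2", "3"), n, replace = TRUE)
  pos <- sample.int(2e6, n, replace = TRUE)
  p <- sample(c(1e-9, 1e-8, 1e-7, 5e-7, 1e-6, 1e-4, 0.5),
              n, replace = TRUE)
  make_stats(paste0("v", seq_len(n)), chrom, pos,
             beta = stats::rnorm(n), p_value = p)
}

# Random scoring instance: dosage matrix with missingness plus betas.
random_prs_instance <- function(n_samples = 50, n_variants = 200,
                                miss = 0.3) {
  d <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE),
              n_samples, n_variants)
  d[matrix(stats::runif(length(d)) < miss, n_samples, n_variants)] <- NA
  # guarantee every variant is observed at least once
  for (j in which(colSums(!is.na(d)) == 0)) d[1, j] <- 1L
  beta <- stats::rnorm(n_variants)
  list(dosage = d, beta = beta)
}

# Small simulated cohort run through QC, returning pieces most tests need.
sim_qc_dataset <- function(seed = 1, shift = 0.1,
                           n_variants = 300, n_trait = 20,
                           periods = c(Mesolithic = 30, Neolithic = 50,
                                       PostNeolithic = 50, Modern = 50),
                           ...) {
  cfg <- sim_config(n_variants = n_variants, n_trait_variants = n_trait,
                    n_samples_per_period = periods,
                    selection_shift = shift, seed = seed, ...)
  st <- simulate_summary_stats(cfg)
  coh <- simulate_cohort(cfg, st)
  ds <- qc_dataset(st, coh$genotypes, coh$metadata)
  list(config = cfg, stats = st, cohort = coh, ds = ds,
       trait_ids = attr(st, "trait_variant_ids"))
}
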