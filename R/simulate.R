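#' Simulation configuration for synthetic temporally stratified cohorts
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' generator emulates the study design the pipeline targets: pseudo-haploid
#' ancient genomes with high missingness sampled from broad archaeological
#' periods, modern diploid genomes at age 0, and GWAS summary statistics with
#' a known set of trait-associated variants whose effect-allele frequencies
#' can be shifted between periods (directional selection) on top of binomial
#' drift shared by all variants.
#'
#' @param n_variants Total number of variants.
#' @param n_trait_variants Number of trait-associated variants (p < 1e-6,
#'   nonzero beta); must not exceed `n_variants`.
#' @param n_samples_per_period Named integer vector, names from
#'   [period_levels()]; periods may be omitted or zero (zero only without a
#'   selection shift across them).
#' @param maf_range Length-2 numeric in (0, 0.5]: range of starting
#'   effect-allele frequencies.
#' @param missing_rate_range Length-2 numeric in \[0, 1): per-ancient-sample
#'   missing-call rate range (modern samples have no missingness).
#' @param selection_shift Signed frequency change applied to trait-variant
#'   effect-allele frequencies, aligned with the beta sign, at each period
#'   transition. Scalar (recycled) or one value per transition between
#'   consecutive periods present in `n_samples_per_period`.
#' @param ld_block_size Number of consecutive variants per correlated LD
#'   block (1 = independent variants).
#' @param n_chromosomes Number of chromosomes variants are laid out on
#'   (at least 2).
#' @param ambiguous_frac Fraction of non-trait variants given strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise the harmonization filters.
#' @param multiallelic_frac Fraction of non-trait variants given a
#'   non-bi-allelic record (comma-separated other allele).
#' @param effective_size Effective population size for the binomial drift
#'   between periods.
#' @param block_missingness If TRUE, missingness is applied to whole LD
#'   blocks per sample instead of independent variants.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 2000,
                       n_trait_variants = 50,
                       n_samples_per_period = c(EUP = 15, LUP = 30,
                                                Mesolithic = 80,
                                                Neolithic = 200,
                                                PostNeolithic = 500,
                                                Modern = 250),
                       maf_range = c(0.05, 0.5),
                       missing_rate_range = c(0.2, 0.6),
                       selection_shift = 0.1,
                       ld_block_size = 5,
                       n_chromosomes = 2,
                       ambiguous_frac = 0.05,
                       multiallelic_frac = 0.02,
                       effective_size = 10000,
                       block_missingness = FALSE,
                       seed = 1) {
  if (!is_count(n_variants) || n_variants < 1)
    stop_config("n_variants", "must be a positive count")
  if (!is_count(n_trait_variants))
    stop_config("n_trait_variants", "must be a non-negative count")
  if (n_trait_variants > n_variants)
    stop_config("n_trait_variants", "must not exceed n_variants")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range", "must be an increasing pair within (0, 0.5]")
  if (length(missing_rate_range) != 2 || any(missing_rate_range < 0) ||
      any(missing_rate_range >= 1) ||
      missing_rate_range[1] > missing_rate_range[2])
    stop_config("missing_rate_range", "must be an increasing pair in [0, 1)")
  if (is.null(names(n_samples_per_period)) ||
      !all(names(n_samples_per_period) %in% period_levels()))
    stop_config("n_samples_per_period",
                paste("must be named with periods among:",
                      paste(period_levels(), collapse = ", ")))
  if (!all(vapply(n_samples_per_period, is_count, logical(1))))
    stop_config("n_samples_per_period", "counts must be non-negative integers")
  # canonical order, oldest first
  n_samples_per_period <-
    n_samples_per_period[order(match(names(n_samples_per_period),
                                     period_levels()))]
  n_periods <- length(n_samples_per_period)
  if (n_periods < 1) stop_config("n_samples_per_period", "must be non-empty")
  if (!is.numeric(selection_shift) ||
      !(length(selection_shift) %in% c(1L, max(n_periods - 1L, 1L))))
    stop_config("selection_shift",
                "must be a scalar or one value per period transition")
  if (any(abs(selection_shift) >= 1))
    stop_config("selection_shift", "must have magnitude below 1")
  if (!is_count(ld_block_size) || ld_block_size < 1)
    stop_config("ld_block_size", "must be a positive count")
  if (!is_count(n_chromosomes) || n_chromosomes < 2)
    stop_config("n_chromosomes", "must be a count of at least 2")
  if (ambiguous_frac < 0 || ambiguous_frac >= 1)
    stop_config("ambiguous_frac", "must be in [0, 1)")
  if (multiallelic_frac < 0 || multiallelic_frac >= 1)
    stop_config("multiallelic_frac", "must be in [0, 1)")
  if (!is_count(effective_size) || effective_size < 2)
    stop_config("effective_size", "must be a count of at least 2")
  if (length(seed) != 1 || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed))
    stop_config("seed", "must be a single integer")
  structure(list(
    n_variants = as.integer(n_variants),
    n_trait_variants = as.integer(n_trait_variants),
    n_samples_per_period = n_samples_per_period,
    maf_range = maf_range,
    missing_rate_range = missing_rate_range,
    selection_shift = selection_shift,
    ld_block_size = as.integer(ld_block_size),
    n_chromosomes = as.integer(n_chromosomes),
    ambiguous_frac = ambiguous_frac,
    multiallelic_frac = multiallelic_frac,
    effective_size = as.integer(effective_size),
    block_missingness = isTRUE(block_missingness),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate GWAS summary statistics with a known trait-variant set
#'
#' Generates `n_variants` variant records laid out on `n_chromosomes`
#' chromosomes with inter-variant spacing uniform on 20-80 kb. Exactly
#' `n_trait_variants` records receive a p-value below 1e-6 and a nonzero
#' beta; all remaining records get p uniform on (1e-4, 1). A controllable
#' fraction of non-trait records carries strand-ambiguous (A/T, C/G) allele
#' pairs or non-bi-allelic annotations so that the downstream filters have
#' something to remove.
#'
#' @param config A [sim_config()].
#' @return A `sumstats` data frame (see [read_summary_stats()]) with
#'   attributes `trait_name` and `trait_variant_ids`.
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  with_seed(config$seed, {
    variant_id <- sprintf("rs%06d", seq_len(n))
    chrom <- as.character(sort(rep_len(seq_len(config$n_chromosomes), n)))
    pos <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- cumsum(as.integer(round(stats::runif(length(idx),
                                                       20000, 80000))))
    }
    trait_idx <- if (config$n_trait_variants > 0)
      sort(sample.int(n, config$n_trait_variants)) else integer(0)
    non_trait <- setdiff(seq_len(n), trait_idx)

    bases <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    effect <- sample(bases, n, replace = TRUE)
    # non-ambiguous partner: any base that is neither the effect allele nor
    # its strand complement
    other <- vapply(effect, function(b) {
      sample(setdiff(bases, c(b, comp[[b]])), 1)
    }, character(1))

    n_amb <- floor(config$ambiguous_frac * length(non_trait))
    n_multi <- floor(config$multiallelic_frac * length(non_trait))
    special <- sample(non_trait, n_amb + n_multi)
    amb_idx <- special[seq_len(n_amb)]
    multi_idx <- setdiff(special, amb_idx)
    other[amb_idx] <- comp[effect[amb_idx]]
    if (length(multi_idx)) {
      third <- vapply(seq_along(multi_idx), function(k) {
        i <- multi_idx[k]
        sample(setdiff(bases, c(effect[i], other[i])), 1)
      }, character(1))
      other[multi_idx] <- paste(other[multi_idx], third, sep = ",")
    }

    beta <- stats::rnorm(n, 0, 0.01)
    p_value <- stats::runif(n, 1e-4, 1)
    if (length(trait_idx)) {
      beta[trait_idx] <- sample(c(-1, 1), length(trait_idx),
                                replace = TRUE) *
        stats::runif(length(trait_idx), 0.05, 0.2)
      p_value[trait_idx] <- 10^(-stats::runif(length(trait_idx), 6.5, 25))
    }
    out <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                      effect_allele = effect, other_allele = unname(other),
                      beta = beta, p_value = p_value,
                      stringsAsFactors = FALSE)
    structure(out, class = c("sumstats", "data.frame"),
              trait_name = "synthetic_trait",
              trait_variant_ids = variant_id[trait_idx])
  })
}

# Age ranges (years before 1950) the simulator draws from per period.
sim_age_ranges <- function() {
  list(EUP = c(25000, 45000), LUP = c(11000, 25000),
       Mesolithic = c(5500, 11000), Neolithic = c(3900, 8500),
       PostNeolithic = c(250, 5000), Modern = c(0, 0))
}

#' Simulate a temporally stratified cohort with known ground truth
#'
#' Evolves every variant's effect-allele frequency across the configured
#' periods by binomial drift (effective size `config$effective_size`), adds
#' the deterministic `selection_shift` (sign-aligned with each trait
#' variant's beta) at every period transition for trait variants, and samples
#' genotypes: ancient samples are pseudo-haploid (one allele observed per
#' call, dosage 0 or 2, per-sample missingness drawn from
#' `missing_rate_range`), modern samples are diploid with no missingness.
#' Consecutive variants within an LD block share a latent haplotype draw,
#' which induces positive dosage correlation. Each variant's counted allele
#' is randomly oriented (effect or other allele) so harmonization is always
#' exercised.
#'
#' @param config A [sim_config()].
#' @param stats Summary statistics from [simulate_summary_stats()] under the
#'   same config.
#' @return A list with elements `genotypes` (a [genotype_matrix()]),
#'   `metadata` (see [read_metadata()]) and `truth` (class
#'   `synthetic_truth`: trait variant ids, per-period effect-allele
#'   frequencies, programmed trend sign per breakpoint segment).
#' @export
simulate_cohort <- function(config, stats) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(stats) != config$n_variants ||
      !identical(stats$variant_id, sprintf("rs%06d",
                                           seq_len(config$n_variants)))) {
    stop("stats were not produced for this config's variant set",
         call. = FALSE)
  }
  nsp <- config$n_samples_per_period
  periods <- names(nsp)
  n_periods <- length(periods)
  shifts <- rep_len(config$selection_shift, max(n_periods - 1L, 0L))
  if (any(nsp == 0) && any(shifts != 0)) {
    stop("period(s) with zero samples requested alongside a selection shift ",
         "across them: ", paste(periods[nsp == 0], collapse = ", "),
         call. = FALSE)
  }
  n <- config$n_variants
  trait_ids <- attr(stats, "trait_variant_ids")
  trait_idx <- match(trait_ids, stats$variant_id)
  beta_sign <- sign(stats$beta[trait_idx])

  with_seed(config$seed + 1L, {
    # allele-frequency paths: drift for everyone, shift for trait variants
    f <- matrix(NA_real_, n, n_periods,
                dimnames = list(stats$variant_id, periods))
    f[, 1] <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    two_ne <- 2L * config$effective_size
    if (n_periods > 1) {
      for (t in seq_len(n_periods - 1L)) {
        drifted <- stats::rbinom(n, two_ne, f[, t]) / two_ne
        drifted[trait_idx] <- drifted[trait_idx] + shifts[t] * beta_sign
        f[, t + 1L] <- pmin(pmax(drifted, 0.001), 0.999)
      }
    }

    # LD blocks: consecutive variants on the same chromosome share a latent
    # haplotype uniform
    block_of <- integer(n)
    b0 <- 0L
    for (ch in unique(stats$chrom)) {
      idx <- which(stats$chrom == ch)
      block_of[idx] <- b0 + ceiling(seq_along(idx) / config$ld_block_size)
      b0 <- max(block_of[idx])
    }
    n_blocks <- b0

    dosage_list <- vector("list", n_periods)
    meta_list <- vector("list", n_periods)
    ranges <- sim_age_ranges()
    for (k in seq_len(n_periods)) {
      m <- nsp[[k]]
      if (m == 0) next
      per <- periods[k]
      ancient <- per != "Modern"
      fm <- matrix(f[, k], m, n, byrow = TRUE)
      if (ancient) {
        U <- matrix(stats::runif(m * n_blocks), m, n_blocks)
        dos <- 2L * (U[, block_of, drop = FALSE] < fm)
      } else {
        U1 <- matrix(stats::runif(m * n_blocks), m, n_blocks)
        U2 <- matrix(stats::runif(m * n_blocks), m, n_blocks)
        dos <- (U1[, block_of, drop = FALSE] < fm) +
          (U2[, block_of, drop = FALSE] < fm)
      }
      storage.mode(dos) <- "integer"
      if (ancient) {
        rate <- stats::runif(m, config$missing_rate_range[1],
                             config$missing_rate_range[2])
        if (config$block_missingness) {
          mb <- matrix(stats::runif(m * n_blocks), m, n_blocks) < rate
          mask <- mb[, block_of, drop = FALSE]
        } else {
          mask <- matrix(stats::runif(m * n), m, n) < rate
        }
        dos[mask] <- NA_integer_
      }
      ids <- sprintf("%s_%04d", per, seq_len(m))
      rownames(dos) <- ids
      dosage_list[[k]] <- dos
      rng <- ranges[[per]]
      meta_list[[k]] <- data.frame(
        sample_id = ids,
        age_bp = if (ancient)
          round(stats::runif(m, rng[1], rng[2])) else 0,
        latitude = if (ancient) stats::runif(m, 36, 69) else NA_real_,
        longitude = if (ancient) stats::runif(m, -9, 39) else NA_real_,
        period = per,
        is_ancient = ancient,
        stringsAsFactors = FALSE
      )
    }
    dosage <- do.call(rbind, dosage_list[!vapply(dosage_list, is.null,
                                                 logical(1))])
    metadata <- do.call(rbind, meta_list[!vapply(meta_list, is.null,
                                                 logical(1))])
    rownames(metadata) <- NULL

    # random counted-allele orientation: for flipped variants the genotype
    # counts the GWAS other allele, so dosage = 2 - effect dosage
    first_other <- sub(",.*$", "", stats$other_allele)
    flip <- stats::runif(n) < 0.5
    dosage[, flip] <- 2L - dosage[, flip]
    snp <- data.frame(
      variant_id = stats$variant_id,
      chrom = stats$chrom,
      pos = stats$pos,
      ref = ifelse(flip, first_other, stats$effect_allele),
      alt = ifelse(flip, stats$effect_allele, first_other),
      stringsAsFactors = FALSE
    )
    genotypes <- genotype_matrix(dosage, snp)

    truth <- structure(list(
      trait_variant_ids = trait_ids,
      frequencies = f[trait_idx, , drop = FALSE],
      programmed_trend_sign = trend_signs(periods, shifts)
    ), class = "synthetic_truth")

    list(genotypes = genotypes, metadata = metadata, truth = truth)
  })
}

# Programmed trend sign per breakpoint segment. A transition belongs to the
# post segment when its destination period is Neolithic or later (the
# Mesolithic->Neolithic transition is the breakpoint itself and counts as
# post). +1 means the trait-increasing allele gains frequency toward the
# present within that segment.
trend_signs <- function(periods, shifts) {
  post_set <- c("Neolithic", "PostNeolithic", "Modern")
  seg <- ifelse(periods[-1] %in% post_set, "post", "pre")
  c(pre = as.integer(sign(sum(shifts[seg == "pre"]))),
    post = as.integer(sign(sum(shifts[seg == "post"]))))
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes the EIGENSTRAT triplet (`cohort.geno`/`.snp`/`.ind`), the summary
#' statistics (`sumstats.tsv`), the sample metadata (`metadata.tsv`), the
#' ground-truth per-period frequencies (`truth_frequencies.tsv`) and a YAML
#' manifest (`manifest.yaml`) with an MD5 checksum per file.
#'
#' @param dir_path Output directory (created if needed).
#' @param stats Summary statistics table.
#' @param genotypes A `genotype_matrix`.
#' @param metadata Sample metadata data frame.
#' @param truth Optional `synthetic_truth`.
#' @param overwrite Refuse to clobber existing files unless TRUE.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(dir_path, stats, genotypes, metadata,
                                 truth = NULL, overwrite = FALSE) {
  if (ncol(genotypes$dosage) == 0L || nrow(stats) == 0L) {
    stop("refusing to write an empty dataset (0 variants)", call. = FALSE)
  }
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", dir_path,
                  call. = FALSE)
  }
  files <- c("cohort.geno", "cohort.snp", "cohort.ind", "sumstats.tsv",
             "metadata.tsv", "manifest.yaml",
             if (!is.null(truth)) "truth_frequencies.tsv")
  paths <- file.path(dir_path, files)
  if (any(file.exists(paths)) && !overwrite) {
    stop("refusing to overwrite existing bundle in ", dir_path,
         " (set overwrite = TRUE)", call. = FALSE)
  }

  dos <- genotypes$dosage
  gm <- t(dos)               # one row per SNP
  gm[is.na(gm)] <- 9L
  geno_lines <- apply(gm, 1, paste, collapse = "")
  writeLines(geno_lines, file.path(dir_path, "cohort.geno"))

  snp <- genotypes$snp
  snp_lines <- sprintf("%s %s %.1f %d %s %s", snp$variant_id, snp$chrom, 0,
                       as.integer(snp$pos), snp$ref, snp$alt)
  writeLines(snp_lines, file.path(dir_path, "cohort.snp"))

  meta_by_id <- metadata[match(rownames(dos), metadata$sample_id), ]
  ind_lines <- sprintf("%s U %s", rownames(dos), meta_by_id$period)
  writeLines(ind_lines, file.path(dir_path, "cohort.ind"))

  write_tsv(as.data.frame(stats), file.path(dir_path, "sumstats.tsv"))
  write_tsv(metadata, file.path(dir_path, "metadata.tsv"))

  if (!is.null(truth)) {
    tf <- data.frame(variant_id = truth$trait_variant_ids,
                     as.data.frame(truth$frequencies),
                     stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv(tf, file.path(dir_path, "truth_frequencies.tsv"))
  }

  payload <- setdiff(files, "manifest.yaml")
  checksums <- as.list(tools::md5sum(file.path(dir_path, payload)))
  names(checksums) <- payload
  manifest <- list(
    trait_name = attr(stats, "trait_name") %||% "trait",
    n_variants = nrow(stats),
    n_samples = nrow(dos),
    programmed_trend_sign = if (!is.null(truth))
      as.list(truth$programmed_trend_sign) else NULL,
    files = checksums
  )
  yaml::write_yaml(manifest, file.path(dir_path, "manifest.yaml"))
  invisible(manifest)
}
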