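#' Count effect and called alleles per period
#'
#' Pseudo-haploid (ancient) samples contribute one allele per non-missing
#' call (dosage 2 = one effect allele of one called; dosage 0 = zero of one);
#' diploid samples contribute two alleles per call (dosage d = d effect
#' alleles of two called); missing calls contribute nothing. Ploidy is taken
#' from the metadata `is_ancient` flag; an ancient sample with dosage 1
#' violates the pseudo-haploid contract and is an error.
#'
#' @param genotypes A [genotype_matrix()] oriented to effect alleles.
#' @param meta Sample metadata.
#' @param period_pair Length-2 character vector of period (or pooled group)
#'   labels; "PreNeolithic" pools EUP, LUP and Mesolithic.
#' @return Data frame with one row per variant: `variant_id`, `n_eff_1`,
#'   `n_called_1`, `n_eff_2`, `n_called_2`.
#' @export
allele_counts_by_period <- function(genotypes, meta, period_pair) {
  stopifnot(length(period_pair) == 2)
  mi <- match(rownames(genotypes$dosage), meta$sample_id)
  if (anyNA(mi)) stop("metadata does not cover all genotyped samples",
                      call. = FALSE)
  meta <- meta[mi, , drop = FALSE]
  counts_one <- function(label) {
    sel <- meta$period %in% resolve_period_group(label)
    if (!any(sel)) stop("period '", label, "' has no samples", call. = FALSE)
    d <- genotypes$dosage[sel, , drop = FALSE]
    anc <- meta$is_ancient[sel]
    if (any(anc) &&
        any(d[anc, , drop = FALSE] == 1L, na.rm = TRUE)) {
      stop("pseudo-haploid violation: ancient sample with dosage 1",
           call. = FALSE)
    }
    called <- !is.na(d)
    weight <- ifelse(anc, 1L, 2L)
    n_called <- as.integer(colSums(called * weight))
    dd <- d
    dd[!called] <- 0L
    # ancient dosage is on the 0/2 diploid scale but carries one allele
    n_eff <- as.integer(colSums(dd * ifelse(anc, 0.5, 1)))
    list(n_eff = n_eff, n_called = n_called)
  }
  c1 <- counts_one(period_pair[1])
  c2 <- counts_one(period_pair[2])
  data.frame(variant_id = genotypes$snp$variant_id,
             n_eff_1 = c1$n_eff, n_called_1 = c1$n_called,
             n_eff_2 = c2$n_eff, n_called_2 = c2$n_called,
             stringsAsFactors = FALSE)
}

# Hudson estimator components: numerator carries the finite-sample
# correction, denominator is p1(1-p2) + p2(1-p1).
hudson_components <- function(n_eff1, n_called1, n_eff2, n_called2) {
  p1 <- n_eff1 / n_called1
  p2 <- n_eff2 / n_called2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n_called1 - 1) -
    p2 * (1 - p2) / (n_called2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Hudson's two-population F_st estimator
#'
#' Per-SNP fixation index from allele counts in two populations:
#' \deqn{F_{st} = \frac{(\hat p_1-\hat p_2)^2
#'   - \hat p_1(1-\hat p_1)/(n_1-1) - \hat p_2(1-\hat p_2)/(n_2-1)}
#'   {\hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1)}}
#' where n are called-allele counts. The finite-sample correction makes the
#' estimator unbiased near zero differentiation, so negative values occur
#' and are deliberately not clamped. When both populations are fixed for the
#' same allele the denominator is 0 and the value is undefined (NA; such
#' SNPs are skipped downstream).
#'
#' @param n_eff1,n_called1 Effect-allele and called-allele counts in
#'   population 1 (vectors).
#' @param n_eff2,n_called2 Counts in population 2.
#' @return Numeric vector of F_st values (NA where undefined).
#' @export
hudson_fst <- function(n_eff1, n_called1, n_eff2, n_called2) {
  if (any(n_called1 < 2) || any(n_called2 < 2)) {
    stop("hudson_fst requires at least 2 called alleles per population",
         call. = FALSE)
  }
  h <- hudson_components(n_eff1, n_called1, n_eff2, n_called2)
  ifelse(h$den == 0, NA_real_, h$num / h$den)
}

#' Mean F_st over a trait SNP set
#'
#' Arithmetic mean over the defined (non-NA) per-SNP values; the number of
#' skipped SNPs is attached as attribute `n_skipped`.
#'
#' @param fst_values Numeric vector of per-SNP F_st values, NA = undefined.
#' @return The mean as a single numeric with attribute `n_skipped`.
#' @export
mean_trait_fst <- function(fst_values) {
  ok <- !is.na(fst_values)
  if (!any(ok)) stop("all per-SNP F_st values are undefined", call. = FALSE)
  structure(mean(fst_values[ok]), n_skipped = sum(!ok))
}

#' LD scores for null matching
#'
#' For every variant, counts the background-pool variants within `window_bp`
#' on the same chromosome whose squared dosage correlation (pairwise-complete
#' observations, pooled over the supplied samples) exceeds `r2_threshold`.
#' This local-neighbour count is the LD summary used to stratify the
#' matched permutation null.
#'
#' @param genotypes A [genotype_matrix()] (restricted to the relevant
#'   samples).
#' @param background_ids Variant ids forming the background pool neighbours
#'   are counted against (default: all variants).
#' @param window_bp Window in base pairs (default 250,000).
#' @param r2_threshold Count neighbours with r^2 above this (default 0.2).
#' @param chunk_size Internal block size for the windowed correlation.
#' @return Named integer vector of LD scores, one per variant.
#' @export
snp_ld_scores <- function(genotypes, background_ids = NULL,
                          window_bp = 250000, r2_threshold = 0.2,
                          chunk_size = 200L) {
  snp <- genotypes$snp
  dos <- genotypes$dosage
  if (is.null(background_ids)) background_ids <- snp$variant_id
  is_bg <- snp$variant_id %in% background_ids
  out <- stats::setNames(integer(nrow(snp)), snp$variant_id)
  x_all <- dos
  storage.mode(x_all) <- "double"
  m_all <- 1 - is.na(x_all)
  x_all[is.na(x_all)] <- 0
  for (ch in unique(snp$chrom)) {
    cidx <- which(snp$chrom == ch)
    cidx <- cidx[order(snp$pos[cidx])]
    pos <- snp$pos[cidx]
    nv <- length(cidx)
    for (s in seq(1L, nv, by = chunk_size)) {
      e <- min(s + chunk_size - 1L, nv)
      lo <- findInterval(pos[s] - window_bp - 1L, pos) + 1L
      hi <- findInterval(pos[e] + window_bp, pos)
      cand <- lo:hi
      r2 <- pairwise_r2(x_all[, cidx[s:e], drop = FALSE],
                        m_all[, cidx[s:e], drop = FALSE],
                        x_all[, cidx[cand], drop = FALSE],
                        m_all[, cidx[cand], drop = FALSE])
      for (i in s:e) {
        sel <- abs(pos[cand] - pos[i]) <= window_bp &
          cand != i & is_bg[cidx[cand]]
        out[cidx[i]] <- sum(r2[i - s + 1L, sel] > r2_threshold, na.rm = TRUE)
      }
    }
  }
  out
}

# Pairwise-complete squared Pearson correlation between two column blocks,
# via moment crossproducts over the non-missing indicator. xa/xb carry 0 in
# place of NA; ma/mb are the non-missing indicators. Undefined pairs (fewer
# than 2 joint calls, or zero variance) are NA.
pairwise_r2 <- function(xa, ma, xb, mb) {
  n   <- crossprod(ma, mb)
  sxy <- crossprod(xa, xb)
  sx  <- crossprod(xa, mb)
  sy  <- crossprod(ma, xb)
  sxx <- crossprod(xa^2, mb)
  syy <- crossprod(ma, xb^2)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  r2 <- ifelse(den > 0 & n >= 2, num^2 / den, NA_real_)
  r2
}

#' Build the MAF/LD-matched null distribution of mean F_st
#'
#' Each trait SNP is assigned a stratum by pooled minor-allele-frequency bin
#' (width `maf_bin_width`) and LD-score quantile bin (`ld_bins` bins, breaks
#' computed on the background pool). Each of the `n_sets` replicates samples,
#' for every trait SNP, one background SNP uniformly from the same stratum,
#' without replacement within the replicate, and records the replicate's
#' mean F_st over the sampled set. A trait SNP whose stratum holds no unused
#' background SNP falls back to MAF-only matching with a warning; if even
#' that pool is empty the build fails.
#'
#' @param fst Named numeric vector of per-SNP F_st values (trait and
#'   background SNPs; NA values must already be excluded).
#' @param maf Named numeric vector of pooled MAFs, same names.
#' @param ld_score Named numeric vector of LD scores, same names.
#' @param trait_ids Trait SNP ids (excluded from the background pool).
#' @param n_sets Number of null replicates (default 10,000).
#' @param maf_bin_width MAF stratum width (default 0.05).
#' @param ld_bins Number of LD-score quantile bins (default 4).
#' @param seed Optional integer seed: fixed seed reproduces the null vector
#'   exactly.
#' @param statistic "mean_of_ratios" (default: mean of per-SNP Hudson
#'   ratios) or a function(idx) -> numeric for custom set statistics.
#' @return Numeric vector of `n_sets` null mean F_st values, with attribute
#'   `n_relaxed` (trait SNPs matched on MAF only).
#' @export
build_matched_null <- function(fst, maf, ld_score, trait_ids,
                               n_sets = 10000, maf_bin_width = 0.05,
                               ld_bins = 4, seed = NULL,
                               statistic = "mean_of_ratios") {
  ids <- names(fst)
  stopifnot(!is.null(ids), identical(ids, names(maf)),
            identical(ids, names(ld_score)))
  if (anyNA(fst)) stop("fst must not contain NA; exclude undefined SNPs first",
                       call. = FALSE)
  trait_ids <- intersect(trait_ids, ids)
  if (length(trait_ids) == 0L) stop("no trait SNPs among supplied ids",
                                    call. = FALSE)
  bg_mask <- !(ids %in% trait_ids)
  if (sum(bg_mask) < 10 * length(trait_ids)) {
    stop("background pool must be at least 10x the trait-set size (have ",
         sum(bg_mask), " background vs ", length(trait_ids), " trait SNPs)",
         call. = FALSE)
  }
  maf_bin <- as.integer(pmin(maf, 0.5 - 1e-12) / maf_bin_width)
  breaks <- unique(stats::quantile(ld_score[bg_mask],
                                   probs = seq(0, 1, length.out = ld_bins + 1)))
  ld_bin <- if (length(breaks) > 1) {
    findInterval(ld_score, breaks[-c(1, length(breaks))]) + 1L
  } else {
    rep(1L, length(ld_score))
  }
  stratum <- paste(maf_bin, ld_bin, sep = ":")

  bg_idx_all <- which(bg_mask)
  pools_full <- split(bg_idx_all, stratum[bg_mask])
  pools_maf <- split(bg_idx_all, maf_bin[bg_mask])

  t_idx <- match(trait_ids, ids)
  t_stratum <- stratum[t_idx]
  t_mafbin <- as.character(maf_bin[t_idx])

  # trait SNPs grouped by stratum; groups overflowing their pool relax to
  # MAF-only matching (sampled sequentially to honour without-replacement)
  grp <- split(seq_along(t_idx), t_stratum)
  full_groups <- list()
  relaxed <- integer(0)
  for (g in names(grp)) {
    pool <- pools_full[[g]]
    k <- length(grp[[g]])
    avail <- length(pool %||% integer(0))
    if (avail >= k) {
      full_groups[[g]] <- list(pool = pool, k = k)
    } else {
      if (avail > 0) {
        full_groups[[g]] <- list(pool = pool, k = avail)
        relaxed <- c(relaxed, grp[[g]][seq_len(k - avail)])
      } else {
        relaxed <- c(relaxed, grp[[g]])
      }
    }
  }
  if (length(relaxed)) {
    warning(length(relaxed), " trait SNP(s) had an empty or exhausted ",
            "(MAF, LD) stratum; relaxed to MAF-only matching")
    for (i in relaxed) {
      if (length(pools_maf[[t_mafbin[i]]] %||% integer(0)) == 0L) {
        stop("no background SNP available even under MAF-only matching for ",
             "trait SNP ", trait_ids[i], call. = FALSE)
      }
    }
  }
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    function(idx) mean(fst[idx])
  }

  with_seed(seed, {
    nulls <- numeric(n_sets)
    n_total <- length(ids)
    used <- logical(n_total)
    for (b in seq_len(n_sets)) {
      idx <- integer(0)
      for (g in full_groups) {
        take <- g$pool[sample.int(length(g$pool), g$k)]
        idx <- c(idx, take)
      }
      if (length(relaxed)) {
        used[] <- FALSE
        used[idx] <- TRUE
        for (i in relaxed) {
          pool <- pools_maf[[t_mafbin[i]]]
          free <- pool[!used[pool]]
          if (length(free) == 0L) {
            stop("MAF-only pool exhausted within a replicate for trait SNP ",
                 trait_ids[i], call. = FALSE)
          }
          pick <- free[sample.int(length(free), 1L)]
          used[pick] <- TRUE
          idx <- c(idx, pick)
        }
      }
      nulls[b] <- stat_fun(idx)
    }
    structure(nulls, n_relaxed = length(relaxed))
  })
}

#' Empirical two-tailed p-value against a permutation null
#'
#' Add-one empirical p: p = min(1, 2 min((#\{null >= obs\} + 1)/(B + 1),
#' (#\{null <= obs\} + 1)/(B + 1))), so p is always positive.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics (non-empty).
#' @return p-value in (0, 1].
#' @export
empirical_two_tailed_p <- function(observed, null_values) {
  b <- length(null_values)
  if (b == 0L) stop("null_values must be non-empty", call. = FALSE)
  hi <- (sum(null_values >= observed) + 1) / (b + 1)
  lo <- (sum(null_values <= observed) + 1) / (b + 1)
  min(1, 2 * min(hi, lo))
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of p-values.
#' @param family_size Number of tests in the family; must be at least
#'   `length(p_values)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p_values, family_size) {
  if (family_size < length(p_values)) {
    stop("family_size must be at least the number of p-values",
         call. = FALSE)
  }
  pmin(1, p_values * family_size)
}

#' Matched-null selective-pressure test on a trait SNP set
#'
#' Computes per-SNP Hudson F_st between two adjacent periods, averages it
#' over the trait SNPs, and compares the observed mean against `n_sets`
#' MAF/LD-matched random SNP sets (see [build_matched_null()]) with an
#' empirical two-tailed p-value and Bonferroni correction. SNPs with fewer
#' than 2 called alleles in either period, or with undefined F_st (both
#' periods fixed for the same allele), are excluded from both the trait set
#' and the background pool.
#'
#' @param genotypes A [genotype_matrix()] oriented to effect alleles.
#' @param meta Sample metadata.
#' @param trait_ids Variant ids of the trait-associated (lead) SNPs.
#' @param period_pair Length-2 character vector of period (group) labels.
#' @param n_sets Number of null sets (default 10,000).
#' @param maf_bin_width,ld_bins Matching strata (defaults 0.05 and 4).
#' @param window_bp,r2_threshold LD-score window and r^2 cutoff.
#' @param estimator "hudson_mean_of_ratios" (default) averages per-SNP
#'   ratios; "hudson_ratio_of_averages" sums numerators and denominators
#'   over the set before dividing.
#' @param family_size Bonferroni family size (default 1; the orchestrator
#'   passes n traits x n period pairs).
#' @param seed Optional integer seed for the null sampling.
#' @param trait Trait label for the result.
#' @return An `fst_test_result`: list with `trait`, `period_pair`,
#'   `observed_mean_fst`, `null_mean`, `null_sd`, `n_null`, `empirical_p`,
#'   `bonferroni_p`, `n_snps`, `n_excluded`, and the `null_values`.
#' @export
fst_selection_test <- function(genotypes, meta, trait_ids, period_pair,
                               n_sets = 10000, maf_bin_width = 0.05,
                               ld_bins = 4, window_bp = 250000,
                               r2_threshold = 0.2,
                               estimator = c("hudson_mean_of_ratios",
                                             "hudson_ratio_of_averages"),
                               family_size = 1, seed = NULL,
                               trait = "trait") {
  estimator <- match.arg(estimator)
  counts <- allele_counts_by_period(genotypes, meta, period_pair)
  usable <- counts$n_called_1 >= 2 & counts$n_called_2 >= 2
  counts_u <- counts[usable, , drop = FALSE]
  h <- hudson_components(counts_u$n_eff_1, counts_u$n_called_1,
                         counts_u$n_eff_2, counts_u$n_called_2)
  defined <- h$den > 0
  n_excluded <- sum(!usable) + sum(!defined)
  if (n_excluded > 0) {
    message("fst_selection_test: excluded ", n_excluded,
            " SNP(s) with insufficient calls or undefined F_st")
  }
  ids <- counts_u$variant_id[defined]
  num <- stats::setNames(h$num[defined], ids)
  den <- stats::setNames(h$den[defined], ids)
  fst <- num / den
  trait_use <- intersect(trait_ids, ids)
  if (length(trait_use) == 0L) {
    stop("no trait SNP with a defined F_st in this period pair",
         call. = FALSE)
  }

  pooled_p <- (counts_u$n_eff_1 + counts_u$n_eff_2)[defined] /
    (counts_u$n_called_1 + counts_u$n_called_2)[defined]
  maf <- stats::setNames(pmin(pooled_p, 1 - pooled_p), ids)

  pair_samples <- meta$sample_id[
    meta$period %in% c(resolve_period_group(period_pair[1]),
                       resolve_period_group(period_pair[2]))]
  g_pair <- subset_genotypes(genotypes,
                             samples = intersect(rownames(genotypes$dosage),
                                                 pair_samples),
                             variants = ids)
  ld <- snp_ld_scores(g_pair, background_ids = setdiff(ids, trait_use),
                      window_bp = window_bp, r2_threshold = r2_threshold)
  ld <- ld[ids]

  stat_fun <- if (estimator == "hudson_mean_of_ratios") {
    function(idx) mean(fst[idx])
  } else {
    function(idx) sum(num[idx]) / sum(den[idx])
  }
  observed <- stat_fun(match(trait_use, ids))
  nulls <- build_matched_null(fst, maf, ld, trait_use, n_sets = n_sets,
                              maf_bin_width = maf_bin_width,
                              ld_bins = ld_bins, seed = seed,
                              statistic = stat_fun)
  p <- empirical_two_tailed_p(observed, nulls)
  structure(list(
    trait = trait,
    period_pair = period_pair,
    observed_mean_fst = unname(observed),
    null_mean = mean(nulls),
    null_sd = stats::sd(nulls),
    n_null = length(nulls),
    empirical_p = p,
    bonferroni_p = unname(bonferroni_adjust(p, family_size)),
    n_snps = length(trait_use),
    n_excluded = n_excluded,
    null_values = as.numeric(nulls)
  ), class = "fst_test_result")
}

#' @export
print.fst_test_result <- function(x, ...) {
  cat(sprintf(
    "fst_test_result [%s: %s vs %s]\n  mean F_st = %.5f over %d SNPs; null %.5f (sd %.5f, B = %d)\n  empirical p = %.4g, Bonferroni p = %.4g\n",
    x$trait, x$period_pair[1], x$period_pair[2], x$observed_mean_fst,
    x$n_snps, x$null_mean, x$null_sd, x$n_null, x$empirical_p,
    x$bonferroni_p))
  invisible(x)
}
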