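#' Filter samples by missingness, geography and dated age
#'
#' Applies the cohort filters to ancient samples: per-sample missing-call
#' fraction above `max_missing` (computed over the variants present in the
#' genotype matrix), location outside the latitude/longitude box (closed
#' bounds; samples without coordinates fail), or absence of a carbon-dated
#' age. Modern samples bypass all three filters (they are externally curated
#' and have age 0 by definition).
#'
#' @param meta Sample metadata covering every genotyped sample.
#' @param genotypes A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction, in \[0, 1);
#'   strictly greater removes (default 0.96).
#' @param lat_range,lon_range Closed geographic bounds in degrees (defaults
#'   \[35, 70\] N and \[-10, 40\] E).
#' @return List with `genotypes` and `meta` restricted to retained samples,
#'   and `log`: a data frame of per-rule removal counts.
#' @export
filter_samples <- function(meta, genotypes,
                           max_missing = 0.96,
                           lat_range = c(35, 70),
                           lon_range = c(-10, 40)) {
  if (length(max_missing) != 1 || max_missing < 0 || max_missing >= 1) {
    stop("max_missing must be in [0, 1)", call. = FALSE)
  }
  ids <- rownames(genotypes$dosage)
  mi <- match(ids, meta$sample_id)
  if (anyNA(mi)) {
    stop("metadata does not cover genotyped sample(s): ",
         paste(utils::head(ids[is.na(mi)], 5), collapse = ", "),
         call. = FALSE)
  }
  m <- meta[mi, , drop = FALSE]
  ancient <- m$is_ancient

  miss_frac <- rowMeans(is.na(genotypes$dosage))
  fail_miss <- ancient & miss_frac > max_missing
  fail_geo <- ancient & (is.na(m$latitude) | is.na(m$longitude) |
                           m$latitude < lat_range[1] |
                           m$latitude > lat_range[2] |
                           m$longitude < lon_range[1] |
                           m$longitude > lon_range[2])
  fail_age <- ancient & is.na(m$age_bp)

  keep <- !(fail_miss | fail_geo | fail_age)
  log <- data.frame(
    rule = c("missingness", "geography", "no_dated_age"),
    n_removed = c(sum(fail_miss), sum(fail_geo), sum(fail_age)),
    stringsAsFactors = FALSE
  )
  list(
    genotypes = subset_genotypes(genotypes, samples = ids[keep]),
    meta = m[keep, , drop = FALSE],
    log = log
  )
}

strand_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary-statistic alleles with genotype coding
#'
#' Restricts both inputs to their shared variants and re-orients dosages to
#' count the GWAS effect allele. Records that are not bi-allelic SNPs (allele
#' fields other than a single A/C/G/T, or identical alleles) and
#' strand-ambiguous pairs (A/T, C/G) are dropped; no strand flipping is
#' attempted beyond that, since flips cannot be resolved reliably in
#' pseudo-haploid data. Where the genotype counted allele equals the GWAS
#' other allele, dosage d becomes 2 - d (missing preserved); variants whose
#' allele sets neither match nor swap-match are dropped as irreconcilable.
#'
#' @param stats A `sumstats` table.
#' @param genotypes A [genotype_matrix()].
#' @return List of class `harmonized_variants` with `stats` and `genotypes`
#'   restricted to retained variants (genotypes re-oriented so the counted
#'   allele is the effect allele) and `log`, a per-rule removal count table.
#' @export
harmonize_variants <- function(stats, genotypes) {
  if (nrow(stats) == 0L || ncol(genotypes$dosage) == 0L) {
    stop("harmonize_variants requires non-empty inputs", call. = FALSE)
  }
  s <- as.data.frame(stats)
  bases <- c("A", "C", "G", "T")
  biallelic <- s$effect_allele %in% bases & s$other_allele %in% bases &
    s$effect_allele != s$other_allele
  n_nonbiallelic <- sum(!biallelic)
  s <- s[biallelic, , drop = FALSE]

  ambiguous <- strand_complement[s$effect_allele] == s$other_allele
  n_ambiguous <- sum(ambiguous)
  s <- s[!ambiguous, , drop = FALSE]

  shared <- intersect(s$variant_id, genotypes$snp$variant_id)
  n_not_shared <- (nrow(s) - length(shared))
  s <- s[match(shared, s$variant_id), , drop = FALSE]
  g <- subset_genotypes(genotypes, variants = shared)

  same <- g$snp$ref == s$effect_allele & g$snp$alt == s$other_allele
  swapped <- g$snp$ref == s$other_allele & g$snp$alt == s$effect_allele
  irreconcilable <- !(same | swapped)
  n_irreconcilable <- sum(irreconcilable)

  keep <- which(!irreconcilable)
  if (length(keep) == 0L) {
    stop("empty intersection: no variant shared between summary statistics ",
         "and genotypes after harmonization", call. = FALSE)
  }
  s <- s[keep, , drop = FALSE]
  g <- subset_genotypes(g, variants = s$variant_id)
  swapped <- swapped[keep]
  if (any(swapped)) {
    g$dosage[, swapped] <- 2L - g$dosage[, swapped]
  }
  g$snp$ref <- s$effect_allele
  g$snp$alt <- s$other_allele
  rownames(s) <- NULL

  log <- data.frame(
    rule = c("non_biallelic", "ambiguous_pair", "not_in_genotypes",
             "irreconcilable_alleles"),
    n_removed = c(n_nonbiallelic, n_ambiguous, n_not_shared,
                  n_irreconcilable),
    stringsAsFactors = FALSE
  )
  structure(list(
    stats = structure(s, class = c("sumstats", "data.frame"),
                      trait_name = attr(stats, "trait_name")),
    genotypes = g,
    log = log
  ), class = "harmonized_variants")
}

#' Run the full cohort QC: sample filters plus allele harmonization
#'
#' @param stats A `sumstats` table.
#' @param genotypes A [genotype_matrix()].
#' @param meta Sample metadata.
#' @param max_missing,lat_range,lon_range Passed to [filter_samples()].
#' @return A `harmonized_dataset`: list with `stats`, `genotypes` (retained
#'   samples, harmonized variants), `meta` and the combined `filter_log`.
#' @export
qc_dataset <- function(stats, genotypes, meta,
                       max_missing = 0.96,
                       lat_range = c(35, 70),
                       lon_range = c(-10, 40)) {
  fs <- filter_samples(meta, genotypes, max_missing = max_missing,
                       lat_range = lat_range, lon_range = lon_range)
  hv <- harmonize_variants(stats, fs$genotypes)
  log <- rbind(
    data.frame(stage = "samples", fs$log, stringsAsFactors = FALSE),
    data.frame(stage = "variants", hv$log, stringsAsFactors = FALSE)
  )
  structure(list(
    stats = hv$stats,
    genotypes = hv$genotypes,
    meta = fs$meta,
    filter_log = log
  ), class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat("harmonized_dataset:", nrow(x$meta), "samples,",
      nrow(x$stats), "variants\n")
  print(x$filter_log)
  invisible(x)
}
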