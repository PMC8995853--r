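#' Greedy distance-based clumping of association signals
#'
#' Selects independent lead variants by the standard greedy rule: candidates
#' are variants with p <= `p_threshold`, visited in ascending p (ties broken
#' by chromosome then position for determinism); a candidate becomes a lead
#' unless an already-selected lead on the same chromosome lies within
#' `window_bp` (inclusive bound). Cross-chromosome pairs never exclude.
#'
#' @param stats A `sumstats` table (restricted to harmonized variants).
#' @param p_threshold Inclusion p-value threshold (default 1e-6).
#' @param window_bp Exclusion window in base pairs (default 250,000).
#' @return A `clump_result`: list with `lead_variant_ids` (in selection
#'   order), `excluded` (named character: excluded variant -> excluding
#'   lead) and `parameters`. Empty lead list with a warning when no variant
#'   passes the threshold.
#' @export
clump_by_distance <- function(stats, p_threshold = 1e-6,
                              window_bp = 250000) {
  clump_greedy(stats, p_threshold, window_bp, exclude_fun = NULL)
}

#' Greedy LD-aware clumping
#'
#' As [clump_by_distance()], but a candidate within `window_bp` of a lead is
#' excluded only if its squared dosage correlation with that lead exceeds
#' `r2_threshold`. r^2 is computed across samples with both calls
#' non-missing (pseudo-haploid dosages enter as 0/2); pairs with fewer than
#' `min_joint_calls` joint non-missing samples, or with an undefined
#' correlation (zero variance), are treated as excluded — the conservative
#' choice, since independence cannot be demonstrated.
#'
#' @inheritParams clump_by_distance
#' @param genotypes A [genotype_matrix()] covering the stats variants,
#'   oriented to effect alleles.
#' @param r2_threshold Exclusion bound: exclude when r^2 > this value
#'   (default 0.2, i.e. r^2 = 0.2 itself is retained).
#' @param min_joint_calls Minimum joint non-missing sample count for an LD
#'   estimate (default 20).
#' @return A `clump_result` (see [clump_by_distance()]).
#' @export
clump_by_ld <- function(stats, genotypes, p_threshold = 1e-6,
                        window_bp = 250000, r2_threshold = 0.2,
                        min_joint_calls = 20) {
  if (length(r2_threshold) != 1 || r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must be in (0, 1]", call. = FALSE)
  }
  dos <- genotypes$dosage
  exclude_fun <- function(cand_id, lead_id) {
    x <- dos[, cand_id]
    y <- dos[, lead_id]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_joint_calls) return(TRUE)
    r <- suppressWarnings(stats::cor(x[ok], y[ok]))
    if (is.na(r)) return(TRUE)
    r^2 > r2_threshold
  }
  res <- clump_greedy(stats, p_threshold, window_bp, exclude_fun)
  res$parameters$ld_r2 <- r2_threshold
  res$parameters$min_joint_calls <- min_joint_calls
  res
}

# Shared greedy core. exclude_fun(candidate_id, lead_id) decides whether a
# lead inside the window excludes the candidate; NULL means distance-only
# (any in-window lead excludes).
clump_greedy <- function(stats, p_threshold, window_bp, exclude_fun) {
  s <- as.data.frame(stats)
  cand <- s[s$p_value <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no variant passes p threshold ", format(p_threshold),
            "; empty clump result")
    return(structure(list(lead_variant_ids = character(0),
                          excluded = stats::setNames(character(0),
                                                     character(0)),
                          parameters = list(p_threshold = p_threshold,
                                            window_bp = window_bp,
                                            ld_r2 = NULL)),
                     class = "clump_result"))
  }
  cand <- cand[order(cand$p_value, cand$chrom, cand$pos), , drop = FALSE]
  leads <- character(0)
  lead_chrom <- character(0)
  lead_pos <- numeric(0)
  excluded <- character(0)
  excluded_by <- character(0)
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    pos <- cand$pos[i]
    near <- which(lead_chrom == ch & abs(lead_pos - pos) <= window_bp)
    blocker <- NA_integer_
    if (length(near)) {
      if (is.null(exclude_fun)) {
        blocker <- near[1]   # earliest-selected in-window lead
      } else {
        for (j in near) {
          if (exclude_fun(cand$variant_id[i], leads[j])) {
            blocker <- j
            break
          }
        }
      }
    }
    if (is.na(blocker)) {
      leads <- c(leads, cand$variant_id[i])
      lead_chrom <- c(lead_chrom, ch)
      lead_pos <- c(lead_pos, pos)
    } else {
      excluded <- c(excluded, cand$variant_id[i])
      excluded_by <- c(excluded_by, leads[blocker])
    }
  }
  structure(list(
    lead_variant_ids = leads,
    excluded = stats::setNames(excluded_by, excluded),
    parameters = list(p_threshold = p_threshold, window_bp = window_bp,
                      ld_r2 = NULL)
  ), class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", length(x$lead_variant_ids), "lead variants,",
      length(x$excluded), "excluded (p <=",
      format(x$parameters$p_threshold), ", window",
      x$parameters$window_bp, "bp",
      if (!is.null(x$parameters$ld_r2))
        paste0(", r2 > ", x$parameters$ld_r2) else "", ")\n")
  invisible(x)
}

#' Compute polygenic scores with mean-dosage imputation
#'
#' For each sample, the raw score is the weighted sum over lead variants of
#' the effect-allele dosage times the GWAS beta, S = sum_n X_n * beta_n.
#' A missing dosage is substituted with the mean observed dosage of that
#' variant over all retained samples (ancient and modern pooled), so missing
#' calls pull a sample's score toward the dataset average rather than
#' skewing it; a sample missing every lead gets exactly the dataset-average
#' score. Lead variants observed in no sample are dropped with a warning.
#'
#' @param genotypes A [genotype_matrix()] oriented to effect alleles.
#' @param stats A `sumstats` table providing betas.
#' @param leads Character vector of lead variant ids (or a `clump_result`).
#' @return A `score_set` data frame with columns `sample_id` and
#'   `raw_score`, and attributes `mean_dosage` (imputation means),
#'   `n_variants_used` and `trait`.
#' @export
compute_prs <- function(genotypes, stats, leads) {
  if (inherits(leads, "clump_result")) leads <- leads$lead_variant_ids
  if (length(leads) == 0L) stop("leads must be non-empty", call. = FALSE)
  idx <- match(leads, stats$variant_id)
  if (anyNA(idx)) stop("lead variant(s) absent from stats", call. = FALSE)
  g <- subset_genotypes(genotypes, variants = leads)
  d <- g$dosage
  means <- colMeans(d, na.rm = TRUE)
  unobserved <- !is.finite(means)
  if (any(unobserved)) {
    warning("dropping ", sum(unobserved),
            " lead variant(s) with no observed dosage in any sample")
    d <- d[, !unobserved, drop = FALSE]
    means <- means[!unobserved]
    idx <- idx[!unobserved]
    if (ncol(d) == 0L) stop("no lead variant observed in any sample",
                            call. = FALSE)
  }
  beta <- stats$beta[idx]
  dd <- d
  storage.mode(dd) <- "double"
  na_pos <- which(is.na(dd), arr.ind = TRUE)
  if (nrow(na_pos)) dd[na_pos] <- means[na_pos[, 2]]
  s <- as.vector(dd %*% beta)
  structure(
    data.frame(sample_id = rownames(d), raw_score = s,
               stringsAsFactors = FALSE),
    class = c("score_set", "data.frame"),
    mean_dosage = means,
    n_variants_used = ncol(d),
    trait = attr(stats, "trait_name") %||% "trait"
  )
}

#' Min-max scale polygenic scores to \[-1, 1\]
#'
#' Applies scaled = 2 (S - min) / (max - min) - 1 over all samples jointly,
#' so the scaled distribution spans exactly -1 to 1. If all raw scores are
#' equal the scaled scores are all 0. Scaling is monotone, so downstream
#' rank-based and correlation statistics are unaffected up to sign.
#'
#' @param scores A `score_set` from [compute_prs()].
#' @return The same `score_set` with a `scaled_score` column added.
#' @export
scale_scores <- function(scores) {
  stopifnot(inherits(scores, "score_set"), nrow(scores) >= 1)
  s <- scores$raw_score
  rng <- range(s)
  scores$scaled_score <- if (rng[1] == rng[2]) {
    rep(0, length(s))
  } else {
    2 * (s - rng[1]) / (rng[2] - rng[1]) - 1
  }
  scores
}
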