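#' Threshold sweep over the scoring and trajectory stack
#'
#' Re-runs sample filtering, clumping, scoring and the piecewise trend fits
#' for every combination of GWAS p-value threshold, per-sample missingness
#' threshold, clumping window and clumping mode, to show whether the
#' correlation signs and significance survive analyst choices. Combinations
#' yielding no usable SNPs or too few samples produce an empty cell, not an
#' error.
#'
#' @param dataset A `harmonized_dataset` from [qc_dataset()].
#' @param grid List with elements `p_thresholds` (default 1e-5..1e-8),
#'   `missingness` (default 0.96, 0.90, 0.80, 0.70), `window_bp` (default
#'   250,000) and `clump_modes` ("distance" and/or "ld"; default
#'   "distance").
#' @param r2_threshold,min_joint_calls Passed to [clump_by_ld()] for the
#'   "ld" mode.
#' @return Data frame with one row per (combination, segment): the grid
#'   coordinates, `segment`, `n_samples`, `n_snps`, `r`, `p_value`,
#'   `signed_logp` and `empty`. Attribute `sign_consistency` holds, per
#'   segment, the fraction of non-empty cells whose signed -log10 p agrees
#'   with the modal sign.
#' @export
run_sweep <- function(dataset,
                      grid = list(),
                      r2_threshold = 0.2,
                      min_joint_calls = 20) {
  stopifnot(inherits(dataset, "harmonized_dataset"))
  grid <- utils::modifyList(list(p_thresholds = 10^-(5:8),
                                 missingness = c(0.96, 0.90, 0.80, 0.70),
                                 window_bp = 250000,
                                 clump_modes = "distance"), grid)
  combos <- expand.grid(p_threshold = grid$p_thresholds,
                        max_missing = grid$missingness,
                        window_bp = grid$window_bp,
                        clump_mode = grid$clump_modes,
                        stringsAsFactors = FALSE)
  rows <- vector("list", 2L * nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    cell <- sweep_cell(dataset, cm$p_threshold, cm$max_missing,
                       cm$window_bp, cm$clump_mode, r2_threshold,
                       min_joint_calls)
    for (k in 1:2) {
      rows[[2L * (i - 1L) + k]] <- cbind(cm, cell[k, ],
                                         row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sc <- vapply(c("pre", "post"), function(s) {
    v <- out$signed_logp[out$segment == s & !out$empty]
    v <- v[!is.na(v) & v != 0]
    if (length(v) == 0) return(NA_real_)
    modal <- sign(sum(sign(v)))
    if (modal == 0) modal <- 1
    mean(sign(v) == modal)
  }, numeric(1))
  structure(out, sign_consistency = sc)
}

sweep_cell <- function(dataset, p_threshold, max_missing, window_bp,
                       clump_mode, r2_threshold, min_joint_calls) {
  empty_cell <- data.frame(segment = c("pre", "post"),
                           n_samples = NA_integer_, n_snps = NA_integer_,
                           r = NA_real_, p_value = NA_real_,
                           signed_logp = NA_real_, empty = TRUE,
                           stringsAsFactors = FALSE)
  fs <- filter_samples(dataset$meta, dataset$genotypes,
                       max_missing = max_missing)
  if (nrow(fs$meta) < 3) return(empty_cell)
  clump <- suppressWarnings(
    if (clump_mode == "ld") {
      clump_by_ld(dataset$stats, fs$genotypes, p_threshold = p_threshold,
                  window_bp = window_bp, r2_threshold = r2_threshold,
                  min_joint_calls = min_joint_calls)
    } else {
      clump_by_distance(dataset$stats, p_threshold = p_threshold,
                        window_bp = window_bp)
    })
  n_snps <- length(clump$lead_variant_ids)
  if (n_snps == 0) return(empty_cell)
  scores <- scale_scores(compute_prs(fs$genotypes, dataset$stats, clump))
  tr <- piecewise_trends(scores, fs$meta)
  data.frame(segment = tr$segment,
             n_samples = tr$n, n_snps = n_snps,
             r = tr$r, p_value = tr$p_value, signed_logp = tr$signed_logp,
             empty = tr$undefined | is.na(tr$r),
             stringsAsFactors = FALSE)
}

#' Down-sampling consistency of the post-breakpoint correlation
#'
#' The post-breakpoint group is much larger than the pre-breakpoint group in
#' cohorts like this one, so the post-segment correlation could in principle
#' be an artifact of sample-size imbalance. This check repeatedly
#' down-samples the post-breakpoint group (without replacement) to the
#' pre-breakpoint group's size, recomputes the post-segment Pearson
#' correlation, and reports the distribution of the down-sampled coefficients
#' together with the fraction matching the full-data sign.
#'
#' @param scores A `score_set` with `scaled_score`.
#' @param meta Sample metadata aligned by `sample_id`.
#' @param n_repeats Number of down-sampling repeats (default 100).
#' @param seed Optional integer seed.
#' @return List: `full_r`, `full_p`, `r_values` (length `n_repeats`),
#'   `sign_match_fraction`, `n_pre`, `n_post`.
#' @export
downsample_consistency <- function(scores, meta, n_repeats = 100,
                                   seed = NULL) {
  stopifnot(inherits(scores, "score_set"), "scaled_score" %in% names(scores))
  mi <- match(scores$sample_id, meta$sample_id)
  if (anyNA(mi)) stop("metadata does not cover all scored samples",
                      call. = FALSE)
  meta <- meta[mi, , drop = FALSE]
  seg <- breakpoint_segment(meta$period)
  n_pre <- sum(seg == "pre")
  post_idx <- which(seg == "post")
  n_post <- length(post_idx)
  if (n_pre >= n_post) {
    stop("post-breakpoint group (", n_post, ") is not larger than the ",
         "pre-breakpoint group (", n_pre, "); nothing to down-sample",
         call. = FALSE)
  }
  if (n_pre < 3) stop("pre-breakpoint group too small (need >= 3)",
                      call. = FALSE)
  x <- scores$scaled_score
  a <- meta$age_bp
  full <- pearson_trend(x[post_idx], a[post_idx])
  with_seed(seed, {
    r_values <- vapply(seq_len(n_repeats), function(b) {
      sub <- post_idx[sample.int(n_post, n_pre)]
      suppressWarnings(stats::cor(x[sub], a[sub]))
    }, numeric(1))
    list(full_r = full$r, full_p = full$p_value, r_values = r_values,
         sign_match_fraction = mean(sign(r_values) == sign(full$r),
                                    na.rm = TRUE),
         n_pre = n_pre, n_post = n_post)
  })
}
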