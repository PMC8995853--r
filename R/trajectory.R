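#' Split samples at the Neolithic breakpoint
#'
#' The piecewise trajectory models split the cohort into everything preceding
#' the Neolithic (EUP, LUP, Mesolithic) and the Neolithic and later
#' (Neolithic, PostNeolithic, Modern).
#'
#' @param meta Sample metadata with an assigned `period` for every sample.
#' @return List with elements `pre` and `post`, each a metadata subset.
#' @export
split_by_breakpoint <- function(meta) {
  seg <- breakpoint_segment(meta$period)
  list(pre = meta[seg == "pre", , drop = FALSE],
       post = meta[seg == "post", , drop = FALSE])
}

#' Breakpoint segment of each period label
#'
#' @param period Character vector of period labels.
#' @return Character vector, "pre" or "post" per sample.
#' @export
breakpoint_segment <- function(period) {
  pre <- c("EUP", "LUP", "Mesolithic")
  post <- c("Neolithic", "PostNeolithic", "Modern")
  unknown <- !(period %in% c(pre, post))
  if (any(unknown)) {
    stop("unknown period label(s): ",
         paste(unique(period[unknown]), collapse = ", "), call. = FALSE)
  }
  ifelse(period %in% pre, "pre", "post")
}

#' Pearson correlation of scores against carbon-dated age
#'
#' Computes the Pearson correlation between polygenic scores and sample ages
#' (years before 1950; larger = older), the two-sided p-value from the t
#' distribution with n - 2 degrees of freedom, and the signed significance
#' score sign(r) * (-log10 p), capped at magnitude 300 (p is clamped to the
#' smallest positive double before the log so perfect correlations do not
#' produce infinities). Because the regressor is age, a trait that increases
#' toward the present has a NEGATIVE correlation; the returned
#' `signed_logp_toward_present` carries the time-forward sign to prevent
#' misreading.
#'
#' @param scores Numeric vector of (scaled or raw) polygenic scores.
#' @param ages Numeric vector of ages in years BP, same length.
#' @return A list of class `piecewise_fit`: `n`, `r`, `p_value`,
#'   `signed_logp`, `signed_logp_toward_present`, `undefined`. When either
#'   vector has zero variance the fit is flagged `undefined = TRUE` (r and p
#'   are NA) rather than raising an error.
#' @export
pearson_trend <- function(scores, ages) {
  ok <- is.finite(scores) & is.finite(ages)
  scores <- scores[ok]
  ages <- ages[ok]
  n <- length(scores)
  if (n < 3) stop("pearson_trend requires at least 3 complete pairs",
                  call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(ages) == 0) {
    return(structure(list(n = n, r = NA_real_, p_value = NA_real_,
                          signed_logp = NA_real_,
                          signed_logp_toward_present = NA_real_,
                          undefined = TRUE),
                     class = "piecewise_fit"))
  }
  r <- stats::cor(scores, ages)
  slp <- signed_logp_from_r(r, n)
  structure(list(n = n, r = r, p_value = slp$p,
                 signed_logp = slp$signed_logp,
                 signed_logp_toward_present = -slp$signed_logp,
                 undefined = FALSE),
            class = "piecewise_fit")
}

# Two-sided p from the t distribution with n - 2 df, with underflow clamped
# to the smallest positive double, and the signed -log10 p capped at 300.
signed_logp_from_r <- function(r, n) {
  r2 <- min(r^2, 1)
  tstat <- if (r2 == 1) Inf else abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, signed_logp = sign(r) * min(-log10(p), 300))
}

#' LOESS trend of scores over time
#'
#' Locally weighted degree-1 regression with tricube weights (the standard
#' LOESS), evaluated on a grid of ages, to display the score trajectory
#' without committing to a breakpoint.
#'
#' @param scores,ages Numeric vectors (n >= 10).
#' @param span Smoothing span in (0, 1]; the local neighbourhood must
#'   contain at least 4 points, so span must be >= 4/n.
#' @param grid Ages at which to evaluate the fit (default: 100 equally
#'   spaced points over the observed age range). Grid points outside the
#'   data range are not extrapolated: their fitted value is NA and they are
#'   flagged.
#' @return Data frame with columns `age`, `fitted`, `extrapolated`.
#' @export
loess_trend <- function(scores, ages, span = 0.75, grid = NULL) {
  ok <- is.finite(scores) & is.finite(ages)
  scores <- scores[ok]
  ages <- ages[ok]
  n <- length(scores)
  if (n < 10) stop("loess_trend requires at least 10 observations",
                   call. = FALSE)
  if (length(span) != 1 || span <= 0 || span > 1) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  min_span <- 4 / n
  if (span < min_span) {
    stop("span too small for local neighbourhoods; minimum span is ",
         signif(min_span, 3), " for n = ", n, call. = FALSE)
  }
  fit <- stats::loess(scores ~ ages, span = span, degree = 1,
                      family = "gaussian", surface = "direct")
  if (is.null(grid)) grid <- seq(min(ages), max(ages), length.out = 100)
  inside <- grid >= min(ages) & grid <= max(ages)
  fitted <- rep(NA_real_, length(grid))
  if (any(inside)) {
    fitted[inside] <- stats::predict(fit,
                                     newdata = data.frame(ages = grid[inside]))
  }
  data.frame(age = grid, fitted = fitted, extrapolated = !inside)
}

#' Piecewise trend fits on both breakpoint segments
#'
#' @param scores A `score_set` with a `scaled_score` column (see
#'   [scale_scores()]).
#' @param meta Sample metadata aligned by `sample_id`.
#' @return Data frame with one row per segment: `segment`, `n`, `r`,
#'   `p_value`, `signed_logp`, `signed_logp_toward_present`, `undefined`.
#' @export
piecewise_trends <- function(scores, meta) {
  stopifnot(inherits(scores, "score_set"), "scaled_score" %in% names(scores))
  mi <- match(scores$sample_id, meta$sample_id)
  if (anyNA(mi)) stop("metadata does not cover all scored samples",
                      call. = FALSE)
  meta <- meta[mi, , drop = FALSE]
  seg <- breakpoint_segment(meta$period)
  rows <- lapply(c("pre", "post"), function(s) {
    sel <- seg == s
    if (sum(sel) < 3) {
      return(data.frame(segment = s, n = sum(sel), r = NA_real_,
                        p_value = NA_real_, signed_logp = NA_real_,
                        signed_logp_toward_present = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    fit <- pearson_trend(scores$scaled_score[sel], meta$age_bp[sel])
    data.frame(segment = s, n = fit$n, r = fit$r, p_value = fit$p_value,
               signed_logp = fit$signed_logp,
               signed_logp_toward_present = fit$signed_logp_toward_present,
               undefined = fit$undefined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Student t-tests between adjacent archaeological periods
#'
#' Two-sided pooled-variance (classical Student) t-tests comparing scaled
#' scores between adjacent period groups. The default pairs are
#' pre-Neolithic vs Neolithic, Neolithic vs PostNeolithic, PostNeolithic vs
#' Modern, and Mesolithic vs Neolithic; "PreNeolithic" pools EUP, LUP and
#' Mesolithic. Pairs with fewer than 2 samples on either side are skipped
#' with a message.
#'
#' @param scores Numeric vector of scores.
#' @param periods Character vector of period labels, same length.
#' @param pairs List of length-2 character vectors of period (group) labels;
#'   NULL for the default pairs.
#' @return Data frame with one row per performed comparison: `period_a`,
#'   `period_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
adjacent_period_ttests <- function(scores, periods, pairs = NULL) {
  stopifnot(length(scores) == length(periods))
  if (is.null(pairs)) {
    pairs <- list(c("PreNeolithic", "Neolithic"),
                  c("Neolithic", "PostNeolithic"),
                  c("PostNeolithic", "Modern"),
                  c("Mesolithic", "Neolithic"))
  }
  rows <- list()
  for (pr in pairs) {
    a <- scores[periods %in% resolve_period_group(pr[1])]
    b <- scores[periods %in% resolve_period_group(pr[2])]
    if (length(a) < 2 || length(b) < 2) {
      message("skipping t-test ", pr[1], " vs ", pr[2],
              ": group with fewer than 2 samples")
      next
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      period_a = pr[1], period_b = pr[2],
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(period_a = character(0), period_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      t_statistic = numeric(0), df = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
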