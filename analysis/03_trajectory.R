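#!/usr/bin/env Rscript
# Temporal trajectory statistics on the scaled scores: piecewise Pearson
# correlations against carbon-dated age (pre- vs post-Neolithic segments,
# signed -log10 p), a LOESS trend curve, and Student t-tests between
# adjacent period groups. Writes results/piecewise_trends.tsv,
# results/loess_trend.tsv and results/period_ttests.tsv.

library(paleoprs)

scores_tab <- read.table("results/scores.tsv", header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
seg <- breakpoint_segment(scores_tab$period)

fits <- lapply(c("pre", "post"), function(s) {
  sub <- scores_tab[seg == s, ]
  fit <- pearson_trend(sub$scaled_score, sub$age_bp)
  data.frame(segment = s, n = fit$n, r = fit$r, p_value = fit$p_value,
             signed_logp = fit$signed_logp,
             signed_logp_toward_present = fit$signed_logp_toward_present)
})
trends <- do.call(rbind, fits)
print(trends)
cat("\nReading the signs: the correlation is taken against age BP, so a",
    "negative signed log-p means the score RISES toward the present.\n\n")

lo <- loess_trend(scores_tab$scaled_score, scores_tab$age_bp, span = 0.75)
tt <- adjacent_period_ttests(scores_tab$scaled_score, scores_tab$period)
print(tt)

write_results(list(piecewise_trends = trends, loess_trend = lo,
                   period_ttests = tt), "results", overwrite = TRUE)
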