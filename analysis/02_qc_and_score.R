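#!/usr/bin/env Rscript
# Read the simulated bundle back through the production readers, apply the
# cohort filters (missingness > 0.96, geography, dated age) and allele
# harmonization, clump at p <= 1e-6 in 250 kb windows, and compute min-max
# scaled polygenic scores. Writes results/scores.tsv and
# results/filter_log.tsv.

library(paleoprs)

stats <- read_summary_stats("results/cohort/sumstats.tsv",
                            trait_name = "synthetic_trait")
geno <- read_eigenstrat("results/cohort/cohort.geno",
                        "results/cohort/cohort.snp",
                        "results/cohort/cohort.ind")
meta <- read_metadata("results/cohort/metadata.tsv")

ds <- qc_dataset(stats, geno, meta)
print(ds$filter_log)

clump <- clump_by_distance(ds$stats, p_threshold = 1e-6,
                           window_bp = 250000)
cat("Lead SNPs after clumping:", length(clump$lead_variant_ids),
    "(", length(clump$excluded), "excluded )\n")

scores <- scale_scores(compute_prs(ds$genotypes, ds$stats, clump))
tab <- data.frame(
  sample_id = scores$sample_id,
  raw_score = scores$raw_score,
  scaled_score = scores$scaled_score,
  age_bp = ds$meta$age_bp[match(scores$sample_id, ds$meta$sample_id)],
  period = ds$meta$period[match(scores$sample_id, ds$meta$sample_id)],
  stringsAsFactors = FALSE)
write_results(list(scores = tab, filter_log = ds$filter_log,
                   lead_variants = data.frame(
                     variant_id = clump$lead_variant_ids)),
              "results", overwrite = TRUE)
cat("Scores for", nrow(tab), "samples written to results/scores.tsv\n")
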