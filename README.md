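# paleoprs

Temporal polygenic-score trajectories and selection tests on ancient DNA.

## The problem

Ancient-DNA compilations now hold hundreds of pseudo-haploid European
genomes spanning the Early Upper Paleolithic through the Post-Neolithic,
alongside modern reference panels. Combining them with GWAS summary
statistics lets one ask how the *genetic* component of complex traits —
height, BMI, lipoprotein levels, skin pigmentation, cognition-related
scores — moved across prehistory, and whether trait-associated loci were
under directional selection around the Neolithic transition rather than
drifting neutrally.

`paleoprs` is an analysis pipeline for exactly that question, written for
population geneticists working with EIGENSTRAT-formatted ancient genotypes
and standard GWAS summary statistics. It provides:

* **Cohort QC** — per-sample missingness (> 0.96 removed), geographic box
  (latitude 35–70 N, longitude −10–40 E), dated-age requirement, and
  allele harmonization (bi-allelic only, strand-ambiguous A/T and C/G pairs
  excluded, dosages re-oriented to the GWAS effect allele).
* **Polygenic scores** — greedy clumping (p ≤ 10⁻⁶ in 250 kb windows, or
  LD-aware with r² > 0.2 exclusion), the weighted sum S = Σₙ Xₙ βₙ with
  missing dosages imputed by the dataset-wide mean dosage, and min–max
  scaling to \[−1, 1\].
* **Trajectory statistics** — piecewise Pearson correlations of score
  against carbon-dated age on the pre-/post-Neolithic segments, reported as
  the signed −log10 p; LOESS trend curves; pooled-variance Student t-tests
  between adjacent periods.
* **Selection test** — per-SNP Hudson F_st between adjacent periods
  (allele-level counts: one allele per pseudo-haploid call, two per diploid
  call), averaged over the trait SNP set and compared against 10,000
  MAF/LD-matched random SNP sets with an empirical two-tailed p and
  Bonferroni correction.
* **Robustness** — threshold sweeps (GWAS p 10⁻⁵–10⁻⁸, missingness
  0.96–0.70, window sizes, clump modes) with sign-consistency summaries,
  and down-sampling of the post-Neolithic group to the pre-Neolithic size.
* **A synthetic-data generator** — temporally stratified pseudo-haploid
  cohorts with binomial drift, programmable per-transition allele-frequency
  shifts aligned with the GWAS betas, LD blocks, and heavy missingness —
  so the whole pipeline is testable with known ground truth and no external
  downloads.

See `vignettes/temporal-polygenic-scores.Rmd` for the methods account.

## Worked example

The numbered scripts under `analysis/` run the full study on a simulated
cohort shaped like the real compilations (1,075 samples: 825 ancient from
EUP through Post-Neolithic plus 250 modern; 2,000 variants of which 50 are
trait-associated with a programmed +0.1 effect-allele frequency shift per
period transition):

```sh
Rscript analysis/01_simulate.R       # write the cohort bundle
Rscript analysis/02_qc_and_score.R   # QC, clump, score
Rscript analysis/03_trajectory.R     # piecewise + LOESS + t-tests
Rscript analysis/04_selection_test.R # matched-null mean-F_st tests
Rscript analysis/05_robustness.R     # threshold sweep + down-sampling
```

`03_trajectory.R` prints the piecewise fits:

```
  segment   n          r      p_value signed_logp signed_logp_toward_present
1     pre 125 -0.3922539 6.063934e-06   -5.217246                   5.217246
2    post 950 -0.5660326 1.412129e-81  -80.850126                  80.850126
```

Both segments correlate negatively with age BP — the score rises toward
the present, strongly so after the Neolithic breakpoint (signed −log10 p of
−80.9 on 950 samples; the `*_toward_present` column carries the
time-forward sign). The adjacent-period t-tests agree (pre-Neolithic vs
Neolithic: t = −13.1, p ≈ 1e-31).

`04_selection_test.R` then asks whether the trait SNPs are unusually
differentiated:

```
fst_test_result [synthetic_trait: PreNeolithic vs Neolithic]
  mean F_st = 0.06074 over 41 SNPs; null 0.00034 (sd 0.00238, B = 10000)
  empirical p = 0.0002, Bonferroni p = 0.0005999
```

The observed mean F_st sits far above all 10,000 matched null sets — the
empirical p is at its add-one floor of 2/10,001 — so the programmed
selection signal is recovered. `05_robustness.R` reports sign consistency
of 1.0 across all 96 sweep combinations and that 100% of down-sampled
repeats (950 → 125 samples) keep the full-data correlation sign.

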