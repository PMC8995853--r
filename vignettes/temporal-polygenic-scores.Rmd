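---
title: "Temporal polygenic-score trajectories and matched-null selection tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal polygenic-score trajectories and matched-null selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleoprs models how the genetic component of complex traits changed across
European prehistory. It scores pseudo-haploid ancient genomes and modern
diploid genomes with GWAS-weighted polygenic scores, fits the score
trajectory against carbon-dated sample age, and asks whether the
trait-associated SNPs are more differentiated between adjacent
archaeological periods than matched random SNPs — the signature of
directional selection rather than drift.

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The data model

Three inputs define an analysis:

* **GWAS summary statistics** — per variant: chromosome, position, effect
  allele, other allele, per-allele effect size (beta) and association
  p-value.
* **Genotypes** in the EIGENSTRAT text triplet (`.geno`/`.snp`/`.ind`), the
  distribution format of the large public ancient-DNA compilations. Ancient
  samples are *pseudo-haploid*: each site is called from a single sequencing
  read, so a sample carries one allele observation per site, encoded as
  dosage 0 or 2 with heavy missingness. Modern samples are ordinary diploids
  (dosage 0/1/2).
* **Sample metadata** — carbon-dated age in years before 1950 (BP),
  latitude/longitude, and an optional explicit period label.

### Periods and the breakpoint

Ages map onto broad archaeological periods using boundaries in years BP:
Early Upper Paleolithic (≥ 25,000), Late Upper Paleolithic
\[11,000, 25,000), Mesolithic \[5,500, 11,000), Neolithic \[3,900, 8,500),
Post-Neolithic (< 5,000), Modern (exactly 0). Two conventions deserve
emphasis, because the printed boundaries do not fix them:

* Intervals are **closed at the older bound, open at the younger**
  (`[young, old)`), chosen so every positive age maps somewhere.
* The Mesolithic/Neolithic (\[5,500, 8,500)) and Neolithic/Post-Neolithic
  (\[3,900, 5,000)) ranges deliberately **overlap**. A sample dated into an
  overlap zone takes its explicitly recorded label — the role that
  archaeological context plays for real samples — and raises an error
  otherwise. The package never silently guesses.
* All printed bounds are treated as years before 1950; external metadata in
  BCE must be converted by the caller (BP ≈ BCE + 1950).

The piecewise trajectory models split the cohort at the Neolithic
breakpoint: *pre* = {EUP, LUP, Mesolithic}, *post* = {Neolithic,
Post-Neolithic, Modern}.

## Cohort and variant QC

Ancient samples are removed when their missing-call fraction exceeds
`max_missing` (default 0.96), when they fall outside latitude \[35, 70\] N /
longitude \[−10, 40\] E (closed bounds; no coordinates counts as outside),
or when they lack a dated age. Modern samples bypass these filters. The
missingness fraction is computed over the variants present in the genotype
matrix at hand — after intersection with the summary statistics when run
through `qc_dataset()` — since the package has no access to the full array
on which an upstream filter might have been computed; this choice is benign
at the default 0.96 but matters for aggressive thresholds.

Variant harmonization keeps the intersection of summary-statistic and
genotype variants; drops non-bi-allelic records and strand-ambiguous A/T
and C/G pairs (no strand-flip rescue is attempted — flips cannot be
verified in pseudo-haploid data, which is exactly why ambiguous pairs are
excluded); and re-orients dosages so they count the GWAS effect allele
(d → 2 − d where the genotype counted the other allele). Variants whose
allele sets neither match nor swap-match are dropped and logged. Every
filter emits a machine-readable count.

## Polygenic scores

Independent association signals are selected by greedy clumping: visit
variants with p ≤ 10⁻⁶ in ascending p; a candidate within 250 kb (inclusive)
of an already-selected lead on the same chromosome is excluded. Ties in p
are broken by (chromosome, position) so results are platform-independent —
a convention this package fixes because greedy clumping is otherwise
order-ambiguous. An LD-aware mode excludes an in-window candidate only when
its squared dosage correlation with the lead exceeds `r2` (default 0.2),
computed over pairwise-complete samples with pseudo-haploid dosages entering
as 0/2; pairs with fewer than 20 joint calls are excluded conservatively.
LD is computed on the pooled (ancient + modern) sample by default — the
natural choice when scores are compared across that pooled set — and can be
restricted by subsetting the genotypes passed in.

The score is the weighted sum S = Σₙ Xₙ βₙ over lead variants. A missing
dosage is replaced by that variant's mean observed dosage **over all
retained samples, ancient and modern pooled**, so missingness pulls a score
toward the dataset average instead of biasing it directionally; a sample
missing every lead lands exactly on the dataset-average score. Raw scores
are then min–max scaled to \[−1, 1\] over all samples jointly (all-equal
scores map to 0). Scaling is a positive affine map, so Pearson correlations
and t statistics are unchanged whether raw or scaled scores are fed in; the
scaled values exist for comparability of effect sizes across traits and
thresholds.

## Trajectory statistics

Within each breakpoint segment the scaled scores are correlated with age BP
(Pearson; two-sided p from the t distribution with n − 2 df). Significance
is reported as the **signed −log10 p**: the sign of the correlation times
−log10 of its p-value, capped at magnitude 300 after clamping p to the
smallest positive double — a finite-representation guard, not a statistical
choice. Because the regressor is age, *a trait that rises toward the
present has a negative correlation*; every output table therefore also
carries `signed_logp_toward_present` (the negated value) so the
time-forward reading is explicit.

A LOESS curve (locally weighted degree-1 regression with tricube weights,
span 0.75 by default — no span is canonical, and 0.75 is the conventional
default) displays the trajectory without committing to the breakpoint. The
fit is evaluated on a grid inside the observed age range only; requested
grid points outside it are flagged rather than extrapolated. Group
contrasts use two-sided pooled-variance Student t-tests between adjacent
periods: pre-Neolithic (pooled) vs Neolithic, Neolithic vs Post-Neolithic,
Post-Neolithic vs Modern, and Mesolithic vs Neolithic; the pair list is an
argument, since "adjacent" admits variations.

## The selection test

Between two adjacent periods, allele counts are accumulated at the allele
level: a pseudo-haploid call contributes one allele, a diploid call two —
pooling the two ploidies without down-weighting either. Per SNP,
differentiation is measured by **Hudson's two-population F_st estimator**

$$F_{st} = \frac{(\hat p_1-\hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{n_1-1}
  - \frac{\hat p_2(1-\hat p_2)}{n_2-1}}
  {\hat p_1(1-\hat p_2)+\hat p_2(1-\hat p_1)},$$

with n the called-allele counts. Hudson's form was chosen because it is the
standard estimator for two-population allele-count data, has no within-
population weighting ambiguity, and its finite-sample correction keeps the
null expectation near zero — negative values are legitimate and are *not*
clamped. SNPs with fewer than 2 called alleles in either period, or fixed
for the same allele in both (denominator 0), are excluded and counted. The
trait statistic is the arithmetic mean of per-SNP values (mean of ratios);
a ratio-of-averages variant (Σ numerators / Σ denominators) is available
behind the `estimator` flag, as the two weightings can differ when sample
sizes vary wildly across SNPs.

The observed trait mean is compared against a permutation null of
**MAF/LD-matched random SNP sets**. The matching procedure is this
package's explicit definition (the idea of LD/MAF matching is standard, but
no single canonical algorithm exists): each trait SNP is assigned a stratum
by pooled-sample minor-allele-frequency bin (width 0.05) and LD-score
quantile bin (quartiles of the background distribution by default), where
the LD score is the number of background SNPs within 250 kb with r² > 0.2.
Each of the 10,000 replicates draws, per trait SNP, one background SNP
uniformly from the same stratum, without replacement within the replicate;
a trait SNP with an empty or exhausted stratum falls back to MAF-only
matching with a logged warning. MAF is computed on the pooled two-period
sample — per-period MAF would make the matching depend on the very
differentiation being tested. The empirical two-tailed p uses the add-one
rule, p = min(1, 2·min(#\{null ≥ obs\}+1, #\{null ≤ obs\}+1)/(B+1)), so it
is never zero, and Bonferroni correction multiplies by the family size
(number of traits × period pairs tested).

## The synthetic-data generator

Nothing in the pipeline depends on restricted external resources: the
generator produces cohorts with known ground truth so every stage is
testable.

* **Frequencies.** Each variant starts at an effect-allele frequency drawn
  from `maf_range` (default 0.05–0.5). Between consecutive periods *all*
  variants drift by binomial resampling with effective size 10,000 — the
  simplest neutral null with the right F_st scaling — and trait variants
  additionally receive a deterministic shift of `selection_shift`
  (default 0.1) per transition, signed to increase the trait-increasing
  allele. The deterministic-shift encoding (rather than a selection
  coefficient) gives closed-form expected frequency paths, so power checks
  have analytic targets; because drift applies to trait variants too,
  setting the shift to zero makes trait SNPs statistically exchangeable
  with the background — the property the matched-null calibration tests
  rely on.
* **Genotypes.** Ancient samples are pseudo-haploid (one latent haplotype
  per LD block per sample; dosage 0/2) with per-sample missing rates drawn
  from `missing_rate_range` (default 0.2–0.6 — heavy, as in low-coverage
  ancient data, while leaving enough calls for desk-scale power); modern
  samples are diploid with no missingness. Consecutive variants within an
  LD block (default 5) share the latent draw, inducing realistic positive
  dosage correlation for the LD-aware code paths. A block-missingness
  option masks whole blocks to stress mean imputation.
* **Layout.** Variants are placed on ≥ 2 chromosomes with 20–80 kb
  spacing. Controllable fractions of non-trait variants get ambiguous
  (A/T, C/G) or non-bi-allelic records so the filters always have work;
  trait variants are kept clean so programmed trait-set sizes survive QC.
  Each variant's counted allele is randomly oriented, so harmonization is
  exercised on every run.
* **Cohort shape.** The default sizes (EUP 15, LUP 30, Mesolithic 80,
  Neolithic 200, Post-Neolithic 500, Modern 250) mirror the strong
  old-to-recent imbalance of real ancient-DNA compilations with a modern
  reference panel of 250.

What the generator does **not** emulate: demographic structure (admixture,
bottlenecks, migration), linked selection, reference bias, post-mortem
damage, and genotyping-batch artifacts. Passing tests therefore demonstrate
that the statistics do what they claim under a clean generative model —
not that real-data signals are free of those confounders.

## Numerical choices and edge cases

* Pearson p-values are clamped to the smallest positive double before the
  log; signed −log10 p is capped at ±300.
* Zero-variance score or age vectors flag the fit `undefined` instead of
  erroring, so sweeps continue past degenerate cells.
* LOESS requires at least 4 points per local neighbourhood; smaller spans
  raise an error naming the minimum usable span.
* Clumping tie-break: sort key (p, chromosome, position), lexicographic on
  chromosome labels.
* The LD-score computation uses an exact pairwise-complete-observation
  Pearson r², evaluated blockwise via moment cross-products for speed; it
  matches `stats::cor(use = "pairwise.complete.obs")` to machine precision.
* The orchestrator derives per-stage seeds as `master_seed * 10 + offset`
  (documented offsets per stage), so stages are individually reproducible
  and a fixed config reproduces every output byte-identically.

## Down-sampling: what "no sign flip" can and cannot show

The post-breakpoint group is several times larger than the pre-breakpoint
group, so `downsample_consistency()` repeatedly shrinks it to the
pre-breakpoint size and checks whether the correlation sign survives. One
subtlety matters when reading the null behaviour: a down-sampled
coefficient is positively correlated with the full-data coefficient
(correlation ≈ √(n_pre/n_post), since the subsample is nested in the full
sample). Under a pure null the probability that the two agree in sign is
therefore not 1/2 but 1/2 + arcsin(√(n_pre/n_post))/π — about 0.62 at the
default cohort shape. The sign-match fraction is thus a measure of
*stability*, not a calibrated test statistic; the package reports the full
distribution of down-sampled coefficients alongside it, and any formal
claim should rest on those.

## Problem sizes used in the checks

The package's statistical checks run at deliberately desk-scale sizes,
chosen to keep Monte-Carlo error well inside the asserted margins: scoring
and clumping oracles on 100 and 1,000 random instances; selection-test
calibration on 200 neutral replicate datasets (50 trait SNPs among 5,050,
100 pseudo-haploid samples per period, 2,000 matched null sets each) with
the rejection rate required to sit in the binomial 95% band around 0.05;
power on 100 seeds at a +0.10 per-transition shift; trajectory direction on
100 seeds and null calibration on 500 replicate p-values under a
Kolmogorov–Smirnov uniformity check; down-sampling on 80 replicate null
datasets of 100 repeats each.

## Known limitations

* The absolute level of a polygenic score in ancient individuals is not
  interpretable (GWAS portability, heritability gaps); only directions of
  change within a consistently scored dataset are modelled.
* Mean imputation at 60–96% missingness shrinks individual scores toward
  the dataset mean, deflating correlation magnitudes; the trajectory
  statistics remain directionally valid but are conservative.
* The matched null conditions on MAF and local LD only; systematic
  confounders shared by trait SNPs (e.g. background selection near genes)
  are not matched away.
* The breakpoint is fixed by definition, not estimated; no change-point
  inference is performed.
* The piecewise fits treat samples as independent, ignoring genetic
  relatedness and spatial structure.
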