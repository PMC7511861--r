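---
title: "Methods: region-level methylome EWAS and the age-DMR clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level methylome EWAS and the age-DMR clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmrclock)
```

## The measurement and its container

MBD-seq measures methylation as read coverage captured by a
methyl-CpG-binding-domain protein, summarized here over non-overlapping
150-bp bins as log10 RPKM (reads per kilobase per million mapped reads,
`log_rpkm()`). Two properties of this proxy matter downstream. First, it
is a *region-level, log-scale* quantity, not a methylation fraction in
[0, 1]; all models in this package are ordinary Gaussian linear models on
that scale. Second, every per-region inference is invariant to adding a
constant to a region's values, so the log base and the pseudocount offset
(default 1, configurable) only move the absolute scale of coefficients,
never p-values or DMR calls. Neither choice is claimed to reproduce any
particular upstream pipeline; they are package conventions, exposed as
arguments.

Missing values are rejected rather than imputed: the intended input is a
bin set already filtered for adequate coverage in all samples, and the
readers enforce that contract (`read_matrix_tsv()` errors on any
non-finite cell).

## The per-region mixed model

At every bin the EWAS fits, by REML via `lme4`,

```
logRPKM ~ age + BW0 + medianLifeSpan + (1 | StrainDiet)
```

* `age` — age at tissue collection, in days, untransformed;
* `BW0` — baseline body weight in grams, measured at young adulthood
  before any diet assignment;
* `medianLifeSpan` — the strain-by-diet group's median age at natural
  death (days), taken from a parallel longevity cohort and therefore
  constant within a group;
* `(1 | StrainDiet)` — a random intercept per strain-by-diet group,
  absorbing the strong strain-level methylome structure.

Three numerical choices deserve comment.

**p-values.** `lme4` deliberately reports no fixed-effect p-values. The
package uses the Wald normal approximation, p = 2 * pnorm(-|beta/se|).
With ~69 samples and 17 groups the denominator degrees of freedom are
large enough that the normal and t references differ only in the extreme
tail, and the null-calibration tests (uniform p under planted-null
simulation) confirm the approximation is adequate at the thresholds the
pipeline uses (1e-4 and the Bonferroni line). This is an implementation
choice, documented rather than hidden.

**Shared-design acceleration.** Every region shares one fixed-effect
design; only the response changes. The scan therefore fits `lmer()` once
and reuses its factorization with `lme4::refit()` for all remaining
regions, which keeps a 10,000-region scan in minutes on one CPU without
changing any estimate (the suite asserts region-order independence).

**Non-convergence.** A region where the mixed fit fails falls back to OLS
and is flagged `converged = FALSE`, so the output always has one row per
input region; dropping rows silently would corrupt downstream tallies.
`medianLifeSpan` is group-constant and thus partially confounded with the
random intercept; the model is nonetheless fit exactly as specified, and
with few groups the LS coefficient should be read with that caveat.

DMRs are regions with trait p below a threshold: the Bonferroni line
`bonferroni_threshold(n_regions, family_alpha = 0.10)` for genome-wide
claims, and the conventional suggestive line p <= 1e-4 for
characterization, with direction = sign(beta).

## DMR characterization

Tallies (`tally_dmrs`) count directions split by genic context — genic
means carrying at least one of promoter/exon/intron/UTR; everything else
is intergenic — and variant content; percentages are always 100 * count /
total and recompute exactly from the counts. Enrichment
(`feature_enrichment`) is hypergeometric against the *retained bin set*
as background, not the whole genome: the question answered is "are DMRs
unusual among the bins actually tested?". Enrichment is the upper tail
P(X >= k), depletion the lower tail P(X <= k), reported separately. A bin
with several labels contributes to each label's contingency
independently; this is an explicit package convention since per-label
exclusive assignment is not recoverable from a label set.

## The clock

The clock is a weighted sum, not a penalized regression: with n ~ 69 no
elastic-net clock could be honestly cross-validated, and the scientific
question — do age-DMRs carry life-span-relevant rate information? — needs
only a summary of their joint movement. "Weighted average" is implemented
as the unnormalized sum S_i = sum_j beta_age_j * m_ij: with mixed-sign
weights a normalizing denominator is ill-defined, and the affine rescaling

```
DMRmAge = (S - min S) * age.range / range(S) + min.age
```

absorbs any positive rescaling of the weights or constant shift of the
sums (asserted numerically in the suite), so all positive-affine variants
of "average" produce identical DMRmAge. The scaling constants (min and
range of S, minimum age and age range) come from the training samples
only; on them, predictions span exactly [min.age, min.age + age.range],
while new samples may fall outside — that is intentional, extrapolation
is information.

Age acceleration is `residuals(lm(DMRmAge ~ age))`, with the line fitted
on the full cohort in a plain analysis and on the training split during
validation, so test-set residuals are measured against a reference the
test set never influenced. `split_validate()` draws the training subset
without replacement from the sex-filtered pool (default females, the
study's primary cohort); filtered-out samples are assigned to the test
split, generalizing the design in which the male samples were evaluated
only as test cases.

The diet contrast of acceleration is restricted to strains carrying both
diets. Whether the original comparison was paired by strain is not
determinable; Welch's unequal-variance test is the default and a
strain-paired variant is exposed (`paired_diet = TRUE`), neither claimed
to be canonical.

## The synthetic cohort

The generator exists so every stage has a ground truth. Its default
layout *is* the study design: the strain-by-diet table (12 strains, 5
with an HFD arm, 17 groups, per-group sample sizes and collection-age
ranges, group mean/SD life spans spanning ~417–933 days) is embedded as
the default `group_table`, yielding 69 samples with ages 181–759 days.
Collection ages are uniform within each group's range, so age is balanced
across life-span classes. Other defaults: 17% of bins carry variants
(mean ~2 per variant bin); CpG counts come from a two-component mixture
(island-like dense bins vs background); baseline weight is strain effect
+ 0.03 g/day * age-at-weighing + noise, with the strain effect negatively
coupled to strain mean life span; HFD adds ~15 g to final weight.

The methylome is linear-Gaussian per region:

```
m_ij = mu_j + beta_age_j * age*_i + beta_bw_j * BW0*_i
            + beta_ls_j * medLS*_g(i) + u_gj + e_ij
```

with covariates cohort-centered so that `mu_j` is both the baseline and
the observed region mean, u ~ N(0, tau^2) per group per region
(tau = 0.10) and e ~ N(0, sigma^2) (sigma = 0.15). Planted fractions are
3% age-, 2% BW0- and 1% LS-DMRs with effect scales 0.0012 per day, 0.03
per gram and 0.0012 per day of median life span; all non-DMR coefficients
are exactly zero. Direction structure mirrors the biology the pipeline
must detect: age-DMRs are hypermethylated with probability increasing in
CpG density and decreasing in baseline methylation (CpG-dense, lowly
methylated bins gain methylation with age), and BW0-DMRs are
hypomethylated with higher weight with probability 0.75.

Differential *aging rates* are planted through an effective age
multiplier, 1 + 0.5 * (mean LS - group LS)/mean LS + 0.12 * [HFD]: mice
of short-lived groups and HFD groups accumulate age-dependent methylation
faster, which is what makes acceleration correlate negatively with life
span and positively with diet downstream. Matched expression covers the
first 52 samples; each gene's transcript tracks its cognate region with a
class-specific slope sign (positive for hypermethylated age-DMRs,
negative for hypomethylated and for BW0-hypomethylated DMRs, weak random
coupling for null genes), planting the quadrant patterns the cis analysis
classifies.

Where no study value existed (variance components, effect scales, cis
strength), defaults were chosen once for realistic testability — per-region
power near 1 for age effects at n = 69, so recovery failures indicate
bugs rather than noise — and are documented here, not tuned. What the
generator does **not** emulate: read-level noise, coverage-dependent
heteroscedasticity, spatial correlation between neighboring bins,
bimodal methylation states, or sex effects (all-female by default). Tests
passing on this cohort therefore certify the statistical machinery, not
performance on any real methylome.

## Other numerical conventions

* PCA (`run_pca`) centers each region and does not scale; samples are
  observations, variance fractions are shares of total between-sample
  variance, and fractions are checked against an SVD oracle.
* Outlier flagging formalizes visual PCA inspection: a sample is flagged
  when its (PC1, PC2) distance from its strain's component-wise *median*
  centroid exceeds `k_sd` (default 6) times the cohort's median
  within-strain distance. The median centroid keeps a single gross
  outlier from dragging its own cluster center; flags are advisory only.
* The cis threshold is derived, not hard-coded: `critical_r(alpha, n)` =
  t*/sqrt(n - 2 + t*^2), which at alpha = 0.05, n = 52 gives the familiar
  |r| >= 0.27.
* Degenerate inputs fail loudly (constant correlation input, zero
  weighted-sum range, constant reference ages) or return flagged
  conventions (welch p = 1 for identical constant groups, not-applicable
  correlation rows), never silent NAs.
* Problem sizes: the test suite runs the generator at 150–3,000 regions
  and the acceptance script at the 10,000-region default with a
  1,000-region 20-seed consistency loop — sizes chosen so the full
  pipeline exercises every path in minutes on one CPU.

## Interfaces

The package is an R API: the exported functions plus the TSV
readers/writers are the pipeline surface (`simulate_study` +
`write_study`, `run_ewas` + `call_dmrs`, `tally_dmrs` /
`feature_enrichment` / `coefficient_profiles`, `run_pca` +
`pc_trait_screen` + `flag_pca_outliers`, `fit_clock` / `predict_age` /
`age_acceleration` / `clock_associations` / `split_validate`,
`pair_dmrs_to_transcripts` + `cis_correlations`), and
`scripts/acceptance.R` is the reproducibility entry point. No shell
subcommand wrapper is shipped; an analysis of this shape is driven from R
scripts, and a thin CLI would add surface without users.

## Known limitations

* Wald p-values are mildly anticonservative in very small-group settings;
  a Satterthwaite correction would require per-region `lmerTest` fits at
  roughly triple cost and is not included.
* The LS coefficient shares variance with the random intercept by
  construction; with 17 groups its effective sample size is the group
  count, not the animal count.
* The hypergeometric feature enrichment treats multi-label bins
  independently per label, which double-counts bins across categories;
  within-category p-values are exact, cross-category comparisons are not.
* The clock's affine scaling assumes the training cohort spans the age
  range of interest; a training split with a narrow age range produces a
  steep, poorly determined map.
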