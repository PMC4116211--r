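---
title: "Methods: caffeine phenotype refinement and the two-SNP instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caffeine phenotype refinement and the two-SNP instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caffscore)
```

## The problem

Single-beverage measures of caffeine intake (usually coffee) dilute the
genetic signal in populations where tea or soft drinks contribute much of
the exposure. `caffscore` builds a refined composite exposure from
longitudinal questionnaire data and evaluates a two-SNP allelic score —
rs2472297 (*CYP1A1/CYP1A2* region) and rs6968865 (*AHR* region), effect
allele T at both — as a genetic instrument for that exposure: association
across waves, variance explained, additivity checks, confounder balance and
decaffeinated-drink negative controls.

## Phenotype model

Raw records arrive per subject × wave × beverage × caffeinated flag in one
of three questionnaire formats, converted to drinks/day as:

- weekday/weekend splits (coffee, tea): day-weighted mean
  $(5\,w + 2\,e)/7$. The source questionnaires do not state a combination
  rule; the 5/7–2/7 weighting is this package's convention and the only
  convex combination whose units are literally "drinks per day".
- open weekly counts (cola, pregnancy and 2-month waves): divided by 7.
- closed frequency categories (cola, later waves): recoded to
  0, 0.5, 2, 5.5 or 7 drinks/week *first*, then divided by 7, preserving
  the two-step order of the original coding.

Daily values above a beverage-specific threshold (coffee 10, tea 15,
cola 21 drinks/day) are masked as missing. The rule is strict (`>`), so a
value exactly at the threshold is kept, and it is applied to the *derived
daily* values, after format conversion. The composite is

$$\text{caffeine (mg/day)} = 75\cdot\text{coffee} + 40\cdot\text{tea} + 34.5\cdot\text{cola},$$

missing whenever any caffeinated component is missing (complete-case per
wave, which is why every reported cell carries its own N). Whether a
missing cola report should instead count as zero is not decidable from the
source coding; `impute_zero_cola = TRUE` provides that sensitivity
analysis, off by default. Decaffeinated records flow through the same
machinery but never enter the composite.

## Genetic model

Genotypes are effect-allele (T) dosages in $[0,2]$ or hard calls in
$\{0,1,2\}$. Best-guess calling uses half-open bins
$[0,0.5)\to0$, $[0.5,1.5)\to1$, $[1.5,2]\to2$; the 0.5 convention is fixed
so calling is deterministic. Readers verify the declared effect allele
against the column suffix (dosage TSV) or REF/ALT (VCF) and refuse to flip
silently — at rs6968865 the T allele is the *major* allele (frequency 0.61,
MAF 0.39), which is exactly the situation where silent flips corrupt
downstream signs.

QC keeps a variant iff MAF ≥ 0.01, call rate ≥ 0.95 and exact HWE
p > 5×10⁻⁶, with all failing reasons reported; subjects with > 5 % missing
calls are removed before variant metrics are computed. The HWE test is the
standard two-sided exact formulation: conditional on the observed allele
counts, enumerate every compatible heterozygote count, compute each
configuration's conditional probability in closed form (log-factorials, so
counts in the tens of thousands are exact to double precision), and sum the
probabilities no greater than the observed configuration's. No mid-p
correction is applied, matching common GWAS-QC practice. Probabilities are
compared with a $1+10^{-9}$ relative cushion so that ties of equal
probability are included rather than lost to rounding.

The allelic score is $s = g_1 + g_2 \in \{0..4\}$ (unweighted, the primary
analysis) or $0.31\,g_1 + 0.26\,g_2$ with the published per-allele weights;
it is missing when either genotype is missing.

## Association and validation

All associations are ordinary least squares of phenotype on predictor via
`stats::lm`, complete-case per cell, with two-sided p-values from the t
distribution at residual degrees of freedom and no multiple-testing
adjustment (raw p-values are reported across the eight waves, as is
conventional for this design). $R^2$ is the squared sample correlation and
equals $\beta^2 \mathrm{Var}(g)/\mathrm{Var}(y)$ exactly at the fitted
$\beta$; under HWE a single SNP contributes score variance $2q(1-q)$.
Non-additivity is tested with a heterozygote indicator added to the additive
count (within-locus dominance) and with a $g_1 g_2$ product term
(between-locus epistasis).

Validation regresses each confounder on each genetic predictor one at a
time (marginal regressions, matching the tabular layout, not a joint
model), with linearity imposed on the ordinal codings — housing tenure
1–3 in the order owned → private rent → council rent, education 1–5 from
none to degree. Negative controls run the identical sweep code path on the
decaffeinated columns and annotate each cell with a `consistent_with_null`
flag (two-sided p > 0.05, uncorrected); the flag is a report annotation,
not an inferential claim.

## The synthetic cohort generator

Real data of this kind are managed-access, so the generator reproduces the
statistical structure the analysis assumes, parameterized by the published
summary rows shipped in `inst/extdata/table_scenarios.tsv` (per phenotype ×
wave: N, mean, SD, per-SNP and combined-score β):

- **Genotypes**: hard calls from HWE proportions at T frequencies 0.27 and
  0.61; an imputed variant adds Gaussian dosage noise scaled so
  $\mathrm{corr}^2(\text{dosage}, \text{call}) \approx r^2$ (0.96 for
  rs6968865), clipped to $[0,2]$. Clipping tightens the realized
  correlation by up to ~0.01, which is accepted rather than compensated.
- **Consumption**: latent value per beverage
  $y = \mu_{\text{adj}} + \beta_1 g_1 + \beta_2 g_2 + \varepsilon$,
  $\varepsilon$ normal with $\sigma$ chosen so the *marginal* SD equals the
  table SD and $\mu_{\text{adj}}$ so the marginal mean equals the table
  mean (infeasible combinations — genetic variance at or above total — are
  rejected). Coffee and tea carry their per-SNP table effects; cola and all
  decaffeinated streams carry zero genetic effect. The default noise model
  is untruncated normal so that OLS recovery targets are unbiased; a
  `censor_at_zero` option exists for realism at the cost of documented
  attenuation.
- **Rendering**: questionnaire counts cannot be negative, so rendered
  observations are the latent values censored at zero; coffee/tea are
  written as equal weekday/weekend splits (an information-free split that
  exercises the 5/7–2/7 combiner without changing the latent value), cola
  as open weekly counts early and closed categories later, discretized to
  the nearest recode value with ties broken toward the smaller category.
  Censoring means the *rendered* per-beverage means sit above the
  configured latent means (by the mass below zero, noticeable for coffee);
  marginal calibration is therefore defined, and tested, on the latent
  scale, and the regression-recovery scenarios use the latent simulator
  directly.
- **Truth table**: each record stores its uncensored latent daily value and
  the value phenotype refinement *should* produce after rendering,
  missingness and outlier injection — making the generator-to-refinement
  round trip exactly testable even in noisy configurations.
- **Confounders**: built from the *non-genetic* component of the reference
  wave's caffeine total only: latent $c = \alpha + \lambda r + e$ with
  $\lambda$ solved so that regressing the phenotype on the confounder
  recovers the configured slope at the configured confounder SD. Because
  genotype never enters, confounder balance is null-calibrated by
  construction for every configured effect size. Ordinals are cut from the
  latent scale into equal-probability levels, which attenuates their
  realized slopes; recovery is asserted for the continuous confounders.
  Default effect sizes follow the published sign pattern (socioeconomic
  measures and tobacco positive, education negative), with tobacco ≈ 7.9
  mg/day per times/day as the anchor. Continuous confounders are left
  untruncated by default for the same unbiasedness reason as the phenotype
  noise; `truncate_confounders` clamps them at zero.
- **Seeding**: one master seed; every stream (each variant, each
  wave × beverage × caffeinated-flag, each confounder) derives a labelled
  sub-seed, so adding a table never perturbs existing ones and identical
  configurations are byte-identical.

Decaffeinated consumption has no published summary rows; modest levels
(means 0.4/0.5 drinks/day for coffee/tea, 0.8 drinks/week for cola, SDs of
similar magnitude) are fixed once in `simulation_config()` as plausible for
a cohort of UK women of this era.

What the generator does *not* emulate: the right skew of real consumption
distributions (a log-normal option was considered but no distributional
parameters are published, so normal is the default), item-level
questionnaire quirks (e.g. unequal weekday/weekend reporting),
linkage-disequilibrium structure, population stratification, and
longitudinal within-subject correlation (waves are drawn independently).
Passing tests therefore demonstrate correctness of the pipeline's
arithmetic and its statistical calibration under the assumed structure, not
robustness to real-data pathologies.

## Numerical and testing choices

- Replicate-recovery runs (`scenario_recovery()`) use 200 replicate cohorts
  at the published row sample sizes (4,460 for the 145-month caffeine row,
  4,632 for tea), giving Monte-Carlo SEs near 0.16 mg on a 17 mg effect.
- Null-calibration checks use 1,000 replicates of 300 subjects; type-I
  error is compared with the 95 % binomial band around 0.05.
- HWE exactness is verified exhaustively against an independent
  conditional-multinomial oracle for every configuration with up to 20
  alleles, against a brute-force allele-placement enumeration at the
  smallest sizes, and against the 1-df chi-square approximation (within
  10 % relative) at n = 10,000.
- Degenerate regressions are contracts, not crashes: a constant response
  returns $\beta = 0$, $R^2 = 0$ with missing SE/p; a constant predictor is
  an error (a monomorphic score cannot be analysed); sweep cells that fail
  are flagged in a `note` column rather than aborting the sweep.

## Limitations

The package stops at instrument validation: it does not estimate causal
effects on outcomes, perform imputation, model ancestry or relatedness, or
include caffeine sources beyond coffee, tea and cola. The published-table
fixture encodes printed summary statistics, not individual-level data, so
simulation-based agreement with those tables is parameter *recovery*, not
replication.
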