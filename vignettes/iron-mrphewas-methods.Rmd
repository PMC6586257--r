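---
title: "Methods: phenome-wide Mendelian randomization for iron status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide Mendelian randomization for iron status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The problem and the model

Systemic iron status is clinically measured through four correlated
biomarkers — serum iron, (log10) ferritin, transferrin, and transferrin
saturation. A small number of variants in *HFE* (rs1800562, rs1799945) and
*TMPRSS6* (rs855791) associate with all four in the concordant pattern
expected of a shift in overall iron status: higher serum iron, ferritin,
and saturation, lower transferrin. Treating these variants as instruments,
two-sample Mendelian randomization asks, for every hospital-derived
phenotype in a biobank-scale cohort, what a 1 SD increase in genetically
determined serum iron does to disease odds.

For instrument $j$, let $\gamma_j$ (SE $\sigma_{\gamma j}$) be its
association with standardized serum iron and $\Gamma_j$ (SE
$\sigma_{\Gamma j}$) its log-OR for the outcome from a covariate-adjusted
logistic regression. The per-instrument (Wald/ratio) estimate and its
second-order-weight standard error are

$$
\hat\beta_j = \frac{\Gamma_j}{\gamma_j}, \qquad
\widehat{se}_j^2 = \frac{\sigma_{\Gamma j}^2}{\gamma_j^2}
  + \frac{\Gamma_j^2\,\sigma_{\gamma j}^2}{\gamma_j^4}.
$$

This is the two-term delta expansion of the ratio with zero
numerator–denominator covariance, appropriate in the two-sample setting
where exposure and outcome associations come from non-overlapping samples.
The second term matters: with instruments of moderate strength, first-order
weights understate the ratio's sampling variance. A Monte-Carlo check (part
of the test suite) confirms the formula tracks the empirical SD of simulated
ratios within 5% whenever $|\gamma_j|/\sigma_{\gamma j} > 10$.

Per-instrument estimates are pooled by fixed-effect inverse-variance
weighting, $w_j = 1/\widehat{se}_j^2$:

$$
\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j}, \qquad
se_{IVW} = \Big(\sum_j w_j\Big)^{-1/2}, \qquad
Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2 \sim \chi^2_{k-1}.
$$

A fixed-effect rather than multiplicative random-effect model is used
because only three instruments are available and heterogeneity is screened
separately: outcomes with $Q$ p-value below 0.05 are set aside as possible
pleiotropy rather than absorbed into a wider interval. Confidence intervals
use normal quantiles ($\pm 1.96\,se$); with three instruments a
t-correction would be poorly calibrated either way, and normal quantiles
match the convention of the summary-statistic MR literature.

### Weighted median

The sensitivity estimator orders $\hat\beta_j$ ascending, normalizes the
weights, places breakpoints $s_j = \sum_{k \le j} w'_k - w'_j/2$, and
linearly interpolates $(s_j, \hat\beta_j)$ at probability $0.5$; if $0.5$
falls outside $[s_1, s_k]$ the estimate clamps to the extreme instrument
(only reachable in the degenerate one-dominant-weight limit). It is
consistent when instruments carrying more than half of the weight are
valid. The SE is a parametric bootstrap: both the numerator and the
denominator of every ratio are redrawn
($\Gamma_j^\ast \sim N(\Gamma_j, \sigma_{\Gamma j})$,
$\gamma_j^\ast \sim N(\gamma_j, \sigma_{\gamma j})$), ratios and weights
recomputed, and the SD over `n_boot` (default 1,000) re-estimates taken.
When only ratio-level summaries are available, the function falls back to
redrawing $\hat\beta_j^\ast \sim N(\hat\beta_j, \widehat{se}_j)$.
Redrawing the components rather than the ratios was chosen because it
propagates denominator uncertainty through both the ordering and the
weights, which the ratio-level resample cannot.

### Phenome-wide screening

IVW p-values across all scanned phecodes enter a Benjamini–Hochberg
step-up at $q = 0.05$ *before* the heterogeneity screen: significance is
declared phenome-wide first, and significant outcomes are then split into a
consistent list ($Q$ p ≥ 0.05), which proceeds to sex-stratified and
biomarker-rescaled follow-up, and a heterogeneous-excluded list. BH rather
than Benjamini–Yekutieli is the default even though phenotypes are
correlated — BH's realized threshold arithmetic $(k/m)\,q$ is what a 19-hit,
904-phenotype scan reporting a cutoff of $1.1\times10^{-3}$ implies — but
BY is available via `fdr_method = "BY"` for arbitrary-dependence control.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `kinship_threshold` | 0.0884 | kinship coefficient | ≈ second-degree relatives; one member of each closer pair is dropped at random |
| `min_cases` | 200 | cases | below this, logistic Wald SEs and hence MR weights are unstable |
| `fdr_q` | 0.05 | rate | phenome-wide false discovery rate |
| `q_alpha` | 0.05 | level | Cochran Q p-value below which an outcome is treated as pleiotropic |
| `sd_serum_iron` | 6.1 | μmol/L | serum-iron SD in the instrument GWAS population; converts absolute effects to SD units |
| `n_boot` | 1000 | resamples | weighted-median bootstrap; SE stabilizes well below this |
| `firth` | FALSE | — | Firth penalized fits for rare outcomes prone to separation |

Instrument effects are supplied already standardized; `scale_to_sd()`
divides absolute (μmol/L) effects and SEs by `sd_serum_iron` when needed.

## The synthetic cohort generator

The generator exists so every downstream stage is testable with no data
access, and its defaults *are* the study conditions the analysis assumes:

* **Genotypes**: independent Binomial(2, EAF) dosages per SNP —
  Hardy–Weinberg equilibrium, no LD (the real instruments were verified to
  be in low LD, so none is simulated).
* **Biomarkers**: serum iron is the per-SNP genetic score plus Gaussian
  noise, with the default residual SD chosen as $\sqrt{1 - R^2}$ so the
  marginal variance is 1 SD unit; the packaged synthetic instruments are
  calibrated so the three SNPs jointly explain ≈3.8% of serum-iron
  variance. Ferritin is generated directly on the log10 scale; the three
  secondary biomarkers are fixed loadings (0.55, −0.65, 0.85) on serum
  iron plus independent noise, giving the concordant sign pattern with unit
  marginal variances. The loadings themselves are a modeling convenience,
  not estimates.
* **Phenome**: each phecode's case status is Bernoulli with logit equal to
  a prevalence-calibrated intercept plus the causal serum-iron term, any
  direct (pleiotropic) per-SNP terms, and centred age/sex effects (defaults
  0.3 per decade and 0.2, nonzero so covariate adjustment is genuinely
  exercised; set to 0 to disable). Cases emit one ICD event; events carry
  no dates because prevalent and incident cases are treated identically.
* **Relatedness**: disjoint pairs with kinship drawn uniformly from a
  configurable range, above or below the pruning threshold.
* **Covariates**: age truncated-normal (mean 56.8, SD 8, range 40–69), 54%
  female, a genotyping-array indicator, and four standard-normal PCs.

Serum iron is assumed normal in SD units — its true marginal distribution
in the target cohort is not published, and the logistic disease model only
requires the linear predictor scale to be meaningful. What passing tests on
this generator demonstrate is that the *estimator chain* is correct and
calibrated under the assumed data-generating model; they cannot speak to
real-data complications the generator omits: LD between instruments,
population stratification beyond PC adjustment, diagnostic misclassification
in hospital codes, non-random healthcare contact, or case/control
imbalance induced by exclusion ranges correlating across phecodes.

Every stochastic stage draws from a stream keyed by `(seed, stage name)`,
so a fixed master seed gives byte-identical cohorts and any single stage
can be regenerated independently of the others.

## Numerical choices and degenerate inputs

* Logistic fits use plain MLE IRLS (iteration cap 100, tolerance $10^{-8}$);
  non-convergence, rank deficiency, or suspected separation
  ($|\hat\beta| > 12$ or SE > 20) produce flagged-failure rows, never
  exceptions, so one pathological outcome cannot abort a scan. Firth's
  hat-diagonal score correction is implemented in-package for the opt-in
  penalized fit.
* Constant covariate columns (e.g. sex inside a sex stratum) are dropped
  from the design rather than treated as errors; a constant *dosage* is a
  flagged failure.
* Allele harmonization is exact: outcome effect alleles equal to the
  instrument's other allele are sign-flipped; any other configuration is a
  hard error, with no strand-flip inference (the three instruments are
  non-palindromic, so ambiguity indicates corrupted input).
* $\gamma_j = 0$ makes the ratio undefined and errors; $\sigma_{\gamma j} = 0$
  is allowed and reduces the SE to the first-order form.
* Reported p-values are floored at $10^{-300}$, never exactly zero.
* Relative pruning resolves pairs greedily in input order with a seeded
  coin flip, so chains (A–B, B–C) leave no retained pair above threshold;
  for disjoint pairs the retained count is seed-invariant while membership
  varies.
* ICD codes are matched exactly after normalization (dots stripped,
  uppercased), with no prefix truncation: truncation rules differ between
  map versions, and silent prefix matches are a larger hazard than
  unmapped-code log lines. Unmapped codes are counted and reported;
  malformed codes are skipped with a warning.
* Sex-specific phecodes are restricted only when the map supplies a `sex`
  column; otherwise both sexes are eligible.

## Design decisions that were genuinely open

* **Self-reported diagnoses** are not an input type at all; the phenome is
  defined solely by coded hospital events.
* **"Related phecodes"** for control exclusion are operationalized as a
  shared `exclusion_root` prefix, defaulting to the integer part of the
  phecode; published maps with explicit exclusion ranges are honored when
  supplied in the same column. The packaged map is a small synthetic
  stand-in for testing, not a vendored copy of any published map.
* **FDR before heterogeneity**: outcomes are flagged phenome-wide first and
  screened by Q second; the alternative (screen first) changes the
  multiplicity base in a way that the realized-threshold arithmetic of a
  19-in-904 scan contradicts.
* **Power is advisory only**: an approximate normal-approximation power
  column (given case/control counts and instrument $R^2 \approx 0.038$) is
  attached to results but never filters them; the ≥200-case rule is the
  only gate.
* **Sex-stratified and biomarker-rescaled analyses** run only for the
  FDR-significant homogeneous outcomes, bounding compute on large scans.
  In stratified runs the sex covariate is dropped and the case filter
  re-applied within stratum.

## Problem sizes used in validation

The packaged validation suite runs the estimator checks at the sizes the
statistics require rather than the largest sizes the model allows:
genotype/biomarker calibration at $n = 10^5$; null-fit calibration over 600
replicate regressions of $n = 10^3$; parameter recovery (causal OR 0.72,
prevalence 5%) over 200 replicate cohorts of $n = 10^5$, where the IVW CI
covers the truth in 96% of replicates; and a global-null phenome of 500
phecodes at $n = 4{,}000$, where IVW p-values pass a Kolmogorov–Smirnov
uniformity check, the Cochran Q type-I error rate sits inside binomial
bounds of 0.05, and BH flags nothing. The acceptance script re-estimates
the headline odds ratios from four replicate cohorts at the full study
scale of 424,439 participants.

## Known limitations

* The instrument table shipped with the package is synthetic; real analyses
  must substitute published consortium estimates.
* The weighted median bootstrap resamples parametrically; with three
  instruments a nonparametric resample is degenerate, but the parametric SE
  inherits the normality of the input summary statistics.
* Relatedness is handled by pruning, not by mixed models; residual cryptic
  relatedness below the threshold is ignored.
* The generator's phecode events are single-code emissions; it does not
  model multi-code episodes, code version drift, or exclusion-range overlap
  between scenario phecodes beyond what the map encodes.
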