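---
title: "Methods: summary-statistics MR, drug-target proxies, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR, drug-target proxies, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the design
choices made where conventions genuinely diverge.

## The instrumental-variable model

Two-sample MR treats per-variant GWAS associations as instrumental
variables. For variant $i$, let $\gamma_i$ be its true effect on the
exposure (here, blood pressure in mmHg) and $\alpha_i$ its direct
("horizontally pleiotropic") effect on the outcome (residual age at onset,
in years). The observed summary statistics are modelled as

$$\hat\beta_{x,i} \sim N(\gamma_i,\ \sigma_{x,i}^2), \qquad
  \hat\beta_{y,i} \sim N(\beta\,\gamma_i + \alpha_i,\ \sigma_{y,i}^2),$$

with $\beta$ the causal effect of interest. A variant is a *valid*
instrument when it is (1) associated with the exposure, (2) independent of
confounders, and (3) affects the outcome only through the exposure
($\alpha_i = 0$). The workflow enforces (1) by the significance and
F-statistic filters, screens (2) against a local confounder lookup table,
and probes (3) with the Egger intercept, Cochran's Q and MR-PRESSO.

## Instrument selection

The genome-wide pipeline runs, in a fixed order: significance filter
(p < 5×10⁻⁸, strict), greedy LD clumping, confounder screen (removal at
p < 5×10⁻⁸ with any listed confounder), and weak-instrument filter
(F = β²/se² < 10 removed; F = 10 exactly is kept). Clumping repeatedly
takes the remaining variant with the smallest p-value as index and discards
remaining variants on the same chromosome within 10,000 kb
(centre-to-centre) whose r² with the index reaches the threshold (0.001).
Ties on p-value break by (chromosome, position, id) so output is
deterministic. The LD reference is a sparse long-format table; a pair
listed gets its value, a pair whose two variants the panel covers but does
not list counts as r² = 0, and a pair involving a variant the panel does
not know is *unknowable* — inside the window it is treated as r² = 1 and
discarded, because clumping must never retain a pair whose LD cannot be
established.

Drug-target ("cis") instruments come from a different funnel: variants
falling inside a class's annotated gene bodies or regulatory intervals
(1-based inclusive containment; BED input is converted from 0-based
half-open exactly once, at the file boundary), significance-filtered, then
pruned with the same greedy rule but *without* the distance window —
every pair in the compact region is checked — at a deliberately lenient
r² < 0.4, with r² < 0.2 as a stricter sensitivity analysis. Lenient
pruning trades correlated instruments for variance explained, which is the
standard compromise when a single gene region offers few independent
signals. The shipped gene lists (ACE for ACEI, ADRB1 for BB, L-type
calcium-channel subunits for CCB) are illustrative fixtures: region
definitions are user input, not package constants. Instruments are then
oriented so the recorded effect allele is the SBP-*lowering* allele
(β ≤ 0 after orientation; β = 0 variants carry no direction and are
excluded). Orientation is pure bookkeeping — Wald-ratio magnitudes are
unchanged — but it makes the "per 10 mmHg decrease" scaling unambiguous.

## Harmonization

Exposure and outcome files may encode the same variant differently:
alleles swapped (β sign and allele frequency complementary), reported on
opposite strands, or both. Non-palindromic variants are aligned
mechanically (swap ⇒ negate β, complement EAF; strand mismatch ⇒ relabel).
Palindromic variants (A/T, C/G) cannot be strand-resolved from alleles, so
alignment falls back on allele frequency: the orientation making the two
EAFs agree is chosen, and variants whose EAF lies within ±0.08 of 0.5 *on
either side* (or is missing) are dropped as unresolvable. The 0.08
half-width is the convention of the summary-statistics MR software
ecosystem and is exposed as `af_window`. Three invariants are enforced by
tests: re-encoding the outcome on the opposite strand changes nothing
(double-flip invariance), harmonizing an already-harmonized pair is the
identity, and every intersected SNP is accounted for as retained, dropped
palindromic, or irreconcilable.

## Estimators and diagnostics

All estimators consume the harmonized per-SNP effect pairs; every estimate
carries a normal-approximation 95% CI (half-width 1.959964 se) and a
two-sided normal p-value.

* **IVW** is the primary estimator. The random-effects form inflates the
  fixed-effect SE by $\max(1, \sqrt{Q/(n-1)})$: over-dispersion widens
  intervals, under-dispersion never narrows them. This multiplicative
  convention (rather than an additive random-effects variance) matches the
  dominant summary-MR software.
* **MR-Egger** frees the intercept; instruments are first flipped so all
  exposure effects are positive (the model is invariant to joint sign
  flips, and the intercept is only interpretable in that orientation).
  Slope and intercept SEs use the same multiplicative inflation with
  $Q/(n-2)$. Whether to inflate the Egger SE at all varies between
  implementations; inflation is the default here and the null calibration
  of the intercept test is verified by simulation (type-I error ≈ 4–5% at
  α = 0.05, slightly conservative because of the max(1,·) floor).
* **Weighted median** interpolates the ratio at 50% of cumulative
  midpoint-adjusted inverse-variance weight. Its SE is a parametric
  bootstrap (resampling $\hat\beta_x$, $\hat\beta_y$ from their reported
  normals), seeded, default 1000 replicates, summarised by the bootstrap
  standard deviation.
* **Modes** maximise the kernel density of the ratios (equal weights /
  inverse-variance weights) with bandwidth = `bandwidth_factor` × the
  modified Silverman rule $0.9\,\min(\mathrm{sd},\mathrm{mad})\,n^{-1/5}$;
  all-identical ratios short-circuit to that value.
* **Cochran's Q** uses the fixed-effect fit (zero-intercept for IVW,
  free-intercept for Egger) with df $n-1$ / $n-2$ and an upper-tail
  chi-square p.
* **MR-PRESSO** compares the observed weighted leave-one-out residual sum
  of squares with its parametric null distribution ($n_\text{sim}$ = 1000
  by default). Empirical p-values use the $(1+\#\{ \text{sim} \ge
  \text{obs}\})/(1+n_\text{sim})$ estimator, so they are never exactly
  zero — and their resolution bounds what the Bonferroni outlier test can
  flag: with $n$ instruments an outlier is only detectable when
  $n_\text{sim} > n/\alpha$. The distortion test compares the
  with/without-outliers estimate change against removals of random
  same-size subsets; the original method's resampling scheme is not
  uniquely documented, so this transparent variant is used and seeded.
* **Multivariable IVW** regresses outcome effects on the exposure-effect
  matrix (weights $1/\sigma_y^2$), inflating SEs by
  $\max(1,\sqrt{Q/(n-k)})$. The instrument set is the union of the
  exposures' univariable instruments, harmonized to the first exposure's
  allele coding — the dominant convention, since the source analyses do
  not document theirs. An exposure column that is identically zero is
  unidentified and reported as NA rather than poisoning the fit;
  conditional F-statistics are attached as a diagnostic only.

Scaling multiplies β, SE and CI by the chosen factor (+10 mmHg SBP,
+5 mmHg DBP, −10 mmHg for drug classes); p-values are scale-invariant.
Significance uses Bonferroni α = 0.05/2 for the two BP indices and 0.05/3
for the three drug classes.

## The synthetic study

`generate_two_sample()` draws, per variant: an EAF (Beta(2,2) truncated to
[0.05, 0.95]); per-sample standard errors from the GWAS approximation
$\mathrm{se} = \mathrm{SD}/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})N}$ with
$N_x = 757{,}601$ and $N_y = 9{,}064$; true effects $\gamma_i$ scaled so
the panel jointly explains the target variance (default 1.6%, giving
per-SNP F in the realistic 20–120 range at the default panel sizes);
observed effects from the IV model above, with pleiotropy off, balanced,
or directional on an invalid set chosen to carry a configurable share of
total instrument weight; optional outliers displaced by 10 outcome SEs;
allele pairs with a configurable palindromic fraction; and an outcome copy
re-encoded by allele swaps and strand scrambling so harmonization is
genuinely exercised. LD blocks are emitted consistently with the physical
layout (blocks separated by more than the clumping window), and drug-class
scenarios plant cis regions whose variants get their own causal slope and
a strength multiplier (target-gene proxies are, by construction of the
real funnels, preselected strong signals). `generate_multi_exposure()`
produces two exposures with correlated true effects (default r = 0.5)
for the multivariable analysis. A single integer seed drives everything;
identical seeds give bit-identical data.

Two calibration choices deserve explanation. Exposure-side conditions
(sample size, trait SDs 21.5/11.4 mmHg, ~450 instruments, 1.59%/1.71%
variance explained) are taken directly from the emulated study. The
outcome phenotype SD is not reported anywhere; the default (0.5 years) is
back-derived from the reported interval widths — given 9,064 patients and
instruments explaining ~1.6% of exposure variance, only per-SNP outcome
SEs of ≈0.007 years reproduce confidence intervals of the published width.
The generator therefore reproduces the *precision structure* of the
emulated analysis rather than a literal phenotype SD.

What the generator does **not** emulate: LD-induced correlation between
observed effect sizes (LD lives only in the reference used for clumping;
effects are drawn independently), winner's-curse-free instrument lists
(selection on observed significance attenuates downstream estimates
slightly, visible as ~1–3% attenuation in end-to-end runs; the recovery
simulations therefore instrument directly, as the validation criteria
specify), population stratification, sample overlap between the two GWAS,
and genome-scale variant counts. Passing tests consequently demonstrate
the estimators' statistical behaviour under the stated generative model,
not robustness to these real-data complications.

## Numerical choices and degenerate inputs

Problem sizes in the tests and the acceptance script are chosen to give
stable Monte-Carlo answers at desk scale: 1000 replicates for null
calibration and recovery (bias, coverage), 200–400 for power and
robustness checks, MR-PRESSO with 300–1000 parametric draws depending on
whether a p-value or an outlier flag is needed. Ties in the weighted
median interpolate linearly; clumping ties break lexicographically;
`max(1e-8, ·)` floors the kernel bandwidth; duplicate SNPs on file read
keep the smallest p-value; multi-base alleles are rejected at the boundary
(palindromy is undefined for them); a single-instrument class falls back
to the Wald ratio with a warning; an empty class reports no estimate row.
Empirical p-values are floored by the +1 correction. All bootstrap and
simulation functions take an explicit seed and restore the caller's RNG
state.

## Known limitations

Correlated cis instruments are passed to the standard estimators exactly
as the emulated workflow does; the report annotates proxy counts per LD
threshold, but no generalized (LD-aware) weighting is applied. No Steiger
filtering, proxy-SNP substitution, leave-one-out scans, or MVMR-Egger are
implemented — they are outside the emulated analysis. The Egger intercept
test's slight conservatism under the SE-inflation floor is documented
above and quantified in the test suite rather than corrected, matching
ecosystem behaviour.
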