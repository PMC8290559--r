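---
title: "Methods: exposome-wide two-sample MR screening with exposomeMR"
author: "exposomeMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposome-wide two-sample MR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposomeMR)
```

## The problem and the model

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to test whether an exposure causally affects an
outcome, using only GWAS summary statistics from two non-overlapping
samples. `exposomeMR` scales this design up to a *screen*: hundreds to
thousands of candidate exposures tested against a binary outcome —
the motivating application is survival past the 90th or 99th
percentile age ("longevity") — with multiplicity control, pleiotropy
diagnostics, and a validation stage.

For exposure $X$ and outcome $Y$, instrument $j$ carries an exposure
association $\hat\beta_{Xj}$ (per SD of $X$) with standard error
$se_{Xj}$, and an outcome association $\hat\beta_{Yj}$ (log odds
ratio) with $se_{Yj}$. Under the instrumental-variable assumptions
(relevance, independence from confounders, exclusion restriction), each
Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
causal effect $\theta$, the log OR per SD increase in the exposure.

The estimators implemented are:

* **IVW** (principal): the inverse-variance-weighted mean of the Wald
  ratios, equivalently weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ through the origin with weights $1/se_{Yj}^2$.
  The reported standard error uses multiplicative random effects
  floored at the fixed-effect value,
  $se = se_{\mathrm{fixed}} \max\{1, \sqrt{Q/(J-1)}\}$, with a normal
  p-value. This matches the default behaviour of the widely used
  summary-MR tooling; the floor prevents heterogeneity from ever
  *shrinking* the nominal uncertainty.
* **Cochran's Q** on the Wald ratios, $J-1$ df, as the heterogeneity
  diagnostic.
* **MR-Egger**: weighted regression *with* an intercept after orienting
  all instruments to non-negative exposure effects. The slope is a
  pleiotropy-robust estimate under the InSIDE assumption; the intercept
  estimates average directional pleiotropy and is used as a pleiotropy
  test. SEs are inflated by $\max(1, \hat\sigma)$ and p-values are
  two-sided $t$ on $J-2$ df.
* **Weighted median**: consistent while valid instruments carry more
  than half the weight. The estimate interpolates the ordered ratios at
  the midpoint of the cumulative normalized weights; its SE is a
  parametric bootstrap (default 1000 replicates, explicit seed)
  redrawing both beta vectors from their sampling distributions. The
  bootstrap was chosen over analytic approximations because it needs no
  extra assumptions and its determinism is guaranteed by the seed
  contract.
* **Multivariable MR**: weighted no-intercept regression of
  $\hat\beta_{Yj}$ on a $J \times K$ matrix of exposure betas, giving
  conditional (direct) effects — used in the validation stage to
  untangle genetically correlated exposures such as the lipid
  fractions (LDL-C, HDL-C, triglycerides), whose instrument sets
  overlap. With $K = 1$ it reproduces the IVW point estimate.
* **MR-PRESSO**: see below.

### Binary exposures analyzed on the linear scale

Large biobank GWAS pipelines often analyze binary traits with a linear
(mixed) model. Such betas live on the 0/1 scale and are converted to
log odds ratios by $\log OR = \beta / (\mu(1-\mu))$, where $\mu$ is the
case fraction; SEs are divided by the same factor. The transformation
is a positive rescaling, so z-scores and p-values are unchanged — a
property the test suite checks to $10^{-12}$. The screen applies it to
every `binary_linear` exposure before estimation; instrument *selection*
happens on the raw scale, which is equivalent because the p-values are
invariant.

## Instrument selection and diagnostics

Candidate instruments require association $p < 5\times10^{-8}$ (strict)
and minor allele frequency $> 0.01$ (strict). Greedy clumping then
prunes them to pairwise $r^2 < 0.001$, always keeping the
smallest-p-value variant of a correlated cluster (p-value ties broken
by lexicographic snp id, so the output is order-invariant). The LD
matrix is supplied by the user (or by the simulator); when absent, the
screen assumes pairwise independence and says so loudly — appropriate
only for pre-pruned instrument sets.

Exposures are screened out when (i) a categorical exposure has fewer
than 250 cases, (ii) fewer than 3 independent genome-wide-significant
instruments remain after clumping, or (iii) the trait id duplicates an
earlier exposure (exact-match rule; the artifact does not attempt fuzzy
de-duplication).

Instrument strength is summarized by
$R^2 = \sum_j 2 p_j (1-p_j) \beta_j^2$ (per-SD betas on a standardized
trait — validated against individual-level regression in the tests) and
$F = \frac{n-k-1}{k}\,\frac{R^2}{1-R^2}$, with $F > 10$ (strict) the
conventional strong-instrument flag. Because it is ambiguous whether a
joint or a mean per-SNP F is the more informative summary, both are
reported (`f_stat`, `f_mean_per_snp`), the joint value being primary.
For binary-linear exposures the per-SD scale for $R^2$ is obtained by
dividing betas by $\sqrt{\mu(1-\mu)}$.

Statistical power for a binary outcome uses the normal-approximation
closed form
$\Phi\!\big(\sqrt{n\,R^2\,\mu(1-\mu)}\,|\log OR| - z_{1-\alpha/2}\big)$
at $\alpha = 0.05$; at $OR = 1$ it correctly degenerates to
$\alpha/2$. The hypothesized OR enters through the configuration field
`orHyp` (default 0.8, a moderate protective effect of the size the
screen is designed to detect); the formula is verified against a
Monte-Carlo IVW rejection oracle in the tests.

## Harmonization

Exposure and outcome records are matched by snp id only (positions are
informational). For each instrument the outcome row is aligned to the
exposure's effect allele:

* same orientation → kept directly;
* swapped alleles → outcome beta negated, frequency reflected;
* alleles matching only after strand complementation → complemented,
  then the two rules above;
* palindromic (A/T, C/G) variants: labels cannot resolve strand, so
  allele frequency must. If the exposure MAF exceeds 0.42 — too close
  to 0.5 to be informative — the variant is dropped; likewise if either
  frequency is missing. Otherwise the outcome is oriented so both
  frequencies fall on the same side of 0.5 and kept only when
  $|eaf_X - eaf_Y| < 0.2$ after orientation. The 0.2 concordance
  tolerance is a package decision (configurable); it guards against
  population mismatch, for which no standard cut-off exists;
* absent or irreconcilable records are dropped.

Every candidate instrument receives exactly one action-log entry, and
the kept set is provably invariant (to $10^{-12}$) under allele-swapped
or strand-complemented re-encodings of the outcome file. Duplicate
outcome rows for one snp id keep the smallest-SE row, for determinism.

## MR-PRESSO

The global test asks whether the instruments' residual dispersion
around the fitted causal line exceeds what their SEs allow. For each
instrument the leave-one-out IVW estimate $\hat\theta_{(-j)}$ defines a
standardized residual
$r_j = (\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})/se_{Yj}$, and
$RSS_{obs} = \sum_j r_j^2$. The null distribution is obtained by
parametric bootstrap from the fitted common causal line: replicates
redraw $\beta^*_{Xj} \sim N(\hat\beta_{Xj}, se_{Xj}^2)$ and
$\beta^*_{Yj} \sim N(\hat\theta\,\hat\beta_{Xj}, se_{Yj}^2)$ with
$\hat\theta$ the full-sample IVW estimate, and the *entire* leave-one-out
statistic is recomputed on each replicate. Recomputing matters: the
observed residuals carry leave-one-out estimation noise, and a null
that omits it rejects at roughly double the nominal rate, while
simulating around the per-SNP leave-one-out estimates (which carry
SNP-specific noise a refit cannot absorb) is markedly conservative.
The common-line bootstrap measures a 3–5% rejection rate at nominal 5%
in the package's null calibration runs.

Empirical p-values use the add-one rule, so they are never below
$1/(n_{sim}+1)$; per-SNP outlier p-values are Bonferroni-adjusted by
$J$, and instruments with adjusted $p < 0.05$ are removed to form the
`presso_corrected` IVW estimate. Note the arithmetic consequence of
the add-one rule: with $J$ instruments the smallest achievable adjusted
p-value is $J/(n_{sim}+1)$, so detecting outliers among 30 instruments
requires $n_{sim} \ge 600$; the default is 1000. Simulation draws use
one seeded substream per snp id, making outlier calls reproducible and
order-invariant. The distortion test is not implemented; the corrected
estimate is always emitted alongside the raw one, and the combination
"outliers found, global test non-significant" is reported rather than
suppressed.

## The screen

`runScreen()` executes, per exposure × outcome: eligibility →
selection → clumping → transformation → harmonization → IVW + Q →
Egger ($J \ge 3$) → weighted median ($J \ge 3$) → MR-PRESSO
($J \ge 4$) → diagnostics. IVW p-values are then Benjamini–Hochberg
adjusted *within each outcome separately* (mirroring a design whose
primary and secondary analyses cover different exposure sets); an
exposure is `significant` at $q < 0.05$, `suggestive` at raw
$p < 0.05$, `null` otherwise. Concordance is sign agreement of the
point estimates across IVW, weighted median and the Egger slope, with
the PRESSO-corrected estimate replacing raw IVW when outliers were
removed, and a zero estimate counting as discordant. Excluded
exposures appear in the output with machine-readable reasons. Every
stochastic step draws its seed from a named substream of the master
seed (exposure id × outcome × method), so any single record can be
reproduced in isolation and two runs are byte-identical.

`mergeValidation()` encodes the component-of-the-exposome decision
rule, in precedence order: a validation-significant exposure is a
component; a validation-null exposure with power $\ge 0.8$ is excluded
(the 0.8 threshold follows the convention that a null result is only
evidence of absence when power was high); an exposure significant or
suggestive for *both* outcomes with concordant estimators is a
component flagged `unvalidated`; anything else inherits its screen
status. The exclusion check deliberately precedes the both-outcomes
clause: a high-powered independent null overrides internal robustness.

## The synthetic-data generator

`simulatePair()` makes the two-sample MR assumption structure
generative: instrument effects $\gamma_j$ are half-normal
$|N(0, \sigma_\gamma^2)|$ truncated at $2 se_X$ (instruments coded to
the exposure-increasing allele, the natural orientation after
genome-wide selection — this is also the frame in which "directional"
pleiotropy is well defined); observed betas add sampling noise;
pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ is balanced,
directional, InSIDE-violating (correlation 0.7 with $\gamma_j$), or
planted on named instruments; outcome betas are
$N(\theta\gamma_j + \alpha_j, se_Y^2)$. Defaults emulate the motivating
study's scale: exposure GWAS of $n = 361{,}194$ with per-SNP
$se_X = 0.003$; primary outcome of 11,262 + 25,483 case/control with
$se_Y = 0.01$; secondary outcome of 3,484 cases with $se_Y$ scaled by
the effective-sample-size ratio ($\approx 1.6$). $\sigma_\gamma = 0.03$
was chosen so that 30 instruments explain about 1.2% of exposure
variance (typical of behavioural/anthropometric biobank traits), per-SNP
F is far above 10, and essentially all drawn instruments clear
$p < 5\times10^{-8}$ — avoiding any winner's-curse modelling, which the
pipeline does not attempt. `simulateExposome()` builds a whole screen
input: independent exposures, an exactly-counted causal subset with
$|\log OR| = 0.35$ effects by default, shared outcome datasets, and a
truth table for scoring. LD is identity by default (instruments emulate
post-clumping data); `simulateLDBlocks()` exists to exercise the
clumping algorithm itself.

What the generator does *not* emulate — and therefore what passing
calibration says nothing about: real LD beyond block toys, selection
("winner's curse") in instrument discovery, sample overlap between the
two GWAS, population stratification, frequency mismatch between
cohorts, and the real correlation structure among biobank exposures.
Empirical FDR control in the synthetic exposome relies on exposure
independence; correlated exposures in real data make BH conservative
in some regimes and is untested here.

## Numerical choices and degenerate inputs

* p-values of 0 in input files are clipped to $10^{-300}$; indels,
  multi-allelic and non-ACGT rows are excluded at read time.
* Instruments with $\beta_X = 0$ are rejected by the ratio layer with
  the offending snp named.
* The Egger and MVMR layers raise explicit collinearity errors
  (identical oriented betas, rank-deficient exposure matrices).
* Estimator preconditions: IVW $J \ge 2$, Egger/weighted median
  $J \ge 3$, PRESSO $J \ge 4$, MVMR $J > K$.
* TSV writers render doubles with 17 significant digits so re-reading
  is bit-exact; readers validate all container invariants and count
  dropped rows by reason.
* The R² estimate is capped just below 1 so the F formula stays finite.

## Problem sizes in the bundled checks

The test suite and the acceptance script recompute every calibration
claim at sizes chosen to keep Monte-Carlo error small relative to the
tested margins: 100 random instances for closed-form oracle agreement;
500 replicates for IVW bias/coverage at $\theta = \log 0.7$, $J = 30$;
1000 replicates for Egger intercept size; 200 for weighted-median
robustness under 40% invalid instruments (pleiotropy $10\,se_Y$, the
same magnitude as the planted-outlier convention); 100 × $n_{sim}=1000$
for PRESSO detection and 500 × $n_{sim}=500$ for its null size; 200
exposures × 2 outcomes × 5 seeds for the null and causal exposome
screens.

## Known limitations

* No proxy-SNP lookup, no Steiger filtering, no mode-based estimators,
  no SIMEX/I²GX weak-instrument correction for Egger.
* The weighted-median SE is bootstrap-only; no analytic fallback.
* `exposureEligible`'s duplicate rule is exact-id; real catalogs need
  curation upstream.
* Ordinal exposures are treated as generic per-SD quantitative traits;
  their causal effects inherit whatever scale ambiguity the source GWAS
  had.
* The concordance rule is sign agreement only; it does not compare
  magnitudes.
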