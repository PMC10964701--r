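---
title: "Triangulating genetic evidence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating genetic evidence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triangulateMR)
```

## The problem

A significant two-sample Mendelian randomization (MR) result is not, by
itself, strong evidence that an exposure causes an outcome: horizontal
pleiotropy, weak instruments, and linkage between distinct causal variants
can all manufacture or distort MR signals. This package triangulates three
complementary lines of genetic evidence, each with different failure modes:

1. **Genetic correlation** (bivariate LD-score regression, LDSC): genome-wide
   sharing of genetic effects, robust to sample overlap but silent on
   causal direction.
2. **Two-sample MR**: a causal-effect estimate from genetic instruments,
   valid only under the instrumental-variable assumptions, so it travels
   with a full sensitivity suite.
3. **Bayesian colocalization**: whether the two traits plausibly share the
   *same* causal variant in each instrument region, which distinguishes a
   shared mechanism from two distinct signals in linkage disequilibrium.

A deterministic decision table maps the three outcomes (with MR and LDSC
signed, colocalization unsigned) onto ten patterns and nine graded
explanations, from "strong genetic evidence for a causal association"
(everything concordant) through "possible false positive" (MR alone) down
to "no genetic evidence".

## MR estimators

All estimators consume harmonized per-variant pairs (exposure and outcome
effects on the same effect allele). With exposure effect $\hat\gamma_j$,
outcome effect $\hat\Gamma_j$ and outcome SE $\sigma_{Y j}$, the Wald
ratio is $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order SE
$\sigma_{Y j}/|\hat\gamma_j|$. The division of labour is conventional:
the first-order SE ignores exposure-side noise for IVW, the medians and
Egger; MR-RAPS is the estimator in the suite that models it explicitly.

- **IVW (primary)**: precision-weighted mean of the ratios, equivalently a
  weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin.
  The multiplicative random-effects SE scales the fixed-effect SE by
  $\sqrt{\max(1, Q/(m-1))}$ with $Q$ Cochran's statistic, so it never
  undercuts the fixed-effect SE.
- **MR-Egger**: the same regression with a free intercept after orienting
  all exposure effects non-negative; the intercept estimates directional
  pleiotropy, the slope the causal effect, and both SEs carry the
  $\sqrt{\max(1, Q'/(m-2))}$ inflation.
- **Weighted / penalized weighted median**: the 50% weighted percentile of
  the ratios (consistent while valid instruments hold a weight majority).
  Penalization multiplies each weight by
  $\min(1, 20\, q_j)$ with $q_j$ the upper-tail $\chi^2_1$ probability of
  the variant's $Q$ contribution. The SE comes from a parametric bootstrap
  *centered at the fitted estimate*: centering at the observed ratios
  would add their dispersion a second time and measurably overstates the
  SE of an order statistic (we observed ~16% inflation and type-I error
  of 0.017 instead of 0.05 under the null).
- **MR-PRESSO**: leave-one-out residual sum of squares against a
  parametric null; the per-variant outlier test is Bonferroni-corrected,
  and when the global test is significant the headline estimate is IVW on
  the outlier-free set (the raw estimate and a distortion-test p-value are
  retained). The attainable minimum p-value is $1/(n_{\text{sim}}+1)$, and
  the function warns when `n_sim` cannot resolve the Bonferroni threshold.
- **MR-RAPS**: solves the profile score
  $\sum_j \psi(t_j)\, \partial t_j/\partial\beta = 0$ with
  $t_j = (\hat\Gamma_j - \beta\hat\gamma_j) /
  \sqrt{\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2 + \tau^2}$; $\tau^2$
  (systematic pleiotropy) is moment-matched when overdispersion is
  enabled, $\psi$ is identity or Huber (c = 1.345), the root is bracketed
  from the median ratio and found with `uniroot` at $10^{-12}$ tolerance,
  and the SE is the profile-score sandwich. With zero exposure SEs and
  $\tau^2 = 0$ it reduces exactly to fixed-effect IVW, which the tests
  assert.
- **Steiger directionality**: compares
  $r^2 = \sum_j 2\,\text{EAF}_j(1-\text{EAF}_j)\hat\beta_j^2$ between
  exposure and outcome through Fisher-transformed correlations. For
  binary traits the same formula is applied on the log-odds scale — a
  documented approximation, not a liability-scale conversion.
- **MVMR**: outcome effects regressed on the matrix of exposure effects
  (no intercept, outcome-precision weights) over the jointly clumped
  union of per-exposure significant variants; conditional
  instrument-strength F statistics residualize each exposure on the
  others.

Significance for every MR call is the nominal 0.05 with no
multiple-testing correction, matching the framework's "suggestive
evidence" convention.

## Instruments

Selection keeps variants with $p < 5\times10^{-8}$ and greedily clumps at
LD $r^2 < 0.001$ within a 10,000 kb window, ranking by p-value with ties
broken by variant id so the output is order-invariant. Per-variant
strength uses $R^2 = 2\,\text{EAF}(1-\text{EAF})\,\beta^2$ and
$F = \beta^2/\text{SE}^2$, summed across the set; $F \le 10$ (minimum or
mean) raises a weak-instrument flag but never auto-filters, because the
rule is descriptive. Summed $R^2$ can arithmetically exceed 100% for
unstandardized betas; the package surfaces this as a warning rather than
silently rescaling. The confounder filter removes instruments annotated
to a configurable confounder-trait list (adiposity, smoking, alcohol,
sleep, mood, activity) at proxy $r^2 \ge 0.8$ and $p \le 5\times10^{-8}$,
emulating a PhenoScanner-style lookup with a local annotation table.

## LD-score regression

Per-trait heritability comes from the weighted regression
$E[z_j^2] = 1 + N h^2 \ell_j / M$ (free intercept), the genetic
covariance from $E[z_{1j} z_{2j}] = b_0 + \sqrt{N_1 N_2}\,\rho_g \ell_j / M$,
and $r_g = \rho_g/\sqrt{h^2_1 h^2_2}$. The covariance intercept $b_0$ is
always free, absorbing sample overlap instead of assuming it away.
Weighting is two-step: an unweighted pass gives provisional
heritabilities, and the final regressions use heteroskedasticity weights
$1/(1+N h^2 \ell/M)^2$ (their product for the covariance regression).
Building all three final regressions from the *same* provisional
estimates makes $r_g(\text{trait}, \text{itself}) = 1$ hold exactly, a
degenerate case the tests pin down. Standard errors are delete-a-block
jackknives over contiguous variant blocks (default 200; the simulation
studies use fewer for small panels). When either heritability estimate is
non-positive — or, optionally, within `h2_z_floor` jackknife SEs of zero —
the genetic correlation is reported as unavailable
(`na_low_heritability`), the same NA behaviour real low-heritability
traits produce. Estimates slightly outside $[-1, 1]$ are legitimate
estimator overshoot; beyond $\pm 1.25$ a warning fires and truncation is
opt-in.

## Colocalization

Each per-variant association contributes a Wakefield approximate log
Bayes factor $\tfrac12\log\frac{V}{V+W} + \tfrac12 z^2 \frac{W}{V+W}$
($V$ the squared SE, $W$ the squared prior effect SD, default 0.2 on the
log-odds scale). Region-level evidence for the five hypotheses (no causal
variant; trait-1 only; trait-2 only; two distinct; one shared) combines
per-variant factors by configuration sums with priors $p_1 = p_2 =
10^{-4}$, $p_{12} = 10^{-5}$ — the field's convention, echoed in every
report since the framework's call depends on them. All hypothesis
arithmetic runs in log space with log-sum-exp, because Bayes factors
overflow doubles near $|z| \gtrsim 40$. One region is built per
instrument (±500 kb); overlapping windows are deliberately *not* merged,
and the final call averages PPH4 across regions against a 0.75
threshold. This mean-PPH4 aggregate is unconventional — a single strongly
colocalizing locus can be diluted, and overlapping windows double-count —
so the per-region table is always emitted for inspection.

## Power

For a binary outcome the two-sided Wald test of the causal log odds
ratio has non-centrality
$\lambda = N\,\text{cf}(1-\text{cf})\,R^2_{XZ}\,\log(\text{OR})^2$ and
power $\Phi(-z_{1-\alpha/2}+\sqrt\lambda) + \Phi(-z_{1-\alpha/2}-\sqrt\lambda)$.
Because only the calculator tool is named by convention, correctness is
defined against a Monte-Carlo oracle: simulating the full two-sample
pipeline at the same parameters must reproduce the closed form (observed
agreement within 0.01 at power ≈ 0.64).

## The synthetic-data generators

The generators define the study conditions; they are not tuning knobs.

- **LD panels** are block-diagonal AR(1) correlation matrices (within a
  block $r_{ij} = \rho^{|i-j|}$, zero across blocks), positive
  semi-definite by construction, with uniform MAFs.
- **MR datasets** place each instrument in its own block (the
  independence assumption holds by construction; block mates carry
  LD-propagated marginal effects so clumping has something to prune).
  Instrument effects have magnitude uniform in `scale * [0.5, 1.5]` with
  random sign — bounded away from zero so Wald ratios stay stable, and
  yielding per-variant F statistics of roughly 50–500 at the default
  30–50 instruments and n = 50,000, the instrument-strength regime of
  consortium GWAS. Summary-statistic SEs use the standard
  $1/\sqrt{2\,\text{maf}(1-\text{maf})\,n}$ approximation, times
  $1/\sqrt{\text{cf}(1-\text{cf})}$ for binary traits on the log-odds
  scale. Directional pleiotropy is applied on the exposure-increasing
  allele orientation: a fixed shift on arbitrary allele coding would
  cancel over random signs and not be directional at all (the Egger
  intercept would sit at zero regardless of the configured mean).
  Confounded instruments act through a latent confounder touching both
  traits and are listed in the annotation table under real confounder
  trait names, so the filter has something faithful to find.
- **Colocalization regions** propagate causal z-scores through the LD
  matrix and add noise with covariance equal to the LD matrix — the
  correct sampling distribution of marginal z-scores — then convert to
  beta/SE at unit-variance scale.
- **LDSC datasets** draw LD scores from a shifted gamma (mean ≈ 39) and
  per-SNP bivariate-normal z-scores with exactly the model's first and
  second moments, including an optional sample-overlap covariance term.

What these generators do *not* emulate: realistic human LD maps,
allele-frequency/effect-size coupling, population stratification,
assortative mating, winner's curse beyond what significance selection
itself induces (the worked example shows mild attenuation of the IVW
estimate for exactly that reason), or multi-causal-variant regions.
Passing tests therefore demonstrate that the estimators and the decision
logic are implemented correctly and are well-calibrated under their own
assumptions — not that any real exposure-outcome verdict is correct.

## Numerical choices

- Clumping ties break by ascending variant id; variants missing from the
  LD panel count as independent, with a warning.
- Harmonization resolves palindromic (A/T, C/G) variants by frequency
  when the minor-allele frequency is below 0.42 on both traits and drops
  them otherwise; missing frequencies on a palindromic variant drop it
  (conservative against strand errors).
- The PWM penalty factor (20) and bootstrap size (1000) follow the
  originating method literature; both are arguments.
- RAPS brackets its root by doubling an interval around the median ratio
  and reports a structured not-estimable result if no sign change is
  found within ±1024.
- All stochastic procedures take explicit seeds and are bit-reproducible
  given them; the pipeline derives per-pair, per-stage seeds from one
  master seed.

## Problem sizes in the verification suite

The test and acceptance studies use 2000 replicates for null calibration
(m = 30, n = 50,000), 500–1000 for recovery and coverage, 200 for
outlier detection, 100 for colocalization and LDSC recovery
(M = 20,000), sizes at which Monte-Carlo error is small relative to every
asserted band. The acceptance script re-runs the same studies at
moderately reduced replicate counts and reports the measured rates.

## Known limitations

- The decision table treats an unavailable genetic correlation as
  not-significant (flagged `ldsc_na_treated_as_ns`); a measured-but-noisy
  rg and an NA rg are therefore classified identically.
- Colocalization assumes at most one causal variant per trait per region;
  no multi-signal (SuSiE-style) extension is provided.
- The Steiger r² formula on the log-odds scale approximates, rather than
  equals, liability-scale variance explained.
- MVMR conditional F statistics use a residualization approximation, not
  the full covariance-aware statistic.
- No liftover, no multi-allelic variants, no VCF ingestion: input is the
  canonical TSV dialect only.
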