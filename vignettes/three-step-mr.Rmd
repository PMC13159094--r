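---
title: "Three-step Mendelian randomization with mediation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-step Mendelian randomization with mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The scientific problem

Inflammatory signalling and circulating metabolites are both implicated in
the progression of complex diseases such as heart failure, but observational
associations between them are confounded. Two-sample Mendelian randomization
(MR) uses genetic variants as instrumental variables: a variant that raises
a cytokine's plasma level from conception onward acts as a natural
randomized exposure, so — under the instrumental-variable assumptions — the
ratio of its outcome association to its exposure association estimates a
causal effect.

`mrmediate` implements a three-step design on GWAS summary statistics:

1. **Forward screen.** Every exposure in a panel (e.g. 91 plasma cytokines)
   is tested against the disease outcome; the inverse-variance-weighted
   (IVW) estimator is the primary gate, with four robust estimators reported
   alongside. Exposures the outcome feeds back onto (reverse MR significant)
   are excluded.
2. **Mediator screen.** A larger panel of candidate mediators (e.g. 1400
   metabolites) is screened against the outcome at a stricter alpha.
3. **Mediation.** For each surviving exposure--mediator pair with a
   significant exposure-to-mediator link, the product-of-coefficients
   decomposition splits the total effect into indirect (through the
   mediator) and direct components.

# Models and estimators

For SNP $j$, let $\hat\beta_{Xj}, \sigma_{Xj}$ be the exposure association
and $\hat\beta_{Yj}, \sigma_{Yj}$ the outcome association (log odds for a
binary outcome). The per-SNP Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_j = \sigma_{Yj}/|\hat\beta_{Xj}|$ (exposure uncertainty
ignored — the usual strong-instrument approximation).

* **IVW**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$ with
  $w_j = 1/\sigma_j^2$, identical to zero-intercept weighted regression of
  $\hat\beta_Y$ on $\hat\beta_X$. A *multiplicative random-effects* model is
  the default: the standard error is inflated by
  $\sqrt{\max(1, Q/(J-1))}$, so heterogeneity widens but never narrows the
  interval. The inflation floor at 1 means fixed- and random-effects
  coincide for homogeneous sets.
* **MR-Egger**: the same regression with a free intercept; the intercept
  estimates the average directional pleiotropy, the slope remains a causal
  estimate under the InSiDE assumption. Rows are oriented to
  $\hat\beta_X \ge 0$ internally (the estimator is not invariant to per-SNP
  sign conventions). P-values use a $t_{J-2}$ reference; confidence bounds
  keep the fixed 1.96 convention used everywhere in this package.
* **Weighted median**: the inverse-variance-weighted interpolated median of
  the $\hat\theta_j$; consistent while valid instruments hold more than
  half the weight.
* **Simple and weighted mode**: argmax of a normal-kernel density of the
  ratios with bandwidth $0.9\,\min(\mathrm{sd},\mathrm{mad})\,J^{-1/5}$
  times a user `bandwidth_factor` (default 1), evaluated on a 512-point
  grid spanning the ratios plus three bandwidths; consistent when the
  largest homogeneous group of instruments is valid. When more than half
  the ratios coincide the MAD collapses; the bandwidth then falls back to
  the sd, and fully degenerate inputs return the common ratio directly.
* Median and mode standard errors come from a seeded parametric bootstrap
  (each ratio redrawn from $N(\hat\theta_j, \sigma_j^2)$, default 1000
  replicates).

Estimates are reported on both the log-odds and odds-ratio scales, with
$\mathrm{OR} = e^{\beta}$ and 95% bounds $e^{\beta \pm 1.96\,\mathrm{SE}}$.

## Sensitivity diagnostics

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta_{\mathrm{fixed}})^2$
(d.f. $J-1$) tests heterogeneity; $Q/(J-1)$ is exactly the random-effects
inflation factor, a cross-module identity asserted in the tests. The Egger
intercept tests directional pleiotropy. MR-PRESSO follows the published
three-test structure: a global test comparing the observed weighted residual
sum of squares (leave-one-out IVW predictions) against a simulated null, a
per-SNP outlier test with Bonferroni correction, and a distortion test
comparing the outlier-corrected estimate against random same-size removals.
Empirical p-values use the add-one rule, so the global p floors at
$1/(n_{\mathrm{sim}}+1)$ — raise `n_sim` when that floor is hit; with the
default 1000 simulations the Bonferroni outlier test loses all power beyond
about 50 instruments, so `n_sim` should scale with the instrument count.
A diagnostic *passes* at level $\alpha$ when its p-value exceeds $\alpha$:
no significant heterogeneity or pleiotropy detected.

## Mediation

Given the total effect $\beta_{\mathrm{all}}$ (exposure to outcome on the
exposure's instruments), $\beta_1$ (exposure to mediator, same instruments)
and $\beta_2$ (mediator to outcome, the mediator's *own* instruments — the
two-step MR convention, univariable throughout), the indirect effect is
$\beta_1\beta_2$ with first-order delta (Sobel) standard error
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$ (the second-order
$\sigma_1^2\sigma_2^2$ term is available behind `second_order`). The
mediated proportion is $\beta_1\beta_2/\beta_{\mathrm{all}}$. When the
indirect and total effects oppose each other the proportion is negative and
flagged as *inconsistent mediation*, never clamped to $[0,1]$. A percentile
bootstrap over independent normal redraws of the three path estimates is
the alternative interval.

The proportion interval treats numerator and denominator as independent.
That is an approximation: the same outcome GWAS enters $\beta_2$ and
$\beta_{\mathrm{all}}$, and the covariance is not recoverable from summary
statistics, so published proportion intervals that account for it cannot be
reproduced exactly here.

# Instrument selection and harmonization

Defaults follow common practice for molecular exposures: candidate
instruments at $p < 10^{-5}$ (the genome-wide $5\times10^{-8}$ leaves too
few variants for cytokine/metabolite panels), greedy clumping at
$r^2 < 0.001$ within 10,000 kb, and a per-SNP strength filter
$F = (\beta/\mathrm{SE})^2 \ge 10$.

Clumping takes an explicit `ld_info` matrix. When none is supplied the
package degrades to *distance-only* clumping — every neighbour inside the
window is removed — which is the honest conservative behaviour when
correlations are unknown; pairs absent from a supplied matrix count as
independent. Ties at equal p-value break lexicographically by variant id,
making the result invariant to input row order.

Harmonization aligns outcome effects to the exposure's effect allele,
flipping signs for swapped (directly or strand-complement) allele pairs and
dropping irreconcilable rows into an audit log. Palindromic variants (A/T,
C/G) are resolved by allele frequency: kept only when both frequencies are
available and outside $0.5 \pm 0.08$, with a strand flip inferred when they
fall on opposite sides of 0.5. The 0.08 window is common practice; the
source analyses this package generalizes do not state one. After
harmonization rows are re-oriented so exposure effects are non-negative
(required for a consistent Egger intercept; ratio-based estimators are
unaffected).

# The synthetic-data generator

`simulate_triple()` generates exposure/mediator/outcome summary statistics
over a shared SNP panel from an explicit causal system, so the whole
pipeline is testable without downloading any GWAS. What it emulates, and
the stated-world defaults:

* **Scale regime.** Default sample sizes 14,824 (exposure), 8,299
  (mediator) and 412,181 with 7.2% cases (outcome) mirror the published
  cohorts this design targets: an Olink-panel pQTL study, a metabolomics
  cohort, and a biobank-scale disease GWAS.
* **Instrument architecture.** Exposure-instrument magnitudes are drawn
  $|N(1, 0.5)|$ and rescaled so the panel jointly explains `h2_exp`
  (default 0.3) — an *ascertained* panel whose effects are bounded away
  from zero, as published instrument sets are. Effects are oriented
  effect-allele-positive; under that convention directional pleiotropy
  (`pleio_mean` $\neq 0$ on the invalid fraction) is directional on the
  ratio scale, which is what biases IVW and exercises the robust
  estimators.
* **Standard errors** follow the analytic GWAS formula
  $1/\sqrt{2p(1-p)\,n}$ for standardized continuous traits and
  $1/\sqrt{2p(1-p)\,n\,v}$, $v = \mathrm{prev}(1-\mathrm{prev})$, for the
  binary outcome on the log-odds scale. Winner's curse arises naturally
  because selection happens on the simulated p-values; no correction is
  applied, matching the screening design.
* **LD** is optional equicorrelated block structure (noise correlated
  within blocks, an `ld_info` matrix emitted alongside); blocks sit more
  than one clumping window apart so instrument counts are controlled by
  configuration.

What it does **not** emulate: realistic allele-frequency spectra, indels
and multi-allelic variants, population stratification, sample overlap
between the two samples, and LD between *true* causal effects. A green
simulation test therefore establishes the estimators' statistical behaviour
under the stated model, not robustness to those artefacts.

# Numerical and design choices

* The F-statistic is implemented as $(\beta/\mathrm{SE})^2$. A literal
  reading of the motivating description ("the ratio of the effect size to
  the square of the standard error") is dimensionally inconsistent with an
  $F \ge 10$ strength rule and is treated as a wording slip.
* IVW weights are inverse *variances* $1/\mathrm{SE}^2$, the convention the
  estimator is named after, even where source descriptions say "inverse of
  the standard errors".
* Reported confidence bounds use a fixed $z = 1.96$ for every estimator so
  the OR identities $e^{\beta \pm 1.96\mathrm{SE}}$ hold exactly; Egger
  p-values still use the $t_{J-2}$ reference, so its p and CI can disagree
  near the boundary at small $J$.
* Single-instrument exposures (possible after clumping) fall back to the
  Wald ratio, reported as `method = "ivw"`, `n_snps = 1`, so every screened
  exposure has a primary answer.
* Screening applies **no multiple-testing correction** by default (nominal
  thresholds 0.05 for exposures, 0.01 for the larger mediator panel, 0.05
  for reverse exclusion), matching the screening design this package
  generalizes; `mr_config(p_adjust = "bonferroni" | "fdr")` switches it on.
* All randomness (bootstraps, MR-PRESSO, the simulator) is seeded through
  explicit arguments; per-exposure seeds are derived deterministically from
  the master seed, and `with_seed` restores the caller's RNG state, so
  pipeline runs are bit-reproducible given the manifest.
* Empirical p-values use $(1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(1+n)$,
  never exactly zero.

# Known limitations

* **Egger attenuation at realistic instrument strength.** With
  exposure-panel strength around mean $F \approx 60$ (a 15--20k-sample
  pQTL study), MR-Egger's slope attenuates by roughly $1 - I^2_{GX}$
  (8--12% here) because exposure-effect measurement error violates NOME.
  The package's consistency property is demonstrated at higher instrument
  strength; at panel strength, treat Egger as a pleiotropy diagnostic
  first and an estimator second.
* **Weighted median at exactly 50% invalid weight.** The 50% breakdown
  point is exclusive: with half the weight invalid and a near-constant
  one-sided pleiotropic shift, the weighted median converges to the gap
  between the valid and invalid ratio clusters. Its advertised robustness
  is exhibited under dispersed directional pleiotropy (pleiotropy sd
  comparable to or larger than its mean), which is what the robustness
  tests instantiate.
* Variant matching is by identifier only (no build liftover, no proxy
  lookup), and LD must be supplied externally; without it clumping is
  distance-only and deliberately conservative.
* The mediated-proportion interval ignores the $\beta_2$ --
  $\beta_{\mathrm{all}}$ covariance (see above).

# A worked example

The package ships the published reference arithmetic as a fixture: a
cytokine with a protective total effect on the disease
($\beta_{\mathrm{all}} = -0.0704$, $\mathrm{OR} = 0.932$), a positive
effect on a metabolite ($\beta_1 = 0.1162$) which itself raises disease
risk ($\beta_2 = 0.1020$, $\mathrm{OR} = 1.107$):

```{r worked}
we <- make_worked_example()
m <- mediate(we$beta_all["beta"], we$beta_all["se"],
             we$beta1["beta"], we$beta1["se"],
             we$beta2["beta"], we$beta2["se"])
m
```

The indirect effect rounds to 0.0119 and the mediated proportion to
-16.8%: the metabolite path *opposes* the protective total effect —
inconsistent mediation, reported with its sign.

```{r sim}
sim <- simulate_triple(sim_config(n_snps = 50, n_med_snps = 50,
                                  theta_em = 0.3, theta_mo = 0.2,
                                  theta_direct = 0.1, seed = 1))
res <- mr_pair(sim$exposure, sim$outcome, mr_config(seed = 1))
res$estimates[, c("method", "n_snps", "beta", "se", "pval", "or")]
```
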