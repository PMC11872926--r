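---
title: "Methods: stepwise two-sample MR mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stepwise two-sample MR mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Observational associations between circulating lipid species,
inflammatory proteins and immune-mediated disease (the motivating case is
ulcerative colitis) are confounded by diet, medication and reverse
causation. Two-sample Mendelian randomization (MR) sidesteps much of this
by using germline genetic variants as instrumental variables: alleles are
assigned at conception, so a SNP that robustly raises a lipid level acts
as a natural randomized nudge to that lipid. With GWAS summary statistics
for an exposure and an outcome measured in separate cohorts, the causal
effect is estimable from per-SNP association pairs alone.

`mrmediate` implements the full stepwise mediation workflow on top of
this machinery: it asks not only *whether* an exposure affects the
outcome, but *how much of that effect is carried by a molecular
mediator* (an inflammatory protein), using three univariable MR fits and
a product-of-coefficients decomposition.

## The decomposition

Write $\beta_{all}$ for the total exposure-to-outcome effect,
$\beta_1$ for the exposure-to-mediator effect and $\beta_2$ for the
mediator-to-outcome effect (all on the log / log-odds scale). Then

$$\beta_{med} = \beta_1 \beta_2, \qquad
  \beta_{dir} = \beta_{all} - \beta_{med}, \qquad
  \mathrm{prop.\ mediated} = \beta_{med} / \beta_{all},$$

with the indirect-effect standard error by the first-order delta method,

$$\mathrm{se}_{med} = \sqrt{\beta_1^2\,\mathrm{se}_2^2 +
  \beta_2^2\,\mathrm{se}_1^2}.$$

The cross term $\mathrm{se}_1^2 \mathrm{se}_2^2$ is deliberately omitted:
the first-order form is the one conventionally reported, and the
package's Monte-Carlo test bounds the approximation error (the exact SD
of a product of independent normals differs by under 2% at the
signal-to-noise ratios of interest). The identities
$\beta_{med} = \beta_1\beta_2$ and
$\beta_{dir} = \beta_{all} - \beta_{med}$ hold exactly (bitwise) by
construction on every call.

Two deliberate representational choices:

* **Sign discordance is reported, not suppressed.** The proportion
  mediated can be negative (an indirect path opposing the total effect);
  the result carries a `sign_discordant` flag. The motivating analysis
  itself exhibits this: a protective total effect with a small adverse
  indirect path through PD-L1.
* **$\beta_2$ is a univariable (total) effect of the mediator.** The
  stepwise design estimates the mediator-to-outcome step by ordinary MR
  of mediator on outcome, not by multivariable MR; when the exposure
  also affects the outcome directly and mediator instruments partially
  overlap exposure loci, this step inherits correlated pleiotropy. The
  synthetic-data studies below quantify when that matters.

`run_two_step()` performs the three fits — each with its own instrument
selection from its own exposure-role GWAS — then decomposes, attaches a
reverse-MR estimate (outcome as exposure) to probe reverse causation,
and records a manifest of every threshold, seed and exclusion count.

## Instrument selection

Defaults follow standard two-sample MR practice and are all strict
inequalities:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance, `p < threshold` |
| `clump_r2` | 0.001 | LD pruning threshold, remove if `r2 > threshold` |
| `clump_window_kb` | 10,000 | physical clumping window (kb) |
| `f_min` | 10 | instrument strength, keep if `(beta/se)^2 > f_min` |
| `palindrome_policy` | drop all | A/T and C/G SNP handling |

Clumping is the classic greedy algorithm: repeatedly keep the remaining
SNP with the smallest p-value and discard same-chromosome SNPs within
the window whose r² with it exceeds the threshold. Ties on p-value are
broken lexicographically by SNP id so results are identical across
platforms. The F statistic is computed per SNP from `beta/se` because
those are the only fields guaranteed in summary files.

Harmonization pairs SNPs by identifier, re-orients outcome rows reported
on swapped alleles (negating beta, complementing the frequency), and
excludes pairs whose allele sets differ. Palindromic SNPs (A/T, C/G) are
dropped by default because allele labels cannot distinguish a swap from
a strand flip. The alternative `drop_ambiguous_only` policy rescues
palindromic SNPs whose effect-allele frequency is outside
`[0.42, 0.58]` in both studies and orients them by frequency — the
window follows common MR practice and is configurable, since published
pipelines rarely state it. Every input SNP ends either in the retained
set or in an exclusion log with a reason
(`not_significant`, `clumped`, `weak_instrument`, `palindromic`,
`allele_mismatch`, `missing_in_outcome`); the two always partition the
input exactly.

## Estimators

All six estimators consume the same harmonized set and report on the
log-OR scale with odds-ratio views; Wald tests use the normal reference
(CI multiplier 1.959963985 at 95%) rather than a t reference, for
cross-platform reproducibility. Per-SNP Wald ratios use first-order SEs
($\mathrm{se}_j = s_{yj}/|\hat\gamma_j|$) by default, matching the
dominant convention in MR tooling; second-order SEs are available.

* **IVW** — precision-weighted mean of the Wald ratios. The
  multiplicative-random-effects variant (the primary method throughout)
  inflates the SE by $\sqrt{\max(1, Q/(J-1))}$; the inflation is floored
  at one so heterogeneity can never shrink an SE, and with one SNP MRE
  equals fixed.
* **MR-Egger** — weighted regression of outcome on exposure associations
  with a free intercept after orienting each pair to the
  exposure-increasing allele; the intercept estimates directional
  pleiotropy. SEs use multiplicative overdispersion floored at one. An
  internal intercept-constrained mode reproduces fixed-effect IVW
  exactly, which the tests exploit as a consistency check.
* **Weighted median** — interpolated median of the ratio distribution at
  cumulative normalized weight 0.5; robust when up to half the weight is
  invalid. SE by parametric bootstrap (both association vectors redrawn
  from normals at their observed values/SEs; default 1,000 replicates,
  seed-deterministic).
* **Simple / weighted mode** — argmax of a normal-kernel density of the
  ratios over a 512-point grid spanning the ratios ± 3 bandwidths, with
  bandwidth $0.9\,\phi \min(\mathrm{SD}, \mathrm{IQR}/1.34)\,J^{-1/5}$
  (the Silverman rule scaled by the tuning factor $\phi$, default 1).
  If every ratio coincides the common value is returned with a bootstrap
  SE. The bandwidth is linear in $\phi$ and reported.
* **BWMR** — a Bayesian-weighted robust estimator. Marginalizing the
  hierarchical model (latent instrument effects, random pleiotropy
  $\alpha_j \sim N(0, \tau^2)$) gives
  $\hat\Gamma_j \sim N(\beta\hat\gamma_j,\;
  s_{yj}^2 + \tau^2 + \beta^2 s_{xj}^2)$. Posterior-mode inference uses a
  weak $N(0, 10^2)$ prior on $\beta$ and a half-normal prior on $\tau$
  (scale 0.5 on the log-OR scale), Nelder-Mead maximization, and
  iteratively updated Bayesian weights
  $w_j \leftarrow \min(1, f_j / (c \cdot \mathrm{median}(f)))$, where
  $f_j$ is the SNP's predictive density and $c$
  (`weight_threshold`, default 0.1) sets the onset of downweighting at
  roughly 2.2 residual SDs — instruments the model finds surprising are
  smoothly downweighted, while on clean data nearly every weight stays
  at 1. The threshold matters: downweighting relative to the median
  density itself would trim half the instruments on every dataset,
  inflating the estimator's variance and leaving the Laplace CI
  anticonservative; the thresholded rule keeps the null coverage at its
  nominal level, which the test suite verifies directly. The SE is the Laplace approximation from the
  numerical Hessian at the mode. Iteration stops when successive $\beta$
  values change by less than `tol` (default 1e-8); non-convergence
  returns the estimate with a flag and a warning rather than an error.
  This is posterior-mode (not MCMC) inference, so agreement with any
  particular external implementation is at the level of the method's
  statistical behaviour — calibration, robustness to outliers,
  equivalence with IVW when $\tau = 0$ — which is exactly what the test
  suite checks.

## Diagnostics and multiplicity

Cochran's $Q$ is computed about the fixed-effect IVW centre and referred
to $\chi^2_{J-1}$; it is numerically the same $Q$ that drives the MRE
inflation (asserted to 12 digits in the tests). $I^2 = \max(0,(Q -
\mathrm{df})/Q)$ is reported as a standard companion even though the
motivating analysis reported only $Q$ and its p-value. Leave-one-out
recomputes IVW-MRE dropping each SNP in turn; funnel tables pair each
ratio with its precision for external plotting (the package exports
plot-ready tables rather than rendering figures). Multiplicity uses
`stats::p.adjust`: Bonferroni with its per-test threshold
$\alpha/m$ (for the 179-exposure screen this is
$0.05/179 = 2.8\times10^{-4}$) and Benjamini–Hochberg for FDR control —
the FDR procedure is not named in most applied reports, and BH is the
standard default. Screening significance is judged on the IVW-MRE
p-value; other estimators are reported, not gated on. The FDR scope in
multi-mediator scans is per-exposure by default (adjusting within each
exposure's scan), since pooling across exposures changes the error rate
being controlled; both conventions are reachable by calling
`adjust_pvalues()` on whichever p-value vector is wanted.

## The synthetic-data generator

`simulate_study()` emits three linked summary-statistics tables over a
shared SNP panel with a known causal chain, standing in for the kind of
data the workflow targets (a lipidomics GWAS of ~7,000 participants, an
Olink-style protein GWAS of ~15,000, a biobank disease GWAS of ~400,000
— the default sample sizes mirror that scale). For SNP $j$ with
effect-allele frequency $f_j$ and sample size $n$, sampling SEs follow
the standardized working model $s = 1/\sqrt{2 n f_j (1-f_j)}$ and
observed effects are true means plus Gaussian noise:

* exposure: $\hat\beta_{xj} \sim N(\gamma_j, s_{xj}^2)$ with
  $\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$ (a configurable fraction
  drawn near-zero to emulate weak instruments);
* mediator: $\hat\beta_{mj} \sim N(\beta_1\gamma_j + \delta_j, s_{mj}^2)$;
* outcome: $\hat\beta_{yj} \sim N((\beta_{dir} + \beta_1\beta_2)\gamma_j
  + \beta_2\delta_j + \alpha_j, s_{yj}^2)$.

Binary-outcome effects are simulated directly on the log-OR scale — no
individual-level logistic model — because two-sample MR consumes only
summary statistics and the Gaussian form keeps every sampling oracle
closed-form. Design choices worth explaining:

* **Mediator-specific instruments** (`mediator_snp_fraction`,
  `delta_sd`). A fraction of SNPs act directly on the mediator
  ($\delta_j \sim N(0, \texttt{delta\_sd}^2)$, no exposure effect), and
  the outcome inherits $\beta_2\delta_j$. Without them the mediator's
  only genetic effects are $\beta_1\gamma_j$, and the
  mediator-to-outcome step has no instruments at all whenever
  $\beta_1 = 0$ — a degenerate genetic architecture no real proteome
  GWAS exhibits. Defaults are 0 (the minimal chain); recovery studies
  enable them.
* **Directional pleiotropy on the exposure-increasing orientation.**
  The mean shift `pleiotropy_mean` is applied relative to the
  exposure-increasing allele ($\alpha_j$ multiplied by the sign of
  $\gamma_j$). Applied to the arbitrary effect allele instead, the
  orientation step in Egger regression would scramble the shift's sign
  and no directional pleiotropy could ever be expressed; for balanced
  pleiotropy the two formulations are distributionally identical.
* **Block-diagonal LD.** Blocks of consecutive SNPs share a configurable
  r², blocks are placed 20,000 kb apart and cycled over chromosomes
  1–22. This is sufficient to exercise the clumping rule
  deterministically; it is not a coalescent and makes no attempt at
  realistic human LD structure.
* **Orientation flips** (`flip_fraction`) swap alleles, negate beta and
  complement the frequency on a random subset of outcome rows — a pure
  representation change that harmonization must (and, by test, does)
  undo exactly.

What the generator does **not** emulate: individual-level genotypes,
realistic LD maps, allele-frequency spectra, population stratification,
sample overlap between the two GWAS, and winner's-curse-inducing
discovery designs. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated sampling model, not
robustness to every pathology of real GWAS data.

## Study sizes and numerical choices in the test suite

Simulation studies in the tests use sizes chosen so that known
small-sample biases are an order of magnitude below the Monte-Carlo
resolution of the check:

* Calibration studies (type-I error of IVW-MRE, BWMR coverage) use
  panels of 50 candidate SNPs with `gamma_sd = 0.3` and GWAS sizes of
  50,000, giving mean instrument F in the hundreds; 2,000 replicates for
  test size, 500 for coverage.
* Mediation-recovery studies use 120-SNP panels of common variants
  (MAF 0.2–0.5), half mediator-specific, with `gamma_sd = 0.05`,
  `delta_sd = 0.3`, an exposure GWAS of 5,000,000 and mediator/outcome
  GWAS of 100,000, and 300 replicates per cell of the
  $(\beta_1, \beta_2, \beta_{dir}) \in \{-0.2, 0, 0.2\}^3$ grid. These
  sizes put per-SNP instrument F in the thousands, which matters for a
  three-sigma Monte-Carlo check on a mean over 300 replicates: Wald
  ratio estimators attenuate toward zero by roughly $1/F$ (denominator
  noise plus winner's curse), so F of a few hundred — e.g. low-MAF
  variants in a 50,000-sample GWAS — leaves an attenuation comparable
  to the check's resolution, while F ≳ 2,000 pushes it an order of
  magnitude below. The asymmetry `delta_sd` ≫ `|beta1| * gamma_sd`
  simultaneously keeps exposure-driven SNPs from reaching
  mediator-GWAS significance, so the $\beta_2$ step's instrument set is
  not contaminated by correlated pleiotropy when $\beta_{dir} \ne 0$.
* Bootstrap SEs in recovery loops use 100 replicates (the documented
  minimum); reported analyses default to 1,000.

Degenerate inputs are handled explicitly: one instrument (IVW falls back
to the single Wald ratio; MRE equals fixed), identical ratios (zero
bandwidth modes return the common ratio; $Q = 0$, $p = 1$), zero
exposure effects (an error naming the SNP), an exactly zero total effect
(proportion mediated flagged undefined rather than returned as ±Inf).

## Known limitations

* The $\beta_2$ step is univariable by design; multivariable MR direct
  effects are out of scope.
* BWMR inference is posterior-mode with a Laplace SE; full posterior
  uncertainty (MCMC) is not computed.
* No proxy-SNP lookup or reference-panel LD estimation: the LD matrix is
  an input.
* Steiger direction filtering and outlier-removal schemes (MR-PRESSO,
  contamination mixture) are not implemented; reverse MR and BWMR's
  weighting are the directionality/robustness tools provided.
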