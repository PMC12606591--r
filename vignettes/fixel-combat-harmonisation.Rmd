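---
title: "ComBat harmonisation of fixel-based metrics: model, simulator and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ComBat harmonisation of fixel-based metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixelharm)
```

## The harmonisation model

Fixel-based analysis (FBA) represents each scan as a vector over a shared
template fixel list: one fibre density (FD), log fibre cross-section
(logFC) or FDC value per fixel. Scans acquired at different sites, on
different scanner models, or with different protocols carry additive and
multiplicative batch effects that `fixelharm` removes with the ComBat
location–scale model, fitted independently per fixel $f$:

$$Y_{i,j,f} = \alpha_f + X_{i,j}\beta_f + \gamma_{i,f} + \delta_{i,f}\,
\varepsilon_{i,j,f}, \qquad \varepsilon_{i,j,f} \sim N(0, \sigma_f^2),$$

with $i$ the batch, $j$ the scan, $X$ the biological covariates, and
$\gamma_{i,f}$, $\delta_{i,f}$ the batch location and scale effects. The
assumptions worth stating explicitly:

* **fixel correspondence** — every scan's data are already mapped to the
  template fixels; a fibre population absent in a subject is encoded as 0
  (the reader also accepts `NaN` and converts it to 0, with a count);
* **linearity** in the covariates, fitted jointly with the batch
  indicators under the sample-size-weighted constraint
  $\sum_i n_i \hat\gamma_{i,f} = 0$, which makes $\hat\alpha_f$ the pooled
  covariate-adjusted mean;
* **exchangeability across fixels** of the batch effects, which is what
  justifies empirical-Bayes pooling: $\gamma_{i,f} \sim N(\bar\gamma_i,
  \tau_i^2)$ and $\delta^2_{i,f} \sim \mathrm{InvGamma}(\lambda_i,
  \theta_i)$, hyperparameters estimated by moment matching across fixels
  ($\lambda = (m^2+2V)/V$, $\theta = (m^3+mV)/V$ for a batch whose
  $\hat\delta^2$ values have mean $m$ and variance $V$).

The conditional posterior modes $(\gamma^*, \delta^{*2})$ solve a coupled
fixed point, iterated from the raw estimates until the largest absolute
change falls below `eb_tol` (default $10^{-4}$) or 100 iterations
(non-converged fixels are counted and the last iterate used). The
harmonised value restores the metric scale through $\hat\sigma_f$:

$$Y^{\mathrm{ComBat}}_{i,j,f} = \hat\sigma_f\,
\frac{Z_{i,j,f} - \gamma^*_{i,f}}{\delta^*_{i,f}} + \hat\alpha_f +
X_{i,j}\hat\beta_f.$$

`method = "direct"` skips the shrinkage ($\gamma^* = \hat\gamma$,
$\delta^* = \hat\delta$) and then removes batch means exactly; `"eb"` is
the default and trades a small residual (shrinkage bias) for much lower
variance when batches are small.

### Numerical conventions and degenerate inputs

* $\hat\sigma_f$ uses divisor $N$ and $\hat\delta^2_{i,f}$ divisor $n_i$.
  With these choices a single-batch fit is an *exact* identity transform
  (the constraint forces $\hat\gamma = 0$ and $\sum_j Z^2_{j,f} = n$ gives
  $\hat\delta^2 = 1$), which is the behaviour a user should expect when a
  grouping variable accidentally has one level. Implementations that use
  the unbiased $n_i - 1$ estimator differ from ours by $O(1/n_i)$; the test
  suite cross-checks against one such implementation at that tolerance.
* Fixels whose values are constant within any batch (or with zero pooled
  residual variance) would make the scale adjustment singular; they are
  excluded by the mask, pass through unchanged, and are reported.
* A batch whose $\hat\delta^2_{i,f}$ are constant across fixels has a
  degenerate inverse-gamma prior; it falls back to the unshrunk estimates
  with a warning.
* Harmonised FD/FDC values may go slightly negative. They are counted and
  reported, not clipped, because clipping changes the moments;
  `clip_negative = TRUE` opts in.
* Covariates enter as given (no internal standardization); the design's
  condition number is monitored and a warning is raised above $10^{12}$.
  Intracranial volume in mm³ routinely gives $\kappa \sim 10^8$, which is
  harmless in double precision.
* Rank-deficient designs (a batch perfectly confounded with a covariate, a
  duplicated covariate) raise a design error naming the collinear columns
  rather than silently dropping them.

### Per-group versus pooled harmonisation

`harmonize(..., group = "group")` runs the whole pipeline separately per
group level (the design used when patients and controls are harmonised
independently) and re-stacks rows in input order; a group containing a
single batch passes through with a warning. Per-group harmonisation is
appropriate when the batch distribution is similar in every group. When
batch assignment is *confounded* with group, per-group ComBat centres each
batch at the group's own pooled mean — which itself retains the confound —
so the between-group contrast cannot be fully repaired that way. For
confounded designs the package recommends pooled harmonisation with the
group indicator included among the biological covariates, which protects
the group effect while batch effects are estimated; this is the
configuration used in the effect-size checks below.

## What the synthetic generator emulates

`sim_config()` + `simulate_dataset()` produce two study designs with full
ground truth (`alpha`, `sigma`, per-batch effects on both the fraction and
the standardized scale, subject covariates, tract labels, and the
counterfactual batch-effect-free matrix `Y_nobatch`):

* **Travelling-subject (TS) modes** (`scan_rescan`, `site_diff`,
  `scanner_diff`, `protocol_diff`): every subject is scanned once per arm
  with identical latent biology, so the expected biological arm difference
  is zero and any systematic arm difference is batch effect. Default
  subject counts are 23 / 10 / 23 / 31 for the four modes, matching a
  four-group TS design. In `scan_rescan` both arms share one batch label
  and one batch-effect realisation, so arms differ by measurement noise
  only.
* **Case–control mode**: 27 patients (`AD`) and 29 controls (`CN`) on six
  scanner models, each scanner seeded with at least two scans per group,
  the remainder assigned with per-group weights that by default confound
  group with the scanners' additive shifts. A contiguous run of 10% of the
  fixels is labelled as the target tract and carries a 15% FD reduction in
  the patient group. MMSE and MoCA scores are generated from the subject's
  noise-free tract-mean FD plus noise, rounded and truncated to 0–30, with
  link parameters chosen so the group means land near 29/22.6 (MMSE) and
  26.4/16.9 (MoCA) at the default effect size.

Generative model per scan:

$$Y_{jf} = \alpha_f (1 + u_j) + X_j\beta + \alpha_f\, c_{i,f} +
\sigma_f\, \delta_{i,f}\, \varepsilon_{jf},$$

with baseline $\alpha_f \sim U(0.3, 0.8)$ (FD-like), noise scale
$\sigma_f \sim U(0.02, 0.06)$, additive batch effect $c_{i,f} \sim
N(g_i, \tau_i^2)$ expressed as a *fraction of the baseline*, and
$\delta^2_{i,f} \sim \mathrm{InvGamma}(\lambda_i, \theta_i)$ (defaults
$\lambda = 51$, $\theta = 50$: mean 1, SD ≈ 0.14) multiplying the noise.
Two design choices deserve comment:

* *Fraction-of-baseline injection.* Expressing the additive effect as
  $\alpha_f c_{i,f}$ (rather than $\sigma_f \gamma_{i,f}$) makes a
  configured `g = 0.10` produce a ~10% percentage difference between arms
  regardless of the noise level — including in the noise-free limit — so
  recovery targets are exact. The ground truth also records the effect on
  the standardized scale ($\alpha_f c_{i,f}/\sigma_f$) used by the fitted
  model. Default effect magnitudes are 8–15% of baseline, the range
  reported for scanner- and protocol-driven variability in FBA metrics.
* *Between-subject deviation* $u_j \sim N(0, 0.10^2)$, a global scaling of
  the subject's baseline shared across arms. Without it, between-subject
  variance in tract means comes only from covariates and noise, and the
  case–control Cohen's d implied by a 15% tract effect exceeds 4 —
  unrealistically large; a 10% global individual difference puts d in the
  1–1.5 range typical of hippocampal-limbic FD effects in dementia.

What the generator does **not** emulate: spatial anatomy (the "tract" is a
contiguous index run, not a bundle), spatially correlated noise,
registration or segmentation error, fixel mismatch across subjects, and
site-by-biology interactions. Consequently, passing checks demonstrate
correct *statistical* behaviour of the harmonisation and inference
machinery under the model's own assumptions, not robustness to the
geometric failure modes of real pipelines.

Randomness is split into a `structure_seed` (template, biology, subjects,
assignment, batch-effect realisations) and a `noise_seed` (measurement and
cognitive noise), both derived from `seed` unless given; fixing the
structure seed while varying the noise seed regenerates the same cohort
with fresh noise.

## Evaluation statistics

* `percentage_difference()` — $100\,(travelled - initial)/initial$ per
  fixel; zero-reference fixels yield `NaN` and are excluded from summaries
  with a count.
* `paired_permutation_test()` — per-fixel paired $t$ on subject
  differences; the null distribution flips the sign of whole subject rows
  (preserving the across-fixel correlation) and family-wise error is
  controlled by the max-|t| distribution with the $(b+1)/(B+1)$ p-value
  estimator. This replaces tractogram-informed enhancement (CFE): it is a
  valid FWE control that needs no tractography, but its significant-fixel
  sets are not comparable to CFE's. Defaults to 5000 permutations.
* `group_permutation_test()` — unpaired two-sample analogue with
  group-label permutation; covariates are regressed out of every fixel
  beforehand (simple residualisation, not Freedman–Lane).
* `cohens_d()` — pooled-SD standardized mean difference, sign convention
  `group_a - group_b` so that controls-minus-patients is positive for a
  patient reduction.
* `ols_bootstrap()` — OLS of a cognitive score on a tract-mean metric plus
  covariates; reports the predictor coefficient, its $t$ p-value, $R^2$,
  and a percentile 95% CI of $R^2$ from case-resampling bootstrap
  (default 10,000 replicates; rank-deficient resamples are redrawn and
  counted). Percentile rather than BCa: it is the minimal-assumption
  interval, and the choice is recorded in the output.
* `batch_variability_summary()` — per fixel, the mean absolute pairwise
  percentage difference between batch means, each ordered pair using the
  earlier batch (first-appearance order) as the reference, consistent with
  the travelled-versus-initial convention; summarised globally (mean,
  median, 95th percentile), optionally over significant fixels only.

## How the verification suite measures things

The acceptance checks (`tests/testthat/test-acceptance.R`, recomputed by
`scripts/acceptance.R`) run at deliberately modest problem sizes so the
whole suite stays in CPU-minutes; sizes are stated with each result.

* *Oracle equivalence*: 50 random small instances (N ≤ 12, M ≤ 6, two
  batches, with and without covariates) against an independently coded
  per-fixel location–scale adjustment; agreement to $10^{-8}$.
* *Batch-effect removal*: `scanner_diff` TS simulation, 23 paired
  subjects, ~1000 fixels, 10% additive scanner effect. Significance is
  assessed pre-harmonisation (2000 sign-flip permutations); the mean
  absolute percentage difference over the *pre-harmonisation significant
  set* is compared before (≥ 8%) and after (< 2%) harmonisation. The
  post-harmonisation significant set is typically empty, which would make
  a post-set summary undefined — fixing the set also makes the comparison
  like-for-like.
* *Covariate preservation*: three balanced batches of ~20 scans, ~510
  fixels, no subject deviation and no group effect (the fitted model's own
  generative conditions), true age slope −0.002 per year; the across-fixel
  mean of the per-fixel OLS age slopes on harmonised data must be within
  10% of truth. The subject deviation is switched off here because with it
  the slope estimator's coherent sampling error at this n (~50% of the
  slope) would swamp the harmonisation bias being measured.
* *Hyperprior recovery*: $10^5$ draws from $\mathrm{InvGamma}(6, 10)$ and
  $N(0.5, 0.2^2)$; moment matching must recover $(\lambda, \theta)$ within
  5% and $(\bar\gamma, \tau^2)$ within 3 Monte-Carlo standard errors.
* *Effect-size restoration*: the default confounded case–control design,
  harmonised pooled with the diagnosis indicator protected (see the
  per-group discussion above). Because a single Cohen's d at n = 56 has
  sampling SD ≈ 0.27, the |d_post − d_true| ≤ 0.15 band is evaluated as
  the mean over 20 simulation replicates — the estimator of the method's
  systematic behaviour, not of one draw's luck; d_post > d_pre is required
  in every replicate.
* *Permutation calibration*: 200 null TS replicates (10 subjects, 50
  fixels, 500 permutations); the family-wise rejection rate at 0.05 must
  lie in [0.02, 0.10].
* *Bootstrap coverage*: 200 replicates (N = 200, population $R^2 = 9/34$,
  500 bootstrap replicates each); the percentile CI must cover the
  population $R^2$ in at least 90% of replicates.
* *Round-trips*: 100 random templates and data vectors through the NIfTI
  fixel-directory format at float32 precision.

## Known limitations

* Parametric priors only; the non-parametric ComBat variant, reference-
  batch mode, longitudinal ComBat and ComBat-GAM are out of scope.
* Harmonisation runs independently per metric, so harmonised FDC is not
  the product of harmonised FD and FC; this mirrors the per-metric
  convention and is documented rather than "fixed".
* The max-statistic permutation test is a substitute for CFE, not a
  reimplementation; whole-brain significance maps from the two are not
  interchangeable.
* Scans harmonised with a saved model must come from batches present at
  fit time; there is no extrapolation to unseen scanners.
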