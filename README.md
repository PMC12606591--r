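# fixelharm

Empirical-Bayes ComBat harmonisation for fixel-based analysis (FBA) metrics
from multi-site diffusion MRI.

## The problem

Fixel-based analysis quantifies white-matter microstructure per *fixel* — a
specific fibre population within a voxel — via fibre density (FD), log fibre
cross-section (logFC) and their product (FDC). When scans come from several
sites, scanner models or imaging protocols, these metrics carry batch
effects of roughly the same magnitude (about 8–15% of the metric value) as
the disease effects one hopes to detect, so multi-centre FBA studies need
harmonisation before group analysis.

`fixelharm` treats each template fixel *f* as an independent feature and
fits the ComBat location–scale model per fixel:

```
Y_{i,j,f} = alpha_f + X_{i,j} beta_f + gamma_{i,f} + delta_{i,f} * eps_{i,j,f},
eps ~ N(0, sigma_f^2)
```

where *i* indexes the batch (site / scanner / protocol), *j* the scan,
`alpha_f` is the overall fixel mean, `X` holds biological covariates (age,
sex, intracranial volume, optionally diagnosis), and `gamma`, `delta` are
additive and multiplicative batch effects. Batch locations obey the
sample-size-weighted constraint `sum_i n_i gamma_hat_{i,f} = 0`. The
per-fixel batch effects are shrunk across fixels by parametric empirical
Bayes (normal prior for `gamma`, inverse-gamma for `delta^2`, hyperpriors by
moment matching, posterior found by fixed-point iteration), and the
harmonised values are

```
Y*_{i,j,f} = sigma_f * (Z_{i,j,f} - gamma*_{i,f}) / delta*_{i,f}
             + alpha_f + X_{i,j} beta_f
```

with `Z` the standardized residuals. The package also ships the
surrounding toolkit: NIfTI-1 fixel-directory I/O, a synthetic generator for
travelling-subject and case–control multi-scanner designs with retained
ground truth, and the evaluation statistics used to judge harmonisation
(percentage-difference maps, max-statistic permutation testing with
family-wise-error control, Cohen's d, tract means, OLS regression of
cognitive scores with percentile-bootstrap confidence intervals).

## Worked example

Simulate a travelling-subject cohort — 23 subjects each scanned on two
scanner models, with a 10% additive scanner effect — then remove it:

```r
library(fixelharm)

cfg <- sim_config("scanner_diff", grid_shape = c(6L, 6L, 3L), seed = 7)
ds  <- simulate_dataset(cfg)
ds$Y
#> fixel_matrix: 46 scans x 207 fixels (207 masked in), metric FD

bv_pre <- batch_variability_summary(ds$Y, ds$covariates$batch)
res <- harmonize(ds$Y, ds$covariates, method = "eb")
res$model
#> ComBat fixel harmonisation model
#>   scans: 46, fixels: 207 (207 harmonised, 0 passed through)
#>   batches (batch): Prisma_fit (n=23), Verio (n=23)
#>   covariates: age, sex, icv
#>   method: eb (tol 0.0001, max 100 iterations; 0 batch(es) not converged)

bv_post <- batch_variability_summary(res$values, ds$covariates$batch)
cat(sprintf("mean |batch difference|: %.1f%% before, %.2f%% after\n",
            bv_pre$global$mean, bv_post$global$mean))
#> mean |batch difference|: 11.0% before, 1.90% after
```

The ~11% between-scanner difference injected by the generator falls below
2% after harmonisation, while the fitted age/sex/ICV coefficients
(`coef(res$model)`) carry the biological signal through unchanged.
`summary(res$model)` prints the per-batch empirical-Bayes priors and the
raw versus shrunken batch effects; `predict(res$model, Y_new, data_new)`
harmonises held-out scans from the same batches, and
`combat_save()` / `combat_load()` archive a fitted model as JSON.

The same pipeline is scriptable from a shell via the installed `fixelharm`
executable (`simulate`, `harmonize`, `evaluate` subcommands); see
`?fixelharm_main`.

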