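# waldrace

Race models of antisaccade control, fitted to reaction-time distributions
by simulated maximum likelihood, with the downstream analyses used to stage
neurodegenerative disease from oculomotor behaviour.

## The problem and who this is for

In the antisaccade task a subject must look *away* from an appearing
target. Failures are fast reflexive saccades towards it; successes are
slower voluntary saccades away. Mean RT and error rate conflate at least
three cognitive processes — the reflexive drive, its inhibition, and the
executive programming of the voluntary response — which can degrade
*selectively* and at *different disease stages*. `waldrace` is for
computational-psychiatry and oculomotor researchers who want to decompose
per-subject antisaccade data into those processes and test whether the
resulting parameters track clinical stage better than summary behaviour.

## The model

Three single-boundary Wald accumulators race on each antisaccade trial: a
prepotent accumulator with drift $v_{pre}$, an inhibitory accumulator with
drift $v_{inhib}$, and an executive accumulator with drift $v_{exec}$ that
starts $t_{exec}$ seconds late. Finishing times are first passages of a
unit diffusion through threshold $a$, i.e. Wald (inverse-Gaussian) variates
with density

$$f(t \mid \mu, \lambda) = \frac{\lambda}{\sqrt{2\pi t^3}}
  \exp\!\left(-\frac{(\lambda - \mu t)^2}{2t}\right).$$

An error occurs iff the prepotent racer beats both others; otherwise the
trial ends correct at the executive finishing time; every RT carries a
non-decision offset $t$. Prosaccades use the prepotent accumulator alone,
so their likelihood is closed-form, while the antisaccade likelihood is
approximated by kernel density estimation over model simulations (the PDA,
probability-density-approximation approach) and maximized per subject by
staged Nelder–Mead searches inside a basin-hopping loop.

Around the core model the package provides: summary statistics and
quantile-range delta plots; per-subject fitting, AIC model comparison and a
parameter-recovery harness; OLS regressions of parameters on disease stage
and clinical scores (TMS, TFC, CAG) plus a piecewise-linear breakpoint
(MARS-style) analysis; repeated cross-validated classification (L2
logistic / random forest) with AUC; and a synthetic cohort generator with
planted stage effects that makes the whole pipeline testable end to end.

## Worked example

Simulate one control-like subject, fit the model, and inspect the
distributional signature:

```r
library(waldrace)

truth <- race_params(v_pre = 6.5, v_inhib = 8, v_exec = 7,
                     a_mean = 1.2, t = 0.15, t_exec = 0.08)
trials <- simulate_trials(truth, n_pro = 200, n_anti = 200, seed = 1)

summary_stats(trials)[c("pro_rt_mean", "anti_correct_rt_mean", "anti_accuracy")]
#>   pro_rt_mean anti_correct_rt_mean anti_accuracy
#> 1   0.3446281            0.3950001          0.64

fit <- fit_subject(trials, fit_config(n_sims = 2000, n_hops = 2,
                                      maxit = 400, restarts = 2, seed = 2))
fit
#> Race-model fit: loglik = 469.22 (2461 evaluations, 2 hops)
#> Antisaccade race-model parameters
#>   drifts      v_pre = 6.656  v_inhib = 7.937  v_exec = 7.229
#>   threshold   a_mean = 1.274  a_diff = 0.000  (a_pro = 1.274, a_anti = 1.274)
#>   timing      t = 0.146 s  t_exec = 0.073 s

round(delta_plot(trials)$y, 3)
#> [1] 0.060 0.054 0.050 0.047 0.048 0.046
```

The subject's prosaccades average 0.345 s; correct antisaccades are 50 ms
slower and accuracy is 64%. The fit recovers every generating parameter to
within a few percent (e.g. executive drift 7.23 vs 7, non-decision time
0.146 s vs 0.15 s). The delta plot — antisaccade-minus-prosaccade RT per
quantile range — declines from 60 ms in the fastest range to 46 ms in the
slowest: the negative slope typical of conflict that is resolved as the
trial unfolds.

Cohort-level work goes through the generator and pipeline driver:

```r
spec <- default_cohort_spec()        # 5 stages with planted effects
res  <- run_pipeline(spec, out_dir = "out", seed = 1)
res$stage_ols                        # stage ~ fitted parameters
res$mars_v_inhib                     # breakpoint at symptomatic stages
res$comparison                       # v_exec vs RT-summary classifiers
```

## Documentation

The methods vignette (`vignettes/race-model-methods.Rmd`) covers the model
assumptions, the simulated likelihood's numerical choices, the staged
optimization, what the synthetic cohorts do and do not emulate, the power
analyses behind the validation scales, and known limitations.
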