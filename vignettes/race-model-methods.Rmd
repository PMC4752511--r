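---
title: "Modelling antisaccade control with a Wald-accumulator race: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antisaccade control with a Wald-accumulator race: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waldrace)
```

## The scientific problem

In the antisaccade task a subject must look *away* from an abruptly
appearing target, suppressing the reflexive glance towards it. Errors are
fast reflexive saccades; correct responses are slower voluntary ones. The
balance between the reflexive drive, the ability to stop it, and the
machinery that programs the voluntary response makes the task a compact
probe of inhibitory and executive control — and of their selective
degradation in neurodegenerative disease. Mean reaction times and error
rates blur these processes together; `waldrace` separates them with a
generative process model fitted to the full RT distributions of correct and
error trials, and provides the downstream staging analyses (distributional
delta plots, stage and clinical-score regressions, cross-validated
classification) that turn the fitted parameters into candidate disease
markers.

## The race model

Three single-boundary Wald accumulators race on each antisaccade trial:

* a **prepotent** accumulator (drift `v_pre`) driving the reflexive saccade;
* an **inhibitory** accumulator (drift `v_inhib`) that can stop it;
* an **executive** accumulator (drift `v_exec`), starting `t_exec` seconds
  late (rule retrieval, vector inversion), driving the correct saccade.

Each accumulator's finishing time is the first passage of a unit-variance
diffusion with its drift through the shared threshold, i.e. a Wald
(inverse-Gaussian) variate with density
$f(t) = \lambda (2\pi t^3)^{-1/2} \exp\{-(\lambda - \mu t)^2 / (2t)\}$
in the (drift $\mu$, threshold $\lambda$) parametrization. The diffusion
coefficient is fixed at 1: it sets the (unidentifiable) evidence scale. An
error occurs when the prepotent racer beats **both** the inhibitory and the
executive racer; in every other case the trial resolves as a correct
antisaccade at the executive finishing time, plus the non-decision time `t`
common to all responses. Requiring the prepotent racer to beat the
executive racer as well — not only the inhibitory one — closes a loophole
where arbitrarily slow inhibition could otherwise produce "errors" slower
than the completed correct response; ties, which have probability zero for
continuous finishing times, resolve in favour of inhibition. Prosaccade
trials engage the prepotent accumulator alone and are always correct
(prosaccade errors are rare in practice and not modelled).

This architecture gives each parameter a separable behavioural signature:
`v_pre` speeds prosaccades *and* antisaccade errors; `v_inhib` censors the
error distribution without touching correct RTs; `v_exec` raises accuracy
while making correct RTs faster and less skewed; `t_exec` shifts the whole
correct-RT distribution and lengthens the window in which errors can
happen. The common-random-number tests in the package verify the censoring
and shift signatures *exactly*, by reusing identical underlying draws
across parameter settings (one normal and one uniform per accumulator per
trial, consumed in fixed order by the Michael–Schucany–Haas inverse-Gaussian
transform).

An optional two-threshold variant allows response caution to differ between
conditions (`a_pro = a_mean - a_diff/2`, `a_anti = a_mean + a_diff/2`);
`a_diff = 0` recovers the shared-threshold model exactly, and the two
variants are compared by AIC over the free-parameter count.

## The simulated (PDA) likelihood

The antisaccade likelihood has no closed form, so it is approximated by
probability density approximation: simulate `n_sims` trials at the
candidate parameters, split them by response channel, and estimate one
Gaussian kernel density per channel with Silverman's rule-of-thumb
bandwidth on the RT scale. Each channel density is *defective* — scaled by
the simulated channel probability — so the two channels jointly integrate
to one. Prosaccade trials use the exact closed-form density; antisaccade
trials use the kernel estimate; their log-likelihoods add. Numerical
choices that matter:

* **Density floor.** Densities below $10^{-10}$ (observations outside the
  simulated support, degenerate channels with fewer than two simulated
  trials) are floored before the log, keeping the objective finite
  everywhere rather than throwing optimization off a cliff.
* **Fixed simulation seed per fit.** A fresh simulation per parameter
  setting would make the objective stochastic; fixing the seed for the
  whole fit makes it a deterministic function of the parameters, so the
  optimizer sees a reproducible surface and refits are bitwise identical.
* **Bandwidth and transform.** Silverman's rule per channel, Gaussian
  kernel, no RT transform. The kernel density is stored on a fine FFT grid
  (1024 points, extending four bandwidths past the simulated extremes, so
  the truncated tail mass is negligible against the $10^{-3}$ normalization
  tolerance) and evaluated by interpolation.
* **Simulation effort.** The fitting default is `n_sims = 10000`. The
  package's own validation studies use 2000 (parameter recovery) and 800
  (cohort-scale fitting); at those sizes the seed-to-seed standard
  deviation of a 200-trial subject's log-likelihood is on the order of one
  nat, which the recovery results below show is compatible with accurate
  estimation.

## Fitting: staged initialization, simplex restarts, basin hops

Estimation is per-subject maximum likelihood over a bounded box (drifts in
(0.1, 40], threshold in (0.3, 5], `t` in [0.05, 0.6] s, `t_exec` in
[0, 0.6] s — generous margins around physiological saccade latencies),
searched on a logistic-transformed scale so the optimizer can never leave
the box. The threshold split is parametrized as a fraction of `a_mean` in
(−0.5, 0.5), which keeps both effective thresholds positive by
construction.

The likelihood surface has a pronounced ridge: threshold and drifts trade
off (the RT mean constrains their ratio much more strongly than either
alone), and the non-decision time trades off against distribution shape.
Three design elements deal with this:

1. **Prosaccade pre-fit.** `v_pre`, `a_mean` and `t` are first estimated on
   prosaccade trials alone with the closed-form likelihood, initialized by
   moment matching (`t0 = 0.9 min(RT)`; threshold/drift ratio matched to
   the mean shifted RT).
2. **Anti-only stage.** `v_inhib`, `v_exec` and `t_exec` are then fitted
   with the prosaccade triple held fixed — a well-behaved three-dimensional
   problem that lands the joint stage near the ridge.
3. **Joint Nelder–Mead with restarts inside basin hops.** A single
   Nelder–Mead run stalls on the ridge as its simplex collapses; each local
   search therefore re-inflates the simplex at the incumbent for up to
   `restarts` rounds, stopping early when a round improves the objective by
   less than 0.01 nat. Basin-hopping perturbs the incumbent by 25% of each
   bound range and repeats; the best point across hops is polished once
   more, and a final polish that no longer moves the objective is the
   convergence signal.

With the staged schedule, a light profile (2 hops, 2 restarts, 400
iterations, `n_sims = 2000`) recovers generating parameters from 200
prosaccade + 200 antisaccade trials with truth–estimate correlations near
0.9 for the drifts; a single-hop profile with `n_sims = 800` — used for
cohort-scale fitting, where hundreds of subjects are fitted — keeps
executive- and inhibitory-drift errors near one evidence unit, which the
power analysis below shows is sufficient for the group-level analyses. The
recovery harness (`recover_parameters()`) draws truths from ranges spanning
antisaccade accuracies of roughly 30–90%; settings with near-total error
rates are excluded because they leave almost no correct antisaccades and
make the executive drift unidentifiable by construction, which would
measure the sampling design rather than the estimator.

## Distributional analysis

`delta_plot()` contrasts antisaccade against prosaccade RTs across six
quantile ranges (0–10, 10–30, 30–50, 50–70, 70–90, 90–100%), using only
correct antisaccades. RTs are assigned quantile positions $(i - 0.5)/n$
after sorting, ranges are half-open (the last closed), and empty ranges
propagate as missing values; this estimator is exact, permutation-invariant
and monotone across ranges. The y-axis is the anti-minus-pro difference of
range means; the x-axis their average. Range means are computed per
subject and averaged across subjects at the group level.

In the model, the canonical *negative* delta-plot slope (conflict largest
among early responses) arises from outcome selection: trials whose
executive finishing time is slow are increasingly likely to end as errors,
so the observed correct-RT distribution is right-censored and its upper
quantiles pulled in. This mechanism dominates in the control regime
(accuracy near 70%, executive spread comparable to prosaccade spread).
When executive accumulation slows substantially — as in the generator's
symptomatic stages — the widening of the correct-RT distribution outweighs
the censoring and the slope can turn positive; the package's delta-plot
signature checks therefore use the control-stage parameters.

## The synthetic cohort generator

Because no per-trial clinical dataset ships with the package, the generator
is a first-class module: it defines the study conditions under which every
downstream stage is validated. Five stages (0 = control, 1–2 =
presymptomatic carriers split near/far from onset, 3–4 = manifest disease)
with per-stage parameter means, between-subject Gaussian variation
truncated to the valid parameter box (inverse-CDF truncation, one uniform
per variate, so the generator consumes a fixed number of draws), and
clinical scores:

* `v_exec` declines linearly across all five stages. The stage-0 versus
  pooled stage-1/2 standardized difference is ≈ 0.35 — detectable but
  subtle, the regime where modelling should out-perform summary statistics.
* `v_inhib` is flat across stages 0–2 and declines only at stages 3–4.
* `v_pre`, threshold, `t` and `t_exec` worsen only at stages 3–4, where
  every process is affected.
* The total motor score follows
  `TMS = max(0, round(exp(0.9 stage + ε)) − 1)` with ε ∼ N(0, 0.5), so
  controls can score zero and the `log(TMS + 1)` regression is well posed;
  functional capacity declines linearly from 13 with unit noise; the CAG
  repeat length is drawn independently of the parameters (expanded in
  carriers, normal range in controls).

Stage means are calibrated to produce realistic task behaviour: control
accuracy near 70% falling towards 45% at stage 4, prosaccade RTs near
0.34 s lengthening with stage, correct antisaccades slower than
prosaccades. Defaults mirror a 123/61/61/63/62 stage layout with 100 trials
per condition per subject.

What the generator deliberately does **not** emulate: measurement noise of
the eye tracker, anticipatory and express saccades, prosaccade errors,
trial-history (sequential) effects, and longitudinal visits. Passing the
end-to-end checks therefore shows that the pipeline recovers planted
structure under the model's own assumptions — it cannot certify behaviour
on real recordings, where those un-modelled features exist.

## Regression and breakpoint analyses

Stage is regressed on the fitted parameters (ordinary least squares with
the standard R², adjusted R², F and information-criterion reporting);
clinical scores are regressed on the parameters, with the motor score
log-transformed as `log(TMS + 1)` and listwise deletion for missing
scores. The breakpoint question — does a parameter decline from the start
or only after symptom onset? — is answered by a single-predictor
piecewise-linear regression in the MARS family: forward selection over
hinge terms `max(0, x − knot)` with candidate knots at observed predictor
values, pruned by generalized cross-validation with penalty 3 per knot and
at most two hinges. An exactly linear relationship retains no hinge; the
planted inhibitory-drift structure places its knot at the symptomatic
stages. Power analysis on the generator's defaults (30 replicate cohorts,
estimation noise at the cohort-profile level) shows knot detection at the
correct location needs roughly 300 subjects to be reliable (≈ 97% at 300;
≈ 70% at 100), which sets the cohort size used in the end-to-end check.

## Classification

Binary discrimination uses L2-regularized logistic regression: an outer
stratified shuffle-split (200 repeats, 20% held out) around an inner
10-fold stratified cross-validation that picks the penalty from 13
log-spaced values spanning $10^{-3}$–$10^3$. Features are z-scored with
training-split statistics only. Performance is the held-out AUC
(mean ± SD over repeats), estimated rank-based. Multiclass staging uses a
500-tree random forest under the same outer protocol, reporting held-out
accuracy and the pooled confusion matrix. Feature sets are compared on
*identical* outer splits (common random numbers) with a paired t-test on
per-split AUC differences. Calibration checks: permuted labels stay at
chance; a planted one-dimensional Gaussian gap of d = 1 attains the
analytic optimum Φ(1/√2) ≈ 0.76; a three-class null sits at the
majority-class baseline.

## Validation scales and known limitations

The package's validation studies run at desk scale by design: recovery at
20 subjects × 400 trials with `n_sims = 2000`; the end-to-end cohort at
300 subjects × 200 trials with the single-hop `n_sims = 800` profile; the
reproduction script at the same cohort scale. These sizes were chosen from the
power analyses above — large enough that the planted qualitative pattern
(negative executive-drift slope, symptomatic-stage inhibitory breakpoint,
executive drift out-classifying RT summaries for control-versus-carrier
discrimination) is reliably recoverable, small enough to run on one CPU in
minutes.

Known limitations, inherited from the modelling choices: no within-trial
interaction between accumulators beyond the stop rule; no across-trial
parameter variability; no hierarchical pooling across subjects (per-subject
maximum likelihood only — with simulated likelihoods, hierarchical Bayesian
estimation is attractive but computationally prohibitive here); the kernel
bandwidth rule and the absence of an RT transform are conventions, not
fitted choices; and the AIC comparison counts parameters but not the
effective flexibility the simulated likelihood adds. The breakpoint search
is restricted to one predictor and two hinges, which matches the staging
question but is not a general MARS implementation.
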