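---
title: "Estimating population impact from trial effectiveness and recruitment-based uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population impact from trial effectiveness and recruitment-based uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popimpact)
```

## The estimand

An intervention shown to work in pragmatic randomised trials changes
population outcomes only to the extent that clinicians actually use it.
popimpact formalises this as

$$\text{impact} = \mathrm{RRR} \times U, \qquad \mathrm{RRR} = 1 - \mathrm{RR},$$

interpreted over the population of clinical encounters that would end in
the outcome (for the shipped example, an antibiotic prescription) absent
the intervention. Each such encounter falls in exactly one of three
strata:

* $U(1-\mathrm{RR})$ — the clinician uses the intervention and the
  outcome is averted;
* $U\,\mathrm{RR}$ — the clinician uses it but the outcome occurs anyway;
* $1-U$ — the intervention is not taken up.

`decompose_encounters()` returns these; they sum to one by construction
and the first stratum *is* the impact. The key assumption is that a
clinician's willingness to participate in a pragmatic trial of the
intervention is a reasonable proxy for willingness to adopt it in
practice; the limitations section returns to this.

## Effectiveness: random-effects meta-analysis of relative risks

Each trial contributes $y_i = \log\mathrm{RR}_i$ with large-sample
variance $v_i = 1/a - 1/n_1 + 1/c - 1/n_2$ (`study_log_rr()`). When
either event count is zero, 0.5 is added to all four cells (the common
continuity-correction convention; the correction constant `cc` is an
argument, and `cc = 0` makes a zero cell an error rather than silently
producing an infinite effect).

`pool_dersimonian_laird()` estimates the between-trial variance
$\tau^2$ by the DerSimonian–Laird moment formula and pools with
inverse-variance weights $1/(v_i+\tau^2)$; the CI is Wald on the log
scale. DL is the default because it is what the standard meta-analysis
toolchain (RevMan-style random effects) computes, so results line up
with published pooled RRs; REML is available via `method = "REML"` for
users who prefer a likelihood-based $\tau^2$. With $k = 1$ the pooled
estimate is the single study, $\tau^2 = 0$, and the result is flagged
`single_study`. Degenerate inputs worth knowing about: an equal-variance
pair of discordant studies has $v + \tau^2 = (y_1-y_2)^2/2$ whenever the
moment estimator is interior, so the random-effects CI is invariant to
rescaling both variances — only in the homogeneous ($\tau^2 = 0$) regime
does inflating the variances widen the CI.

For the shipped worked example the pooled RRs (0.36, 0.39, 0.78, 0.61)
are *inputs* (`read_effects()`, `effect_estimate()`): the per-study 2×2
tables live in the four external systematic reviews and are not
re-extracted here. The engine itself is validated against a frozen
hand-computed three-study example, against `metafor::rma(method = "DL")`,
and by parameter recovery on synthetic data (200 simulated trials of
500–1000 per arm recover $\mu$ within ±0.05 and $\tau^2$ within 50%).

## Uptake from recruitment cascades

A cascade is the ordered list of (participated, approached) counts from
the outermost recruitment level inwards (`recruitment_cascade()`,
`read_recruitment()`; `level_order` is explicit in the file, outermost
= 1, so the rule generalises beyond the one- and two-level cascades seen
in practice). `cascade_uptake()` returns

* the proportion $U = \prod_i p_i$ (participation proportions
  multiplied across levels),
* the numerator (innermost participated count), and
* the *effective denominator*: the innermost approached count scaled up
  by the inverse participation of the outer levels, e.g.
  $92 \times (61/22) = 255.09$ potential clinicians.

The unrounded denominator satisfies $U = x/n$ exactly and is what
downstream arithmetic uses; the integer-rounded value (255) is reported
and serves as the binomial $n$. An outer level with zero participating
units makes the scaling undefined and is an error naming the level. A
level with full participation $(n, n)$ leaves the result unchanged.

**Single trial.** The CI is exact Clopper–Pearson by default, computed
through the beta-quantile form of the binomial tail inversion
(`binomial_ci()`); Wilson and Wald are provided because published
intervals are not always exact ones (in the worked example the
procalcitonin interval 12–19% matches Wald rounding while the others
match Clopper–Pearson; both are exposed and the summary-table footnotes
say which was used). The test suite checks the exact interval against a
brute-force root-finding inversion of `pbinom` and verifies its coverage
by exhaustive enumeration at small $n$; it also records that the
conjectured width ordering Wald ≤ Wilson fails in general (at 35/125
Wilson is narrower), while the exact interval is the widest.

**Several trials.** `pool_uptake_glmm()` reduces each population-based
cascade to its count pair and fits the one-observation-per-trial
binomial GLMM $\mathrm{logit}(p_j) = \beta_0 + u_j$,
$u_j \sim N(0, \sigma^2)$, by maximising the exact marginal likelihood
with *adaptive* Gauss–Hermite quadrature: 21 nodes by default, each
trial's integrand re-centred at its mode and re-scaled by the curvature
there. Plain (non-adaptive) quadrature is inaccurate here because a
trial with a large denominator concentrates its integrand far from
zero. One observation per cluster makes this model fragile, so the
optimiser (bounded quasi-Newton on $(\beta_0, \sigma)$ with
$\sigma \in [0, 10]$) is restarted from three fixed starting values and
the best kept; underflowed likelihoods are clamped to a large finite
penalty so the optimiser never sees `-Inf`. $\hat\sigma = 0$ is a valid
boundary fit (flagged `boundary`), at which the model collapses to the
pooled binomial $\sum x_j / \sum n_j$ and the Fisher information
$\sum n_j p(1-p)$ gives the intercept SE exactly; off the boundary the
SE comes from the numerical Hessian at the optimum. Trials flagged as
not population-based are excluded from pooling (recruitment restricted
to, say, academic volunteers does not estimate population uptake).

Two summaries of the fitted model are reported:

* the **population-averaged (marginal) mean**
  $E[\mathrm{expit}(\beta_0 + u)]$, computed by the same quadrature —
  this is the package's headline uptake, since "mean uptake rate" is
  what the impact product needs, and its CI transforms
  $\beta_0 \pm z\,\mathrm{se}$ through the same marginalisation (floored
  at 0);
* the **conditional (median-trial)** value $\mathrm{expit}(\beta_0)$
  with a delta-method interval on the proportion scale using a $t$
  quantile on $k-1$ degrees of freedom, lower bound floored at 0 — the
  convention of mixed-model software such as SAS PROC NLMIXED, supplied
  so results can be compared against outputs produced that way. For the
  three shared-decision-making trials these are 10.4% and 9.5% (0–20%)
  respectively; the published 9.5% (0–20%) is evidently the conditional
  one.

The fit is validated against a coarse-to-fine dense-grid maximisation of
the same marginal likelihood (trapezoid integration over the random
effect; agreement to $10^{-4}$ on the proportion), against
`lme4::glmer(nAGQ = 25)`, and by parameter recovery (50 synthetic trials
of $n = 300$ recover $\beta_0 = -1.8$ within ±0.15 and $\sigma = 0.5$
within ±0.2).

**The shared-decision-making reconstruction.** The published three-trial
totals (281 of 3389) are not exactly recoverable from the published
per-trial counts: the third trial reports 4/24 practice groups and 33/42
clinicians within them, and the effective-denominator rule turns that
into 33/252, which is arithmetic-inconsistent with the totals. The
package ships the published cascade as-is in
`antibiotic_recruitment.csv` and, separately, the reconstruction
45/345, 101/2036, 135/1008 (the residuals of the totals) in
`sdm_recruitment_synthetic_reconstruction.csv`, clearly labelled
synthetic. The discrepancy is documented, not resolved; the pooled fit
on the reconstruction lands at 9.5–10.4% depending on the summary scale,
consistent with the published value.

## Combining and propagating uncertainty

`population_impact()` multiplies RRR by uptake and stores unrounded
fractions; all rounding happens in the reporting layer. A negative RRR
(harmful intervention) is propagated with a prominent warning, never
clipped — silent clipping would hide harm.

`impact_ci_mc()` propagates both intervals by Monte Carlo under
*independence* of effectiveness and uptake: the log-RR is drawn normal
with SE recovered from the RR interval, uptake is drawn normal on the
logit scale with SE recovered from its interval by the delta method
(when the lower uptake bound has been floored at 0 the SE is recovered
from the upper half-width alone), and each draw's impact is
$(1-\mathrm{RR})\,U$. The percentile interval is returned with the lower
bound floored at 0 for beneficial interventions (not for harmful ones,
where a floor would again hide harm). Independence is the only
defensible default — the two components come from different data — and
is stated here rather than estimated. The interval is deterministic
given the seed, leaves the caller's RNG state untouched, and at $10^5$
draws is stable to three decimals across reruns; zero-width inputs
return a point mass with a warning. 100,000 draws (the default) take
well under a second.

`rank_interventions()` orders by impact, breaking ties by higher uptake
(between equally effective options the more adopted one matters more),
then alphabetically for determinism.

## Reporting

`render_summary_table()` emits one row per intervention — pooled RR with
CI, RRR (whole percent), participating and potential clinician counts,
uptake (whole percent) with CI, impact (one-decimal percent), rank —
with footnotes recording the CI method per intervention, any effective
denominator scaled from a multi-level cascade, and any CI lower bound
floored at 0. `render_decomposition()` returns the three strata per
intervention in long format; `plot()` on the model stacks them.
Rendering is pure formatting of stored unrounded values, so it is
idempotent, and re-rendering never compounds rounding error (the
reporting precisions live in `run_config()`).

## The synthetic-data generator

`sim_scenario()` fixes the generative assumptions the analysis itself
makes, so every stage is testable without external data:
per-trial true effects $\log\mathrm{RR}_j \sim N(\mu, \tau^2)$ with
binomial arm outcomes (treated risk clipped at 1 with a warning naming
the trial — clipping keeps the generator total, and the warning keeps it
auditable), and recruitment counts that are binomial with a trial-level
normal random effect on the participation log-odds. Defaults emulate the
antibiotic-prescribing setting: control-arm event risk 0.9 (most
patients prescribed under usual care), $\mu = \log 0.36$, $\tau = 0.3$
(substantial between-trial heterogeneity), participation log-odds
$\mathrm{logit}(0.19)$ with $\sigma = 0.5$, 20–60 units approached per
trial. One shared seed drives a per-trial splittable stream (trial $j$
reseeds at `seed + 1000 j`), so datasets are reproducible while trials
stay independent. Single-level (clinician) cascades are the default
since that is the structure the pooled model assumes; a two-level mode
exercises the cascade plumbing, including the unusable-cascade path when
no practice participates.

What the generator deliberately does **not** emulate — and hence what
passing tests cannot show about real data: selection of which trials
report their recruitment at all, the research-burden and
trial-support biases that make trial participation an under- or
over-estimate of real-world adoption, correlation between a trial's
effect size and its recruitment success, patient-level (third-tier)
uptake, and non-binomial overdispersion within a level. Recovery tests
on this generator validate the *estimators*, not the proxy assumption
itself.

## Validation problem sizes

The shipped suite runs the worked example exactly as printed (desk
scale, seconds); parameter-recovery at 200 simulated trials for the
meta-analysis and 50 trials for the mixed model; an end-to-end check
that the mean estimated impact over 20 simulation seeds is within 0.01
of the generative $\mathrm{RRR}^\* \times U^\*$ (12 trials per seed);
and the Monte Carlo checks at $10^5$ draws. These sizes were chosen to
make the stochastic tolerances tight enough to catch sign and
scale errors while keeping the full suite around a minute on one core.

## Known limitations

* The central proxy assumption — trial participation ≈ real-world
  uptake — is untestable from trial data alone; external validation
  against observed adoption is the right check and is out of scope here.
* Uptake pooling uses one aggregated observation per trial; with two or
  three trials, $\sigma$ is weakly identified and the Wald interval for
  $\beta_0$ is optimistic. The grid oracle guards the numerics, not the
  asymptotics.
* Impacts are relative (fractions of otherwise-affected encounters);
  absolute impact would need baseline event rates, which are not
  modelled.
* Effectiveness and uptake are treated as independent in the Monte
  Carlo propagation.
* Only relative risks are supported as the effect scale; odds ratios,
  risk differences, meta-regression and publication-bias diagnostics
  are out of scope.
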