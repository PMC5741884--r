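# popimpact

Effectiveness in a pragmatic randomised trial does not translate directly
into effect at the population level, because most clinicians never adopt the
intervention. **popimpact** estimates the *population impact* of a clinical
intervention as the product of two quantities:

```
population impact = RRR x U
```

where

- **RRR = 1 − RR** is the relative risk reduction, with RR the pooled
  relative risk from a random-effects meta-analysis of pragmatic trials
  (DerSimonian–Laird by default: per-study log-RR `y_i` with variance `v_i`,
  fixed weights `w_i = 1/v_i`, Cochran's `Q = Σ w_i (y_i − ŷ_FE)²`,
  `τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, pooled
  `ŷ = Σ w*_i y_i / Σ w*_i` with `w*_i = 1/(v_i + τ²)`, Wald CI on the log
  scale; REML is available as an option), and
- **U** is the intervention's *uptake* by clinicians, estimated from the
  trials' own recruitment cascades: if 22/61 practices approached
  participated, and 48/92 clinicians within those practices recruited
  patients, then `U = (22/61)(48/92) = 48 / 255` — 48 participating
  clinicians out of `92 × (61/22) ≈ 255` potential ones. A single trial
  gets an exact (Clopper–Pearson) binomial confidence interval on that
  count pair; several trials are pooled with a random-intercept binomial
  logistic model `logit(p_j) = β₀ + u_j`, `u_j ~ N(0, σ²)`, fitted by
  adaptive Gauss–Hermite quadrature.

The impact decomposes every clinical encounter that would otherwise end in
the outcome (say, an antibiotic prescription) into three strata that sum
to one: `U(1 − RR)` (intervention used and outcome averted), `U·RR`
(used, outcome still occurs), and `1 − U` (intervention not taken up).
Uncertainty is propagated to the impact scale by Monte Carlo, and
interventions are ranked by impact. The intended user is anyone comparing
candidate interventions for implementation or funding when trial reports
are the only evidence about likely adoption.

## Worked example

Four interventions that reduce antibiotic prescribing for acute
respiratory infections in primary care. Pooled relative risks come from
the underlying systematic reviews (shipped in
`inst/extdata/antibiotic_effects.csv`); recruitment cascades come from the
trial reports (`inst/extdata/antibiotic_recruitment.csv`). The three
shared-decision-making trials are pooled with the random-intercept model;
because the published per-trial counts do not exactly reproduce the
published totals (281/3389), the third trial's counts are a documented
reconstruction (`inst/extdata/sdm_recruitment_synthetic_reconstruction.csv`).

```r
library(popimpact)

effects  <- read_effects(system.file("extdata", "antibiotic_effects.csv",
                                     package = "popimpact"))
cascades <- read_recruitment(system.file("extdata", "antibiotic_recruitment.csv",
                                         package = "popimpact"))
sdm      <- read_recruitment(system.file("extdata",
                                         "sdm_recruitment_synthetic_reconstruction.csv",
                                         package = "popimpact"))
cascades <- c(Filter(function(x) x$intervention_id != "shared_decision_making",
                     cascades), sdm)

fit <- estimate_impact(effects = effects, recruitment = cascades,
                       config = run_config(seed = 42))
fit
```

```
Population impact model (4 intervention(s))

        intervention_id               rr rrr_pct participating potential
    delayed_prescribing 0.36 (0.27-0.48)      64            48       255
          procalcitonin 0.39 (0.17-0.86)      61            53       345
                    crp 0.78 (0.66-0.92)      22            35       125
 shared_decision_making 0.61 (0.55-0.68)      39           281      3389
 uptake_pct impact_pct rank
 19 (14-24)       12.0    1
 15 (12-20)        9.4    2
 28 (20-37)        6.2    3
  10 (6-17)        4.0    4

  delayed_prescribing: uptake CI by clopper_pearson
  delayed_prescribing: potential clinicians scaled from a multi-level cascade
  procalcitonin: uptake CI by clopper_pearson
  crp: uptake CI by clopper_pearson
  shared_decision_making: uptake CI by glmm_wald_marginal (3 trials pooled, random-intercept model)
  shared_decision_making: lower CI set as >= 0
```

Reading the top row: delayed prescribing has the strongest trial effect
(RRR 64%) and a 19% clinician uptake, so in 12.0% of encounters where a
patient would otherwise consume antibiotics the intervention is both used
and effective; in 7% it is used without changing the outcome; in the
remaining 81% it is simply not taken up
(`decompose_encounters(48/255, 0.36)`). `plot(fit)` draws the stacked
decomposition; `render_summary_table(fit)` / `render_decomposition(fit)`
return the tables, and `write_summary_table()` writes TSV or markdown.

For the pooled shared-decision-making uptake, the model's
population-averaged mean is 10.4%; the trial-median summary
`expit(β₀) = 9.5%` with its delta-method interval floored at zero
(0–20%) is also reported, matching the convention of mixed-model software
that fits this model (see the fit's `$fit$conditional`).

Every stage is also exercised on synthetic data with the same generative
structure (`sim_scenario()`, `simulate_trials()`,
`simulate_recruitment()`), which is how the meta-analysis and mixed-model
engines are validated where real per-study data are unavailable.

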