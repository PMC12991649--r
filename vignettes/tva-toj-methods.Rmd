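---
title: "Modelling temporal order judgements with TVA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temporal order judgements with TVA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvatoj)
```

## The race model

In a two-stimulus temporal order judgement (TOJ), a probe and a reference
stimulus change (here: flicker) with a stimulus onset asynchrony (SOA),
and the observer reports which changed first. The Theory of Visual
Attention (TVA) treats the two stimuli as racing toward encoding into
visual short-term memory: each stimulus's encoding completion time is
exponentially distributed with rate $v_p$ (probe) or $v_r$ (reference),
and the first to finish is reported first. The rates are set by how the
total processing capacity $C$ (items/ms) is split by the attentional
weights: $v_p = w_p C$ and $v_r = (1 - w_p) C$, so the rates always
partition the capacity. A probe weight $w_p = 0.5$ means neutral
selection; a larger $w_p$ produces "prior entry" -- the probe is
perceived earlier than a physically simultaneous reference.

With the convention that negative SOA means the probe leads, integrating
the race gives the probability of reporting the probe first:

$$
P_{p\,1st}(v_p, v_r, \mathrm{SOA}) =
\begin{cases}
1 - e^{-v_p|\mathrm{SOA}|} + e^{-v_p|\mathrm{SOA}|}\,
  \dfrac{v_p}{v_p + v_r} & \mathrm{SOA} < 0\\[6pt]
e^{-v_r|\mathrm{SOA}|}\, \dfrac{v_p}{v_p + v_r} & \mathrm{SOA} \ge 0.
\end{cases}
$$

Both exponential terms decay: the first branch is the probability the
probe finishes during its head start, plus the probability it survives
the head start and then wins the simultaneous race by rate share. Any
form with a growing exponential would leave the unit interval and
contradict the generative race, so the decaying form is the one
implemented; `p_probe_first()` is verified in the test suite against an
independent Monte-Carlo simulation of the race itself (exponential
finishing times, SOA-shifted onsets) on a grid of rate/SOA combinations,
to within three binomial standard errors at $10^6$ replicates. At
$\mathrm{SOA}=0$ the function reduces to $v_p/(v_p+v_r) = w_p$, which the
tests assert at machine precision.

Internally all rates are items/ms; 0.06 items/ms equals 60 Hz, the
typical capacity with dense shape displays. Reporting in Hz is a
display-layer multiplication by 1000, never an internal unit.

### Change scores

Effects of an experimental manipulation (social or perceptual salience)
are expressed relative to each participant's baseline:
$C_{effect} = C_{cond} - C_{base}$, $w_{peffect} = w_{cond} - w_{base}$,
$\Delta v_p$, $\Delta v_r$, and the relative advantage
$\Delta v_p - \Delta v_r$. Because $v_p + v_r = C$ within every
condition, $\Delta v_p + \Delta v_r = C_{effect}$ identically;
`change_scores()` computes $\Delta v_r$ in complement form so both
identities are exact in floating point. Draw-wise application of the
same arithmetic (`derive_effects()`) preserves posterior correlations --
summaries of $\Delta v_p - \Delta v_r$ are summaries of the draw-wise
difference, not differences of summaries.

## The hierarchical model

`build_toj_model()` binds an SOA-aggregated trial table to a binomial
likelihood: for each participant $j$, condition $c$ and SOA $s$,

$$k_{jcs} \sim \mathrm{Binomial}\!\left(n_{jcs},\,
P_{p\,1st}(w_{jc} C_{j[c]},\, (1-w_{jc}) C_{j[c]},\, s)\right).$$

Two variants encode the two candidate selection mechanisms:

* **`shared_C`** -- one capacity per participant, shared across
  conditions. Salience can only re-allocate resources (weight shifts).
* **`condition_C`** -- capacity free per condition. Salience may also
  change the total encoding rate.

Participant weights are logit-normal around a condition-level group
weight, $\mathrm{logit}(w_{jc}) \sim \mathrm{N}(\mathrm{logit}(\mu_w^c),
\sigma_w^c)$, which guarantees $w \in (0,1)$. Participant capacities are
positive-truncated normal, $C_{jc} \sim \mathrm{N}^+(\mu_C^c,
\sigma_C^c)$; the truncated-normal choice keeps the group capacity prior
on the literal items/ms scale of its constants. Group-level priors are
$\mu_w \sim \mathrm{N}(0.5, 0.2)$ truncated to $(0,1)$ and
$\mu_C \sim \mathrm{N}^+(0.08, 0.05)$ items/ms -- a neutral attentional
split and a weakly informative capacity location, vague enough for data
to dominate (`tva_hyperpriors()` exposes all constants). The
between-participant spreads get half-$t_3$ priors with scales 1 (logit
units) and 0.05 items/ms.

Baseline correction happens *inside* the joint model: baseline and
salience conditions share participant-level structure and are contrasted
draw-wise, rather than fitting conditions separately and subtracting
point estimates.

### Sampling and diagnostics

The posterior is sampled with JAGS (adaptive slice/Gibbs conditional
updates) through `rjags`. With conditional samplers the centered
hierarchical parameterization mixes well and keeps the truncated-normal
capacity nodes natural, so the package uses centered hierarchies
throughout; non-centering is a remedy for Hamiltonian funnel geometry
that does not arise here. Per-chain RNG seeds derive deterministically
from one master seed, so a fit is exactly reproducible from its
settings. Diagnostics are split-chain R-hat and effective sample size
for every monitored parameter; any R-hat above 1.01 raises a warning
(never silent). Divergence counts are a Hamiltonian-specific diagnostic
and have no analogue under conditional sampling.

Three sampler profiles are provided: `cheap` (600 draws / 300 adaptation
/ 2 chains) for simulation loops, `default` (2000/1000/4) for
interactive fits, and `full` (30000/1000/4) for full-fidelity
posteriors. Adaptation is followed by an equal-length burn-in before
retention.

Likelihood evaluation clips $P$ to $[10^{-12}, 1-10^{-12}]$ to protect
the log-density at extreme SOAs; the public `p_probe_first()` is never
clipped.

## Model comparison

`psis_loo()` implements Pareto-smoothed importance sampling
leave-one-out cross-validation from the pointwise log-likelihood that
every fit stores. The held-out unit is the binomial cell (participant
x condition x SOA): responses within a cell are exchangeable under the
model, and the elpd scale depends on this granularity, so it is fixed
rather than configurable. Tail smoothing uses the profile-likelihood
generalized-Pareto estimator with the usual weak-prior regularization of
the shape; shapes above 0.7 are flagged and the flagged fraction is
reported. The implementation is validated in the test suite against an
exact conjugate leave-one-out oracle (a beta-binomial model whose
held-out predictive is available in closed form).

`loo_compare()` reports the elpd difference (best minus other), its
standard error from the pointwise differences, and per-model weights.
The default weights are pseudo-BMA+ (softmax of total elpd under
Bayesian-bootstrap resampling of the pointwise contributions), which
yields the single probability-like number per model that arbitration
reporting wants; stacking of predictive distributions is available via
`method = "stacking"`.

## Synthetic data: what it emulates, and what not

`population_spec()` + `simulate_study()` generate data with the
statistical structure the analysis assumes: the 11-level SOA schedule
(0, +/-14, +/-28, +/-42, +/-63, +/-83 ms) with 8-24 repetitions densest
near simultaneity (the exact per-SOA counts within the published 8-24
range are a package choice: 24 at $|\mathrm{SOA}|\le14$, 16 at 28-42 ms,
8 at 63-83 ms), binomial probe-first counts from the race model,
between-participant heterogeneity on unconstrained scales (log $C$,
logit $w_p$, so every simulated participant is valid by construction),
condition-level injected effects ($\Delta w$, $\Delta C$, each with
optional between-participant spread), and matching-task accuracy with a
self-over-other advantage.

Defaults are fixed study conditions, not tuning knobs: baseline capacity
0.06 items/ms (60 Hz, the typical value for such displays) with 0.01
items/ms between-participant SD; baseline weight 0.5 with a logit-scale
SD of 0.3 (weights mostly within roughly 0.35-0.65, the spread seen in
neutral TOJ baselines); no injected TOJ effect unless requested (assumed
effect sizes are inputs to a power analysis, not facts the generator
should presuppose); matching accuracies 0.95 (self-match) and 0.80
(other-match) with a 0.5 log-odds between-participant SD -- a strong,
reliably observed self-prioritization gap.

The generator deliberately omits features of real data: lapses and
response biases, reaction times, display lateralization, sequential
dependencies, and any mismatch between the fitted likelihood and the
generating process. Passing recovery and calibration tests therefore
shows the estimation machinery is correct and well calibrated *under the
model's own assumptions*; it cannot certify robustness to
misspecification in human data.

## Power analysis

`run_power()` estimates, per sample size, the probability of a
"successful result": by default a 95% HDI of the group weight effect
that excludes zero. Each simulated experiment runs the full pipeline
(population draw, data simulation, fit, effect derivation, success
test). The success proportion gets a uniform Beta(1, 1) prior, so after
$s$ successes in $m$ completed simulations power is reported as the
Beta$(1+s,\,1+m-s)$ mean with its exact HDI. Failed fits are counted and
reported separately, never silently treated as failures or successes.
Inner fits default to the `cheap` profile and the `shared_C` variant
(the target statistic is a weight effect); a master seed ladders into
per-simulation seeds, so the whole analysis is reproducible and
individual simulations can be replayed. Raw power estimates are reported
without monotone smoothing.

Under a null effect the HDI-exclusion rule fires at or below its nominal
5%: hierarchical shrinkage pulls the group effect toward zero, so the
rule is conservative rather than exactly calibrated. This is a property
of HDI-exclusion decision rules in hierarchical models generally, not of
the implementation.

## Numerical choices and degenerate inputs

* HDIs are shortest-interval estimates on sorted draws; the power
  posterior uses the exact Beta HDI via quantile optimization.
* Degenerate draw vectors collapse the HDI to a point; a race with both
  rates zero is an error, while a zero reference rate at non-negative
  SOA legitimately yields probability 1.
* Zero-trial cells are accepted and contribute nothing to the
  likelihood, which is what makes prior-predictive checks expressible as
  ordinary fits.
* SOA sign is fixed at ingest (negative = probe leads) and which
  stimulus is "the probe" is part of the ingested coding -- e.g. the
  self-associated or the physically salient shape -- and is never
  inferred from the data.
* Trial-long CSV input (0/1 `probe_first` per row) is aggregated to
  cells by summation; duplicate keys in already-aggregated input are an
  error rather than being merged silently.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen as
reduced-but-realistic analogues of a TOJ study: 12-30 participants per
simulated experiment, the full 11-level SOA schedule (168 trials per
participant and condition), 20 replicate studies for interval
calibration, 5 seeds per generating mechanism for model arbitration, and
100 cheap-profile simulations for the null calibration of the power
pipeline. The `full` sampler profile (30000 retained draws) is the
full-fidelity setting for real analyses.

## Limitations

* The likelihood is the pure two-stimulus race: no lapse/guessing
  mixture, no response bias term. Strong biases in real data load onto
  $w_p$.
* PSIS-LOO is approximate; observations flagged with high Pareto shape
  deserve a refit-based check, which the package reports but does not
  automate.
* The matching-task module provides descriptive SPE scores and
  correlations only; it does not model the matching task generatively.
* Full-scale posteriors (the `full` profile on dozens of participants)
  are minutes-to-hours of sampling, not interactive.
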