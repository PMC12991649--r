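# tvatoj

Hierarchical Bayesian modelling of temporal order judgements (TOJ) with
the Theory of Visual Attention (TVA).

In a TVA-TOJ experiment, a probe and a reference stimulus flicker with a
stimulus onset asynchrony (SOA), and the observer reports which came
first. TVA treats the two stimuli as an exponential race toward encoding
into visual short-term memory: the total processing capacity *C*
(items/ms) is split by the attentional weight *w<sub>p</sub>* into
encoding rates *v<sub>p</sub> = w<sub>p</sub>C* and
*v<sub>r</sub> = (1 − w<sub>p</sub>)C*. The probability of reporting the
probe first, with SOA < 0 when the probe leads, is

```
P = 1 − exp(−v_p·|SOA|) + exp(−v_p·|SOA|) · v_p/(v_p+v_r)   (SOA < 0)
P = exp(−v_r·|SOA|) · v_p/(v_p+v_r)                          (SOA ≥ 0)
```

Decomposing TOJ data into *C* and *w<sub>p</sub>* separates two
mechanisms of attentional selection — a re-allocation of a fixed
capacity (weight shift) versus a change in the capacity itself — which
is the arbitration at the heart of studies of social and perceptual
salience ("prior entry" effects).

The package provides:

* **`tva_core`** — the closed-form psychometric function
  (`p_probe_first()`), the capacity/weight parameterization
  (`tva_params()`, `rates_from_params()`) and baseline-corrected change
  scores (`change_scores()`).
* **Synthetic data** — `population_spec()`, `sample_population()`,
  `simulate_toj()`, `simulate_matching()`, `simulate_study()`: generate
  TOJ and shape-label matching datasets with the statistical structure
  the analysis assumes, so the full pipeline runs without experimental
  data.
* **Hierarchical estimation** — `build_toj_model()` /`fit_toj_model()`
  fit participant- and group-level *C* and *w<sub>p</sub>* by MCMC
  (JAGS) under a shared-capacity (`shared_C`) or
  condition-specific-capacity (`condition_C`) variant;
  `derive_effects()` turns posterior draws into draw-wise effect scores
  (`w_peffect`, `C_effect`, `Δv_p`, `Δv_r`, `Δv_p − Δv_r`).
* **Model comparison** — `psis_loo()` (Pareto-smoothed importance
  sampling leave-one-out) and `loo_compare()` with pseudo-BMA+ or
  stacking weights.
* **Power analysis** — `run_power()`: simulation-based Bayesian power
  (success = group weight-effect HDI excludes zero) across sample sizes.
* **Self-prioritization** — `compute_spe()` scores matching-task
  accuracy advantages; `correlate()` / `correlate_spe_effects()` relate
  them to attentional effect scores.
* **IO and CLI** — CSV readers/writers with validation
  (`read_toj()`, `read_matching()`, `write_outputs()`), and a
  command-line wrapper (`tvatoj_cli()`; script in `inst/cli/tvatoj.R`)
  with `simulate`, `fit`, `compare`, `power`, `spe`, `report` commands.

## Worked example

```r
library(tvatoj)

# a synthetic 20-participant study with a +0.06 group weight effect
spec  <- population_spec(C_mean = 0.06,
                         effects = list(salience = list(dw = 0.06)))
study <- simulate_study(spec, 20, seed = 501)

fit <- fit_toj_model(build_toj_model(study$toj, variant = "shared_C"),
                     draws = 2000, tune = 600, chains = 2, seed = 503)
posterior_summary(fit)
#>            parameter       mean          sd   hdi_lower  hdi_upper p_gt_0 ...
#> 1     mu_w[baseline] 0.48886214 0.021441325 0.449227095 0.53386292      1
#> 2     mu_w[salience] 0.56309116 0.018621030 0.528343997 0.60032105      1
#> 3               mu_C 0.06350291 0.004064552 0.056082411 0.07228064      1
#> ...

derive_effects(fit, "salience")
#> Effect scores: salience vs baseline (baseline)
#>  parameter         mean          sd    hdi_lower    hdi_upper p_gt_0
#>   C_effect  0.000000000 0.000000000  0.000000000  0.000000000  0.000
#>  w_peffect  0.074229017 0.028995437  0.012861662  0.126514231  0.994
#>       dv_p  0.004708359 0.001862709  0.001085485  0.008342433  0.994
#>       dv_r -0.004708359 0.001862709 -0.008342433 -0.001085485  0.006
#>     dv_rel  0.009416718 0.003725418  0.002170970  0.016684867  0.994
```

The group weight-effect posterior (mean 0.074, 95% HDI 0.013–0.127)
covers the injected +0.06, and under the shared-capacity variant the
rate changes are a pure trade-off (`dv_p = −dv_r`): the salience
condition shifts about 0.005 items/ms (≈5 Hz) of encoding rate toward
the probe.

```r
# which mechanism generated the data?
fit2 <- fit_toj_model(build_toj_model(study$toj, variant = "condition_C"),
                      draws = 2000, tune = 600, chains = 2, seed = 504)
loo_compare(fit, fit2)
#> PSIS-LOO model comparison (pseudobma weights):
#>        model   elpd    se p_loo d_elpd  d_se  weight bad_k_fraction
#>     shared_C -714.8 20.47 44.71   0.00 0.000 0.91737              0
#>  condition_C -720.3 20.08 54.02   5.43 3.681 0.08263              0
```

Weight-shift data were generated, and the simpler shared-capacity model
correctly takes the weight (0.92).

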