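# avoidgen

Generative modelling of how instrumental avoidance generalizes across
perceptually similar stimuli — for computational psychiatry and
learning researchers who want to separate **perceptual** confusion
between danger cues and their neighbours from **value-based** transfer
of learned threat and safety.

Stimuli live on a perceptually linear "spikiness" axis ρ ∈ (0, 1):
two danger cues (CS+), one safety cue (CS−), and four generalization
stimuli (GS) placed one discrimination threshold θ away from each
CS+. Avoidance behaviour is modelled with hybrid
Rescorla–Wagner / Pearce–Hall Q-learners,

    V[i, t+1] = V[i, t] + κ · α_t · (R_t − V[i, t])
    α_{t+1}   = η · |R_t − V[i, t]| + (1 − η) · α_t
    P(avoid)  = 1 / (1 + exp(−β · (0 − V[i, t] − 0.2 − bias)))

with three nested variants: perceptual confusion only (a GS is
evaluated as 0.75·V_GS + 0.25·V_CS+), plus Gaussian value
generalization over the axis with one width σ, or with separate
widths for aversive and neutral feedback (σ_A, σ_N):

    G_j = exp(−(ρ_i − ρ_j)² / (2σ²)),   V[j] ← V[j] + κ · α_t · PE · G_j

The package provides:

* **Task design and trial sequencing** (`build_design()`,
  `generate_sequence()`) with the study's ratios, 80% reinforcement
  and pseudorandomisation constraints.
* **Likelihood and simulation** for all three model variants
  (`rl_loglik()`, `simulate_agent()`; compiled core), with per-trial
  latent traces (expected P(shock), prediction error, associability)
  for regressor export.
* **Hierarchical empirical-Bayes fitting** (`fit_subject()`,
  `fit_population()`): MAP + Laplace evidence with iterative prior
  refinement, predictive accuracy, and a Bayesian p value against
  random choice.
* **Random-effects Bayesian model selection** (`rfx_bms()`) with
  exceedance probabilities.
* **Psychophysics** (`fit_psychometric()`, `threshold()`):
  lapse-bounded logistic fits and closed-form 75% thresholds.
* **Behavioural statistics** (`avoidance_summary()`,
  `peak_shift_index()`, `qc_filter()`, `nyholt_meff()`,
  `precision_weighted_regression()`).
* **Crossnobis representational distances** (`noise_normalize()`,
  `cv_ldc()`, `distance_change()`).
* **Synthetic cohorts** (`cohort_spec()`, `generate_study()`,
  `generate_patterns()`) emulating the behavioural study for recovery
  work, plus a pipeline front end (`run_pipeline()`, with a CLI
  wrapper in `inst/cli/avoidgen.R`).

Everything takes and returns tibbles where tabular, pipes cleanly,
and has `tidy()`/`glance()`/`autoplot()` methods for fitted objects.

## Worked example

Simulate one subject from the two-width model and fit it back:

```r
library(avoidgen)

design <- build_design()                      # 2 CS+, 1 CS-, 4 GS; theta 0.071
trials <- generate_sequence(design, seed = 1) # 5 blocks x 38 trials
spec   <- model_spec("value_2w")
truth  <- agent_params(kappa = 0.5, eta = 0.3, beta = 5, bias = 0.4,
                       sigma_a = 0.75, sigma_n = 0.03)

sim <- simulate_agent(truth, spec, trials, design, seed = 2)
avoidance_summary(sim$session, design)
#> <avoidance_summary>
#> # A tibble: 3 × 4
#>   role     n_trials prop_avoid      z
#>   <chr>       <int>      <dbl>  <dbl>
#> 1 CS_MINUS       50       0.14 -1.12
#> 2 GS             40       0.6   0.325
#> 3 CS_PLUS       100       0.75  0.797
```

GS avoidance is intermediate between safety and danger — the
generalization gradient — and its within-subject z value (0.33) is
the *relative* GS avoidance measure. Fitting recovers the generating
parameters and their evidence:

```r
post <- fit_subject(sim$session, spec, design, seed = 3)
post
#> <subject_posterior> F = -110.183  logLik = -95.8601
#> # A tibble: 6 × 4
#>   parameter estimate latent_mean latent_var
#> 1 kappa       0.375     -0.511      0.132
#> 2 eta         0.177     -1.54       0.506
#> 3 beta        6.89       1.93       0.0636
#> 4 bias        0.412      0.412      0.00261
#> 5 sigma_a     1.01       0.00981    0.608
#> 6 sigma_n     0.0352    -3.35       0.171

predictive_accuracy(post, sim$session, spec, design)
#> [1] 0.7631579
bayes_p_random(post)
#> [1] 4.533003e-10
```

The wide aversive width (σ̂_A ≈ 1.0 vs σ̂_N ≈ 0.035) reproduces the
generating asymmetry: threat spreads broadly across the axis, safety
barely at all. The reciprocal of `latent_var` is the precision used
to weight this subject in group-level regressions. Cohort-level
recovery, model comparison and the peak-shift dissociation run the
same way from `cohort_spec()` / `generate_study()` /
`fit_population()` / `rfx_bms()`.

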