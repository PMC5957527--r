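---
title: "Modelling avoidance generalization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling avoidance generalization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avoidgen)
```

avoidgen models how instrumental avoidance, learned for specific
danger cues, spreads to perceptually similar stimuli — and how much of
that spread is perceptual (failing to tell stimuli apart) versus
value-based (actively transferring learned value across stimuli that
are discriminated perfectly well). This vignette documents the models,
the fitting machinery, the synthetic-data generator, and the design
decisions that were genuinely open, so that a reader can judge exactly
what the package's recovery studies do and do not establish.

## The task and its stimulus space

Stimuli are parameterised by a single perceptually linear "spikiness"
coordinate $\rho \in (0, 1)$. The default design places two danger
cues (CS+) at $\rho = 0.25$ and $0.75$, one safety cue (CS-) at
$\rho = 0.40$, and four generalization stimuli (GS), one on each side
of each CS+ at an offset $\theta$ equal to the 75% discrimination
threshold (0.071 for the laboratory preset, 0.065 for the online
preset). Subjects complete 5 blocks of 38 trials (10 per CS+, 10 CS-,
2 per GS), deciding on each trial whether to make a costly avoidance
response. Unavoided CS+ trials deliver an aversive outcome with
probability 0.8; GS and CS- trials never do.

The CS- coordinate is not a published constant; 0.40 is the package
default because it reproduces the asymmetric geometry that matters for
peak shift — each CS+ has one GS on the near side of the CS- and one
on the far side — and it is configurable. The reinforcement rate is
realised as independent Bernoulli draws per trial by default ("80% of
non-avoidance trials" describes a rate, not a quota); an exact
per-block quota mode is available via `generate_sequence(quota =
TRUE)`. Pseudorandomisation constraints (no two consecutive GS trials,
no GS in the first five trials of block 1) are package inventions in
the spirit of minimising GS learning; they are configurable through
`sequence_constraints()`.

## The learning models

All three model variants are hybrid Q-learners over stimulus states
with the avoid action pinned at value 0 (avoidance always cancels the
outcome). For presented stimulus $i$ with outcome $R_t \in \{0, -1\}$:

$$V_{i,t+1} = V_{i,t} + \kappa\,\alpha_t\,(R_t - V_{i,t})$$
$$\alpha_{t+1} = \eta\,|R_t - V_{i,t}| + (1 - \eta)\,\alpha_t$$

The trial-varying associability $\alpha_t$ (Pearce–Hall) scales
learning by the recent magnitude of prediction errors. Choices follow
a softmax on the value difference with a response cost $c = 0.2$ and a
bias $b$:

$$P(\text{avoid}) = \frac{1}{1 + \exp(-\beta\,(0 - V_{i,t} - c - b))}$$

Perceptual generalization enters as identity confusion: a GS is
evaluated as $(1 - p_c)V_{GS} + p_c V_{CS+}$ with $p_c = 0.25$ by
default, i.e. held at the calibrated 75% discriminability. A linear
schedule for $p_c$ across the session is available for modelling
conditioning-induced acuity change.

Value-based generalization adds a Gaussian spread of each update over
all states $j$:

$$G_j = \exp\!\left(-\frac{(\rho_i - \rho_j)^2}{2\sigma^2}\right),
  \qquad V_{j,t+1} = V_{j,t} + \kappa\,\alpha_t\,(R_t - V_{i,t})\,G_j$$

with one width $\sigma$ in the one-width variant, and separate widths
$\sigma_A$ (aversive outcomes) and $\sigma_N$ (neutral outcomes) in
the two-width variant. Setting $\sigma_A = \sigma_N$ reproduces the
one-width likelihood exactly, and $\sigma \to 0$ recovers the
perceptual-only model; the variants are strictly nested.

Decisions the equations do not pin down, resolved as follows:

* **Initial conditions.** $V = 0$ for all states (neutral on the
  $\{0, -1\}$ outcome scale); $\alpha_0 = 1$, fixed, configurable, not
  a free parameter.
* **Associability scope.** $\alpha_t$ is a single global scalar (the
  notation indexes it by trial only) and updates on every trial; on
  avoided trials the prediction error is zero by definition, so
  $\alpha$ decays geometrically by $(1 - \eta)$.
* **What learns.** Updates target the objectively presented stimulus;
  perceptual confusion affects evaluation only.
* **Width selection.** The realised outcome valence on the trial
  selects the width ($R = -1 \to \sigma_A$, $R = 0 \to \sigma_N$),
  including neutral outcomes on CS+ trials.
* **No clipping.** Spread updates are applied exactly as written;
  values are not clipped to $[-1, 0]$ (boundedness can fail under
  spread, and does not fail under the perceptual-only variant with
  $\kappa\alpha \le 1$).

A consequence worth knowing: because aversive updates spread widely
while safety updates stay narrow ($\sigma_N \ll \sigma_A$), GS states
accumulate the CS+'s negative value without its safety corrections,
so simulated GS avoidance can *exceed* CS+ avoidance under strong
aversive generalization. This is the model mechanism, not an artifact.

### Peak shift

Under perceptual confusion alone, the two GS flanking a CS+ share one
value distribution, so the far-minus-near contrast
(`peak_shift_index()`, near/far defined by rho distance to the CS-)
has expectation zero. With value spread, safety updates at the CS-
reach the near GS more than the far GS, displacing avoidance away
from the CS-. The package's simulations reproduce this dissociation:
perceptual-only cohorts of 100 show $|$mean index$| < 0.02$, while
two-width cohorts with $\sigma_N$ comparable to the CS+/CS- gap
(0.15) show a reliably positive index.

## Fitting

Subjects are fitted on an unconstrained latent scale: logistic
transforms for $\kappa, \eta$, log for $\beta$ and the widths,
identity for the bias. `fit_subject()` maximises the log posterior
under an independent Gaussian prior (default mean 0, variance 3 —
weakly informative, centring $\kappa, \eta$ at 0.5 and $\beta$,
$\sigma$ at 1) with multistart BFGS (8 seeded starts), and
approximates the log evidence by the Laplace free energy

$$F = \log p(y\,|\,\theta^*) + \log p(\theta^*)
  - \tfrac{1}{2}\log|H| + \tfrac{d}{2}\log 2\pi .$$

This replaces a full variational scheme: the asymptotics are the
same, the diagnostics (posterior variances for precision weights, $F$
for model comparison) are the same, and it is far easier to verify.
Printed parameter estimates from variational toolboxes are therefore
matched qualitatively, not numerically.

Numerical choices: the Hessian is computed by central differences
(step $10^{-4}$ in latent space). Its eigenvalues are floored at the
weakest prior precision before inversion — under a concave
log-likelihood the posterior can never be broader than the prior, and
without the floor a single near-flat direction (common for width
parameters, see below) produces essentially unbounded Laplace
variances that then poison the group-level variance update. Fits where
the floor engaged are flagged (`ridged`). The objective returns a
large finite penalty outside $|\text{latent}| \le 50$ so stray starts
cannot crash the optimiser.

`fit_population()` implements empirical-Bayes refinement: subject fits
under the current prior, then moment matching of the prior to the
posterior latents (variance = spread of posterior means + mean
posterior variance), iterated until the summed free energy changes by
less than `tol` (0.01) or `max_iter` (32). After the first sweep
subjects are warm-started from their previous optimum with 3 fresh
starts. `tol = Inf` yields exactly one sweep, i.e. independent fits
under the initial prior. Three consecutive tolerance-sized drops in
summed $F$ abort refinement with a diagnostic; small transient drops
can occur at small cohort sizes because the moment-matched variance
is itself noisy.

### Evidence for model comparison

`evidence_matrix()` defaults to the free energies of the *first*
sweep, under the common fixed prior, rather than the refined-prior
values. The reason is structural: once the prior has been
moment-matched to the same data, the Occam penalty that separates
nested models collapses (measured at ~0.02 nats/subject between the
perceptual-only model and the one-width model on perceptual-only
data), because the refined prior concentrates exactly where the
richer model's extra parameter mimics the simpler model. Under the
fixed weakly-informative prior the penalty is restored (~1.5–4
nats/subject) and cohorts simulated from each variant are recovered
by `rfx_bms()` with exceedance probability above 0.9 at 15 subjects.
Refined evidences remain available (`evidence = "refined"`).

`rfx_bms()` is the standard random-effects scheme: variational
Dirichlet updates over model frequencies, exceedance probabilities by
closed-form Beta comparison for two models and by $10^6$ Monte-Carlo
Dirichlet draws otherwise (MC error below 0.001).

## Psychophysics

`fit_psychometric()` fits the lapse-bounded logistic
$P(\text{diff}) = (1 - \lambda) / (1 + \exp((\alpha - \Delta\rho)/\beta))$
to same/different counts by constrained maximum likelihood
(`L-BFGS-B`, 10 starts plus a scaled polish step so independent start
sets agree within $10^{-8}$ in log-likelihood). The guess rate is
fixed at 0, matching the stated response range; the lapse bound
defaults to 0.06 (the original toolbox's bound is unpublished) and the
slope is constrained positive because the spikiness axis is
perceptually monotone. `threshold()` inverts the fitted curve in
closed form; the 75% point is the $\theta$ used to place GS stimuli.

## Synthetic cohorts

`cohort_spec()` + `generate_study()` emulate the behavioural arm of a
generalization study end to end: latent-Gaussian cohorts mapped
through the fitting transforms, per-subject trial sequences and
simulated sessions, discrimination data from per-subject psychometric
observers (levels 0–0.15, 160 trials), and a subject table carrying a
symptom score with a planted standardized association to
$\log \sigma_A$ plus heteroscedastic parameter "estimates" with known
precisions for the regression stage.

Generating values are settings, not reproduced results: group means
$\kappa = 0.5$, $\eta = 0.3$, $\beta = 5$, bias 0.4, $\sigma_A =
0.75$, $\sigma_N = 0.03$, with dispersions moment-matched to the
reported group SDs where such SDs exist ($\sigma_A \pm 0.29$,
$\sigma_N \pm 0.03$, bias $\pm 0.14$) and latent SDs 0.5/0.5/0.25 for
$\kappa$/$\eta$/$\log\beta$ otherwise. Symptom scores are generated on
the standardized scale with residual SD $\sqrt{1 - \text{slope}^2}$,
so the planted slope is a correlation-scale quantity; estimate noise
is uniform on SD 0.1–0.3 (latent scale), defining the attached
precisions.

What the generator does *not* emulate: reaction times, attention
lapses and stimulus-independent responding, questionnaire item
structure, fMRI time series. Passing recovery tests therefore show
that the pipeline is self-consistent under the model's own
assumptions at realistic sizes — not that real data satisfy those
assumptions.

### What recovery can and cannot show here

Profiling the likelihood in $\sigma_A$ reveals a structural
identifiability limit: with stimuli spanning at most 0.64 in $\rho$,
widths above roughly 0.5 produce near-uniform spread ($G \ge 0.7$
everywhere), so the likelihood is nearly flat across $0.5 - 2.5$
(within ~0.3 nats of its maximum). Small widths are well identified;
large widths are distinguished from small ones but not from each
other. Consequently, with the cohort dispersion matched to the
reported group SD ($\pm 0.29$ around 0.752), most subjects lie in the
flat region and the rank correlation between true and recovered
$\sigma_A$ plateaus around 0.25 at 40 subjects — while the *group
mean* is recovered well (within 0.1), the $\sigma_A > \sigma_N$
ordering is preserved for essentially all subjects, and the same
pipeline reaches rank correlations above 0.6 when the cohort spans
the identifiable region (latent SD 1.0). Individual-difference
analyses of wide aversive generalization should therefore lean on the
precision weights, which correctly down-weight the flat-likelihood
subjects.

## Representational distances

`cv_ldc()` computes the leave-one-run-out cross-validated linear
discriminant contrast: per fold, the training-run pattern difference
is projected onto the held-out run's difference, and fold values are
averaged and divided by the voxel count $P$ so distances are
comparable across regions of different size (the division is a
package choice; no normalisation recipe is published). Independence of
train and test noise gives the estimator a meaningful zero — its
expectation is 0 for identical condition distributions and it may go
negative. `noise_normalize()` whitens patterns by the inverse square
root of a per-run residual covariance shrunk toward its diagonal
(analytic shrinkage by default; floored at 0.5 when residual samples
are fewer than a tenth of the voxel count). `distance_change()` is
the late-minus-early contrast (runs 3–5 vs 1–2 by default), negative
when representations converge.

## Problem sizes and reproducibility

The recovery studies shipped in the tests and in
`scripts/acceptance.R` use: 200 random 50-trial fixtures for the
likelihood oracle; 40 subjects x 190 trials for two-width parameter
recovery; 15 subjects per generating variant (one fitting sweep per
model, which is exactly what the fixed-prior evidence needs) for
model recovery; 100-subject cohorts for the peak-shift dissociation;
200 simulations for the crossnobis zero point; 100 replicates each
for threshold recovery and symptom-slope calibration at $n = 482$.
Every stage derives its seeds from one master seed, and identical
seeds give byte-identical artifacts.

## Known limitations

* MAP + Laplace is an approximation to full variational inference;
  evidences and posterior variances inherit its local-curvature
  character.
* The precision-weighted regression stage uses model-based SEs from
  the weighted normal equations; when the dominant residual is
  homoscedastic (as in the planted-slope simulations) its 2-SE
  intervals cover at slightly below the nominal rate (~91–92%
  measured).
* The $\sigma_A$ identifiability ceiling described above is a
  property of the stimulus geometry, not of the optimiser; wider
  stimulus arrays would be needed to resolve large widths.
* `rfx_bms()` implements plain exceedance probabilities; protected
  exceedance probabilities and family-level inference are out of
  scope.
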