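---
title: "Hierarchical Wiener diffusion modelling of two-choice priming data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Wiener diffusion modelling of two-choice priming data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wienerhdm)
```

## The model

`wienerhdm` analyses two-choice response-time experiments -- in particular a
4 (face prime) x 2 (target word valence) affective priming task under
continuous flash suppression -- with a hierarchical Bayesian Wiener
diffusion model. Each trial's response and latency are treated as the first
passage of a Wiener diffusion between two absorbing boundaries:

* boundary separation $\alpha > 0$: evidence required to respond;
* relative starting point $\beta \in (0,1)$: fixed at $0.5$ (an unbiased
  process), never estimated;
* drift rate $\delta$: mean rate of evidence accumulation (evidence units
  per second);
* nondecision time $\tau \ge 0$ (seconds): encoding and motor time outside
  the diffusion;
* within-trial diffusion coefficient $s = 1$ (the scale convention; it is a
  constant, not a parameter).

Responses are **accuracy coded**: the upper boundary is the correct valence
categorisation. Two observations force this choice over stimulus coding:
the starting point is fixed at 0.5, and with observed accuracies near 97%
all condition-level drifts must then be positive and of similar size --
which is what a model of correct/error coding produces, while a
stimulus-coded model would need drifts of opposite signs per response
option.

The hierarchy (per participant $p$, condition $i$, trial $j$):

$$\delta_{pij} \sim \mathrm{N}(\nu_{pi}, \eta^2), \qquad
  \tau_{pij} \sim \mathrm{N}(\theta_{pi}, \chi^2)\ \text{truncated at } 0,$$
$$\nu_{pi} \sim \mathrm{N}(\mu_{\nu[i]}, \sigma_\nu^2), \qquad
  \theta_{pi} \sim \mathrm{N}(\mu_{\theta[i]}, \sigma_\theta^2)\ (\ge 0),
  \qquad \alpha_p \sim \mathrm{N}(\mu_\alpha, \sigma_\alpha^2)\ (>0).$$

The condition-level means $\mu_{\nu[i]}$ and $\mu_{\theta[i]}$ (8
conditions) are the quantities of scientific interest; $\alpha_p$ is a
participant-level random effect; $\eta$ and $\chi$ are trial-level spreads
shared across participants (a per-participant variant was considered and
rejected for the default because the data sizes here cannot separate 20
extra variance parameters; the shared values already absorb the bulk of
trial-level overdispersion).

### Trial-level parameters are marginalised, not sampled

With 320 trials per participant, sampling $\delta_{pij}$ and $\tau_{pij}$
would add two latent variables per trial. Instead the likelihood integrates
them out:

* drift: the drift enters the first-passage density only through
  $\exp(-\delta \alpha w - \delta^2 t/2)$, so its Gaussian integral has a
  closed form -- the marginalisation is exact;
* nondecision: the convolution over $\tau$ has no closed form and is
  integrated by Gauss--Hermite quadrature against
  $\mathrm{N}(\theta_{pi}, \chi^2)$, 5 nodes by default (configurable 1--7;
  5 nodes integrate polynomials of degree 9 exactly and were accurate to
  about $10^{-3}$ relative error against dense numerical integration in the
  regimes exercised by the tests). Nodes falling below zero are clamped at
  zero, consistent with the truncation in the generating model; with
  $\theta \approx 0.46$ s and $\chi \approx 0.05$ s the affected mass is
  negligible.

### Priors

The priors are weakly informative on the scales of this task (the analysis
this package replays did not publish its priors, so these are the package's
own defaults; any prior set passing the recovery suite is acceptable and
all are overridable via `hdm_priors()`):

| parameter | prior | rationale |
|---|---|---|
| $\mu_{\nu[i]}$ | N(0, 5²) | drifts of magnitude 2--3 are typical; 5 is diffuse |
| $\mu_{\theta[i]}$ | N(0.3, 0.5²), $\ge 0$ | nondecision times live in 0.2--0.6 s |
| $\mu_\alpha$ | N(2, 1²), $> 0$ | boundary separations 1--3 under $s = 1$ |
| all SDs ($\sigma_\nu, \sigma_\theta, \sigma_\alpha, \eta, \chi$) | half-N(0, 1) | keeps spreads proper without forcing them |

The truncation of the hierarchy normals at zero is enforced on the
person-level parameters; the truncation's normalising constant is omitted
from the hierarchy densities because at the posterior's scale
($\theta/\sigma_\theta$ and $\alpha/\sigma_\alpha$ both far from 0) the
omitted mass is numerically zero.

## The first-passage density

The likelihood kernel is the defective first-passage density of the Wiener
process, evaluated through the standardised driftless density with two
series expansions -- one that converges quickly for small scaled times and
one for large -- choosing whichever needs fewer terms for a truncation
error at most `eps` (default `1e-10` in `dwiener()`, `1e-7` inside the
sampler; both well within the `1e-7` accuracy contract). The two
expansions agree to better than `1e-9` at the switch point across the
tested parameter grid. The lower-boundary density is the reflection
$(\alpha, 1-\beta, -\delta)$; the drift-free limits of the choice
probability and mean decision time are evaluated by series around
$\delta = 0$, so nothing divides by zero.

Densities below `1e-300` are floored before taking logs inside the
sampler: a proposal that makes an observed response time impossible is
rejected through an overwhelming (but finite) penalty instead of
propagating `-Inf` through the chain.

## Sampling

`hdm()` runs independent chains (3 by default, 2000 burn-in + 2000
retained sweeps by default) of an adaptive Metropolis-within-Gibbs sampler:

* random-walk Metropolis for each $\nu_{pi}$, $\theta_{pi}$, $\alpha_p$,
  with per-parameter scales adapted towards 44% acceptance during burn-in
  and frozen afterwards ($\nu$ updates reuse cached series terms because
  the drift only enters the closed-form factor);
* exact conjugate Gibbs draws for $\mu_{\nu[i]}$, $\mu_{\theta[i]}$,
  $\mu_\alpha$;
* joint *shift* moves that translate a group mean together with all its
  person-level parameters (and one global shift for $\alpha$). The centred
  hierarchy couples these parameters -- tightly so when a group SD is
  small -- and without the joint moves the group level can mix arbitrarily
  slowly (in the degenerate limit of the recovery tests, not at all);
* slice sampling on $\log \sigma$ for the three group SDs (cheap, since
  only hierarchy terms are involved, and far better behaved than a random
  walk near the bottom of the funnel);
* random-walk Metropolis on $\log \eta$, $\log \chi$ against the full
  marginal likelihood.

Initial values are method-of-moments: cell accuracy mapped through the
analytic choice probability for drifts, 85% of the participant's 5th RT
percentile (capped below each cell's fastest response) for nondecision
times, and chain-specific overdispersing jitter. Everything is
reproducible from a single integer seed.

Convergence is assessed with the split-chain potential scale reduction
factor (`rhat()`); reporting functions refuse to summarise a fit whose
worst R-hat exceeds the configured threshold (1.1) unless explicitly
overridden. HDIs are sample-based shortest intervals (`hdi()`), with ties
resolved to the lowest interval.

## The simulator

`rwiener()` integrates the diffusion path by Euler--Maruyama with step
`dt = 1e-4` s and applies the Broadie--Glasserman--Kou continuity
correction (boundaries pulled inward by $0.5826\,s\sqrt{dt}$), cancelling
the leading-order bias of discrete boundary monitoring; the residual bias
at the default step is below the Monte-Carlo error of every oracle check
used here (choice probabilities and mean RTs agree with the closed forms
to well under 1% at $n = 10^5$). The simulator keeps its own
counter-seeded generator so large simulations are fast and reproducible
independent of R's RNG state, and the seed is drawn from R's RNG when not
given, so `set.seed()` still governs end-to-end runs.

## The synthetic-data generator

`simulate_napt_study()` emulates the target study's design: 4 face primes
x 2 word valences, 40 trials per condition, presented in 4 blocks of 80
trials balanced across the 8 conditions, with word identities drawn from
pools of 20 words per valence. Group-level truth defaults to the scale of
the study's posterior estimates (drifts 2.4--2.8, nondecision times
0.45--0.49 s, boundaries around 2), with between-person spreads
$\sigma_\nu = 0.3$, $\sigma_\theta = 0.02$ s, $\sigma_\alpha = 0.3$ and
trial-level spreads $\eta = 0.5$, $\chi = 0.05$ s -- values fixed once as
realistic for this class of task. Built-in scenarios: `paper`
(study-scale), `null` (no condition differences), and `pattern` (the
effects of interest planted: a +0.4 positive-vs-negative drift gap for the
scrambled prime only and a +0.03 s negative-vs-positive nondecision gap
for the happy and neutral primes only).

Nuisance processes give the preprocessing cascade work to do: prime-aware
trials (default rate 0.025 -- a modelling choice, as the empirical
pre-exclusion rate is not published), unknown and meaning-reversed words
(consistent per participant-word; for reversed words the diffusion runs on
the participant's internal, opposite valence and the recorded correctness
refers to the nominal valence, so the preprocessing recode exactly
restores the coherent trial), and RT contaminants replacing the response
time with uniform draws in (50, 199) or (5001, 8000) ms.

What the generator does **not** emulate: suppression depth and its trial
dynamics, word arousal, sequential effects, response-key effects, or
realistically heavy-tailed contaminant distributions. Passing tests
therefore show that the pipeline recovers truth *under the model's own
assumptions plus simple contamination*, not that the model is correct for
any real dataset.

## Preprocessing

`run_preprocessing()` applies, in a fixed and logged order: aware-trial
exclusion, participant exclusion (accuracy below 90% or fewer than 30
retained unaware trials in any condition -- both computed before RT
filtering), absolute RT cutoffs (strictly faster than 200 ms or strictly
slower than 5000 ms), a per-participant $\pm 2$ SD filter on log RT
computed across each participant's surviving trials (not per condition),
and unknown-word removal with meaning-reversal recoding. Each excluded
trial is attributed to the first rule it fails; the report carries counts
and fractions per reason and conserves rows exactly.

Two numerical consequences of the published rules are worth knowing:

* a $\pm 2$ SD trim removes roughly 5% of *any* continuous RT sample, so
  even a contamination-free dataset loses about that share at this stage
  (set `log_sd_mult = Inf` to disable);
* trimming shrinks the SD, so naively re-running the cascade would trim
  again — and trials removed by later stages would re-trip the per-condition
  trial-count rule. The per-participant log-RT bounds and the vetted
  participant list are therefore computed once and travel with the cleaned
  table, making the cascade idempotent on its own output.

Whether the log-SD statistics should include aware trials is ambiguous in
the source description; the default computes them after aware-trial
removal, and `logsd_include_aware = TRUE` switches to the other reading.

## Posterior readouts

`condition_summary()` gives the 8-condition posterior means and 95% HDIs
of $\mu_\nu$ and $\mu_\theta$. `valence_difference()` returns
negative-minus-positive contrasts per face; the facial-identity contrast
(`identity_contrast()`) compares the scrambled prime's positive-minus-
negative *drift change* with the mean change of the three intact faces.
Sign conventions are stated in each contrast's name. A contrast is flagged
when its 95% HDI excludes zero; no multiplicity correction is applied
(matching the analysis being replayed), so callers running many contrasts
should interpret flags accordingly.

The posterior-predictive check simulates replicate datasets from randomly
selected posterior draws (trial-level variability included), pools RTs
over participants within each condition, and correlates predicted with
empirical deciles (10/30/50/70/90% by default; pooling across participants
rather than averaging per-participant quantiles is a package choice --
the source is silent on it -- and is configurable through `probs`).

## Problem sizes used by the tests

The test-suite's simulation studies are sized to make their statistical
assertions meaningful while remaining desk-scale; these are package
choices: recovery at the study's 20 participants with convergence-gated chains
(R-hat < 1.1); HDI calibration and false-flag control on 40 null-truth
datasets of 8 participants; planted-effect detection on 20 datasets at the
study's own 20 participants; all with 40 trials per condition. Multi-seed
studies use reduced chain budgets without convergence gating -- their
assertions are about frequencies across seeds, not about any single fit.
One caveat made explicit: at 40 trials per cell, per-person cell mean RTs
carry ~0.045 s of sampling noise against a ~0.09 s spread of true cell
means, which caps their correlation with the analytic moments near 0.9;
the tests verify the correlation climbs well past 0.9 when cells are
enlarged, isolating sampling noise from generator error.

## Known limitations

* The sampler is a single-site Metropolis scheme with conjugate and slice
  refreshments; it is adequate at these problem sizes but no match for
  gradient-based samplers on much larger hierarchies.
* $\eta$ is weakly identified once the exclusion cascade clips the RT
  tails; fits to filtered data recover location parameters well but
  compress trial-level spreads. Recovery benchmarks therefore fit clean
  data, and scientific users should treat $\eta$, $\chi$ estimates from
  filtered data as lower bounds.
* Inter-trial variability of the starting point and the "full" diffusion
  model's uniform variability parameters are out of scope; $\beta$ is
  fixed at 0.5 by design.
* The Gauss--Hermite nondecision integral assumes $\chi$ small relative to
  the distance between $\theta$ and the fastest responses; pathological
  configurations (e.g. $\theta$ far above the fastest RT) are handled by
  the density floor, not by extra quadrature nodes.
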