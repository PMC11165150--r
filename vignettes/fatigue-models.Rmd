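---
title: "Production-cycle models of PVT fatigue: simulation, motivation moderators, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Production-cycle models of PVT fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvtfatigue)
```

## The model

The Psychomotor Vigilance Test (PVT) is a 10-minute simple reaction-time
task: a millisecond counter appears after a 2–10 s inter-stimulus interval
(ISI, whole seconds, uniform) and the participant presses a key as fast as
possible. Performance degrades with time-on-task — RT distributions stretch
rightward and lapses (RT > 500 ms) become more frequent — the *vigilance
decrement*.

`pvtfatigue` implements a family of production-cycle models of this task.
Behaviour is a sequence of conflict-resolution cycles of duration $\phi$
(seconds). In each cycle the state-appropriate *productions* (wait, attend,
respond) compete: each candidate's utility receives an independent draw of
logistic noise with scale $s$ (variance $\pi^2 s^2 / 3$), and the noisy
maximum fires if it clears the utility threshold $UT$. If no candidate
clears the threshold the cycle is a **microlapse**: a brief breakdown of
goal-directed control that consumes $\phi + t_{ml}$ seconds
($t_{ml} = 50$ ms) and further lowers utility, so microlapses beget
microlapses.

Three variants moderate the single utility value $\upsilon$:

* **CMF** (computational model of fatigue):
  $U = \upsilon\,\lambda^{N_{ml}}(1+t)^{\rho}$ and
  $UT = \tau\,(1+t)^{\kappa}$, with $t$ the time-on-task in minutes,
  $\lambda \in (0,1]$ the microlapse penalty and $\rho, \kappa \in (-1, 0]$
  time-on-task exponents. The declining threshold is compensatory: it keeps
  weakened productions firing at the price of more inappropriate firings.
* **Binned gamma model**: $U = \upsilon\,\lambda^{N_{ml}}\zeta$ with
  constant threshold $\tau$, where the motivation parameter $\zeta$ is
  derived from frontal high-gamma (70–80 Hz) EEG band power aggregated in
  five 2-minute bins: $\zeta_b = 1 + (\gamma_b - \gamma_1)/\mathrm{range}(\gamma)$,
  so $\zeta_1 = 1$ and all values lie in $[0, 2]$.
* **Single-trial gamma model**: as above but per trial,
  $\zeta_t = 1 + \log_b\!\big(\gamma_t / \bar\gamma_{1:k}\big)$ with
  baseline trials $k = 10$ and base $b = 10$ by default; values can exceed 1
  (compensatory effort, end-spurts) and are clamped at 0 (absolute fatigue).

$\zeta = 1$ is baseline effort. The closed-form selection rule
$\Pr[i] = e^{U_i/2s} / \sum_J e^{U_j/2s}$ over the above-threshold set $J$
is exposed by `selection_probabilities()`; it is exact for extreme-value
noise and, for the logistic noise actually used, a conventional
approximation of the operational noisy-max that `resolve_conflict()` and the
simulator run. The microlapse probability
$\prod_j F\!\big((UT - U_j)/s\big)$ (logistic CDF $F$) is exact either way,
and the package's tests verify the noisy-max frequencies against numeric
integration rather than against the soft-max.

## Process reconstruction

The published account names the states (waiting, attending, responding) but
not the cycle-level rules, so the following reconstruction is this package's
design:

* **Pre-stimulus** candidates are wait and respond; a respond firing is a
  false start. Respond is state-inappropriate while nothing is on screen and
  carries an additive *mismatch penalty* (default 6.0 utility units, a
  configuration constant in the spirit of partial matching). Without it, two
  equal-utility candidates would make ~half of all pre-stimulus cycles false
  starts; empirically false starts are rare (a fraction of a percent of
  trials). Failed pre-stimulus cycles advance time silently: with no
  stimulus to process there is no processing to delay, so they neither count
  toward $N_{ml}$ nor incur the 50 ms penalty.
* **Post-stimulus** candidates are attend and wait at the shared utility
  (a wait firing wastes one cycle — this competition, a geometric number of
  wasted 57 ms cycles, is what spreads alert RTs over the 150–500 ms band);
  after attend fires, respond is the sole candidate. RT is the cycle time
  from onset through the respond firing plus the motor time
  ($t_{motor} = 100$ ms, so the noise-free floor is
  $2\phi + t_{motor} \approx 214$ ms at the typical $\phi = 0.057$). No
  response within 30 s is a sleep attack.
* **Microlapse-penalty scope.** The $\lambda^{N_{ml}}$ term uses the
  microlapses accumulated since the current trial's stimulus onset;
  utilities are restored once a response completes. A session-cumulative
  penalty is numerically untenable at the reported $\lambda$ magnitudes
  (0.88–0.98): a 10-minute session accumulates enough microlapses that
  $\lambda^{N_{ml}}$ collapses below threshold within minutes, while the
  within-trial reading reproduces the documented growth of lapses from ~1%
  to ~5% over a long vigil at $\lambda = 0.98$. The session-level count is
  still tracked and reported per trial and per session.
* **Timing.** $t$ enters the moderators in minutes and is refreshed every
  post-stimulus cycle; during the pre-stimulus phase of a trial it is held
  at the phase-start value (it changes by under 0.2% of $(1+t)^\rho$ across
  a single ISI), which lets the ISI phase be drawn in one geometric step. A
  microlapse consumes $\phi + t_{ml}$ (the cycle happened, then the
  penalty). With $s = 0$, ties break toward the state-appropriate candidate
  (lowest index), making the noise-free model fully deterministic.

The per-cycle outcome probabilities used by the compiled simulator are the
exact closed forms of the noisy-max competition (for equal utilities the
three-way split is $F^2$ microlapse and $(1-F^2)/2$ each for attend/wait;
the pre-stimulus false-start probability is computed by 64-point quadrature),
so the simulator is distributionally identical to drawing every noise
variate, at a fraction of the cost.

## Parameters

| parameter | meaning | units | default / bound |
|---|---|---|---|
| $\upsilon$ | initial production utility | – | free, $(0,\infty)$; fitting box caps at 20 so the uniform prior is proper |
| $\tau$ | initial utility threshold | – | fixed 2.0 |
| $\lambda$ | microlapse penalty | – | free, $(0,1)$ |
| $\phi$ | conflict-resolution cycle | s | free, $(0.01, 0.1)$ |
| $\rho$ | utility time-on-task exponent | – | free, $(-1,0)$; CMF only |
| $\kappa$ | threshold time-on-task exponent | – | free, $(-1,0]$; CMF only (may equal 0, $\rho$ may not) |
| $s$ | utility-noise scale | – | 0.45, configuration constant |
| $t_{ml}$ | microlapse time penalty | s | 0.050 |
| $t_{motor}$ | motor execution time | s | 0.100, chosen so the noise-free RT floor sits inside the alert band |
| mismatch | penalty on state-inappropriate candidates | – | 6.0, configuration constant |

## Fitting

The likelihood of a parameter vector is approximated by forward simulation
(`approx_loglik()`): sessions are simulated until at least `n_sim` (default
2,000) trials are collected, and a defective mixture is formed — point
masses for false starts and sleep attacks plus a density over response RTs
(10-ms histogram bins over 150–1,000 ms, log-spaced tail bins up to the
timeout, or optionally a Gaussian KDE), everything floored at $10^{-6}$ so
no observation scores $-\infty$. Because a trial's outcome distribution
depends on its moderator, the mixture is built *conditionally*: per
$\zeta$-quartile stratum for the single-trial gamma model and per 2-minute
bin otherwise. A pooled marginal mixture would discard exactly the
trial-level $\zeta$–RT coupling that distinguishes the single-trial gamma
model from the CMF. The tail is split into log-spaced bins because cascade
depth — how far $\lambda^{N_{ml}}$ drives utility down within a trial — is
what the microlapse penalty governs; lumping all slow responses together
discards most of the information about $\lambda$.

`fit_subject()` maximises this likelihood with differential-evolution MCMC:
$4d$ chains for $d$ free parameters, step $2.38/\sqrt{2d}$, uniform priors
on the bounds with reflection, and a fresh simulation seed per proposal
derived from (root seed, chain, iteration), so every fit is exactly
reproducible. Two safeguards address the stochastic likelihood surface:
each held log-likelihood is re-evaluated with probability 0.2 per iteration
(a stuck chain otherwise clings to one lucky simulation draw), and the
reported point estimate is a *polished* posterior mode — the leading
post-burn-in states are re-scored under five fresh seeds and the best
averaged log-likelihood wins (a raw argmax over noisy evaluations
systematically selects noise spikes; the posterior mean was examined and is
worse still, because at these chain counts the chains do not mix well
enough for a stable average). AIC is $-2LL + 2p$ with $p = 5$ (CMF) or
$p = 3$ (gamma variants).

Identifiability is asymmetric: $\phi$ is pinned by the RT floor, $\upsilon$
by the lapse tail, but $\lambda$ only acts when cascades occur, i.e. when
$\zeta$ dips low enough that utility approaches the threshold. For a
subject whose motivation never dips, the $\lambda$ posterior is nearly flat
above ~0.85 and no estimator can localise it; recovery studies should
expect a minority of such subjects under realistic motivation variability.

## Synthetic data

`generate_gamma_series()` draws per-trial gamma power as lognormal noise
(log-SD 0.5) around a five-bin mean profile, by default non-monotonic with a
dip in the final bin — the qualitative shape of binned frontal high-gamma
during a brief vigil; bins follow expected trial time so that a series
generated longer than a session (overrun protection for the emergent trial
count) still unfolds the profile on the session's time scale.
`generate_synthetic_cohort()` couples everything: the very $\zeta$ series
that moderated a subject's simulated session is emitted alongside the
behaviour, which is what parameter- and model-recovery studies need.
`generate_synthetic_epochs()` builds white-noise epochs with sinusoidal
70–80 Hz bursts inside the −300..800 ms analysis window for the spectral
pipeline. The generators emulate the structure of the real data (positive
skewed powers, binned non-monotonicity, end-spurts), not its physiology: no
1/f background, no artifacts, no channel structure — so passing tests
demonstrate the pipeline's correctness, not EEG realism.

The spectral pipeline itself follows the stated procedure: −300..800 ms
windows (floor-based half-open indexing, 563 samples at 512 Hz), Welch
averaging of periodic-Hamming 367 ms segments with 25% overlap, zero-padded
to a power-of-two FFT no coarser than the 2,560-point output grid over
0–256 Hz, inclusive 70–80 Hz band summation, natural log. The original
transform length is not recoverable from the description; the grid
convention here is declared, and none of the downstream rank/ratio
properties depend on it.

## Numerical and degenerate-input choices

* Constant binned power (zero range) yields an all-ones $\zeta$ series with
  a warning, not an error; trial-mode $\zeta$ clamps at 0 with a reported
  count.
* The log base restriction ("multiples of 10") is honoured as the default
  but any base > 1 is accepted with a warning — nothing in the transform
  requires the restriction.
* Quintile cuts use stable ranks with near-equal sizes (difference ≤ 1);
   2-minute bins are right-open with the final bin closed at 600 s.
* The chi-square is the plain Pearson statistic without continuity
  correction (delegated to `stats::chisq.test`); the bootstrap for the
  lagged cross-correlation resamples (lagged, current) index pairs i.i.d.
* Timeouts count as lapses in `lapse_proportion()` (a 30 s non-response
  exceeds 500 ms by any reading — the standard PVT lapse rule).

## Problem sizes

The shipped tests and the acceptance script use 10-minute sessions
(~85–105 trials), cohorts of 2–10 subjects, 200-session decrement studies,
DE-MCMC at 500 iterations × 12 chains with 2,000 simulated trials per
proposal for recovery and 150 iterations with 1,000 trials per proposal for
model comparison — sizes chosen so a complete study runs on a laptop in
minutes while leaving every qualitative conclusion stable under reseeding.

## Known limitations

* At the weak moderator values fitted to a 35-minute study
  ($\lambda = 0.98, \rho = -0.05, \kappa = -0.01$), the 10-minute decrement
  is real but small (lapse proportions of roughly 1.5% early vs 2–3% late in
  the acceptance script's 200-session study). With ~20 trials per 2-minute
  bin, single-session early-vs-late comparisons are then dominated by
  counting noise; only the stronger 10-minute refit
  ($\rho = -0.20, \kappa = -0.15, \lambda = 0.88$) produces a decrement
  visible in nearly every session. This mirrors the published observation
  that the weak values under-predict short-task decrements.
* The production set, matching rules and timing constants are a declared
  reconstruction; RTs should be compared to the original implementation
  at the level of distributional properties, not trial-by-trial equality.
* The mismatch penalty and noise scale are configuration constants, not
  fitted; sensitivity is exercised in tests.
* Fitting assumes the observed session's task settings and, for gamma
  variants, its $\zeta$ series; EEG preprocessing (filtering, ICA,
  re-referencing) is out of scope — epoch matrices are expected clean.

## A worked example

```{r example}
p <- model_params(3.82, 0.88, 0.057, rho = -0.20, kappa = -0.15,
                  variant = "cmf")
ses <- simulate_session(p, seed = 1)
table(ses$trials$type)
round(vapply(0:4, function(b)
  lapse_proportion(ses$trials, b * 120, (b + 1) * 120), numeric(1)), 3)
```

```{r fit, eval = FALSE}
# Recover parameters of a single-trial gamma subject (about half a minute)
coh <- generate_synthetic_cohort(1, "gamma2",
  param_sampler = param_sampler_default("gamma2",
    point = list(upsilon = 4, lambda = 0.93, phi = 0.058)), seed = 2)
fit_subject(coh$sessions[[1]], "gamma2",
            de = de_settings(iterations = 500, burn_in = 250), seed = 3)
```
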