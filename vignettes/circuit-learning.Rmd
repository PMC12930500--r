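---
title: "Modeling nonassociative learning with minimal gene circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nonassociative learning with minimal gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlearn)
library(dplyr)
```

## The models

circlearn simulates four minimal transcriptional circuits in which a cell's
response to repeated stimulation changes with stimulation history — the
hallmark of nonassociative learning. All models are nondimensional ODE
systems driven by a piecewise-constant input `x(t)` (a train of rectangular
pulses), with promoter activities described by squared Hill transfer
functions: activating `theta_plus(c) = c^2 / (K^2 + c^2)` and repressing
`theta_minus(c) = 1 / (1 + (c/K)^2)`, both with half-activation `K = 1`
unless stated otherwise. The ligand-bound receptor complex that drives the
activating promoters is taken as the instantaneous mass-action product
`X * x` with unit association constant; no separate binding ODE is
modeled, and this choice reduces to the obvious limits when either factor
is zero.

**Habituation** is an incoherent feed-forward loop. A constitutive receptor
`X` binds the input; the complex activates both a slowly degrading memory
repressor `I` and the fast-degrading output `G`, while `I` represses `G`:

    dX/dt = mu            - lambda X
    dI/dt = alpha theta+(X x) - gamma I
    dG/dt = beta theta+(X x) theta-(I) - lambda G

Because `I` decays at the slow rate `gamma` while everything else decays at
`lambda >> gamma`, `I` integrates stimulation history across pulses and
progressively suppresses the output: peak responses shrink.

**Sensitization** replaces the direct repression of the output with a
double-repression cascade onto the receptor: the memory `I` represses an
intermediate repressor `R`, which represses `X`'s production, so memory
accumulation indirectly amplifies the receptor and with it the output
(`dG/dt = beta theta+(X x) - lambda G`). Peak responses grow.

**The hybrid circuit** is the sensitization circuit plus the habituation
circuit's hybrid output promoter, whose repressor curve has a raised
half-activation `K_out > 1` (`theta-` evaluated at `I / K_out`). Early on,
receptor amplification dominates and peaks grow; once `I` accumulates past
the shifted repression scale, suppression wins and peaks shrink —
sensitization followed by habituation.

**Massed–spaced learning (MSL)** is a linear activator chain `X -> A -> G`
in which every species decays at the slow rate `gamma` and output
production is decoupled from the presence of input: the inducer `A`
persists after a pulse ends and keeps driving `G`. Splitting a fixed total
stimulus duration into spaced pulses lets `A` accumulate across pulses and
can produce a higher output maximum than one massed block — provided the
gaps are short relative to `1 / gamma`.

## Learning metrics

All metrics operate on per-stimulus output peaks. The trajectory is
partitioned at pulse onsets; `interval_peaks()` takes the maximum of `G`
within each interval (the final interval extends to the simulation
horizon). `fold_change()` is the log2 ratio of the final-interval peak to
the first-interval peak: negative for habituation, positive for
sensitization, and `-1` means the response fell to half. For the hybrid
circuit, `hybrid_fold_changes()` compares the first and the last peak to
the *highest* peak; signs are oriented so the sensitization component is
nonnegative and the habituation component nonpositive, matching the
single-behavior conventions. For MSL, `msl_fold_change()` compares global
output maxima of a spaced and a massed run with identical parameters and
total on-time.

The orientation of the two hybrid ratios is a package convention: what is
fixed by the definition is which peaks are compared, and the signs are
chosen so magnitudes read like the single-behavior metrics.

## Numerical scheme

The input is discontinuous, so the integrator never steps across a pulse
edge: the horizon is split into segments on which `x` is constant, and a
classical fixed-step 4th-order Runge–Kutta scheme runs within each
segment, restarting exactly at each edge. The fixed step makes every run
bit-for-bit reproducible; there is no adaptive error control to introduce
platform- or history-dependence, and no randomness anywhere in the tool.
Defaults: `max_step = min(0.01, dur_on / 100)` (so at least 100 steps per
pulse), dense output every `dur_on / 10` by cubic Hermite interpolation of
the accepted steps (using stored derivatives), and a horizon of the last
onset plus one period plus a settling tail of `10 / lambda` (or
`5 / gamma` for MSL, which has no fast species) so the final peak and its
decay are captured. Step-halving changes sampled values by less than
1e-6 relative on all shipped configurations, which bounds the peak-metric
error without sub-sample peak refinement.

Roundoff can push a species infinitesimally negative; excursions above
-1e-9 are clipped to zero on output and anything worse is an error, as is
a non-finite state. Simulations start at the circuit's resting state — the
closed-form no-input fixed point — unless an explicit `state0` is given
(used, e.g., to study a preloaded memory).

`lambda >= gamma` is enforced; a ratio below 10 only warns, because sweeps
that approach the time-scale-separation boundary are legitimate even
though the memory interpretation degrades there.

## The analytic layer

When pulses are much shorter than the gaps and the memory stays far from
saturation, each pulse acts as an instantaneous memory jump of size
`alpha * dur_on` followed by exponential decay (`impulsive_memory()`).
Three consequences are implemented in closed form:

* the net change per cycle, `(I0 + w) exp(-gamma dur_off) - I0`
  (`memory_increment()`), and the critical relaxation interval
  `log(1 + w / I0) / gamma` at which it changes sign
  (`critical_relaxation()`) — memory accumulates across cycles only for
  gaps below it;
* the periodic steady-state envelope
  `w exp(-gamma tau) / (1 - exp(-gamma period))` approached as the pulse
  count grows (`periodic_envelope()`);
* a simplified all-or-nothing MSL model in which output is produced at
  full rate exactly while the memory sits above a normalized threshold of
  1 (the threshold is part of the model's normalization, not a tunable):
  post-pulse memory levels (`msl_state_after_pulse()`), production
  windows clipped by the next arrival (`msl_production_windows()`), the
  summed output (`msl_output()`), and closed-form peak outputs for one
  massed pulse and a two-pulse split (`massed_peak()`,
  `two_pulse_peak()`), with the sufficient condition
  `log(alpha dur_on / N) >= gamma dur_off` under which spacing provably
  beats massing (`spaced_superiority_holds()`).

Two indexing conventions coexist, each matching the model it serves: the
habituation-side pulse sum places pulses at `k * period` for `k = 1..N`,
while the simplified MSL model places them at `k * dur_off` from `k = 0`.
The Heaviside step used throughout takes `H(0) = 1`, so a pulse arriving
exactly at the evaluation time counts in full; note many numerical
libraries use `H(0) = 1/2`. `two_pulse_peak()` refuses inputs outside the
validity condition rather than extrapolating a formula whose derivation
assumes production spans the whole gap.

The test suite checks the closed forms against an independent event-driven
integration of the simplified model (analytic inter-pulse decay, exact
per-segment output integration) and checks the impulsive approximation
against the full habituation ODE in its regime (pulse:gap ratio 1:10,
agreement within 5%).

## Reference configurations and sweeps

`make_fixture()` bundles the operating points at which each behavior is
displayed: habituation (`alpha = 1.5, beta = 5, gamma = 0.01, lambda = 1,
mu = 1`), sensitization (adding `rho = 1.75`), the hybrid (`beta = 10`,
`K_out = 1.5`), all under 1-unit pulses at period 10; and MSL
(`alpha = 1, beta = 1, gamma = 0.01, mu = 1`) with total on-time 10
delivered as five pulses with gaps of 50, or massed. Choices the models
themselves do not fix — and which are therefore package conventions, made
once — are: input amplitude 1 (the activating transfer functions are near
saturation for amplitudes of order 1 and above, so results are insensitive
to the exact height); 10 pulses per train; and 20 pulses for the hybrid,
whose turnover from growing to shrinking peaks occurs near pulse 13 at the
reference parameters, so a 10-pulse train would end inside the
sensitization phase and never display the habituation arm.

`sweep_fc()` maps a fold-change metric over any two parameters
(`alpha` × `gamma` is the classic habituation/sensitization phase
diagram); `sweep_msl()` maps the spacing effect over pulse count and gap
against a shared massed reference. Default grids (41 points per axis,
rates log-spaced over `alpha` in [0.1, 10] and `gamma` in [1e-4, 1]; MSL
gaps linear in [0, 200]) are reconstructions chosen to bracket the regime
boundaries, not canonical values. Undefined cells (a zero first peak)
carry an explicit `NA` plus a reason string, never a numeric sentinel.
`threshold_mask()` flags cells beyond a level in the metric's natural
direction — e.g. `fc <= -1` for habituation maps.

The test suite exercises small grids (a few points per axis) and verifies
sweep cells against direct simulation, monotonicity of habituation
strength in `alpha`, and bisection refinement of the `fc = -1` boundary;
the 41×41 defaults are for interactive use.

## What the simulations do and do not show

These are deterministic, single-cell, nondimensional models with lumped
degradation–dilution, no promoter leak, no gene-expression noise, no
resource competition and no cell-to-cell communication dynamics. Passing
tests establish the dynamical claims about the model family — which
regimes habituate, sensitize, switch between the two, or prefer spaced
input — not that a wet-lab implementation with particular parts will show
the same quantitative behavior. The analytic layer is an approximation
valid for short pulses and unsaturated memory; outside that regime only
the full simulator is meaningful, which is why the closed forms refuse or
flag their assumptions rather than extrapolate.

## A worked example

```{r example, eval = FALSE}
fx <- make_fixture("habituation_default")
traj <- simulate_protocol(fx$circuit, fx$params, fx$schedule)
peaks <- interval_peaks(traj)
fold_change(peaks)
autoplot(traj)

# phase diagram around the reference point (coarse grid for speed)
sweep_fc("habituation", fx$params, fx$schedule,
         sweep_axis("alpha", 0.1, 10, n = 11),
         sweep_axis("gamma", 1e-4, 1, n = 11)) |>
  threshold_mask(-1) |>
  plot_sweep()
```
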