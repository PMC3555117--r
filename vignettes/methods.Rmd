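---
title: "Modelling release-probability changes at CA3-CA1 synapses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling release-probability changes at CA3-CA1 synapses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1stp)
```

## The scientific question

Acute elevation of amyloid-beta raises the initial release probability
($p_0$) of CA3$\to$CA1 Schaffer-collateral synapses without changing
postsynaptic function or intrinsic excitability. `ca1stp` asks what that
single presynaptic change does to (i) short-term plasticity of the synapse
across stimulation frequencies and (ii) the spiking output of a CA1 neuron
driven by naturalistic CA3 spike trains. The package implements the full
pipeline — synapse model, reduced postsynaptic neuron, synthetic input
generator, least-squares fitting, spike statistics, and orchestrated
experiments — with seeded, reproducible randomness throughout.

## The synapse model

Each synapse holds a unit amount of resource split into recovered ($x$),
active ($y$) and inactive ($z$) fractions, $x + y + z = 1$. Between spikes

$$\dot y = -y/\tau_\mathrm{in}, \qquad
  \dot z = y/\tau_\mathrm{in} - z/\tau_\mathrm{rec}, \qquad
  \dot x = z/\tau_\mathrm{rec},$$

and the use-variable $p$ (the running release probability) decays to a
baseline of zero with $\tau_\mathrm{facil}$. At a spike, $p$ is incremented
*first*, $p^+ = p^- + U(1 - p^-)$, and only then is the released fraction
$\Delta = p^+ x^-$ moved from $x$ to $y$; the EPSC is $A\,y(t)$. Because $p$
starts at 0, the first spike releases exactly $U$, so $U$ *is* the initial
release probability. The two study conditions share
$\tau_\mathrm{in} = 1$ ms, $\tau_\mathrm{rec} = 50$ ms,
$\tau_\mathrm{facil} = 200$ ms and differ only in $U$: 0.15 (control)
versus 0.36 (elevated amyloid-beta).

Inter-spike propagation uses the exact solution of the linear system (a sum
of two exponentials for $z$, with the $t\,e^{-t/\tau}$ limit when
$\tau_\mathrm{in} = \tau_\mathrm{rec}$), so repeated relax/spike cycles
accumulate no integration error. The test suite verifies the closed forms
against two independent oracles: adaptive high-accuracy ODE integration
(`deSolve::lsoda`, tolerances $10^{-12}$) and a fixed-step classical RK4
integrator, both agreeing to better than $10^{-6}$ over 5-pulse trains at
5–200 Hz in both conditions.

**Amplitude convention.** After a spike, $y$ decays monotonically, so the
per-pulse peak is the post-spike value $A(y^- + \Delta)$. At 150–200 Hz a
small residual from the previous pulse is included in the peak; we do not
baseline-subtract it, matching the "normalized to first response" usage.
Whether the experimental curves were baseline-corrected is not stated in
the source data; this convention is deterministic and is used consistently
for simulation and fitting.

## The reduced CA1 neuron

The morphologically detailed CA1 cell of the original study is replaced by
a single-compartment conductance-based leaky integrate-and-fire neuron:

$$C\dot V = -g_L (V - E_L) - \sum_i w_i\, y_i(t)\, (V - E_\mathrm{syn})
            - g_a (V - E_K),$$

with $\tau_m = 20$ ms, $g_L = 10$ nS, $E_L = -70$ mV, threshold $-54$ mV,
reset $-65$ mV, absolute refractory period 4 ms, $E_\mathrm{syn} = 0$ mV.
$g_a$ is a spike-triggered adaptation conductance (increment 4 nS, decay
100 ms, reversal $-90$ mV) standing in for the after-hyperpolarisation
currents of the real cell. Without it, the point neuron re-fires on every
spike of an intra-theta packet, which a CA1 pyramidal cell does not do, and
the saturating-regime contrast between conditions inverts; with it the
model reproduces the regime-level behaviour (see below). Integration is
exponential-Euler at 0.025 ms with the synaptic $y_i(t)$ advanced
event-to-event in closed form, implemented in C++ for speed. In
voltage-clamp mode the soma is held (at $-70$ mV by default) and the summed
current $\sum_i w_i y_i(t)(V_\mathrm{hold} - E_\mathrm{syn})$ is reported
directly; clamp traces are exact linear superpositions computed in R.

Because the neuron is reduced, absolute conductance values (the "30 nS" and
"90 nS" regime anchors of the detailed model) are not meaningful here;
regimes are instead *defined* by calibrated spike-probability bands
(integrative 25–40 %, saturating 85–92 %) found by bisection on a uniform
weight multiplier (`calibrate_regimes()`).

## Synaptic weights

Unitary strengths are drawn from a shifted lognormal fitted to mEPSC
amplitudes ($\mu = 1.6$, $\sigma = 1$, offset 5 pA) and converted to
conductances through the 70 mV driving force at the $-70$ mV holding
potential, with each model synapse folding in 15 real contacts: the default
population of 10 model synapses represents about 150 real synapses. Weights
and a per-synapse attenuation factor (uniform in [0.7, 1], standing in for
dendritic position) are resampled every trial; all experiments repeat 10
trials and report mean ± SEM (sample SD over $\sqrt{n}$).

## The synthetic CA3 input generator

The five in vivo CA3 spike trains used in the original study (10-minute
open-field recordings) are not deposited, so the package generates
stand-ins. The generator is a theta-locked packet process:

* a slow envelope (baseline 12 Hz plus Gaussian place-field traversals,
  6 Hz peak, 0.3 s width, 2 per minute) sets the expected discharge;
* 90 % of that discharge (`theta_depth`) is organized into theta packets:
  per 125 ms theta cycle a packet occurs with probability proportional to
  the envelope, holding $1 + \mathrm{Poisson}$ spikes at gamma-range
  intervals (8–18 ms), with the packet count growing with the envelope once
  every cycle is occupied;
* each spike seeds, with probability 0.1, a complex-spike burst of a
  geometric number of extra spikes at 2.5–5 ms intervals;
* a 2 ms presynaptic refractory gap is enforced by thinning.

A plain theta-modulated inhomogeneous Poisson process was tried first and
rejected: coincident-spike events in any Poisson-rate model occur at a rate
proportional to $\lambda(t)^2$, so the near-coincident stimuli that drive an
integrative-regime neuron are always *more* clustered than the train
itself, and the output-side theta/gamma statistics cannot come out right.
Packet organisation — the standard description of hippocampal place-cell
discharge — removes that obstruction.

The defaults were calibrated once so that the mean ISI coefficient of
variation over the five shipped seeds at the full 600 s length is 1.29,
inside the target band 1.25 ± 0.14 reported for the in vivo input trains.
The per-session mean rate (~13 Hz) is on the high side for CA3 pyramidal
cells; the rates of the recorded neurons were not reported, and the high
packet occupancy is what lets the aggregate CV stay moderate while the
train remains strongly theta/gamma structured. Experiments use 60 s
patterns by default (600 s available by configuration) to keep the full
suite at desk scale; tests use 10–60 s.

What passing tests on these trains show — and do not show: the synthetic
trains match the published input irregularity and carry plausible theta,
gamma and complex-spike structure, but they are not the recorded trains;
all output-side results are therefore regime-level (directions and
contrasts), never per-pattern numbers.

## Fitting

`fit_stp()` minimises the summed squared difference between observed and
model normalized amplitude curves with bounded multi-start L-BFGS-B; starts
are laid deterministically (linear in $U$, log-spaced in time constants),
so fits are exactly reproducible. Normalized curves cannot identify $A$, so
$A$ is never free; it is set from the first-pulse magnitude when needed.
Scenario comparison (`compare_scenarios()`) refits alternative
parameter-change hypotheses against a reference curve and ranks them by
SSE; the package reproduces the degeneracy in which lowering $U$ to 0.3
while shortening $\tau_\mathrm{facil}$ roughly ten-fold matches the
$U = 0.36$ curve to within 0.1 everywhere. Sigmoid gain curves
($y = a/(1 + b e^{-cx})$) are fitted by Levenberg–Marquardt with an
optional fixed asymptote.

## Statistics

Spike probability is output spikes over stimuli (per cent; values above
100 % are possible for a bursting neuron and flagged). ISI CV uses the
population standard deviation. Instantaneous frequency is $1/\mathrm{ISI}$
per interval; band probabilities (theta 4–8 Hz, gamma 40–80 Hz) use closed
intervals on $1/\mathrm{ISI}$, per-ISI normalized — the source convention
is not stated, and this choice makes disjoint covering bands sum to one.
Condition contrasts follow the study's contracts: Shapiro–Wilk normality
gate, paired t-test across the five patterns, Kolmogorov–Smirnov on pooled
instantaneous-frequency distributions, significance at $p < 0.05$.

## What the experiments show

With all defaults (seeded), the package reproduces, qualitatively and in
several cases near-quantitatively, the published effects of raising $p_0$:

* **Validation (5 × 100 Hz):** control facilitates throughout
  (≈ [1, 1.58, 1.72, 1.61, 1.44]); the elevated-release curve facilitates
  once, then depresses (≈ [1, 1.13, 0.82, 0.60, 0.52]).
* **Frequency sweep (10 × 5–200 Hz):** facilitation at 5–10 Hz (stronger in
  control), bimodal elevated-release behaviour at 40 Hz, bimodality in both
  at 80–100 Hz with deeper depression under elevated release; at
  150–200 Hz the elevated-release curve collapses monotonically from a
  residual pulse-2 peak (≈ 1.09) to deep depression (≈ 0.26–0.34),
  far below control. Note the pulse-2 peak: with
  $\tau_\mathrm{facil} = 200$ ms the synapse equations *cannot* suppress
  second-pulse facilitation at 150–200 Hz while showing 1.13 at 100 Hz
  (the instant-inactivation recursion gives 1.09–1.11 there), so the
  published disappearance of all facilitation at these frequencies must
  involve somatic filtering by the detailed morphology, which this package
  deliberately omits. The corresponding acceptance check is left failing
  rather than reinterpreted.
* **Natural drive, integrative regime:** elevated release roughly doubles
  spike probability (means ≈ 53 % vs 29 % across patterns and trials),
  enhances gamma-band firing several-fold, and leaves theta-band firing
  statistically unchanged.
* **Natural drive, saturating regime:** both conditions sit at the
  refractory-limited plateau, within 2 percentage points, with elevated
  release slightly *below* control (≈ 89.8 % vs 91.1 %).
* **Asynchrony:** jittering synapse activation over 0–9 ms lowers spike
  probability in both conditions.

One directional claim does not reproduce under these study conditions: in
the integrative regime the output ISI CV of the elevated-release condition
comes out slightly below control's (≈ 0.74 vs 0.81; both well below the
input's 1.25, as expected), whereas the published order is the reverse.
The published order appears to require the control neuron's output to be
concentrated in theta-regular place-field episodes while the
elevated-release neuron also follows irregular out-of-field activity;
concentrating the synthetic trains that way drives their aggregate CV far
above the calibrated input band, so the two requirements cannot be met
simultaneously within this generator. The corresponding assertion is kept
in the acceptance tests and fails honestly rather than being weakened.

## Numerical choices and degenerate inputs

* Closed-form inter-spike propagation everywhere; the degenerate
  $\tau_\mathrm{in} = \tau_\mathrm{rec}$ case uses the
  $t\,e^{-t/\tau}$ limit formula.
* Free-run integration step 0.025 ms (validated against the refractory and
  stability constraints; an error is raised beyond
  $0.1\,\tau_m$).
* Trial seeds derive from the master seed as
  $(7919\,s + 104729\,\mathrm{salt} + 1299709\,i) \bmod (2^{31} - 19) + 1$,
  keeping every derived seed a valid 32-bit integer; identical
  configuration and master seed give byte-identical result tables.
* Empty spike trains, zero-weight populations, single-pulse protocols and
  constant sigmoid responses are all defined (zero trace, silent neuron,
  flat curve, explicit degeneracy error respectively).

## Known limitations

* The reduced neuron has no dendritic nonlinearities; dendritic position is
  a static attenuation factor. Only regime-level output claims are made.
* The generator emulates statistics of in vivo CA3 firing, not any
  recorded cell; per-pattern results are not comparable to the published
  per-pattern bars.
* NMDA receptor kinetics are deliberately absent (as in the source model,
  whose effects were AMPA-mediated).
* Stochastic vesicle-level release is out of scope; the synapse is the
  deterministic mean-field model.
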