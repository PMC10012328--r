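---
title: "Theta-gated STDP in a spiking cortico-hippocampal network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gated STDP in a spiking cortico-hippocampal network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaSTDP)
```

## The model

thetaSTDP simulates a small spiking network in which associative learning
between two sensory streams is carried by spike timing-dependent plasticity
(STDP) gated by the phase of an ongoing hippocampal theta oscillation.  The
architecture has two regions: a neocortex (NC) of 20 leaky
integrate-and-fire neurons split into visual and auditory subgroups of 10,
and a hippocampus of 10 neurons split into matching subgroups of 5.  NC
neurons connect within subgroup with probability 0.25 (fixed weight 0.3)
and not at all across subgroups; each NC subgroup is fully bipartitely
connected with the hippocampal subgroup of its modality (0.35 down, 0.08
up); hippocampal directed pairs exist with probability 0.5 (weight 0.65)
and are the only plastic synapses.  Intra-subgroup hippocampal efficacies
start saturated, inter-subgroup efficacies start at zero; learning the
visual-auditory association means driving the inter-subgroup efficacies up.

Membranes follow

$$C_m \frac{dV_m}{dt} = g_m (E_L - V_m) + I_{syn} + I_{AC} + I_{DC} + I_{ADP}$$

with resting potential $E_L = -70$ mV, threshold $V_{th} = -55$ mV, leak
conductance $g_m = 0.03$, a 2 ms absolute refractory period during which
the voltage is clamped to rest, and forward-Euler integration at
$dt = 1$ ms.  All amplitudes below are in the model's dimensionless current
unit; the rheobase (the constant current whose steady state just reaches
threshold) is $g_m \cdot 15\,\mathrm{mV} = 0.45$.

Spike events are delivered after a 2 ms synaptic delay and elicit an
alpha-function EPSP

$$EPSP(\Delta t) = W_{max}\,\rho\,\frac{e\,\Delta t}{\tau_s}\,
  e^{-\Delta t/\tau_s}, \qquad \tau_s = 20\ \mathrm{ms},$$

which is zero at the origin and peaks at exactly $W_{max}\rho$ at
$\Delta t = \tau_s$.  Efficacy $\rho \in [0,1]$ multiplies the maximal
weight.  The engine superposes the kernels of all delivered events with an
exact two-state recursion (the discrete update reproduces the closed form
on the step grid to machine precision), and multiplies the sum by a global
synaptic gain before it enters the membrane equation as $I_{syn}$ (see
*Numerical and unit choices*).

Hippocampal neurons additionally receive an afterdepolarization (ADP) ramp
$I_{ADP}(\Delta t) = A_{ADP} (\Delta t/\tau_{ADP}) e^{1-\Delta t/\tau_{ADP}}$
with $A_{ADP} = 0.2$ and $\tau_{ADP} = 250$ ms, reset by each spike.  With
the 4 Hz theta drive (amplitude 0.25) the two peaks sum to exactly the
0.45 rheobase, so an undriven hippocampal neuron grazes threshold
precisely when a full ADP ramp coincides with the theta excitation peak:
the ADP paces spontaneous firing at theta and, because each spike resets
the ramp, suppresses firing in the cycle after a stimulus-driven volley.
NC neurons receive a 10 Hz alpha oscillation (amplitude 0.1) with a random
phase per trial.  Background bombardment is modelled per neuron as a
Poisson train (4000 spikes/s at weight 0.023 in NC; 1500 spikes/s at 0.015
in the hippocampus) of brief one-timestep current pulses: a subthreshold
depolarizing bias plus shot noise.

Transmission from NC to the hippocampus passes through an entorhinal relay
modelled as a multiplicative gate

$$\theta_{EC} = \frac{(1-\theta_{Hip}) + (1-W_{EC})}{1 + (1-W_{EC})},
\qquad W_{EC} = 0.3,$$

where $\theta_{Hip} = (1+\cos\varphi)/2 \in [0,1]$ is the normalized
hippocampal theta sharing one phase variable with the theta current
$I_{AC} = 0.25\cos\varphi$.  Under this convention $\theta = 1$ is the
depolarizing (excitatory, depression-inducing) extreme and $\theta = 0$
the hyperpolarizing (inhibitory, potentiation-inducing) extreme; the gate
is maximal (1) at the trough and minimal (0.41) at the peak, so cortical
input arrives preferentially in the potentiation-permissive phase.  The
gate uses the instantaneous theta at each event's delivery time.

## The plasticity rule

When a neuron spikes at time $t$, potential plasticity is evaluated from
the spike histories of its plastic partners:

$$F_{LTP}(t,i) = \sum_{t_i < t} A_+ \,[1-\theta(t_i)]\, e^{(t_i-t)/\tau_s},
\qquad
F_{LTD}(t,j) = \sum_{t_j < t} A_- \,\theta(t_j)\, e^{(t_j-t)/\tau_s}$$

with $A_+ = A_- = 0.65$.  Potentiation credits presynaptic partners that
fired shortly before, weighted toward the inhibitory phase; depression
debits postsynaptic partners weighted toward the excitatory phase.  The
efficacy updates are thresholded and graded:

$$\Delta\rho_i = \gamma_p (1-\rho_i)\, [F_{LTP}-\varepsilon_{LTP}]_+ ,
\qquad
\Delta\rho_j = -\gamma_d \rho_j\, [F_{LTD}-\varepsilon_{LTD}]_+$$

with $\gamma_p = 1.5 = 2\gamma_d$ and
$\varepsilon_{LTP} = \varepsilon_{LTD} = 1$, applied once at the
millisecond of the spike.  Because a single historic spike contributes at
most 0.65, singlet and doublet pairings can never cross the threshold — a
burst of three or more spikes within a few tens of milliseconds is the
gateway to plasticity, and the excess above threshold grades the change
with burst size.  The soft bounds $(1-\rho)$ and $\rho$ pull updates
toward the interval limits; because a discrete update with excess above
$1/\gamma_p$ would overshoot, efficacies are clipped into $[0,1]$ after
each event.  Same-millisecond spikes are excluded from each other's
updates (the sums are strict in $t_i < t$), and all updates within one
millisecond are computed from the pre-update efficacies and traces, in
ascending neuron order.

The engine maintains the two sums per neuron incrementally (decay by
$e^{-dt/\tau_s}$ per step, increment at each spike); the test suite holds
the incremental values to within $10^{-9}$ of a brute-force re-summation,
and replays an entire simulated spike record through the reference
implementation to verify the in-loop updates end to end.

## Protocols

**Burst stimulation.**  `run_burst_protocol()` injects a single burst of
1-4 current pulses (amplitude 3) at 100 Hz into one hippocampal subgroup,
timed so the elicited spikes centre on a chosen theta extreme.  Pulses are
6 ms wide so each reliably elicits exactly one spike at the 10 ms spacing
(a 1 ms pulse of amplitude 3 depolarises only ~2.6 mV against the 15 mV
threshold distance).  Each stimulated neuron's train is shifted by an
integer latency drawn from 0-2 ms, modelling the response-latency spread
of a stimulated population; perfectly millisecond-synchronous spikes could
never pair under the strict history rule.  Plastic synapses onto or from
the stimulated neurons are measured, their intra-subgroup efficacies
initialised mid-range (0.5) so both potentiation and depression have
headroom, and the result is reported per trial as the percentage change of
the mean efficacy between a 500 ms baseline window and a 500 ms window
starting 250 ms after the burst.  At the default parameters the protocol
yields no change for 1-2 spike bursts at either phase, graded potentiation
at the trough (about +9% at 3 spikes and +22% at 4, across 25 trials) and
depression at the peak (about -12% at 4 spikes).

**Entrainment memory paradigm.**  `run_memory_condition()` /
`run_memory_grid()` simulate trials of a multisensory associative
paradigm: after a 2 s interstimulus interval, cosine-modulated direct
currents drive the visual and auditory NC subgroups for 3 s.  The unipolar
envelope $A(1-\cos 2\pi f t)/2$ starts at its trough (no onset
discontinuity); the auditory envelope leads the visual one by the phase
offset (0, 45, ..., 315 degrees).  Amplitude follows the frequency-scaling
rules $1.75\,e^{(f/20)^3}$ below 14 Hz and $2.2\log_{10} f$ above
(the two curves cross near 13.9 Hz), which compensates the shorter
integration window per cycle at faster modulation.  A no-flicker control
feeds a constant 1.75 for half the duration.  At stimulus onset the
hippocampal theta phase is reset so that its potentiation-permissive
trough coincides with the hippocampal response to each visual envelope
peak; the response lags the envelope by the 2 ms delay, the 20 ms EPSP
rise and the membrane charging time, so the reset applies a 45 ms
alignment lag (`reset_lag_ms`).  Aligning to the raw envelope instead
would rotate the effective phase map by that lag and favour a
quarter-cycle-leading stream over the synchronous one.  The read-out is
the mean auditory-to-visual inter-subgroup efficacy between 2.75 and 3 s
after onset (one theta cycle), with 2.75-0 s before onset as the
prestimulus baseline.

Per-trial noise sources (all drawn once per trial from normal
distributions, each independently switchable) model entrainment
variability: the stimulus frequency (SD 0.015 of its nominal value), the
hippocampal theta frequency (SD 0.02 Hz), the entorhinal phase offset
(mean 180, SD 0.167 degrees, taken as printed although conspicuously
small) and the stimulus phases (SD 5 degrees).

**Lesioned variants.**  `variant = "stdp_only"` removes every
theta-dependence: the phase factors in the trace sums become 1, the gate
is identically 1, the hippocampal theta current is silenced and the phase
is not reset; paradigm inputs are made bipolar ($\pm 1.75$) to narrow the
firing windows so that spike order alone is informative.
`variant = "theta_only"` removes the STDP timing kernel: partner spikes
are summed without decay over the current theta half-cycle (window 100 ms)
with theta re-ranged to $[-1,1]$, and the eliciting spike's own phase
selects the branch — a spike in the inhibitory half potentiates all of the
neuron's plastic synapses with recently active partners, a spike in the
excitatory half depresses them, bidirectionally and without regard to
spike order.  This makes the two quarter-cycle offsets symmetric, as pure
phase-dependent learning should be.

## Numerical and unit choices

The source experiments print their amplitudes in mixed units (pA and nA,
with a unitless leak conductance); the package treats every printed value
as the same dimensionless model unit at its printed magnitude.  One
normalization is then still free: the scale that converts summed EPSP
kernels into membrane current.  Left at 1, the numbers are mutually
inconsistent — the background alone would average
$\lambda W e \tau_s \approx 5.0$ units per NC neuron (11 times rheobase)
and the recurrent loop gain would exceed 1, driving the network into
refractory-limited saturation in which every phase-offset condition reads
out identically.  The package therefore exposes a single synaptic gain
(`syn_gain`, default 0.08) applied to all synaptic spike-event currents,
calibrated so that a full NC volley drives a hippocampal neuron at a few
times rheobase and stimulus-driven volleys contain the 3-5 spike bursts
the plasticity thresholds were built around, while the entorhinal gate
(0.41-1) and the theta current ($\pm 0.25$) remain decisive for firing
phase.  The background enters as one-timestep pulses rather than
accumulated kernels for the same reason: accumulated at the printed rate
it would be a tonic suprathreshold drive rather than noise.

Other numerical choices: fixed-step Euler at `dt_ms = 1` (all delays and
the refractory period are whole milliseconds; `dt` is configurable);
membrane capacitance $C_m = 1$ (unstated in the source parameter set; only
current-to-capacitance ratios are constrained); spike histories pruned
beyond 200 ms ($10\tau_s$, tail contribution $< 5\cdot 10^{-3}$ of a
spike's weight); the ADP clock starts at trial onset; degenerate network
draws with an empty inter-subgroup synapse set report a mean efficacy of 0
with a warning.  The percentile threshold of the memory decision index
interpolates linearly between order statistics (nearest-rank is available)
and recall is strict (`>`), which keeps the all-equal pool well defined.
The model-comparison F statistic uses the nested-RSS form
$F = (RSS_{variant}-RSS_{full})/(RSS_{full}/3)$ on $(1,3)$ degrees of
freedom — comparing non-nested 4-point fits with an F ratio is itself a
convention, adopted and documented as such — and BIC is Gaussian,
$n\log(RSS/n) + k\log n$ with $n = 4$, $k = 2$.

## What the simulations show, and what they do not

With 10 trials per condition at the defaults, the mean auditory-to-visual
efficacy in the read-out window is about 0.72 for theta-modulated
synchronous input and essentially 0 for the 90/180/270-degree offsets;
delta-modulated input sits near 0.15 regardless of offset, alpha near 0,
the no-flicker control near 0.35 and the prestimulus baseline at 0.  The
synchrony advantage is therefore theta-specific and exceeds the
unmodulated control, and the burst protocol reproduces the
trough-potentiation/peak-depression pattern with its 3-spike gateway.
The acceptance suite verifies these patterns at 32 trials per condition
(25 for the burst protocol), sizes chosen to keep the default test run in
minutes on one CPU while leaving the Welch comparisons decisively powered
given the near-saturated noise-free effects.

The generator is a model of the study conditions, not of real recordings:
sensory streams are perfect cosines, theta is a noiseless oscillator
(unless the noise sources are enabled), the network has 30 neurons and no
inhibitory population, and the background is stationary.  Passing tests
show that the mechanism — burst-thresholded STDP split across opposing
theta phases behind a phase-reversed entorhinal gate — produces the
phase-offset, frequency-specificity, no-flicker and variant-dissociation
patterns under these idealised conditions; they do not show that the
parameter values are uniquely identified, nor anything about recordings
from real tissue.

## Known limitations

Heterosynaptic depression of non-stimulated pathways is not implemented
(the flag `heterosynaptic_enabled` is reserved and must remain `FALSE`).
The hippocampal volleys are wider than a quarter theta cycle, so a residual
asymmetry between the 90- and 270-degree offsets remains in the lesioned
variants.  The exact F and BIC values reported for fits to behavioural
data depend on those external datasets and large stochastic grids;
`compare_models()` reproduces the statistics' construction and qualitative
ordering, not printed values.  A synthetic four-row accuracy table is
shipped at `system.file("extdata", "accuracy_synthetic.csv", package =
"thetaSTDP")` purely to demonstrate the interface.
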