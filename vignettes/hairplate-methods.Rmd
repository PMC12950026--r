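---
title: "Encoding joint kinematics with spiking hair-field arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding joint kinematics with spiking hair-field arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairplate)
```

`hairplate` models the first two stages of insect leg proprioception: an
array of narrowly tuned, spike-rate-adapting mechanosensory afferents (the
hair field), and the first-order interneurons that decode joint angle and
angular velocity from their converging spike trains. This vignette documents
the models, the numerical scheme, the tunable parameters, the calibration
procedures, and the design decisions taken where the problem was genuinely
open — the things a user should know before trusting numbers that come out of
the package.

## Receptive-field geometry

A hair field with `n_hairs` hairs tiles the sensitivity range
`[theta_min, theta_max]` with uniform receptive fields. Interior edges for
hair $i$ are

$$\theta^{(rf0)}_i = s\,(i-1) + \theta_{min} - \tfrac{\theta_{ol}}{2},\qquad
  \theta^{(rf90)}_i = s\,i + \theta_{min} + \tfrac{\theta_{ol}}{2},$$

with spacing $s = (\theta_{max}-\theta_{min})/n_{hairs}$ and overlap
$\theta_{ol}$; the first hair's lower edge and the last hair's upper edge are
pinned to the range bounds so coverage is exact. Deflection is the clamped
linear map onto $[0^\circ, 90^\circ]$; a negative-orientation hair is fully
deflected *below* its receptive field and releases as the joint angle rises.

Two conventions deserve a note because the geometry of opposing hair rows can
be written several equivalent ways:

* **Negative orientation.** We keep the same ascending edge formulas for both
  orientations and flip only the deflection law. One could instead mirror the
  edge indexing for the opposing row; the two conventions relabel hairs but
  produce identical plate behaviour. Our choice keeps the raster numbering of
  a 50-hair plate intuitive (hairs 1–50 negative field, 51–100 positive), and
  reproduces the expected rest-state sparsity: at the resting angle exactly
  the innermost position-wired hair of each field (numbers 25 and 26 of the
  position-wired raster) is partially deflected.
* **Outer-edge pinning in extended fields.** The extended bi-directional
  plate spans the full working range with both fields. We apply the
  outer-hair pinning rule to the expanded bounds as well, which keeps the
  coverage invariant exact for every field; whether the pinning should apply
  there is not specified anywhere, so this is a package decision (tested by
  the coverage property tests).

The `extended` plate exists because velocity must be encoded across the whole
working range while each hair is direction-selective: both fields span the
full range, but only the hairs whose receptive fields lie in each field's
original half-range stay wired to the position interneurons
(`position_mask`); the supplementary hairs feed the velocity chains alone.

## Neuron models and the integration scheme

The afferent is an adaptive exponential integrate-and-fire (AdEx) neuron; the
interneurons are leaky integrate-and-fire (LIF) neurons (see `?adex_params`,
`?lif_params` for the equations and calibrated values). All dynamics are
solved with a fixed-step backward-difference scheme at `dt = 0.25` ms:

* linear terms (leak, adaptation) are treated implicitly — the update divides
  by `(1 + dt/tau)` rather than multiplying by `(1 - dt/tau)`, which is
  unconditionally stable;
* the AdEx exponential term is evaluated at the previous step's voltage
  (a fully implicit solve would need a nonlinear iteration each step for no
  practical gain at this step size), with its argument clamped at
  `(V - V_T)/Delta_T <= 20`. The clamp only shapes the supra-threshold
  overshoot: spikes are detected at `V > V_T`, strictly, after each update,
  so spike timing at the default step is unaffected;
* on a spike, `V` resets to `E_L` exactly and the adaptation current jumps by
  `b`. There is no refractory period and no noise — the model is fully
  deterministic, and the test suite asserts bit-identical reruns.

The LIF update decays first, then adds the summed synaptic weights of the
step, then tests the threshold. Events landing on the same step sum. With the
velocity-interneuron parameters (tau = 5 ms, omega = 10.8 mV) this scheme
reproduces the textbook worked example exactly: a 333.3 Hz presynaptic train
yields one output spike per three inputs, at constant 9 ms intervals.

One parameter needs a unit note: the adaptation increment `b` is a current
(it adds to `w`, which enters the voltage equation as a current), and the
calibrated value is 264 pA. Printed parameter tables sometimes carry it in
volt-like units; dimensional consistency fixes the interpretation.

## Calibrating the velocity chain's high-pass stage

A fully deflected hair fires tonically at the plateau rate `f_ss`
(257 Hz with the default parameters; `steady_state_rate(I_const = 90 * 50)`).
The velocity chain only works if the per-hair high-pass LIF blocks that
plateau while passing phasic bursts, i.e. its cutoff input rate `f_c` must
sit *just above* `f_ss`. With `tau` fixed at 5 ms the weight `omega` is the
only dial: raising it lowers `f_c`. `calibrate_cutoff()` automates the
published tuning procedure — walk `omega` up a 0.1 mV grid and keep the last
value for which the realized tonic train of a fully deflected hair passes
zero spikes while a slow reference ramp still elicits output.

Under this package's integrators that endpoint is **10.5 mV**
(`f_ss = 257 Hz < f_c = 260 Hz`), not the 10.8 mV that the same procedure
produced in the original implementation. The bracket is knife-edge: the
tonic plateau realizes as inter-spike intervals alternating between 15 and 16
steps of 0.25 ms, and whether a mixed train of those intervals crosses a LIF
threshold depends on discretisation details below the resolution of any
printed parameter table. At 10.8 mV the plateau leaks through at ~37 Hz per
fully deflected hair — about 1.4 kHz of background across a 50-hair field —
which destroys rest-state silence, direction selectivity, and the linear
rate–velocity relation the chain exists to produce. The network default is
therefore the calibration endpoint `hp_lif_params()` (10.5 mV), with the
published table value kept as `velocity_lif_params()`; re-running
`calibrate_cutoff()` on any non-default afferent parameters is recommended.
The integrator stage after the high-pass uses omega = 25 mV, above the
20 mV threshold gap, so it relays every surviving spike.

## Rate estimation and evaluation metrics

The model emits spike times; every rate is an estimate, and the estimator is
a choice:

* `spike_rate(method = "isi")` (default): the reciprocal of each inter-spike
  interval, held over that interval, zero outside. This is the estimator used
  for decoding and for *peak* rates (`peak_rate()` is the reciprocal of the
  minimum interval).
* `spike_rate(method = "boxcar")`: centred spike count over a window (default
  50 ms), smoother, used for plotting and available wherever stair-stepping
  is a concern.

Decoding quality is scored on shape alone: the antagonistic interneuron rates
are subtracted and z-normalised (`combined_signal()`), the reference (joint
angle, or its central-difference angular velocity) is z-normalised, and
`mse_traces()` averages the squared difference over time steps — and, via
`mse_table()`, over joints and trials with equal weight per trace.
`lag_shift()` corrects the systematic encoding delay of the velocity chain
(the second half of a phasic burst trails the receptive-field crossing; on
gait-like input the delay is ~25 ms) before comparison. Direction encoding is
additionally scored as a binary classifier (`velocity_confusion()`): spikes
of the rising-direction interneuron during rising movement are true
positives, and accuracy is the mean of sensitivity and specificity. Samples
with |angular velocity| below 1e-6 deg/ms are excluded — the direction is
undefined while the joint is stationary, and the metric assumes balanced
classes rather than defining a zero class.

For afferent calibration, `ramp_battery_rates()` runs the two classic
ramp-and-hold batteries (five ramp velocities 980–96 °/s to a 37° hold; five
hold angles 60–15° at 240.4 °/s) and extracts per-trial peak and steady-state
rates (trailing 100 ms of the hold). `mae_fit()` averages the twenty absolute
deviations from a reference table, and `grid_search_adex()` sweeps the
mechanotransduction gain (10–150 pA/°) and adaptation increment `b`
(50–350 pA) against it, reporting all argmin ties explicitly
(`select_argmin()` picks lexicographically or with a seeded draw). The
packaged reference table (`reference_rates_synthetic()`) is a synthetic
stand-in constructed to match the published envelope of the cockroach
hair-plate recordings (peaks 118–166 Hz, ~150% of steady state, no tonic
response at the smallest hold angle); MAE values against it exercise the
machinery but are not a quantitative fit to the physiology.
`grid_search_position()` likewise sweeps the position-interneuron
`(tau, omega)` over the full decoding pipeline, simulating the sensory layer
once per trace and reusing it across cells.

Two aggregation details are worth making explicit. The whole-body error
averages over all 18 leg joints (3 joints × 6 legs) with equal weight; and
the velocity-interneuron MSE is quoted after the 25 ms lag correction, since
the uncorrected value mostly measures the known systematic delay rather than
encoding quality.

## What the synthetic gait generator does and does not emulate

`synthetic_gait()` stands in for motion-capture joint-angle recordings: a
~1 Hz quasi-periodic oscillation (fundamental plus two harmonics with random
phases), optional low-pass-filtered Gaussian noise, soft-clipped (tanh) so
the trace stays strictly inside the working range with smooth reversals,
sampled at 5 ms like a 200 Hz capture system and resampled to the 0.25 ms
simulation grid by exact linear interpolation. It reproduces the features the
encoder cares about — bounded range, stepping periodicity, smooth reversals,
plateau/swing asymmetry — and is a pure function of its seed.

It does **not** emulate inter-trial variability structure, step-class
transitions, inter-joint coupling, or measurement artefacts of real
kinematics. Tests passing on synthetic gait therefore validate the encoding
and decoding machinery, not biological fidelity of error magnitudes; on
recorded walking data the numbers will differ (the published position-decoder
error on 78 real trials, 0.031, happens to be close to the ~0.036 we measure
on synthetic gait, but that agreement is incidental).

## Problem sizes and tolerances

Defaults used throughout the examples, tests and the acceptance script, all
chosen as realistic study conditions: `dt = 0.25` ms; 50 hairs per field
(100 afferents per joint, the anatomically plausible maximum); gain
50 pA/°; overlap 0.1°; working ranges taken per joint from the observed
min/max of the trace. The test suite runs whole-joint encodings on 0.3–5 s
traces and the full 18-joint body on 0.3 s traces; the rate–velocity curve
uses one full triangle cycle per speed at 25–400 °/s (the sweep bracket is
not pinned down anywhere, so it is fixed here once). Floating-point
comparisons in the geometry layer are exact to 1e-9; spike-time comparisons
are exact (the scheme is deterministic).

## Known limitations

* Hair spacing and length are uniform; real hair fields grade both, and an
  efficient-coding layout would space receptive fields by stimulus
  statistics. The geometry layer is the natural extension point.
* One-dimensional hair rows: no two-dimensional plate geometry with
  multi-hair overlap beyond the configured `theta_ol`.
* The femur-tibia joint is served by a chordotonal organ, not a hair plate;
  the package applies the same encoder there on the stated assumption that
  the encoding features (range fractionation, phasic-tonic response) carry
  over.
* Velocity interneurons are direction-selective by construction and blind to
  movement *within* a receptive field; their resolution is set by the number
  of receptive-field edges, and their response trails the stimulus by
  ~25 ms.
* The AdEx adaptation time constant (50 ms) is a deliberate compromise: the
  physiological adaptation transient is slower (~600 ms fits it better), but
  a slow adaptation current suppresses the afferent after movement reversals
  and degrades downstream velocity encoding.
* Peak-rate figures depend on the estimator; with `peak_rate()` (1/min ISI)
  the five-velocity battery spans 114–200 Hz under this scheme.
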