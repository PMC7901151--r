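---
title: "Simulating discontinuous current-clamp artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating discontinuous current-clamp artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccrig)
```

## The problem

Intracellular recordings through sharp microelectrodes face a confound: the
electrode itself is an RC element in series with the cell, so any injected
current produces an IR drop across the electrode that adds to the membrane
potential. Two amplifier modes address this. *Bridge* mode injects
continuously and subtracts an estimate of the electrode drop through a
balance resistor. *Discontinuous current-clamp* (DCC) mode alternates, at a
switching rate of a few kHz, between a brief current pulse (a fraction
`duty` of the period, 1/3 by convention, scaled by `1/duty` to conserve
charge) and a current-free interval at the end of which the voltage is
sampled and held. If the electrode is much faster than the membrane, its IR
drop has vanished by sampling time while the membrane potential has barely
decayed.

The switching rate is therefore a compromise. Too low, and the membrane
itself decays between pulses: the sampled potential underestimates the true
depolarization (apparent input resistance falls), while the hidden
peak-to-trough "ripples" of the true membrane potential grow large enough
to trigger spikes on their crests — the cell fires at lower current and
higher rates than it would under continuous injection, and its interspike
intervals (ISIs) lock to integer multiples of the DCC period, producing
stepwise "plateaus" in the frequency–current (F-I) curve. Too high, and the
electrode no longer settles, contaminating the sample and inflating the
apparent resistance. `dccrig` simulates all of this and implements the
measurements used to quantify it.

## Models

**Passive cell and electrode.** Both are linear RC elements:

$$C\,\frac{dV}{dt} = G\,(V_0 - V) + I_{inj},\qquad C = G\,\tau .$$

Units are µS, ms, mV, nA throughout, so resistances are MΩ and capacitances
nF. The electrode carries the injected current and its potential adds to
the tip potential, `V_total = V_m + V_e`. Electrode nonlinearity
(current-dependent impedance) is deliberately out of scope; the electrode
is linear RC.

**Integrate-and-fire motoneuron with AHP.** Repetitive firing is governed
by an afterhyperpolarization (AHP) conductance:

$$C\,\frac{dV_m}{dt} = G_{in}(V_r - V_m) + \bar g_{AHP}\,z\,(E_K - V_m)
  + I_{inj} + \sigma\xi,\qquad \frac{dz}{dt} = -z/\tau_{AHP},$$

with a spike emitted when `V` crosses `V_th` from below. At each spike the
open fraction of the AHP is incremented instantaneously,

$$z_{after} = (1-\alpha)\,z_{before} + \alpha,$$

which recruits a fraction α of the remaining conductance, keeps `z` in
[0, 1] (fixed point `z = 1`; after *n* spikes from rest,
`z = 1 − (1−α)^n`), and drives the classic ISI lengthening as the AHP
accumulates. The AHP dynamics *during* the spike are not modelled, and the
model has no spike shape.

Default parameters (all configurable through `lif_params()`):

| parameter | default | meaning |
|---|---|---|
| `G_in` | 0.2 / 0.4 / 0.67 µS | input conductance of S / FR / FF motoneurons |
| `tau_m` | 2–5 ms | membrane time constant |
| `V_r`, `V_th` | 0, 10 mV | rest and spike threshold |
| `g_ahp_max`, `E_K` | 2 µS, −5 mV | AHP conductance and reversal |
| `tau_ahp`, `alpha` | 10 ms, 0.25 | AHP relaxation and per-spike recruitment |
| `sigma` | 0 nA | white current noise amplitude |
| `V_reset`, `t_refractory` | `V_r`, 1 ms | spike handling (see below) |

**Spike handling.** The model definition is silent on what happens to the
membrane potential at a spike, so this is a design choice of the package:
spikes are emitted on the upward `V_th` crossing (linearly interpolated
within the step), the membrane is set to `V_reset` (default: back to rest)
and an absolute refractory period of 1 ms applies. Both are configurable,
and — usefully — the firing statistics of this model are nearly insensitive
to `V_reset` because the membrane re-equilibrates within `~tau_m` (a couple
of ms) while ISIs are governed by the much slower AHP decay; we verified
numerically that `V_reset` ∈ {0, 5, 10} mV leaves the entrainment
experiments unchanged to < 0.01 DCC periods.

**Spike rendering.** For the stored traces only, spikes are drawn as a
marker of `spike_peak` = 40 mV lasting `spike_width` = 1 ms (about an
action-potential width). This makes the traces behave like real recordings
under dV/dt-based spike detection and under the amplifier's sample-and-hold
(a one-sample marker would be invisible to the sampler); the dynamics never
see the marker.

**Noise.** The σξ term is additive Gaussian current noise with per-step
standard deviation `sigma/sqrt(dt)` (white-noise scaling), giving a
membrane-voltage SD of `R*sigma/sqrt(2*tau)`. The deterministic experiments
use `sigma = 0`. Where a noisy discharge is needed (the entrainment-index
comparison below) we use `sigma = 2` nA, i.e. ≈1.5 mV of voltage noise on
the FF model — mid-range of what in vivo intracellular recordings show.
The noiseless model, lacking any discharge variability, phase-locks weakly
to the DCC clock at *any* rate; realistic noise erases that locking except
where the ripples are large (low rates), which is the phenomenon of
interest.

## The amplifier

In DCC mode each period starts with the on-phase (pulse first, then
settle), and the output is `V_total` sampled at `sample_offset` (default
1.0 = the instant before the next pulse) and held. The chopper conserves
charge exactly for arbitrary commands: within each period the commanded
charge is integrated and delivered uniformly over the on-phase (for a
constant command this is exactly `I/duty`, e.g. 3× for duty 1/3). Bridge
mode injects the command unchanged and outputs
`V_total − bridge_balance·I_com`; the default balance is the exact
electrode resistance, since Bridge is used as the artifact-free control.

## Closed-form steady states

For a linear RC element under charge-conserving chopped current the
steady-state response is periodic and solvable. With `x = T/τ`, end-of-period
sampling and duty `d`, the sampled-to-Bridge ratio is

$$\rho = \frac{1}{d}\,
  \frac{(1 - e^{-d x})\,e^{-(1-d)x}}{1 - e^{-x}},$$

(`steady_sampled_ratio()`; the general `sample_offset` shifts the decay
factor). ρ → 1 as the rate grows and decreases monotonically with `T/τ`:
ρ = 0.934 at 5 cycles per τ, 0.691 at one cycle per τ. The ripple amplitude
is the crest-to-trough excursion,

$$A = I R \rho\,\bigl(e^{(1-d)T/\tau} - 1\bigr)$$

(`steady_ripple()`), and with an electrode in series the sampled voltages
superpose, giving the apparent resistance
`R_cell·ρ(T, τ_cell) + R_e·ρ(T, τ_e)` (`apparent_resistance_total()`) with
its characteristic U-shape against rate. Every closed form is verified
against long steady-state simulations to better than 1e−6 relative over a
grid of `T/τ` ∈ [0.02, 2] and duty ∈ {1/4, 1/3, 1/2}; the closed forms in
turn serve as oracles for the simulator.

```{r}
steady_sampled_ratio(1, 5)      # 5 cycles per tau
steady_ripple(2.5, 3, 10, 1)    # FR-like cell, 10 nA, 1 kHz -> ~5.5 mV
recommend_min_rate(4.0)         # slow motoneuron: 3.75 kHz
```

## Numerical choices

* **Integration.** Exact exponential stepping for all linear elements
  (zero discretization error for piecewise-constant current); exponential
  Euler for the LIF with the AHP conductance frozen within the step. The
  step is `dt = min(τ_e/5, T_DCC/30, 0.005 ms)`, and the DCC period is
  snapped to an integer number of steps with the on-phase boundary and the
  sampling instant exact grid points (the realized duty equals the
  requested one exactly; for duty 1/3 the period is a multiple of 3 steps).
* **Spike times** are linearly interpolated within the crossing step; the
  AHP increment applies to the end-of-step `z` (the within-step decay it
  ignores is < `dt/τ_AHP` ≈ 5·10⁻⁴ relative).
* **Determinism.** With `sigma = 0` runs are bit-reproducible; with noise,
  reproducible given a seed. Sweeps offset the base seed by the rate index
  and record it.
* **Degenerate inputs** are rejected at construction (non-positive
  conductances, time constants, duties outside (0, 1), off-grid sampling
  instants error rather than interpolate).

## Measurement definitions

All measurements of the excitability literature are implemented on traces:
spike detection at the 10 V/s slope criterion (with an optional voltage
floor for ripple-distorted low-rate traces, which — as with real
recordings — defeat pure slope detection); voltage threshold at the last
10 V/s crossing before the spike (with a 1 ms lookahead so the criterion
works on sampled-and-held traces, where the upstroke appears only at the
first sample taken on the spike); F-I curves as reciprocal-ISI versus
commanded current at the spike, split at the ramp apex; onset/offset
currents; F-I gain as a least-squares slope over a user-chosen current
window (an `"auto"` mode picks the best-R² contiguous span covering ≥30%
of ascending points — a labelled heuristic, since "the most linear part"
is a judgement call); apparent input resistance as the slope of peak
response versus amplitude over a ±3 nA pulse series; membrane time
constant by log-linear fit of the relaxation after a −5 nA / 1 ms pulse.

**Plateau detection** works on ISIs expressed in DCC periods: integer `k`
is a plateau when at least `min_count = 4` ISIs fall within `tol = 0.1`
periods of `k`, for `k ≤ k_max = 20`. The cap encodes resolvability:
adjacent subharmonics `rate/k` are spaced `≈ rate/k²`, so beyond roughly 20
periods per ISI the steps are finer than any realistic discharge
variability and no plateau is observable even if weak locking exists. We
chose this ISI-quantization rule over clustering the frequency histogram
because it encodes the phenomenon directly and has a low false-positive
rate on diffuse (Poisson) trains, which the tests check by Monte Carlo.
Reported plateau centers are the subharmonics themselves (e.g. a 1050 Hz
clock gives 95.5, 87.5, 80.8, … Hz for k = 11, 12, 13, …).

**Minimum recommended rate.** Excitability measurements converge to their
Bridge values once the switching rate exceeds roughly 15–20 cycles per
membrane time constant (the older 10-cycle rule of thumb is not
sufficient). `recommend_min_rate(tau_m, cycles_per_tau = 15)` returns
`cycles_per_tau/tau_m` kHz: 3.75 kHz suffices for a slow motoneuron with
τ = 4 ms, while a fast fatigable motoneuron at τ ≈ 2 ms needs ≥ 7 kHz.

## Study conditions and problem sizes

The demonstration experiments (also used by the test suite and the
acceptance script) are:

* **Entrainment**: FF motoneuron (R_in 1.5 MΩ, τ_m 2 ms), 10 nA triangular
  ramp at 1 nA/s (22 s simulated per run, ≈5·10⁶ steps), DCC at 1, 3 and
  8 kHz, noiseless. The minimal ISI in DCC periods and the plateau flags
  quantify the quantization of firing by the DCC clock.
* **Resistance vs rate**: passive 5 MΩ / 5 ms cell with a 1 MΩ / 25 µs
  electrode, ±pulse series per rate.
* **Ripple vs rate**: passive 2.5 MΩ / 3 ms cell at 10 nA.
* **Spurious firing**: a LIF chosen from the closed form so that a 4 nA /
  200 ms pulse is steadily subthreshold in Bridge yet crosses threshold on
  the ripple crests at 1.5 kHz: R_in = 2.45 MΩ, τ_m = 4.9 ms gives a
  steady Bridge level of 9.8 mV < V_th = 10 mV, a 1.5 kHz crest of
  `I·R·ρ·e^{(1-d)T/τ}` = 10.25 mV (fires repetitively), and an 8 kHz crest
  of 9.88 mV (silent). The parameters were derived from the closed form
  before simulating.

## What the generator does and does not emulate

The simulator produces the artifact phenomenology of a linear cell +
electrode and an idealized sample-and-hold amplifier: rate-dependent
under/over-estimation of resistance, hidden ripples, ripple-driven firing,
ISI quantization and plateau formation, and spurious firing at low rates.
It does **not** emulate: electrode nonlinearity (impedance growing with
current — the practical reason low rates tempt experimenters); spike
biophysics (Na/K currents, mixed-mode oscillations and the subprimary
firing range they produce); capacitance-compensation dynamics, amplifier
saturation or anti-alias filtering; or synaptic (colored) noise — σξ is
white. Passing tests therefore validate the artifact mechanism and the
measurement pipeline, not a quantitative match to any particular neuron;
in particular, real motoneurons show additional plateau-like structure of
*biological* origin (mixed-mode oscillations) at low firing rates that
this model intentionally lacks.

## Known limitations

* The LIF's maximal firing rate under strong AHP parameters is modest
  (~80 Hz at 10 nA for the FF parameter set); plateau phenomena at a given
  DCC rate appear only where the discharge actually reaches ISIs below
  `k_max` periods.
* `fi_gain(..., "auto")` is a heuristic; reported gains should use an
  explicit window.
* Spike detection on raw low-rate DCC membrane traces is unreliable by
  nature (ripples exceed the slope criterion); use the simulator's emitted
  spike times for model traces, or a voltage floor (`min_v`) for external
  ones.
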