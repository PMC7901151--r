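# dccrig

A virtual current-clamp rig for studying how the switching rate of a
discontinuous current-clamp (DCC) amplifier distorts intracellular
measurements of neuronal excitability.

Sharp-microelectrode recordings inject current through the same electrode
that measures voltage. DCC amplifiers separate the two in time: each period
(at a switching rate of a few kHz) starts with a brief current pulse —
scaled by `1/duty` (3× for the conventional duty cycle of 1/3) to conserve
charge — followed by a current-free interval at whose end the voltage is
sampled and held. The technique works only in a window of switching rates.
`dccrig` simulates the whole chain — passive RC cell, RC electrode,
integrate-and-fire motoneuron with an afterhyperpolarization (AHP)
conductance, chopper and sample-and-hold — and implements the standard
excitability measurements, so that the artifacts of a badly chosen rate can
be quantified and predicted.

The core quantitative result is the closed-form steady state of a linear RC
element (resistance *R*, time constant *τ*) under charge-conserving chopped
current with period *T* and duty *d*, sampled at the end of the period:

ρ(T, τ) = (1/d) · (1 − e^(−dT/τ)) · e^(−(1−d)T/τ) / (1 − e^(−T/τ))

The sampled voltage is `I·R·ρ` (so the apparent resistance falls below *R*
as the rate drops), the hidden membrane ripple has amplitude
`I·R·ρ·(e^((1−d)T/τ) − 1)`, and with an electrode in series the sampled
steady states superpose: `R_app = R_cell·ρ(T, τ_cell) + R_e·ρ(T, τ_e)`,
which reproduces both the low-rate underestimation and the high-rate
electrode contamination. On the firing side, the ripples entrain spikes to
integer multiples of the DCC period, producing stepwise "plateaus" in the
frequency–current curve at the subharmonics `rate/k` and an artificial
increase of apparent excitability (firing at lower current, higher rates).
The package's rule of thumb, `recommend_min_rate(tau_m, cycles_per_tau =
15)`, converts the finding that ≥15–20 cycles per membrane time constant
are needed into a minimum rate per cell type.

## Worked example

A fast fatigable (FF) motoneuron model (R_in = 1.5 MΩ, τ_m = 2 ms) driven
by a 10 nA triangular ramp at 1 nA/s, recorded in DCC mode at 1, 3 and
8 kHz:

```r
library(dccrig)
ff   <- lif_params(G_in = 0.67, tau_m = 2)
ramp <- make_triangular_ramp(slope = 1, peak = 10)
sw <- run_rate_sweep(ff, NULL, c(1, 3, 8), ramp,
                     measure = "metrics", keep_traces = FALSE)
sw[, c("rate", "onset", "offset", "n_spikes",
       "min_isi_periods", "plateau_flag")]
#>   rate onset offset n_spikes min_isi_periods plateau_flag
#> 1    1 5.726  5.765      628           7.999         TRUE
#> 2    3 6.346  6.390      436          31.998        FALSE
#> 3    8 6.565  6.633      384          92.995        FALSE
```

Reading the table: at 8 kHz (16 cycles per time constant — above the
recommended minimum) the cell starts firing at 6.57 nA, close to its true
rheobase of `G_in·V_th = 6.7` nA. Dropping the rate to 1 kHz makes the
same cell *appear* more excitable — onset current falls to 5.7 nA and the
ramp elicits 628 instead of 384 spikes — even though the apparent
resistance is lower. The shortest interspike interval shrinks to 8 DCC
periods and the firing locks to the DCC clock (`plateau_flag`), the
signature of a suboptimal rate. Closed-form calculators predict the
underlying quantities directly:

```r
steady_sampled_ratio(1 / 8, 2)  # sampled/true voltage at 8 kHz: 0.9792
steady_ripple(2.5, 3, 10, 1)    # ripple, 2.5 MOhm/3 ms cell, 10 nA, 1 kHz: 5.54 mV
recommend_min_rate(4.0)         # slow motoneuron (tau 4 ms): 3.75 kHz
recommend_min_rate(2.1)         # fast fatigable (tau 2.1 ms): 7.14 kHz
```

See `vignette("dcc-artifacts")` for the models, the derivations and the
design decisions, and `run_recipe()` for self-contained demonstrations
(resistance-vs-rate, ripple, entrainment, gain distortion, spurious
firing).

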