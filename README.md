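# ephapsim

Simulation and analysis of **ephaptic entrainment** — phase locking of a
single neuron's spikes to an extracellular field — under degradation of the
neuron's passive membrane properties.  The package is aimed at computational
neuroscientists studying how membrane damage of the kind produced by
misfolded-protein oligomers (channel inactivation, bilayer disruption)
reshapes a neuron's frequency preference, the single-cell counterpart of the
band-power shifts seen in Parkinson's and Alzheimer's disease.

## Model

The neuron is a quadratic integrate-and-fire model forced through a
point-source extracellular potential by a sinusoidal local-field-potential
surrogate:

    dV/dt = (V - V_rest)(V - V_thresh) / [R_dfl C_dfl (V_thresh - V_rest)]
            - rho_ext I_eph(t) / (4 pi R_dfl C_dfl r)
            + I_0 / C_dfl,            with   V >= V_peak  =>  V <- c

Damage enters through two fractions: `b`, the proportion of inactivated ion
channels (`R_dfl = R_m / (1 - b)`), and `h`, the proportion of impaired
bilayer patches (`C_dfl = C_m (1 - h)`).  Entrainment is quantified by the
spike-field coherence, the ratio of the power of the spike-triggered average
to the mean power of the individual spike-centred one-period stimulus
segments, evaluated at the stimulus frequency:

    SFC = Psi(STA) / mean_i Psi(l_i)   in [0, 1].

Frequency sweeps (1–45 Hz) per damage condition yield SFC curves whose peak
frequency and preference band are the experiment's endpoints.  The headline
behaviour: combined or channel-only damage drives the preferred frequency
from below 10 Hz into the beta and gamma bands; bilayer-only damage leaves it
below 10 Hz.

## Worked example

```r
library(ephapsim)

mp <- membrane_parameters()   # standard cortical constants, SI units
mp
#> Membrane parameters (SI units)
#>   V_rest      -65.0 mV   V_thresh    -55.0 mV
#>   V_peak       55.0 mV   c_reset     -70.0 mV
#>   C_m  0.02 F/m^2   R_m  0.1 Ohm.m^2   (tau = 2 ms)
#>   rho_ext  3.5 Ohm.m   r_dist  50 um

# one 3-s run of the healthy neuron under a 5 Hz field
sim <- simulate_qif(simulation_config(mp, damage_parameters(),
                                      stimulus_spec(f_stim = 5),
                                      duration = 3, dt = 2e-5, seed = 1))
sim
#> QIF-E simulation: 3 s at dt = 2e-05 s, b = 0, h = 0
#>   stimulus 5 Hz, 17 spikes (5.67 /s)

sta <- spike_triggered_average(sim$t, sim$I_eph,
                               sim$spikes$times[sim$spikes$times >= 0.5], 5)
spike_field_coherence(sta)
#> SFC = 0.5695 at 5 Hz (14 spikes)

# frequency sweeps: healthy vs 4% combined damage
cfg <- sweep_config(stim = stimulus_spec(), f_grid = seq(1, 45, by = 2),
                    repeats = 3, duration = 5, dt = 2e-5, seed0 = 42)
sfc_curve(cfg, damage_parameters(0, 0))
#> SFC curve (b = 0, h = 0): 23 frequencies in [1, 45] Hz
#>   peak 7 Hz (SFC 0.980), band 7-11 Hz
sfc_curve(cfg, damage_parameters(0.04, 0.04))
#> SFC curve (b = 0.04, h = 0.04): 23 frequencies in [1, 45] Hz
#>   peak 17 Hz (SFC 0.975), band 15-19 Hz
```

The healthy neuron fires tonically at ~5.7 spikes/s and locks to slow fields
(peak 7 Hz, partial coherence 0.57 at 5 Hz in a single short run); 4%
combined damage multiplies its suprathreshold margin and moves the
preference into the beta band (peak 17 Hz), with near-perfect coherence at
the peak of the averaged curve.

A command-line front end is installed with the package
(`system.file("scripts", "ephapsim", package = "ephapsim")`):
`ephapsim calibrate` writes a calibrated stimulus spec as JSON, and
`ephapsim sweep --mode {bh|b|h} --levels 0,0.04,...` writes per-condition
SFC curves as CSV plus summary and manifest JSON.

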