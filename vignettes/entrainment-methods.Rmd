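---
title: "Ephaptic entrainment of a damaged quadratic integrate-and-fire neuron: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ephaptic entrainment of a damaged quadratic integrate-and-fire neuron: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephapsim)
```

## The scientific question

Ephaptic coupling is neuronal interaction carried purely by extracellular
electric fields: a population's local field potential (LFP) weakly polarises
nearby membranes and can entrain their spiking without any synaptic contact.
Healthy cortical neurons entrain preferentially to slow fields (below
~10 Hz).  This package asks how that preference moves when the passive
electrical properties of the membrane degrade, as happens when misfolded
protein oligomers inactivate ion channels or disrupt the lipid bilayer in
neurodegenerative disease.  Its core result, reproduced end to end by
`scripts/acceptance.R`, is that channel damage pushes the preferred
entrainment frequency out of the slow band and across the beta (13--30 Hz)
into the gamma (>30 Hz) range, while bilayer damage alone leaves the
preference below 10 Hz.

## Model

The neuron is a quadratic integrate-and-fire (QIF) point model with an
ephaptic forcing term.  With membrane potential $V_m$, the healthy dynamics
are

$$\frac{dV_m}{dt} =
  \frac{(V_m - V_\mathrm{rest})(V_m - V_\mathrm{thresh})}
       {R_m C_m (V_\mathrm{thresh} - V_\mathrm{rest})}
  \;-\; \frac{\rho_\mathrm{ext}\, I_\mathrm{eph}(t)}{4\pi R_m C_m r}
  \;+\; \frac{I_0}{C_m},$$

with the hard reset $V_m \ge V_\mathrm{peak} \Rightarrow V_m \gets c$.  The
ephaptic current $I_\mathrm{eph}$ is a sinusoid standing in for the LFP; it
reaches the membrane through the point-source extracellular potential
$\rho_\mathrm{ext} I / (4\pi r)$ of a homogeneous resistive medium.  $I_0$
is a tonic synaptic current density.

Damage enters through two fractions.  Treating the membrane as parallel
unit conductances (ion channels) and parallel unit capacitors (bilayer
patches), inactivating a fraction $b$ of the channels raises the specific
resistance to $R_\mathrm{dfl} = R_m/(1-b)$, and impairing a fraction $h$ of
the capacitive patches lowers the specific capacitance to
$C_\mathrm{dfl} = C_m(1-h)$.  Substituting these into the healthy equation
gives the damaged model; equivalently, the quadratic and ephaptic terms are
rescaled by $(1-b)/(1-h)$ and the synaptic term by $1/(1-h)$.  The
microscopic counts behind $b$ and $h$ never appear in the interface — only
the two fractions do, each validated on $[0, 1)$ ($1$ is the singular
total-damage limit).  Fractions above $0.2$ are legal inputs even though no
entrainment peak is expected there.

Internally everything is SI (volts, seconds, F/m², Ω·m², amperes): that is
the only unit system in which $R_m C_m$ is a time and
$\rho_\mathrm{ext} I/(4\pi r)$ a potential.  Defaults are standard
cortical values: $V_\mathrm{rest} = -65$ mV, $V_\mathrm{thresh} = -55$ mV,
$V_\mathrm{peak} = +55$ mV, $c = -70$ mV, $C_m = 2\times10^{-2}$ F/m²,
$R_m = 10^{-1}$ Ω·m² (so $\tau = R_m C_m = 2$ ms),
$\rho_\mathrm{ext} = 3.5$ Ω·m, $r = 50$ µm.

### Why the preference moves

The QIF model fires tonically once $I_0$ exceeds the rheobase
$(V_\mathrm{thresh}-V_\mathrm{rest})/(4 R_\mathrm{dfl})$, and close to that
bifurcation the firing rate grows like the square root of the suprathreshold
margin.  Combined damage $b = h$ cancels exactly in $\tau_\mathrm{eff} =
R_\mathrm{dfl} C_\mathrm{dfl}$ but not in the synaptic coefficient
$I_0/(C_m(1-h))$, so even a 4% damage multiplies the tiny margin severalfold
and the tonic rate jumps from ~6 to ~18 spikes/s.  The neuron entrains best
(1:1 phase locking, coherence near 1) at stimulus frequencies near its tonic
rate, so the preference band tracks the rate: that is the entire mechanism
behind the band shifts.  Channel-only damage both raises the drive and
lowers rheobase sensitivity through $(1-b)$, producing a smaller rate
increase than $b=h$ at equal level; bilayer-only damage rescales the whole
right-hand side by $1/(1-h)$ — a pure change of clock that moves the rate
only from 5.7 to 7.1 spikes/s at $h = 0.20$, which is why its preference
stays below 10 Hz.

## Entrainment measurement

For each stimulus frequency $f$ the spike-triggered average (STA) collects
the stimulus segment of duration $1/f$ **centred** on every spike and
averages element-wise; spikes whose window leaves the record are dropped
(padding would bias the spectrum) and counted.  The spike-field coherence is

$$\mathrm{SFC} = \frac{\Psi(\mathrm{STA})}{\tfrac1n \sum_i \Psi(l_i)},$$

where $\Psi$ is the raw (untapered) periodogram $|\mathrm{DFT}|^2$ and
$l_i$ are the individual spike-centred segments, evaluated at the
fundamental bin — with a one-period window that bin sits exactly at the
stimulus frequency.  By linearity of the DFT this equals
$|\overline{z}|^2 / \overline{|z|^2}$ for the segments' fundamental Fourier
coefficients, hence $0 \le \mathrm{SFC} \le 1$ by Cauchy--Schwarz: 1 when
every spike sits at the same stimulus phase, about $1/n$ for phases spread
uniformly.  Two conventions are free and fixed here: the SFC reported per
stimulus frequency is the value at the stimulus bin (not a maximum over
bins), and the denominator segments are exactly the spike-centred $l_i$,
not independent stimulus epochs.  A zero-frequency stimulus is degenerate
for the $1/f$ window, so frequency grids start at 1 Hz.

## Calibration of the drive

Two amplitudes have no printed values anywhere and set the operating point:

* **`I_0`** (tonic synaptic density): calibrated so the stimulus-free,
  noise-free rate — computed exactly by quadrature of $1/F(V)$ from $c$ to
  $V_\mathrm{peak}$ (`analytic_isi()`) — falls in 5--15 spikes/s.  The
  default is $1.005 \times$ rheobase $= 0.0251250$ A/m² (5.70 spikes/s).
  Proximity to rheobase is what makes the rate, and with it the preference
  band, sensitive to small damage fractions.
* **`A_eph`** (ephaptic amplitude): calibrated so the healthy SFC peak sits
  at or below 10 Hz.  The default produces a peak extracellular potential
  of ~0.1 mV.  This is deliberately **not** the millivolt scale of bulk
  LFPs: a neuron held 0.5% above rheobase has a suprathreshold margin
  equivalent to ~12 µV of membrane polarisation, and a millivolt field
  overdrives it — it fires bursts inside each slow stimulus cycle and is
  slaved one-spike-per-cycle up to ~20 Hz, so no sub-10 Hz preference can
  exist.  Frequency-selective entrainment requires field modulation
  comparable to the margin; 0.1 mV at the electrode (≈ tens of µV effective
  drive modulation) is where the healthy model shows the canonical slow
  preference.  Physically this is consistent with a neuron responding to
  the local, partially shielded residue of the population field.
* **`sigma_noise`** (synaptic white-noise intensity,
  per-step SD $= \sigma/\sqrt{dt}$ so injected variance per unit time is
  step-independent): chosen perturbative at $2\times10^{-5}$
  A·s$^{1/2}$/m², shifting the tonic rate by under 5%.  Its two roles:
  it generates the trial-to-trial spread summarised by the sweep error
  bars, and it destroys the fragile high-order $1\!:\!q$ subharmonic
  locking that would otherwise hold coherence near 1 far above the firing
  rate and flatten the frequency preference.  Stronger noise (intensity
  $10^{-4}$) starts to move the operating point itself (healthy rate
  >10 spikes/s) and was rejected on that ground.

`calibrate_baseline()` encodes this procedure as a grid search with the
template amplitudes tried first, so the shipped defaults are its fixed
point; the calibrated spec is then frozen and reused unchanged for every
damage condition.

## Experiment design and numerical choices

* Integration is explicit forward Euler, default $dt = 10^{-5}$ s
  ($\tau/200$), capped at $10^{-4}$ s.  Adaptive steppers mishandle the
  hard reset; Euler with the reset converges at $O(dt)$ to the quadrature
  oracle (measured first-order constant ≈ 2.5 on the interspike interval).
  Spikes are stamped at the step where the crossing is detected — no
  sub-step interpolation, since STA windows (≥ 22 ms at 45 Hz) dwarf $dt$.
  A step carrying $V_m$ more than 100 mV past $V_\mathrm{peak}$ aborts with
  a stability error naming $dt$.
* $V_m(0) = V_\mathrm{rest}$, and the first 0.5 s of every run is discarded
  before analysis to remove onset artifacts.
* Sweeps run 1--45 Hz in 1 Hz steps, 10 repeats of 10 s by default;
  the acceptance script uses 5 repeats of 5 s, and the test suite 2 repeats
  of 3 s on a 2 Hz grid at $dt = 2\times10^{-5}$ s — sizes chosen so the
  full ladder of damage conditions reruns in minutes while each curve still
  rests on tens of spikes per frequency.
* Seeds are hierarchical: each (frequency, repeat, damage) cell hashes into
  its own stream below $2^{31}$, xored with the master seed, so any subset
  of a grid reruns bit-identically.
* Band summarisation: the peak is the argmax of the repeat-averaged curve
  (ties to the lowest frequency); the band is the maximal contiguous grid
  run containing the peak with mean SFC ≥ 0.9 of the maximum.  The 0.9 is a
  free choice — no published definition of band edges exists — and missing
  frequencies (too few usable spikes) break contiguity rather than counting
  as zero.

## What the synthetic fixtures do and do not show

`locked_spike_train()` manufactures spike trains locked to a sinusoid at a
fixed phase with von Mises phase jitter, from perfect locking
($\kappa = \infty$, SFC exactly 1) to uniform phase ($\kappa = 0$, SFC
$\sim 1/n$).  These fixtures validate the analysis layer — bounds,
monotonicity in jitter, shift invariance, agreement with a direct
sine/cosine projection oracle — independently of the neuron model.  They do
not emulate bursting, refractoriness or rate--phase correlations of real
spike trains, so passing them says nothing about STA behaviour under those
features; the simulation layer is the only source of realistic trains here.

## Known limitations

* The reported decline of peak SFC *intensity* with increasing damage is
  usually attributed to the low-pass filtering of neural tissue.  That
  filter is not part of the model equation: the sinusoidal drive amplitude
  is frequency-independent, and both the coupling and the noise scale with
  the suprathreshold margin in the same way, so in this implementation the
  peak coherence stays roughly constant (~0.97 at test scale) across damage
  levels.  The peak *position* — the quantity behind every published band —
  is unaffected.  Adding an explicit tissue filter on
  $I_\mathrm{eph}$ would be a natural extension.
* The model is a single point neuron; no network or spatial membrane
  extension, no conductance-based synapses, no separate Na/K channel
  resistances, no temperature dependence.
* Damage above 20% is accepted but the preference band degrades gracefully
  toward flat curves; no quantitative claims are made there.
* Euler + hard reset biases the interspike interval by ≈ $2.5\,dt$; at the
  default step this is 0.04% of the healthy interval and far below the
  1 Hz frequency-grid resolution.

## A minimal session

```{r example, eval = FALSE}
cfg <- sweep_config(stim = stimulus_spec(), f_grid = seq(1, 45, by = 2),
                    repeats = 3, duration = 5, dt = 2e-5, seed0 = 42)
healthy <- sfc_curve(cfg, damage_parameters(0, 0))
damaged <- sfc_curve(cfg, damage_parameters(0.04, 0.04))
healthy$peak_f   # 7  (slow preference)
damaged$peak_f   # 17 (beta-band preference)
```
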