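---
title: "The swell-burst model: mechanics, transport, and cycle dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The swell-burst model: mechanics, transport, and cycle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swellburst)
```

## The phenomenon

A giant unilamellar vesicle (GUV) loaded with an impermeant osmolyte
(say 200 mM sucrose) and transferred into water experiences a van't Hoff
pressure difference $\Delta P = R T \Delta c$ — about 0.5 MPa for
200 mM at 25 °C. Water crosses the bilayer far faster than sucrose
does, so the vesicle swells. A flaccid vesicle first inflates to a
sphere at no tensile cost; further influx irons out thermal undulations
and then stretches the area per lipid, building membrane tension
$\sigma$. Bilayers tolerate only a few percent of area dilation: at a
lytic tension of a few mN/m a micron-scale pore opens, the Laplace
pressure $2\sigma/R$ ejects interior fluid and part of the solute load
escapes, tension collapses, the pore reseals, and — because the vesicle
is still hyperosmotic, albeit less so — the cycle repeats. Each cycle
removes solute, so successive swell phases take longer: the oscillation
is damped, and it ends in a quiescent state where the residual osmotic
pressure is balanced by a sub-lytic Laplace tension. Because membrane
tension also couples to lipid miscibility, the optically uniform
membrane breaks into liquid-ordered/liquid-disordered domains in the
tense part of each cycle and returns to uniformity after each burst,
which is what the fluorescence readout sees.

This package implements that mechanism as an event-driven ODE model,
plus the observable layer: a synthetic fluorescence-homogeneity index
and the analyses that recover cycle periods, damping, and effusion
times from it.

## Membrane mechanics

**Tension from dilation.** The projected-area dilation at tension
$\sigma$ is the superposition of undulation smoothing and molecular
stretching,
$$
\alpha(\sigma) \;=\; \frac{k_B T}{8\pi\kappa}
\ln\!\Big(1 + \frac{c\,\sigma A_0}{\kappa}\Big) \;+\; \frac{\sigma}{E},
\qquad c = \frac{1}{24\pi},
$$
with bending modulus $\kappa$ (default $10^{-19}$ J), area-expansion
modulus $E$ (default 0.2 N/m) and relaxed membrane area $A_0$. The
crossover from the logarithmic to the linear regime sits at
0.1–1 mN/m for these defaults. `area_dilation()` evaluates this;
`tension_from_dilation()` inverts it with a safeguarded Newton
iteration to ~1e-12 relative tolerance (the function is concave and
strictly increasing, so the inverse is unique; the iteration starts
from the smaller of the two single-regime inverses, which
underestimates, and converges monotonically).

**Pore energetics.** A pore of radius $r$ in a membrane at tension
$\sigma$ costs $E(r) = 2\pi r\gamma - \pi r^2\sigma$ with edge tension
$\gamma$ (default 10 pN): the classical barrier
$\pi\gamma^2/\sigma$ at $r^\* = \gamma/\sigma$. At sub-mN/m tensions
the barrier exceeds ~40 $k_BT$ and pores are thermally inaccessible;
near the lytic threshold it falls to a few $k_BT$. Because the
experiments show one reproducible pore per cycle at maximal swelling,
the engine treats poration as a deterministic threshold event at
$\sigma_{lys}$ and exposes `pore_nucleation_barrier()` as a diagnostic
only. Two lytic-tension conventions circulate (a few mN/m under slow
osmotic loading; tens of mN/m under fast mechanical loading); the
default is $\sigma_{lys} = 5$ mN/m with a `"high_lysis"` preset at
35 mN/m.

**Relaxation by a large pore.** With the vesicle contents momentarily
fixed, redistributing lipids around a pore of radius $r$ relaxes
tension completely at the critical radius
$r_c = 2R_0\sqrt{\sigma_0/E}$ (`critical_pore_radius()`); for the
default scenario $r_c \approx 3.2\ \mu$m, *smaller* than the observed
(and default) 5 µm pore. The static tension-ratio relation
$\sigma/\sigma_0 = 1 - r^2/r_c^2 - 4(R_i^2-R^2)/r_c^2$
(`open_pore_tension_ratio()`) expresses the two relaxation routes —
pore growth and content efflux — and is clamped at zero where it would
go negative.

## Transport

Water crosses the intact membrane with permeability $P_w$ (default
$10^{-5}$ m/s; a $10^{-4}$ m/s `"fast_water"` preset covers the upper
reported range), giving the volume flux
$Q_{in} = P_w v_w A\,[\Delta c - 2\sigma/(R\,R_{gas}T)]$, which
vanishes at osmotic/Laplace balance. Solute leaves an *open* pore by
diffusion, $j = \pi r^2 c D / R$; balancing that against the interior
reservoir gives exponential decay with e-folding time
$$
\tau = \frac{4R^4}{3r^2 D},
$$
about 0.53 s for $R = 10\ \mu$m, $r = 5\ \mu$m, $D = 10^{-9}$ m²/s —
the scale of observed pore lifetimes. (This is the time constant
obtained by actually solving the effusion balance; it is the form that
reproduces the ~0.5 s estimate and has the right dimensions.) Volume is
ejected through the pore by the Laplace pressure with the Sampson
orifice conductance $Q_{out} = r^3\Delta P/(3\eta)$. Neither a water
flux law nor a pore outflow law is uniquely dictated by the
phenomenology; the linear osmotic law and Sampson flow are the minimal
standard closures and both are configurable.

## The engine and its design choices

`simulate_vesicle()` integrates states $(V, n_s, \text{leaked})$ with
`deSolve::lsodar`, locating pore opening ($\sigma = \sigma_{lys}$) and
resealing ($\sigma = \sigma_{close}$) by root-finding, so event times
are independent of the output grid and of the step cap `dt_max`
(halving `dt_max` changes periods by strictly less than 0.1%). Choices
that were genuinely open:

* **Pore radius.** No pore-growth law is identifiable from the
  phenomenology; the pore opens instantaneously to a fixed radius
  (default 5 µm, within the observed 5–15 µm diameters) and closes at
  $\sigma_{close} = 0.02\,\sigma_{lys}$ (near-complete relaxation; no
  measured closure threshold exists).
* **Tension accounting while the pore is open.** Dilation stays
  referenced to the sphere area, $\alpha = (4\pi R^2 - A_0)/A_0$, and
  tension relaxes *continuously* through volume ejection. The
  alternative — crediting the pore area $\pi r^2$ against the dilation —
  collapses tension discontinuously to zero the moment the pore opens,
  because the default pore exceeds $r_c$; the closure threshold would
  then fire instantly, no solute would leave, and the cycles would never
  damp. Continuous relaxation through outflow reproduces the described
  closure route ("reduced net membrane area and partial solute loss")
  with finite pore lifetimes. The $\pi r^2$ accounting remains available
  as the static relation `open_pore_tension_ratio()`.
* **Solute carriage.** The ejected volume leaves at the interior
  concentration, so solute crosses the open pore both convectively
  ($c\,Q_{out}$) and diffusively ($j$). Pure volume ejection without
  solute carriage would concentrate the interior, which is unphysical;
  `convective_solute = FALSE` disables it for exploring the
  diffusion-only limit.
* **Water influx during the open phase** stays on: influx and leakage
  are simultaneous opposing processes.
* **Initial flaccidity.** The relaxed area is
  $A_0 = (1+\alpha_{excess})\,4\pi R_{init}^2$ with
  $\alpha_{excess} = 0.05$, the order of excess area a
  few-percent-stretchable bilayer can present; tension is zero until the
  sphere of area $A_0$ is filled.
* **Quiescence.** Before each swell phase the engine solves the
  osmotic/Laplace balance (`equilibrium_state()`) for the current
  solute load; if the balance tension is sub-lytic no further burst is
  possible, a `QUIESCENT` event is recorded, and the trajectory relaxes
  to within 0.1% of the balance radius (or to `t_max`).

With the canonical scenario (10 µm, 200 mM sucrose, water bath) the
engine produces first periods of ~5 s that lengthen by ~5% per cycle,
~4–5% solute loss per cycle, pore lifetimes of tens of microseconds
(volume ejection at a 1 kPa Laplace pressure through a 5 µm pore is
fast), and quiescence after ~130 cycles. The experimental record shows
initial periods of tens of seconds, pore lifetimes of 0.3–1 s, and
quiescence after 60–120 min: the model reproduces the qualitative
structure — damped cycles, period fold-increases well above 3, partial
per-cycle solute loss, a final sub-lytic state — but compresses the
pore-open timescale, because the instantaneous-fixed-pore idealisation
omits the pore-growth and membrane-friction dynamics that hold real
pores open near the effusion time. Quantities that depend on the open
phase only through "how much solute left per cycle" are robust to
this; absolute pore lifetimes are not, and only their upper bound
(≤ 1 s) should be read as reproducing the observations.

## Phase state and the synthetic observable

`phase_state()` classifies the membrane as `UNIFORM` or `DOMAINS`. The
default is a tension threshold at $\sigma_{phase} = 0.5$ mN/m (inside
the mechanical crossover band): the reported tension-induced shift of
the miscibility temperature ($dT/d\sigma \approx -1$ K per mN/m,
`miscibility_shift()`) has the *wrong sign* to explain domain formation
in the tense state, so a combined pressure/tension mechanism without a
usable closed form must be at work; the threshold is the minimal model
that reproduces the observed synchronization (domains in the swollen
state, uniformity after each burst). The `temperature_shift` mode
implements the literal $dT/d\sigma$ mechanism for exploration.

`synthesize_trace()` emulates the imaging readout: homogeneity index
$h = 1$ (uniform) / $0$ (domains), causally smoothed over an optical
response time (default 0.2 s), sampled at `sample_dt` (default 0.1 s)
with up to 10% timing jitter, plus additive Gaussian noise clipped to
$[0,1]$, all deterministic in the seed. What it does *not* emulate:
spatial domain patterns, coarsening, photobleaching, or focus drift —
so recovery tests validate the period-extraction pipeline, not image
analysis. `extract_cycle_periods()` finds upward threshold crossings
(interpolated between samples, debounced over 1 s — the scale of the
fastest real transition) and `damping_summary()` reduces them to the
cycle count, period fold-increase, and quiescence time. Round-trip
recovery of the engine's periods holds within two sample intervals at
10% noise, and period estimates are threshold-invariant across
[0.3, 0.7] at 5% noise.

`recover_effusion_time()` fits $\log c$ versus $t$ by least squares;
the slope estimate is unbiased under multiplicative noise (the noise
enters the intercept), and the e-folding time follows with a
delta-method standard error.

## Problem sizes and numerics

Solver tolerances are `rtol = 1e-10`, `atol = 1e-24` (states of order
$10^{-15}$–$10^{-13}$), which keeps the solute balance
(interior + leaked = initial) below 1e-9 relative over a full run.
Each phase is integrated twice: once with a two-point grid to locate
the event root, then densely (default 120 rows/phase) for output.
The shipped tests exercise the canonical scenario over a 120 s horizon
(~14 cycles, under a second of CPU) and one long 2×10⁵ s horizon run
(~135 cycles, a few seconds) that reaches quiescence and the analytic
balance state; parameter-recovery checks use 200 replicates at 5%
noise. Degenerate inputs are first-class: isotonic configurations give
valid zero-cycle trajectories, closed pores give infinite effusion
times, non-decaying concentration samples are a graceful error.

## Limitations

Single vesicle, single pore, spatially unresolved membrane, no pore
growth or membrane viscosity, no daughter-vesicle expulsion, no
thermal noise in tension, ideal-solution osmotic pressure. The
temperature-shift phase mode and the threshold mode bracket an
unresolved mechanism; neither should be read as a validated phase
diagram.
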