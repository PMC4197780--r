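# swellburst

Mechanistic simulation and analysis of **swell–burst cycles** in giant
unilamellar vesicles (GUVs) under osmotic stress, for membrane
biophysicists studying vesicle osmoregulation, transient poration, and
tension-coupled lipid phase separation.

An osmolyte-loaded GUV in a hypotonic bath swells under the van't Hoff
pressure ΔP = RTΔc, builds membrane tension σ as undulations smooth out
and the area per lipid stretches,

    α(σ) = (k_B T / 8πκ) · ln(1 + c σ A₀ / κ) + σ/E ,   c = 1/24π,

ruptures through a micron-scale transient pore at a lytic tension
σ_lys, ejects volume through the pore under the Laplace pressure
2σ/R, loses solute diffusively with e-folding time

    τ = 4R⁴ / (3 r² D)

(≈ 0.5 s for R = 10 µm, r = 5 µm, D = 10⁻⁹ m²/s), reseals, and
repeats with ever-longer periods until the residual osmotic pressure is
balanced by a sub-lytic Laplace tension. The package provides:

* the static **membrane mechanics** (Laplace coupling, dilation law and
  its inverse, pore energetics, critical pore radius) and **transport
  laws** (van't Hoff pressure, osmotic water flux, pore effusion,
  Sampson outflow) as plain vectorised functions;
* an event-driven **swell–burst engine**, `simulate_vesicle()`, with
  root-located pore opening/closure, per-cycle records, and quiescence
  detection;
* a tension-coupled **phase-state indicator**
  (uniform ↔ liquid-ordered/disordered domains);
* a **synthetic fluorescence-homogeneity observable** and analyses that
  recover cycle periods, damping, and effusion times
  (`synthesize_trace()`, `extract_cycle_periods()`,
  `damping_summary()`, `recover_effusion_time()`);
* config-file I/O, a pipeline driver (`run_pipeline()`), and a thin
  command-line wrapper (`inst/cli/swellburst.R`).

## Worked example

```r
library(swellburst)

vant_hoff_pressure(200, 298.15)   # 495791.4 Pa  (~0.5 MPa for 200 mM)
laplace_tension(0.5e6, 10e-6)     # 2.5 N/m
effusion_time(10e-6, 5e-6, 1e-9)  # 0.5333333 s

cfg <- sim_config(t_max = 600)    # 10 um GUV, 200 mM sucrose, water bath
sim <- simulate_vesicle(cfg)
sim
#> Swell-burst trajectory
#>   scenario: R_init 10 um, 200 mM in / 0 mM out
#>   simulated 600 s; 41 pore events, 40 completed cycles
#>   horizon reached before quiescence
#>   periods 5.11 -> 29.7 s (5.8-fold)

head(sim$cycles[, c("index", "period", "pore_lifetime",
                    "solute_lost_fraction")], 3)
#>   index   period pore_lifetime solute_lost_fraction
#> 1     1 5.114023  3.027689e-05           0.04398163
#> 2     2 5.349552  3.027687e-05           0.04398162
#> 3     3 5.595942  3.027684e-05           0.04398161

trace   <- synthesize_trace(sim, sample_dt = 0.1, noise_sd = 0.1, seed = 1)
periods <- extract_cycle_periods(trace)
damping_summary(periods, trace)
#> Damping summary: 40 cycles, periods 5.06 -> 29.6 s (5.9-fold)
```

Each burst loses ~4.4% of the remaining solute, so swell phases
lengthen by ~5% per cycle — the damped-oscillation signature. The
noisy synthetic trace recovers the engine's periods to within two
sample intervals. A long-horizon run (`t_max = 2e5`) reaches the
quiescent state after ~135 cycles and relaxes onto the analytic
osmotic/Laplace balance of `equilibrium_state()`. `plot(sim)` shows
tension, interior concentration, and radius versus time.

See `vignette("swell-burst-model")` for the model, its assumptions,
and the design decisions (pore closure accounting, convective solute
carriage, phase-state modes), and `?sim_config` for every tunable
parameter.

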