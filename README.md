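# brinesim

Mass-transfer analysis for wet (immersion) curing of muscle-tissue slabs:
salt/water exchange kinetics, effective NaCl diffusivity estimation from
Fick's second law, empirical time-variant concentration models, and a
finite-difference transient diffusion simulator for the slab geometry.
Written for food-process engineers and researchers studying brine curing —
in particular xylitol-mediated low-salt curing, where a polyol additive
slows NaCl transport into the tissue.

The emulated experiment: 30 × 30 × 10 mm pork slabs in 8% (w/w) NaCl brine
(meat:brine 1:4 w/w) with 0/4/8/12% (w/w) xylitol, sampled in triplicate
every 2 h over 24 h; one-way (single exposed face) samples sectioned into
2 mm slices along the diffusion axis. A synthetic-data generator reproduces
this design from known ground-truth parameters, so every estimator can be
validated by round trip.

## What it computes

- **Composition**: aqueous-phase salt content `Z = Xs/(Xw+Xs)`, the
  two-phase equilibrium balance `Ze`, and the driving-force complement
  `1 − Y(t) = 1 − (z_t − y_t)/(z_0 − z_e)`.
- **Kinetics**: the square-root law `y(t) = 1 + ΔM/100 = k1 + k2·√t`
  fitted per change variable (total weight, moisture, salt).
- **Time-variant models** for `Z(t)`: linear `At + b`, power `A·t^b + c`,
  exponential `A(1 − e^(−bt))`, with R²-based ranking and an optional
  shared-exponent joint power fit across groups.
- **Effective diffusivity** (m²·s⁻¹):
  - slope method, `1 − Y = (2/L)·√(De·t/π) + K`, so `De = π(sL/2)²`;
  - erf-profile inversion of the semi-infinite solution
    `(Cs − C)/(Cs − C0) = erf(x / 2√(De·t))` per 2 mm slice;
  - a model-implied De composing a fitted `Z(t)` with the slope method;
  - a sliding-window variant tracing the drift of apparent De over curing.
- **Simulation**: Crank–Nicolson (1D) and Douglas ADI (3D) solvers for
  constant-De Fickian diffusion on the slab, with Dirichlet (brine-contact)
  and zero-flux (sealed) faces, penetration depth, slice averaging,
  simulated-vs-observed profile error, and CSV/legacy-VTK field export.

## Worked example

```r
library(brinesim)

cfg <- run_config(groups = c("0%", "12%"), sim_group = "0%", seed = 1)
s <- run_pipeline(cfg, quiet = TRUE)

unlist(s$groups[["0%"]]$kinetics$salt[c("k1", "k2", "r2")])
#>          k1          k2          r2
#> 0.995372688 0.009230571 0.977383896

sapply(s$groups, function(g) g$de$erf_profile$de)
#>           0%          12%
#> 1.228939e-09 1.135391e-09

s$simulation$penetration_depth_m
#> [1] 0.01

s$validation
#>   time_h error_pct flagged
#> 1     12  1.200469   FALSE
```

Reading: with 2% measurement noise the salt-uptake kinetic fit for the 0%
group lands near its generating parameters (k2 ≈ 0.0092 h⁻⁰·⁵ vs a true
0.010715), the erf-profile estimator recovers each group's one-way
diffusivity to within a few percent (true 1.29e-9 and 1.15e-9 m²·s⁻¹),
12 h of one-face curing penetrates the full 10 mm slab at the 1%
threshold, and the simulated 12-h slice profile differs from the noisy
synthetic observations by ~1.2% on average. At `noise_sd = 0` the erf
round trip is exact:

```r
gt <- curing_ground_truth("0%", noise_sd = 0, seed = 1)
p  <- generate_slice_profiles(gt, times = 12)[[1]]
erf_profile_method(p, cs = 0.08, c0 = gt$meat0$salt_frac)
#> De = 1.29e-09 m^2 s^-1 (erf_profile method, n = 5)
```

A thin command-line front end over the same functions lives at
`inst/cli/brinesim.R` (subcommands `run-all`, `simulate-data`,
`fit-kinetics`, `fit-models`, `estimate-de`, `simulate-3d`, `validate`).

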