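# myelinpet

An in-silico feasibility study of PET imaging of multiple-sclerosis (MS)
lesions with a myelin-targeted radiotracer, written for imaging
scientists and pharmacokinetic modelers who want to explore when a
myelin-basic-protein (MBP) binding agent could make demyelinated lesions
visible on PET.

MS lesions are *cold spots*: MBP is ~7–8× more concentrated in white
matter than gray matter, and lesions lose 10–100× of it. The package
therefore scores a signal **deficit** with a negative-contrast
signal-to-noise ratio,

```
SNR = (μ_BGR − μ_LES) / σ_BGR
```

where μ_BGR and σ_BGR are the mean and standard deviation of the
lesion-free image over the lesion ROI and μ_LES the mean of the paired
lesion-bearing image over the same pixels. A region is called imageable
for SNR ≥ 2, possibly imageable for 1 ≤ SNR < 2, and not imageable
below 1.

The simulation chain, each stage a package module:

1. **composition** — tissue water/protein data → molar MBP
   concentrations per compartment.
2. **binding** — exact single-site equilibrium: the bound fraction
   solves `LT² − (T+L+Kd)·LT + T·L = 0` (stable quadratic root); at
   `T/Kd ≈ 10⁵` binding saturates, which is why stronger binders do
   *not* image lesions better.
3. **pbpk** — a 12-state whole-body ODE model (deSolve): bolus → plasma,
   flow-limited organs with lipophilicity-derived partitioning,
   permeability-limited brain block with mass-action MBP binding,
   nonspecific protein binding, hepatic + renal clearance.
4. **phantom** — a synthetic voxel head phantom (white/gray matter,
   ventricles, deep nuclei) with spherical lesions at the published
   coordinates, plus a calibrated MS lesion-size sampler (20/60/20%
   below 3.5 / in 3.5–9 / above 9 mm).
5. **petsim** — 2D parallel-beam projector with attenuation, 4 mm
   resolution blur, decay-weighted Poisson counts, 15% scatter, and
   quantitative filtered back-projection.
6. **roi_analysis** — lesion ROI from a lesion-only reconstruction
   (cutoff at 25% of peak height), negative-contrast SNR, feasibility
   classes, ROI-inflation experiment.
7. **sensitivity** — one-at-a-time sensitivity coefficients, logP sweep,
   500-run Monte-Carlo Kd × lesion-MBP sweep.

## Worked example

```r
library(myelinpet)

# 1. Target concentrations from tissue composition
comps <- brain_compositions()
sapply(comps, molar_target_concentration)
#> white_matter  gray_matter       lesion
#> 1.015260e-03 1.345135e-04 3.610716e-04

# 2. Why affinity does not help: bound ligand fraction at target excess
equilibrium_bound_fraction(1e5 * 1e-6, 1e-6, 1e-6)
#> [1] 0.99999    # ~100% bound; a 10x target drop changes this by ~9e-05

# 3. Biodistribution at micromolar affinity, 100-fold demyelination
phys  <- physiology_model(comps,
           lesion_target_M = scaled_lesion_concentration(1.01526e-3, 100))
agent <- agent_properties(binding = binding_params(kd = 1e-6, kon = 5.5e5))
tac   <- simulate_biodistribution(phys, agent)
concentration_ratio(tac, "white_matter", "lesion", t = 7200)
#> [1] 33.2      # lesion washes out; at kd = 1e-9 this ratio is ~1.04

# 4. Image it: 8 mm lesion inside white matter, 20-min scan
vol  <- generate_head_phantom(dim = c(160, 160, 80), seed = 1)
spec <- lesion_spec(c(69, 65, 28), 8, "interior_wm")
conc <- c(white_matter = 1.00e-10, gray_matter = 3.38e-11,
          lesion = 3.03e-12, other = 1.67e-11)   # 2 h concentrations
expt <- lesion_snr_experiment(vol, spec, conc, acquisition_params(),
                              seeds = 1:10, calibrate_counts = 1e6)
mean(expt$snr)
#> [1] 2.62      # "feasible": SNR >= 2
```

The numbers mean: lesion MBP concentrations derived from composition
data land exactly on the published table; binding is saturated so
contrast must come from kinetics; a micromolar tracer gives a 33-fold
2 h concentration ratio for a strongly demyelinated lesion; and the
full imaging chain turns that into SNR ≈ 2.6 for an 8 mm interior
lesion — imageable.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study's experiments and
write tables (and figures, if ggplot2 is present) under `results/`:

| script | experiment |
|---|---|
| `01_composition.R` | composition table, white/gray MBP ratio |
| `02_binding_curves.R` | saturation curves vs target/Kd |
| `03_biodistribution.R` | time–activity curves for 4 affinity × demyelination scenarios |
| `04_sensitivity.R` | sensitivity coefficients, logP sweep, 500-run Monte-Carlo sweep |
| `05_acquisition_time.R` | 10- vs 20-min scan SNR comparison (100 paired replicates) |
| `06_feasibility_grid.R` | full 32-condition SNR/feasibility grid + ROI inflation |

Run them from the repository root, e.g.
`Rscript analysis/06_feasibility_grid.R`.

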