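---
title: "Methods: simulating PET imageability of demyelinated brain lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating PET imageability of demyelinated brain lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`myelinpet` asks a quantitative feasibility question: could a small,
lipophilic PET tracer that binds myelin basic protein (MBP) make
multiple-sclerosis lesions visible as *cold spots* inside hot,
myelin-rich white matter? The package chains four models — tissue
composition, receptor–ligand binding, whole-body pharmacokinetics, and
PET image formation — into a scored detectability grid. This vignette
documents each model, its assumptions, the tunable parameters, and the
design decisions taken where the problem was genuinely open.

## 1. Tissue composition and target concentration

White matter, gray matter and lesion tissue are described by their water
fraction of wet weight, total protein fraction of dry weight, and MBP
content per gram of total protein. Two derivations connect these inputs
to the PBPK model:

* protein wet fraction = protein dry fraction × (1 − water fraction),
* molar MBP concentration = (MBP mg/g protein × protein wet fraction ×
  density) / MW.

Both are exact arithmetic; the test suite checks them cell-by-cell
against the published composition table. Two conventions matter:

* **Density 1 g/mL.** Converting mg per g wet tissue into mg/mL needs a
  density; the published table is only internally consistent at
  1 g/mL. It is the default and can be overridden per compartment.
* **MBP molecular weight 18.5 kDa** (major human isoform). Isoforms span
  17.2–21 kDa; `target_mw` is exposed for that range.

All internal values are fractions and mol/L; percentages appear only in
the exported table. The derived white/gray molar ratio (≈7.5) falls in
the literature band of 7–8, which is the entire physical premise of
myelin-targeted imaging. Demyelination scenarios divide the *white
matter* concentration by a fold factor (10 or 100 in the core grid),
spanning the published lesion concentration range.

## 2. Saturable binding

Single-site equilibrium binding is solved exactly: the bound complex
concentration is the root of `LT² − (T + L + Kd)·LT + T·L = 0` that does
not exceed `min(T, L)`, evaluated as `2TL / (b + sqrt(b² − 4TL))` with
`b = T + L + Kd`. This form avoids the catastrophic cancellation of the
textbook quadratic formula when `T/Kd` spans nine orders of magnitude,
which it does here (`T/Kd` up to 10⁶). A bisection oracle on the
mass-action balance verifies the root to 10⁻¹⁰ relative error.

The binding curves explain the study's least intuitive finding. At
`T/Kd = 10⁴–10⁵` essentially *all* ligand is bound, so a 10-fold drop in
target concentration changes the bound fraction by ~10⁻⁴: a nanomolar
binder cannot distinguish lesion from white matter by equilibrium
binding alone. `koff` is always derived as `kon × Kd`, so affinity and
on-rate are the only free binding parameters.

## 3. The PBPK model

The proprietary whole-body simulator behind the original study is not
available, so the package implements its own reduced compartmental model
that expresses the same mechanisms: delivery, competition between
binding and washout, partitioning, and biliary/renal clearance. The
state is amounts (mol) in twelve compartments:

* plasma (3 L), with an intravenous bolus at t = 0;
* liver (1.8 L), kidney (0.31 L), rest-of-body (36 L): flow-limited,
  `dA/dt = Q (fu_p·C_pl − C_t/Kp_t)` with the free plasma fraction
  `fu_p = 1 − PPB` and partition coefficient
  `Kp = 1 + (1 − water fraction) × 10^logP × s` (calibration constant
  `s = 2 × 10⁻³`, giving Kp ≈ 6–8 for soft tissue at logP 4);
* brain extracellular fluid (15% of a 1.4 kg brain), exchanging with
  plasma through a blood–brain-barrier conductance in series with brain
  plasma flow (0.75 L/min);
* white matter / gray matter / lesion cellular spaces (42/56/2% of the
  remaining brain mass), each holding a free+nonspecifically-bound pool
  and a specifically bound pool.

Specific binding is dynamic mass action against the compartment's MBP
concentration (`kon`, `koff`, saturable in the target). Nonspecific
binding to bulk tissue protein (Kd 10⁻³ M, protein expressed in molar
units of a 50 kDa reference protein) is treated as an instantaneous
linear equilibrium, since at tracer doses it is far from saturation.
Hepatic clearance scales microsomal intrinsic clearance by 45 mg
microsomal protein/g liver × 1800 g liver; renal clearance removes the
free plasma fraction at GFR (0.12 L/min). The lesion is perfused like
white matter, consistent with the maintained vascular component of MS
plaques.

**Lipophilicity and membrane permeability.** The partition coefficient
`Kp(logP)` applies to the flow-limited peripheral tissues. Inside the
brain, lipophilicity instead scales the membrane permeabilities (BBB and
cellular PS) as `10^(0.35·(logP − 4))`. This is the package's own design
choice, and it is what produces the observed logP behaviour: a more
lipophilic agent is delivered to, and equilibrates with, brain tissue
faster. White matter remains binding-trapped over the 2 h window
regardless, while a demyelinated lesion approaches equilibrium with the
falling extracellular concentration and washes out — so the 2 h
white-matter/lesion ratio *rises* with logP, falls with lesion target
concentration, and rises with Kd, reproducing all published directional
findings. The same washout picture explains why nanomolar affinity makes
the white-matter and lesion time–activity curves coincide (both trapped)
while micromolar affinity separates them, increasingly with
demyelination.

Numerics: `deSolve::lsoda` with `rtol = 10⁻⁸` and an absolute tolerance
of 10⁻¹² times the dose scale; output every 120 s over 3 h. Binding
rates (up to `kon·T ≈ 550 s⁻¹`) make the system stiff. The formulation
conserves mass by construction; the suite asserts conservation to 10⁻⁶
relative (compartments + cumulative cleared = dose) at every output
time. Magnitudes of the published sensitivity coefficients are *not*
reproduced — they belong to a different internal model — only their
signs and dominance ordering, which the acceptance suite checks.

## 4. The head phantom

A synthetic stand-in emulates the published voxel head phantom on a
256 × 256 × 128 reference grid (1.1 mm voxels by default, both
configurable; smaller grids rescale the same geometry). It has an
ellipsoidal head (label 1), a brain with cortical gray-matter shell
(label 2), white-matter interior (label 3) with ventricle voids, and
deep gray-matter nuclei. The cortical boundary radius carries a small
seeded angular ripple, so phantoms are deterministic per seed without
being perfectly smooth.

The published lesion coordinates are honored by construction: the four
border-class sites lie on the surfaces of deep gray nuclei (each nucleus
is a sphere whose surface passes through the site), and the four
interior sites are verified to sit in pure white matter. The white/gray
voxel split lands within ±15% of the 42/56 brain mass split. Lesions
are spheres that relabel only white- or gray-matter voxels — never
background, ventricles or skull — so insertion is a pure relabeling and
disjoint insertions commute.

Lesion diameters, where sampled, come from a log-normal calibrated to
the published MS lesion-size survey: 20% below 3.5 mm and 20% above
9 mm (`meanlog = (ln 3.5 + ln 9)/2`, `sdlog` from the 80% quantile). The
two-parameter family is the package's choice — the survey gives only
three bin masses — and the middle-bin mass (60%) follows and is checked
empirically.

## 5. PET acquisition and reconstruction

Image formation is a 2D parallel-beam analytical simulator applied to
the transverse slice through each lesion center (the analysis surface of
the study is single slices):

1. **Forward projection**: line integrals of activity (bilinear
   sampling, 96 angles over [0, π), bins at the pixel pitch), multiplied
   by the full-chord attenuation factor `exp(−∫μ dl)` (both annihilation
   photons must escape; μ = 0.0096 mm⁻¹ water-equivalent inside the
   head), then blurred by a 4 mm FWHM Gaussian in projection space
   representing system resolution.
2. **Count scaling**: expected counts = sensitivity × injected dose
   (10 mCi) × positron yield (0.97) × the decay integral over the scan
   window (half-life 6588 s, 2 h delay, 20 min scan). The sensitivity
   constant is calibrated so a lesion-free brain slice collects 10⁶ true
   counts in a 20-min scan — a realistic per-slice count level; absolute
   published SNR values depend on an unrecoverable scanner calibration,
   so scaling laws, not absolute SNRs, are the test surface.
3. **Scatter and noise**: scattered+random events are a uniform additive
   background of `sf/(1 − sf)` times the trues (sf = 0.15), and every
   bin draws an independent Poisson count, deterministically per seed.
4. **Reconstruction**: scatter subtraction, attenuation correction,
   division by the count scale, then filtered back-projection with a
   Hann-apodized ramp filter. The normalization is verified by
   round-trip: a uniform disk reconstructs to its true activity level
   within 5%.

Paired runs (lesion-free / lesion-bearing) share one noise seed per
replicate, because the SNR statistic reads its background statistics off
the lesion-free member of the pair; the lesion-only run used for ROI
definition is reconstructed without noise.

## 6. ROI definition and the negative-contrast SNR

Lesions are *signal deficits*, so the usual hot-spot SNR is replaced by
`SNR = (μ_BGR − μ_LES) / σ_BGR`. The ROI comes from the lesion-only
image: threshold at `baseline + (max − baseline)/4` (baseline = mean
over the entire image, including outside the head — the published
definition), strict-above thresholding, 8-connected components, nearest
known lesion center. The published cutoff formula can be read two ways
(`(max − baseline)/4` absolute, or 25% of peak height above baseline);
they nearly coincide because the lesion-only baseline is close to zero,
and the 25%-of-height reading is implemented.

`μ_BGR` and `σ_BGR` are computed over the ROI pixels of the lesion-free
image and `μ_LES` over the same pixels of the lesion image. Restricting
σ to the ROI (rather than whole white matter) keeps the statistic
location-specific and consistent with the ROI-restricted mean; the
sample (n−1) standard deviation is used — the difference is negligible
at ROI sizes ≥ 12 px but must be fixed for reproducibility. Feasibility
classes: SNR < 1 not imageable, 1 ≤ SNR < 2 maybe, SNR ≥ 2 imageable
(boundaries inclusive upwards); an alternative lower threshold of 1.3 is
supported.

The delineation-error experiment grows the ROI by whole 8-neighbor
dilation rings and trims the farthest-from-centroid pixels of the last
ring (ties by scan order) to hit exactly 1.5× the original area; SNR
must strictly decrease at every grid point, which the suite checks.

## 7. Sensitivity analysis and sweeps

One-at-a-time sensitivity coefficients are
`SC = (ΔY/Y) / (ΔX/X)` of the 2 h white- and gray-matter/lesion ratios.
The relative input changes are read off the perturbed parameter values
themselves (PPB 10→20% ⇒ ΔX = 1.0; clearance 8→8.8 ⇒ 0.1; logP 4→5
treated as 0.25 on the raw value; lesion target 3.61→5.42 × 10⁻⁴ ⇒
≈0.5; Kd 1→2 × 10⁻⁶ ⇒ 1.0; kon 5.5→10 × 10⁵ ⇒ ≈0.818). The Monte-Carlo
sweep samples Kd log-uniformly over 10⁻⁹–10⁻⁶ M and the lesion
concentration uniformly over 10⁻⁴–9 × 10⁻⁴ M (the sampling measures are
not specified in the source material; log-uniform is the natural choice
for a parameter explored across decades), 500 runs by default, ratio
evaluated at exactly 2 h.

## 8. Problem sizes and determinism

The analysis scripts and acceptance checks run the imaging chain on a
160 × 160 × 80 phantom (1.76 mm voxels) with 96 projection angles and
8–100 noise replicates per condition; the 256-grid geometry is verified
separately. These sizes were chosen so a reconstructed slice still
resolves a 4 mm lesion under the 4 mm system blur while a full
32-condition grid remains a desk-scale computation. Every stochastic
step (phantom ripple, diameter sampling, Poisson noise, Monte-Carlo
sweeps) takes an explicit integer seed and is reproducible bit-for-bit.

## 9. What the synthetic data does and does not emulate

The generator reproduces the *structural* conditions of the study —
compartment concentrations, lesion sizes/placements, count statistics,
scatter level, resolution — but not: anatomical gyral detail or
partial-volume mixtures at tissue boundaries; within-lesion
heterogeneity of myelin loss (each compartment is uniform); scanner
geometry, detector normalization, randoms estimation or dead time; 3D
reconstruction; patient motion. Passing tests therefore support the
*relative* claims (scaling with acquisition time, ordering across
diameters, placements, affinities and demyelination levels) rather than
absolute clinical detectability. The published absolute SNR values
(e.g. 1.01 vs 0.61) are matched in order of magnitude only; the
corresponding check asserts the √duration scaling law.

## 10. Known limitations

* The PBPK model has no metabolites, no inter-individual variability,
  and a single lumped plasma pool; its sensitivity-coefficient
  magnitudes are model-specific.
* The permeability–lipophilicity exponent (0.35 per logP unit) is a
  plausible but uncalibrated constant; only the direction and convexity
  of the logP response are asserted.
* Scatter is spatially uniform; real scatter has structure that would
  slightly bias μ_BGR.
* The FBP chain assumes exact knowledge of attenuation and scatter —
  an idealized correction.
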