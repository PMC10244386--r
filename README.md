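# pvsnet

Perivascular network segmentation and transport analysis for
high-resolution 3D MR volumes of the brain.

Perivascular spaces (PVS) are slender fluid sheaths around cerebral blood
vessels that exchange solutes between cerebrospinal fluid (CSF) and brain
tissue, and are central to proposed waste-clearance ("glymphatic")
mechanisms. In contrast-enhanced, high-field ex vivo MRI (40 μm isotropic
voxels), tracer-filled PVS appear as bright near-voxel-width tubes.
`pvsnet` provides the full analysis chain for such data, exercised on
synthetic phantoms with known ground truth:

- **Phantoms** — brain-shaped volumes with ventricles, tubular PVS,
  bias field, and noise, plus matched unenhanced controls
  (`generate_phantom`, `generate_naive`).
- **Projections** — partial and shifting maximum intensity projections
  through 30-slice slabs (`partial_mip`, `shifting_mip`).
- **Segmentation** — Hessian-eigenvalue tubeness
  `T = sqrt(λ₂ λ₃)` (for `λ₂, λ₃ < 0`, eigenvalues sorted
  `λ₁ ≥ λ₂ ≥ λ₃`), with per-region thresholds calibrated as the mean
  0.95-quantile of tubeness in naive controls after histogram-peak
  alignment (`compute_tubeness`, `calibrate_threshold`, `segment_pvs`).
- **Connectivity** — region growing from the 3-voxel-dilated ventricle
  compartment through the PVS mask, and centroid-chain segment lengths
  (`extract_periventricular_network`, `measure_segment_length`).
- **Clearance** — exact anisotropic Euclidean distance transform giving
  the minimum clearance distance `L` from parenchyma to the nearest CSF
  compartment, with/without PVS counted as CSF, and time scales
  `τ_d = L²/D*` and `τ_a = L/u` (`distance_to_csf`, `diffusive_time`,
  `advective_time`), plus voxel-averaging and fixation-shrinkage
  corrections.
- **Dispersion** — closed-form oscillatory (Taylor) dispersion in a
  semi-infinite perivascular channel: `α = 1 − erf(x/√(4kDt))`, front
  position `x = 2√(kD)·erf⁻¹(1−α)·√t` and velocity `v = x/(2t)`
  (`concentration_profile`, `front_position`, `front_velocity`,
  `traversal_time`).

## Worked example

Transport models (closed form):

```r
library(pvsnet)

albumin <- dispersion_params(D = 83, k = 1.05)   # um^2/s; modest enhancement
format_duration(traversal_time(250, 0.5, albumin))
#> [1] "13.1 min"
front_velocity(0.1, c(10, 100), albumin)         # um/s at t = 10 s and 100 s
#> [1] 3.433570 1.085790
format_duration(diffusive_time(c(0.784, 0.169), 62.3))
#> [1] "2.74 h"   "7.64 min"
```

The half-concentration albumin front needs ~13 minutes to cross a 250 μm
perivascular segment by dispersion alone, and its velocity decays from
3.4 to 1.1 μm/s between 10 s and 100 s — an order of magnitude below
observed perivascular advection (~19 μm/s). The diffusive clearance time
scale for amyloid-beta (`D* = 62.3 μm²/s`) drops from 2.74 h to under
8 min when the PVS network (mean clearance distance 0.784 → 0.169 mm) is
counted as CSF.

Full pipeline on the default seeded phantom:

```r
man <- run_pipeline(list(seed = 1))
round(man$clearance$mcd_mean_mm, 3)
#> without_pvs    with_pvs
#>       0.235       0.110
format_duration(man$clearance$tau_d_s)
#> [1] "14.8 min" "3.23 min"
round(man$clearance$fold_reduction, 1)
#> [1] 4.6
man$network$captured_tube        # periventricular-connected tubes (segmentation)
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE FALSE
```

On the phantom, counting segmented PVS as CSF halves the mean clearance
distance and cuts the diffusive time scale 4.6-fold (the square of the
distance ratio). The manifest also records the calibrated thresholds,
the intensity scale factor, and segmentation Dice against ground truth
(whole-brain and brain-interior). Note that on the noisy segmentation
the region grow can reach tubes the ground truth marks as isolated via
chance voxel bridges; the same analysis on the ground-truth masks
recovers the declared connectivity exactly (see the test suite).

See `vignettes/perivascular-transport-methods.Rmd` for the models,
parameter choices, and known limitations.

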