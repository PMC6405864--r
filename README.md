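# fibriltrace

Quantitative, segmentation-free analysis of cellulose elementary-fibril
(EF) geometry in electron tomograms of the wood cell wall — aimed at
thin, densely packed regions such as the S1–2 transition layer, where
fibrils a few nanometres thick cannot be traced by manual segmentation.

Instead of labelling voxels, `fibriltrace` fits each fibril centerline
with a parametric space curve

    C(t) = ( a·cos(ωt + φ) + Σ cᵢ tⁱ,   a·sin(ωt + φ) + Σ dᵢ tⁱ,   t )

— a helicoidal term plus a polynomial deviation — directly to the
tomographic density, by minimising a tube-weighted negative mean
density with a particle-swarm optimizer refined by a Nelder–Mead
simplex. Fibrils are extracted iteratively (fit, soft-mask, re-seed)
until the density no longer supports another curve. From the fitted
curve set the package computes the field's standard descriptors:

* nearest-neighbour distances d_NN between curves (two functionals:
  symmetric mean-of-minima for lattice spacing, closest approach for
  crossings/contacts),
* orientation angles against the anatomical directions of the cell
  wall — signed angle to the tangential plane, angle to the
  longitudinal axis (with circular statistics where needed),
* bundle membership (sustained proximity below a contact threshold,
  connected components) and the bundled fraction,
* spatial grid maps of angles and spacings over the tomogram plane,

plus volume I/O (MRC2014 / TIFF stacks), Gaussian denoising, middle-slab
cropping, subvolume grids and rigid re-alignment. Because no tomograms
are publicly deposited for this system, the package ships a synthetic
phantom generator (soft tubes, seeded noise, single-axis missing-wedge
anisotropy) whose ground-truth curves double as the oracle for every
recovery test.

## Worked example

Generate the "crossed" demonstration scene (two fibril families
perpendicular to the longitudinal axis, tilted +45° and −45° out of the
tangential plane, crossing at near-contact distance), run the full
pipeline on it, and look at the recovered descriptors:

```r
library(fibriltrace)

cfgs <- demo_scenarios(out_dir = "demo_runs", seed = 3)
res  <- run_pipeline(cfgs$crossed)
res$metrics
#> <fibril_metrics> 8 curves | mean nn 10.13 nm | median tangential +0.1 deg (|.| 44.4) | bundled 0.0%
res$recovery$n_matched
#> [1] 8
```

Reading the numbers: all 8 planted fibrils were recovered (no misses,
no spurious fits). The mean nearest-neighbour distance of 10.13 nm
recovers the planted 10 nm within-family lattice spacing; the median
tangential-angle magnitude of 44.4° recovers the planted ±45° crossing
(the signed median is ~0° because the two families tilt in opposite
directions); and no bundles are reported, because crossing contacts are
momentary rather than sustained. The run directory contains the scene
volume (`scene.mrc`), ground truth and fits as JSON, per-curve metrics
as CSV, and a manifest with content hashes; the same config and seed
reproduce byte-identical numeric outputs.

The same functions work on real data:

```r
v  <- read_volume("tomogram.mrc")              # voxel size from header
v  <- gaussian_denoise(v, sigma_nm = 1.0)
fits <- fit_all(v, fit_config(fit_axis = "T"))
m  <- compute_metrics(lapply(fits, `[[`, "curve"), axes = v$axes)
```

A thin CLI wrapper lives at `inst/scripts/fibriltrace.R`
(`Rscript fibriltrace.R demo --scenario bundled --out run/`).

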