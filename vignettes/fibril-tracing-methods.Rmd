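---
title: "Model-based fibril tracing in tomographic volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based fibril tracing in tomographic volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cellulose elementary fibrils (EFs) in the wood secondary cell wall are a
few nanometres thick and densely embedded in a hemicellulose/lignin
matrix. In electron tomograms of thin sections — particularly of the
narrow S1–2 transition layer, where the fibril winding direction
reverses — the fibrils are visible as tube-like high-density tracks, but
their tight packing defeats manual segmentation. `fibriltrace`
implements a segmentation-free alternative: each fibril centerline is a
*parametric space curve* fitted directly to the tomographic density by
global optimization, and all quantitative structure descriptors
(spacings, angles, bundling, spatial maps) are computed on the fitted
curves rather than on voxels.

# The centerline model

In a local frame whose $z$ axis runs roughly along the fibril, a
centerline is

$$
C(t) \;=\; \Big(a\cos(\omega t + \varphi) + \textstyle\sum_i c_i t^i,\;\;
               a\sin(\omega t + \varphi) + \textstyle\sum_i d_i t^i,\;\; t\Big),
\qquad t \in [t_0, t_1],
$$

a *helicoidal* term (radius $a$ in nm, angular rate $\omega$ in rad/nm,
phase $\varphi$) plus *polynomial* deviations in $x$ and $y$ that absorb
departures from a perfect helix. A rigid pose (rotation + translation)
places the local frame in the volume. With $a = 0$ and zero polynomial
coefficients the curve degenerates to a straight segment, and every
geometric quantity (tangent, arclength, inter-curve distance) has a
closed form the implementation is tested against.

Two deliberate choices:

* **Parameterization by local $z$, not arclength.** This keeps
  evaluation closed-form and matches the "helix about an axis"
  construction; statistics that need arclength use Simpson quadrature
  (`curve_length()`, refinement-stable to $10^{-4}$ relative).
* **Low polynomial degree** (default 2, configurable 1–5), so the
  polynomial cannot imitate the helix and the two terms stay
  identifiable.

# Fitting

## Cost function

The cost of a candidate curve is the *negative tube-weighted mean
density* along it: the curve is sampled at `n_cost_samples` points
(default 48); each sample is averaged with its four neighbours on a ring
of radius `tube_sigma_nm` (default 1.2 nm) in the plane normal to the
local tangent, with Gaussian weights; samples falling outside the volume
contribute the volume's median density, so a curve is never rewarded for
escaping the box. The cost is linear in the intensities (doubling the
volume doubles the cost magnitude), deterministic, and minimized when
the curve runs along the centre of a dense tube. This functional is this
package's own design, validated by the recovery experiments below; it is
intentionally simple, bounded and scale-equivariant.

## Optimization

Minimization follows the classical two-stage scheme for this problem:

1. **Particle swarm** over a bounded parameter box (constriction
   weights: inertia 0.7298, cognitive = social = 1.49618; default 24
   particles, 40 iterations). Particles are initialized around a seed
   curve; one particle *is* the seed. All randomness flows from one
   seeded generator, so runs are bit-reproducible.
2. **Nelder–Mead simplex** refinement of the swarm's best vertex
   (`stats::optim`), with parameters clamped to the box inside the
   objective.

The returned fit satisfies, on every run: final cost ≤ swarm cost ≤
best initial particle cost, and the recorded best-so-far history is
non-increasing. The helix term is *off by default* during fitting
(`fit_helix = FALSE`): for nearly straight fibrils a degenerate helix
($a \to 0$) leaves $\omega$ and $\varphi$ unidentifiable and only adds
noise dimensions. With the term enabled and sensible $\omega$ bounds the
optimizer recovers planted helices (radius and angular rate within a few
percent; see the test suite).

## Seeding

Seeds are straight lines traced through local density maxima: slices
perpendicular to the fit axis are lightly smoothed, strict 8-neighbour
maxima above a robust threshold are detected, and maxima are linked
across slices by nearest-neighbour tracking (with a constant-velocity
prediction and a slope-limited link radius) starting from the middle
slice. Tracks covering at least half the slices are least-squares fitted
with lines, ranked by mean density along the seed, and de-duplicated. A
featureless volume yields no seeds — and downstream, an empty fit list.

## Multi-fibril extraction

`fit_all()` peels fibrils greedily: fit the best seed, accept the fit if
its cost improvement over the background level exceeds
`accept_threshold` (default 3) times the volume's robust noise scale
(MAD-based, floored at 2% of the intensity range), softly suppress the
accepted fibril's density with a raised-cosine mask of radius
`mask_radius_nm`, re-seed, repeat. Accepted fits are guaranteed mutually
non-duplicate (pairwise mean distance above half the mask radius).
Sequential peeling — rather than joint optimization of all fibrils — is
a deliberate simplification; on phantoms at the densities studied here
it recovers every planted fibril exactly once.

# Descriptors

All metrics operate on curve sets (fitted or ground truth), under the
anatomical axis tags carried by each volume: **L** (longitudinal, along
the fibre), **T** (tangential) and **N** (normal/radial; the
thin-section and beam direction).

* **Pair distances.** Both curves are sampled at ≤ `sampling_nm` arc
  spacing (panel counts rounded to powers of two, so refinement nests
  and the sampled minimum is monotone). Two functionals are reported:
  the *symmetric mean of per-sample minima* — robust for nearly
  parallel fibrils with partial overlap, and the statistic behind the
  lattice-spacing numbers — and the *plain minimum* (polished by a
  local 2-D Nelder–Mead over both curve parameters), under which
  crossing fibrils read as near-contact. The historical "average
  nearest-neighbour distance" could be either a mean over curves or
  over pairs; summaries emit both (`mean_nn_distance_nm`,
  `mean_nn_distance_pairs_nm`), asserting neither as canonical.
* **Angles.** Each curve's mean unit tangent is canonicalized (largest
  component positive — a centerline has no intrinsic direction) and
  compared with the tangential plane (signed angle; sign = side of the
  plane), the transverse plane, and the longitudinal axis (angle in
  [0°, 180°), so a fibril perpendicular to the fibre axis reads 90°).
  The longitudinal SD switches to a circular (axial, angle-doubled)
  estimator when the spread exceeds 30°.
* **Bundles.** Two fibrils are linked when their distance profile stays
  within `contact_nm` over at least `min_overlap_fraction` (default
  0.5) of samples in both directions; bundles are connected components
  of size ≥ 2 (via `igraph`), and the bundled fraction is reported in
  percent, always alongside the threshold used. The default contact
  threshold is twice the tube radius plus one voxel
  (2 × 1.75 + 0.9 ≈ 4.4 nm) — "contact" is not sharply defined in
  stained tomograms, so the threshold is exposed and the fraction is
  monotone non-decreasing in it.
* **Grid maps.** Curves are binned by midpoint into square cells on the
  in-plane (T, L) axes; per-cell means of angles and spacings satisfy
  the conservation invariant (count-weighted cell means = global
  means). The classical analysis used squares of side 40.5 on the
  tomogram plane without stating the unit (nm vs. pixels); the cell
  side here is a free parameter in nm with a voxel-unit override in the
  tiling helpers.
* **Recovery reports.** Fits are matched one-to-one against ground
  truth by the Hungarian algorithm on the pair-distance matrix
  (implemented in-package and tested against brute-force permutation
  enumeration); matches farther than a tolerance count as miss +
  spurious. Centerline RMSD uses exact point-to-segment distances, so
  identical curves score 0.

# The synthetic generator

No tomograms were deposited for this system, so every stage is
validated against phantom scenes with known geometry. The generator
(`make_scene()` / `render_scene()` / `apply_noise()` /
`apply_missing_wedge()`) emulates:

* **Tube-like fibrils**, radius 1.75 nm by default ("a few nm thick";
  the exact diameter is not established, so it is configurable),
  rendered as soft tubes with a raised-cosine cross-section
  ($\cos^2(\pi u/3)$ for $u = d/r < 1.5$) — smooth enough that the
  optimizer sees a differentiable-ish landscape. Fibrils are the
  *bright* (high-density) phase, matching the density convention of
  lignin-stained tomograms.
* **Arrangements**: parallel lattices with configurable spacing
  (default 10 nm); two families crossing at ±θ to the tangential plane
  whose common perpendicular is the longitudinal axis, so crossing
  pairs pass at exactly the configured contact distance; bundles of
  2–3 at contact, with the bundled count following the documented
  round(n·fraction/size) rule; and an optional reduced mid-band
  spacing emulating a denser middle of the layer.
* **Noise**: seeded additive Gaussian (optional Poisson stage), with
  the contrast/σ ratio attached as an SNR report.
* **Missing wedge**: single-axis limited-tilt anisotropy (default
  −63°…+63°, the acquisition geometry of this kind of experiment),
  implemented as a binary Fourier wedge mask — fast, deterministic and
  idempotent; a ±90° range is an identity. The mask reproduces the
  hallmark elongation of the point response along the beam axis
  (FWHM anisotropy ≈ 1.65 at ±63°). A projection/iterative
  reconstruction path was considered and deliberately left out: the
  mask captures the geometric effect the fitting stage must survive.

What the phantoms do *not* emulate: stain granularity and its
contrast chemistry, CTF effects, reconstruction streaking beyond the
wedge mask, fibril thickness variation, and curvature of real
transition-layer fibrils beyond the helix + polynomial family. Passing
recovery tests therefore demonstrates correctness of the machinery and
adequacy under idealized contrast, not performance on any particular
real tomogram.

Scene generation is bit-reproducible: same seed + parameters → the same
truth curves, the same volume, the same noise field. The generator and
the metrics module deliberately cross-validate each other — metrics
computed on truth curves must return the construction parameters
exactly (planted 40% bundled → reported 40.0%; planted ±45° → reported
{+45°, −45°}).

# Demonstration scenarios and study conditions

`demo_scenarios()` packages three archetypes, mirroring the fibril
organisations reported for the transition layer:

| scenario  | geometry | planted values |
|-----------|----------|----------------|
| `crossed` | two families ⊥ L | ±45° tangential, crossings at contact (3.5 nm), 10 nm within-family spacing |
| `bundled` | parallel lattice | 10 nm spacing, 40% of fibrils in bundles of 2 |
| `tilted`  | parallel lattice | ±6° tangential (alternating sign), 10 nm spacing with 9.7 nm mid-band, 10° SD in-plane angular oscillation |

Scene sizes (8–10 fibrils in 64×64×48 voxels at 0.9 nm/voxel — a
2×-binned tomographic pixel) were chosen as the smallest volumes in
which every planted statistic is measurable with margin; the full
three-scenario recovery runs in about a minute on one CPU. Noise is
σ = 0.25 at unit fibril–matrix contrast, followed by the same 0.9 nm
Gaussian denoising a practitioner applies before visual analysis.

# Numerical choices and degenerate inputs

* Voxel-centred, 0-based coordinates; nm position = index × voxel size
  + origin. One interpolation scheme (trilinear) serves rotation,
  cost evaluation and resampling; axis-aligned 90° rotations bypass
  interpolation entirely (exact transpose/flip path).
* Fractional tile strides floor to whole voxels (documented and
  tested); middle-slab cropping uses the floor(extent/2) centre with a
  half-open index range.
* MRC I/O is a minimal MRC2014 implementation (mode 2, float32):
  values are quantised to single precision on first write; a second
  round trip is bit-exact. TIFF stacks carry no voxel size and
  require one explicitly — missing both is a hard error.
* Degenerate inputs: uniform volumes yield no seeds and empty fit
  lists (not errors); a curve entirely outside a volume is a cost
  error; a degenerate wedge (min = max) and an improper rotation
  (det ≠ +1) are rejected with named errors.
* Angle statistics near the axial wrap use angle doubling; tangential
  angles live in (−90°, +90°] by construction of the canonicalized
  tangent.

# Limitations

* The cost functional and acceptance threshold were designed for
  bright-tube contrast at moderate noise; heavily textured matrix
  density would require a matched-filter cost.
* Sequential peeling can in principle mis-assign density where many
  fibrils run at sub-voxel separations; the bundle scenarios here stay
  at touching-tube distance, where it behaves correctly.
* Orientation angles of fibrils whose extent along an axis is very
  short are intrinsically ill-determined (the historical analysis
  could not evaluate longitudinal angles on a <20 nm section); the
  angle machinery reports them regardless, and judging their
  confidence is left to the curve extents, which are part of every
  fit record.
* The missing-wedge model degrades isotropy but not contrast; real
  reconstructions lose both.
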