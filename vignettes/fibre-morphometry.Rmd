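---
title: "Methods: 3D fibre morphometry in fibremorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D fibre morphometry in fibremorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fibremorph` measures the three-dimensional architecture of dermal elastin
fibres from confocal Z-stacks of cleared skin: volume fraction, surface
area, branch count, and per-fibre length, thickness and curvature, plus the
fibrillin-1/tropoelastin intensity ratio and young-vs-aged group
statistics. This vignette is the package's own account of how each number
is computed, which knobs exist, what the synthetic phantoms do and do not
emulate, and where the known limitations are.

## Pipeline

For each stack: depth crop → preprocess → binarize → speckle removal →
skeletonize → graph → spur pruning → centre-of-gravity refinement → tip
repair → 1 µm arc-length resampling → per-fibre metrics → field metrics.
Every stage is deterministic for a fixed input and configuration, and
`analyze_field()` attaches the fully resolved configuration to its result.

### Depth crop

Fluorescence in cleared skin degrades with depth; analysis is restricted to
the superficial `max_depth_um` (default 100 µm). A slice at exactly the
limit is *included*: with the acquisition step dz = 0.8 µm, a 188-slice
stack keeps 126 slices (z = 0 … 100.0 µm). The inclusive convention is a
package choice — either convention is defensible, but only one is allowed
to exist.

### Binarization

Default is Otsu's threshold on a 256-bin histogram of the whole
(depth-cropped, optionally smoothed) volume. Per-volume thresholding avoids
slice-to-slice flicker; for strongly depth-attenuated stacks a per-slice
Otsu mode exists behind `segmentation$per_slice` (never the default).
Speckles below `min_volume_um3` (default 10 µm³) are removed by
26-connected component labelling. No published threshold exists for this
assay, so these are declared defaults, not reproductions.

### Skeletonization

The mask is resampled to an isotropic working grid at `min(spacing)`
(nearest neighbour — 3D thinning assumes isotropy), then thinned by
distance-ordered homotopic thinning: only *simple* points (Bertrand &
Malandain characterization: one 26-component of foreground neighbours, one
6-component of adjacent background) are ever deleted, in ascending
chamfer-distance order, one distance level at a time, with curve endpoints
(single-neighbour voxels) preserved. Three implementation details matter
and were each forced by observed failure modes:

- **Level-at-a-time deletion.** A single globally sorted sweep lets
  deletions cascade along a fibre axis and can consume a whole branch from
  its free end; processing one distance level at a time bounds end
  retraction to one layer per level.
- **Plate-interior protection.** Deleting the interior point of a
  one-voxel-thick ribbon is legal for 3D homotopy (the pierced hole is open
  above and below) but shreds ribbons into locked "ladders"; voxels whose
  only two background 6-neighbours are an opposite pair are therefore never
  deleted, so ribbons erode from their edges and collapse to clean curves.
- **A final unconstrained simple-point pass** removes redundant staircase
  corners; by then curves are one voxel wide and their interiors are
  non-simple, so nothing essential can be lost.

One known deviation from the behaviour of simultaneous-deletion algorithms
(e.g. Lee's): a solid ball collapses not to a point but to a short path —
endpoint protection freezes one rasterization-bump ray. Curing this would
require dropping endpoint protection away from the local thickness maximum,
which retracts the thin parts of mixed-calibre fibres; for fibre morphometry
the ray is the better trade. Balls are degenerate inputs here.

### Skeleton graph, spur pruning

Skeleton voxels with ≥ 3 neighbours are junction candidates;
26-connected candidate clusters merge into one junction node at their
centroid (thick crossings otherwise double-count). Degree-2 chains become
polyline edges; closed loops get an anchor node. Terminal edges shorter
than `prune_um` (default 3 µm) hanging off junctions are thinning spurs and
are removed, after which degree-2 junctions are dissolved. The branch count
is the number of junction nodes after pruning.

### Centreline refinement and tip repair

Thinning yields voxel-quantized centrelines. Each interior point is moved
to the centre of gravity of the mask voxels in a slab normal to the local
tangent; the slab is weighted by a tent of half-width 1.5 voxels along the
tangent (a hard slab makes the CoG jump as voxels cross its boundary) and
restricted radially to 1.5 × the local distance-transform value plus one
voxel. Two sweeps by default; the refinement is a fixed point on perfectly
centred paths.

Within about one tube radius of a fibre end the skeleton is unreliable — it
retracts and often hooks toward cap corners. Tip repair trims the cap zone
(1.5 × the median fibre radius) and regrows the path by open-loop
extrapolation of a local quadratic fit in arc length until the centreline
leaves the mask; a closing refinement sweep pulls the regrown stretch onto
curved axes. Closed-loop (tangent-following) regrowth was tried first and
rejected: on tightly curved tubes it can crawl along the flat cap face.

### Resampling, smoothing, curvature

Edges are resampled at Δs = 1 µm by linear interpolation (the last interval
may be shorter) and smoothed by a moving average (`smooth_window`, default
7) whose window *shrinks symmetrically* near the ends instead of using
padding: any symmetric average preserves straight lines exactly, whereas
reflective or extrapolated padding biases curvature at the ends of curved
fibres. The points whose window was truncated are marked `end_affected` and
excluded from curvature averaging.

Curvature at an interior point is the norm of the vector second difference
divided by the product of the two flanking interval lengths — equal to
‖p(i+1) − 2 p(i) + p(i−1)‖/Δs² for uniform spacing, and exactly 1/R on a
circle sampled at any uniform step (the plain Δs² denominator gives
2R(1 − cos(Δs/R))/Δs², within 0.1% of 1/R at Δs = 1, R ≥ 8). The fibre
value is the mean over usable interior points; a fibre with fewer than
`min_curvature_points` (default 10) usable points reports `NA` — never 0 —
because second differences on stubs consist mostly of junction and end
artefacts. Per-fibre values are averaged per field by default
(`curvature_mode = "per_fibre"`); a length-weighted pooled mode exists.
Points within `max(2 µm, 1.5 × fibre radius + 1)` of a junction are
excluded from curvature and diameter averaging: the centreline is distorted
for about one tube radius around a junction, and a fixed 2 µm zone proved
far too small for thick fibres.

Accuracy, as enforced by the test suite on noise-free arc phantoms with
r = 3 µm tubes at 1 µm voxels: mean curvature within 10% of 1/R for
R ∈ {8, 15, 30} µm, length within 3%, diameter within 1 voxel. The
residual negative curvature bias on the tightest arcs is real and
understood: the cross-section CoG of a curved tube is biased outward by
roughly r²/4R (the torus volume element grows with radius), which
reconstructs slightly too large a radius.

### Diameter

At each path point, rays are cast on a polar grid in the plane normal to
the tangent, stepping at a third of a voxel, until the trilinearly
interpolated mask drops below 0.5; the enclosed area A = Σρ²Δθ/2 gives the
equivalent diameter 2√(A/π). Ray casting keeps the section connected to the
centreline point, so neighbouring fibres are not swept in. A fallback
estimator (`diameter_method = "edt"`) returns twice the distance-transform
value at the point; the two agree within one voxel on straight tubes.
Thickness is reported as a *diameter* and labelled as such everywhere.

### Volume fraction and surface area

Volume fraction is plain voxel counting. Surface area is the area of the
0.5-level isosurface extracted by marching tetrahedra (six tetrahedra per
grid cube sharing the main diagonal; one or two interpolated triangles per
tetrahedron). The classic marching-cubes triangle table offers no accuracy
advantage for area summation and is a large constant that is easy to get
subtly wrong, so the tetrahedral decomposition is used instead. The binary
mask is padded and pre-smoothed with a Gaussian of 0.8 voxels before
extraction: the isosurface of a raw 0/1 field is a beveled voxel hull that
overestimates smooth surfaces by roughly 10–50%, while the smoothed field
meets the analytic sphere (4πr²) within 5% at 1 µm voxels with the error
shrinking as the spacing halves. Objects so small that smoothing pushes
them entirely below the level fall back to the raw hull rather than
reporting zero. End caps: analytic tube truths exclude caps (2πrL), the
measured isosurface includes them; comparisons must add 2πr².

### Intensity ratio

Mean fibrillin-1 intensity over the fibre mask divided by mean tropoelastin
intensity over the same mask. Exact on noise-free two-channel phantoms;
within 5% of the generator ratio across ten noisy seeds in the tests.

## Synthetic phantoms

Phantoms are tubes of radius r around parametric centrelines — segments,
circular arcs (curvature 1/R), helices (curvature a/(a² + c²), with c the
rise per radian — stated explicitly to avoid pitch-convention confusion),
polylines, rooted trees, candelabras (one arched base, n upward prongs,
branch count n by construction) and "field" phantoms (a candelabra plus
three arched elaunin-like fibres, so one field carries branch, curvature
and diameter signals simultaneously, as a papillary-dermis field does).

Rasterization marks voxels whose centre lies within the clamped distance r
of the centreline polyline, with flat end caps enforced within one radius
of each endpoint. Round joints are essential: a perpendicular-foot
membership test leaves hairline wedge gaps at polyline joints that can
align with the voxel lattice on curved tubes and punch spurious tunnels
through the mask — which homotopic thinning then faithfully preserves as
skeleton cycles. Auto-fitted grids snap their origin shift to whole voxels:
an axis-parallel tube centred exactly between lattice rows has a two-wide
medial set with no possible curve endpoint, which *any*
endpoint-preserving thinning retracts completely; integer-coordinate
geometry therefore stays well posed. Analytic truths are capless:
volume πr²L, lateral surface 2πrL.

The imaging model is `blur(peak·mask) · exp(−z/ζ) + background + noise`
with a separable Gaussian PSF (defaults σ = (1.0, 0.5, 0.5) µm — generic
confocal values, no instrument was fitted), optional Poisson shot noise and
additive Gaussian noise, and exponential depth attenuation ζ motivated by
the signal loss beyond ~100 µm in cleared tissue. Identical seed and
parameters give bit-identical output; generators are pure functions of
(parameters, seed).

What the phantoms do *not* emulate: nuclei and appendages, fibre tapering
and calibre variation along one fibre, touching/crossing fibres of separate
identity, anisotropic PSF side lobes, depth-dependent blur, or the tiled
450 × 450 µm field of a real acquisition (tests run on small fields purely
for speed). A green phantom suite therefore establishes the correctness of
the *measurement chain*, not segmentation robustness on real tissue.

Cohort emulation: population templates draw tube radius and curvature
lognormally (mean, CV; CV = 0.15 and 0.08 are the package's notion of a
biologically plausible spread) and fix the prong count per group. The
acceptance study uses young-like fields (curvature 1/45 µm⁻¹, r = 2 µm,
5 prongs) versus aged-like fields (1.65× curvature, r = 3.3 µm, 3 prongs),
n = 10 fields per group — directions and the 1.65× contrast follow the
reported aged-vs-young pattern (more curved, thicker, fewer branches).

## Statistics

Both tests are always computed because the source methods name Student's
t while the figure legends name Mann–Whitney; the discrepancy is surfaced,
not resolved, and Mann–Whitney is the headline test. The exact Mann–Whitney
p enumerates all C(n_A+n_B, n_A) assignments of the observed midranks
(ties handled by midranks) for n_A + n_B ≤ 12, and uses a tie-corrected,
continuity-corrected normal approximation above. A consequence worth
stating: with n = 3 per group the exact two-sided p can never fall below
0.1, so starred results at n = 3 cannot come from an exact two-sided
Mann–Whitney test. Both percent conventions (ratio ×100, change ×100) are
reported because phrases like "165% thicker" are ambiguous between them. No
multiple-testing correction is applied, matching the source analysis; the
star thresholds are 0.05 / 0.01 / 0.005.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_depth_um` | 100 | µm | signal degrades deeper in cleared tissue; inclusive cut |
| `segmentation$smooth_sigma_um` | (0.5, 0.5, 0.5) | µm | mild denoising before Otsu |
| `segmentation$min_volume_um3` | 10 | µm³ | a few voxels at 1 µm³; speckle floor |
| `segmentation$connectivity` | 26 | – | diagonal fibre continuity |
| `centerline$step_um` | 1.0 | µm | the 1 µm sampling that defines the curvature metric |
| `centerline$prune_um` | 3 | µm | spur length scale of thinning on thick tubes |
| `centerline$smooth_window` | 7 | points | jitter suppression vs curvature flattening; validated on R ∈ {8,15,30} arcs |
| `morphometry$junction_exclusion_um` | max(2, 1.5 r + 1) | µm | junction distortion extends ~one radius |
| `morphometry$min_curvature_points` | 10 | points | below this, second differences are artefact |
| `morphometry$surface_smooth_sigma_vox` | 0.8 | voxels | beveled-hull bias vs shape erosion |

## Degenerate inputs and tie-breaks

Empty masks yield explicitly flagged empty field metrics (zeros plus
`empty = TRUE`), never silent zeros for undefined quantities; metrics that
cannot be computed are `NA`. Constant images refuse Otsu. A fixed threshold
outside the intensity range warns. Single-voxel objects are isolated nodes;
closed loops get one anchor node. Fibres shorter than two points are
errors; curvature of fewer than three equally spaced points is `NA`. The
arc of a population draw whose radius cannot span the requested width is
shortened to a sub-semicircular arch rather than rejected.

## Limitations

- Metrics are per skeleton edge; a biological fibre crossing several
  junctions is reported as several fibres. Fibre-type classification
  (oxytalan / elaunin / elastic) is out of scope.
- Curvature on fibres with radius-to-bend ratios near the self-intersection
  limit (R ≲ 3r) carries the outward CoG bias discussed above; the 10%
  validation band covers R ≥ 8 µm at r = 3 µm.
- The minimal TIFF codec reads uncompressed TIFFs only (8/16-bit unsigned,
  32-bit integer, 32/64-bit float); compressed or tiled files from other
  software must be re-saved uncompressed.
- Broken fibres are not re-joined (no gap closing), and masks are taken at
  face value: segmentation quality on real stained tissue is the caller's
  responsibility.
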