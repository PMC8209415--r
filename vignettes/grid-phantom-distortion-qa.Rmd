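---
title: "Measuring MRI geometric distortion with a grid phantom: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring MRI geometric distortion with a grid phantom: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

MRI-guided radiotherapy (MR-Linac) requires that the geometry of the MR
image be faithful to the patient: a control point imaged 2 mm away from its
true position translates directly into a 2 mm error in target delineation.
System-dependent geometric distortion has two dominant sources:

* **Gradient nonlinearity (GNL)** — the encoding gradients deviate from
  linearity away from the magnet isocenter, displacing image content by an
  amount that grows with distance from the center and is essentially
  independent of the imaging bandwidth.
* **B0 inhomogeneity** — static off-resonance of `dB0` Hz shifts content
  along the frequency-encode axis by `dB0 / BW_pixel` pixels, where
  `BW_pixel` is the pixel bandwidth. Halving the bandwidth doubles this
  displacement.

`mrgridqa` implements a complete desk-scale version of a grid-phantom QA
study of these effects: it models a water-filled 3D-printed grid phantom, a
set of scanner acquisition protocols, and a parametric distortion field;
renders reference (CT-role, gold-standard geometry) and distorted (MR-role)
volumes; extracts the grid intersections automatically at sub-pixel
precision; and summarizes the displacement field with the statistics used
in distortion QA reports, plus a simplified geometric dose-impact analysis.

Because no scanner data ships with the package, the simulator is not a test
fixture but the first-class instrument of the package: every downstream
stage is validated by parameter recovery against the simulator's exact
ground truth.

## The phantom model

The phantom (`build_phantom()`) is a cylinder of photosensitive-resin walls
filled with water: a 40 cm diameter circular face, 22 cm thick, with the
bottom cut flat for mechanical stability, a 10 mm square-cell grid, and a
solid diamond marker at the center used to align the phantom with the
isocenter and to register image centers. All dimensions are parametric.

Two constants are design calibrations rather than free parameters:

* `grid_inner_radius_mm = 170` and `cut_chord_offset_mm = 150`. Enumerating
  every complete 10 mm cell inside the closed 170 mm disc, above the chord
  at y = -150 mm, yields exactly **822 cells** (832 in the full disc minus
  the ten-cell row below the chord) bounded by 886 grid intersections.
  These two numbers were fixed once by exhaustive enumeration and are not
  searched at run time.
* The chord at 150 mm also places the 180-degree mark point of the 15 cm
  ring exactly on the cut edge, which is why the default mark-point set has
  11 usable points out of the 12 requested (3 radii times 4 angles).

Values not determined by the geometry above (wall thickness 2 mm, diamond
half-width 7 mm) only affect rendering contrast and marker detectability,
not node positions; 7 mm makes the marker clearly distinguishable from an
ordinary crossing at a 512^2 matrix.

The coordinate frame follows the QA convention: origin at the diamond
center, +y is the 0-degree direction, angles grow **clockwise** (90 degrees
= +x), z runs foot to head.

## The distortion model

`distortion_model()` carries one sparse polynomial per displacement axis
(the GNL term) and a scalar polynomial off-resonance map in Hz (the B0
term). The total displacement at a point p is

```
d(p) = d_gnl(p) + (dB0(p) / BW_pixel) * pixel_size * e_freq
```

with `e_freq` the frequency-encode unit vector. Both polynomial fields are
constrained to vanish at the isocenter — the physical reason the
center-point registration used throughout is meaningful. Deliberate
rigid-shift constructions can disable the constraint
(`enforce_isocenter = FALSE`).

The default GNL parameterization (`radial_gnl()`) is a radially directed
field with odd-order magnitude

```
|d|(r) = dmax * ((1 - w5) (r/170)^3 + w5 (r/170)^5),   w5 = 0.25
```

so the displacement vanishes with zero slope at the center and reaches
exactly `dmax` at the lattice edge (r = 170 mm). The three field presets
`unity_like`, `ge_hde_like`, `ge_750_like` set `dmax` to 1, 1.5 and 3 mm —
the relative magnitudes of an MR-Linac, a 1.5 T diagnostic system and a 3 T
system in this class of phantom studies. The cubic/quintic mixture is a
modeling choice, not a fit to any specific scanner: real GNL fields are
machine-specific spherical-harmonic expansions, and the B0 default
(`parabolic_b0()`, a parabolic bowl) is likewise illustrative. What the
presets preserve is the structure every such field shares: smoothness, zero
at the isocenter, growth toward the periphery.

## Scanner protocols

Three presets reproduce the acquisition geometries the package is built
around:

| preset   | FOV (mm) | matrix | px (mm) | BW (Hz/px) | slices        |
|----------|---------:|-------:|--------:|-----------:|---------------|
| `unity`  | 537.6    | 1008   | 0.5333  | 1033       | 3D, 1.6 mm    |
| `ge_hde` | 480      | 512    | 0.9375  | 195.31     | 5 mm          |
| `ge_750` | 500      | 512    | 0.9766  | 195.31     | 3 mm          |

The 3D series of the MR-Linac preset is rendered as contiguous thin
(1.6 mm) slices. Voxel centers sit at `pixel_size * (index - (matrix-1)/2)`,
so the isocenter falls on the central voxel for odd matrices and exactly
between voxels for even ones; the detection accuracy tests cover both
phase situations.

## Rendering

The phantom is an analytic solid extruded along z, so rasterization needs
no mesh: each sample position is classified as air, water or resin.
Reference volumes use CT-like contrast (resin bright), MR volumes T2-like
contrast (water bright); node detection is contrast-agnostic, so the
inversion costs nothing downstream.

Distortion is applied as an **inverse warp**: the MR intensity at output
position p is the material at the pre-image q solving `q + d(q) = p`,
found by fixed-point iteration `q <- p - d(q)`. Three iterations leave a
residual below `|d| * |grad d|^3`, which is sub-micron for the sub-cell
fields used here; because the object is analytic, the warp samples the true
solid rather than interpolating a rasterized reference, keeping the ground
truth exact at node positions. Each pixel is averaged over a 4 x 4 subgrid
(`supersample = 4`) so edge intensities approximate area coverage — this
anti-aliasing is what makes sub-pixel localization accurate.

Noise is Rician: independent Gaussians of standard deviation
`water_signal / snr` added to the in-phase channel and a zero-mean
quadrature channel before taking the magnitude, the textbook model of
magnitude MR images. The model's `seed` makes renders bit-reproducible;
reference volumes are noiseless by definition (CT plays the role of the
geometric gold standard).

## Node detection

The historical workflow this replaces was manual: enlarge the transverse
image and click each intersection. `detect_nodes()` automates it in three
stages:

1. **Candidate detection.** Normalized cross-correlation with a cross
   template (arm length half a pitch, arm width the wall thickness). The
   absolute NCC value is used so CT-like and T2-like contrast give
   identical responses. Local maxima above a response threshold are kept
   with non-maximum suppression at half a pitch.
2. **Sub-pixel refinement.** Each wall position is measured independently:
   the x coordinate comes from the column profile of rows that *exclude*
   the horizontal wall band (so the perpendicular wall — or its absence at
   arm-end corners — cannot bias the estimate), baseline-corrected by a
   linear fit through the two flanks, then localized with an intensity
   centroid whose window has fractional-coverage edge weights and is
   iterated to its own fixed point (at convergence the window is symmetric
   about the reported position, removing clipping bias). Noiseless
   localization error on the presets is ~0.01-0.06 mm.
3. **Validity vetoes.** A profile whose two flank levels differ by more
   than its ridge amplitude is an *edge*, not a wall ridge — this occurs on
   T2 contrast along the cut chord, where the dark wall borders dark air —
   and is rejected. Crossings whose windows exit the image are skipped. In
   practice ~2% of the 886 nodes (the chord row and the eight lattice-edge
   corner nodes) are rejected on T2 contrast; they are reported as
   unmatched and excluded from summaries rather than imputed.

The solid diamond produces no crossing response of its own;
`find_center_marker()` locates it with a diamond-template NCC followed by a
2D version of the same iterated fuzzy-window centroid, and the marker
center stands in for the central node.

`match_nodes()` registers detections to the design lattice by **center
translation only** — no rotation or scale, mirroring the physical
laser-alignment plus center-registration procedure — and pairs nodes
one-to-one, greedily by ascending distance, within a gate of half a pitch
(5 mm), the largest unambiguous assignment radius. The `upsample` argument
mirrors the display zoom of manual point-picking workflows and is accepted
for compatibility; the centroid refinement is already sub-pixel, so values
above 1 change nothing measurable.

## Distortion statistics

* `plane_distortion()` / `distortion_3d()` — the 2D/3D Euclidean distance
  between reference and registered imaged coordinates.
* `radial_summary()` — mean, SD (sample, n-1), maximum and count over
  **cumulative discs** at 50/100/150/200 mm. Cumulative (not annular)
  binning is deliberate: the largest-radius row then reproduces the
  whole-phantom mean +/- SD identically, which QA reports in this style
  rely on.
* `fraction_below()` — share of control points with distortion strictly
  below a threshold (default 2 mm, the usual clinical gate).
* `distortion_histogram()` — half-open 0.5 mm bins.
* `mark_points()` — the tracking set at radii 50/100/150 mm and angles
  0/90/180/270 degrees clockwise from +y, minus points removed by the cut.
* `track_slices()` — the 30-layer rule: the most-foot slice is the bottom
  layer; the remaining stack is split into equal groups and each group
  contributes its head-most member.
* `mark_point_3d_summary()` — for consecutive selected layers, the 3D
  distortion with (x, y, z) from the foot-side and (x1, y1, z1) from the
  head-side layer. With `z_mode = "slice_position"` (default) the
  head-foot term of geometrically identical layers equals the selected
  layer spacing; the alternative `"in_plane_only"` sets the z term to zero
  and isolates in-plane drift. Both readings of the head-foot subtraction
  are defensible; the default is the literal one, and the flag preserves
  the other.

## Dose impact

A full treatment-planning comparison (IMRT optimization, electron-return
effect, electron-density assignment) is beyond what a distortion
measurement determines, so `dose_impact_table()` isolates the purely
geometric component: each region of interest is displaced by the measured
field and the relative change of its mean dose is reported,
`100 * |mean(displaced) - mean(reference)| / mean(reference)`. The ROI
layout is the standard one — a central 2 x 2 cm square plus 1 x 1 cm
squares at 5/10/15/17 cm (14 in total, angular placement following the
mark-point convention with positions lost to the cut dropped; the angular
placement is an assumption, as published layouts rarely state it) and a
whole-phantom disc. Square-ROI voxel weights are exact overlap fractions,
so a symmetric ROI on a linear dose ramp returns its center value exactly
and the rigid-shift oracle `100 * g * s / D` is reproduced to rounding.
`synthetic_dose()` provides a deterministic rotationally symmetric plateau
(tanh falloff) standing in for a plan's dose grid; any externally computed
dose resampled onto the image raster can be supplied instead.

With the default plateau covering all ROIs, fields up to 3 mm change ROI
mean doses by well under 5% — the geometric echo of the finding that
distortion at clinical QA levels only slightly perturbs planned dose.

## Pipeline, reproducibility, problem sizes

`run_pipeline()` chains simulate -> detect -> match -> metrics -> dose and
writes a bundle of stamped CSVs plus a JSON QA report; the QA verdict is
`fraction_below(2 mm) >= qa_gate`. Every output embeds the seed and the
MD5 of the serialized configuration, and a re-run from the same
configuration is byte-identical. Plane statistics use the central
transverse slice; `three_d = TRUE` renders a slice stack and adds the
mark-point 3D summary.

Default problem sizes were chosen so a complete validation (unit tests,
parameter recovery over three field magnitudes with five noise seeds each,
and the acceptance script) runs in minutes on a single core: recovery runs
use the 512^2 presets, and the 1008^2 MR-Linac preset is exercised for the
null-recovery check. Detection cost is dominated by two FFT correlations
per slice; rendering by the supersampled material evaluations.

## What the synthetic data does and does not show

The simulator reproduces the geometry chain end to end: a known smooth
displacement field, its bandwidth-dependent B0 component, contrast
inversion between modalities, Rician noise, and partial-volume rendering.
Passing the recovery tests therefore demonstrates that the detection and
statistics stages measure smooth fields without systematic bias at the
0.05 mm level under these conditions.

It does not demonstrate performance against: machine-specific GNL shapes
(spherical-harmonic structure, through-plane curvature), susceptibility
gradients at resin-water interfaces, sequence-specific artifacts (ghosting,
blurring along phase-encode), phantom setup rotation (the registration is
translation-only by design), or manufacturing deviations of a physical
phantom from its CAD geometry. Real-scanner headline numbers (e.g. a
specific system's 0.79 mm whole-phantom mean) are properties of those
machines, not reproducible from simulation — which is why the package's
validation is parameter recovery rather than value matching.

## Known limitations

* Translation-only registration: a rotated phantom setup biases all nodes
  coherently; rotation estimation is out of scope.
* Chord-row and lattice-corner nodes are undetectable on T2-like contrast
  (see the veto above); summaries exclude them with logged counts.
* The B0 default is a parabola; real shim residuals have higher-order
  structure. Users with measured B0 maps can supply their own monomial
  tables.
* DICOM export is not provided; volumes are exchanged as NIfTI.
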