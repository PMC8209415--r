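# mrgridqa

Geometric-distortion quality assurance for MRI and MR-Linac systems using
a water-filled 3D-printed grid phantom.

MRI-guided radiotherapy stands or falls with the geometric fidelity of the
MR image: a control point imaged away from its true position displaces the
target by the same amount. `mrgridqa` implements the complete analysis
chain of a grid-phantom distortion study as a reusable, tested R package:

* **Phantom model** — a parametric 40 cm water-filled grid phantom
  (22 cm thick, 10 mm cells, central diamond marker, stability cut) whose
  default build enumerates exactly 822 complete 1 cm² cells bounded by
  886 control points.
* **Scan simulator** — renders reference (CT-role) and distorted (MR-role)
  volumes under the acquisition protocols of three scanners (an MR-Linac
  at 537.6 mm FOV / 1008² / 1033 Hz per pixel, and two 512² diagnostic
  systems at 195.31 Hz per pixel) with a parametric displacement field and
  Rician noise, together with exact ground-truth node displacements.
* **Distortion field** — gradient-nonlinearity polynomial plus a B0
  off-resonance map divided by the pixel bandwidth:
  `d(p) = d_gnl(p) + (ΔB0(p)/BW_px)·px·ê_freq`, so halving the bandwidth
  exactly doubles the B0 displacement component.
* **Node detection** — automated sub-pixel extraction of every grid
  intersection (normalized cross-correlation, wall-profile centroids,
  contrast-agnostic), center-marker registration and one-to-one matching
  to the design lattice.
* **Statistics** — the plane distortion `√((x₁−x)² + (y₁−y)²)` per node,
  cumulative-radius summaries (mean ± SD at 5/10/15/20 cm), the fraction
  of points below 2 mm, histograms, vector fields, and the 3D mark-point
  distortion `√((x₁−x)² + (y₁−y)² + (z₁−z)²)` across a 30-layer slice
  selection.
* **Dose impact** — the purely geometric component of dose change: each of
  the 14 standard regions of interest (2×2 cm center, 1×1 cm squares at
  5/10/15/17 cm) is displaced by the measured field on a 50 Gy synthetic
  plateau dose and the relative mean-dose change is reported.

## Worked example

Simulate a 1.5 T scan of the phantom under a radial distortion field whose
maximum displacement at the lattice edge (r = 170 mm) is 1.5 mm, recover
the control points, and summarize:

```r
library(mrgridqa)

spec    <- build_phantom()
lattice <- build_lattice(spec)
lattice
#> Grid-phantom lattice: 822 cells, 886 nodes, pitch 10 mm

cfg <- run_config(protocol = "ge_hde", field = "ge_hde_like",
                  snr = 30, seed = 1)
bundle <- run_pipeline(cfg)

bundle$radial_summary
#>   radius_mm   n   mean_mm      sd_mm    max_mm
#> 1        50  81 0.1219716 0.05135830 0.2448824
#> 2       100 317 0.1696540 0.08312542 0.3883214
#> 3       150 708 0.4071583 0.27857714 1.1483341
#> 4       200 869 0.5562890 0.40782024 1.6651421

bundle$fraction_below
#> [1] 1
```

Reading the table: 869 of the 886 lattice nodes were detected and matched
(nodes on the cut chord and the lattice-edge corners are not measurable on
T2-like contrast and are excluded, not imputed). Distortion grows from
0.12 mm mean inside the 5 cm disc to 0.56 mm over the whole phantom —
the radially growing field is recovered — and every matched point is below
the 2 mm clinical gate, so the run passes QA. The rows are cumulative
discs, so the 200 mm row is identically the whole-phantom mean ± SD.

The dose stage reports the geometric dose impact of the same field on a
50 Gy plateau; for this 1.5 mm field the largest ROI change is ~0.013 %
(at the 17 cm edge ROIs), echoing that distortion at clinical QA levels
barely perturbs planned dose:

```r
head(bundle$dose_table[order(-bundle$dose_table$change_rate_pct), ], 3)
#>        roi reference_dose_gy change_rate_pct
#> 13    p4-1          49.99779    1.256887e-02
#> 14    p4-2          49.99779    1.256887e-02
#> 15 phantom          50.00000    2.217692e-05
```

With `out_dir` set, `run_pipeline()` writes the correspondence table,
radial summary, histogram, vector field and dose CSVs plus a JSON QA
report, each stamped with the seed and configuration hash; identical
configurations reproduce byte-identical bundles. A thin command-line
front end is provided in `inst/scripts/mrgridqa.R`
(`simulate` / `analyze` / `compare`).

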