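# contourfit

Shape parametrisation and measurement reliability for stylus-digitised
articular cartilage contours.

After dissection, the rim of an articular cartilage (e.g. the glenoid
cartilage of the shoulder, or the clavicular cartilage of the
acromioclavicular joint) can be digitised with a hand-held,
fiducial-marker-tracked stylus recorded by a single camera: the operator
traces the rim and the system stores the 3D tip position at 10 Hz. This
package is for anatomists and biomechanists who use such data. It provides:

* **Contour parametrisation** — reduce a contour point cloud (in its bone
  coordinate system, mm) to nine parameters: the position
  `T = (x, y, z)` and orientation `R = (α, β, γ)` (Cardan angles, intrinsic
  X–Y′–Z″, degrees) of the best-fitting ellipse, the ellipse axis lengths
  `L1 ≥ L2`, and a curvature radius `r` from a least-squares circle fitted
  to the cloud projected along the ellipse minor axis. Plane, ellipse
  (orthogonal-distance) and circle (Kåsa + geometric refinement) fits are
  exposed individually.
* **Anatomical frames** — scapula and clavicle coordinate systems from
  palpated landmarks (SIA, SRS, SAA; CAJ, CSJ, CAS, CSC), with left-sided
  specimens mirrored to right-sided geometry.
* **Stylus tracking** — fusion of multi-marker poses into a body pose
  (quaternion eigenvector rotation averaging), pivot calibration of the tip
  offset, and tip-trajectory reconstruction with explicit gaps on marker
  dropout.
* **Reliability analysis** — variance components of the crossed
  cartilage × operator × digitalisation design
  (σ²_total = σ²_cartilage + σ²_operator + σ²_digitalisation + σ²_residual),
  from which

      ICC_intra = (σ²_total − (σ²_digitalisation + σ²_residual)) / σ²_total
      ICC_inter = (σ²_total − (σ²_operator + σ²_residual)) / σ²_total
      SEM       = sqrt(σ²_total × (1 − ICC)),    CI95 = ±1.96·SEM

  with the standard qualitative bands (ICC: poor < 0.5 ≤ moderate < 0.75 ≤
  good < 0.90 ≤ excellent; SEM: excellent < 1 ≤ good < 2 ≤ moderate < 3 ≤
  poor, mm or degrees).
* **A synthetic-study generator** — per-specimen true parameters,
  hierarchical operator/trial/point noise, landmark sets and marker-pose
  streams emulating the full 10-specimen × 2-cartilage × 3-operator ×
  3-digitalisation protocol, so every stage is testable without cadaveric
  data.

Everything is tidyverse-shaped: functions take data frames (point clouds as
`x/y/z` tibbles, measurements as long tables) and return tibbles or fitted
objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate one digitised glenoid contour and recover its parameters:

```r
library(contourfit)

cloud <- generate_contour_cloud(
  list(x = 31.8, y = -17.7, z = -16.6,      # ellipse centre, bone frame (mm)
       alpha = 0.9, beta = 10.4, gamma = 86.2,  # orientation (deg)
       l1 = 28.8, l2 = 20.4, r = 38.1),     # axis lengths, curvature (mm)
  n_points = 350, sigma_point = 0.2, seed = 7
)
parametrise_contour(cloud)
#> <contour_parameters>
#>   T (mm):     31.803  -17.707  -16.599
#>   R (deg):     0.933   10.370   86.059
#>   L1 28.853 mm, L2 20.420 mm, r 38.392 mm
#>   fit rms (mm): plane 0.9847, ellipse 0.1966, circle 0.2098; n = 350
```

With 0.2 mm of per-point jitter the nine parameters come back within a few
hundredths of a millimetre / degree of the generating values; the plane rms
(≈ 1 mm) reflects the out-of-plane sag that carries the curvature, and the
ellipse/circle rms reflect the point jitter.

A full reliability study, end to end:

```r
study  <- generate_study(study_config(seed = 42))
report <- reliability_report(study$measurement_table)
dplyr::select(dplyr::filter(report, cartilage_type == "glenoid"),
              parameter, mean, sd, icc_intra, icc_inter, sem_intra, sem_inter)
#> # A tibble: 9 × 7
#>   parameter   mean    sd icc_intra icc_inter sem_intra sem_inter
#> 1 x          33.1   3.24     0.999     0.984     0.128     0.427
#> 2 y         -19.5   3.26     0.992     0.965     0.313     0.640
#> 3 z         -17.6   6.67     0.997     0.999     0.376     0.164
#> 4 alpha       3.18  2.95     0.986     0.992     0.361     0.280
#> 5 beta       11.0   4.05     0.998     0.979     0.185     0.615
#> 6 gamma      85.9   6.66     1.000     0.995     0.123     0.470
#> 7 l1         28.1   1.09     0.964     0.878     0.220     0.405
#> 8 l2         19.8   1.27     0.930     0.715     0.369     0.747
#> 9 r          39.8   6.16     1.000     0.998     0.100     0.286
```

Each row mirrors a reliability-table row: descriptives, intra-/inter-observer
ICC and SEM (here at the generator's default noise levels, so agreement is
mostly excellent), with classification bands and %SEM in further columns.
`write_reliability_report()` writes the rounded CSV (1 decimal for mm/deg,
2 for ICC) plus a full-precision JSON twin, and `autoplot(report)` draws the
ICC dot plot with the classification thresholds.

A thin command-line interface wraps the same functions
(`inst/cli/contourfit`): `simulate`, `parametrise`, `reliability`,
`pivot-calibrate`, `digitise`.

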