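---
title: "Cartilage contour parametrisation and digitalisation reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cartilage contour parametrisation and digitalisation reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourfit)
```

## The measurement problem

A hand-held stylus tracked by a single camera is a cheap, versatile way to
digitise anatomical structures after dissection: the operator traces the rim
of an articular cartilage while the system records the 3D position of the
stylus tip at 10 Hz. The result is a loop-shaped point cloud in the camera
frame. Two questions follow. First, how should such a cloud be reduced to a
small set of interpretable shape parameters? Second, how reproducible are
those parameters when the same cartilage is traced repeatedly by the same or
by different operators — i.e. is the instrument reliable enough to be useful?

`contourfit` implements both halves: the geometric reduction of a contour
cloud to nine parameters, and the variance-component reliability analysis of
a crossed cartilage x operator x digitalisation study, together with a
synthetic-study generator that emulates the whole experiment so every stage
can be tested without cadaveric data.

## From point cloud to nine parameters

All coordinates are millimetres; angles are degrees. A contour cloud is
first expressed in an anatomical bone coordinate system (see below) and
mirrored to right-sided geometry if the specimen is left-sided, so that
parameters are comparable across sides. The pipeline in
`parametrise_contour()` then runs:

1. **Total-least-squares plane.** The plane through the centroid whose
   normal is the smallest-variance principal direction of the centred
   cloud; it minimises the sum of squared orthogonal distances.
2. **Orthogonal projection** of the cloud onto that plane.
3. **Orthogonal-distance ellipse fit** of the projected points. A direct
   algebraic conic fit (ellipse-specific, in centred and scaled coordinates
   for conditioning) provides the initial estimate; a quasi-Newton
   refinement then minimises the exact sum of squared orthogonal distances,
   with the point-to-ellipse distance solved per point by a safeguarded
   Newton iteration on the perimeter angle. Axis lengths are reported as
   full lengths with `L1 >= L2` enforced by swapping.
4. **Ellipse frame.** X along the major axis, Z along the plane normal
   pointing laterally, Y = Z x X along the minor axis. The contour position
   `T = (x, y, z)` is the ellipse centre in the bone frame and the contour
   orientation `R = (alpha, beta, gamma)` is the Cardan decomposition of
   the ellipse frame.
5. **Minor-axis projection.** The *original* 3D cloud is projected onto the
   plane whose normal is the ellipse minor axis, using (major axis, plane
   normal) as the in-plane basis. Projecting the original cloud rather than
   the already-flattened one preserves the out-of-plane sag that carries
   the curvature information.
6. **Least-squares circle.** The Kåsa algebraic solution refined
   geometrically (radius profiled out, centre optimised) gives the
   curvature radius `r`.

Nine numbers result: `x, y, z` (mm), `alpha, beta, gamma` (deg),
`l1, l2, r` (mm), plus the rms residuals of the three fits as quality
measures.

### Conventions that make the output deterministic

Several signs are not determined by the data alone and are fixed by
convention so that repeated digitalisations of the same cartilage map to
the same parameter vector:

* **Cardan sequence.** Intrinsic X–Y′–Z″ (mobile axes), the common
  biomechanics convention. Near gimbal lock (`|beta| = 90`) alpha is set to
  0 and gamma absorbs the free angle; the result carries a flag.
* **Plane-normal sign.** Z of the ellipse frame points laterally, resolved
  as the positive medio-lateral (third) bone-frame coordinate, with
  deterministic fallbacks when the contour plane contains that axis.
* **Major-axis sign.** X of the ellipse frame points positively along its
  dominant bone-frame component. The dominant-component rule keeps the sign
  stable under noise as long as a population of contours does not straddle
  a 45° boundary, which the anatomical orientations simulated here do not.
* **2D axis signs.** In-plane, the major-axis direction takes a positive
  first component (positive second if the first vanishes).

A degenerate case deserves note: a perfectly flat contour makes the
minor-axis projection collapse onto a line, so no circle is defined. The
pipeline then reports `r = Inf` with a `circle_degenerate` flag rather than
failing, mirroring the observation that very flat cartilages resist
curvature estimation; an optional `flat_r_threshold` flags suspiciously
large finite radii (off by default).

## Bone coordinate systems

`build_scapula_frame()` uses three scapular landmarks: origin at the
acromial angle (SAA), Z along the spine-root-to-acromial-angle line (SRS to
SAA, lateral on a right scapula), X perpendicular to the SIA–SAA–SRS plane
pointing anteriorly, Y = Z x X pointing superiorly.
`build_clavicle_frame()` uses four clavicular landmarks: origin at the
sternoclavicular joint centre (CSJ), Z along CSJ to CAJ, and — because a
thorax is not available in a dissected-specimen setting — an
anteroposterior X built from the CAS–CSC line, orthogonalised against Z by
Gram–Schmidt. Landmark coordinates cannot by themselves distinguish
anterior from posterior, so both constructors take an `anterior_hint`
direction (default `+x` of the digitiser world frame) that resolves the
sign; the hint is recorded as part of the analysis configuration rather
than guessed from the data. Left-sided specimens are homogenised by
negating the medio-lateral bone-frame coordinate (`mirror_to_right()`),
which preserves distances and flips chirality exactly once.

## Stylus tip localisation

The stylus carries fiducial markers on a double-dodecahedron head so that
several markers face the camera from any direction. `fuse_body_pose()`
converts each visible marker pose into a candidate body pose through the
marker's fixed body-frame transform and averages the candidates with equal
weights — translations arithmetically, rotations by the quaternion
outer-product eigenvector mean, which is deterministic and needs no
iteration. The spread across candidates is reported as a per-frame quality
measure. `pivot_calibrate()` estimates the tip offset by the classic pivot
formulation: rotating the stylus about a fixed contact point gives the
linear system `R_i t + t_i = p`, solved by stacked least squares with a
rank check that rejects rotation-free motion. `tip_trajectory()` composes
fused poses with the calibrated offset; frames with no usable marker are
emitted as gaps, never interpolated, because a gap is information about
the recording. The 1-mm spherical probe radius is stored in the stylus
model for optional surface-offset correction but no correction is applied
by default.

## Reliability analysis

The study design is fully crossed: every cartilage is digitised by every
operator in every trial. For one parameter the measurement model is

$$ y_{cod} = \mu + a_c + b_o + d_t + \varepsilon_{cod}, \qquad
\sigma^2_{total} = \sigma^2_{cartilage} + \sigma^2_{operator} +
\sigma^2_{digitalisation} + \sigma^2_{residual}, $$

with the digitalisation (trial) index treated as a crossed factor whose
labels are shared across operators, matching the flat additive
decomposition. `estimate_variance_components()` offers two estimators: for
balanced designs the closed-form expected-mean-squares (EMS) path equates
the ANOVA mean squares of the crossed main-effects model to their
expectations (negative raw estimates truncated to zero before summing);
for unbalanced data a REML path (`lme4`, three crossed random intercepts)
is available. For balanced data with interior estimates the two coincide,
which the test suite verifies against a brute-force REML optimisation of
the dense restricted-likelihood criterion.

From the components,

$$ ICC_{intra} = \frac{\sigma^2_{total} - (\sigma^2_{digitalisation} +
\sigma^2_{residual})}{\sigma^2_{total}}, \qquad
ICC_{inter} = \frac{\sigma^2_{total} - (\sigma^2_{operator} +
\sigma^2_{residual})}{\sigma^2_{total}}, $$

$$ SEM = \sqrt{\sigma^2_{total}\,(1 - ICC)}, \qquad
CI_{95} = \pm 1.96\, SEM . $$

ICCs are classified poor (< 0.5), moderate (0.5–0.75), good (0.75–0.90) or
excellent (>= 0.90), lower bounds inclusive; SEMs are classified excellent
(< 1 mm or deg), good (1–2), moderate (2–3) or poor (>= 3). %SEM is
reported as `100 * SEM / |mean|` by default; the reference magnitude is
configurable because no single choice suits every parameter — in
particular, a near-zero mean (as for some orientation angles) makes the
percentage uninformative, which is why the absolute SEM carries the
classification.

Angle parameters are unwrapped to the 360° branch nearest their circular
mean before any statistic is computed; otherwise a population sitting near
the ±180° cut would show a catastrophically inflated variance. The report
lists both the pooled sample SD and `sqrt(sigma2_total)` under separate
names since the two need not coincide.

If a parameter has exactly zero total variance (every measurement
identical), the ICC ratio is formally undefined; `icc_intra()` and
`icc_inter()` raise an error, while `reliability_report()` adopts the
convention ICC = 1, SEM = 0 for such constant columns, since a constant
measurement is perfectly repeatable.

## The synthetic-study generator

`generate_study()` emulates the full experiment: 10 specimens (5 left, 5
right), two cartilage types (glenoid and acromioclavicular), 3 operators,
3 digitalisations, ~350 stylus points per contour (35 s of tracing at
10 Hz). Per-specimen true parameters are drawn from normal populations
whose means and SDs default to published cadaveric summary values, so
synthetic cohorts are anatomically plausible; draws are repeated until
geometrically admissible (`l1 > l2 > 0`, `r >= l1/2 + 0.5`) and drawn
orientations are canonicalised to the sign conventions the pipeline can
recover.

The geometric forward model in `generate_contour_cloud()` is the inverse
of the parametrisation: points are sampled on the ellipse perimeter in
antipodal pairs, lifted onto the sphere of radius `r` tangent to the
ellipse plane with the curvature applied along the major-axis arc (so the
minor-axis projection of step 5 sees a circular arc of exactly radius
`r`), re-centred so the cloud centroid coincides with the requested
position, posed by the requested orientation, and jittered isotropically.
Antipodal sampling makes the lift exactly uncorrelated with the in-plane
coordinates, so at zero noise the fitted plane, ellipse and circle all
recover the generating parameters to solver precision — the round-trip
oracle the test suite relies on. The lift geometry requires
`r >= l1/2` (the arc spans the major axis), which is why admissibility is
enforced at sampling time. Since real cartilage is not literally an
ellipse-on-a-sphere, residuals from real clouds will exceed the synthetic
ones; what the round-trip shows is the correctness of the estimator, not
the realism of the shape model.

The measurement hierarchy follows the crossed design: operator biases are
drawn once per operator x parameter x cartilage type, digitalisation
effects once per trial index x parameter x type, and a cell-level residual
completes the analytic measurement table. The same cell parameters can
instead be turned into point clouds and pushed through the real pipeline
(`empirical_measurement_table()`), in which case the residual arises from
point jitter through the fits; the two routes agree in their variance
structure, which is a tested invariant.

Noise defaults are the package's own choices, stated once: operator bias
SD 0.5 and digitalisation SD 0.3 (parameter units), sized so that
simulated SEMs fall in the 0.2–3 mm/deg range seen in practice; point
jitter 0.2 mm, matching the sub-millimetre precision of a
fiducial-marker stylus (0.1–0.3 mm depending on axis); and a cell residual
of 0.05, matching the small fit-induced scatter the empirical route
produces at the default sampling density. Marker streams additionally use
anisotropic translational noise of 0.1/0.1/0.3 mm, the depth (optical)
axis of a monocular camera being the least constrained.

## Numerical choices

* Ellipse refinement: BFGS on (centre, angle, log-axes), relative
  objective tolerance 1e-10, at most 200 iterations; non-convergence is an
  error carrying the best iterate. The per-point distance Newton iteration
  runs to 1e-14 with step clamping.
* Circle refinement: radius profiled out; same tolerances.
* Plane fit: SVD of the centred cloud; collinearity detected by the ratio
  of the second singular value to the first (< 1e-10).
* Pivot calibration: SVD solve with a 1e-8 relative rank threshold; the
  reported rms is per residual component, i.e. on the scale of the
  per-axis measurement noise.
* Variance components: EMS truncation at zero happens before the
  components are summed, so the additivity of the total is exact by
  construction.
* Determinism: every stochastic function takes a seed (or inherits the
  caller's RNG state); a study configuration plus seed reproduces every
  generated artefact bit for bit. R's default Mersenne-Twister is used
  throughout.

## Problem sizes used in the shipped checks

The test suite and the acceptance script keep simulations at sizes chosen
to exercise the estimators well while staying quick to run: 100 zero-noise
round-trip contours at 80 points each; 200 replicate 10 x 3 x 3 studies
for ICC recovery (a single parameter column per study is analysed, as the
parameters are generated independently); 25 random clouds for the
plane-fit oracle; 60-pose pivot calibrations at four noise levels. These
sizes were fixed when the checks were written.

## Known limitations

* The shape model is an ellipse lifted onto a sphere; real cartilage rims
  deviate from it, so absolute residual magnitudes from real data carry
  information the synthetic tests cannot calibrate.
* The clavicle anteroposterior axis is thorax-free by construction and may
  be rotated about the medio-lateral axis relative to thorax-referenced
  conventions.
* No outlier handling or duplicate-sample filtering is applied to contour
  clouds: every recorded stylus sample enters the fits with equal weight.
  A stylus held still therefore concentrates weight at one rim location.
* Marker detection and camera calibration are out of scope; the stylus
  module starts from detected marker poses, and marker-to-body transforms
  are taken as given (from file or from the generator), not estimated.
* %SEM depends on an essentially arbitrary reference magnitude for
  near-zero-mean parameters; compare absolute SEMs across studies instead.
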