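---
title: "Regional 3-D morphometry of the scoliotic spine: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional 3-D morphometry of the scoliotic spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The measurement model

Adolescent idiopathic scoliosis (AIS) is a three-dimensional deformity: a
coronal curvature (quantified by the Cobb angle), vertebral axial rotation,
and a sagittal-plane disturbance in which the anterior spinal column becomes
longer than the posterior column ("relative anterior overgrowth"). Because
every vertebra and every endplate of a scoliotic spine is oriented
differently, plain sagittal radiographs cannot measure the anterior--posterior
length difference; it has to be reconstructed endplate by endplate in 3-D.

`spinemorph` implements that reconstruction from per-endplate boundary
contours (36-point loops plus a spinal-canal centroid per endplate, in mm):

1. **Endplate geometry.** Each contour gets a total-least-squares plane
   (smallest principal direction of the centred points), an area-weighted
   polygon centroid, and an anterior--posterior (AP) axis: the in-plane
   direction from the canal centroid toward the endplate centroid. The
   most anterior and most posterior contour vertices are the landmarks with
   extreme scalar projection on that axis.
2. **Heights and lengths.** The anterior height of a vertebra is the
   Euclidean distance between the anterior landmarks of its two endplates;
   disc heights connect the facing endplates of adjacent vertebrae.
   Posterior heights are analogous. Regional anterior/posterior lengths are
   sums of element heights, and the primary statistic is
   \[\Delta(A\!-\!P) = \frac{L_{anterior} - L_{posterior}}{L_{posterior}}
   \times 100\%,\]
   positive when the anterior column is longer (lordosis), negative for
   kyphosis. The identity is exact by construction and asserted in the
   tests to machine precision. Posterior bony elements (pedicles, laminae,
   processes) are not part of the model.
3. **Angles.** The coronal Cobb angle of a curve is the angle between the
   coronal-plane intersection lines of the two end-vertebra endplate planes.
   Axial rotation of an endplate is the signed transverse-plane angle
   between its AP axis and the AP axis of the sacral plate (superior S1
   endplate), right-sided positive; S1 is used as the reference because it
   is not normally part of the idiopathic deformity.
4. **Regions.** Curves are detected from the smoothed per-vertebra coronal
   tilt profile (local extrema are end vertebrae; the apex is the vertebra
   with maximal perpendicular distance from the end-vertebra chord; curves
   under a configurable 10 degree Cobb floor are discarded; clinical end
   vertebrae can be supplied as an override). Each curve contributes its
   span, an apical zone (apical vertebra plus both neighbours and the discs
   between), and - for the thoracic curve - proximal and distal junctional
   segments (end vertebra, one level beyond, disc between). Control
   subjects without curves are measured over the representative segments
   T4-T12 and L1-L5.

### The measurement frame

All metrics are computed in a frame derived from the geometry itself: the
longitudinal axis is the first principal direction of all endplate
centroids (the radiographic patient axis), the anterior axis is the sacral
AP direction orthogonalized to it, and x = y x z points to patient right.
Two consequences are deliberate:

* every reported quantity is **exactly invariant under rigid motion** of
  the input coordinates (asserted under random rigid motions in the tests);
* the "coronal" and "transverse" planes agree with radiographic convention
  for a normally positioned subject, rather than being slaved to the sacral
  endplate orientation - important because lumbar endplates are pitched
  20-40 degrees against the body axis, and a sacrum-normal frame would
  systematically inflate projected Cobb angles.

### Numerical conventions

* Plane normals are flipped into the cranial hemisphere; landmark ties are
  broken by the lowest vertex index; apex ties go to the more cranial
  vertebra. All choices exist solely to make results deterministic.
* The curve detector refines each smoothed-profile extremum to the raw-tilt
  extremum among its immediate neighbours; running-mean smoothing otherwise
  drags shallow caudal minima toward the flat end of the profile.
* Degenerate inputs (collinear contours, coincident centroids, axes
  perpendicular to their projection plane, non-positive posterior lengths)
  raise errors naming the vertebral level rather than propagating NaNs.

## The synthetic cohort generator

No imaging data ships with the package; the generator is the package's
stand-in for a surgical AIS population (77 scoliotic spines, 22 controls)
and is first-class, tested code. A subject is a chain of wedge elements
(vertebrae and discs, T1-S1, heights and endplate ellipse sizes growing
craniocaudally through the adolescent range) stacked from the sacral plate:
each element translates along its local cranial axis and rotates the
running frame by its coronal wedge, sagittal wedge and axial twist.

The generator is *target driven*. Per-subject targets are drawn from the
calibrated configuration (`ais_cohort_config()`, `control_cohort_config()`)
and the wedge profiles are solved so the finished geometry realizes them:

* **Coronal:** the thoracic curve runs T5-T11 (right convex, apex T8); the
  (thoraco)lumbar curve shares the lower thoracic end vertebra, as adjacent
  curves do clinically, and runs to L4 (left convex). Tilt ramps are linear
  with the Cobb target as end-to-end angle. Three margins are calibrated
  per subject so that detection recovers the designed limits: a tilt drop
  across the inter-curve disc, a caudal overshoot below L4, and a
  lumbosacral takeoff lean that keeps the column balanced over the sacrum.
* **Sagittal:** the relative anterior-posterior asymmetry of each element
  follows a raised-cosine bump centred at each apex over a kyphotic
  (thoracic) / lordotic (lumbar) background, with one joint linear solve
  meeting all six regional delta(A-P) targets (curve, apical zone,
  junctional segments) exactly. The smooth two-parameter bump is a modelling
  choice: the emulated study establishes the *pattern* (apex-concentrated
  anterior excess, straight junctions) but no functional form.
* **Axial:** endplate azimuth follows a raised-cosine bump peaking at the
  apex, near zero at the junctions, zero at the sacrum.
* **Calibration loop:** coronal wedges, twist amplitudes and the sagittal
  solve are refined by a damped fixed-point iteration against metrics
  recomputed analytically from the transform chain. Damping (0.6, 10
  iterations) is required because curvature-torsion cross-terms (the
  rotation a twisted, curved column picks up beyond its planned twist) give
  the responses gains above one. Ground truth is always *recomputed from
  the chain*, never copied from the requested targets; the tests assert
  pipeline-vs-truth agreement within 1 degree (angles) and 0.3 points
  (delta).

### Cohort composition

The curve-pattern mix (69% primary thoracic / 8% primary (thoraco)lumbar /
23% double) is apportioned by largest remainder. Per-stratum Cobb,
rotation and delta(A-P) distributions are those of the emulated study's
stratified tables. Because the configuration *is* the calibration, subject
draws use moment-matched deviates (`rnorm_matched()`: exact sample mean and
SD per stratum) and coupling residuals orthogonalized against the
regressor, so a generated calibration cohort reproduces its configured
means and slopes exactly rather than up to sampling noise; individual
subjects remain random. Axial rotation and delta(A-P) are linear in the
simulated standing Cobb angle (0.5 degrees and 0.12 points per degree),
with the standing radiograph Cobb modelled as the internal (prone-CT) Cobb
plus a 5 degree offset and Gaussian noise.

Two constraints shape the joint draws. The compensatory lumbar Cobb is
truncated from below at the tilt the thoracic curve leaves at the shared
end vertebra (plus margin): a lumbar "curve" smaller than that cannot
return the spine toward the sacrum and has no detectable lower end
vertebra. And the junctional delta(A-P) draws are expressed as fractions of
the subject's apical values (capped at 0.8 of the smaller apical delta), so
junctional segments are straighter than apical zones for *every* subject,
not just on average - the qualitative finding the generator emulates.

### What the generator does *not* emulate

Elliptical endplates, a cylindrical canal, no posterior elements, no rib
cage, no vertebral body torsion separate from endplate twist, no growth
dynamics, identical curve layout across subjects (T5-T11/T11-L4 with
per-subject apex shifts only through curve asymmetry). A green cohort test
therefore establishes that the *measurement pipeline* recovers known
regional geometry from raw contours at realistic magnitudes - not that the
generator reproduces real anatomical variability.

## Observer simulation and reliability

`perturb_observer()` models a second trained observer as a smooth random
displacement field along each contour (random Fourier modes up to order 3,
zero mean, isotropic, pointwise SD = `jitter_mm`) plus Gaussian noise on
the canal centroids. Spatially white per-vertex noise was rejected
deliberately: real delineation errors are coherent over sectors of a
boundary, and white noise makes the discrete most-anterior-vertex landmark
jump between vertices across the flat anterior rim of an endplate - a
failure mode no human re-measurement exhibits, which would dominate the
reliability budget with an artefact of the contour discretization.

The calibrated amplitude (0.15 mm, `ais_cohort_config()$observer_jitter_mm`)
reproduces the emulated study's reported measurement quality: replicate
anterior/posterior height error around 0.16 mm (reported: 0.2 mm) and
delta(A-P) ICC(2,1) of 0.98-0.99 between two simulated observers on 10
subjects (reported: 0.97 and above). ICC falls monotonically as the jitter
grows, which the acceptance suite checks empirically.

ICC uses the two-way random-effects, absolute-agreement, single-measures
form. The emulated study names no ICC variant; ICC(2,1) is the standard
choice for interchangeable trained raters, and the implementation is
verified against an independent reference implementation on a fixed table.

## Statistical battery

`run_paper_battery()` applies the study-style analysis to any cohort
table: Welch two-sample t-tests for scoliosis-vs-control contrasts (the
pooled form is available by flag; the emulated analysis does not say
which), one-way ANOVA across curve types with Bonferroni-adjusted pairwise
post hoc tests (family size always k(k-1)/2), paired t-tests for apical
versus junctional segments, and Pearson correlations with least-squares
regression lines for the three-plane couplings. Kolmogorov-Smirnov
normality screens are computed and reported but never switch a test to a
non-parametric variant, matching the all-parametric source analysis. The
sample-size helper uses the two-mean normal-approximation formula; with
means 3.8 and 2.5, SD 2.8, power 80% and two-sided alpha 0.05 it returns
73 per group. (The stated "type II error 0.05" alongside "power 80%" in
the source description is internally inconsistent; the implementation uses
alpha = 0.05 and power = 0.80.)

## Voxel round trip

`rasterize()` converts a spine model into a labelled voxel volume
(vertebra solids swept between their endplate contours and bounded by the
tilted plate planes, a sacrum block, a canal tube), and
`extract_contours()` recovers endplate contours from the label map alone:
per-label cap surfaces are isolated along the local chain axis, trimmed
one-sidedly (projection-overhang voxels always lie below the true plate),
refined on the full voxel cloud, and the boundary is the arc-length
resampled convex hull. At 0.6 mm spacing a straight spine round-trips with
|delta(A-P)| < 0.3 points and AP-projected landmark errors below one voxel
diagonal; a 60 degree scoliotic subject round-trips its Cobb angle within
a fraction of a degree. This path emulates working from a labelled CT
segmentation rather than from contours directly; NIfTI file export is not
provided because no NIfTI library is available in the supported
environment - the labelled volume is an in-memory object.

## Known limitations

* Curve layout is fixed at T5-T11 / T11-L4; the detector handles other
  layouts, but the generator does not produce them.
* The junctional rotation profile is qualitative (not calibrated); only
  junctional delta(A-P) is a recovery target.
* At extreme parameter combinations (thoracic Cobb near 85 degrees with a
  minimal compensatory curve) the lumbar lower end vertebra can become
  genuinely ambiguous between L4 and L5; one or two subjects per arbitrary
  seed may be measured over a one-level-longer lumbar span. Cohort-level
  recovery is unaffected.
* delta(A-P) compares column lengths, not arc lengths; this matches the
  landmark-summation definition it implements.
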