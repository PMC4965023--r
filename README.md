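# spinemorph

Three-dimensional regional morphometry of the scoliotic spine.

## The problem

Adolescent idiopathic scoliosis (AIS) is a 3-D deformity: a coronal
curvature (Cobb angle), vertebral axial rotation, and a sagittal
disturbance in which the anterior spinal column outgrows the posterior
one. Whether this "anterior overgrowth" affects the whole spine or only
parts of it can only be decided by measuring each region separately in
3-D — primary curve, compensatory curve, apical zones, and the junctional
segments in between — because every endplate of a scoliotic spine points
in a different direction.

`spinemorph` is an R package for researchers in spinal deformity and
morphometry. From per-endplate boundary contours (3-D point loops plus a
spinal-canal centroid, mm) it computes, per region:

* **Δ(A-P)** = (anterior length − posterior length) / posterior length ×
  100%, where lengths are sums of per-vertebra and per-disc distances
  between "true" anterior (posterior) endplate landmarks — the landmark
  with extreme projection on each endplate's anterior–posterior axis (the
  in-plane line through the canal and endplate centroids);
* the **coronal Cobb angle** between the end-vertebra endplate planes,
  projected on the coronal plane;
* **axial rotation** of each endplate relative to the sacral plate in the
  transverse plane, right-sided positive (apex rotation summarises a
  curve).

Because no imaging data can ship with the package, a parametric synthetic
cohort generator with exact ground truth stands in for a surgical AIS
population (77 scoliotic + 22 control spines): wedge-shaped vertebrae and
discs whose anterior–posterior asymmetry is concentrated at the curve
apices and absent at the junctions, coronal curvature per curve pattern,
axial rotation coupled to curve size, and a smooth observer-jitter model
for reliability studies. The full statistical battery of a cohort study
(Welch/pooled t, one-way ANOVA + Bonferroni, paired t, Pearson +
regression, ICC(2,1), sample size) is included.

## Worked example

```r
library(spinemorph)

ais <- generate_cohort(ais_cohort_config(n = 77, seed = 20160728))
ctl <- generate_cohort(control_cohort_config(n = 22, seed = 20160729))
tbl <- measure_cohort(c(ais$subjects, ctl$subjects))

aggregate(cbind(delta_ap_percent, axial_rotation_deg) ~ region, tbl, mean)
#>                region delta_ap_percent axial_rotation_deg
#> 1       apical_lumbar           11.200             -8.747
#> 2     apical_thoracic            7.129             24.602
#> 3   distal_junctional            0.869             -0.312
#> 4         lumbar_L1L5            7.800             -1.152
#> 5       main_thoracic            3.873             24.602
#> 6 proximal_junctional           -1.297              4.401
#> 7      thoracic_T4T12           -4.100              0.841
#> 8       thoracolumbar            9.426             -8.747
```

The scoliotic thoracic spine is anteriorly longer (+3.9%) where the
matched control segment is kyphotic (−4.1%); the excess concentrates in
the apical zones (+7.1% thoracic, +11.2% lumbar) while the junctional
segments stay nearly straight (−1.3%, +0.9%) — the regional pattern the
pipeline is built to resolve. The study-style battery:

```r
rep <- run_paper_battery(tbl)
rep$group_comparisons$thoracic_delta_ap
#> two-sample t (Welch): statistic 16.49, df 48.285, p 1.793e-21 (none)
#>   group means: 3.873 +/- 2.580, -4.100 +/- 1.800
rep$couplings$standing_vs_rotation
#> r = 0.863 (p = 5.93e-24), y = -7.706 + 0.508 x  [slope 95% CI 0.439..0.576], n = 77
rep$couplings$per_10deg
#> rotation  delta_ap
#> 5.08      1.18
```

i.e. every 10° of standing Cobb angle carries ≈5° more apex rotation and
≈1.2 points more anterior excess. A single subject:

```r
measure_subject(ais$subjects[[1]]$spine)
#>                region upper_end lower_end apex cobb_deg axial_rotation_deg delta_ap_percent
#> 1       main_thoracic        T5       T11   T8    65.56              32.36            5.398
#> 2     apical_thoracic        T7        T9   T8    27.69              32.36            8.922
#> 3 proximal_junctional        T4        T5 <NA>     3.03               9.24           -0.701
#> 4   distal_junctional       T11       T12 <NA>     2.61               5.82            0.524
#> 5       thoracolumbar       T11        L4   L2    33.74              -2.60            3.236
#> 6       apical_lumbar        L1        L3   L2    19.62              -2.60            8.521
```

Contour JSON I/O (`write_spine()` / `read_spine()`, schema in
`inst/extdata/contour-schema.json`), a voxel round trip
(`rasterize()` / `extract_contours()`), observer simulation
(`perturb_observer()`) and a CLI (`generate`, `measure`, `stats`,
`reproduce`; see `inst/cli/spinemorph`) are documented in the package help
and the vignette `vignettes/regional-spine-morphometry.Rmd`.

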