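Package: spinemorph
Title: Three-Dimensional Regional Morphometry of the Scoliotic Spine
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Endplate-based three-dimensional spinal morphometry for
    adolescent idiopathic scoliosis research. Computes coronal Cobb angles,
    vertebral axial rotation relative to the sacral plate, and the relative
    anterior-posterior length discrepancy (delta(A-P)) of primary curves,
    compensatory curves, apical zones and junctional segments from
    per-endplate boundary contours, together with a parametric synthetic
    cohort generator with exact ground truth, a voxel round-trip
    (rasterize/extract) path, and the accompanying statistical battery
    (t-tests, one-way ANOVA with Bonferroni post hoc, paired tests,
    Pearson correlation with linear regression, ICC(2,1), sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
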