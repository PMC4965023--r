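# Voxel round trip: rasterize a spine, recover the contours from the label
# map alone, and re-measure. Run at the scanner-like 0.6 mm spacing for the
# straight reference and at 0.9 mm for the scoliotic subject to keep the
# suite fast.

test_that("straight spine survives the voxel round trip", {
  subj <- straight_subject()
  vol <- rasterize(subj$spine, spacing = 0.6)
  nlab <- length(setdiff(unique(as.integer(vol$labels)), 0L))
  # one label per vertebra incl. the sacrum, plus the canal
  expect_identical(nlab, length(subj$spine$levels) + 2L)
  expect_gt(sum(vol$labels == vol$canal_label), 0)

  cts <- extract_contours(vol)
  back <- spine_model(cts, validate = FALSE)
  m <- measure_subject(back)
  expect_lt(max(abs(m$delta_ap_percent)), 0.5)

  # landmark error along the measurement (AP) axis within one voxel diagonal
  diag <- vol$spacing * sqrt(3)
  errs <- unlist(lapply(names(subj$spine$vertebrae), function(lv) {
    vapply(c("superior", "inferior"), function(sd) {
      g1 <- subj$spine$vertebrae[[lv]][[sd]]
      g2 <- back$vertebrae[[lv]][[sd]]
      max(abs(sum((g1$anterior_point - g2$anterior_point) * g1$ap_axis)),
          abs(sum((g1$posterior_point - g2$posterior_point) * g1$ap_axis)))
    }, 0)
  }))
  expect_lt(max(errs), diag)
})

test_that("scoliotic subject: round-trip Cobb within 2 degrees of the contour path", {
  subj <- thoracic_subject()
  vol <- rasterize(subj$spine, spacing = 0.9)
  back <- spine_model(extract_contours(vol), validate = FALSE)
  m1 <- measure_subject(subj$spine)
  m2 <- measure_subject(back)
  m2 <- m2[match(m1$region, m2$region), ]
  curves <- m1$region %in% c("main_thoracic", "thoracolumbar")
  expect_lt(max(abs(m2$cobb_deg[curves] - m1$cobb_deg[curves])), 2)
  expect_lt(max(abs(m2$delta_ap_percent[curves] - m1$delta_ap_percent[curves])), 2)
  expect_identical(m2$apex[m1$region == "main_thoracic"],
                   m1$apex[m1$region == "main_thoracic"])
})

test_that("rasterize rejects sub-scanner spacings", {
  expect_error(rasterize(straight_subject()$spine, spacing = 0.2), ">= 0.3")
})
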