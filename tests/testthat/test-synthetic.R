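# Generator: self-consistency of ground truth, determinism, cohort
# composition, observer jitter.

test_that("a zero-parameter subject is perfectly straight", {
  m <- measure_subject(straight_subject()$spine)
  expect_equal(m$delta_ap_percent, rep(0, nrow(m)), tolerance = 1e-9)
  expect_equal(m$axial_rotation_deg, rep(0, nrow(m)), tolerance = 1e-9)
  expect_equal(m$cobb_deg, rep(0, nrow(m)), tolerance = 1e-9)
})

test_that("sagittal-only control subject realizes the requested profile", {
  m <- measure_subject(control_subject()$spine)
  expect_equal(m$delta_ap_percent[m$region == "lumbar_L1L5"], 7.8,
               tolerance = 0.2 / 7.8)
  expect_equal(m$delta_ap_percent[m$region == "thoracic_T4T12"], -4.1,
               tolerance = 0.2 / 4.1)
})

test_that("pipeline measurements equal ground truth within stated tolerances", {
  for (subj in list(thoracic_subject(), double_subject(),
                    cached_subject("fix_lumbar", ais_test_params("lumbar")))) {
    m <- measure_subject(subj$spine)
    tr <- subj$truth$regions
    m <- m[match(tr$region, m$region), ]
    expect_identical(m$apex, tr$apex)
    expect_lt(max(abs(m$cobb_deg - tr$cobb_deg)), 1)
    expect_lt(max(abs(m$axial_rotation_deg - tr$axial_rotation_deg)), 1)
    expect_lt(max(abs(m$delta_ap_percent - tr$delta_ap_percent)), 0.3)
  }
})

test_that("calibration drives geometry to the requested targets", {
  subj <- thoracic_subject()
  tr <- subj$truth$regions
  prm <- subj$truth$params
  expect_equal(tr$cobb_deg[tr$region == "main_thoracic"], prm$C_T, tolerance = 0.02)
  expect_equal(tr$axial_rotation_deg[tr$region == "main_thoracic"], prm$R_T,
               tolerance = 0.02)
  expect_equal(tr$delta_ap_percent[tr$region == "main_thoracic"], prm$d_mt,
               tolerance = 0.01)
  expect_equal(tr$delta_ap_percent[tr$region == "apical_lumbar"], prm$d_al,
               tolerance = 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generate_cohort(ais_cohort_config(2, seed = 123))
  c2 <- generate_cohort(ais_cohort_config(2, seed = 123))
  expect_identical(
    lapply(c1$subjects, function(s) lapply(s$contours, `[[`, "points")),
    lapply(c2$subjects, function(s) lapply(s$contours, `[[`, "points"))
  )
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(ais_cohort_config(2, seed = 124))
  expect_false(identical(c1$truth$delta_ap_percent, c3$truth$delta_ap_percent))
})

test_that("generate_cohort preserves the caller's RNG state", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(ais_cohort_config(2, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("curve-pattern mix follows the configured proportions", {
  coh <- generate_cohort(ais_cohort_config(77, seed = 3))
  counts <- table(vapply(coh$subjects, `[[`, "", "pattern"))
  expect_equal(unname(counts[c("thoracic", "lumbar", "double")]),
               c(53, 6, 18), ignore_attr = TRUE)
})

test_that("moment matching makes stratum means exact", {
  set.seed(7)
  x <- rnorm_matched(40, 10, 3)
  expect_equal(mean(x), 10, tolerance = 1e-12)
  expect_equal(sd(x), 3, tolerance = 1e-12)
  expect_identical(rnorm_matched(1, 5, 2), 5)
})

test_that("observer jitter is unbiased plumbing: zero is identity, seeds reproduce", {
  subj <- control_subject()
  expect_identical(perturb_observer(subj$spine, 0), subj$spine)
  j1 <- perturb_observer(subj$spine, 0.3, seed = 42)
  j2 <- perturb_observer(subj$spine, 0.3, seed = 42)
  expect_equal(spine_contours(j1)[["T5 superior"]]$points,
               spine_contours(j2)[["T5 superior"]]$points)
  expect_false(isTRUE(all.equal(spine_contours(j1)[["T5 superior"]]$points,
                                spine_contours(subj$spine)[["T5 superior"]]$points)))
  expect_error(perturb_observer(subj$spine, -1), ">= 0")
  # heavy jitter must actually disturb the measured metrics
  m0 <- measure_subject(subj$spine)
  m5 <- measure_subject(perturb_observer(subj$spine, 2, seed = 1))
  expect_gt(max(abs(m5$delta_ap_percent - m0$delta_ap_percent)), 0.1)
})

test_that("invalid generator input fails loudly", {
  bad <- ais_test_params()
  bad$C_T <- 170   # tilts beyond fold-over
  expect_error(generate_subject(bad), "non-monotone|invalid")
})
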