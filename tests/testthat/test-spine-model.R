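# Contour validation, model assembly invariants, and rigid-motion behaviour.

make_ring <- function(level = "T8", side = "superior", centre = c(0, 0, 100),
                      a = 15, b = 11, n = 36) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(a * cos(phi) + centre[1], b * sin(phi) + centre[2],
               rep(centre[3], n))
  endplate_contour(level, side, pts, centre + c(0, -(b + 6), 0))
}

test_that("contour validation enforces planarity, canal side and simplicity", {
  expect_s3_class(make_ring(), "endplate_contour")

  phi <- seq(0, 2 * pi, length.out = 37)[-37]
  warped <- cbind(15 * cos(phi), 11 * sin(phi), 2 * sin(2 * phi))
  expect_error(endplate_contour("T8", "superior", warped, c(0, -17, 0)),
               "not planar")

  pts <- cbind(15 * cos(phi), 11 * sin(phi), 0)
  expect_error(endplate_contour("T8", "superior", pts, c(0, 3, 0)),
               "inside the endplate boundary")

  bow <- rbind(c(0, 0, 0), c(2, 2, 0), c(2, 0, 0), c(0, 2, 0),
               cbind(-1 - (1:8) / 8, seq(2, 0, length.out = 8), 0))
  expect_error(endplate_contour("T8", "superior", bow, c(0.5, -9, 0)),
               "self-intersects")

  expect_error(endplate_contour("T9", "superior", pts[1:8, ], c(0, -17, 0)),
               ">= 12 points")
  expect_error(endplate_contour("X4", "superior", pts, c(0, -17, 0)))
})

test_that("spine_model enforces structural invariants", {
  spine <- straight_subject()$spine
  contours <- spine_contours(spine)

  expect_error(spine_model(contours[names(contours) != "S1 superior"],
                           validate = FALSE), "sacral plate")
  expect_error(spine_model(contours[names(contours) != "T6 inferior"],
                           validate = FALSE), "T6")
  # duplicated contour
  expect_error(spine_model(c(contours, contours["T5 superior"]),
                           validate = FALSE), "duplicate")

  m <- spine_model(contours, validate = FALSE)
  expect_s3_class(m, "spine_model")
  expect_identical(m$levels, c(paste0("T", 1:12), paste0("L", 1:5)))
  expect_output(print(m), "spine_model")
})

test_that("every metric is invariant under rigid motion of the subject", {
  subj <- thoracic_subject()
  base <- measure_subject(subj$spine)
  set.seed(33)
  for (rep in 1:3) {
    R <- random_rotation()
    t <- rnorm(3, 0, 100)
    moved <- rigid_transform_spine(subj$spine, R, t)
    m <- measure_subject(moved)
    expect_equal(m[measured_cols], base[measured_cols], tolerance = 1e-6)
    expect_identical(m$apex, base$apex)
    expect_identical(m$upper_end, base$upper_end)
  }
})

test_that("axial rotations are referenced to the transformed sacral axis", {
  subj <- control_subject()
  base <- measure_subject(subj$spine)
  a <- 40 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  m <- measure_subject(rigid_transform_spine(subj$spine, Rz, c(5, -3, 12)))
  expect_equal(m$axial_rotation_deg, base$axial_rotation_deg, tolerance = 1e-6)
})
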