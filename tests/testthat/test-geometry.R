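# Per-endplate geometric primitives against closed-form and brute-force
# oracles.

test_that("fit_endplate_plane recovers exact planes and orients to +z", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_endplate_plane(sq)
  expect_equal(pl$point, c(0.5, 0.5, 0))
  expect_equal(pl$normal, c(0, 0, 1))

  a <- 30 * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  pl2 <- fit_endplate_plane(sq %*% t(rot))
  expect_equal(pl2$normal, c(0, -sin(a), cos(a)), tolerance = 1e-12)

  # normal always flipped into the +z hemisphere
  expect_gte(fit_endplate_plane(sq %*% t(rot) * -1)$normal[3], 0)
})

test_that("fit_endplate_plane matches an eigen-decomposition oracle on noisy data", {
  set.seed(11)
  a <- 20 * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  truth_normal <- as.numeric(rot %*% c(0, 0, 1))
  phi <- runif(40, 0, 2 * pi); r <- runif(40, 5, 15)
  pts <- cbind(r * cos(phi), r * sin(phi), 0) %*% t(rot) +
    matrix(rnorm(120, 0, 0.3), 40, 3)
  pl <- fit_endplate_plane(pts)
  # independent oracle: smallest eigenvector of the covariance matrix
  ev <- eigen(stats::cov(pts))$vectors[, 3]
  if (ev[3] < 0) ev <- -ev
  expect_equal(pl$normal, ev, tolerance = 1e-8)
  ang <- acos(abs(sum(pl$normal * truth_normal))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("plane fit residual and normal error shrink as noise vanishes", {
  set.seed(12)
  phi <- seq(0, 2 * pi, length.out = 41)[-41]
  base <- cbind(15 * cos(phi), 11 * sin(phi), 0)
  errs <- vapply(c(1, 0.3, 0.1, 0.01), function(s) {
    pts <- base + matrix(rnorm(120, 0, s), 40, 3)
    pl <- fit_endplate_plane(pts)
    acos(abs(pl$normal[3])) * 180 / pi
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate point sets raise named errors", {
  line <- cbind(1:5, 2 * (1:5), 0)
  expect_error(fit_endplate_plane(line, level = "T7"),
               "degenerate geometry at level T7")
  expect_error(fit_endplate_plane(matrix(1, 5, 3)), "degenerate")
})

test_that("contour_centroid is the area centroid, not the vertex mean", {
  phi <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(15 * cos(phi), 15 * sin(phi), 0)
  expect_equal(contour_centroid(circ), c(0, 0, 0), tolerance = 1e-9)

  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(contour_centroid(sq), c(1, 1, 0))

  # L-shaped polygon; oracle = rectangle decomposition:
  # [0,2]x[0,1] area 2 centroid (1, .5); [0,1]x[1,2] area 1 centroid (.5, 1.5)
  L <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(1, 1, 0), c(1, 2, 0), c(0, 2, 0))
  expect_equal(contour_centroid(L), c(2.5 / 3, 2.5 / 3, 0), tolerance = 1e-12)
  # vertex mean would be (1, 1): must differ
  expect_false(isTRUE(all.equal(contour_centroid(L)[1], 1)))

  # uneven vertex spacing must not bias the centroid
  dense <- rbind(cbind(seq(0, 2, length.out = 30), 0, 0)[-30, ],
                 c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(contour_centroid(dense), c(1, 1, 0), tolerance = 1e-9)
})

test_that("ap_axis projects the canal-to-centroid direction into the plane", {
  expect_equal(ap_axis(c(0, 0, 0), c(0, -20, 0), c(0, 0, 1)), c(0, 1, 0))

  a <- 20 * pi / 180
  n <- c(0, -sin(a), cos(a))
  # Gram-Schmidt oracle
  v <- c(0, 1, 0); v_expect <- v - sum(v * n) * n
  v_expect <- v_expect / sqrt(sum(v_expect^2))
  expect_equal(ap_axis(c(0, 0, 0), c(0, -20, 0), n), v_expect, tolerance = 1e-12)
  expect_lt(abs(sum(ap_axis(c(0, 0, 0), c(0, -20, 0), n) * n)), 1e-9)

  d <- c(-5, 18, 0) / sqrt(25 + 324)
  expect_equal(ap_axis(c(0, 0, 0), c(5, -18, 0), c(0, 0, 1)), d, tolerance = 1e-12)

  expect_error(ap_axis(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)), "coincide")
  expect_error(ap_axis(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1)), "perpendicular")
})

test_that("extreme_points equals the exhaustive brute-force scan", {
  phi <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(15 * cos(phi), 15 * sin(phi), 0)
  ext <- extreme_points(circ, c(0, 1, 0))
  expect_equal(ext$anterior, c(0, 15, 0), tolerance = 1e-12)
  expect_equal(ext$posterior, c(0, -15, 0), tolerance = 1e-12)

  ell <- cbind(20 * cos(phi), 15 * sin(phi), 0)
  expect_equal(extreme_points(ell, c(0, 1, 0))$anterior, c(0, 15, 0),
               tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    poly <- cbind(rnorm(50), rnorm(50), rnorm(50))
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ext <- extreme_points(poly, axis)
    # brute force over all vertices
    s <- apply(poly, 1, function(p) sum(p * axis))
    expect_equal(ext$anterior_index, which.max(s))
    expect_equal(ext$posterior_index, which.min(s))
  }
})

test_that("axial_rotation sign convention and antisymmetry hold", {
  y <- c(0, 1, 0)
  expect_equal(axial_rotation(y, y), 0)
  # 24 deg clockwise viewed from cranial = anterior tip toward patient right
  a <- 24 * pi / 180
  ax <- c(sin(a), cos(a), 0)
  expect_equal(axial_rotation(ax, y), 24, tolerance = 1e-12)
  b <- -9 * pi / 180
  expect_equal(axial_rotation(c(sin(b), cos(b), 0), y), -9, tolerance = 1e-12)

  set.seed(22)
  for (rep in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    u[3] <- u[3] / 4; v[3] <- v[3] / 4
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    expect_equal(axial_rotation(u, u), 0, tolerance = 1e-9)
    expect_equal(axial_rotation(u, v), -axial_rotation(v, u), tolerance = 1e-9)
  }
  expect_error(axial_rotation(c(0, 0, 1), y), "degenerate projection")
})

test_that("coronal_cobb measures the projected endplate line angle", {
  horiz <- list(plane_normal = c(0, 0, 1))
  expect_equal(coronal_cobb(horiz, horiz), 0)
  tilt <- function(deg) {
    a <- deg * pi / 180
    list(plane_normal = c(sin(a), 0, cos(a)))
  }
  expect_equal(coronal_cobb(tilt(29), tilt(-29)), 58, tolerance = 1e-9)
  expect_equal(coronal_cobb(tilt(10), tilt(25)), 15, tolerance = 1e-9)
  expect_error(coronal_cobb(list(plane_normal = c(0, 1, 0)), horiz),
               "degenerate projection")
})
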