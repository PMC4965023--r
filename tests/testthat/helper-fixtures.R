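# Shared fixtures: parameter sets for single synthetic subjects and small
# caches so expensive cohorts are generated once per test file.

ais_test_params <- function(pattern = "thoracic") {
  base <- list(
    group = "ais", pattern = pattern,
    upper_t = "T5", lower_t = "T11", lower_l = "L4",
    d_at = 7.1, d_al = 11.2, d_jp = -1.3, d_jd = 1.0,
    r_p = 5, r_d = -1, delta_upper = -4.1, delta_lower = 7.8
  )
  extra <- switch(pattern,
    thoracic = list(C_T = 60, C_L = 32, R_T = 26, R_L = -4,
                    d_mt = 4.2, d_tl = 8.6, S_T = 65, S_L = 37),
    lumbar = list(C_T = 40, C_L = 57, R_T = 14, R_L = -20,
                  d_mt = 1.8, d_tl = 10.8, S_T = 45, S_L = 62),
    double = list(C_T = 61, C_L = 55, R_T = 24, R_L = -19,
                  d_mt = 3.6, d_tl = 11.4, S_T = 66, S_L = 60)
  )
  c(base, extra)
}

control_test_params <- function(d_t = -4.1, d_l = 7.8, rot_t = 1, rot_l = -1) {
  list(group = "control", d_t = d_t, d_l = d_l, rot_t = rot_t, rot_l = rot_l)
}

straight_params <- function() control_test_params(0, 0, 0, 0)

# memoised single subjects (constructed once per test file run)
.fixture_cache <- new.env(parent = emptyenv())

cached_subject <- function(key, params) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_subject(params, subject_id = key)
  }
  .fixture_cache[[key]]
}

thoracic_subject <- function() cached_subject("fix_thoracic", ais_test_params("thoracic"))
double_subject <- function() cached_subject("fix_double", ais_test_params("double"))
straight_subject <- function() cached_subject("fix_straight", straight_params())
control_subject <- function() cached_subject("fix_control", control_test_params())

# apply a rigid motion to every contour of a spine model (in its stored
# frame) and rebuild the model from the transformed contours
rigid_transform_spine <- function(spine, R, t) {
  contours <- lapply(spine_contours(spine), function(ct) {
    ct$points <- sweep(ct$points %*% t(R), 2, t, "+")
    ct$canal_centroid <- as.numeric(R %*% ct$canal_centroid + t)
    ct
  })
  spine_model(contours, subject_id = spine$subject_id, validate = FALSE)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

measured_cols <- c("cobb_deg", "axial_rotation_deg", "anterior_mm",
                   "posterior_mm", "delta_ap_percent")
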