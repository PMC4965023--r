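# Parametric generator of scoliotic and control spines with exact ground
# truth. A subject is a chain of wedge elements (vertebrae and discs) stacked
# from the sacral plate upward: each element translates the running frame
# along its local cranial axis by its height and rotates it by its coronal
# wedge, sagittal wedge and axial twist. Elliptical endplate contours and
# canal centroids are emitted in the world frame.
#
# The generator is target-driven: per-subject regional targets (Cobb, apex
# rotation, regional delta(A-P)) are drawn from the calibrated cohort
# configuration and the wedge profiles are solved - then refined by a short
# fixed-point calibration against the analytically reconstructed chain - so
# that the stated targets are realized exactly by the geometry. Ground truth
# is recomputed from the transform chain, never copied from the draw.

CONTOUR_POINTS <- 36L

#' Per-level anatomical dimensions used by the generator
#'
#' Heights and endplate ellipse semi-axes (mm) increase craniocaudally in the
#' range of adolescent anatomy; the canal centroid sits posterior to the
#' endplate centroid by the endplate AP semi-axis plus a fixed canal gap.
#'
#' @return data.frame with one row per level T1..L5 and S1: `level`,
#'   `height` (vertebral body), `disc_below` (disc to the next caudal level),
#'   `a` (lateral semi-axis), `b` (AP semi-axis), `canal_offset`.
#' @export
spine_dimensions <- function() {
  lv <- c(paste0("T", 1:12), paste0("L", 1:5), "S1")
  height <- c(seq(16, 22, length.out = 12), seq(25, 28, length.out = 5), 30)
  disc <- c(rep(4.5, 11), 6, rep(9, 4), 10, NA)
  a <- c(seq(13, 16.5, length.out = 12), seq(17, 19, length.out = 5), 19.5)
  b <- c(seq(9.5, 12, length.out = 12), seq(12.5, 14.5, length.out = 5), 15)
  data.frame(level = lv, height = height, disc_below = disc,
             a = a, b = b, canal_offset = b + 6, stringsAsFactors = FALSE)
}

# Plate/element scaffolding, caudal -> cranial. Plates: S1 superior, then
# inferior+superior of each vertebra L5..T1. Elements connect consecutive
# plates, alternating disc / vertebra.
make_layout <- function() {
  dims <- spine_dimensions()
  rownames(dims) <- dims$level
  vlv <- rev(setdiff(dims$level, "S1"))      # L5 .. T1
  plate_level <- c("S1", rep(vlv, each = 2))
  plate_side <- c("superior", rep(c("inferior", "superior"), length(vlv)))
  np <- length(plate_level)
  plates <- data.frame(
    level = plate_level, side = plate_side,
    a = dims[plate_level, "a"], b = dims[plate_level, "b"],
    canal_offset = dims[plate_level, "canal_offset"],
    stringsAsFactors = FALSE
  )
  el_id <- character(np - 1); el_type <- character(np - 1); el_h <- numeric(np - 1)
  for (i in seq_len(np - 1)) {
    lo <- plates[i, ]; hi <- plates[i + 1, ]
    if (lo$level == hi$level) {
      el_id[i] <- lo$level; el_type[i] <- "vertebra"
      el_h[i] <- dims[lo$level, "height"]
    } else {
      el_id[i] <- paste0(hi$level, "-", lo$level); el_type[i] <- "disc"
      el_h[i] <- dims[hi$level, "disc_below"]
    }
  }
  elements <- data.frame(
    id = el_id, type = el_type, h = el_h,
    lower_plate = seq_len(np - 1), upper_plate = seq_len(np - 1) + 1,
    b_low = plates$b[seq_len(np - 1)], b_up = plates$b[seq_len(np - 1) + 1],
    stringsAsFactors = FALSE
  )
  list(plates = plates, elements = elements,
       levels = rev(vlv),                       # cranial -> caudal, T1..L5
       plate_key = paste(plates$level, plates$side))
}

plate_index <- function(layout, level, side) {
  match(paste(level, side), layout$plate_key)
}

element_index <- function(layout, ids) {
  match(ids, layout$elements$id)
}

# Raised-cosine bump on positions `pos`: 1 at `center`, 0 at `center - left`
# and `center + right`, 0 outside.
raised_bump <- function(pos, center, left, right) {
  x <- pos - center
  side <- ifelse(x < 0, left, right)
  out <- (1 + cos(pi * pmin(1, abs(x) / side))) / 2
  out[abs(x) >= side] <- 0
  out
}

# Compose the frame chain from the sacral plate upward. Each element applies
# half its rotation, translates along the intermediate local cranial axis,
# then applies the other half; this keeps wedges symmetric about the element
# mid-plane. theta = sagittal wedge (anterior-taller positive), gamma =
# coronal wedge, tau = axial twist, all radians.
build_chain <- function(layout, theta, gamma, tau) {
  np <- nrow(layout$plates)
  p <- matrix(0, 3, np)
  Q <- vector("list", np)
  Q[[1]] <- diag(3)
  for (e in seq_len(np - 1)) {
    half <- rot_y(gamma[e] / 2) %*% rot_x(theta[e] / 2) %*% rot_z(tau[e] / 2)
    Qm <- Q[[e]] %*% half
    p[, e + 1] <- p[, e] + Qm %*% c(0, 0, layout$elements$h[e])
    Q[[e + 1]] <- Qm %*% half
  }
  if (any(diff(p[3, ]) <= 0)) {
    stop("invalid parameters: frame composition produced non-monotone height",
         call. = FALSE)
  }
  list(p = p, Q = Q)
}

# Re-express a raw chain in the same measurement frame the pipeline anchors
# to: longitudinal axis = first principal direction of the plate centroids,
# anterior axis = sacral canal-to-centroid direction orthogonalized to it.
reframe_chain <- function(chain) {
  p <- chain$p
  x0 <- sweep(t(p), 2, rowMeans(p))
  z <- svd(x0, nu = 0, nv = 1)$v[, 1]
  if (sum((rowMeans(p) - p[, 1]) * z) < 0) z <- -z
  y_raw <- c(0, 1, 0)                      # sacral AP axis in build coordinates
  y <- y_raw - sum(y_raw * z) * z
  y <- y / sqrt(sum(y * y))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  R <- t(cbind(x, y, z))
  list(p = R %*% (p - p[, 1]), Q = lapply(chain$Q, function(Qi) R %*% Qi))
}

# Analytic plate landmarks straight from the chain (no contours): anterior /
# posterior points, plate normals, transverse-plane azimuth of the AP axis.
chain_landmarks <- function(layout, chain) {
  np <- nrow(layout$plates)
  ant <- matrix(0, 3, np); post <- matrix(0, 3, np)
  normal <- matrix(0, 3, np); az <- numeric(np)
  for (i in seq_len(np)) {
    Q <- chain$Q[[i]]; b <- layout$plates$b[i]
    ant[, i] <- chain$p[, i] + Q %*% c(0, b, 0)
    post[, i] <- chain$p[, i] - Q %*% c(0, b, 0)
    normal[, i] <- Q[, 3]
    y <- Q[, 2]
    az[i] <- atan2(y[1], y[2]) * DEG    # right positive, vs sacral +y
  }
  list(anterior = ant, posterior = post, normal = normal, azimuth = az)
}

chain_element_heights <- function(layout, lm) {
  el <- layout$elements
  antd <- sqrt(colSums((lm$anterior[, el$upper_plate] - lm$anterior[, el$lower_plate])^2))
  postd <- sqrt(colSums((lm$posterior[, el$upper_plate] - lm$posterior[, el$lower_plate])^2))
  data.frame(id = el$id, type = el$type, anterior_mm = antd, posterior_mm = postd,
             stringsAsFactors = FALSE)
}

chain_cobb <- function(layout, lm, upper_level, lower_level) {
  iu <- plate_index(layout, upper_level, "superior")
  il <- plate_index(layout, lower_level, "inferior")
  coronal_cobb(list(plane_normal = lm$normal[, iu]),
               list(plane_normal = lm$normal[, il]))
}

chain_vertebra_rotation <- function(layout, lm, level) {
  (lm$azimuth[plate_index(layout, level, "superior")] +
     lm$azimuth[plate_index(layout, level, "inferior")]) / 2
}

chain_mean_rotation <- function(layout, lm, levels) {
  idx <- c(vapply(levels, plate_index, 0L, layout = layout, side = "superior"),
           vapply(levels, plate_index, 0L, layout = layout, side = "inferior"))
  mean(lm$azimuth[idx])
}

# Apex of a curve on the chain: vertebra with the largest lateral offset from
# the end-vertebra chord in coronal projection (ties -> more cranial).
chain_apex <- function(layout, chain, upper_level, lower_level) {
  lv <- layout$levels
  i1 <- match(upper_level, lv); i2 <- match(lower_level, lv)
  cen <- vapply(i1:i2, function(i) {
    (chain$p[, plate_index(layout, lv[i], "superior")] +
       chain$p[, plate_index(layout, lv[i], "inferior")]) / 2
  }, numeric(3))
  a <- cen[c(1, 3), 1]; bb <- cen[c(1, 3), ncol(cen)]
  chord <- (bb - a) / sqrt(sum((bb - a)^2))
  dev <- vapply(seq_len(ncol(cen)), function(j) {
    d <- cen[c(1, 3), j] - a
    off <- d - sum(d * chord) * chord
    off[1]
  }, 0)
  lv[(i1:i2)[which.max(abs(dev))]]
}

# level offset helper: the level `offset` positions caudal of `level`
lvl_at <- function(layout, level, offset) {
  layout$levels[match(level, layout$levels) + offset]
}

delta_to_mean_w <- function(delta_percent) {
  d <- delta_percent / 100
  d / (1 + d / 2)
}

region_delta_from_heights <- function(heights, ids) {
  rows <- heights[match(ids, heights$id), ]
  delta_ap(sum(rows$anterior_mm), sum(rows$posterior_mm))
}

# ---------------------------------------------------------------------------
# Wedge-profile construction for one scoliotic subject

# Solve w = c + W * bump over a curve span so that the height-weighted mean w
# equals the target over the whole span and over the apical zone. Elements of
# the apical zone outside the span contribute their (known) baseline w.
solve_curve_profile <- function(layout, span_ids, apical_ids, bump, w_known,
                                m_span, m_apical) {
  el <- layout$elements
  hs <- el$h[element_index(layout, span_ids)]
  A <- matrix(0, 2, 2); rhs <- numeric(2)
  A[1, ] <- c(sum(hs), sum(hs * bump))
  rhs[1] <- m_span * sum(hs)
  ia <- element_index(layout, apical_ids)
  in_span <- apical_ids %in% span_ids
  ha <- el$h[ia]
  A[2, ] <- c(sum(ha[in_span]), sum(ha[in_span] * bump[match(apical_ids[in_span], span_ids)]))
  rhs[2] <- m_apical * sum(ha) - sum(ha[!in_span] * w_known[ia[!in_span]])
  sol <- solve(A, rhs)
  list(c = sol[1], W = sol[2])
}

# AIS tilt/azimuth/wedge profiles for one subject; `state` carries the
# calibration-adjusted quantities. The thoracic and (thoraco)lumbar curves
# share the lower thoracic end vertebra, as adjacent curves do clinically;
# the relative-wedge profile is obtained from one joint linear solve so that
# every regional delta(A-P) target is met exactly.
build_ais_profiles <- function(layout, prm, state) {
  el <- layout$elements
  np <- nrow(layout$plates)
  lvl <- layout$levels
  tilt <- numeric(np); az <- numeric(np)

  span_t <- span_elements(lvl, prm$upper_t, prm$lower_t)
  span_l <- span_elements(lvl, prm$lower_t, prm$lower_l)   # shared end vertebra

  p_t_top <- plate_index(layout, prm$upper_t, "superior")
  p_t_bot <- plate_index(layout, prm$lower_t, "inferior")
  p_l_bot <- plate_index(layout, prm$lower_l, "inferior")
  p_l_top <- p_t_bot - 1                                   # T12 superior

  # -- coronal tilt targets per plate (degrees). Thoracic ramp from
  # -C_T/2 (upper end superior) to +C_T/2 (lower end inferior): right convex.
  # The lumbar ramp continues caudally so that the angle between the shared
  # end vertebra's superior plate and the lumbar lower end inferior plate is
  # C_L (left convex).
  C_T <- state$C_T; C_L <- state$C_L
  tilt[p_t_bot:p_t_top] <- seq(C_T / 2, -C_T / 2, length.out = p_t_top - p_t_bot + 1)
  tilt[p_t_top:np] <- seq(-C_T / 2, 0, length.out = np - p_t_top + 1)
  t_l4 <- tilt[p_t_bot + 1] - C_L
  # a tilt drop across the inter-curve disc keeps the shared end vertebra
  # unambiguously the most tilted one; its size is calibrated so the
  # realized margin survives the curvature-torsion cross-terms
  tilt[p_l_bot:p_l_top] <- seq(t_l4, tilt[p_t_bot] - state$j_drop,
                               length.out = p_l_top - p_l_bot + 1)
  # below the lumbar curve the tilt returns toward the horizontal sacral
  # plate with a slight overshoot (max 14 deg across the disc), so the lumbar
  # lower end vertebra is always the most tilted vertebra of its curve
  os <- max(0, state$os)
  v <- t_l4 - sign(t_l4) * min(abs(t_l4) + 3 + os, 14 + os)
  tilt[plate_index(layout, "L5", "superior")] <- v
  tilt[plate_index(layout, "L5", "inferior")] <- v / 2
  # coronal balance: a calibrated lumbosacral takeoff lean keeps the spine's
  # longitudinal axis aligned with the sacral normal, as a compensated
  # patient stands; without it large curves lean the whole column and the
  # measurement frame with it
  tilt[-1] <- tilt[-1] + state$lean
  tilt[1] <- 0

  # -- axial azimuth targets per plate (degrees)
  r_p <- prm$r_p; r_d <- prm$r_d
  az[1:p_l_bot] <- 0
  lum_plates <- p_l_bot:p_l_top
  kl <- p_l_top - lum_plates                 # 0 at T12 sup ... at L4 inf
  nl <- p_l_top - p_l_bot
  kc_l <- mean(p_l_top - c(plate_index(layout, state$apex_l, "superior"),
                           plate_index(layout, state$apex_l, "inferior")))
  az[lum_plates] <- r_d * (1 - (kl + 1) / (nl + 1)) +
    state$A_L * raised_bump(kl, kc_l, kc_l + 1, nl + 1 - kc_l)

  tho_plates <- p_t_bot:p_t_top
  kt <- p_t_top - tho_plates                 # 0 at T5 sup ... nt at T11 inf
  nt <- p_t_top - p_t_bot
  kc_t <- mean(p_t_top - c(plate_index(layout, state$apex_t, "superior"),
                           plate_index(layout, state$apex_t, "inferior")))
  az[tho_plates] <- r_p + (r_d - r_p) * kt / nt +
    state$A_T * raised_bump(kt, kc_t, kc_t, nt - kc_t)
  az[p_t_top:np] <- seq(r_p, 0, length.out = np - p_t_top + 1)

  # -- sagittal relative-wedge profile: w = base + M u, six unknowns
  # (c_T, W_T, c_L, W_L, proximal-junction w, inter-curve disc w) solved so
  # the six regional height-weighted mean-w targets hold exactly
  ne <- nrow(el)
  base_w <- numeric(ne)
  i_t4 <- element_index(layout, "T4")
  base_w[(i_t4 + 1):ne] <- delta_to_mean_w(prm$delta_upper)
  i_l4 <- element_index(layout, prm$lower_l)
  base_w[seq_len(i_l4 - 1)] <- delta_to_mean_w(prm$delta_lower)

  apex_t_i <- match(state$apex_t, lvl)
  apical_t <- span_elements(lvl, lvl[apex_t_i - 1], lvl[apex_t_i + 1])
  apex_l_i <- match(state$apex_l, lvl)
  apical_l <- span_elements(lvl, lvl[apex_l_i - 1], lvl[apex_l_i + 1])
  above_t <- lvl[match(prm$upper_t, lvl) - 1]
  below_t <- lvl[match(prm$lower_t, lvl) + 1]
  pj_ids <- span_elements(lvl, above_t, prm$upper_t)
  dj_ids <- span_elements(lvl, prm$lower_t, below_t)

  M <- matrix(0, ne, 6)
  it <- element_index(layout, span_t)
  ec_t <- match(state$apex_t, span_t)
  M[it, 1] <- 1
  M[it, 2] <- raised_bump(seq_along(span_t), ec_t, ec_t, length(span_t) + 1 - ec_t)
  pos_l <- seq_along(span_l)
  ec_l <- match(state$apex_l, span_l)
  bump_l <- raised_bump(pos_l, ec_l, ec_l - 1, length(span_l) + 1 - ec_l)
  owned <- pos_l >= 3                         # beyond the shared vertebra + disc
  il <- element_index(layout, span_l)
  M[il[owned], 3] <- 1
  M[il[owned], 4] <- bump_l[owned]
  M[element_index(layout, dj_ids[2]), 6] <- 1  # inter-curve disc
  M[element_index(layout, pj_ids[1:2]), 5] <- 1

  regions <- list(mt = span_t, at = apical_t, jp = pj_ids, jd = dj_ids,
                  tl = span_l, al = apical_l)
  A <- matrix(0, 6, 6); rhs <- numeric(6)
  for (r in seq_along(regions)) {
    ir <- element_index(layout, regions[[r]])
    h <- el$h[ir]
    A[r, ] <- colSums(M[ir, , drop = FALSE] * h)
    rhs[r] <- state[[paste0("m_", names(regions)[r])]] * sum(h) -
      sum(h * base_w[ir])
  }
  u <- solve(A, rhs)
  w <- base_w + as.numeric(M %*% u)

  list(w = w, tilt = tilt, az = az,
       spans = list(thoracic = span_t, lumbar = span_l,
                    apical_t = apical_t, apical_l = apical_l,
                    proximal = pj_ids, distal = dj_ids))
}

wedges_from_profiles <- function(layout, prof) {
  el <- layout$elements
  theta <- prof$w * el$h / (el$b_low + el$b_up)
  gamma <- diff(prof$tilt) / DEG
  tau <- -diff(prof$az) / DEG
  list(theta = theta, gamma = gamma, tau = tau)
}

# ---------------------------------------------------------------------------
# Subject construction with fixed-point calibration

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ais_truth_targets <- function(prm) {
  list(m_mt = delta_to_mean_w(prm$d_mt), m_at = delta_to_mean_w(prm$d_at),
       m_jp = delta_to_mean_w(prm$d_jp), m_jd = delta_to_mean_w(prm$d_jd),
       m_tl = delta_to_mean_w(prm$d_tl), m_al = delta_to_mean_w(prm$d_al))
}

build_ais_geometry <- function(prm, iterations = 10, damping = 0.6) {
  layout <- make_layout()
  state <- c(ais_truth_targets(prm),
             list(C_T = prm$C_T, C_L = prm$C_L,
                  A_T = prm$R_T - prm$r_p, A_L = prm$R_L - prm$r_d,
                  j_drop = 3, lean = 0, os = 0, apex_t = "T8", apex_l = "L2"))
  prof <- NULL; chain <- NULL; lm <- NULL
  relocks <- 0
  it <- 0
  while (it < iterations) {
    it <- it + 1
    prof <- build_ais_profiles(layout, prm, state)
    wd <- wedges_from_profiles(layout, prof)
    chain <- reframe_chain(build_chain(layout, wd$theta, wd$gamma, wd$tau))
    lm <- chain_landmarks(layout, chain)
    heights <- chain_element_heights(layout, lm)
    apex_t <- chain_apex(layout, chain, prm$upper_t, prm$lower_t)
    apex_l <- chain_apex(layout, chain, prm$lower_t, prm$lower_l)
    if ((it == 1 || it == iterations) &&
        (!identical(apex_t, state$apex_t) || !identical(apex_l, state$apex_l))) {
      # lock bump centres to the apices the geometry actually realizes; if
      # the final geometry settles on a different apex, recalibrate once
      state$apex_t <- apex_t
      state$apex_l <- apex_l
      if (it == iterations && relocks < 3) {
        relocks <- relocks + 1
        it <- 1
      }
    }
    real <- list(
      cobb_t = chain_cobb(layout, lm, prm$upper_t, prm$lower_t),
      cobb_l = chain_cobb(layout, lm, prm$lower_t, prm$lower_l),
      rot_t = chain_vertebra_rotation(layout, lm, state$apex_t),
      rot_l = chain_vertebra_rotation(layout, lm, state$apex_l),
      d_mt = region_delta_from_heights(heights, prof$spans$thoracic),
      d_at = region_delta_from_heights(heights, prof$spans$apical_t),
      d_jp = region_delta_from_heights(heights, prof$spans$proximal),
      d_jd = region_delta_from_heights(heights, prof$spans$distal),
      d_tl = region_delta_from_heights(heights, prof$spans$lumbar),
      d_al = region_delta_from_heights(heights, prof$spans$apical_l)
    )
    # damped fixed-point updates: the rotation/tilt responses have gain
    # above one (curvature-torsion holonomy), so undamped updates ring
    # realized tilt margin between the shared end vertebra and the vertebra
    # below it (coronal lean of the plate normals)
    tilt_of <- function(level) {
      ns <- lm$normal[, plate_index(layout, level, "superior")]
      ni <- lm$normal[, plate_index(layout, level, "inferior")]
      (atan2(ns[1], ns[3]) + atan2(ni[1], ni[3])) / 2 * DEG
    }
    below_t <- lvl_at(layout, prm$lower_t, 1)
    margin <- abs(tilt_of(prm$lower_t)) - abs(tilt_of(below_t))
    state$j_drop <- clamp(state$j_drop + damping * (3 - margin), 0, 15)
    # apparent coronal tilt of the sacral plate in the measurement frame;
    # driven to zero by the takeoff lean
    n_s <- lm$normal[, 1]
    state$lean <- state$lean + damping * atan2(n_s[1], n_s[3]) * DEG
    # realized caudal margin: the lumbar lower end vertebra must out-tilt L5
    dir_l <- -sign(tilt_of(prm$lower_t) )   # lumbar curve tilts opposite
    m_c <- (tilt_of("L5") - tilt_of(prm$lower_l)) * dir_l
    state$os <- clamp(state$os + damping * (3 - m_c), 0, 20)
    state$C_T <- state$C_T + damping * (prm$C_T - real$cobb_t)
    state$C_L <- state$C_L + damping * (prm$C_L - real$cobb_l)
    state$A_T <- state$A_T + damping * (prm$R_T - real$rot_t)
    state$A_L <- state$A_L + damping * (prm$R_L - real$rot_l)
    for (nm in c("mt", "at", "jp", "jd", "tl", "al")) {
      tgt <- paste0("m_", nm)
      state[[tgt]] <- state[[tgt]] +
        delta_to_mean_w(prm[[paste0("d_", nm)]]) - delta_to_mean_w(real[[paste0("d_", nm)]])
    }
  }
  list(layout = layout, profiles = prof, chain = chain, landmarks = lm,
       apex_t = state$apex_t, apex_l = state$apex_l)
}

build_control_profiles <- function(layout, prm, state) {
  np <- nrow(layout$plates)
  el <- layout$elements
  tilt <- numeric(np)
  az <- numeric(np)
  lum_lo <- plate_index(layout, "L5", "inferior")
  lum_hi <- plate_index(layout, "L1", "superior")
  tho_lo <- plate_index(layout, "T12", "inferior")
  tho_hi <- plate_index(layout, "T4", "superior")
  az[lum_lo:lum_hi] <- prm$rot_l
  az[tho_lo:tho_hi] <- prm$rot_t
  az[tho_hi:np] <- seq(prm$rot_t, 0, length.out = np - tho_hi + 1)
  w <- numeric(nrow(el))
  span_t <- span_elements(layout$levels, "T4", "T12")
  span_l <- span_elements(layout$levels, "L1", "L5")
  w[] <- state$w_t
  w[element_index(layout, span_l)] <- state$w_l
  w[element_index(layout, c("L5-S1"))] <- state$w_l
  w[element_index(layout, "T12-L1")] <- (state$w_t + state$w_l) / 2
  list(w = w, tilt = tilt, az = az, spans = list(thoracic = span_t, lumbar = span_l))
}

build_control_geometry <- function(prm, iterations = 3) {
  layout <- make_layout()
  state <- list(w_t = delta_to_mean_w(prm$d_t), w_l = delta_to_mean_w(prm$d_l))
  prof <- NULL; chain <- NULL; lm <- NULL
  for (it in seq_len(iterations)) {
    prof <- build_control_profiles(layout, prm, state)
    wd <- wedges_from_profiles(layout, prof)
    chain <- reframe_chain(build_chain(layout, wd$theta, wd$gamma, wd$tau))
    lm <- chain_landmarks(layout, chain)
    heights <- chain_element_heights(layout, lm)
    state$w_t <- state$w_t + delta_to_mean_w(prm$d_t) -
      delta_to_mean_w(region_delta_from_heights(heights, prof$spans$thoracic))
    state$w_l <- state$w_l + delta_to_mean_w(prm$d_l) -
      delta_to_mean_w(region_delta_from_heights(heights, prof$spans$lumbar))
  }
  list(layout = layout, profiles = prof, chain = chain, landmarks = lm)
}

# Emit 36-point elliptical endplate contours (and canal centroids) for every
# plate of a built chain, as endplate_contour objects in the world frame.
emit_contours <- function(layout, chain) {
  phi <- (seq_len(CONTOUR_POINTS) - 1) / CONTOUR_POINTS * 2 * pi
  lapply(seq_len(nrow(layout$plates)), function(i) {
    pl <- layout$plates[i, ]
    Q <- chain$Q[[i]]
    local <- rbind(pl$a * cos(phi), pl$b * sin(phi), rep(0, CONTOUR_POINTS))
    pts <- t(Q %*% local + chain$p[, i])
    canal <- as.numeric(chain$p[, i] - pl$canal_offset * Q[, 2])
    endplate_contour(pl$level, pl$side, pts, canal, validate = FALSE)
  })
}

truth_region_row <- function(layout, lm, heights, name, upper, lower, apex,
                             rotation) {
  ids <- span_elements(layout$levels, upper, lower)
  rows <- heights[match(ids, heights$id), ]
  ant <- sum(rows$anterior_mm); post <- sum(rows$posterior_mm)
  data.frame(region = name, upper_end = upper, lower_end = lower,
             apex = if (is.null(apex)) NA_character_ else apex,
             cobb_deg = chain_cobb(layout, lm, upper, lower),
             axial_rotation_deg = rotation,
             anterior_mm = ant, posterior_mm = post,
             delta_ap_percent = delta_ap(ant, post),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic subject from explicit truth parameters
#'
#' Builds the spine by sequential frame composition from the sacral plate and
#' returns both the raw contour representation and the ground truth
#' recomputed analytically from the same transform chain (not copied from the
#' requested targets; a short fixed-point calibration makes the chain realize
#' the targets).
#'
#' @param params parameter list as produced by the cohort samplers: for AIS
#'   subjects fields `pattern`, `C_T`, `C_L` (internal Cobb targets, deg),
#'   `R_T`, `R_L` (apex axial rotations, deg, right positive), regional
#'   delta(A-P) targets `d_mt`, `d_at`, `d_jp`, `d_jd`, `d_tl`, `d_al` (%),
#'   junction rotations `r_p`, `r_d`, curve layout `upper_t`/`lower_t`/
#'   `upper_l`/`lower_l`, background profile `delta_upper`/`delta_lower`, and
#'   standing Cobb `S_T`/`S_L`; for controls `group = "control"` with `d_t`,
#'   `d_l`, `rot_t`, `rot_l`.
#' @param seed unused placeholder for interface symmetry; the geometry is a
#'   deterministic function of `params`.
#' @param subject_id identifier stored in the model.
#' @return list with `subject_id`, `group`, `pattern`, `spine` (a
#'   [spine_model()]), `contours`, `standing_cobb`, and `truth` (list with
#'   `regions` data.frame and `elements` wedge table).
#' @export
generate_subject <- function(params, seed = NULL, subject_id = NULL) {
  ais <- !identical(params$group, "control")
  geo <- if (ais) build_ais_geometry(params) else build_control_geometry(params)
  layout <- geo$layout; lm <- geo$landmarks
  heights <- chain_element_heights(layout, lm)
  lvl <- layout$levels
  if (ais) {
    at <- match(geo$apex_t, lvl); al <- match(geo$apex_l, lvl)
    regions <- rbind(
      truth_region_row(layout, lm, heights, "main_thoracic", params$upper_t,
                       params$lower_t, geo$apex_t,
                       chain_vertebra_rotation(layout, lm, geo$apex_t)),
      truth_region_row(layout, lm, heights, "apical_thoracic", lvl[at - 1],
                       lvl[at + 1], geo$apex_t,
                       chain_vertebra_rotation(layout, lm, geo$apex_t)),
      truth_region_row(layout, lm, heights, "proximal_junctional",
                       lvl[match(params$upper_t, lvl) - 1], params$upper_t, NULL,
                       chain_mean_rotation(layout, lm,
                                           lvl[match(params$upper_t, lvl) - 1:0])),
      truth_region_row(layout, lm, heights, "distal_junctional",
                       params$lower_t, lvl[match(params$lower_t, lvl) + 1], NULL,
                       chain_mean_rotation(layout, lm,
                                           lvl[match(params$lower_t, lvl) + 0:1])),
      truth_region_row(layout, lm, heights, "thoracolumbar", params$lower_t,
                       params$lower_l, geo$apex_l,
                       chain_vertebra_rotation(layout, lm, geo$apex_l)),
      truth_region_row(layout, lm, heights, "apical_lumbar", lvl[al - 1],
                       lvl[al + 1], geo$apex_l,
                       chain_vertebra_rotation(layout, lm, geo$apex_l))
    )
    standing <- c(thoracic = params$S_T, lumbar = params$S_L)
  } else {
    regions <- rbind(
      truth_region_row(layout, lm, heights, "thoracic_T4T12", "T4", "T12", NULL,
                       chain_mean_rotation(layout, lm, lvl[match("T4", lvl):match("T12", lvl)])),
      truth_region_row(layout, lm, heights, "lumbar_L1L5", "L1", "L5", NULL,
                       chain_mean_rotation(layout, lm, lvl[match("L1", lvl):match("L5", lvl)]))
    )
    standing <- c(thoracic = NA_real_, lumbar = NA_real_)
  }
  contours <- emit_contours(layout, geo$chain)
  wd <- wedges_from_profiles(layout, geo$profiles)
  elements <- data.frame(
    id = layout$elements$id, type = layout$elements$type,
    base_height_mm = layout$elements$h,
    relative_wedge = geo$profiles$w,
    sagittal_wedge_deg = wd$theta * DEG,
    coronal_wedge_deg = wd$gamma * DEG,
    axial_twist_deg = wd$tau * DEG,
    stringsAsFactors = FALSE
  )
  list(
    subject_id = subject_id, group = if (ais) "ais" else "control",
    pattern = if (ais) params$pattern else NA_character_,
    spine = spine_model(contours, subject_id = subject_id, validate = FALSE),
    contours = contours, standing_cobb = standing,
    truth = list(regions = regions, elements = elements, params = params)
  )
}

# ---------------------------------------------------------------------------
# Cohort configuration and sampling

#' Moment-matched normal deviates
#'
#' Draws `n` normal deviates and rescales them to the exact requested sample
#' mean and standard deviation. The cohort sampler uses these so that a
#' generated calibration cohort reproduces its configured stratum means
#' exactly rather than up to sampling error; individual subjects remain
#' random.
#'
#' @param n number of deviates.
#' @param mean,sd target sample moments (`sd` uses the n-1 denominator).
#' @return numeric vector of length `n`.
#' @export
rnorm_matched <- function(n, mean = 0, sd = 1) {
  if (n == 0) return(numeric(0))
  if (n == 1 || sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n)
  while (stats::sd(x) == 0) x <- stats::rnorm(n)   # vanishing probability
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# Matched-moment deviates additionally orthogonalized against covariates so
# their sample covariance with `X` is exactly zero; keeps the configured
# regression slopes deterministic in a finite calibration cohort.
rnorm_orth <- function(n, sd = 1, X = NULL) {
  if (n == 0) return(numeric(0))
  if (is.null(X)) return(rnorm_matched(n, 0, sd))
  X <- cbind(X)
  if (n <= ncol(X) + 1) return(rnorm_matched(n, 0, sd))
  z <- stats::rnorm(n)
  r <- stats::lm.fit(cbind(1, X), z)$residuals
  if (stats::sd(r) == 0) return(rnorm_matched(n, 0, sd))
  r / stats::sd(r) * sd
}

#' Calibrated AIS cohort configuration
#'
#' Curve-pattern mix, per-stratum Cobb / rotation / delta(A-P) distributions,
#' the coronal-axial-sagittal coupling slopes and the regional
#' (apical/junctional) profile of the emulated surgical AIS population.
#'
#' @param n number of subjects.
#' @param seed RNG seed for [generate_cohort()].
#' @return list of class `cohort_config`.
#' @export
ais_cohort_config <- function(n = 77, seed = 20160728) {
  structure(list(
    group = "ais", n = n, seed = seed,
    # curve-pattern mix of the emulated surgical population
    patterns = c(thoracic = 53 / 77, lumbar = 6 / 77, double = 18 / 77),
    strata = data.frame(
      pattern = c("thoracic", "lumbar", "double"),
      cobb_t_mean = c(60, 40, 61), cobb_t_sd = c(11, 13, 17),
      rot_t_mean = c(26, 14, 24),
      delta_mt_mean = c(4.2, 1.8, 3.6),
      cobb_l_mean = c(28, 57, 55), cobb_l_sd = c(10, 12, 12),
      rot_l_mean = c(-4, -20, -19),
      delta_tl_mean = c(8.6, 10.8, 11.4),
      stringsAsFactors = FALSE
    ),
    coupling = list(
      rotation_slope = 0.5,      # deg apex rotation per deg standing Cobb
      delta_slope = 0.12,        # delta(A-P) points per deg standing Cobb
      rotation_slope_lumbar = -0.35,
      delta_slope_lumbar = 0.10,
      standing_offset = 5,       # standing Cobb exceeds internal (prone) Cobb
      standing_sd = 4,
      rotation_resid_sd = 4,
      delta_resid_sd = 2
    ),
    regional = list(
      apical_t_mean = 7.1, apical_l_mean = 11.2,
      junction_p_mean = -1.3, junction_d_mean = 1.0,
      apical_coupling = 1.0,     # apical delta follows the curve delta
      apical_resid_sd = 1.5, apical_floor = 0.8,
      junction_ratio_sd_p = 0.25, junction_ratio_sd_d = 0.18,
      junction_cap = 0.8         # |junction| < cap * min(apical deltas)
    ),
    junction_rotation = list(proximal_mean = 5, distal_mean = -1, sd = 3),
    # delineation variability calibrated so replicate anterior/posterior
    # height error is ~0.2 mm and delta(A-P) reliability matches the
    # reported inter-observer ICC range
    observer_jitter_mm = 0.15,
    layout = list(upper_t = "T5", lower_t = "T11", lower_l = "L4"),
    background = list(delta_upper = -4.1, delta_lower = 7.8),
    cobb_t_range = c(18, 85), cobb_l_range = c(15, 80)
  ), class = "cohort_config")
}

#' Control cohort configuration
#'
#' Straight spines with a physiological sagittal profile: thoracic kyphosis
#' over T4-T12 and lumbar lordosis over L1-L5, with near-zero axial rotation.
#'
#' @inheritParams ais_cohort_config
#' @return list of class `cohort_config`.
#' @export
control_cohort_config <- function(n = 22, seed = 20160729) {
  structure(list(
    group = "control", n = n, seed = seed,
    delta_t = c(mean = -4.1, sd = 1.8),
    delta_l = c(mean = 7.8, sd = 3.6),
    rot_t = c(mean = 1, sd = 3),
    rot_l = c(mean = -1, sd = 5)
  ), class = "cohort_config")
}

# Largest-remainder apportionment of n subjects over pattern proportions.
pattern_counts <- function(n, probs) {
  raw <- n * probs
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

sample_ais_params <- function(config) {
  st <- config$strata
  cp <- config$coupling
  rg <- config$regional
  counts <- pattern_counts(config$n, config$patterns[st$pattern])
  per <- list()
  for (g in seq_len(nrow(st))) {
    ng <- counts[g]
    if (ng == 0) next
    C_T <- clamp(rnorm_matched(ng, st$cobb_t_mean[g], st$cobb_t_sd[g]),
                 config$cobb_t_range[1], config$cobb_t_range[2])
    # the (thoraco)lumbar curve must at least return the tilt that the
    # thoracic curve leaves at the shared end vertebra (plus margin), and
    # the straightening below the curve must stay anatomical
    C_L <- clamp(rnorm_matched(ng, st$cobb_l_mean[g], st$cobb_l_sd[g]),
                 pmax(config$cobb_l_range[1], (1 / 2 - 1 / 13) * C_T + 6),
                 pmin(config$cobb_l_range[2], 0.46 * C_T + 50))
    S_T <- C_T + cp$standing_offset + rnorm_orth(ng, cp$standing_sd, C_T)
    S_L <- C_L + cp$standing_offset + rnorm_orth(ng, cp$standing_sd, C_L)
    # couplings are centred on the realized stratum sample mean (so stratum
    # target means survive the Cobb clamping exactly) and their residuals are
    # orthogonal to the regressor (so the configured slopes are realized
    # exactly, not only in expectation)
    R_T <- st$rot_t_mean[g] + cp$rotation_slope * (S_T - mean(S_T)) +
      rnorm_orth(ng, cp$rotation_resid_sd, S_T)
    R_L <- st$rot_l_mean[g] + cp$rotation_slope_lumbar * (S_L - mean(S_L)) +
      rnorm_orth(ng, cp$rotation_resid_sd, S_L)
    d_mt <- st$delta_mt_mean[g] + cp$delta_slope * (S_T - mean(S_T)) +
      rnorm_orth(ng, cp$delta_resid_sd, S_T)
    d_tl <- st$delta_tl_mean[g] + cp$delta_slope_lumbar * (S_L - mean(S_L)) +
      rnorm_orth(ng, cp$delta_resid_sd, S_L)
    r_p <- rnorm_matched(ng, config$junction_rotation$proximal_mean,
                         config$junction_rotation$sd)
    r_d <- rnorm_matched(ng, config$junction_rotation$distal_mean,
                         config$junction_rotation$sd)
    per[[g]] <- data.frame(pattern = st$pattern[g], C_T = C_T, C_L = C_L,
                           S_T = S_T, S_L = S_L, R_T = R_T, R_L = R_L,
                           d_mt = d_mt, d_tl = d_tl, r_p = r_p, r_d = r_d,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, per)
  n <- nrow(tab)
  # pooled regional targets; floors keep the apical zones strictly lordotic
  tab$d_at <- pmax(rg$apical_t_mean + rg$apical_coupling * (tab$d_mt - mean(tab$d_mt)) +
                     rnorm_matched(n, 0, rg$apical_resid_sd), rg$apical_floor)
  tab$d_al <- pmax(rg$apical_l_mean + rg$apical_coupling * (tab$d_tl - mean(tab$d_tl)) +
                     rnorm_matched(n, 0, rg$apical_resid_sd), rg$apical_floor)
  cap <- rg$junction_cap * pmin(tab$d_at, tab$d_al)
  jp <- rnorm_matched(n, rg$junction_p_mean / rg$apical_t_mean,
                      rg$junction_ratio_sd_p) * tab$d_at
  tab$d_jp <- clamp(jp - mean(jp) + rg$junction_p_mean, -cap, cap)
  jd <- rnorm_matched(n, rg$junction_d_mean / rg$apical_l_mean,
                      rg$junction_ratio_sd_d) * tab$d_al
  tab$d_jd <- clamp(jd - mean(jd) + rg$junction_d_mean, -cap, cap)
  tab
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject targets from the configured distributions (stratum means
#' are moment-matched; see [rnorm_matched()]), builds every subject with
#' [generate_subject()], and collects the ground-truth table. Reproducible
#' under a fixed seed; the caller's RNG state is preserved.
#'
#' @param config an [ais_cohort_config()] or [control_cohort_config()].
#' @return list of class `spine_cohort`: `subjects` (list as accepted by
#'   [measure_cohort()]), `truth` (data.frame of per-subject, per-region
#'   ground truth), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n < 2) stop("cohort needs n >= 2", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  if (config$group == "ais") {
    tab <- sample_ais_params(config)
    subjects <- lapply(seq_len(nrow(tab)), function(i) {
      prm <- as.list(tab[i, ])
      prm$group <- "ais"
      prm <- c(prm, config$layout,
               list(delta_upper = config$background$delta_upper,
                    delta_lower = config$background$delta_lower))
      generate_subject(prm, subject_id = sprintf("AIS%03d", i))
    })
  } else {
    d_t <- rnorm_matched(config$n, config$delta_t["mean"], config$delta_t["sd"])
    d_l <- rnorm_matched(config$n, config$delta_l["mean"], config$delta_l["sd"])
    rot_t <- rnorm_matched(config$n, config$rot_t["mean"], config$rot_t["sd"])
    rot_l <- rnorm_matched(config$n, config$rot_l["mean"], config$rot_l["sd"])
    subjects <- lapply(seq_len(config$n), function(i) {
      prm <- list(group = "control", d_t = d_t[i], d_l = d_l[i],
                  rot_t = rot_t[i], rot_l = rot_l[i])
      generate_subject(prm, subject_id = sprintf("CTRL%03d", i))
    })
  }
  truth <- do.call(rbind, lapply(subjects, function(s) {
    tr <- s$truth$regions
    tr$subject_id <- s$subject_id
    tr$group <- s$group
    tr$pattern <- s$pattern
    tr$standing_cobb_thoracic <- s$standing_cobb[["thoracic"]]
    tr$standing_cobb_lumbar <- s$standing_cobb[["lumbar"]]
    tr
  }))
  rownames(truth) <- NULL
  structure(list(subjects = subjects, truth = truth, config = config),
            class = "spine_cohort")
}

#' @export
print.spine_cohort <- function(x, ...) {
  cat(sprintf("<spine_cohort> %s, n = %d (seed %d)\n",
              x$config$group, length(x$subjects), x$config$seed))
  invisible(x)
}

#' Simulate an independent observer by contour jitter
#'
#' Adds a zero-mean isotropic displacement to every contour (and plain
#' Gaussian noise to the canal centroids) and rebuilds the model.
#' `jitter_mm` is the pointwise standard deviation per coordinate;
#' `jitter_mm = 0` returns the input unchanged.
#'
#' The displacement is a smooth random field along each boundary (random
#' Fourier modes up to order 3) rather than independent noise per vertex:
#' trained observers err coherently - over- or under-segmenting a whole
#' sector of the endplate - and spatially white vertex noise would make the
#' discrete most-anterior-vertex landmark artificially unstable in a way no
#' human re-measurement is.
#'
#' @param x a [spine_model()] or a generated subject (list with `spine`).
#' @param jitter_mm pointwise standard deviation of the displacement field
#'   (mm), >= 0.
#' @param seed optional seed for reproducible jitter (restored afterwards).
#' @return object of the same shape as `x`.
#' @export
perturb_observer <- function(x, jitter_mm, seed = NULL) {
  if (jitter_mm < 0) stop("jitter_mm must be >= 0", call. = FALSE)
  if (is.list(x) && !inherits(x, "spine_model") && !is.null(x$spine)) {
    x$spine <- perturb_observer(x$spine, jitter_mm, seed)
    return(x)
  }
  stopifnot(inherits(x, "spine_model"))
  if (jitter_mm == 0) return(x)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  contours <- spine_contours(x)
  contours <- lapply(contours, function(ct) {
    n <- nrow(ct$points)
    phi <- 2 * pi * (seq_len(n) - 1) / n
    field <- vapply(1:3, function(coord) {
      coef <- stats::rnorm(8, 0, jitter_mm / 2)   # orders 0..3, sin+cos
      coef[1] * 1 + coef[2] * 0 +
        coef[3] * cos(phi) + coef[4] * sin(phi) +
        coef[5] * cos(2 * phi) + coef[6] * sin(2 * phi) +
        coef[7] * cos(3 * phi) + coef[8] * sin(3 * phi)
    }, numeric(n))
    ct$points <- ct$points + field
    ct$canal_centroid <- ct$canal_centroid + stats::rnorm(3, 0, jitter_mm)
    ct
  })
  spine_model(contours, subject_id = x$subject_id, validate = FALSE)
}
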