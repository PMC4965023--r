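# Domain containers: endplate contours, derived endplate geometry, and the
# ordered spine model. The measurement frame is anchored to the sacral plate
# (superior endplate of S1): its plane normal defines the cranial axis, its
# anterior-posterior axis the anterior direction. For a subject imaged in the
# standard patient frame this coincides with the world frame; anchoring makes
# every reported metric exactly invariant under rigid motion of the subject.

LEVELS_ALL <- c(paste0("T", 1:12), paste0("L", 1:5), "S1")

#' Create an endplate contour
#'
#' @param level vertebral label, one of `"T1"`..`"T12"`, `"L1"`..`"L5"`, `"S1"`
#'   (S1 contributes only its superior endplate, the sacral plate).
#' @param side `"superior"` or `"inferior"`.
#' @param points numeric matrix (>= 12 rows) of ordered 3-D boundary points
#'   (mm) forming a closed loop.
#' @param canal_centroid 3-D centroid (mm) of the spinal canal at this level.
#' @param validate run geometric validity checks (planarity residual,
#'   canal position).
#' @return object of class `endplate_contour`.
#' @export
endplate_contour <- function(level, side, points, canal_centroid, validate = TRUE) {
  level <- match.arg(level, LEVELS_ALL)
  side <- match.arg(side, c("superior", "inferior"))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("contour points must be an n x 3 matrix", call. = FALSE)
  if (nrow(points) < 12) {
    stop("contour", level_tag(level), " needs >= 12 points", call. = FALSE)
  }
  canal_centroid <- as.numeric(canal_centroid)
  x <- structure(
    list(level = level, side = side, points = points,
         canal_centroid = canal_centroid),
    class = "endplate_contour"
  )
  if (validate) validate_contour(x)
  x
}

# Planarity and canal-position invariants; the in-plane simplicity check is
# cheap at contour sizes used here (O(n^2) segment pairs).
validate_contour <- function(contour, max_residual = 1.5) {
  pl <- fit_endplate_plane(contour$points, contour$level)
  res <- abs(as.numeric(sweep(contour$points, 2, pl$point) %*% pl$normal))
  if (max(res) >= max_residual) {
    stop("contour", level_tag(contour$level), " is not planar: max residual ",
         format(max(res), digits = 3), " mm (limit ", max_residual, " mm)",
         call. = FALSE)
  }
  ctr <- contour_centroid(contour$points, contour$level)
  ap_axis(ctr, contour$canal_centroid, pl$normal, contour$level)  # must exist
  # the canal sits behind the vertebral body: its centroid must fall outside
  # the endplate boundary (a canal inside the contour means mislabelled data)
  basis <- plane_basis(pl$normal)
  uv <- sweep(contour$points, 2, pl$point) %*% basis
  cuv <- as.numeric((contour$canal_centroid - pl$point) %*% basis)
  if (point_in_polygon(cuv, uv)) {
    stop("contour", level_tag(contour$level),
         ": canal centroid lies inside the endplate boundary", call. = FALSE)
  }
  if (!polygon_is_simple(contour$points, pl)) {
    stop("contour", level_tag(contour$level),
         " self-intersects in its best-fit plane", call. = FALSE)
  }
  invisible(contour)
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  jn <- c(2:n, 1)
  inside <- FALSE
  for (j in seq_len(n)) {
    yj <- poly[j, 2] - p[2]; yk <- poly[jn[j], 2] - p[2]
    if ((yj > 0) != (yk > 0)) {
      xint <- poly[j, 1] + (0 - yj) * (poly[jn[j], 1] - poly[j, 1]) / (yk - yj)
      if (xint > p[1]) inside <- !inside
    }
  }
  inside
}

polygon_is_simple <- function(points, plane) {
  uv <- sweep(as.matrix(points), 2, plane$point) %*% plane_basis(plane$normal)
  n <- nrow(uv)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    a <- uv[i, ]; b <- uv[nxt[i], ]
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]   # skip edges sharing a vertex
    for (j in js) {
      cc <- uv[j, ]; d <- uv[nxt[j], ]
      if (segments_cross(a, b, cc, d)) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b, c, d) {
  orient <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  orient(a, b, c) != orient(a, b, d) && orient(c, d, a) != orient(c, d, b)
}

#' Derive endplate geometry from a contour
#'
#' Computes the best-fit plane, the area-weighted endplate centroid, the
#' anterior-posterior axis through the canal centroid, the extreme anterior
#' and posterior landmarks, and (when the sacral axis is known) the axial
#' rotation relative to the sacral plate.
#'
#' @param contour an [endplate_contour()].
#' @param sacral_axis unit anterior-posterior axis of the sacral plate, or
#'   `NULL` if rotations are not yet referenced.
#' @return object of class `endplate_geometry`.
#' @export
endplate_geometry <- function(contour, sacral_axis = NULL) {
  pl <- fit_endplate_plane(contour$points, contour$level)
  ctr <- contour_centroid(contour$points, contour$level)
  axis <- ap_axis(ctr, contour$canal_centroid, pl$normal, contour$level)
  ext <- extreme_points(contour$points, axis)
  rot <- if (is.null(sacral_axis)) NA_real_ else axial_rotation(axis, sacral_axis)
  structure(
    list(
      level = contour$level, side = contour$side,
      plane_point = pl$point, plane_normal = pl$normal,
      endplate_centroid = ctr, canal_centroid = contour$canal_centroid,
      ap_axis = axis,
      anterior_point = ext$anterior, posterior_point = ext$posterior,
      axial_rotation_deg = rot
    ),
    class = "endplate_geometry"
  )
}

#' Assemble a spine model from endplate contours
#'
#' Orders contours craniocaudally, re-expresses everything in the
#' sacral-plate-anchored measurement frame, derives per-endplate geometry and
#' axial rotations relative to the sacral plate, and checks the structural
#' invariants (both endplates per vertebra, centroid heights strictly
#' decreasing craniocaudally).
#'
#' @param contours list of [endplate_contour()] objects covering consecutive
#'   levels down to L5, plus the superior endplate of S1 (sacral plate).
#' @param subject_id optional identifier carried through to measurements.
#' @param validate run per-contour geometric validation.
#' @return object of class `spine_model`: fields `subject_id`, `levels`
#'   (vertebral labels, cranial first), `vertebrae` (per level, list with
#'   `superior`/`inferior` geometry and contours), `sacral_plate`,
#'   `sacral_contour`, and the rigid transform (`frame_rotation`,
#'   `frame_offset`) mapping input coordinates into the measurement frame.
#' @export
spine_model <- function(contours, subject_id = NULL, validate = TRUE) {
  if (validate) lapply(contours, validate_contour)
  key <- vapply(contours, function(x) paste(x$level, x$side), "")
  if (anyDuplicated(key)) {
    stop("duplicate contour for ", key[duplicated(key)][1], call. = FALSE)
  }
  names(contours) <- key

  sac <- contours[["S1 superior"]]
  if (is.null(sac)) stop("incomplete subject: missing sacral plate (S1 superior)", call. = FALSE)

  levels <- intersect(LEVELS_ALL, unique(vapply(contours, `[[`, "", "level")))
  vlevels <- setdiff(levels, "S1")
  if (length(vlevels) < 2 || vlevels[length(vlevels)] != "L5") {
    stop("spine model must extend through L5", call. = FALSE)
  }
  idx <- match(vlevels, LEVELS_ALL)
  if (any(diff(idx) != 1)) {
    stop("incomplete subject: vertebral levels are not consecutive (",
         paste(vlevels, collapse = ", "), ")", call. = FALSE)
  }

  # sacral-anchored measurement frame
  frame <- sacral_frame(sac, contours)
  contours <- lapply(contours, function(ct) {
    ct$points <- transform_points(ct$points, frame$R, frame$t)
    ct$canal_centroid <- as.numeric(frame$R %*% ct$canal_centroid + frame$t)
    ct
  })
  sac <- contours[["S1 superior"]]
  sacral_plate <- endplate_geometry(sac, sacral_axis = NULL)
  sacral_plate$axial_rotation_deg <- 0
  sax <- sacral_plate$ap_axis

  vertebrae <- lapply(vlevels, function(lv) {
    sup <- contours[[paste(lv, "superior")]]
    inf <- contours[[paste(lv, "inferior")]]
    if (is.null(sup) || is.null(inf)) {
      stop("incomplete subject: vertebra ", lv, " is missing an endplate", call. = FALSE)
    }
    list(level = lv,
         superior = endplate_geometry(sup, sax),
         inferior = endplate_geometry(inf, sax),
         superior_contour = sup, inferior_contour = inf)
  })
  names(vertebrae) <- vlevels

  z <- unlist(lapply(vertebrae, function(v) {
    c(v$superior$endplate_centroid[3], v$inferior$endplate_centroid[3])
  }))
  z <- c(z, sacral_plate$endplate_centroid[3])
  if (any(diff(z) >= 0)) {
    stop("invalid spine: endplate centroid heights are not strictly decreasing craniocaudally",
         call. = FALSE)
  }

  structure(
    list(subject_id = subject_id, levels = vlevels, vertebrae = vertebrae,
         sacral_plate = sacral_plate, sacral_contour = sac,
         frame_rotation = frame$R, frame_offset = frame$t),
    class = "spine_model"
  )
}

# Rigid-motion-invariant measurement frame derived from the geometry itself:
# the longitudinal (cranial) axis is the first principal direction of all
# endplate centroids (the radiographic patient axis), the anterior axis is
# the sacral plate's canal-to-centroid direction orthogonalized to it, and
# x = y cross z points to patient right. Returns the rigid transform mapping
# input coordinates into this frame.
sacral_frame <- function(sacral_contour, contours) {
  cents <- t(vapply(contours, function(ct) contour_centroid(ct$points), numeric(3)))
  sc <- contour_centroid(sacral_contour$points)
  x0 <- sweep(cents, 2, colMeans(cents))
  z <- svd(x0, nu = 0, nv = 1)$v[, 1]
  if (sum((colMeans(cents) - sc) * z) < 0) z <- -z
  y_raw <- sc - sacral_contour$canal_centroid
  y <- unitize(y_raw - sum(y_raw * z) * z, "sacral anterior-posterior axis")
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  R <- t(cbind(x, y, z))          # world -> measurement coordinates
  list(R = R, t = as.numeric(-R %*% sc))
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model>", if (!is.null(x$subject_id)) x$subject_id else "", "\n")
  cat("  levels:", x$levels[1], "-", x$levels[length(x$levels)],
      sprintf("(%d vertebrae + sacral plate)\n", length(x$levels)))
  span <- x$vertebrae[[1]]$superior$endplate_centroid[3]
  cat(sprintf("  height above sacral plate: %.1f mm\n", span))
  invisible(x)
}

#' @export
print.endplate_geometry <- function(x, ...) {
  cat(sprintf("<endplate_geometry> %s %s  rotation %.2f deg\n",
              x$level, x$side, x$axial_rotation_deg))
  invisible(x)
}

# All contours of a spine model as a flat list (including the sacral plate),
# in the original input coordinate frame when `original = TRUE`.
spine_contours <- function(spine, original = FALSE) {
  out <- list()
  for (v in spine$vertebrae) {
    out[[paste(v$level, "superior")]] <- v$superior_contour
    out[[paste(v$level, "inferior")]] <- v$inferior_contour
  }
  out[["S1 superior"]] <- spine$sacral_contour
  if (original) {
    Rt <- t(spine$frame_rotation)
    out <- lapply(out, function(ct) {
      ct$points <- transform_points(sweep(ct$points, 2, spine$frame_offset),
                                    t(spine$frame_rotation))
      ct$canal_centroid <- as.numeric(Rt %*% (ct$canal_centroid - spine$frame_offset))
      ct
    })
  }
  out
}
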