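# Voxel round-trip emulating CT segmentation: vertebra solids are swept
# between their two endplate contours and voxelized into an integer label
# volume together with a spinal-canal tube; extraction recovers per-vertebra
# endplate surfaces from the label map alone, refits planes and rebuilds
# boundary contours.

#' Rasterize a spine model into a labeled voxel volume
#'
#' Each vertebra (and a sacrum block under the sacral plate) becomes one
#' label; the spinal canal, swept as a tube through the canal centroids, is
#' the highest label. Axes follow the model's measurement frame (RAS, mm).
#'
#' @param spine a [spine_model()].
#' @param spacing isotropic voxel edge length in mm, >= 0.3.
#' @param canal_radius radius of the canal tube (mm).
#' @return object of class `labeled_volume`: `labels` (integer 3-D array, 0
#'   background), `spacing`, `origin` (world coordinates of voxel [1,1,1]
#'   centre), `level_map` (label id -> vertebral level), `canal_label`,
#'   `frame` tag.
#' @export
rasterize <- function(spine, spacing = 0.6, canal_radius = 4.5) {
  if (spacing < 0.3) stop("spacing must be >= 0.3 mm", call. = FALSE)
  contours <- spine_contours(spine)
  sac <- spine$sacral_contour
  # sacrum block: sacral plate ring extruded caudally
  sac_lower <- sac
  sac_lower$points <- sweep(sac$points, 2, c(0, 0, 25))
  sac_lower$canal_centroid <- sac$canal_centroid - c(0, 0, 25)

  solids <- lapply(spine$levels, function(lv) {
    v <- spine$vertebrae[[lv]]
    list(level = lv, upper = v$superior_contour$points, lower = v$inferior_contour$points)
  })
  solids[[length(solids) + 1]] <- list(level = "S1", upper = sac$points,
                                       lower = sac_lower$points)

  canal_chain <- do.call(rbind, lapply(contours, function(ct) ct$canal_centroid))
  allpts <- do.call(rbind, c(lapply(solids, function(s) rbind(s$upper, s$lower)),
                             list(sweep(canal_chain, 2, rep(canal_radius, 3), "-"),
                                  sweep(canal_chain, 2, rep(canal_radius, 3), "+"))))
  lo <- apply(allpts, 2, min) - 2 * spacing
  hi <- apply(allpts, 2, max) + 2 * spacing
  dim3 <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  labels <- array(0L, dim3)

  voxel_grid <- function(lo_w, hi_w) {
    # voxel index ranges covering a world-space box
    i0 <- pmax(1L, as.integer(floor((lo_w - lo) / spacing)) + 1L)
    i1 <- pmin(dim3, as.integer(ceiling((hi_w - lo) / spacing)) + 1L)
    if (any(i0 > i1)) return(NULL)
    list(ix = i0[1]:i1[1], iy = i0[2]:i1[2], iz = i0[3]:i1[3])
  }
  world <- function(idx, d) lo[d] + (idx - 1) * spacing

  for (si in seq_along(solids)) {
    s <- solids[[si]]
    g <- voxel_grid(pmin(apply(s$upper, 2, min), apply(s$lower, 2, min)) - spacing,
                    pmax(apply(s$upper, 2, max), apply(s$lower, 2, max)) + spacing)
    if (is.null(g)) next
    pts <- as.matrix(expand.grid(x = world(g$ix, 1), y = world(g$iy, 2),
                                 z = world(g$iz, 3)))
    c0 <- colMeans(s$lower); c1 <- colMeans(s$upper)
    axis <- c1 - c0
    len2 <- sum(axis * axis)
    # the solid is bounded by the two (tilted) plate planes, not by cuts
    # perpendicular to the sweep axis - otherwise the voxel caps would be
    # flattened and the recovered plate orientation biased
    n0 <- fit_endplate_plane(s$lower)$normal
    if (sum(n0 * axis) < 0) n0 <- -n0
    n1 <- fit_endplate_plane(s$upper)$normal
    if (sum(n1 * axis) < 0) n1 <- -n1
    t <- (sweep(pts, 2, c0) %*% axis) / len2
    keep <- which(as.numeric(sweep(pts, 2, c0) %*% n0) >= 0 &
                    as.numeric(sweep(pts, 2, c1) %*% n1) <= 0)
    if (!length(keep)) next
    tk <- pmin(1, pmax(0, t[keep]))   # ring-blend parameter within the solid
    centre <- sweep(outer(tk, c1 - c0), 2, c0, "+")          # c0 + t*(c1-c0)
    q <- pts[keep, , drop = FALSE] - centre
    # in-slice polygon test in the plane perpendicular to the sweep axis
    e1 <- plane_basis(axis / sqrt(len2))
    qu <- q %*% e1[, 1]; qv <- q %*% e1[, 2]
    n_ring <- nrow(s$lower)
    ru_l <- sweep(s$lower, 2, c0) %*% e1[, 1]; rv_l <- sweep(s$lower, 2, c0) %*% e1[, 2]
    ru_u <- sweep(s$upper, 2, c1) %*% e1[, 1]; rv_u <- sweep(s$upper, 2, c1) %*% e1[, 2]
    ru <- outer(1 - tk, as.numeric(ru_l)) + outer(tk, as.numeric(ru_u))
    rv <- outer(1 - tk, as.numeric(rv_l)) + outer(tk, as.numeric(rv_u))
    # even-odd crossing test, vectorized over voxels x ring edges
    inside <- rep(FALSE, length(tk))
    jn <- c(2:n_ring, 1)
    for (j in seq_len(n_ring)) {
      yj <- rv[, j] - qv; yk <- rv[, jn[j]] - qv
      xj <- ru[, j] - qu; xk <- ru[, jn[j]] - qu
      cross <- ((yj > 0) != (yk > 0)) &
        ((xj + (0 - yj) * (xk - xj) / (yk - yj)) > 0)
      cross[!is.finite(cross)] <- FALSE
      inside <- xor(inside, cross)
    }
    sel <- keep[inside]
    if (length(sel)) {
      idx <- arrayInd(sel, c(length(g$ix), length(g$iy), length(g$iz)))
      labels[cbind(g$ix[idx[, 1]], g$iy[idx[, 2]], g$iz[idx[, 3]])] <- si
    }
  }

  # canal tube through the chain of canal centroids
  canal_label <- length(solids) + 1L
  canals <- canal_chain[order(canal_chain[, 3]), , drop = FALSE]
  # extend the tube past the end plates (through the sacrum block and above
  # the most cranial vertebra) so every cap has canal voxels at its height
  nc <- nrow(canals)
  canals <- rbind(canals[1, ] - 30 * unitize(canals[2, ] - canals[1, ]),
                  canals,
                  canals[nc, ] + 15 * unitize(canals[nc, ] - canals[nc - 1, ]))
  for (j in seq_len(nrow(canals) - 1)) {
    p0 <- canals[j, ]; p1 <- canals[j + 1, ]
    g <- voxel_grid(pmin(p0, p1) - canal_radius, pmax(p0, p1) + canal_radius)
    if (is.null(g)) next
    pts <- as.matrix(expand.grid(x = world(g$ix, 1), y = world(g$iy, 2),
                                 z = world(g$iz, 3)))
    d <- p1 - p0
    tt <- pmin(1, pmax(0, (sweep(pts, 2, p0) %*% d) / sum(d * d)))
    near <- sweep(outer(as.numeric(tt), d), 2, p0, "+")
    dist2 <- rowSums((pts - near)^2)
    sel <- which(dist2 <= canal_radius^2)
    if (length(sel)) {
      idx <- arrayInd(sel, c(length(g$ix), length(g$iy), length(g$iz)))
      flat <- cbind(g$ix[idx[, 1]], g$iy[idx[, 2]], g$iz[idx[, 3]])
      free <- labels[flat] == 0L
      labels[flat[free, , drop = FALSE]] <- canal_label
    }
  }

  structure(list(labels = labels, spacing = spacing, origin = lo,
                 level_map = c(spine$levels, "S1"), canal_label = canal_label,
                 frame = "RAS-mm"),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels @ %.2f mm, %d vertebra labels + canal\n",
              paste(dim(x$labels), collapse = "x"), x$spacing,
              length(x$level_map) - 1))
  invisible(x)
}

# Extract the cap surface (top or bottom along `axis`) of one label's voxel
# cloud: bin the voxels in the plane perpendicular to `axis`, keep the
# extreme voxel per bin, then fit a trimmed least-squares plane.
cap_surface <- function(pts, axis, spacing, top = TRUE) {
  ax <- if (top) axis else -axis            # orient so the cap is "up"
  basis <- plane_basis(ax)
  u <- pts %*% basis[, 1]; v <- pts %*% basis[, 2]; h <- pts %*% ax
  bu <- round(u / spacing); bv <- round(v / spacing)
  key <- paste(bu, bv)
  ord <- order(key, -h)
  first <- !duplicated(key[ord])
  surf <- pts[ord[first], , drop = FALSE]
  # one-sided trim: where the plate tilts away from the sweep axis, the
  # projected footprint overhangs the cap and the per-bin maxima fall on the
  # side wall, always BELOW the true plate plane - drop those iteratively
  ctr <- colMeans(surf); nrm <- ax
  for (pass in 1:8) {
    ctr <- colMeans(surf)
    x0 <- sweep(surf, 2, ctr)
    nrm <- svd(x0, nu = 0, nv = 3)$v[, 3]
    if (sum(nrm * ax) < 0) nrm <- -nrm
    res <- as.numeric(x0 %*% nrm)
    keep <- res >= -1.2 * spacing
    if (all(keep) || sum(keep) < 12) break
    surf <- surf[keep, , drop = FALSE]
  }
  # refine on the full voxel cloud: the initial plane selects the cap's
  # boundary slab, whose least-squares plane is much less sensitive to the
  # projection overhang than the per-bin maxima
  for (pass in 1:3) {
    res_all <- as.numeric(sweep(pts, 2, ctr) %*% nrm)
    sel <- abs(res_all) <= 0.9 * spacing
    if (sum(sel) < 12) break
    surf <- pts[sel, , drop = FALSE]
    ctr <- colMeans(surf)
    x0 <- sweep(surf, 2, ctr)
    nrm <- svd(x0, nu = 0, nv = 3)$v[, 3]
    if (sum(nrm * ax) < 0) nrm <- -nrm
  }
  list(points = surf, centre = ctr, normal = nrm)
}

# Resample the convex hull of in-plane surface points to n contour vertices
# by uniform arc length.
hull_contour <- function(surf, n = 36) {
  ctr <- colMeans(surf$points)
  basis <- plane_basis(surf$normal)
  uv <- sweep(surf$points, 2, ctr) %*% basis
  ch <- grDevices::chull(uv)
  loop <- uv[c(ch, ch[1]), , drop = FALSE]
  seg <- sqrt(rowSums(diff(loop)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  tpos <- seq(0, total, length.out = n + 1)[-(n + 1)]
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- findInterval(tpos[i], s, rightmost.closed = TRUE)
    f <- (tpos[i] - s[j]) / max(seg[j], 1e-12)
    out[i, ] <- loop[j, ] * (1 - f) + loop[j + 1, ] * f
  }
  sweep(out %*% t(basis), 2, ctr, "+")
}

#' Recover endplate contours from a labeled volume
#'
#' For every vertebra label the cranial-most and caudal-most voxel layers
#' along the local spine axis are isolated, a plane is fitted to each, and
#' the boundary contour is rebuilt as the resampled convex hull of the
#' surface voxels; the canal centroid is taken from canal voxels at the
#' plate's height. The sacral label contributes its superior plate only.
#'
#' @param volume a `labeled_volume` from [rasterize()].
#' @param n_points number of contour vertices to emit per endplate.
#' @return list of [endplate_contour()] objects suitable for [spine_model()].
#' @export
extract_contours <- function(volume, n_points = 36) {
  sp <- volume$spacing
  nlab <- length(volume$level_map)
  vox <- which(volume$labels > 0L & volume$labels <= nlab)
  lab <- volume$labels[vox]
  idx <- arrayInd(vox, dim(volume$labels))
  pts_all <- sweep((idx - 1) * sp, 2, volume$origin, "+")
  centroids <- t(vapply(seq_len(nlab), function(l) {
    colMeans(pts_all[lab == l, , drop = FALSE])
  }, numeric(3)))
  canal_vox <- which(volume$labels == volume$canal_label)
  canal_idx <- arrayInd(canal_vox, dim(volume$labels))
  canal_pts <- sweep((canal_idx - 1) * sp, 2, volume$origin, "+")

  canal_near <- function(centre, axis) {
    h <- as.numeric(canal_pts %*% axis)
    h0 <- sum(centre * axis)
    sel <- abs(h - h0) <= 2 * sp
    if (sum(sel) < 3) sel <- abs(h - h0) <= 4 * sp
    if (sum(sel) < 3) stop("canal voxels missing near level plane", call. = FALSE)
    colMeans(canal_pts[sel, , drop = FALSE])
  }

  contours <- list()
  for (l in seq_len(nlab)) {
    lv <- volume$level_map[l]
    pts <- pts_all[lab == l, , drop = FALSE]
    if (nrow(pts) < 30) {
      stop("resolution too coarse: label ", lv, " has too few voxels", call. = FALSE)
    }
    # local axis from the neighbouring labels' centroids (fall back to z)
    nb <- centroids[intersect(c(l - 1, l + 1), seq_len(nlab)), , drop = FALSE]
    axis <- if (nrow(nb) == 2) nb[2, ] - nb[1, ] else c(0, 0, 1)
    if (sum(axis^2) < 1e-9) axis <- c(0, 0, 1)
    if (axis[3] < 0) axis <- -axis
    axis <- axis / sqrt(sum(axis^2))
    sides <- if (lv == "S1") "superior" else c("superior", "inferior")
    for (side in sides) {
      # two passes: the chain axis seeds a first cap fit; re-extracting along
      # the fitted plate normal removes the projection overhang that
      # flattens strongly tilted end-vertebra plates
      cap_axis <- axis
      for (pass in 1:2) {
        surf <- cap_surface(pts, cap_axis, sp, top = side == "superior")
        n_cranial <- if (side == "superior") surf$normal else -surf$normal
        if (sum(n_cranial * axis) < 0) n_cranial <- -n_cranial
        cap_axis <- n_cranial
      }
      ring <- hull_contour(surf, n_points)
      contours[[paste(lv, side)]] <- endplate_contour(
        lv, side, ring, canal_near(surf$centre, axis), validate = FALSE
      )
    }
  }
  contours
}
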