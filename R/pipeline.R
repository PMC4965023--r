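# Measurement procedure: per-endplate geometry -> element heights -> curve
# and region decomposition -> per-region metrics.

#' Relative anterior-posterior length discrepancy
#'
#' `delta_ap = (anterior - posterior) / posterior * 100`. Positive values
#' indicate greater anterior length (lordosis), negative values greater
#' posterior length (kyphosis).
#'
#' @param anterior_mm,posterior_mm summed anterior and posterior lengths (mm);
#'   `posterior_mm` must be positive.
#' @return discrepancy in percent.
#' @export
delta_ap <- function(anterior_mm, posterior_mm) {
  if (any(posterior_mm <= 0)) stop("posterior length must be positive", call. = FALSE)
  (anterior_mm - posterior_mm) / posterior_mm * 100
}

#' Anterior and posterior heights of every vertebra and disc
#'
#' The anterior height of a vertebra is the Euclidean distance between the
#' anterior landmarks of its superior and inferior endplates; disc heights
#' connect the facing endplates of adjacent vertebrae (the disc below L5 uses
#' the sacral plate). Posterior heights are analogous. Posterior bony elements
#' (pedicles, laminae, processes) are not part of the model and are excluded
#' by construction.
#'
#' @param spine a [spine_model()].
#' @return data.frame with columns `id`, `type` (`"vertebra"`/`"disc"`),
#'   `anterior_mm`, `posterior_mm`, ordered craniocaudally.
#' @export
element_heights <- function(spine) {
  vs <- spine$vertebrae
  n <- length(vs)
  ids <- character(0); types <- character(0); ant <- numeric(0); post <- numeric(0)
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  for (i in seq_len(n)) {
    v <- vs[[i]]
    ids <- c(ids, v$level); types <- c(types, "vertebra")
    ant <- c(ant, dist3(v$superior$anterior_point, v$inferior$anterior_point))
    post <- c(post, dist3(v$superior$posterior_point, v$inferior$posterior_point))
    lower <- if (i < n) vs[[i + 1]]$superior else spine$sacral_plate
    lower_lv <- if (i < n) vs[[i + 1]]$level else "S1"
    ids <- c(ids, paste0(v$level, "-", lower_lv)); types <- c(types, "disc")
    ant <- c(ant, dist3(v$inferior$anterior_point, lower$anterior_point))
    post <- c(post, dist3(v$inferior$posterior_point, lower$posterior_point))
  }
  if (any(ant[types == "vertebra"] <= 0) || any(post[types == "vertebra"] <= 0)) {
    stop("invalid spine: non-positive vertebral height", call. = FALSE)
  }
  data.frame(id = ids, type = types, anterior_mm = ant, posterior_mm = post,
             stringsAsFactors = FALSE)
}

#' Summed anterior and posterior lengths over a region
#'
#' @param heights output of [element_heights()].
#' @param region a `region_spec` (see [define_regions()]) or a character
#'   vector of element ids.
#' @return named numeric vector `c(anterior_mm, posterior_mm)`.
#' @export
region_lengths <- function(heights, region) {
  ids <- if (inherits(region, "region_spec")) region$elements else as.character(region)
  if (length(ids) == 0) stop("empty region", call. = FALSE)
  miss <- setdiff(ids, heights$id)
  if (length(miss)) {
    stop("region elements not present in spine: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- heights[match(ids, heights$id), ]
  c(anterior_mm = sum(rows$anterior_mm), posterior_mm = sum(rows$posterior_mm))
}

# Coronal (lateral) lean of an endplate normal, degrees; positive when the
# plate's upside tips toward patient-right.
endplate_coronal_tilt <- function(geom) {
  atan2(geom$plane_normal[1], geom$plane_normal[3]) * DEG
}

vertebra_tilt <- function(v) {
  (endplate_coronal_tilt(v$superior) + endplate_coronal_tilt(v$inferior)) / 2
}

vertebra_centroid <- function(v) {
  (v$superior$endplate_centroid + v$inferior$endplate_centroid) / 2
}

running_mean <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, 0)
}

#' Detect scoliotic curves from spine geometry
#'
#' Scans the smoothed per-vertebra coronal tilt profile for local extrema;
#' consecutive extrema delimit candidate curves whose end vertebrae are the
#' maximally tilted ones. The apex is the vertebra with the largest
#' perpendicular coronal-plane distance from the end-vertebra chord (ties go
#' to the more cranial vertebra). Candidates whose Cobb angle falls below
#' `cobb_floor` are discarded; a straight spine yields an empty list.
#'
#' @param spine a [spine_model()].
#' @param cobb_floor minimum Cobb angle (degrees) for a detected curve.
#' @param smooth_window running-mean window (vertebrae) for the tilt profile.
#' @param override optional list of manually specified curves, each a list
#'   with `upper_end`, `lower_end` and optionally `apex` (vertebral labels);
#'   used in place of detection, mirroring radiograph-defined end vertebrae.
#' @return list of curves: `upper_end`, `lower_end`, `apex`, `cobb_deg`,
#'   `convexity` (`"right"`/`"left"`).
#' @export
detect_curves <- function(spine, cobb_floor = 10, smooth_window = 3, override = NULL) {
  lv <- spine$levels
  if (length(lv) < 5) stop("curve detection needs >= 5 vertebrae", call. = FALSE)
  if (!is.null(override)) {
    return(lapply(override, function(ov) finalize_curve(spine, ov$upper_end, ov$lower_end,
                                                        apex = ov$apex)))
  }
  # the sacral plate extends the profile caudally so the smoothing window
  # does not bias the most caudal vertebrae
  tilt_raw <- c(vapply(spine$vertebrae, vertebra_tilt, 0),
                endplate_coronal_tilt(spine$sacral_plate))
  tilt <- running_mean(tilt_raw, smooth_window)
  n <- length(tilt) - 1
  ext <- integer(0)
  for (i in 2:n) {
    if ((tilt[i] > tilt[i - 1] && tilt[i] >= tilt[i + 1]) ||
        (tilt[i] < tilt[i - 1] && tilt[i] <= tilt[i + 1])) {
      # refine the smoothed extremum to the raw-tilt extremum among the
      # vertebra and its immediate neighbours (smoothing shifts shallow
      # minima toward the flat side)
      win <- max(1, i - 1):min(n, i + 1)
      j <- if (tilt[i] > tilt[i - 1]) win[which.max(tilt_raw[win])]
           else win[which.min(tilt_raw[win])]
      ext <- c(ext, j)
    }
  }
  ext <- unique(ext)
  ext <- ext[order(ext)]
  if (length(ext) < 2) return(list())
  out <- list()
  for (k in seq_len(length(ext) - 1)) {
    cv <- finalize_curve(spine, lv[ext[k]], lv[ext[k + 1]])
    if (cv$cobb_deg >= cobb_floor) out[[length(out) + 1]] <- cv
  }
  out
}

finalize_curve <- function(spine, upper_end, lower_end, apex = NULL) {
  lv <- spine$levels
  i1 <- match(upper_end, lv); i2 <- match(lower_end, lv)
  if (is.na(i1) || is.na(i2) || i2 <= i1) {
    stop("invalid curve limits ", upper_end, "-", lower_end, call. = FALSE)
  }
  cobb <- coronal_cobb(spine$vertebrae[[i1]]$superior, spine$vertebrae[[i2]]$inferior)
  cen <- vapply(spine$vertebrae, vertebra_centroid, numeric(3))  # 3 x n
  a <- cen[c(1, 3), i1]; b <- cen[c(1, 3), i2]
  chord <- b - a
  chord <- chord / sqrt(sum(chord^2))
  # signed perpendicular offset in the coronal (x, z) plane; +x is right
  # lateral (x) component of the perpendicular offset from the chord
  dev <- vapply(i1:i2, function(i) {
    d <- cen[c(1, 3), i] - a
    off <- d - sum(d * chord) * chord
    off[1]
  }, 0)
  if (is.null(apex)) {
    apex <- lv[(i1:i2)[which.max(abs(dev))]]
  }
  convex <- if (dev[which.max(abs(dev))] >= 0) "right" else "left"
  list(upper_end = upper_end, lower_end = lower_end, apex = apex,
       cobb_deg = cobb, convexity = convex)
}

curve_region_name <- function(apex) {
  if (match(apex, LEVELS_ALL) <= match("T11", LEVELS_ALL)) "main_thoracic" else "thoracolumbar"
}

span_elements <- function(levels, upper, lower) {
  i1 <- match(upper, levels); i2 <- match(lower, levels)
  ids <- character(0)
  for (i in i1:i2) {
    ids <- c(ids, levels[i])
    if (i < i2) ids <- c(ids, paste0(levels[i], "-", levels[i + 1]))
  }
  ids
}

region_spec <- function(name, elements, end_vertebrae = NULL, apex = NA_character_) {
  structure(list(name = name, elements = elements,
                 end_vertebrae = end_vertebrae, apex = apex),
            class = "region_spec")
}

#' Decompose a spine into named measurement regions
#'
#' For scoliotic subjects: each curve span (Cobb end vertebra to Cobb end
#' vertebra), its apical zone (apical vertebra, the two adjacent vertebrae and
#' the discs in between), and the junctional segments of the thoracic curve
#' (proximal: upper end vertebra, one level above and the disc in between;
#' distal: lower end vertebra, one level below and the disc in between). For
#' subjects without detected curves, the representative control segments
#' T4-T12 and L1-L5 are emitted instead.
#'
#' @param spine a [spine_model()].
#' @param curves output of [detect_curves()].
#' @return list of `region_spec` objects.
#' @export
define_regions <- function(spine, curves) {
  lv <- spine$levels
  if (length(curves) == 0) {
    if (!all(c("T4", "T12", "L1", "L5") %in% lv)) {
      stop("control segments T4-T12 / L1-L5 not covered by this spine", call. = FALSE)
    }
    return(list(
      region_spec("thoracic_T4T12", span_elements(lv, "T4", "T12"),
                  end_vertebrae = c("T4", "T12")),
      region_spec("lumbar_L1L5", span_elements(lv, "L1", "L5"),
                  end_vertebrae = c("L1", "L5"))
    ))
  }
  out <- list()
  for (cv in curves) {
    nm <- curve_region_name(cv$apex)
    if (nm %in% vapply(out, `[[`, "", "name")) next  # keep the first (larger) of duplicates
    out[[length(out) + 1]] <- region_spec(nm, span_elements(lv, cv$upper_end, cv$lower_end),
                                          end_vertebrae = c(cv$upper_end, cv$lower_end),
                                          apex = cv$apex)
    ia <- match(cv$apex, lv)
    if (ia <= 1 || ia >= length(lv)) {
      stop("apical zone of curve at ", cv$apex, " is truncated by the spine boundary",
           call. = FALSE)
    }
    out[[length(out) + 1]] <- region_spec(
      if (nm == "main_thoracic") "apical_thoracic" else "apical_lumbar",
      span_elements(lv, lv[ia - 1], lv[ia + 1]),
      end_vertebrae = c(lv[ia - 1], lv[ia + 1]), apex = cv$apex
    )
    if (nm == "main_thoracic") {
      iu <- match(cv$upper_end, lv); il <- match(cv$lower_end, lv)
      if (iu <= 1) {
        stop("proximal junctional segment above ", cv$upper_end,
             " is truncated by the spine boundary", call. = FALSE)
      }
      if (il >= length(lv)) {
        stop("distal junctional segment below ", cv$lower_end,
             " is truncated by the spine boundary", call. = FALSE)
      }
      out[[length(out) + 1]] <- region_spec("proximal_junctional",
                                            span_elements(lv, lv[iu - 1], cv$upper_end),
                                            end_vertebrae = c(lv[iu - 1], cv$upper_end))
      out[[length(out) + 1]] <- region_spec("distal_junctional",
                                            span_elements(lv, cv$lower_end, lv[il + 1]),
                                            end_vertebrae = c(cv$lower_end, lv[il + 1]))
    }
  }
  out
}

region_rotation <- function(spine, region) {
  if (!is.na(region$apex)) {
    v <- spine$vertebrae[[region$apex]]
    (v$superior$axial_rotation_deg + v$inferior$axial_rotation_deg) / 2
  } else {
    vlv <- region$elements[region$elements %in% spine$levels]
    mean(unlist(lapply(spine$vertebrae[vlv], function(v) {
      c(v$superior$axial_rotation_deg, v$inferior$axial_rotation_deg)
    })))
  }
}

#' Measure all regions of one subject
#'
#' @param spine a [spine_model()].
#' @param regions optional list of `region_spec`; when `NULL`, curves are
#'   detected and regions defined automatically.
#' @param cobb_floor,smooth_window,override passed to [detect_curves()].
#' @return data.frame, one row per region: `region`, `cobb_deg`,
#'   `axial_rotation_deg` (apex rotation for curve/apical regions, mean
#'   endplate rotation otherwise), `anterior_mm`, `posterior_mm`,
#'   `delta_ap_percent`, plus the curve limits.
#' @export
measure_subject <- function(spine, regions = NULL, cobb_floor = 10,
                            smooth_window = 3, override = NULL) {
  if (is.null(regions)) {
    curves <- detect_curves(spine, cobb_floor = cobb_floor,
                            smooth_window = smooth_window, override = override)
    regions <- define_regions(spine, curves)
  }
  heights <- element_heights(spine)
  rows <- lapply(regions, function(rg) {
    len <- region_lengths(heights, rg)
    ends <- rg$end_vertebrae
    cobb <- coronal_cobb(spine$vertebrae[[ends[1]]]$superior,
                         spine$vertebrae[[ends[2]]]$inferior)
    data.frame(
      region = rg$name,
      upper_end = ends[1], lower_end = ends[2], apex = rg$apex,
      cobb_deg = cobb,
      axial_rotation_deg = region_rotation(spine, rg),
      anterior_mm = unname(len["anterior_mm"]),
      posterior_mm = unname(len["posterior_mm"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$delta_ap_percent <- delta_ap(out$anterior_mm, out$posterior_mm)
  out
}

#' Measure a cohort of subjects into one table
#'
#' @param subjects list of subjects; each is either a [spine_model()] or a
#'   list with fields `spine`, `subject_id`, `group`, `pattern` and
#'   `standing_cobb` (named vector with entries `thoracic`/`lumbar`, degrees)
#'   as produced by [generate_cohort()].
#' @param ... passed to [measure_subject()].
#' @return data.frame with one row per subject and region, unique on
#'   (`subject_id`, `region`), including `standing_cobb_deg` for the curve
#'   the region belongs to.
#' @export
measure_cohort <- function(subjects, ...) {
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (inherits(s, "spine_model")) s <- list(spine = s)
    spine <- s$spine
    m <- measure_subject(spine, ...)
    m$subject_id <- if (!is.null(s$subject_id)) s$subject_id else
      if (!is.null(spine$subject_id)) spine$subject_id else sprintf("subject_%03d", i)
    m$group <- if (!is.null(s$group)) s$group else NA_character_
    m$pattern <- if (!is.null(s$pattern)) s$pattern else NA_character_
    thoracic_regions <- c("main_thoracic", "apical_thoracic",
                          "proximal_junctional", "distal_junctional")
    m$standing_cobb_deg <- NA_real_
    if (!is.null(s$standing_cobb)) {
      m$standing_cobb_deg[m$region %in% thoracic_regions] <- s$standing_cobb[["thoracic"]]
      m$standing_cobb_deg[m$region %in% c("thoracolumbar", "apical_lumbar")] <-
        s$standing_cobb[["lumbar"]]
    }
    m
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out[, c("subject_id", "region")]))
  rownames(out) <- NULL
  out[, c("subject_id", "group", "pattern", "region", "upper_end", "lower_end",
          "apex", "cobb_deg", "axial_rotation_deg", "anterior_mm",
          "posterior_mm", "delta_ap_percent", "standing_cobb_deg")]
}
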