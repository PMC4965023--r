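# Interchange formats: contour JSON (canonical), cohort CSV, report JSON,
# YAML run configuration. Every artifact carries the seed and a config hash
# so a run is replayable from its outputs.

#' Write a spine model to contour JSON
#'
#' One subject per file: `{subject_id, frame: "RAS-mm", levels: [{level,
#' side, points, canal_centroid}, ...]}`. Coordinates are millimetres in a
#' right-handed RAS frame (+x right, +y anterior, +z cranial).
#'
#' @param spine a [spine_model()] (contours are written in its measurement
#'   frame) or a plain list of [endplate_contour()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spine <- function(spine, path) {
  contours <- if (inherits(spine, "spine_model")) spine_contours(spine) else spine
  doc <- list(
    subject_id = if (inherits(spine, "spine_model") && !is.null(spine$subject_id))
      spine$subject_id else "subject",
    frame = "RAS-mm",
    levels = lapply(unname(contours), function(ct) {
      list(level = ct$level, side = ct$side,
           points = unname(apply(ct$points, 1, as.numeric, simplify = FALSE)),
           canal_centroid = as.numeric(ct$canal_centroid))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spine model from contour JSON
#'
#' Validates the schema field by field (naming the offending level in error
#' messages) and assembles a [spine_model()].
#'
#' @param path contour JSON file written by [write_spine()] or compatible.
#' @param validate run full geometric contour validation.
#' @return a [spine_model()].
#' @export
read_spine <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path)
  for (field in c("subject_id", "frame", "levels")) {
    if (is.null(doc[[field]])) {
      stop("contour file ", path, ": missing field '", field, "'", call. = FALSE)
    }
  }
  if (!identical(doc$frame, "RAS-mm")) {
    stop("contour file ", path, ": unsupported frame '", doc$frame,
         "' (expected RAS-mm)", call. = FALSE)
  }
  contours <- lapply(doc$levels, function(entry) {
    level <- entry$level; side <- entry$side
    if (is.null(level) || !is.character(level) || !(level %in% LEVELS_ALL)) {
      stop("contour file ", path, ": malformed level label '",
           paste(unlist(level), collapse = ""), "'", call. = FALSE)
    }
    if (is.null(side) || !(side %in% c("superior", "inferior"))) {
      stop("contour file ", path, ": field 'side' invalid at level ", level,
           call. = FALSE)
    }
    rows <- lapply(entry$points, function(p) as.numeric(unlist(p)))
    if (length(rows) < 12 || any(lengths(rows) != 3)) {
      stop("contour file ", path, ": field 'points' invalid at level ", level,
           call. = FALSE)
    }
    pts <- do.call(rbind, rows)
    canal <- as.numeric(unlist(entry$canal_centroid))
    if (length(canal) != 3 || anyNA(canal)) {
      stop("contour file ", path, ": field 'canal_centroid' invalid at level ",
           level, call. = FALSE)
    }
    if (anyNA(pts)) {
      stop("contour file ", path, ": field 'points' invalid at level ", level,
           call. = FALSE)
    }
    endplate_contour(level, side, pts, canal, validate = validate)
  })
  spine_model(contours, subject_id = doc$subject_id, validate = FALSE)
}

#' Write / read a cohort measurement table
#'
#' Plain CSV with one row per subject and region; columns as documented in
#' [measure_cohort()].
#'
#' @param tbl cohort table.
#' @param path CSV file.
#' @return `path` (write) or the table (read).
#' @export
write_cohort_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#'
#' Recognized top-level keys: `seed`, `ais` / `control` (cohort sizes and
#' overrides), `thresholds` (`cobb_floor_deg`, `smooth_window`), `out`.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return named list with validated entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "ais", "control", "thresholds", "out", "raster")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

# Tiny stable FNV-1a hash over a canonical serialization; used to stamp
# artifacts so a run is identifiable from its outputs.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  # 32-bit FNV-1a in split 16-bit arithmetic (doubles cannot hold the full
  # 32x25-bit product exactly)
  h_lo <- 2166136261 %% 65536
  h_hi <- 2166136261 %/% 65536
  prime <- 16777619
  for (b in bytes) {
    h_lo <- bitwXor(h_lo, b)
    prod_lo <- h_lo * prime
    prod_hi <- (h_hi * prime) %% 65536
    tot <- (prod_lo + prod_hi * 65536) %% 4294967296
    h_lo <- tot %% 65536
    h_hi <- tot %/% 65536
  }
  sprintf("%04x%04x", h_hi, h_lo)
}

# Serializable provenance stamp for output directories.
run_stamp <- function(config, seed) {
  list(seed = seed, config_hash = config_hash(config),
       package = "spinemorph",
       version = as.character(utils::packageVersion("spinemorph")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# Flatten a paper_battery (or any nested result list) into plain lists for
# JSON serialization.
report_to_list <- function(x) {
  if (inherits(x, c("test_result", "association_result", "reliability_result"))) {
    return(lapply(unclass(x), report_to_list))
  }
  if (is.list(x)) return(lapply(x, report_to_list))
  x
}

#' Write an analysis report to JSON
#'
#' @param report a `paper_battery` (or any nested list of results).
#' @param path output JSON file.
#' @param stamp optional provenance stamp to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, stamp = NULL) {
  payload <- report_to_list(report)
  if (!is.null(stamp)) payload$run <- stamp
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Scatterplots of the three-plane couplings
#'
#' Simple static plots of measured Cobb angle, apex rotation and delta(A-P)
#' of the main thoracic curve against the simulated standing Cobb angle,
#' with the least-squares line.
#'
#' @param tbl cohort table from [measure_cohort()].
#' @param file optional PNG path; when `NULL`, plots on the active device.
#' @return invisibly, the list of [pearson_with_regression()] fits.
#' @export
plot_coupling <- function(tbl, file = NULL) {
  mt <- tbl[tbl$region == "main_thoracic" & is.finite(tbl$standing_cobb_deg), ]
  if (nrow(mt) < 3) stop("not enough thoracic curves with standing Cobb", call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 420)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old), add = TRUE)
  panels <- list(
    c("cobb_deg", "CT Cobb (deg)"),
    c("axial_rotation_deg", "apex axial rotation (deg)"),
    c("delta_ap_percent", "delta(A-P) (%)")
  )
  fits <- lapply(panels, function(p) {
    fit <- pearson_with_regression(mt$standing_cobb_deg, mt[[p[1]]])
    graphics::plot(mt$standing_cobb_deg, mt[[p[1]]],
                   xlab = "standing Cobb (deg)", ylab = p[2],
                   main = sprintf("r = %.2f", fit$pearson_r), pch = 19,
                   col = "grey30")
    graphics::abline(fit$intercept, fit$slope, col = "red3", lwd = 2)
    fit
  })
  invisible(fits)
}
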