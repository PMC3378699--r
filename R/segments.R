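# AHA 16-segment partitioning with epicardial/endocardial compartments and
# regional time courses.
#
# Segment angles use the displayed (foot-to-head) view: the visual angle of
# a voxel is measured counterclockwise from east as it appears on screen,
# and AHA ordering proceeds counterclockwise from segment 1 (anterior),
# which by default is centered at 12 o'clock.  Basal and mid slices carry
# six equiangular segments (AHA 1-6 / 7-12), the apical slice four
# (AHA 13-16); segment 17 (apex cap) is excluded.

AHA_NAMES_6 <- c("anterior", "anteroseptal", "inferoseptal",
                 "inferior", "inferolateral", "anterolateral")
AHA_NAMES_4 <- c("anterior", "septal", "inferior", "lateral")

#' AHA segment model for one slice level
#'
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @param reference_angle_deg Visual angle (degrees counterclockwise from
#'   east, as displayed) at which segment 1 starts.  The default centers
#'   the anterior segment at 12 o'clock; the anatomical landmark anchoring
#'   it is a user choice.
#' @return A `segment_model` with `n_segments` (6 basal/mid, 4 apical),
#'   segment `names`, global AHA `ids` (basal 1-6, mid 7-12, apical 13-16)
#'   and the segment width in degrees.
#' @export
segment_model <- function(slice_level = c("mid", "basal", "apical"),
                          reference_angle_deg = NULL) {
  slice_level <- match.arg(slice_level)
  ns <- if (slice_level == "apical") 4L else 6L
  width <- 360 / ns
  ref <- reference_angle_deg %||% (90 - width / 2)
  ids <- switch(slice_level, basal = 1:6, mid = 7:12, apical = 13:16)
  structure(list(slice_level = slice_level, n_segments = ns,
                 width_deg = width, reference_angle_deg = ref,
                 names = if (ns == 6L) AHA_NAMES_6 else AHA_NAMES_4,
                 ids = ids),
            class = "segment_model")
}

visual_angle_deg <- function(dx, dy) (atan2(-dy, dx) * 180 / pi) %% 360

#' Partition a mask frame into equiangular segments
#'
#' Assigns every mask voxel to exactly one segment by its visual polar
#' angle about the center; boundaries are half-open
#' `[start, start + width)`, so the labels form a disjoint cover of the
#' mask.
#'
#' @param mask_frame Logical matrix, non-empty.
#' @param center `(x, y)` in mm.
#' @param model A [segment_model()].
#' @param voxel_mm Voxel size in mm.
#' @return Integer matrix of local segment labels (1..n_segments, NA off
#'   the mask).
#' @export
partition <- function(mask_frame, center, model, voxel_mm) {
  if (!any(mask_frame)) stop("empty mask")
  g <- coord_grids(dim(mask_frame), voxel_mm)
  ang <- visual_angle_deg(g$x - center[1L], g$y - center[2L])
  lab <- 1L + (floor(((ang - model$reference_angle_deg) %% 360) /
                       model$width_deg) %% model$n_segments)
  lab[!mask_frame] <- NA_integer_
  lab
}

#' Split segment voxels into epicardial and endocardial compartments
#'
#' Per segment, voxels with radius below the segment's median voxel radius
#' form the endocardial compartment, the rest (radius >= median) the
#' epicardial one.
#'
#' @param labels Integer label matrix from [partition()].
#' @param center `(x, y)` in mm.
#' @param voxel_mm Voxel size in mm.
#' @return Character matrix (`"endo"`/`"epi"`, NA off the mask).
#' @export
split_epi_endo <- function(labels, center, voxel_mm) {
  g <- coord_grids(dim(labels), voxel_mm)
  r <- sqrt((g$x - center[1L])^2 + (g$y - center[2L])^2)
  comp <- matrix(NA_character_, nrow(labels), ncol(labels))
  for (s in sort(unique(labels[!is.na(labels)]))) {
    idx <- which(labels == s)
    if (length(idx) < 2L)
      stop("segment ", s, " has fewer than 2 voxels")
    med <- stats::median(r[idx])
    comp[idx] <- ifelse(r[idx] < med, "endo", "epi")
  }
  comp
}

#' Regional velocity time courses
#'
#' Per AHA segment, compartment (`full`, `epi`, `endo`) and velocity
#' component (`radial`, `tangential`, `longitudinal`), the voxel-mean
#' velocity per frame, together with voxel counts, the median voxel radius
#' of each segment/compartment per frame, and (for the tangential
#' component) the voxel-mean angular velocity `mean(v_phi / r)`, which is
#' exact under rigid rotation and feeds the twist integration.  A segment
#' empty at some frame yields missing values, never zeros.
#'
#' @param pf A [polar_field()].
#' @param model A [segment_model()].
#' @return Data frame with columns `frame`, `time_ms`, `segment` (AHA id),
#'   `segment_name`, `compartment`, `component`, `v_cm_s`, `n_vox`,
#'   `median_radius_mm`, `v_rot_rad_s`.
#' @export
regional_time_courses <- function(pf, model) {
  stopifnot(inherits(pf, "polar_field"), inherits(model, "segment_model"))
  nf <- dim(pf$v_r)[3L]
  g <- coord_grids(dim(pf$v_r)[1:2], pf$voxel_mm)
  comps <- list(radial = pf$v_r, tangential = pf$v_phi)
  if (!is.null(pf$v_z)) comps$longitudinal <- pf$v_z
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    m <- pf$mask[, , f]
    ctr <- pf$centers[f, ]
    lab <- partition(m, ctr, model, pf$voxel_mm)
    cp <- split_epi_endo(lab, ctr, pf$voxel_mm)
    r <- sqrt((g$x - ctr[1L])^2 + (g$y - ctr[2L])^2)
    out <- expand.grid(seg = seq_len(model$n_segments),
                       compartment = c("full", "epi", "endo"),
                       component = names(comps),
                       stringsAsFactors = FALSE)
    vals <- mapply(function(s, cpart, comp) {
      sel <- !is.na(lab) & lab == s
      if (cpart != "full") sel <- sel & !is.na(cp) & cp == cpart
      if (!any(sel)) return(c(NA_real_, 0, NA_real_, NA_real_))
      v <- comps[[comp]][, , f][sel]
      # voxelwise angular velocity (exact for rigid rotation); only
      # meaningful for the tangential component
      vrot <- if (comp == "tangential") mean(v / (r[sel] / 10)) else NA_real_
      c(mean(v), sum(sel), stats::median(r[sel]), vrot)
    }, out$seg, out$compartment, out$component)
    rows[[f]] <- data.frame(
      frame = f, time_ms = (f - 1) * pf$frame_interval_ms,
      segment = model$ids[out$seg],
      segment_name = model$names[out$seg],
      compartment = out$compartment, component = out$component,
      v_cm_s = vals[1L, ], n_vox = as.integer(vals[2L, ]),
      median_radius_mm = vals[3L, ], v_rot_rad_s = vals[4L, ])
  }
  res <- do.call(rbind, rows)
  attr(res, "model") <- model
  attr(res, "frame_interval_ms") <- pf$frame_interval_ms
  res
}

#' Peak systolic and diastolic velocities of a series
#'
#' Peak systole is the maximum of the series inside the systolic window,
#' peak diastole the minimum inside the diastolic window.  Missing frames
#' propagate to a missing peak.
#'
#' @param values Numeric velocity series.
#' @param systole_idx,diastole_idx Integer frame windows (must be
#'   non-empty and within the series).
#' @return Named numeric `c(peak_sys, peak_dia)`.
#' @export
peak_velocities <- function(values, systole_idx, diastole_idx) {
  if (length(systole_idx) == 0L || length(diastole_idx) == 0L)
    stop("empty phase window")
  if (max(systole_idx, diastole_idx) > length(values) ||
      min(systole_idx, diastole_idx) < 1L)
    stop("phase window outside the series")
  sys <- values[systole_idx]; dia <- values[diastole_idx]
  c(peak_sys = if (anyNA(sys)) NA_real_ else max(sys),
    peak_dia = if (anyNA(dia)) NA_real_ else min(dia))
}

#' Peak-velocity table for one slice
#'
#' Applies [peak_velocities()] to every segment x compartment x component
#' series of a regional time-course table.  The default windows split the
#' cycle at end-systole: systole is frames `[1, es_frame]`, diastole
#' `(es_frame, n]`.
#'
#' @param regional Output of [regional_time_courses()].
#' @param es_frame End-systolic frame (1-based).
#' @return Data frame with `segment`, `segment_name`, `compartment`,
#'   `component`, `peak_sys`, `peak_dia`.
#' @export
peak_table <- function(regional, es_frame) {
  nf <- max(regional$frame)
  if (es_frame < 1L || es_frame >= nf) stop("es_frame outside the cycle")
  sys_idx <- seq_len(es_frame)
  dia_idx <- seq.int(es_frame + 1L, nf)
  key <- unique(regional[, c("segment", "segment_name", "compartment",
                             "component")])
  pk <- t(apply(key, 1L, function(k) {
    sel <- regional$segment == as.integer(k[["segment"]]) &
      regional$compartment == k[["compartment"]] &
      regional$component == k[["component"]]
    v <- regional$v_cm_s[sel][order(regional$frame[sel])]
    peak_velocities(v, sys_idx, dia_idx)
  }))
  out <- cbind(key, peak_sys = pk[, 1L], peak_dia = pk[, 2L])
  rownames(out) <- NULL
  out
}

#' Cross-subject bull's-eye table
#'
#' Mean and sample SD of per-subject segment values in AHA order; segment
#' 17 never appears (the model stops at 16).
#'
#' @param subject_values List of data frames with columns `segment` and
#'   `value`, one per subject; all subjects must cover the same segments.
#' @return Data frame with `segment`, `mean`, `sd`, `n`.
#' @export
bullseye <- function(subject_values) {
  stopifnot(length(subject_values) >= 1L)
  segs <- sort(unique(subject_values[[1L]]$segment))
  if (any(segs > 16L)) stop("segment ids beyond 16 are not part of the model")
  for (sv in subject_values)
    if (!identical(sort(unique(sv$segment)), segs))
      stop("inconsistent segment sets across subjects")
  m <- vapply(subject_values, function(sv)
    sv$value[match(segs, sv$segment)], numeric(length(segs)))
  m <- matrix(m, nrow = length(segs))
  data.frame(segment = segs,
             mean = rowMeans(m),
             sd = if (ncol(m) > 1L) apply(m, 1L, stats::sd) else 0,
             n = ncol(m))
}
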