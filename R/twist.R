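# Twist and torsion: angular velocity from tangential velocity and the
# segment's median radius, twist by trapezoidal time integration from
# end-diastole to end-systole, torsion as apical minus basal twist.

#' Angular velocity from tangential velocity
#'
#' `v_rot = v_phi / r` with the units reconciled (cm/s over cm), keeping
#' the sign of `v_phi` (positive = clockwise, foot-to-head view).
#'
#' @param v_phi_cm_s Mean tangential velocity (cm/s), vectorized.
#' @param r_median_mm Median radius of the segment (mm), > 0.
#' @return Angular velocity in rad/s.
#' @export
angular_velocity <- function(v_phi_cm_s, r_median_mm) {
  if (any(r_median_mm <= 0, na.rm = TRUE)) stop("median radius must be > 0")
  v_phi_cm_s / (r_median_mm / 10)
}

#' Twist angle by temporal integration
#'
#' Trapezoidal integral of the angular-velocity series over the
#' end-diastole to end-systole window at the native frame interval,
#' converted to degrees.  The rule telescopes, so twist is additive over
#' adjacent windows.
#'
#' @param v_rot Angular-velocity series (rad/s), one value per frame.
#' @param frame_interval_ms Frame interval in ms.
#' @param ed_frame,es_frame Integration window (1-based frames,
#'   `ed_frame < es_frame`, both inside the series).
#' @return Twist in degrees.
#' @export
twist <- function(v_rot, frame_interval_ms, ed_frame = 1L, es_frame) {
  if (ed_frame >= es_frame) stop("integration window must satisfy ED < ES")
  if (ed_frame < 1L || es_frame > length(v_rot))
    stop("integration window outside the series")
  idx <- ed_frame:es_frame
  t_s <- (idx - 1) * frame_interval_ms / 1000
  trapz(t_s, v_rot[idx]) * 180 / pi
}

#' Torsion of a wall
#'
#' Defined as apical twist minus basal twist over the same normalized
#' window.
#'
#' @param twist_apical_deg,twist_basal_deg Twist angles in degrees.
#' @return Torsion in degrees.
#' @export
torsion <- function(twist_apical_deg, twist_basal_deg) {
  twist_apical_deg - twist_basal_deg
}

#' Collapse six-segment values onto the four apical walls
#'
#' The two septal segments (anteroseptal, inferoseptal) average into
#' `septum`, the two lateral ones (inferolateral, anterolateral) into
#' `lateral`; anterior and inferior map one to one.
#'
#' @param values Named numeric vector over the six basal/mid segment names.
#' @return Named numeric vector over `septum`, `inferior`, `lateral`,
#'   `anterior`.
#' @export
wall_map_6_to_4 <- function(values) {
  req <- AHA_NAMES_6
  if (!all(req %in% names(values)))
    stop("unknown or missing segment name; expected: ",
         paste(req, collapse = ", "))
  c(septum = unname((values[["anteroseptal"]] + values[["inferoseptal"]]) / 2),
    inferior = unname(values[["inferior"]]),
    lateral = unname((values[["inferolateral"]] + values[["anterolateral"]]) / 2),
    anterior = unname(values[["anterior"]]))
}

#' Twist per segment and compartment for one slice
#'
#' Integrates each segment's/compartment's angular-velocity series (the
#' voxel-mean of `v_phi / r`, which recovers a rigid rotation exactly)
#' from end-diastole to end-systole.  Each compartment uses its own voxel
#' set.
#'
#' @param regional Output of [regional_time_courses()].
#' @param es_frame End-systolic frame.
#' @param ed_frame End-diastolic frame (default 1, the trigger).
#' @return Data frame with `segment`, `segment_name`, `compartment`,
#'   `twist_deg`, `ed_frame`, `es_frame`.
#' @export
twist_table <- function(regional, es_frame, ed_frame = 1L) {
  dt <- attr(regional, "frame_interval_ms")
  if (is.null(dt)) stop("regional table lacks its frame interval attribute")
  tang <- regional[regional$component == "tangential", ]
  key <- unique(tang[, c("segment", "segment_name", "compartment")])
  tw <- apply(key, 1L, function(k) {
    sel <- tang$segment == as.integer(k[["segment"]]) &
      tang$compartment == k[["compartment"]]
    sub <- tang[sel, ][order(tang$frame[sel]), ]
    twist(sub$v_rot_rad_s, dt, ed_frame, es_frame)
  })
  out <- cbind(key, twist_deg = tw, ed_frame = ed_frame, es_frame = es_frame)
  rownames(out) <- NULL
  out
}

#' Torsion table across a basal and an apical slice
#'
#' Maps the six basal twists onto the four apical walls with
#' [wall_map_6_to_4()] and subtracts them from the apical twists, per
#' compartment (`full` is reported as `overall`).
#'
#' @param twist_basal,twist_apical [twist_table()] outputs for a basal
#'   (6-segment) and an apical (4-segment) slice.
#' @return Data frame with `wall`, `compartment` (`overall`/`epi`/`endo`),
#'   `torsion_deg`, `twist_apical_deg`, `twist_basal_deg`.
#' @export
torsion_table <- function(twist_basal, twist_apical) {
  walls <- c("septum", "inferior", "lateral", "anterior")
  ap_name <- c(septum = "septal", inferior = "inferior",
               lateral = "lateral", anterior = "anterior")
  rows <- list()
  for (comp in c("full", "epi", "endo")) {
    b <- twist_basal[twist_basal$compartment == comp, ]
    a <- twist_apical[twist_apical$compartment == comp, ]
    bv <- stats::setNames(b$twist_deg, b$segment_name)
    b4 <- wall_map_6_to_4(bv)
    av <- stats::setNames(a$twist_deg, a$segment_name)
    for (w in walls) {
      ap <- av[[if (ap_name[[w]] == "septal") "septal" else ap_name[[w]]]]
      rows[[length(rows) + 1L]] <- data.frame(
        wall = w,
        compartment = if (comp == "full") "overall" else comp,
        torsion_deg = torsion(ap, b4[[w]]),
        twist_apical_deg = ap, twist_basal_deg = b4[[w]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
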