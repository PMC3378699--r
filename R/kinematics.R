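# Polar decomposition of the velocity field about the LV center of mass,
# bulk-motion correction, and global time courses.
#
# Sign conventions (displayed image = foot-to-head view, y down):
#   v_r   positive toward the center of mass (contraction),
#   v_phi positive clockwise as displayed,
#   v_z   positive base-to-apex.

#' Center of mass of a mask frame
#'
#' Unweighted centroid of the myocardial mask voxel centers, in mm.
#'
#' @param mask_frame Logical matrix.
#' @param voxel_mm Voxel size in mm.
#' @return Numeric `(x, y)` in mm.
#' @export
center_of_mass <- function(mask_frame, voxel_mm) {
  if (!any(mask_frame)) stop("empty mask")
  g <- coord_grids(dim(mask_frame), voxel_mm)
  c(mean(g$x[mask_frame]), mean(g$y[mask_frame]))
}

#' Bulk-motion correction of one velocity frame
#'
#' Subtracts the myocardial-mask mean of each component from every voxel of
#' that component, removing global translational motion.  The
#' post-correction mask means are zero to machine precision.
#'
#' @param vx,vy Velocity matrices (cm/s).
#' @param vz Velocity matrix or `NULL`.
#' @param mask_frame Logical matrix, non-empty.
#' @return List of corrected `vx`, `vy`, `vz`.
#' @export
bulk_correct <- function(vx, vy, vz = NULL, mask_frame) {
  if (!any(mask_frame)) stop("empty mask")
  list(vx = vx - mean(vx[mask_frame]),
       vy = vy - mean(vy[mask_frame]),
       vz = if (!is.null(vz)) vz - mean(vz[mask_frame]))
}

#' Cartesian to polar velocity components
#'
#' Projects in-plane velocities onto the radial and tangential directions
#' about `center`: with the outward unit vector `r^` and the clockwise
#' (as displayed, foot-to-head) tangential unit vector `t^`,
#' `v_r = -(v . r^)` (positive toward the center, i.e. contraction) and
#' `v_phi = +(v . t^)` (positive clockwise).  A voxel coinciding with the
#' center has no defined direction and is excluded with a warning.
#'
#' @param vx,vy Velocity matrices (cm/s).
#' @param mask_frame Logical matrix; components are returned on mask voxels
#'   only (`NA` elsewhere).
#' @param center `(x, y)` center in mm.
#' @param voxel_mm Voxel size in mm.
#' @return List of matrices `v_r`, `v_phi` (NA off the mask).
#' @export
to_polar <- function(vx, vy, mask_frame, center, voxel_mm) {
  g <- coord_grids(dim(vx), voxel_mm)
  dx <- g$x - center[1L]; dy <- g$y - center[2L]
  r <- sqrt(dx^2 + dy^2)
  degen <- mask_frame & r < voxel_mm * 1e-9
  if (any(degen)) {
    warning("excluding ", sum(degen), " voxel(s) coinciding with the center")
    mask_frame <- mask_frame & !degen
  }
  v_r <- v_phi <- matrix(NA_real_, nrow(vx), ncol(vx))
  m <- mask_frame
  v_r[m] <- -(vx[m] * dx[m] + vy[m] * dy[m]) / r[m]
  v_phi[m] <- (-vx[m] * dy[m] + vy[m] * dx[m]) / r[m]
  list(v_r = v_r, v_phi = v_phi)
}

#' Polar velocity field over all frames
#'
#' Per frame: recomputes the center of mass from the mask, bulk-corrects
#' all components, and projects to radial/tangential components.  Because
#' bulk correction zeroes the mask mean of every component, the global
#' longitudinal time course is taken from the *uncorrected* v_z (otherwise
#' it would be identically zero); regional maps use the corrected one.
#' The in-plane speed is preserved voxelwise by the projection.
#'
#' @param vel A [velocity_field()].
#' @param seg An `lv_segmentation` rasterized at the same matrix.
#' @return An object of class `polar_field`: arrays `v_r`, `v_phi`, `v_z`
#'   (bulk-corrected, NA off the mask; `v_z` `NULL` if absent), `centers`
#'   (`n_frames x 2`, mm), the global time-course data frame (see
#'   [global_time_course()]), `voxel_mm` and the mask.
#' @export
polar_field <- function(vel, seg) {
  stopifnot(inherits(vel, "velocity_field"),
            inherits(seg, "lv_segmentation"))
  d <- dim(vel$vx)
  if (!identical(d[1:2], seg$dim))
    stop("segmentation grid (", seg$dim[1L],
         ") does not match the velocity field (", d[1L], ")")
  nf <- d[3L]
  v_r <- v_phi <- array(NA_real_, d)
  v_z <- if (!is.null(vel$vz)) array(NA_real_, d)
  centers <- matrix(NA_real_, nf, 2L)
  vz_global <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    m <- seg$mask[, , f]
    ctr <- center_of_mass(m, seg$voxel_mm)
    centers[f, ] <- ctr
    vzf <- if (!is.null(vel$vz)) vel$vz[, , f]
    if (!is.null(vzf)) vz_global[f] <- mean(vzf[m])
    bc <- bulk_correct(vel$vx[, , f], vel$vy[, , f], vzf, m)
    pol <- to_polar(bc$vx, bc$vy, m, ctr, seg$voxel_mm)
    v_r[, , f] <- pol$v_r
    v_phi[, , f] <- pol$v_phi
    if (!is.null(v_z)) { tmp <- matrix(NA_real_, d[1L], d[2L]); tmp[m] <- bc$vz[m]; v_z[, , f] <- tmp }
  }
  obj <- structure(list(v_r = v_r, v_phi = v_phi, v_z = v_z,
                        centers = centers, mask = seg$mask,
                        voxel_mm = seg$voxel_mm,
                        frame_interval_ms = vel$meta$frame_interval_ms,
                        meta = vel$meta, vz_global_raw = vz_global),
                   class = "polar_field")
  obj$global <- global_time_course(obj)
  obj
}

#' Global velocity time courses
#'
#' Mask-mean radial, tangential and longitudinal velocity per frame, with
#' time stamps `(frame - 1) * frame_interval_ms` from the trigger.  The
#' longitudinal series is the pre-bulk-correction mask mean (bulk
#' correction would zero it by construction).
#'
#' @param pf A [polar_field()].
#' @return Data frame with columns `frame`, `time_ms`, `v_r`, `v_phi`,
#'   `v_z` (NA when no through-plane encoding exists).
#' @export
global_time_course <- function(pf) {
  stopifnot(inherits(pf, "polar_field"))
  nf <- dim(pf$v_r)[3L]
  out <- data.frame(frame = seq_len(nf),
                    time_ms = (seq_len(nf) - 1) * pf$frame_interval_ms)
  out$v_r <- vapply(seq_len(nf), function(f) {
    m <- pf$mask[, , f]; if (!any(m)) stop("empty mask at frame ", f)
    mean(pf$v_r[, , f][m])
  }, numeric(1))
  out$v_phi <- vapply(seq_len(nf), function(f)
    mean(pf$v_phi[, , f][pf$mask[, , f]]), numeric(1))
  out$v_z <- if (!is.null(pf$v_z)) pf$vz_global_raw else NA_real_
  out
}

#' Cohort averaging of time courses normalized to end-systole
#'
#' Each subject's time axis is rescaled linearly so that end-systole maps
#' to normalized time 1 (the cycle end maps to its own rescaled position);
#' the series are resampled by linear interpolation onto a common
#' normalized grid and averaged pointwise.  Amplitudes are untouched.
#'
#' @param series_list List of numeric vectors, one per subject.
#' @param es_index Integer vector (or scalar) of end-systolic frame indices
#'   (1-based; the frame at the trigger is 1, so `es_index` must be > 1).
#' @param n_out Number of points of the common grid (default: the longest
#'   series).
#' @return Data frame with `t_norm`, `mean`, `sd`, `n`.
#' @export
normalize_and_average <- function(series_list, es_index, n_out = NULL) {
  stopifnot(length(series_list) >= 1L)
  es_index <- rep_len(es_index, length(series_list))
  if (any(es_index <= 1L)) stop("es_index must be > 1")
  n_out <- n_out %||% max(lengths(series_list))
  # normalized time of frame k (k = 1 at trigger): (k-1)/(es-1)
  t_end <- min(vapply(seq_along(series_list), function(i)
    (length(series_list[[i]]) - 1) / (es_index[i] - 1), numeric(1)))
  grid <- seq(0, t_end, length.out = n_out)
  resampled <- vapply(seq_along(series_list), function(i) {
    y <- series_list[[i]]
    tn <- (seq_along(y) - 1) / (es_index[i] - 1)
    stats::approx(tn, y, xout = grid)$y
  }, numeric(n_out))
  resampled <- matrix(resampled, nrow = n_out)
  data.frame(t_norm = grid,
             mean = rowMeans(resampled),
             sd = if (ncol(resampled) > 1L) apply(resampled, 1L, stats::sd)
                  else rep(0, n_out),
             n = length(series_list))
}
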