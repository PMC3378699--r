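# Method-comparison and disease-normalization statistics.

#' Percent change of a diseased value against control
#'
#' `delta = 100 * (v_ir - v_control) / v_control`.  The signed denominator
#' keeps the reading meaningful for signed components: a reduced magnitude
#' (weaker contraction, or weaker relaxation on a negative diastolic peak)
#' reads negative either way, and the measure is invariant under rescaling
#' both inputs by any nonzero factor.  A zero control value is undefined
#' and reported missing.
#'
#' @param v_ir,v_control Velocities (vectorized).
#' @return Percent difference(s); `NA` where the control is zero.
#' @export
ir_normalize <- function(v_ir, v_control) {
  out <- 100 * (v_ir - v_control) / v_control
  out[v_control == 0] <- NA_real_
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is the mean difference, the limits of
#' agreement are bias plus/minus 2 sample standard deviations (the 2-SD
#' convention, not 1.96).
#'
#' @param a,b Paired measurement vectors (>= 3 pairs).
#' @param min_pairs Minimum number of pairs accepted (default 3; the
#'   sample SD is defined from 2 pairs up, so 2 is the lowest usable
#'   value).
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`, `n_points`.
#' @export
bland_altman <- function(a, b, min_pairs = 3L) {
  if (length(a) != length(b)) stop("a and b must be paired")
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  if (length(d) < max(2L, min_pairs))
    stop("Bland-Altman needs at least ", max(2L, min_pairs), " pairs")
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd_diff = sdd,
       loa_low = bias - 2 * sdd, loa_high = bias + 2 * sdd,
       n_points = length(d))
}

#' Regression with a slope-equals-one test
#'
#' Ordinary least squares of `b` on `a` (free intercept) with the Pearson
#' correlation and a two-sided Student's t-test of the null hypothesis
#' that the slope equals `null_slope`, on `n - 2` degrees of freedom.  A
#' perfect fit (zero residual standard error) cannot reject: if the slope
#' equals the null the p-value is 1, otherwise 0.
#'
#' @param a Predictor (the reference method).
#' @param b Response (the test method).
#' @param null_slope Null-hypothesis slope (default 1).
#' @return List with `slope`, `intercept`, `pearson_r`, `se_slope`,
#'   `t`, `p_slope`, `n_points`.
#' @export
regression_slope_test <- function(a, b, null_slope = 1) {
  if (length(a) != length(b)) stop("a and b must be paired")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("regression needs at least 3 pairs")
  if (stats::var(a) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(b ~ a)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r <- stats::cor(a, b)
  rss <- sum(stats::residuals(fit)^2)
  se <- sqrt(rss / (n - 2)) / sqrt(sum((a - mean(a))^2))
  # a numerically perfect fit leaves only rounding residue; the t-test is
  # then degenerate (p = 1 at the null slope, 0 elsewhere)
  perfect <- rss <= .Machine$double.eps^0.5 * sum((b - mean(b))^2)
  if (perfect || se == 0) {
    p <- if (isTRUE(all.equal(slope, null_slope))) 1 else 0
    tval <- if (p == 1) 0 else Inf
  } else {
    tval <- (slope - null_slope) / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(slope = slope, intercept = intercept, pearson_r = r,
       se_slope = se, t = tval, p_slope = p, n_points = n)
}

#' Full agreement report between two methods
#'
#' Combines [regression_slope_test()] and [bland_altman()] on
#' frame-matched pairs, truncating to the shorter series when the frame
#' counts differ (as when bright-blood cines carry a couple more frames).
#'
#' @param a,b Velocity series of the two methods.
#' @return List of class `agreement_report` with the regression and
#'   Bland-Altman fields.
#' @export
agreement_report <- function(a, b) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  reg <- regression_slope_test(a, b)
  ba <- bland_altman(a, b)
  structure(c(reg, ba), class = "agreement_report")
}

#' Angular synchrony correlation map
#'
#' Pearson correlation of each angular segment's mean radial-velocity time
#' course with the global radial time course.  Values near 1 characterize
#' synchronous contraction/expansion; artifact-corrupted sectors fall
#' away from 1.  A constant series has no defined correlation and is
#' reported missing.
#'
#' @param segment_series Numeric matrix, one column per angular segment
#'   (conventionally 24), rows = frames.
#' @param global_series Global velocity time course (same number of
#'   frames, length >= 3).
#' @return Numeric vector of per-segment correlation coefficients.
#' @export
correlation_map <- function(segment_series, global_series) {
  segment_series <- as.matrix(segment_series)
  if (nrow(segment_series) != length(global_series))
    stop("segment and global series lengths differ")
  if (length(global_series) < 3L) stop("series too short to correlate")
  apply(segment_series, 2L, function(s) {
    if (stats::sd(s) == 0 || stats::sd(global_series) == 0) return(NA_real_)
    stats::cor(s, global_series)
  })
}

#' Mean radial velocity in equiangular sectors
#'
#' Helper feeding [correlation_map()]: partitions the myocardium of every
#' frame into `n_sectors` equiangular sectors about the per-frame center
#' and returns each sector's mean radial velocity over time.
#'
#' @param pf A [polar_field()].
#' @param n_sectors Number of angular sectors (default 24).
#' @return Matrix `[n_frames, n_sectors]`.
#' @export
sector_time_courses <- function(pf, n_sectors = 24L) {
  stopifnot(inherits(pf, "polar_field"))
  nf <- dim(pf$v_r)[3L]
  g <- coord_grids(dim(pf$v_r)[1:2], pf$voxel_mm)
  out <- matrix(NA_real_, nf, n_sectors)
  width <- 360 / n_sectors
  for (f in seq_len(nf)) {
    m <- pf$mask[, , f]
    ang <- visual_angle_deg(g$x - pf$centers[f, 1L], g$y - pf$centers[f, 2L])
    lab <- 1L + (floor(ang / width) %% n_sectors)
    v <- pf$v_r[, , f]
    for (s in seq_len(n_sectors)) {
      sel <- m & lab == s
      if (any(sel)) out[f, s] <- mean(v[sel])
    }
  }
  out
}
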