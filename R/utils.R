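# Internal numeric helpers shared across modules.

# Centered FFT conventions: k-space frames are stored with DC at
# (floor(n/2)+1) in both dimensions ("centered"), so zero-filling is a
# plain symmetric pad.

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((floor(n1 / 2) + 1):n1, seq_len(floor(n1 / 2)))
  i2 <- c((floor(n2 / 2) + 1):n2, seq_len(floor(n2 / 2)))
  m[i1, i2, drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((ceiling(n1 / 2) + 1):n1, seq_len(ceiling(n1 / 2)))
  i2 <- c((ceiling(n2 / 2) + 1):n2, seq_len(ceiling(n2 / 2)))
  m[i1, i2, drop = FALSE]
}

# forward 2-D FFT, image -> centered k-space
fft2c <- function(img) {
  fftshift2(stats::fft(ifftshift2(img)))
}

# inverse 2-D FFT, centered k-space -> image (unitary up to 1/N)
ifft2c <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE)) / length(ksp)
}

# trapezoidal rule on (x, y) samples
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

# Voxel-center coordinate grids in mm.  Image convention: x increases with
# the column index (rightward as displayed), y with the row index
# (downward as displayed); origin at the first voxel center.
coord_grids <- function(dim, voxel_mm) {
  ny <- dim[1L]; nx <- dim[2L]
  list(
    x = matrix((seq_len(nx) - 1) * voxel_mm, ny, nx, byrow = TRUE),
    y = matrix((seq_len(ny) - 1) * voxel_mm, ny, nx)
  )
}

# Even-odd (crossing-number) polygon rasterization by scanline.  `poly` is
# an n x 2 matrix of (x, y) vertices in mm, implicitly closed.  A voxel
# belongs to the polygon iff its center lies inside under the even-odd rule.
rasterize_polygon <- function(poly, dim, voxel_mm) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L)
  ny <- dim[1L]; nx <- dim[2L]
  xs <- (seq_len(nx) - 1) * voxel_mm
  ys <- (seq_len(ny) - 1) * voxel_mm
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  mask <- matrix(FALSE, ny, nx)
  for (r in seq_len(ny)) {
    y0 <- ys[r]
    cr <- (y1 <= y0) != (y2 <= y0)
    if (!any(cr)) next
    xint <- sort(x1[cr] + (y0 - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr]))
    cnt <- length(xint) - findInterval(xs, xint)   # intersections right of x
    mask[r, ] <- (cnt %% 2L) == 1L
  }
  mask
}

# Even-odd point-in-polygon test for arbitrary points (vectorized over points).
points_in_polygon <- function(px, py, poly) {
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  inside <- logical(length(px))
  for (e in seq_along(x1)) {
    cr <- (y1[e] <= py) != (y2[e] <= py)
    if (!any(cr)) next
    xint <- x1[e] + (py - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
    inside <- xor(inside, cr & (xint > px))
  }
  inside
}

# Shoelace area of a planar polygon (mm^2), sign dropped.
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
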