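# Domain types and on-disk formats.
#
# Image stacks are stored as 3-D arrays indexed [row (y), column (x), frame];
# all geometry is in mm with voxel size = fov_mm / matrix and the origin at
# the first voxel center (x rightward with the column index, y downward with
# the row index, i.e. as displayed, which is taken to be the foot-to-head
# view).  Complex stacks go to disk as paired real/imaginary NIfTI volumes
# so that write-then-read is bit exact.

#' Acquisition metadata for one tissue phase mapping slice
#'
#' Bundles the geometric and velocity-encoding parameters of a single
#' short-axis cine acquisition: field of view, acquired matrix size, frame
#' interval, number of cine frames, the in-plane and through-plane velocity
#' encoding limits (venc, the tissue velocity that produces a phase shift of
#' pi), and the anatomical slice level.
#'
#' @param fov_mm Square field of view in mm.
#' @param matrix Acquired matrix size per dimension (square matrix assumed).
#' @param frame_interval_ms Time between cine frames in ms.
#' @param n_frames Number of cine frames.
#' @param venc_inplane_cm_s In-plane velocity encoding limit in cm/s
#'   (applies to the x and y encodings).
#' @param venc_through_cm_s Through-plane velocity encoding limit in cm/s
#'   (applies to the z encoding).
#' @param slice_level One of `"basal"`, `"mid"`, `"apical"`.
#' @param slice_thickness_mm Slice thickness in mm.
#' @return An object of class `tpm_meta`.
#' @export
acquisition_meta <- function(fov_mm, matrix, frame_interval_ms, n_frames,
                             venc_inplane_cm_s, venc_through_cm_s,
                             slice_level = c("mid", "basal", "apical"),
                             slice_thickness_mm = 1) {
  slice_level <- match.arg(slice_level)
  if (missing(venc_inplane_cm_s) || is.null(venc_inplane_cm_s))
    stop("missing required field 'venc_inplane_cm_s'")
  if (missing(venc_through_cm_s) || is.null(venc_through_cm_s))
    stop("missing required field 'venc_through_cm_s'")
  stopifnot(fov_mm > 0, matrix > 0, frame_interval_ms > 0, n_frames >= 1,
            venc_inplane_cm_s > 0, venc_through_cm_s > 0,
            slice_thickness_mm > 0)
  structure(list(
    fov_mm = as.numeric(fov_mm), matrix = as.integer(matrix),
    frame_interval_ms = as.numeric(frame_interval_ms),
    n_frames = as.integer(n_frames),
    venc_inplane_cm_s = as.numeric(venc_inplane_cm_s),
    venc_through_cm_s = as.numeric(venc_through_cm_s),
    slice_level = slice_level,
    slice_thickness_mm = as.numeric(slice_thickness_mm)
  ), class = "tpm_meta")
}

#' Four-scan cine encoding set
#'
#' Container for the four interleaved scans of one slice: the
#' motion-compensated reference plus the x-, y- and z-motion-encoded scans.
#' The encoding order is fixed as (ref, x, y, z).  A missing z encoding
#' (two-encoding in-plane protocols) is accepted; longitudinal outputs are
#' then reported as absent rather than zero.
#'
#' @param ref,x,y Complex arrays `[ny, nx, n_frames]`.
#' @param z Complex array like `ref`, or `NULL` if no through-plane encoding
#'   was acquired.
#' @param meta An [acquisition_meta()] object.
#' @param domain `"kspace"` or `"image"`.
#' @return An object of class `cine_set`.
#' @export
cine_encoding_set <- function(ref, x, y, z = NULL, meta,
                              domain = c("image", "kspace")) {
  domain <- match.arg(domain)
  stopifnot(inherits(meta, "tpm_meta"))
  scans <- list(ref = ref, x = x, y = y)
  if (!is.null(z)) scans$z <- z
  d <- dim(ref)
  for (nm in names(scans)) {
    if (!identical(dim(scans[[nm]]), d))
      stop("encoding shape mismatch: scan '", nm,
           "' does not match the reference scan")
    if (!is.complex(scans[[nm]]))
      scans[[nm]] <- scans[[nm]] + 0i
  }
  if (length(d) != 3L) stop("scans must be [ny, nx, n_frames] arrays")
  if (d[3L] != meta$n_frames)
    stop("encoding shape mismatch: stack has ", d[3L],
         " frames but meta declares ", meta$n_frames)
  structure(list(scans = scans, meta = meta, domain = domain),
            class = "cine_set")
}

#' @export
print.cine_set <- function(x, ...) {
  d <- dim(x$scans$ref)
  cat("<cine_set> ", length(x$scans), " encodings (",
      paste(names(x$scans), collapse = ", "), "), ",
      d[1], "x", d[2], " x ", d[3], " frames, domain=", x$domain,
      ", slice=", x$meta$slice_level, "\n", sep = "")
  invisible(x)
}

#' Voxelwise velocity field
#'
#' Per-frame velocity maps in cm/s for the x, y and (optionally) z
#' directions plus the combined magnitude image (sum of the four scan
#' magnitudes), on the reconstructed grid.
#'
#' @param vx,vy Numeric arrays `[ny, nx, n_frames]`, cm/s.
#' @param vz Like `vx`, or `NULL` when no through-plane encoding exists.
#' @param magnitude Numeric array `[ny, nx, n_frames]`, arbitrary units.
#' @param meta An [acquisition_meta()] object.
#' @return An object of class `velocity_field`.  The reconstructed matrix
#'   size (after any zero-filling) is `dim(vx)[1]`; the voxel size is
#'   `meta$fov_mm / dim(vx)[1]`.
#' @export
velocity_field <- function(vx, vy, vz = NULL, magnitude, meta) {
  stopifnot(inherits(meta, "tpm_meta"))
  stopifnot(identical(dim(vx), dim(vy)), identical(dim(vx), dim(magnitude)))
  if (!is.null(vz)) stopifnot(identical(dim(vx), dim(vz)))
  if (!all(is.finite(vx)) || !all(is.finite(vy)) ||
      (!is.null(vz) && !all(is.finite(vz))))
    stop("velocity maps must be finite everywhere")
  structure(list(vx = vx, vy = vy, vz = vz, magnitude = magnitude,
                 meta = meta),
            class = "velocity_field")
}

recon_matrix <- function(obj) {
  if (inherits(obj, "velocity_field")) dim(obj$vx)[1L]
  else if (inherits(obj, "lv_segmentation")) obj$dim[1L]
  else stop("unsupported object")
}

#' Per-frame LV contour set
#'
#' Epicardial and endocardial borders as closed planar polygons in mm, one
#' pair per cine frame, plus an optional static-reference region polygon
#' (the agarose tube surrogate used for background phase correction).
#' Polygons are stored without the repeated closing vertex.
#'
#' @param epi,endo Lists of `n x 2` matrices (x, y in mm), one per frame.
#' @param ref_block Optional single polygon (matrix) outlining the static
#'   reference region.
#' @return An object of class `lv_contours`.
#' @export
lv_contours <- function(epi, endo, ref_block = NULL) {
  stopifnot(is.list(epi), is.list(endo), length(epi) == length(endo),
            length(epi) >= 1L)
  chk <- function(p, what, f) {
    if (!is.matrix(p) || ncol(p) != 2L)
      stop(what, " contour at frame ", f, " is not an n x 2 matrix")
    if (nrow(p) < 3L)
      stop(what, " contour at frame ", f, " has fewer than 3 vertices")
    p
  }
  for (f in seq_along(epi)) {
    chk(epi[[f]], "epicardial", f)
    chk(endo[[f]], "endocardial", f)
    if (!all(points_in_polygon(endo[[f]][, 1], endo[[f]][, 2], epi[[f]])))
      stop("endocardial contour not strictly inside epicardial contour ",
           "at frame ", f)
  }
  structure(list(epi = epi, endo = endo, ref_block = ref_block,
                 n_frames = length(epi)),
            class = "lv_contours")
}

#' Rasterize LV contours onto an image grid
#'
#' Builds the per-frame myocardial mask (voxels whose centers lie between
#' the endocardial and epicardial contours under the even-odd fill rule),
#' the per-frame center of mass of the mask, and the static-reference mask.
#'
#' @param contours An [lv_contours()] object.
#' @param matrix Grid size per dimension (use the reconstructed matrix,
#'   i.e. acquired matrix times the zero-fill factor).
#' @param fov_mm Field of view in mm.
#' @return An object of class `lv_segmentation` with elements `mask`
#'   (`[ny, nx, n_frames]` logical), `com` (`n_frames x 2`, mm),
#'   `static_reference_mask`, `voxel_mm`, `dim`, and the original contours.
#' @export
rasterize_segmentation <- function(contours, matrix, fov_mm) {
  stopifnot(inherits(contours, "lv_contours"))
  n <- as.integer(matrix)
  vox <- fov_mm / n
  nf <- contours$n_frames
  mask <- array(FALSE, c(n, n, nf))
  com <- base::matrix(NA_real_, nf, 2L)
  g <- coord_grids(c(n, n), vox)
  for (f in seq_len(nf)) {
    m <- rasterize_polygon(contours$epi[[f]], c(n, n), vox) &
      !rasterize_polygon(contours$endo[[f]], c(n, n), vox)
    if (!any(m)) stop("empty myocardial mask at frame ", f)
    mask[, , f] <- m
    com[f, ] <- c(mean(g$x[m]), mean(g$y[m]))
    if (!points_in_polygon(com[f, 1L], com[f, 2L], contours$endo[[f]]))
      stop("center of mass outside the endocardial contour at frame ", f)
  }
  ref_mask <- if (!is.null(contours$ref_block))
    rasterize_polygon(contours$ref_block, c(n, n), vox)
  else base::matrix(FALSE, n, n)
  structure(list(mask = mask, com = com,
                 static_reference_mask = ref_mask,
                 voxel_mm = vox, dim = c(n, n), fov_mm = fov_mm,
                 n_frames = nf, contours = contours),
            class = "lv_segmentation")
}

meta_to_list <- function(meta) unclass(meta)

meta_from_list <- function(l) {
  acquisition_meta(
    fov_mm = l$fov_mm, matrix = l$matrix,
    frame_interval_ms = l$frame_interval_ms, n_frames = l$n_frames,
    venc_inplane_cm_s = l$venc_inplane_cm_s %||%
      stop("missing required field 'venc_inplane_cm_s'"),
    venc_through_cm_s = l$venc_through_cm_s %||%
      stop("missing required field 'venc_through_cm_s'"),
    slice_level = l$slice_level, slice_thickness_mm = l$slice_thickness_mm
  )
}

#' Write a cine encoding set to a directory
#'
#' One pair of NIfTI volumes (`<enc>_real.nii.gz`, `<enc>_imag.nii.gz`) per
#' encoding plus `meta.json`.  Double-precision storage makes the
#' write-then-read round trip bit exact.
#'
#' @param set A [cine_encoding_set()] object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cine_dataset <- function(set, path) {
  stopifnot(inherits(set, "cine_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(set$scans)) {
    s <- set$scans[[nm]]
    RNifti::writeNifti(Re(s), file.path(path, paste0(nm, "_real.nii.gz")),
                       datatype = "double")
    RNifti::writeNifti(Im(s), file.path(path, paste0(nm, "_imag.nii.gz")),
                       datatype = "double")
  }
  meta <- c(meta_to_list(set$meta), list(domain = set$domain,
                                         encodings = names(set$scans)))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cine encoding set from a directory
#'
#' Counterpart of [write_cine_dataset()].  Validates that all encodings
#' share one shape and that the metadata is complete (a missing venc is a
#' hard error naming the field).
#'
#' @param path Directory written by [write_cine_dataset()].
#' @return A [cine_encoding_set()] object.
#' @export
read_cine_dataset <- function(path) {
  if (!dir.exists(path)) stop("no such dataset directory: ", path)
  ml <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  meta <- meta_from_list(ml)
  rd <- function(nm) {
    re <- file.path(path, paste0(nm, "_real.nii.gz"))
    im <- file.path(path, paste0(nm, "_imag.nii.gz"))
    if (!file.exists(re)) return(NULL)
    a <- array(as.numeric(RNifti::readNifti(re)), dim = dim(RNifti::readNifti(re)))
    b <- array(as.numeric(RNifti::readNifti(im)), dim = dim(a))
    complex(real = a, imaginary = b) |> array(dim = dim(a))
  }
  cine_encoding_set(ref = rd("ref"), x = rd("x"), y = rd("y"), z = rd("z"),
                    meta = meta, domain = ml$domain)
}

#' Write LV contours (plus grid declaration) to JSON
#'
#' Polygons are written closed (first vertex repeated); [read_contours()]
#' requires this and errors on open polygons.
#'
#' @param contours An [lv_contours()] object.
#' @param path Output JSON file.
#' @param matrix,fov_mm Grid on which [read_contours()] will rasterize.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path, matrix, fov_mm) {
  stopifnot(inherits(contours, "lv_contours"))
  close_poly <- function(p) rbind(p, p[1L, ])
  obj <- list(
    grid = list(matrix = matrix, fov_mm = fov_mm),
    epi = lapply(contours$epi, close_poly),
    endo = lapply(contours$endo, close_poly),
    ref_block = if (!is.null(contours$ref_block))
      close_poly(contours$ref_block)
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read LV contours from JSON and rasterize them
#'
#' @param path JSON file written by [write_contours()].
#' @return An `lv_segmentation` object (see [rasterize_segmentation()]).
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_poly <- function(p) {
    do.call(rbind, lapply(p, function(row) as.numeric(unlist(row))))
  }
  open_poly <- function(p, what, f) {
    p <- as_poly(p)
    if (is.null(p) || ncol(p) != 2L || nrow(p) < 4L ||
        any(p[1L, ] != p[nrow(p), ]))
      stop("open polygon: ", what, " contour at frame ", f,
           " does not repeat its first vertex")
    p[-nrow(p), , drop = FALSE]
  }
  epi <- lapply(seq_along(obj$epi),
                function(f) open_poly(obj$epi[[f]], "epicardial", f))
  endo <- lapply(seq_along(obj$endo),
                 function(f) open_poly(obj$endo[[f]], "endocardial", f))
  rb <- if (!is.null(obj$ref_block)) open_poly(obj$ref_block, "reference", 1L)
  ct <- lv_contours(epi, endo, ref_block = rb)
  rasterize_segmentation(ct, matrix = as.integer(unlist(obj$grid$matrix)),
                         fov_mm = as.numeric(unlist(obj$grid$fov_mm)))
}

#' Write result tables and a run manifest
#'
#' Each element of `tables` (a named list of data frames) becomes
#' `<name>.csv` under `path`; an empty data frame yields a header-only CSV.
#' The manifest records configuration, seed and package version for
#' reproducibility and is written as `manifest.json`.
#'
#' @param tables Named list of data frames.
#' @param path Output directory.
#' @param config Configuration list echoed into the manifest.
#' @param seed Seed echoed into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, path, config = list(), seed = NULL) {
  stopifnot(is.list(tables), all(nzchar(names(tables))))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    config = config, seed = seed,
    package = "mtpm",
    version = as.character(utils::packageVersion("mtpm")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

#' Read a run manifest
#' @param path Directory containing `manifest.json`, or the file itself.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  jsonlite::read_json(f, simplifyVector = TRUE)
}
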