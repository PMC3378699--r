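# Shared fixtures, generated in code.  The "small" phantom keeps the
# reconstructed voxel size of the full protocol (0.1 mm after 2x
# zero-fill) on a quarter-size field of view so unit tests stay fast.

small_spec <- function(slice_level = "basal", noise_sd = 0, ...) {
  phantom_spec(slice_level = slice_level, matrix = 64L, fov_mm = 12.8,
               n_frames = 10L, noise_sd = noise_sd,
               ref_block_center_mm = c(10.8, 2.0),
               ref_block_halfwidth_mm = 1.0, ...)
}

# image-domain generation + unfiltered pass-through keeps phases exact
small_analysis <- local({
  cache <- new.env(parent = emptyenv())
  function(slice_level = "basal") {
    key <- slice_level
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- small_spec(slice_level)
    sim <- generate_cine(spec, domain = "image")
    seg <- rasterize_segmentation(sim$contours, spec$meta$matrix,
                                  spec$meta$fov_mm)
    vel <- reconstruct_velocity(sim$set,
                                recon_config(background_correction = "off"))
    ana <- analyze_velocity(vel, seg)
    cache[[key]] <- list(spec = spec, sim = sim, seg = seg, vel = vel,
                         ana = ana)
    cache[[key]]
  }
})

# a rigid rotation at constant rate: 0.1745 rad/s over a 100 ms ED-ES
# window (frames 1..21 at 5 ms)
rigid_spec <- function(omega = 0.1745) {
  phantom_spec(slice_level = "mid", matrix = 64L, fov_mm = 12.8,
               endo_shortening = 0, epi_shortening = 0,
               omega_endo_peak = omega, omega_epi_peak = omega,
               omega_waveform = "constant", vz_peak_cm_s = 0,
               frame_interval_ms = 5, n_frames = 24L, noise_sd = 0,
               ref_block_center_mm = c(10.8, 2.0),
               ref_block_halfwidth_mm = 1.0)
}

rigid_analysis <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (!is.null(cache$a)) return(cache$a)
    spec <- rigid_spec()
    sim <- generate_cine(spec, domain = "image")
    seg <- rasterize_segmentation(sim$contours, 64L, spec$meta$fov_mm)
    vel <- reconstruct_velocity(sim$set,
                                recon_config(background_correction = "off"))
    cache$a <- list(spec = spec, seg = seg, vel = vel,
                    ana = analyze_velocity(vel, seg, es_frame = 21L))
    cache$a
  }
})

# truth evaluated on the mask voxels of a frame
truth_on_mask <- function(spec, seg, frame) {
  g <- mtpm:::coord_grids(seg$dim, seg$voxel_mm)
  m <- seg$mask[, , frame]
  t_ms <- (frame - 1) * spec$meta$frame_interval_ms
  c(analytic_velocity(spec, g$x[m], g$y[m], t_ms), list(mask = m))
}

tiny_meta <- function(n = 8L, nf = 3L) {
  acquisition_meta(fov_mm = 8, matrix = n, frame_interval_ms = 4.6,
                   n_frames = nf, venc_inplane_cm_s = 6,
                   venc_through_cm_s = 8, slice_level = "mid")
}

random_cine <- function(n = 8L, nf = 3L, seed = 42L) {
  meta <- tiny_meta(n, nf)
  arr <- function() {
    re <- stats::rnorm(n * n * nf); im <- stats::rnorm(n * n * nf)
    array(complex(real = re, imaginary = im), c(n, n, nf))
  }
  mtpm:::with_seed(seed,
    cine_encoding_set(ref = arr(), x = arr(), y = arr(), z = arr(),
                      meta = meta, domain = "image"))
}
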