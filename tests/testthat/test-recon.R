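test_that("zero-filling pads symmetrically and preserves the DC impulse", {
  n <- 16L
  k <- matrix(0i, n, n)
  k[n / 2 + 1, n / 2 + 1] <- 1 + 0i     # impulse at DC
  z <- zerofill(k, 2L)
  expect_identical(dim(z), c(32L, 32L))
  expect_identical(zerofill(k, 1L), k)
  expect_error(zerofill(k, 0L), ">= 1")
  expect_error(zerofill(matrix(0i, 4, 6), 2L), "square")
  # DC stays at the center of the larger grid
  expect_equal(z[17, 17], 1 + 0i)
  # impulse at DC -> uniform image magnitude before and after zero-fill
  img1 <- Mod(mtpm:::ifft2c(k))
  img2 <- Mod(mtpm:::ifft2c(z))
  expect_lt(diff(range(img1)) / mean(img1), 1e-12)
  expect_lt(diff(range(img2)) / mean(img2), 1e-12)
})

test_that("Butterworth apodization has the textbook radial response", {
  n <- 64L
  ones <- matrix(1 + 0i, n, n)
  # cutoff at 1/4 Nyquist = 8 index units
  h <- Re(apodize(ones, order = 3L, cutoff_frac = 0.25))
  dc <- floor(n / 2) + 1L
  expect_equal(h[dc, dc], 1)                       # H(0) = 1
  expect_equal(h[dc, dc + 8L], 0.5)                # half power at cutoff
  expect_equal(h[dc + 8L, dc], 0.5)                # radially symmetric
  expect_equal(h[dc, dc + 16L], 1 / (1 + 2^6))     # H(2 k_c)
  # monotone non-increasing along a radius
  expect_true(all(diff(h[dc, dc:n]) <= 1e-15))
  expect_error(apodize(ones, cutoff_frac = 0), "> 0")
})

test_that("apodization and zero-filling commute (absolute-frequency cutoff)", {
  k <- mtpm:::with_seed(5L, matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16))
  a_then_z <- zerofill(apodize(k, 3L, 0.7), 2L)
  z_then_a <- apodize(zerofill(k, 2L), 3L, 0.7, acquired_matrix = 16L)
  expect_lt(max(Mod(a_then_z - z_then_a)), 1e-10)
})

test_that("reconstruction inverts the forward FFT and recovers a disk", {
  n <- 32L
  g <- mtpm:::coord_grids(c(n, n), 1)
  disk <- (sqrt((g$x - 15)^2 + (g$y - 15)^2) <= 8) + 0i
  k <- mtpm:::fft2c(disk)
  expect_lt(max(Mod(mtpm:::ifft2c(k) - disk)), 1e-10)   # unitary round trip

  meta <- acquisition_meta(fov_mm = n, matrix = n, frame_interval_ms = 4.6,
                           n_frames = 1, venc_inplane_cm_s = 6,
                           venc_through_cm_s = 8)
  kset <- cine_encoding_set(ref = array(k, c(n, n, 1)),
                            x = array(k, c(n, n, 1)),
                            y = array(k, c(n, n, 1)),
                            z = array(k, c(n, n, 1)),
                            meta = meta, domain = "kspace")
  img <- reconstruct(kset, recon_config(zerofill_factor = 1L,
                                        filter_cutoff_frac = 1,
                                        background_correction = "off"))
  expect_equal(img$domain, "image")
  # matches the manually composed apodize + inverse FFT chain
  manual <- mtpm:::ifft2c(apodize(k, 3L, 1))
  expect_lt(max(Mod(img$scans$ref[, , 1] - manual)), 1e-10)
  # zero k-space reconstructs to a zero image
  zset <- cine_encoding_set(ref = array(0i, c(n, n, 1)),
                            x = array(0i, c(n, n, 1)),
                            y = array(0i, c(n, n, 1)),
                            meta = meta, domain = "kspace")
  expect_equal(max(Mod(reconstruct(zset)$scans$ref)), 0)
  # a disk survives default zero-fill recon with its radius within 1 voxel
  img2 <- reconstruct(kset, recon_config(background_correction = "off"))
  m2 <- Mod(img2$scans$ref[, , 1])
  area <- sum(m2 > 0.5) * (n / (2 * n))^2
  expect_lt(abs(sqrt(area / pi) - 8), 1)
})

test_that("magnitude combination is the voxelwise sum of magnitudes", {
  u <- array(exp(1i * runif(48)), c(4, 4, 3))
  expect_equal(combine_magnitude(list(u, u, u, u)),
               array(4, c(4, 4, 3)))
  z <- array(0i, c(4, 4, 3))
  expect_equal(combine_magnitude(list(u, u, u, z)), array(3, c(4, 4, 3)))
  set <- random_cine(6L, 2L)
  brute <- Mod(set$scans$ref) + Mod(set$scans$x) + Mod(set$scans$y) +
    Mod(set$scans$z)
  expect_equal(combine_magnitude(set$scans), brute, tolerance = 1e-14)
  expect_error(combine_magnitude(list(u, u[, , 1:2])), "shape mismatch")
})

test_that("phase differences map linearly to velocity and alias beyond venc", {
  ref <- exp(1i * 0.3)
  expect_equal(phase_velocity(ref, ref, 6), 0)
  expect_equal(phase_velocity(ref * exp(-1i * pi / 2), ref, 6), 3)
  # true velocity 1.2 venc wraps to -0.8 venc
  enc <- ref * exp(-1i * pi * 1.2)
  expect_equal(phase_velocity(enc, ref, 6), -0.8 * 6, tolerance = 1e-12)
  expect_error(phase_velocity(ref, ref, 0), "venc")
})

test_that("background plane fits are exact for the model class", {
  n <- 32L
  g <- mtpm:::coord_grids(c(n, n), 0.5)
  ref_mask <- g$x > 10 & g$x < 14 & g$y > 2 & g$y < 6
  truth <- mtpm:::with_seed(9L, matrix(rnorm(n * n, sd = 0.3), n, n))
  for (co in list(c(0.1, 0.02, 0), c(-0.2, 0.013, -0.04))) {
    plane <- co[1] + co[2] * g$x + co[3] * g$y
    corr <- background_correct(truth + plane, ref_mask, "linear",
                               voxel_mm = 0.5)
    # residual over the reference is zero and the field is restored up to
    # the component of `truth` lying in the plane space over the mask
    clean_fit <- background_correct(truth, ref_mask, "linear", voxel_mm = 0.5)
    expect_lt(max(abs(corr - clean_fit)), 1e-9)
    expect_lt(abs(mean(corr[ref_mask])), 1e-9)
  }
  # plane-only input: myocardial (everywhere) velocities restored to zero
  plane <- 0.1 + 0.02 * g$x
  expect_lt(max(abs(background_correct(plane, ref_mask, "linear", 0.5))),
            1e-9)
  expect_identical(background_correct(plane, ref_mask, "off"), plane)
  const <- background_correct(plane, ref_mask, "constant", voxel_mm = 0.5)
  expect_lt(abs(mean(const[ref_mask])), 1e-12)
  expect_error(background_correct(plane, ref_mask & FALSE, "linear"),
               "3 reference voxels")
})

test_that("phase noise propagates to velocity SD as venc * sigma * sqrt(2) / pi", {
  n <- 128L; sig <- 0.05; venc <- 6
  mtpm:::with_seed(11L, {
    mk <- function() matrix(complex(real = 1 + rnorm(n * n, 0, sig),
                                    imaginary = rnorm(n * n, 0, sig)), n, n)
    v <- phase_velocity(mk(), mk(), venc)
  })
  expect_gt(length(v), 1e4)
  predicted <- venc * sig * sqrt(2) / pi
  expect_lt(abs(stats::sd(c(v)) / predicted - 1), 0.1)
})
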