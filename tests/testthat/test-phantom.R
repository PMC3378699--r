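test_that("analytic velocities decompose into wall, rotational and through-plane parts", {
  # zero motion
  still <- small_spec(endo_shortening = 0, epi_shortening = 0,
                      omega_endo_peak = 0, omega_epi_peak = 0,
                      vz_peak_cm_s = 0)
  v <- analytic_velocity(still, still$center_mm[1] + 2.5, still$center_mm[2], 10)
  expect_equal(unname(unlist(v)), c(0, 0, 0))

  # rigid rotation omega = 2.5 rad/s at r = 2 mm: |v_t| = 0.5 cm/s, v_r = 0
  rot <- small_spec(endo_shortening = 0, epi_shortening = 0,
                    omega_endo_peak = 2.5, omega_epi_peak = 2.5,
                    omega_waveform = "constant", vz_peak_cm_s = 0,
                    r_endo_mm = 1.5)
  v <- analytic_velocity(rot, rot$center_mm[1] + 2, rot$center_mm[2], 0)
  expect_equal(sqrt(v$vx^2 + v$vy^2), 0.5, tolerance = 1e-12)
  # due east, clockwise on screen means +y (downward): vx = 0, vy > 0
  expect_equal(v$vx, 0, tolerance = 1e-12)
  expect_equal(v$vy, 0.5, tolerance = 1e-12)

  # pure contraction: inward radial velocity, vx = -cos(theta) * |dR/dt|
  con <- small_spec(omega_endo_peak = 0, omega_epi_peak = 0,
                    vz_peak_cm_s = 0)
  t_ms <- 10
  rate <- mtpm:::phantom_radius_rate(con, t_ms / 1000)
  R <- phantom_radii(con, t_ms)
  for (th in c(0, pi / 3, 5 * pi / 4)) {
    p <- con$center_mm + R$endo * c(cos(th), sin(th))
    v <- analytic_velocity(con, p[1], p[2], t_ms)
    expect_equal(v$vx, rate$endo / 10 * cos(th), tolerance = 1e-9)
    expect_equal(v$vy, rate$endo / 10 * sin(th), tolerance = 1e-9)
  }
  expect_error(analytic_velocity(con, con$center_mm[1], con$center_mm[2], 0),
               "outside the annulus")
})

test_that("encoded phases follow the velocity prescription", {
  # zero motion, zero plane, noiseless: encoded scans equal the reference
  still <- small_spec(endo_shortening = 0, epi_shortening = 0,
                      omega_endo_peak = 0, omega_epi_peak = 0,
                      vz_peak_cm_s = 0)
  sim <- generate_cine(still, domain = "image")
  for (ax in c("x", "y", "z"))
    expect_equal(sim$set$scans[[ax]], sim$set$scans$ref, tolerance = 1e-14)

  # constant vz = 4 cm/s against venc_z = 8: z phase difference pi/2
  vz4 <- small_spec(endo_shortening = 0, epi_shortening = 0,
                    omega_endo_peak = 0, omega_epi_peak = 0,
                    vz_peak_cm_s = 4, omega_waveform = "constant")
  sim <- generate_cine(vz4, domain = "image")
  f <- 3L
  block <- rasterize_segmentation(sim$contours, 64L,
                                  12.8)$static_reference_mask
  tissue <- Mod(sim$set$scans$ref[, , f]) > 0.5 & !block
  dphi <- Arg(sim$set$scans$ref[, , f] * Conj(sim$set$scans$z[, , f]))
  expect_equal(unname(stats::median(dphi[tissue])), pi / 2, tolerance = 1e-9)
})

test_that("generation is deterministic in the seed and noise scales as prescribed", {
  a <- generate_cine(small_spec(noise_sd = 0.02, seed = 5L))
  b <- generate_cine(small_spec(noise_sd = 0.02, seed = 5L))
  expect_identical(a$set$scans, b$set$scans)
  c_ <- generate_cine(small_spec(noise_sd = 0.02, seed = 6L))
  expect_false(identical(a$set$scans, c_$set$scans))
  # velocity difference between seeds stays within the noise bound
  seg <- rasterize_segmentation(a$contours, 128L, 12.8)
  cfg <- recon_config(background_correction = "off")
  va <- reconstruct_velocity(a$set, cfg)
  vc <- reconstruct_velocity(c_$set, cfg)
  m <- seg$mask
  sigma_v <- 6 * 0.02 * sqrt(2) / pi
  # zero-fill interpolation correlates voxels; compare mask-level SD of the
  # difference against sqrt(2) * sigma_v with a generous factor
  expect_lt(stats::sd(va$vx[m] - vc$vx[m]), 3 * sigma_v)
  expect_gt(stats::sd(va$vx[m] - vc$vx[m]), sigma_v / 3)
})

test_that("analytic twist matches constant and quadrature oracles", {
  # constant 10 deg/s over the systolic window
  sp <- phantom_spec(slice_level = "mid", matrix = 64L, fov_mm = 12.8,
                     endo_shortening = 0, epi_shortening = 0,
                     omega_endo_peak = 0.1745329, omega_epi_peak = 0.1745329,
                     omega_waveform = "constant", n_frames = 24L,
                     frame_interval_ms = 5, systolic_fraction = 100 / 120)
  expect_equal(analytic_twist(sp, "full"), 0.1745329 * 0.1 * 180 / pi,
               tolerance = 1e-9)
  z <- phantom_spec(slice_level = "mid", omega_endo_peak = 0,
                    omega_epi_peak = 0)
  expect_equal(analytic_twist(z, "full"), 0)

  # time-varying profile against a 1e4-step Riemann quadrature
  spec <- small_spec("basal")
  te <- spec$systolic_fraction * spec$cycle_ms / 1000
  for (cp in c("full", "endo", "epi")) {
    tt <- seq(0, te, length.out = 10001L)
    rmed <- vapply(tt, function(t_) {
      R <- phantom_radii(spec, t_ * 1000)
      m <- sqrt((R$endo^2 + R$epi^2) / 2)
      switch(cp, full = m, endo = sqrt((R$endo^2 + m^2) / 2),
             epi = sqrt((m^2 + R$epi^2) / 2))
    }, numeric(1))
    om <- vapply(seq_along(tt), function(i)
      mtpm:::phantom_omega(spec, rmed[i], tt[i]), numeric(1))
    brute <- mtpm:::trapz(tt, om) * 180 / pi
    expect_equal(analytic_twist(spec, cp), brute, tolerance = 1e-6)
  }
})

test_that("flow-tube phantoms carry the prescribed volume rate", {
  # plug: v = 1 cm/s through R = 2 mm -> Q = pi * 0.04 * 1 * 60 mL/min
  q_plug <- pi * 0.2^2 * 1 * 60
  tube <- generate_flow_tube(q_plug, tube_radius_mm = 2, venc_cm_s = 6,
                             profile = "plug")
  expect_equal(tube$truth$v_max_cm_s, 1, tolerance = 1e-12)
  vz <- phase_velocity(tube$set$scans$z[, , 1], tube$set$scans$ref[, , 1], 6)
  expect_equal(max(vz), 1, tolerance = 1e-9)
  expect_equal(measure_flow(vz, tube$truth$mask, tube$truth$voxel_mm),
               q_plug, tolerance = 0.01)

  # parabolic with the same Q has v_max = 2 cm/s
  tube2 <- generate_flow_tube(q_plug, tube_radius_mm = 2, venc_cm_s = 6,
                              profile = "parabolic")
  expect_equal(tube2$truth$v_max_cm_s, 2, tolerance = 1e-12)
  vz2 <- phase_velocity(tube2$set$scans$z[, , 1], tube2$set$scans$ref[, , 1], 6)
  expect_equal(measure_flow(vz2, tube2$truth$mask, tube2$truth$voxel_mm),
               q_plug, tolerance = 0.01 * q_plug)

  # zero flow -> zero velocity map
  tube0 <- generate_flow_tube(0, 2, venc_cm_s = 6)
  expect_equal(max(Mod(tube0$set$scans$z[, , 1] - tube0$set$scans$ref[, , 1])),
               0)
  expect_error(generate_flow_tube(500, 2, venc_cm_s = 6), "not below venc")
})

test_that("the noiseless phantom-recon loop recovers the analytic field", {
  a <- small_analysis("basal")
  for (f in c(1L, 4L, 8L)) {
    tr <- truth_on_mask(a$spec, a$seg, f)
    m <- tr$mask
    expect_lt(max(abs(a$vel$vx[, , f][m] - tr$vx)), 0.01 * 6)
    expect_lt(max(abs(a$vel$vy[, , f][m] - tr$vy)), 0.01 * 6)
    expect_lt(max(abs(a$vel$vz[, , f][m] - tr$vz)), 0.01 * 8)
  }
})
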