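test_that("segment models follow the 6/6/4 AHA layout", {
  b <- segment_model("basal"); m <- segment_model("mid"); a <- segment_model("apical")
  expect_equal(b$n_segments, 6L); expect_equal(m$n_segments, 6L)
  expect_equal(a$n_segments, 4L)
  expect_equal(b$ids, 1:6); expect_equal(m$ids, 7:12); expect_equal(a$ids, 13:16)
  expect_equal(a$width_deg, 90)
  expect_false(17L %in% c(b$ids, m$ids, a$ids))
})

test_that("partitioning covers the mask disjointly with balanced segments", {
  a <- small_analysis("basal")
  f <- 2L
  # balance is a rasterization-limited symmetry: check it on the fine grid
  fine <- rasterize_segmentation(a$sim$contours, 256L, a$spec$meta$fov_mm)
  mf <- fine$mask[, , f]
  ctrf <- center_of_mass(mf, fine$voxel_mm)
  for (lev in c("basal", "apical")) {
    mod <- segment_model(lev)
    lab <- partition(mf, ctrf, mod, fine$voxel_mm)
    expect_identical(is.na(lab), !mf)             # disjoint cover of mask
    expect_setequal(unique(lab[mf]), seq_len(mod$n_segments))
    counts <- table(lab[mf])
    expect_lt(diff(range(counts)) / mean(counts), 0.02)  # equiangular balance
  }
  m <- a$seg$mask[, , f]
  ctr <- a$ana$polar$centers[f, ]
  # rotating the reference by one width permutes labels cyclically
  mod <- segment_model("basal")
  mod2 <- segment_model("basal", reference_angle_deg =
                          mod$reference_angle_deg + mod$width_deg)
  lab1 <- partition(m, ctr, mod, a$seg$voxel_mm)
  lab2 <- partition(m, ctr, mod2, a$seg$voxel_mm)
  expect_equal(lab2[m], 1L + (lab1[m] - 2L) %% 6L)
  expect_error(partition(m & FALSE, ctr, mod, a$seg$voxel_mm), "empty mask")
})

test_that("median-radius split puts inner voxels endo and ties epi", {
  # radii {1, 2, 3, 4}: endo = {1, 2}, epi = {3, 4}
  lab <- matrix(NA_integer_, 1, 5)
  lab[1, 2:5] <- 1L
  cp <- split_epi_endo(lab, center = c(0, 0), voxel_mm = 1)
  expect_equal(cp[1, 2:5], c("endo", "endo", "epi", "epi"))
  # all voxels at the same radius: all epi (r >= median)
  lab2 <- matrix(NA_integer_, 3, 3)
  lab2[1, 2] <- lab2[2, 1] <- lab2[2, 3] <- lab2[3, 2] <- 1L
  cp2 <- split_epi_endo(lab2, center = c(1, 1), voxel_mm = 1)
  expect_true(all(cp2[!is.na(lab2)] == "epi"))
  # random segment against brute-force sort-and-halve
  a <- small_analysis("basal")
  f <- 3L
  m <- a$seg$mask[, , f]; ctr <- a$ana$polar$centers[f, ]
  lab <- partition(m, ctr, segment_model("basal"), a$seg$voxel_mm)
  cp <- split_epi_endo(lab, ctr, a$seg$voxel_mm)
  g <- mtpm:::coord_grids(dim(lab), a$seg$voxel_mm)
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  for (s in 1:6) {
    idx <- which(lab == s)
    med <- stats::median(r[idx])
    expect_identical(cp[idx], ifelse(r[idx] < med, "endo", "epi"))
    # epi + endo partition the segment
    expect_equal(sum(cp[idx] == "endo") + sum(cp[idx] == "epi"), length(idx))
  }
  expect_error(split_epi_endo(matrix(c(1L, NA), 1), c(0, 0), 1), "fewer than 2")
})

test_that("regional courses aggregate to the global mean and localize changes", {
  a <- small_analysis("basal")
  reg <- a$ana$regional
  # count-weighted segment means reproduce the global mask mean per frame
  for (f in c(1L, 5L, 9L)) {
    for (comp in c("radial", "tangential")) {
      sub <- reg[reg$frame == f & reg$compartment == "full" &
                   reg$component == comp, ]
      wmean <- sum(sub$v_cm_s * sub$n_vox) / sum(sub$n_vox)
      glob <- switch(comp, radial = a$ana$global$v_r[f],
                     tangential = a$ana$global$v_phi[f])
      expect_equal(wmean, glob, tolerance = 1e-9)
    }
    sub <- reg[reg$frame == f & reg$compartment == "full", ]
    expect_equal(sum(sub$n_vox[sub$component == "radial"]),
                 sum(a$seg$mask[, , f]))
  }
  # transmural rotation gradient: endo |v_phi| above epi |v_phi| at peak
  f_peak <- 5L
  tang <- reg[reg$frame == f_peak & reg$component == "tangential", ]
  for (s in unique(tang$segment)) {
    endo <- tang$v_cm_s[tang$segment == s & tang$compartment == "endo"]
    epi <- tang$v_cm_s[tang$segment == s & tang$compartment == "epi"]
    expect_gt(abs(endo), abs(epi))
  }
})

test_that("peak extraction takes the systolic max and diastolic min", {
  v <- c(0.1, 0.5, 0.82, 0.4, -0.2, -1.5, -0.9, 0)
  pk <- peak_velocities(v, 1:4, 5:8)
  expect_equal(unname(pk), c(0.82, -1.5))
  expect_equal(unname(peak_velocities(rep(3, 6), 1:3, 4:6)), c(3, 3))
  mtpm:::with_seed(2L, { r <- rnorm(20) })
  expect_equal(unname(peak_velocities(r, 1:10, 11:20)),
               c(max(r[1:10]), min(r[11:20])))
  expect_error(peak_velocities(v, integer(0), 5:8), "empty")
  expect_error(peak_velocities(v, 1:4, 5:9), "outside")
  # missing frames propagate
  v[2] <- NA
  expect_true(is.na(peak_velocities(v, 1:4, 5:8)[["peak_sys"]]))
})

test_that("bull's-eye tables aggregate subjects with sample SD", {
  one <- bullseye(list(data.frame(segment = 1:16, value = rnorm(16))))
  expect_equal(nrow(one), 16L)
  expect_equal(one$sd, rep(0, 16))
  expect_false(17L %in% one$segment)
  v <- 0.7
  two <- bullseye(list(data.frame(segment = 1:4, value = rep(v, 4)),
                       data.frame(segment = 1:4, value = rep(-v, 4))))
  expect_equal(two$mean, rep(0, 4))
  expect_equal(two$sd, rep(v * sqrt(2), 4), tolerance = 1e-12)
  expect_error(bullseye(list(data.frame(segment = 1:6, value = 1:6),
                             data.frame(segment = 1:4, value = 1:4))),
               "inconsistent segment sets")
  expect_error(bullseye(list(data.frame(segment = c(1:16, 17),
                                        value = rnorm(17)))),
               "beyond 16")
})
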