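test_that("speed map is the per-voxel Euclidean norm", {
  g <- small_grid(n = 6)
  dat <- array(0, c(g$shape, g$n_frames, 3))
  dat[, , , , 1] <- 0.3
  dat[, , , , 2] <- 0.4
  f <- velocity_field(dat, g)
  expect_equal(unique(as.vector(speed_map(f))), 0.5)
  f0 <- uniform_field(g, u = c(0, 0, 0))
  expect_equal(max(speed_map(f0)), 0)
})

test_that("global velocities aggregate per-voxel temporal stats", {
  g <- grid_spec(c(6, 6, 6), 5, n_frames = 2, frame_duration_s = 0.5,
                 mv_open_frame = 1)
  dat <- array(0, c(g$shape, 2, 3))
  dat[, , , 1, 1] <- 0.1
  dat[, , , 2, 1] <- 0.3
  f <- velocity_field(dat, g)
  mask <- la_mask(array(TRUE, g$shape), g$spacing_mm)
  gv <- global_velocity_stats(f, mask)
  expect_equal(gv$peak_velocity_m_s, 0.3)
  expect_equal(gv$mean_velocity_m_s, 0.2)
  # "max" reduction returns the single highest speed anywhere
  dat[3, 3, 3, 2, 1] <- 0.9
  f2 <- velocity_field(dat, g)
  expect_equal(global_velocity_stats(f2, mask, "max")$peak_velocity_m_s, 0.9)
  expect_lt(global_velocity_stats(f2, mask, "mean")$peak_velocity_m_s, 0.31)
})

test_that("rotation mean velocity equals omega times mean axial radius", {
  g <- small_grid(n = 16)
  omega <- 2
  rot <- rotation_field(g, omega = omega)
  mask <- ellipsoid_mask(g, c(30, 25, 20))
  gv <- global_velocity_stats(rot, mask)
  ctr <- grid_center_mm(g)
  idx <- which(mask$data, arr.ind = TRUE)
  r_mm <- sqrt(((idx[, 1] - 1) * g$spacing_mm[1] - ctr[1])^2 +
                 ((idx[, 2] - 1) * g$spacing_mm[2] - ctr[2])^2)
  expect_equal(gv$mean_velocity_m_s, omega * mean(r_mm) / 1000,
               tolerance = 1e-10)
})

test_that("stasis counting is integer-exact with a strict threshold", {
  g <- grid_spec(c(5, 5, 5), 4, n_frames = 20, frame_duration_s = 0.05,
                 mv_open_frame = 8)
  dat <- array(0.2, c(g$shape, 20, 3))
  dat[, , , , 2:3] <- 0
  # voxel (2,2,2): below threshold in exactly 5 of 20 frames
  dat[2, 2, 2, 1:5, 1] <- 0.05
  # voxel (3,3,3): speed exactly at the threshold never counts (strict <)
  dat[3, 3, 3, , 1] <- 0.1
  f <- velocity_field(dat, g)
  mask <- la_mask(array(TRUE, g$shape), g$spacing_mm)
  st <- compute_stasis(f, mask)
  expect_identical(st$n_stasis[2, 2, 2], 5L)
  expect_equal(st$per_voxel[2, 2, 2], 0.25)
  expect_identical(st$n_stasis[3, 3, 3], 0L)
  expect_equal(st$n_tot, 20L)
  expect_equal(st$global_stasis, 5 / (20 * 125))
  # extremes
  f_slow <- uniform_field(g, u = c(0.05, 0, 0))
  expect_equal(compute_stasis(f_slow, mask)$global_stasis, 1)
  f_fast <- uniform_field(g, u = c(0.2, 0, 0))
  expect_equal(compute_stasis(f_fast, mask)$global_stasis, 0)
})

test_that("stasis is monotone in the threshold and bounded in [0, 1]", {
  set.seed(2)
  g <- small_grid(n = 8)
  dat <- array(abs(rnorm(prod(g$shape) * g$n_frames * 3, sd = 0.08)),
               c(g$shape, g$n_frames, 3))
  f <- velocity_field(dat, g)
  mask <- la_mask(array(TRUE, g$shape), g$spacing_mm)
  th <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  gs <- vapply(th, function(t_) compute_stasis(f, mask, t_)$global_stasis,
               numeric(1))
  expect_true(all(diff(gs) >= 0))
  expect_true(all(gs >= 0 & gs <= 1))
})

test_that("vorticity curve scales with the temporal profile and the AUC sums it", {
  g <- small_grid(n = 14, n_frames = 4, frame_duration = 0.25)
  prof <- c(1, 0.5, 0.25, 0)
  rot <- rotation_field(g, omega = 1, profile = prof)
  mask <- ellipsoid_mask(g, rep(20, 3))
  vc <- vorticity_curve(rot, mask)
  expect_equal(vc$vorticity_rad_s, 2 * prof, tolerance = 1e-10)
  expect_equal(attr(vc, "auc_rad"), sum(2 * prof) * 0.25, tolerance = 1e-10)
  # uniform flow: identically zero
  vcu <- vorticity_curve(uniform_field(g), mask)
  expect_equal(max(vcu$vorticity_rad_s), 0)
  expect_equal(attr(vcu, "auc_rad"), 0)
})

test_that("Lamb-Oseen peak vorticity matches Gamma / (pi r_c^2)", {
  # core radius = 6 voxels
  g <- grid_spec(c(37, 37, 9), 2, n_frames = 2, frame_duration_s = 0.5,
                 mv_open_frame = 1)
  rc <- 0.012   # 12 mm = 6 voxels
  gamma <- 0.004
  lo <- analytic_field("lamb_oseen",
                       list(circulation_m2_s = gamma, core_radius_m = rc),
                       g)
  J <- laflow4d:::velocity_gradient(lo$data[, , , 1, , drop = TRUE],
                                    g$spacing_mm)
  w <- laflow4d:::curl_from_gradient(J)
  wmag <- sqrt(w[[1]]^2 + w[[2]]^2 + w[[3]]^2)
  ctr_idx <- (dim(wmag) + 1) / 2
  peak <- wmag[ctr_idx[1], ctr_idx[2], ctr_idx[3]]
  expect_equal(peak, gamma / (pi * rc^2), tolerance = 0.02)
})

test_that("lambda2 is -omega^2 for rotation, 0 for uniform flow", {
  g <- small_grid(n = 14)
  omega <- 2
  rot <- rotation_field(g, omega = omega)
  mask <- ellipsoid_mask(g, rep(20, 3))
  l2 <- lambda2_field(rot, mask)
  vals <- l2$lambda2[, , , 1][mask$data]
  expect_true(all(abs(vals - (-omega^2)) / omega^2 < 0.01))
  # threshold: half the mean of the (all equal) negative values
  expect_equal(l2$threshold, -omega^2 / 2, tolerance = 1e-6)
  l2u <- lambda2_field(uniform_field(g), mask)
  expect_lt(max(abs(l2u$lambda2)), 1e-10)
  expect_equal(l2u$threshold, 0)
})

test_that("vortex volumes count the largest 26-connected component", {
  g <- grid_spec(c(12, 12, 12), 2, n_frames = 2, frame_duration_s = 0.5,
                 mv_open_frame = 1)
  mask <- la_mask(array(TRUE, g$shape), g$spacing_mm)
  l2v <- array(0, c(g$shape, 2))
  # blob A: 3x3x3 = 27 voxels; blob B (disjoint): 2x2x2 = 8 voxels
  l2v[2:4, 2:4, 2:4, 1] <- -10
  l2v[8:9, 8:9, 8:9, 1] <- -10
  l2 <- structure(list(lambda2 = l2v, threshold = -5, mask = mask),
                  class = "lambda2_field")
  vv <- vortex_volumes(l2, mask, g)
  expect_equal(vv$volume_ml[1], 27 * 0.008)   # 2 mm voxels -> 0.008 ml
  expect_equal(vv$volume_ml[2], 0)            # no vortex voxels: volume 0
  expect_equal(attr(vv, "mean_ml"), 27 * 0.008 / 2)
  expect_equal(attr(vv, "systolic_peak_ml"), 27 * 0.008)
  expect_equal(attr(vv, "diastolic_peak_ml"), 0)
  # diagonal touch merges under 26-connectivity
  l2d <- array(0, c(g$shape, 2))
  l2d[2:3, 2:3, 2:3, 1] <- -10
  l2d[4, 4, 4, 1] <- -10
  l2c <- structure(list(lambda2 = l2d, threshold = -5, mask = mask),
                   class = "lambda2_field")
  expect_equal(vortex_volumes(l2c, mask, g)$volume_ml[1], 9 * 0.008)
})

test_that("a fully vortical mask reports mask volume exactly", {
  g <- grid_spec(c(10, 10, 10), 2, n_frames = 2, frame_duration_s = 0.5,
                 mv_open_frame = 1)
  mask <- ellipsoid_mask(g, rep(8, 3))
  n_vox <- sum(mask$data)
  l2v <- array(-10, c(g$shape, 2))
  l2 <- structure(list(lambda2 = l2v, threshold = -5, mask = mask),
                  class = "lambda2_field")
  vv <- vortex_volumes(l2, mask, g)
  expect_equal(vv$volume_ml, rep(n_vox * 0.008, 2))
})

test_that("extract_biomarkers is deterministic and linear in velocity scale", {
  ph <- make_phantom(corruption = NULL)
  b1 <- extract_biomarkers(ph$clean, ph$mask, patterns = FALSE)
  b2 <- extract_biomarkers(ph$clean, ph$mask, patterns = FALSE)
  expect_identical(b1, b2)
  doubled <- velocity_field(2 * ph$clean$data, ph$clean$grid,
                            venc_m_s = ph$clean$venc_m_s)
  b3 <- extract_biomarkers(doubled, ph$mask, patterns = FALSE)
  expect_equal(b3$peak_velocity_m_s, 2 * b1$peak_velocity_m_s)
  expect_equal(b3$mean_velocity_m_s, 2 * b1$mean_velocity_m_s)
  expect_equal(b3$vorticity_auc_rad, 2 * b1$vorticity_auc_rad)
  # lambda2 and its threshold scale together: vortex volumes unchanged
  expect_equal(b3$vortex_mean_ml, b1$vortex_mean_ml)
  # zero field: stasis 1, everything else 0
  z <- velocity_field(0 * ph$clean$data, ph$clean$grid)
  bz <- extract_biomarkers(z, ph$mask, patterns = FALSE)
  expect_equal(bz$global_stasis, 1)
  expect_equal(bz$peak_velocity_m_s, 0)
  expect_equal(bz$vorticity_auc_rad, 0)
  expect_equal(bz$vortex_mean_ml, 0)
})

test_that("biomarkers are invariant to rigid translation of field + mask", {
  g <- small_grid(n = 14)
  shift <- 2L
  ctr <- grid_center_mm(g)
  rot1 <- analytic_field("rigid_rotation",
                         list(omega_rad_s = 25, axis = c(0, 0, 1),
                              center_mm = ctr), g)
  ctr2 <- ctr + shift * g$spacing_mm
  rot2 <- analytic_field("rigid_rotation",
                         list(omega_rad_s = 25, axis = c(0, 0, 1),
                              center_mm = ctr2), g)
  m1 <- ellipsoid_mask(g, rep(15, 3), center_mm = ctr)
  m2 <- ellipsoid_mask(g, rep(15, 3), center_mm = ctr2)
  b1 <- extract_biomarkers(rot1, m1, patterns = FALSE)
  b2 <- extract_biomarkers(rot2, m2, patterns = FALSE)
  for (col in c("peak_velocity_m_s", "mean_velocity_m_s", "global_stasis",
                "vorticity_auc_rad", "vortex_mean_ml")) {
    expect_equal(b1[[col]], b2[[col]], tolerance = 1e-10)
  }
})

test_that("finite-difference error on rotation shrinks at least quadratically", {
  err_at <- function(n, spacing) {
    g <- grid_spec(rep(n, 3), spacing, n_frames = 2,
                   frame_duration_s = 0.5, mv_open_frame = 1)
    lo <- analytic_field(
      "lamb_oseen", list(circulation_m2_s = 0.004, core_radius_m = 0.012),
      g)
    mask <- ellipsoid_mask(g, rep(9, 3))
    l2 <- lambda2_field(lo, mask)
    J <- laflow4d:::velocity_gradient(lo$data[, , , 1, , drop = TRUE],
                                      g$spacing_mm)
    w <- laflow4d:::curl_from_gradient(J)
    wmag <- sqrt(w[[1]]^2 + w[[2]]^2 + w[[3]]^2)
    # analytic vorticity of a Lamb-Oseen vortex at radius r
    co <- lapply(1:3, function(a) (seq_len(n) - 1) * spacing)
    ctr <- (n - 1) * spacing / 2
    X <- array(rep(co[[1]], times = n^2), rep(n, 3))
    Y <- array(rep(rep(co[[2]], each = n), times = n), rep(n, 3))
    r2 <- ((X - ctr)^2 + (Y - ctr)^2) / 1e6
    w_true <- 0.004 / (pi * 0.012^2) * exp(-r2 / 0.012^2)
    max(abs(wmag - w_true)[mask$data])
  }
  # same physical extent, half the spacing
  e1 <- err_at(15, 4)
  e2 <- err_at(29, 2)
  order <- log2(e1 / e2)
  expect_gt(order, 1.9)
})
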