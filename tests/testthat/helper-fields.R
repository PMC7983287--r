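# shared fixtures: small grids and analytic fields built in code

small_grid <- function(n = 12, spacing = 6, n_frames = 4,
                       frame_duration = 0.25, mv_open = 2) {
  grid_spec(rep(n, 3), spacing, n_frames = n_frames,
            frame_duration_s = frame_duration, mv_open_frame = mv_open)
}

grid_center_mm <- function(grid) (grid$shape - 1) * grid$spacing_mm / 2

rotation_field <- function(grid, omega = 1, venc = NULL, profile = NULL) {
  analytic_field("rigid_rotation",
                 list(omega_rad_s = omega, axis = c(0, 0, 1)),
                 grid, venc_m_s = venc, temporal_profile = profile)
}

uniform_field <- function(grid, u = c(0.2, 0, 0), venc = NULL) {
  analytic_field("uniform", list(u = u), grid, venc_m_s = venc)
}

# interior voxel index range (margin voxels from every face)
interior_idx <- function(grid, margin = 2) {
  lapply(grid$shape, function(n) (1 + margin):(n - margin))
}

# simulated paired measurements: truth * (1 + e), e ~ N(0, cv^2)
sim_pairs <- function(n, cv, truth_mean = 0.4, truth_sd = 0.1,
                      shared_x1 = NULL, truth = NULL) {
  truth <- truth %||% pmax(rnorm(n, truth_mean, truth_sd), 0.05)
  x1 <- shared_x1 %||% (truth * (1 + rnorm(n, 0, cv)))
  cbind(x1, truth * (1 + rnorm(n, 0, cv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
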