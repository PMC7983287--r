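#' Analytic velocity primitives
#'
#' Samples a closed-form velocity field at the voxel centres of a grid and
#' replicates it over cardiac frames with an optional per-frame temporal
#' profile. These fields have known curl and known biomarkers, so they serve
#' as ground-truth oracles for the whole processing chain.
#'
#' Supported kinds and their parameters (all positions in mm, velocities in
#' m/s):
#' * `"uniform"`: `u`, a length-3 velocity vector. Zero curl.
#' * `"rigid_rotation"`: `omega_rad_s` (angular speed), `axis` (rotation
#'   axis, need not be unit length), `center_mm`. Velocity
#'   `v = omega x (r - c)`; curl magnitude is `2 * omega` everywhere.
#' * `"lamb_oseen"`: `circulation_m2_s` (Gamma), `core_radius_m` (r_c),
#'   `axis`, `center_mm`. Tangential speed
#'   `v(r) = Gamma / (2 pi r) * (1 - exp(-r^2 / r_c^2))` about the axis;
#'   peak vorticity at the core centre is `Gamma / (pi r_c^2)`.
#'
#' @param kind One of `"uniform"`, `"rigid_rotation"`, `"lamb_oseen"`.
#' @param params Named list of parameters for `kind` (see Details).
#' @param grid A [grid_spec()].
#' @param venc_m_s Optional VENC recorded on the returned field.
#' @param temporal_profile Optional non-negative multiplier per frame
#'   (length `grid$n_frames`); default is a flat profile of 1s.
#' @return A [velocity_field()].
#' @examples
#' g <- grid_spec(c(8, 8, 8), 5, n_frames = 4, frame_duration_s = 0.25,
#'                mv_open_frame = 2)
#' f <- analytic_field("rigid_rotation",
#'                     list(omega_rad_s = 1, axis = c(0, 0, 1)), g)
#' @export
analytic_field <- function(kind, params, grid, venc_m_s = NULL,
                           temporal_profile = NULL) {
  kinds <- c("uniform", "rigid_rotation", "lamb_oseen")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    stop("unknown analytic field kind ", deparse(kind),
         "; supported kinds: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  frame <- analytic_frame(kind, params, grid)
  data <- replicate_frames(frame, grid, temporal_profile)
  velocity_field(data, grid, venc_m_s = venc_m_s,
                 log = paste0("analytic:", kind))
}

# one spatial frame (nx, ny, nz, 3) for a primitive
analytic_frame <- function(kind, params, grid) {
  co <- voxel_coords_mm(grid)
  dims <- grid$shape
  # coordinate arrays in metres
  X <- array(rep(co[[1]], times = prod(dims[2:3])), dims) / 1000
  Y <- array(rep(rep(co[[2]], each = dims[1]), times = dims[3]), dims) / 1000
  Z <- array(rep(co[[3]], each = prod(dims[1:2])), dims) / 1000
  ctr <- params$center_mm %||% ((dims - 1) * grid$spacing_mm / 2)
  ctr <- ctr / 1000
  frame <- array(0, c(dims, 3L))
  if (kind == "uniform") {
    u <- params$u
    stopifnot(length(u) == 3, all(is.finite(u)))
    for (c_ in 1:3) frame[, , , c_] <- u[c_]
  } else if (kind == "rigid_rotation") {
    omega <- params$omega_rad_s
    stopifnot(is.finite(omega))
    ax <- unit3(params$axis %||% c(0, 0, 1))
    w <- omega * ax
    rx <- X - ctr[1]; ry <- Y - ctr[2]; rz <- Z - ctr[3]
    frame[, , , 1] <- w[2] * rz - w[3] * ry
    frame[, , , 2] <- w[3] * rx - w[1] * rz
    frame[, , , 3] <- w[1] * ry - w[2] * rx
  } else if (kind == "lamb_oseen") {
    gamma <- params$circulation_m2_s
    rc <- params$core_radius_m
    stopifnot(is.finite(gamma), is.finite(rc), rc > 0)
    ax <- unit3(params$axis %||% c(0, 0, 1))
    rx <- X - ctr[1]; ry <- Y - ctr[2]; rz <- Z - ctr[3]
    # component of r perpendicular to the axis
    dot <- rx * ax[1] + ry * ax[2] + rz * ax[3]
    px <- rx - dot * ax[1]; py <- ry - dot * ax[2]; pz <- rz - dot * ax[3]
    r <- sqrt(px^2 + py^2 + pz^2)
    vt <- ifelse(r > 0,
                 gamma / (2 * pi * pmax(r, .Machine$double.eps)) *
                   (1 - exp(-r^2 / rc^2)),
                 0)
    # tangential unit vector: axis x r_perp / |r_perp|
    safe_r <- pmax(r, .Machine$double.eps)
    frame[, , , 1] <- vt * (ax[2] * pz - ax[3] * py) / safe_r
    frame[, , , 2] <- vt * (ax[3] * px - ax[1] * pz) / safe_r
    frame[, , , 3] <- vt * (ax[1] * py - ax[2] * px) / safe_r
  }
  frame
}

replicate_frames <- function(frame, grid, temporal_profile = NULL) {
  prof <- temporal_profile %||% rep(1, grid$n_frames)
  stopifnot(length(prof) == grid$n_frames, all(is.finite(prof)),
            all(prof >= 0))
  dims <- grid$shape
  data <- array(0, c(dims, grid$n_frames, 3L))
  for (t_ in seq_len(grid$n_frames)) data[, , , t_, ] <- frame * prof[t_]
  data
}

unit3 <- function(v) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  n <- sqrt(sum(v^2))
  if (n == 0) stop("axis must be non-zero", call. = FALSE)
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phantom configuration
#'
#' Describes a composite analytic phantom: one or more analytic primitives
#' summed voxel-wise, a shared temporal profile, and an ellipsoidal
#' stand-in for the left atrial segmentation. The defaults describe the
#' package's reference phantom: a rigid rotation at 28 rad/s (volume-averaged
#' vorticity 56 rad/s, in the range seen in atrial flow; fast enough that
#' the finite-difference curl noise floor sits well below the signal, slow
#' enough that the corrupted field stays within the VENC envelope, keeping
#' aliasing temporally recoverable) inside a 28 x 24 x 20 mm semi-axis ellipsoid,
#' flat temporal profile.
#'
#' The analytic flow is windowed by a smooth spatial envelope: full strength
#' up to level `envelope_inner` of the mask ellipsoid equation (level 1 is
#' the mask surface), tapering with a cosine-squared profile to exactly zero
#' at level `envelope_outer`, so that the tissue outside the taper is truly
#' static — as required by the stationary-tissue eddy-current correction,
#' which fits its polynomial there.
#'
#' @param components List of component specs; each a named list with element
#'   `kind` plus the parameters [analytic_field()] documents.
#' @param temporal_profile Per-frame non-negative multipliers or `NULL` (flat).
#' @param mask_semiaxes_mm Ellipsoid semi-axes in mm (length 3).
#' @param mask_center_mm Ellipsoid centre in mm, default grid centre.
#' @param envelope_inner Ellipsoid level up to which the flow keeps full
#'   strength (>= 1).
#' @param envelope_outer Ellipsoid level at which the flow envelope reaches
#'   zero (> `envelope_inner`); beyond it the phantom is static.
#' @param seed Integer seed recorded for downstream corruption.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(components = list(list(kind = "rigid_rotation",
                                                  omega_rad_s = 28,
                                                  axis = c(0, 0, 1))),
                           temporal_profile = NULL,
                           mask_semiaxes_mm = c(28, 24, 20),
                           mask_center_mm = NULL,
                           envelope_inner = 1,
                           envelope_outer = 1.3,
                           seed = 1L) {
  stopifnot(length(components) >= 1,
            all(vapply(components, function(cc) !is.null(cc$kind), TRUE)),
            envelope_inner >= 1, envelope_outer > envelope_inner)
  structure(list(components = components,
                 temporal_profile = temporal_profile,
                 mask_semiaxes_mm = mask_semiaxes_mm,
                 mask_center_mm = mask_center_mm,
                 envelope_inner = envelope_inner,
                 envelope_outer = envelope_outer,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Corruption configuration
#'
#' The inverse of the preprocessing chain: additive Gaussian noise, a
#' time-invariant affine (order-1 polynomial) eddy-current velocity offset,
#' and VENC wrapping. `eddy_coeffs` is a 3 x 4 matrix, one row per velocity
#' component, columns `(a, b, c, d)` giving offset
#' `a + b*x + c*y + d*z` with `x, y, z` in mm, `a` in m/s and `b, c, d` in
#' m/s per mm.
#'
#' @param noise_sd_m_s Gaussian noise SD per component, m/s (>= 0).
#' @param eddy_coeffs 3 x 4 numeric matrix or `NULL` for no offset.
#' @param wrap_at_venc Wrap the corrupted values into `(-venc, +venc]`?
#' @return Object of class `corruption_config`.
#' @export
corruption_config <- function(noise_sd_m_s = 0, eddy_coeffs = NULL,
                              wrap_at_venc = FALSE) {
  stopifnot(is.finite(noise_sd_m_s), noise_sd_m_s >= 0)
  if (!is.null(eddy_coeffs)) {
    eddy_coeffs <- as.matrix(eddy_coeffs)
    stopifnot(all(dim(eddy_coeffs) == c(3, 4)), all(is.finite(eddy_coeffs)))
  }
  structure(list(noise_sd_m_s = noise_sd_m_s, eddy_coeffs = eddy_coeffs,
                 wrap_at_venc = isTRUE(wrap_at_venc)),
            class = "corruption_config")
}

#' Default corruption used by the reference phantom
#'
#' Noise SD 0.05 m/s (a visually plausible phase-contrast noise floor; the
#' magnitude is a free parameter of the generator), a few-cm/s affine eddy
#' offset, and VENC wrapping enabled.
#'
#' @return A [corruption_config()].
#' @export
default_corruption <- function() {
  corruption_config(
    noise_sd_m_s = 0.05,
    eddy_coeffs = rbind(c(0.02,  0.001,  0,      0),
                        c(-0.01, 0,      5e-4,   0),
                        c(0.005, 0,      0,     -5e-4)),
    wrap_at_venc = TRUE)
}

# wrap into the half-open interval (-venc, +venc]
wrap_to_venc <- function(v, venc) venc - ((venc - v) %% (2 * venc))

#' Apply controlled corruptions to a velocity field
#'
#' Adds i.i.d. Gaussian noise per component, then the time-invariant affine
#' eddy-current offset, then (optionally) wraps every value into
#' `(-venc, +venc]` exactly as phase-contrast aliasing would. The applied
#' corruptions are recorded in the field's provenance log.
#'
#' @param field A [velocity_field()].
#' @param cfg A [corruption_config()].
#' @param seed Integer seed for the noise draw.
#' @return The corrupted [velocity_field()], flagged `wrapped` when
#'   wrapping was applied.
#' @export
corrupt_field <- function(field, cfg, seed = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(cfg, "corruption_config"))
  data <- field$data
  applied <- character()
  if (cfg$noise_sd_m_s > 0) {
    old <- .Random.seed_get()
    set.seed(as.integer(seed))
    data <- data + array(stats::rnorm(length(data), sd = cfg$noise_sd_m_s),
                         dim(data))
    .Random.seed_restore(old)
    applied <- c(applied, sprintf("noise sd=%g", cfg$noise_sd_m_s))
  }
  if (!is.null(cfg$eddy_coeffs)) {
    off <- eddy_offset_field(cfg$eddy_coeffs, field$grid)
    for (t_ in seq_len(field$grid$n_frames)) {
      data[, , , t_, ] <- data[, , , t_, ] + off
    }
    applied <- c(applied, "eddy offset")
  }
  wrapped <- FALSE
  if (cfg$wrap_at_venc) {
    if (is.null(field$venc_m_s)) {
      stop("wrap_at_venc requires the field to carry a VENC", call. = FALSE)
    }
    data <- wrap_to_venc(data, field$venc_m_s)
    wrapped <- TRUE
    applied <- c(applied, sprintf("wrapped at venc=%g", field$venc_m_s))
  }
  out <- velocity_field(data, field$grid, venc_m_s = field$venc_m_s,
                        wrapped = wrapped, log = field$log)
  annotate_field(out, paste0("corrupt[", paste(applied, collapse = ", "), "]"))
}

# affine offset sampled on the grid: array (nx, ny, nz, 3)
eddy_offset_field <- function(coeffs, grid) {
  co <- voxel_coords_mm(grid)
  dims <- grid$shape
  X <- array(rep(co[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(co[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(co[[3]], each = prod(dims[1:2])), dims)
  off <- array(0, c(dims, 3L))
  for (c_ in 1:3) {
    off[, , , c_] <- coeffs[c_, 1] + coeffs[c_, 2] * X +
      coeffs[c_, 3] * Y + coeffs[c_, 4] * Z
  }
  off
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default acquisition grid of the reference phantom
#'
#' 20^3 voxels at 6 mm isotropic spacing, 20 frames of 50 ms (1 s cycle),
#' mitral valve opening after frame 8. The temporal envelope matches
#' clinical atrial 4D-flow protocols; the spatial sampling is deliberately
#' coarse: the voxel noise that survives denoising enters the curl as
#' sigma/h, so a larger h keeps the vorticity noise floor well below the
#' phantom's vorticity while staying cheap to process.
#'
#' @return A [grid_spec()].
#' @export
default_phantom_grid <- function() {
  grid_spec(c(20L, 20L, 20L), 6, n_frames = 20L, frame_duration_s = 0.05,
            mv_open_frame = 8L)
}

#' Build a phantom dataset with known ground truth
#'
#' Composes the configured analytic primitives, builds the ellipsoidal LA
#' mask, computes ground-truth biomarkers on the clean field, and returns the
#' corrupted field alongside. The ground truth is computed before corruption,
#' so recovery of these values after preprocessing measures the whole
#' correction chain.
#'
#' @param cfg A [phantom_config()].
#' @param corruption A [corruption_config()] or `NULL` for a clean phantom.
#' @param grid A [grid_spec()]; default [default_phantom_grid()].
#' @param venc_m_s VENC recorded on the field (m/s).
#' @param patterns Classify flow patterns for the ground-truth biomarkers?
#'   Off by default (pathline integration is comparatively slow).
#' @return A list with elements `field` (corrupted), `clean`, `mask`,
#'   `static_mask` (logical array: voxels where the phantom flow is exactly
#'   zero, for the eddy-current fit), and `truth` (a `biomarker_set` row,
#'   see [extract_biomarkers()]).
#' @export
make_phantom <- function(cfg = phantom_config(), corruption = NULL,
                         grid = default_phantom_grid(), venc_m_s = 1.2,
                         patterns = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  frame <- array(0, c(grid$shape, 3L))
  for (comp in cfg$components) {
    params <- comp[setdiff(names(comp), "kind")]
    frame <- frame + analytic_frame(comp$kind, params, grid)
  }
  mask <- ellipsoid_mask(grid, cfg$mask_semiaxes_mm, cfg$mask_center_mm)
  env <- flow_envelope(grid, cfg$mask_semiaxes_mm, cfg$mask_center_mm,
                       cfg$envelope_inner %||% 1, cfg$envelope_outer)
  for (c_ in 1:3) frame[, , , c_] <- frame[, , , c_] * env
  data <- replicate_frames(frame, grid, cfg$temporal_profile)
  clean <- velocity_field(data, grid, venc_m_s = venc_m_s,
                          log = "phantom:composite")
  truth <- extract_biomarkers(clean, mask, patterns = patterns)
  field <- if (is.null(corruption)) clean else {
    corrupt_field(clean, corruption, seed = cfg$seed)
  }
  list(field = field, clean = clean, mask = mask,
       static_mask = env == 0, truth = truth)
}

# smooth cos^2 window: 1 up to level `inner` of the mask ellipsoid, 0 at and
# beyond level `outer`
flow_envelope <- function(grid, semiaxes_mm, center_mm, inner, outer) {
  extent <- (grid$shape - 1) * grid$spacing_mm
  ctr <- center_mm %||% (extent / 2)
  co <- voxel_coords_mm(grid)
  dims <- grid$shape
  X <- array(rep(co[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(co[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(co[[3]], each = prod(dims[1:2])), dims)
  lev <- sqrt(((X - ctr[1]) / semiaxes_mm[1])^2 +
                ((Y - ctr[2]) / semiaxes_mm[2])^2 +
                ((Z - ctr[3]) / semiaxes_mm[3])^2)
  w <- array(0, dims)
  w[lev <= inner] <- 1
  taper <- lev > inner & lev < outer
  w[taper] <- cos((lev[taper] - inner) / (outer - inner) * pi / 2)^2
  w
}

#' Ellipsoidal mask on a grid
#'
#' @param grid A [grid_spec()].
#' @param semiaxes_mm Ellipsoid semi-axes in mm.
#' @param center_mm Centre in mm; default grid centre. The ellipsoid must fit
#'   inside the grid extent.
#' @return A [la_mask()].
#' @export
ellipsoid_mask <- function(grid, semiaxes_mm = c(28, 24, 20),
                           center_mm = NULL) {
  stopifnot(length(semiaxes_mm) == 3, all(semiaxes_mm > 0))
  extent <- (grid$shape - 1) * grid$spacing_mm
  ctr <- center_mm %||% (extent / 2)
  if (any(ctr - semiaxes_mm < 0) || any(ctr + semiaxes_mm > extent)) {
    stop("ellipsoid (centre ", paste(signif(ctr, 4), collapse = ", "),
         " mm, semi-axes ", paste(semiaxes_mm, collapse = ", "),
         " mm) does not fit in the grid extent ",
         paste(signif(extent, 4), collapse = " x "), " mm", call. = FALSE)
  }
  co <- voxel_coords_mm(grid)
  dims <- grid$shape
  X <- array(rep(co[[1]], times = prod(dims[2:3])), dims)
  Y <- array(rep(rep(co[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(co[[3]], each = prod(dims[1:2])), dims)
  inside <- ((X - ctr[1]) / semiaxes_mm[1])^2 +
    ((Y - ctr[2]) / semiaxes_mm[2])^2 +
    ((Z - ctr[3]) / semiaxes_mm[3])^2 <= 1
  la_mask(inside, grid$spacing_mm)
}
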