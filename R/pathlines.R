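#' Seed plane for pathline emission
#'
#' A rectangular patch of seed points, mimicking probe planes placed at the
#' pulmonary vein ostia. Seeds are laid out on a regular grid centred on the
#' origin, spanning `extent_mm` in the two in-plane directions.
#'
#' @param origin_mm Plane centre, mm (length 3).
#' @param normal Plane normal (normalised internally).
#' @param extent_mm In-plane extent, mm (length 2 or scalar).
#' @param seeds_per_frame Number of seeds emitted per release frame.
#' @return Object of class `seed_plane`.
#' @export
seed_plane <- function(origin_mm, normal, extent_mm = c(20, 20),
                       seeds_per_frame = 25L) {
  if (length(extent_mm) == 1) extent_mm <- rep(extent_mm, 2)
  stopifnot(length(origin_mm) == 3, length(extent_mm) == 2,
            all(extent_mm > 0), seeds_per_frame >= 1)
  structure(list(origin_mm = as.numeric(origin_mm), normal = unit3(normal),
                 extent_mm = as.numeric(extent_mm),
                 seeds_per_frame = as.integer(seeds_per_frame)),
            class = "seed_plane")
}

# in-plane orthonormal basis + seed coordinates (m x 3, mm)
seed_points <- function(plane) {
  n <- plane$normal
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  k <- ceiling(sqrt(plane$seeds_per_frame))
  u <- if (k == 1) 0 else seq(-0.5, 0.5, length.out = k)
  gg <- as.matrix(expand.grid(u1 = u * plane$extent_mm[1],
                              u2 = u * plane$extent_mm[2]))
  gg <- gg[seq_len(plane$seeds_per_frame), , drop = FALSE]
  t(plane$origin_mm + t(gg[, 1, drop = FALSE] %*% t(e1) +
                          gg[, 2, drop = FALSE] %*% t(e2)))
}

#' Default seed plane and mitral-valve plane derived from a mask
#'
#' For phantom work: the seed plane sits near the superior (+z) pole of the
#' mask (where the pulmonary veins enter the atrium) facing down; the
#' mitral-valve plane sits near the inferior (-z) pole facing up.
#'
#' @param mask A [la_mask()].
#' @return A [seed_plane()] / a list `origin_mm`, `normal`.
#' @export
default_seed_plane <- function(mask) {
  bb <- mask_bounds_mm(mask)
  ctr <- colMeans(bb)
  seed_plane(c(ctr[1], ctr[2], bb[2, 3] - 0.15 * (bb[2, 3] - bb[1, 3])),
             normal = c(0, 0, -1),
             extent_mm = 0.4 * (bb[2, 1:2] - bb[1, 1:2]),
             seeds_per_frame = 16L)
}

#' @rdname default_seed_plane
#' @export
default_mv_plane <- function(mask) {
  bb <- mask_bounds_mm(mask)
  ctr <- colMeans(bb)
  list(origin_mm = c(ctr[1], ctr[2],
                     bb[1, 3] + 0.1 * (bb[2, 3] - bb[1, 3])),
       normal = c(0, 0, 1))
}

mask_bounds_mm <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * mask$spacing_mm
  hi <- (apply(idx, 2, max) - 1) * mask$spacing_mm
  rbind(lo, hi)
}

# trilinear (space) + linear (time, cyclic) velocity interpolation
# pos_mm: m x 3; returns m x 3 in m/s with NA rows outside the grid
interp_velocity <- function(field, pos_mm, t_s) {
  grid <- field$grid
  n <- grid$shape
  h <- grid$spacing_mm
  nt <- grid$n_frames
  tau <- grid$frame_duration_s
  u <- sweep(pos_mm, 2, h, "/")            # continuous 0-based indices
  inside <- u[, 1] >= 0 & u[, 1] <= n[1] - 1 &
    u[, 2] >= 0 & u[, 2] <= n[2] - 1 &
    u[, 3] >= 0 & u[, 3] <= n[3] - 1
  m <- nrow(pos_mm)
  out <- matrix(NA_real_, m, 3)
  if (!any(inside)) return(out)
  ui <- u[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(ui), 0), matrix(rep(n - 2, each = nrow(ui)),
                                        ncol = 3))
  fr <- ui - i0
  tf <- (t_s / tau) %% nt
  f0 <- floor(tf)
  wt <- tf - f0
  f0 <- as.integer(f0 %% nt)
  f1 <- as.integer((f0 + 1L) %% nt)
  nvox <- prod(n)
  base <- 1 + i0[, 1] + n[1] * (i0[, 2] + n[2] * i0[, 3])
  vals <- matrix(0, nrow(ui), 3)
  dat <- field$data
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- base + dx + n[1] * dy + n[1] * n[2] * dz
    for (c_ in 1:3) {
      off_c <- nvox * nt * (c_ - 1)
      v0 <- dat[lin + nvox * f0 + off_c]
      v1 <- dat[lin + nvox * f1 + off_c]
      vals[, c_] <- vals[, c_] + w * ((1 - wt) * v0 + wt * v1)
    }
  }
  out[inside, ] <- vals
  out
}

#' Integrate pathlines through the time-resolved field
#'
#' Massless particles are released from every seed plane at each release
#' frame and advected with classic 4th-order Runge-Kutta through the
#' time-varying velocity field, using trilinear interpolation in space and
#' linear (cyclic) interpolation in time. Integration runs from the release
#' time to the end of one averaged cardiac cycle; a pathline terminates early
#' when it leaves the grid or crosses the mitral-valve plane. Pathlines that
#' leave the grid within two steps are discarded as seeding artefacts.
#'
#' @param field A preprocessed [velocity_field()].
#' @param seeds A [seed_plane()] or list of seed planes.
#' @param dt_s Integration step in seconds; must be positive and no larger
#'   than the frame duration.
#' @param mv_plane `NULL` or a list `origin_mm`, `normal`; a sign change of
#'   the signed distance to this plane terminates the pathline as
#'   `reached_mv_plane`.
#' @param release_frames Frames at which seeds are emitted (default: all).
#' @param qc Discard pathlines that exit the grid within 2 steps?
#' @return A `pathline_set`: tibble with columns `pathline_id`,
#'   `release_frame`, `t_s`, `x_mm`, `y_mm`, `z_mm`, plus an attribute
#'   `terminations` (tibble `pathline_id`, `release_frame`, `reason` with
#'   reason one of `cycle_end`, `left_grid`, `reached_mv_plane`).
#' @export
integrate_pathlines <- function(field, seeds, dt_s, mv_plane = NULL,
                                release_frames = NULL, qc = TRUE) {
  stopifnot(inherits(field, "velocity_field"))
  if (inherits(seeds, "seed_plane")) seeds <- list(seeds)
  stopifnot(all(vapply(seeds, inherits, TRUE, "seed_plane")))
  grid <- field$grid
  if (!is.finite(dt_s) || dt_s <= 0) {
    stop("dt_s must be positive", call. = FALSE)
  }
  if (dt_s > grid$frame_duration_s + 1e-12) {
    stop("dt_s must not exceed the frame duration (",
         grid$frame_duration_s, " s)", call. = FALSE)
  }
  release_frames <- release_frames %||% seq_len(grid$n_frames)
  cycle_T <- cycle_length_s(grid)
  seed_xyz <- do.call(rbind, lapply(seeds, seed_points))
  traj <- list(); term <- list(); pid <- 0L
  for (f in release_frames) {
    t0 <- (f - 1) * grid$frame_duration_s
    res <- rk4_advect(field, seed_xyz, t0, cycle_T, dt_s, mv_plane)
    np <- nrow(seed_xyz)
    keep <- rep(TRUE, np)
    if (qc) keep <- !(res$reason == "left_grid" & res$n_steps <= 2L)
    for (s_ in which(keep)) {
      pid <- pid + 1L
      nst <- res$n_steps[s_] + 1L
      traj[[pid]] <- tibble::tibble(
        pathline_id = pid, release_frame = f,
        t_s = t0 + (seq_len(nst) - 1L) * dt_s,
        x_mm = res$path[seq_len(nst), s_, 1],
        y_mm = res$path[seq_len(nst), s_, 2],
        z_mm = res$path[seq_len(nst), s_, 3])
      # the final (possibly partial) step lands exactly on the cycle end
      if (res$reason[s_] == "cycle_end") {
        traj[[pid]]$t_s[nst] <- cycle_T
      }
      term[[pid]] <- tibble::tibble(pathline_id = pid, release_frame = f,
                                    reason = res$reason[s_])
    }
  }
  out <- dplyr::bind_rows(traj)
  attr(out, "terminations") <- dplyr::bind_rows(term)
  attr(out, "dt_s") <- dt_s
  class(out) <- c("pathline_set", class(out))
  out
}

# vectorised RK4 over one release; returns path array (steps+1, m, 3),
# per-particle step counts and termination reasons
rk4_advect <- function(field, x0, t0, t_end, dt_s, mv_plane) {
  m <- nrow(x0)
  n_steps <- max(0L, ceiling((t_end - t0) / dt_s - 1e-9))
  path <- array(NA_real_, c(n_steps + 1L, m, 3))
  path[1, , ] <- x0
  reason <- rep("cycle_end", m)
  last <- rep(n_steps, m)
  active <- rep(TRUE, m)
  pos <- x0
  sdist <- NULL
  if (!is.null(mv_plane)) {
    nrm <- unit3(mv_plane$normal)
    sdist <- as.vector((pos - matrix(mv_plane$origin_mm, m, 3,
                                     byrow = TRUE)) %*% nrm)
  }
  t_cur <- t0
  for (s_ in seq_len(n_steps)) {
    if (!any(active)) break
    h <- min(dt_s, t_end - t_cur)
    ai <- which(active)
    p <- pos[ai, , drop = FALSE]
    k1 <- interp_velocity(field, p, t_cur) * 1000            # mm/s
    k2 <- interp_velocity(field, p + h / 2 * k1, t_cur + h / 2) * 1000
    k3 <- interp_velocity(field, p + h / 2 * k2, t_cur + h / 2) * 1000
    k4 <- interp_velocity(field, p + h * k3, t_cur + h) * 1000
    newp <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    bad <- !is.finite(rowSums(newp))
    if (any(bad)) {
      reason[ai[bad]] <- "left_grid"
      last[ai[bad]] <- s_ - 1L
      active[ai[bad]] <- FALSE
    }
    ok <- !bad
    if (any(ok)) {
      pos[ai[ok], ] <- newp[ok, , drop = FALSE]
      path[s_ + 1L, ai[ok], ] <- newp[ok, , drop = FALSE]
      if (!is.null(sdist)) {
        newd <- as.vector((newp[ok, , drop = FALSE] -
                             matrix(mv_plane$origin_mm, sum(ok), 3,
                                    byrow = TRUE)) %*% nrm)
        crossed <- sign(newd) != sign(sdist[ai[ok]]) & sdist[ai[ok]] != 0
        if (any(crossed)) {
          idc <- ai[ok][crossed]
          reason[idc] <- "reached_mv_plane"
          last[idc] <- s_
          active[idc] <- FALSE
        }
        sdist[ai[ok]] <- newd
      }
    }
    t_cur <- t_cur + h
  }
  list(path = path, n_steps = last, reason = reason)
}

#' Rule-based flow-pattern classification
#'
#' A quantitative proxy for the visual categories used in atrial 4D-flow
#' reading: per pathline released in the phase of interest, the winding
#' angle about the vertical axis through the mask centroid is accumulated,
#' and the fraction of pathlines that reached the mitral-valve plane is
#' computed. The label is `vortex` when the median absolute winding is at
#' least `winding_threshold` and the reach fraction is at least
#' `reach_threshold`; `short_range_vortex` when the winding criterion holds
#' but the reach fraction falls short (rotating flow that fails to reach the
#' mitral valve within the averaged cycle); `other` otherwise.
#'
#' @param pl A `pathline_set` from [integrate_pathlines()].
#' @param phase `"systole"` or `"diastole"` — selects pathlines by release
#'   frame block.
#' @param grid The [grid_spec()] (defines the phase blocks).
#' @param mask A [la_mask()] (the rotation axis passes through its centroid).
#' @param winding_threshold Median winding (rad) required for a vortex;
#'   default `pi` (half a turn).
#' @param reach_threshold Minimum MV reach fraction for a full vortex;
#'   default 0.5.
#' @return A `pattern_call`: list with `label`, `mv_reach_fraction`,
#'   `median_winding_rad`, `phase`, `n_pathlines`.
#' @export
classify_flow_pattern <- function(pl, phase = c("systole", "diastole"),
                                  grid, mask,
                                  winding_threshold = pi,
                                  reach_threshold = 0.5) {
  phase <- match.arg(phase)
  stopifnot(inherits(pl, "pathline_set"))
  frames <- if (phase == "systole") systolic_frames(grid) else
    diastolic_frames(grid)
  sel <- dplyr::filter(tibble::as_tibble(pl), .data$release_frame %in% frames)
  ids <- unique(sel$pathline_id)
  if (length(ids) < 10) {
    stop("need >= 10 pathlines released in ", phase, "; got ", length(ids),
         call. = FALSE)
  }
  idxc <- which(mask$data, arr.ind = TRUE)
  ctr <- (colMeans(idxc) - 1) * mask$spacing_mm
  winding <- vapply(split(sel, sel$pathline_id), function(df) {
    th <- atan2(df$y_mm - ctr[2], df$x_mm - ctr[1])
    d <- diff(th)
    d <- (d + pi) %% (2 * pi) - pi
    abs(sum(d))
  }, numeric(1))
  terms <- attr(pl, "terminations")
  terms <- terms[terms$pathline_id %in% ids, ]
  reach <- mean(terms$reason == "reached_mv_plane")
  med_w <- stats::median(winding)
  label <- if (med_w >= winding_threshold && reach >= reach_threshold) {
    "vortex"
  } else if (med_w >= winding_threshold) {
    "short_range_vortex"
  } else "other"
  structure(list(label = label, mv_reach_fraction = reach,
                 median_winding_rad = med_w, phase = phase,
                 n_pathlines = length(ids)),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("<pattern_call> ", x$phase, ": ", x$label,
      " (median winding ", signif(x$median_winding_rad, 3), " rad, MV reach ",
      signif(x$mv_reach_fraction, 3), ", n = ", x$n_pathlines, ")\n",
      sep = "")
  invisible(x)
}
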