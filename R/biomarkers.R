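#' Voxel-wise speed
#'
#' Euclidean norm of the three velocity components per voxel and frame.
#'
#' @param field A [velocity_field()].
#' @return Numeric array `(x, y, z, frame)` of speeds in m/s.
#' @export
speed_map <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  sqrt(field$data[, , , , 1]^2 + field$data[, , , , 2]^2 +
         field$data[, , , , 3]^2)
}

#' Global peak and mean LA velocity
#'
#' Per-voxel temporal statistics come first: each in-mask voxel contributes
#' its temporal peak speed and its temporal mean speed. The global values are
#' spatial averages of these per-voxel statistics over the mask. For the peak
#' an alternative reduction — the single maximum speed over all voxels and
#' frames — is available via `peak_reduction = "max"`; the spatial mean of
#' per-voxel peaks is the default because a single noisy voxel cannot
#' dominate it.
#'
#' @param field A preprocessed [velocity_field()].
#' @param mask A [la_mask()].
#' @param peak_reduction `"mean"` (default) or `"max"`.
#' @return Named list `peak_velocity_m_s`, `mean_velocity_m_s`.
#' @export
global_velocity_stats <- function(field, mask,
                                  peak_reduction = c("mean", "max")) {
  peak_reduction <- match.arg(peak_reduction)
  check_mask_field(field, mask)
  sp <- speed_map(field)
  nt <- field$grid$n_frames
  nvox <- prod(field$grid$shape)
  spm <- matrix(sp, nrow = nvox, ncol = nt)[as.vector(mask$data), ,
                                            drop = FALSE]
  if (nrow(spm) == 0) stop("mask is empty", call. = FALSE)
  vox_peak <- apply(spm, 1, max)
  vox_mean <- rowMeans(spm)
  list(
    peak_velocity_m_s = if (peak_reduction == "mean") mean(vox_peak)
                        else max(vox_peak),
    mean_velocity_m_s = mean(vox_mean))
}

#' LA stasis
#'
#' Stasis of a voxel is the fraction of cardiac frames in which its speed is
#' strictly below the threshold (default 0.1 m/s): `n_stasis / n_tot`.
#' Global stasis is the average of the per-voxel stasis over all mask voxels,
#' a proportion from 0 (no stasis) to 1 (complete stasis). The comparison is
#' strict (`<`) so the frame counts are integer-exact and bit-reproducible.
#'
#' @param field A preprocessed [velocity_field()].
#' @param mask A [la_mask()].
#' @param threshold_m_s Positive stasis threshold, m/s.
#' @return A `stasis_result`: list with `per_voxel` (3-D array of
#'   proportions, `NA` outside the mask), `n_stasis` (3-D integer array of
#'   below-threshold frame counts), `n_tot`, `global_stasis`,
#'   `threshold_m_s`.
#' @export
compute_stasis <- function(field, mask, threshold_m_s = 0.1) {
  check_mask_field(field, mask)
  stopifnot(is.finite(threshold_m_s), threshold_m_s > 0)
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  sp <- speed_map(field)
  nt <- field$grid$n_frames
  below <- sp < threshold_m_s
  n_stasis <- apply(below, c(1, 2, 3), sum)
  per_voxel <- n_stasis / nt
  per_voxel[!mask$data] <- NA_real_
  structure(
    list(per_voxel = per_voxel,
         n_stasis = array(as.integer(n_stasis), dim(n_stasis)),
         n_tot = nt,
         global_stasis = mean(per_voxel[mask$data]),
         threshold_m_s = threshold_m_s),
    class = "stasis_result")
}

#' @export
print.stasis_result <- function(x, ...) {
  cat("<stasis_result> global stasis ", signif(x$global_stasis, 4),
      " (threshold ", x$threshold_m_s, " m/s, ", x$n_tot, " frames)\n",
      sep = "")
  invisible(x)
}

#' Vorticity-time curve and its cycle integral
#'
#' The curl of the velocity field is evaluated by central differences
#' (one-sided at grid edges; spacing converted mm to m), its magnitude is
#' averaged over the mask per frame (rad/s), and the area under the
#' vorticity-time curve over the cycle (rad) is accumulated by the rectangle
#' rule, `sum(curve) * frame_duration_s` — frames are uniform-width bins of
#' the cycle.
#'
#' @param field A preprocessed [velocity_field()].
#' @param mask A [la_mask()].
#' @return A `vorticity_curve`: tibble with columns `frame`, `time_s`,
#'   `vorticity_rad_s`, and attribute `auc_rad` (also via `$auc_rad` of the
#'   returned object's attributes or [glance()]).
#' @export
vorticity_curve <- function(field, mask) {
  check_mask_field(field, mask)
  grid <- field$grid
  if (any(grid$shape < 3L)) {
    stop("vorticity needs at least 3 voxels per axis", call. = FALSE)
  }
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  msk <- mask$data
  curve <- vapply(seq_len(grid$n_frames), function(t_) {
    J <- velocity_gradient(field$data[, , , t_, , drop = TRUE],
                           grid$spacing_mm)
    w <- curl_from_gradient(J)
    mag <- sqrt(w[[1]]^2 + w[[2]]^2 + w[[3]]^2)
    mean(mag[msk])
  }, numeric(1))
  out <- tibble::tibble(
    frame = seq_len(grid$n_frames),
    time_s = (seq_len(grid$n_frames) - 0.5) * grid$frame_duration_s,
    vorticity_rad_s = curve)
  attr(out, "auc_rad") <- sum(curve) * grid$frame_duration_s
  attr(out, "frame_duration_s") <- grid$frame_duration_s
  class(out) <- c("vorticity_curve", class(out))
  out
}

#' Lambda2 vortex-core field
#'
#' The lambda2 criterion marks vortex cores where the middle eigenvalue of
#' `S^2 + W^2` is negative, with `S` and `W` the symmetric and antisymmetric
#' parts of the velocity-gradient tensor. The vortex threshold is defined as
#' half the mean of the negative lambda2 values over all mask voxels and all
#' frames of the cycle; a vortex voxel must be more negative than this
#' threshold. (Averaging only the negative values keeps the threshold from
#' being diluted toward zero by irrotational voxels.)
#'
#' @param field A preprocessed [velocity_field()].
#' @param mask A [la_mask()].
#' @return A `lambda2_field`: list with `lambda2` (array `(x, y, z, frame)`,
#'   units 1/s^2), `threshold` (<= 0) and the mask.
#' @export
lambda2_field <- function(field, mask) {
  check_mask_field(field, mask)
  grid <- field$grid
  if (any(grid$shape < 3L)) {
    stop("lambda2 needs at least 3 voxels per axis", call. = FALSE)
  }
  l2 <- array(0, c(grid$shape, grid$n_frames))
  for (t_ in seq_len(grid$n_frames)) {
    J <- velocity_gradient(field$data[, , , t_, , drop = TRUE],
                           grid$spacing_mm)
    # A = S^2 + W^2 where S = (J + J')/2, W = (J - J')/2; equivalently
    # A_ij = (J_ik J_kj + J_ki J_jk)/2... computed directly from J entries
    S11 <- J[[1]][[1]]; S22 <- J[[2]][[2]]; S33 <- J[[3]][[3]]
    S12 <- (J[[1]][[2]] + J[[2]][[1]]) / 2
    S13 <- (J[[1]][[3]] + J[[3]][[1]]) / 2
    S23 <- (J[[2]][[3]] + J[[3]][[2]]) / 2
    W12 <- (J[[1]][[2]] - J[[2]][[1]]) / 2
    W13 <- (J[[1]][[3]] - J[[3]][[1]]) / 2
    W23 <- (J[[2]][[3]] - J[[3]][[2]]) / 2
    a11 <- S11^2 + S12^2 + S13^2 - W12^2 - W13^2
    a22 <- S12^2 + S22^2 + S23^2 - W12^2 - W23^2
    a33 <- S13^2 + S23^2 + S33^2 - W13^2 - W23^2
    a12 <- S11 * S12 + S12 * S22 + S13 * S23 - W13 * W23
    a13 <- S11 * S13 + S12 * S23 + S13 * S33 + W12 * W23
    a23 <- S12 * S13 + S22 * S23 + S23 * S33 - W12 * W13
    l2[, , , t_] <- sym3_middle_eigenvalue(a11, a22, a33, a12, a13, a23)
  }
  vals <- as.vector(l2)[rep(as.vector(mask$data), grid$n_frames)]
  neg <- vals[vals < 0]
  threshold <- if (length(neg)) mean(neg) / 2 else 0
  structure(list(lambda2 = l2, threshold = threshold, mask = mask),
            class = "lambda2_field")
}

#' @export
print.lambda2_field <- function(x, ...) {
  cat("<lambda2_field> threshold ", signif(x$threshold, 4), " 1/s^2, ",
      sum(x$lambda2 < x$threshold &
            array(x$mask$data, dim(x$lambda2))),
      " vortex voxel-frames\n", sep = "")
  invisible(x)
}

#' Largest vortex-ring volumes over the cycle
#'
#' Per frame, vortex voxels are the mask voxels with lambda2 strictly below
#' the threshold; connected components are formed with 26-connectivity and
#' the largest component's voxel count times the voxel volume gives that
#' frame's vortex volume in ml (0 when no vortex voxel exists). Reported as
#' the per-frame series plus the cycle mean and the peak within the systolic
#' and diastolic frame blocks.
#'
#' @param l2 A [lambda2_field()].
#' @param mask A [la_mask()].
#' @param grid The [grid_spec()] (for frame blocks and voxel volume).
#' @return A `vortex_volumes`: tibble with `frame`, `phase`, `volume_ml` and
#'   attributes `mean_ml`, `systolic_peak_ml`, `diastolic_peak_ml`.
#' @export
vortex_volumes <- function(l2, mask, grid) {
  stopifnot(inherits(l2, "lambda2_field"), inherits(mask, "la_mask"),
            inherits(grid, "grid_spec"))
  nt <- grid$n_frames
  vols <- vapply(seq_len(nt), function(t_) {
    cand <- mask$data & (l2$lambda2[, , , t_] < l2$threshold)
    largest_component_size(cand) * mask$voxel_volume_ml
  }, numeric(1))
  phase <- ifelse(seq_len(nt) <= grid$mv_open_frame, "systole", "diastole")
  out <- tibble::tibble(frame = seq_len(nt), phase = phase, volume_ml = vols)
  attr(out, "mean_ml") <- mean(vols)
  attr(out, "systolic_peak_ml") <- max(vols[systolic_frames(grid)])
  attr(out, "diastolic_peak_ml") <- max(vols[diastolic_frames(grid)])
  class(out) <- c("vortex_volumes", class(out))
  out
}

# size (voxel count) of the largest 26-connected component of a logical 3-D
# array; 0 for an empty array. Components via an explicit voxel adjacency
# graph (no 3-D labelling routine in the installed stack).
largest_component_size <- function(vox) {
  idx <- which(vox, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0)
  if (n == 1) return(1)
  dims <- dim(vox)
  key <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  ord <- order(key)
  key <- key[ord]; idx <- idx[ord, , drop = FALSE]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]   # half the neighbourhood; edges are undirected
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    ni <- idx[, 1] + offs[r, 1]
    nj <- idx[, 2] + offs[r, 2]
    nk <- idx[, 3] + offs[r, 3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    nkey <- (ni - 1) + dims[1] * ((nj - 1) + dims[2] * (nk - 1))
    m <- match(nkey[ok], key)
    hit <- !is.na(m)
    if (any(hit)) {
      edges[[length(edges) + 1]] <-
        cbind(which(ok)[hit], m[hit])
    }
  }
  if (!length(edges)) return(1)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  max(igraph::components(g)$csize)
}

#' Extract the full LA biomarker set
#'
#' Runs every global biomarker on a preprocessed field: peak and mean
#' velocity, stasis, vorticity AUC, lambda2 vortex volumes, and (optionally)
#' the rule-based flow-pattern classification for systole and diastole.
#' Deterministic for a fixed input.
#'
#' @param field A preprocessed [velocity_field()].
#' @param mask A [la_mask()].
#' @param stasis_threshold_m_s Stasis threshold, m/s.
#' @param peak_reduction See [global_velocity_stats()].
#' @param patterns Run the pathline classifier? (Slower; requires a usable
#'   default seed plane, see [default_seed_plane()].)
#' @param dt_s Pathline integration step when `patterns = TRUE`.
#' @return A one-row tibble of class `biomarker_set` with columns
#'   `peak_velocity_m_s`, `mean_velocity_m_s`, `global_stasis`,
#'   `vorticity_auc_rad`, `vortex_mean_ml`, `vortex_systolic_peak_ml`,
#'   `vortex_diastolic_peak_ml`, `pattern_systole`, `pattern_diastole`.
#' @export
extract_biomarkers <- function(field, mask, stasis_threshold_m_s = 0.1,
                               peak_reduction = c("mean", "max"),
                               patterns = TRUE, dt_s = NULL) {
  peak_reduction <- match.arg(peak_reduction)
  vel <- global_velocity_stats(field, mask, peak_reduction)
  st <- compute_stasis(field, mask, stasis_threshold_m_s)
  vc <- vorticity_curve(field, mask)
  l2 <- lambda2_field(field, mask)
  vv <- vortex_volumes(l2, mask, field$grid)
  pat_sys <- NA_character_; pat_dia <- NA_character_
  if (isTRUE(patterns)) {
    dt_s <- dt_s %||% (field$grid$frame_duration_s / 5)
    pl <- integrate_pathlines(field, list(default_seed_plane(mask)),
                              dt_s = dt_s, mv_plane = default_mv_plane(mask))
    pat_sys <- tryCatch(
      classify_flow_pattern(pl, "systole", field$grid, mask)$label,
      error = function(e) NA_character_)
    pat_dia <- tryCatch(
      classify_flow_pattern(pl, "diastole", field$grid, mask)$label,
      error = function(e) NA_character_)
  }
  out <- tibble::tibble(
    peak_velocity_m_s = vel$peak_velocity_m_s,
    mean_velocity_m_s = vel$mean_velocity_m_s,
    global_stasis = st$global_stasis,
    vorticity_auc_rad = attr(vc, "auc_rad"),
    vortex_mean_ml = attr(vv, "mean_ml"),
    vortex_systolic_peak_ml = attr(vv, "systolic_peak_ml"),
    vortex_diastolic_peak_ml = attr(vv, "diastolic_peak_ml"),
    pattern_systole = pat_sys,
    pattern_diastole = pat_dia)
  class(out) <- c("biomarker_set", class(out))
  out
}
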