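#' Cardiac-gated acquisition grid
#'
#' Describes the spatial and temporal sampling of a 4D-flow acquisition: the
#' voxel grid, its spacing, the number of reconstructed cardiac frames and
#' their duration, and the frame at which the mitral valve opens (the boundary
#' between the systolic and diastolic frame blocks).
#'
#' Voxel centres sit at world position `(index - 1) * spacing_mm` along each
#' axis (0-based voxel indices, positions in mm). Frame `f` covers the time
#' interval `[(f - 1), f) * frame_duration_s`; the cardiac cycle length is
#' `n_frames * frame_duration_s`. Frames `1:mv_open_frame` form the systolic
#' block and `(mv_open_frame + 1):n_frames` the diastolic block, so
#' `mv_open_frame` must lie in `[1, n_frames - 1]` to keep both non-empty.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing_mm Positive numeric vector of length 3 (or scalar), voxel
#'   spacing in millimetres.
#' @param n_frames Integer >= 2, number of cardiac frames.
#' @param frame_duration_s Positive scalar, duration of one frame in seconds.
#' @param mv_open_frame Integer in `[1, n_frames - 1]`: the last systolic
#'   frame; the mitral valve is open from frame `mv_open_frame + 1` onwards.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(c(24, 24, 24), 4, n_frames = 20, frame_duration_s = 0.05,
#'           mv_open_frame = 8)
#' @export
grid_spec <- function(shape, spacing_mm, n_frames, frame_duration_s,
                      mv_open_frame) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(spacing_mm) == 3, all(is.finite(spacing_mm)),
            all(spacing_mm > 0))
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 2, is.finite(frame_duration_s), frame_duration_s > 0)
  mv_open_frame <- as.integer(mv_open_frame)
  if (mv_open_frame < 1L || mv_open_frame >= n_frames) {
    stop("`mv_open_frame` must lie in [1, n_frames - 1] so that both the ",
         "systolic and diastolic frame blocks are non-empty.", call. = FALSE)
  }
  structure(
    list(shape = shape, spacing_mm = as.numeric(spacing_mm),
         n_frames = n_frames, frame_duration_s = as.numeric(frame_duration_s),
         mv_open_frame = mv_open_frame),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "), " voxels @ ",
      paste(signif(x$spacing_mm, 4), collapse = " x "), " mm, ",
      x$n_frames, " frames x ", x$frame_duration_s, " s (cycle ",
      cycle_length_s(x), " s), MV opens after frame ", x$mv_open_frame,
      "\n", sep = "")
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
cycle_length_s <- function(grid) grid$n_frames * grid$frame_duration_s

#' Frame indices of the systolic / diastolic blocks
#'
#' @param grid A [grid_spec()].
#' @return Integer vector of frame indices.
#' @export
systolic_frames <- function(grid) seq_len(grid$mv_open_frame)

#' @rdname systolic_frames
#' @export
diastolic_frames <- function(grid) (grid$mv_open_frame + 1L):grid$n_frames

#' Time-resolved three-directional velocity field
#'
#' The container every processing stage transforms: a 5-D numeric array of
#' velocities in m/s indexed `(x, y, z, frame, component)` plus its
#' [grid_spec()] and the velocity-encoding limit (VENC). Velocities beyond
#' +/-VENC alias (wrap) into the encoded range `(-venc, +venc]`.
#'
#' @param data Numeric array with dim `c(grid$shape, grid$n_frames, 3)`, m/s.
#' @param grid A [grid_spec()].
#' @param venc_m_s Positive scalar velocity-encoding limit in m/s, or `NULL`
#'   when not applicable (purely synthetic fields).
#' @param wrapped Logical; `TRUE` marks a field whose values are stored
#'   modulo the VENC range and still need unwrapping.
#' @param log Character vector of processing-step annotations (provenance).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(data, grid, venc_m_s = NULL, wrapped = FALSE,
                           log = character()) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- dim(data)
  expect_dim <- c(grid$shape, grid$n_frames, 3L)
  if (length(d) != 5L || !all(d == expect_dim)) {
    stop("velocity data must have dim (", paste(expect_dim, collapse = ", "),
         "); got (", paste(d, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("velocity data must be finite everywhere", call. = FALSE)
  }
  if (!is.null(venc_m_s)) stopifnot(is.finite(venc_m_s), venc_m_s > 0)
  structure(
    list(data = data, grid = grid,
         venc_m_s = if (is.null(venc_m_s)) NULL else as.numeric(venc_m_s),
         wrapped = isTRUE(wrapped), log = as.character(log)),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("<velocity_field> ", paste(x$grid$shape, collapse = " x "), " x ",
      x$grid$n_frames, " frames x 3 components",
      if (!is.null(x$venc_m_s)) paste0(", VENC ", x$venc_m_s, " m/s"),
      if (x$wrapped) " [wrapped]", "\n", sep = "")
  cat("  speed range: ", paste(signif(range(speed_map(x)), 4),
                               collapse = " .. "), " m/s\n", sep = "")
  if (length(x$log)) cat("  log: ", paste(x$log, collapse = "; "), "\n",
                         sep = "")
  invisible(x)
}

# append a provenance entry, preserving class
annotate_field <- function(field, entry) {
  field$log <- c(field$log, entry)
  field
}

#' Left atrial segmentation mask
#'
#' A boolean 3-D region defining the segmented left atrium on the velocity
#' grid (one value per voxel, shared by all frames).
#'
#' @param data Logical 3-D array, same spatial shape as the velocity grid;
#'   must contain at least one `TRUE` voxel.
#' @param spacing_mm Voxel spacing in mm (length 3 or scalar); used to derive
#'   the voxel volume in ml.
#' @return An object of class `la_mask` with element `voxel_volume_ml`
#'   (`prod(spacing_mm) / 1000`).
#' @export
la_mask <- function(data, spacing_mm) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(dim(data)) == 3, is.logical(data) || all(data %in% c(0, 1)),
            length(spacing_mm) == 3, all(spacing_mm > 0))
  data <- array(as.logical(data), dim(data))
  if (!any(data)) stop("mask must contain at least one voxel", call. = FALSE)
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         voxel_volume_ml = prod(spacing_mm) / 1000),
    class = "la_mask")
}

#' @export
print.la_mask <- function(x, ...) {
  cat("<la_mask> ", sum(x$data), " voxels of ",
      paste(dim(x$data), collapse = " x "), " (",
      signif(sum(x$data) * x$voxel_volume_ml, 4), " ml)\n", sep = "")
  invisible(x)
}

check_mask_field <- function(field, mask) {
  if (!all(dim(mask$data) == field$grid$shape)) {
    stop("mask shape (", paste(dim(mask$data), collapse = ", "),
         ") does not match velocity grid (",
         paste(field$grid$shape, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' @param grid A [grid_spec()].
#' @return List of three numeric vectors (mm), one per axis.
#' @keywords internal
voxel_coords_mm <- function(grid) {
  lapply(1:3, function(a) (seq_len(grid$shape[a]) - 1) * grid$spacing_mm[a])
}
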