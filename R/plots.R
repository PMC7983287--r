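# ggplot2 visualisations of the result objects.

#' Plot a vorticity-time curve
#'
#' @param object A `vorticity_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vorticity_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$vorticity_rad_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (s)", y = "volume-averaged |vorticity| (rad/s)",
                  subtitle = sprintf("AUC = %.3g rad", attr(object, "auc_rad")))
}

#' Plot vortex volumes over the cycle
#'
#' @param object A `vortex_volumes`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vortex_volumes <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame, y = .data$volume_ml,
                               fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cardiac frame", y = "largest vortex volume (ml)")
}

#' Plot pathlines (axial projection)
#'
#' @param object A `pathline_set`.
#' @param ... Unused.
#' @return A ggplot of the x-y projection, one line per pathline.
#' @export
autoplot.pathline_set <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               group = .data$pathline_id,
                               colour = .data$t_s)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "t (s)")
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means with the bias and the
#' 95% limits of agreement.
#'
#' @param pairs Pair table (columns `x1`, `x2`).
#' @return A ggplot.
#' @export
plot_bland_altman <- function(pairs) {
  m <- as_pairs(pairs)
  st <- bland_altman(pairs)
  df <- tibble::tibble(mean = (m[, 1] + m[, 2]) / 2, diff = m[, 1] - m[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = st$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(st$loa_low, st$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "pair mean", y = "difference (x1 - x2)")
}

#' Histogram of per-voxel stasis
#'
#' @param object A `stasis_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stasis_result <- function(object, ...) {
  vals <- object$per_voxel[!is.na(object$per_voxel)]
  ggplot2::ggplot(tibble::tibble(stasis = vals),
                  ggplot2::aes(x = .data$stasis)) +
    ggplot2::geom_histogram(bins = 21, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$global_stasis, linetype = 2) +
    ggplot2::labs(x = "per-voxel stasis (proportion of frames)",
                  y = "voxels",
                  subtitle = sprintf("global stasis = %.3f",
                                     object$global_stasis))
}
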