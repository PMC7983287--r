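# broom-style tidiers for the fitted/estimated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a within-subject CV estimate
#'
#' @param x A `cv_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `n.subjects`, `n.boot`.
#' @export
tidy.cv_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$cv, conf.low = x$ci_low, conf.high = x$ci_high,
                 n.subjects = x$n_subjects, n.boot = x$n_boot)
}

#' Tidy a CV comparison
#'
#' @param x A `cv_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (delta CV), `conf.low`, `conf.high`,
#'   `p.value`, `paired`, `n.boot`.
#' @export
tidy.cv_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$delta_cv, conf.low = x$ci_low,
                 conf.high = x$ci_high, p.value = x$p_value,
                 paired = x$paired, n.boot = x$n_boot)
}

#' Tidy Bland-Altman agreement statistics
#'
#' @param x An `agreement_stats`.
#' @param ... Unused.
#' @return One-row tibble: `bias`, `loa.low`, `loa.high`, `sd.diff`, `n`.
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa.low = x$loa_low, loa.high = x$loa_high,
                 sd.diff = x$sd_diff, n = x$n)
}

#' Tidy / glance an ICC fit
#'
#' @param x An `icc_fit`.
#' @param ... Unused.
#' @return `tidy()`: one-row tibble `estimate`, `statistic`, `p.value`,
#'   `n`, `k`. `glance()`: the ANOVA mean squares.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$icc, statistic = x$f_statistic,
                 p.value = x$p_value, n = x$n, k = x$k)
}

#' @rdname tidy.icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(msr = x$msr, msc = x$msc, mse = x$mse, icc = x$icc,
                 p.value = x$p_value)
}

#' Glance at a vorticity curve
#'
#' @param x A `vorticity_curve`.
#' @param ... Unused.
#' @return One-row tibble: `auc.rad`, `peak.rad.s`, `n.frames`.
#' @export
glance.vorticity_curve <- function(x, ...) {
  tibble::tibble(auc.rad = attr(x, "auc_rad"),
                 peak.rad.s = max(x$vorticity_rad_s),
                 n.frames = nrow(x))
}

#' Glance at vortex volumes
#'
#' @param x A `vortex_volumes`.
#' @param ... Unused.
#' @return One-row tibble: `mean.ml`, `systolic.peak.ml`,
#'   `diastolic.peak.ml`.
#' @export
glance.vortex_volumes <- function(x, ...) {
  tibble::tibble(mean.ml = attr(x, "mean_ml"),
                 systolic.peak.ml = attr(x, "systolic_peak_ml"),
                 diastolic.peak.ml = attr(x, "diastolic_peak_ml"))
}
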