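# Reproducibility statistics: RMS within-subject CV with bootstrap
# inference, Bland-Altman agreement, two-way mixed ICC, McNemar, stratified
# bootstrap Pearson, Spearman, Bonferroni, and Bland-Altman agreement power.

# coerce pair input (tibble from cv_pairs(), 2-column data frame/matrix) to
# an n x 2 numeric matrix, keeping subject ids when present
as_pairs <- function(pairs) {
  if (is.matrix(pairs)) {
    stopifnot(ncol(pairs) == 2)
    m <- pairs
    ids <- rownames(pairs)
  } else if (is.data.frame(pairs)) {
    cols <- if (all(c("x1", "x2") %in% names(pairs))) c("x1", "x2") else {
      nc <- names(pairs)[vapply(pairs, is.numeric, TRUE)]
      if (length(nc) < 2) stop("pair input needs two numeric columns",
                               call. = FALSE)
      nc[1:2]
    }
    m <- cbind(pairs[[cols[1]]], pairs[[cols[2]]])
    ids <- if ("subject_id" %in% names(pairs)) pairs$subject_id else NULL
  } else {
    stop("pairs must be a matrix or data frame", call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("pairs must not contain missing values", call. = FALSE)
  attr(m, "subject_id") <- ids
  m
}

# per-subject squared-CV terms of the RMS formula
cv_terms <- function(m) {
  if (any(m <= 0)) {
    stop("within-subject CV is undefined for non-positive values",
         call. = FALSE)
  }
  ((m[, 1] - m[, 2])^2 / 2) / ((m[, 1] + m[, 2]) / 2)^2
}

rms_cv_from_terms <- function(terms) sqrt(mean(terms))

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

#' Within-subject coefficient of variation (root-mean-square method)
#'
#' For paired measurements `(x1, x2)` of the same subjects, the
#' within-subject CV is
#' `sqrt( mean( ((x1 - x2)^2 / 2) / ((x1 + x2) / 2)^2 ) )`:
#' the root mean square over subjects of the per-subject variance (for two
#' replicates, `d^2 / 2`) divided by the squared pair mean. It is reported
#' as a proportion. A non-parametric 95% CI is obtained by percentile
#' bootstrap over subjects.
#'
#' @param pairs Two-column data frame or matrix of positive paired values
#'   (columns `x1`, `x2`; e.g. from [cv_pairs()]).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @param conf_level Confidence level (default 0.95).
#' @return A `cv_estimate`: list with `cv`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_boot`. Supports [tidy()].
#' @examples
#' within_subject_cv(data.frame(x1 = c(9, 19), x2 = c(11, 21)), seed = 1)
#' @export
within_subject_cv <- function(pairs, n_boot = 1000L, seed = NULL,
                              conf_level = 0.95) {
  m <- as_pairs(pairs)
  terms <- cv_terms(m)
  n <- length(terms)
  cv <- rms_cv_from_terms(terms)
  ci <- c(NA_real_, NA_real_)
  if (n >= 2 && n_boot > 0) {
    boots <- with_seed(seed, boot_cv_draws(terms, n_boot))
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  structure(list(cv = cv, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, n_boot = as.integer(n_boot),
                 conf_level = conf_level),
            class = "cv_estimate")
}

# bootstrap CV draws by resampling per-subject terms
boot_cv_draws <- function(terms, n_boot) {
  n <- length(terms)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  sqrt(rowMeans(matrix(terms[idx], n_boot, n)))
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat("<cv_estimate> CV = ", signif(x$cv, 4), " (",
      100 * x$conf_level, "% CI ", signif(x$ci_low, 4), " to ",
      signif(x$ci_high, 4), "; n = ", x$n_subjects, ", ", x$n_boot,
      " bootstraps)\n", sep = "")
  invisible(x)
}

two_tailed_boot_p <- function(deltas) {
  b <- length(deltas)
  min(1, 2 * min(sum(deltas <= 0) + 1, sum(deltas >= 0) + 1) / (b + 1))
}

#' Compare within-subject CVs of two independent groups
#'
#' Bootstraps the CV difference `cv(A) - cv(B)` by resampling subjects
#' within each group independently; the CI is the percentile interval of the
#' bootstrap difference distribution, and the two-tailed p-value is
#' `2 * min(#\{delta* <= 0\} + 1, #\{delta* >= 0\} + 1) / (n_boot + 1)`,
#' capped at 1.
#'
#' @param pairs_a,pairs_b Pair tables (see [within_subject_cv()]) of the two
#'   groups, each with >= 2 subjects.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @param conf_level Confidence level for the delta CI.
#' @return A `cv_comparison`: `delta_cv`, `ci_low`, `ci_high`, `p_value`,
#'   `n_boot`, `paired = FALSE`. Supports [tidy()].
#' @export
compare_cv_independent <- function(pairs_a, pairs_b, n_boot = 1000L,
                                   seed = NULL, conf_level = 0.95) {
  ta <- cv_terms(as_pairs(pairs_a))
  tb <- cv_terms(as_pairs(pairs_b))
  stopifnot(length(ta) >= 2, length(tb) >= 2)
  delta <- rms_cv_from_terms(ta) - rms_cv_from_terms(tb)
  deltas <- with_seed(seed, {
    boot_cv_draws(ta, n_boot) - boot_cv_draws(tb, n_boot)
  })
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(deltas, c(a, 1 - a)))
  structure(list(delta_cv = delta, ci_low = ci[1], ci_high = ci[2],
                 p_value = two_tailed_boot_p(deltas),
                 n_boot = as.integer(n_boot), paired = FALSE),
            class = "cv_comparison")
}

#' Compare two dependent within-subject CVs
#'
#' For two reproducibility contrasts measured on the same subjects (e.g.
#' same-day rescan vs interval scan), subjects are resampled jointly — each
#' bootstrap draw carries a subject's pairs from both contrasts — preserving
#' their dependence. CI and p-value as in [compare_cv_independent()].
#'
#' @param pairs_a,pairs_b Pair tables over identical subjects, aligned or
#'   carrying a `subject_id` column to align by.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Optional seed.
#' @param conf_level Confidence level for the delta CI.
#' @return A `cv_comparison` with `paired = TRUE`.
#' @export
compare_cv_dependent <- function(pairs_a, pairs_b, n_boot = 10000L,
                                 seed = NULL, conf_level = 0.95) {
  ma <- as_pairs(pairs_a)
  mb <- as_pairs(pairs_b)
  ida <- attr(ma, "subject_id"); idb <- attr(mb, "subject_id")
  if (!is.null(ida) && !is.null(idb)) {
    only_a <- setdiff(ida, idb); only_b <- setdiff(idb, ida)
    if (length(only_a) || length(only_b)) {
      stop("subject sets differ: only in A {",
           paste(utils::head(only_a, 5), collapse = ", "),
           "}, only in B {", paste(utils::head(only_b, 5), collapse = ", "),
           "}", call. = FALSE)
    }
    mb <- mb[match(ida, idb), , drop = FALSE]
  } else if (nrow(ma) != nrow(mb)) {
    stop("dependent CV comparison needs the same subjects in both pair ",
         "tables (", nrow(ma), " vs ", nrow(mb), " rows)", call. = FALSE)
  }
  ta <- cv_terms(ma); tb <- cv_terms(mb)
  n <- length(ta)
  delta <- rms_cv_from_terms(ta) - rms_cv_from_terms(tb)
  deltas <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    sqrt(rowMeans(matrix(ta[idx], n_boot, n))) -
      sqrt(rowMeans(matrix(tb[idx], n_boot, n)))
  })
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(deltas, c(a, 1 - a)))
  structure(list(delta_cv = delta, ci_low = ci[1], ci_high = ci[2],
                 p_value = two_tailed_boot_p(deltas),
                 n_boot = as.integer(n_boot), paired = TRUE),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("<cv_comparison", if (x$paired) " (paired)", "> dCV = ",
      signif(x$delta_cv, 4), " [", signif(x$ci_low, 4), ", ",
      signif(x$ci_high, 4), "], p = ", signif(x$p_value, 3), " (",
      x$n_boot, " bootstraps)\n", sep = "")
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Mean bias and 95% limits of agreement, `bias +/- 1.96 * SD(diff)` with
#' the sample (n-1) standard deviation of the paired differences.
#'
#' @param pairs Pair table (columns `x1`, `x2`); differences are `x1 - x2`.
#' @return An `agreement_stats`: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`. Supports [tidy()].
#' @export
bland_altman <- function(pairs) {
  m <- as_pairs(pairs)
  if (nrow(m) < 2) stop("Bland-Altman needs n >= 2 pairs", call. = FALSE)
  d <- m[, 1] - m[, 2]
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = nrow(m)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats> bias ", signif(x$bias, 4), " (LoA ",
      signif(x$loa_low, 4), " to ", signif(x$loa_high, 4), ", n = ", x$n,
      ")\n", sep = "")
  invisible(x)
}

#' Two-way mixed-model ICC, absolute agreement, single measures
#'
#' ICC(A,1) from the two-way ANOVA mean squares of a complete subjects x 2
#' raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with `MSR` the between-subject, `MSC` the between-rater and `MSE` the
#' residual mean square. The p-value tests `ICC = 0` via `F = MSR / MSE`
#' with `(n-1)` and `(n-1)(k-1)` degrees of freedom.
#'
#' @param ratings Complete n x 2 numeric matrix or data frame (one column
#'   per rater), n >= 3, no missing cells.
#' @return An `icc_fit`: `icc`, `p_value`, `n`, `k`, and the mean squares
#'   (`msr`, `msc`, `mse`). Supports [tidy()] and [glance()].
#' @export
icc_two_way_mixed <- function(ratings) {
  m <- as_pairs(ratings)
  n <- nrow(m); k <- ncol(m)
  if (anyNA(m)) stop("ICC requires a complete table (no missing cells)",
                     call. = FALSE)
  if (n < 3) stop("ICC needs at least 3 subjects", call. = FALSE)
  g <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - g)^2) / (n - 1)
  msc <- n * sum((colm - g)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  f <- msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, p_value = p, n = n, k = k,
                 msr = msr, msc = msc, mse = mse, f_statistic = f),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat("<icc_fit> ICC(A,1) = ", signif(x$icc, 4), ", p = ",
      format.pval(x$p_value, digits = 3), " (n = ", x$n, ", k = ", x$k,
      ")\n", sep = "")
  invisible(x)
}

#' McNemar's test on discordant counts
#'
#' For paired categorical calls, only the discordant pairs are informative:
#' `b` changed one way, `c` the other. When `b + c < 25` the exact
#' two-tailed binomial test on `(b, b + c, 1/2)` is used; otherwise the
#' chi-square approximation with continuity correction
#' (via [stats::mcnemar.test()]). `b = c = 0` gives p = 1.
#'
#' @param b,c Non-negative integer discordant counts.
#' @return List with `p_value`, `method`, `b`, `c`.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0,
            b == round(b), c == round(c))
  nd <- b + c
  if (nd == 0) {
    return(list(p_value = 1, method = "exact binomial", b = b, c = c))
  }
  if (nd < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    method <- "exact binomial"
  } else {
    p <- stats::mcnemar.test(matrix(c(0, c, b, 0), 2, 2),
                             correct = TRUE)$p.value
    method <- "chi-square with continuity correction"
  }
  list(p_value = p, method = method, b = b, c = c)
}

#' Pearson correlation with stratified bootstrap CI
#'
#' The correlation is computed on the pooled data; the percentile CI comes
#' from resampling observations within each stratum (preserving stratum
#' sizes), so that e.g. the SR/AF composition of every resample matches the
#' observed one.
#'
#' @param x,y Numeric vectors.
#' @param strata Factor-like stratum labels (default: one stratum). Each
#'   stratum needs >= 3 observations.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional seed.
#' @param conf_level Confidence level.
#' @return List with `r`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
pearson_bootstrap <- function(x, y, strata = NULL, n_boot = 1000L,
                              seed = NULL, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  strata <- if (is.null(strata)) rep(1L, n) else as.factor(strata)
  stopifnot(length(strata) == n)
  if (any(table(strata) < 3)) {
    stop("each stratum needs at least 3 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  groups <- split(seq_len(n), strata)
  rs <- with_seed(seed, vapply(seq_len(n_boot), function(b_) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_ else
      stats::cor(xs, ys)
  }, numeric(1)))
  rs <- rs[is.finite(rs)]
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(rs, c(a, 1 - a)))
  list(r = r, ci_low = ci[1], ci_high = ci[2], n = n,
       n_boot = as.integer(n_boot))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rank correlation undefined: zero rank variance", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` per value (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Power of a Bland-Altman agreement study
#'
#' Power that both estimated 95% limits of agreement fall inside the
#' pre-defined clinical agreement limits `+/- max_allowed_diff`, under the
#' normal-approximation framework of Lu et al. (2016): with expected bias
#' `mu`, SD of differences `sigma`, the standard error of an estimated limit
#' is `sigma * sqrt(1/n + z^2 / (2(n - 1)))` with `z = 1.96`, and
#' `power = Phi(tau1) + Phi(tau2) - 1` where
#' `tau_i = (delta -/+ mu - z * sigma) / SE - z_{1 - alpha/2}`.
#' Degenerate configurations (agreement limit at or inside the expected
#' limits of agreement) report power near 0 rather than erroring.
#'
#' @param n Number of subjects (>= 2).
#' @param mean_diff Expected mean difference (bias).
#' @param sd_diff Expected SD of differences (> 0).
#' @param max_allowed_diff Pre-defined clinical agreement limit
#'   (> `|mean_diff|`).
#' @param alpha Two-tailed type-I error (default 0.05).
#' @return Power as a proportion in \[0, 1\].
#' @references Lu M-J et al. (2016) Sample size for assessing agreement
#'   between two methods of measurement by Bland-Altman method.
#'   Int J Biostat 12(2).
#' @examples
#' ba_agreement_power(n = 74, mean_diff = 0.01, sd_diff = 0.05,
#'                    max_allowed_diff = 0.15)
#' @export
ba_agreement_power <- function(n, mean_diff, sd_diff, max_allowed_diff,
                               alpha = 0.05) {
  stopifnot(n >= 2, is.finite(mean_diff), sd_diff > 0,
            is.finite(max_allowed_diff))
  if (max_allowed_diff <= abs(mean_diff)) {
    stop("max_allowed_diff must exceed |mean_diff|", call. = FALSE)
  }
  z_loa <- stats::qnorm(0.975)          # the 95% limits-of-agreement factor
  z_a <- stats::qnorm(1 - alpha / 2)
  se <- sd_diff * sqrt(1 / n + z_loa^2 / (2 * (n - 1)))
  tau1 <- (max_allowed_diff - mean_diff - z_loa * sd_diff) / se - z_a
  tau2 <- (max_allowed_diff + mean_diff - z_loa * sd_diff) / se - z_a
  min(1, max(0, stats::pnorm(tau1) + stats::pnorm(tau2) - 1))
}

#' @rdname ba_agreement_power
#' @param target_power Power to reach (default 0.9).
#' @param n_max Search ceiling.
#' @return `ba_sample_size`: the smallest n reaching `target_power`.
#' @export
ba_sample_size <- function(target_power = 0.9, mean_diff, sd_diff,
                           max_allowed_diff, alpha = 0.05, n_max = 1e6) {
  stopifnot(target_power > 0, target_power < 1)
  lo <- 2; hi <- 2
  while (ba_agreement_power(hi, mean_diff, sd_diff, max_allowed_diff,
                            alpha) < target_power) {
    lo <- hi; hi <- hi * 2
    if (hi > n_max) {
      stop("no n <= ", n_max, " reaches power ", target_power, call. = FALSE)
    }
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (ba_agreement_power(mid, mean_diff, sd_diff, max_allowed_diff,
                           alpha) >= target_power) hi <- mid else lo <- mid
  }
  hi
}
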