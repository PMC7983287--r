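test_that("RMS within-subject CV matches hand evaluation", {
  # equal pairs: CV exactly 0
  expect_equal(within_subject_cv(data.frame(x1 = c(10, 20),
                                            x2 = c(10, 20)),
                                 n_boot = 0)$cv, 0)
  # sqrt(((2/100) + (2/400)) / 2) = 0.1118...
  est <- within_subject_cv(data.frame(x1 = c(9, 19), x2 = c(11, 21)),
                           n_boot = 0)
  expect_equal(est$cv, sqrt((4 / 2 / 100 + 4 / 2 / 400) / 2))
  expect_equal(est$cv, 0.1118034, tolerance = 1e-7)
})

test_that("CV is scale invariant and zero iff all pairs agree", {
  set.seed(8)
  m <- sim_pairs(40, 0.08)
  cv1 <- within_subject_cv(m, n_boot = 0)$cv
  cv2 <- within_subject_cv(m * 7.3, n_boot = 0)$cv
  expect_equal(cv1, cv2, tolerance = 1e-12)
  expect_gt(cv1, 0)
})

test_that("non-positive values are rejected for the CV", {
  expect_error(within_subject_cv(data.frame(x1 = c(1, -2), x2 = c(1, 2))),
               "non-positive")
})

test_that("CV estimation recovers the generating coefficient", {
  set.seed(15)
  m <- sim_pairs(500, 0.10)
  expect_lt(abs(within_subject_cv(m, n_boot = 0)$cv - 0.10), 0.02)
})

test_that("bootstrap CI is seeded-reproducible and subject-order invariant", {
  set.seed(9)
  m <- sim_pairs(50, 0.12)
  e1 <- within_subject_cv(m, n_boot = 500, seed = 3)
  e2 <- within_subject_cv(m, n_boot = 500, seed = 3)
  expect_identical(e1, e2)
  expect_true(e1$ci_low <= e1$cv && e1$cv <= e1$ci_high)
  # permuting subjects changes nothing about the estimate; the bootstrap CI
  # endpoints are resample-identical because terms are drawn by index only
  perm <- m[sample(nrow(m)), ]
  e3 <- within_subject_cv(perm, n_boot = 500, seed = 3)
  expect_equal(e1$cv, e3$cv, tolerance = 1e-12)
})

test_that("identical independent groups give a null p-value", {
  set.seed(10)
  m <- sim_pairs(60, 0.10)
  cmp <- compare_cv_independent(m, m, n_boot = 1000, seed = 2)
  expect_gte(cmp$p_value, 0.8)
  expect_equal(cmp$delta_cv, 0)
})

test_that("well-separated CVs are detected with high power", {
  set.seed(12)
  hits <- 0
  for (r in 1:40) {
    a <- sim_pairs(50, 0.05)
    b <- sim_pairs(50, 0.20)
    cmp <- compare_cv_independent(a, b, n_boot = 500, seed = r)
    hits <- hits + (cmp$p_value < 0.05 && cmp$delta_cv < 0)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("independent-CV CI covers the true difference", {
  set.seed(13)
  true_delta <- 0.05 - 0.12
  cover <- 0
  for (r in 1:100) {
    a <- sim_pairs(60, 0.05)
    b <- sim_pairs(60, 0.12)
    cmp <- compare_cv_independent(a, b, n_boot = 400, seed = r)
    cover <- cover + (cmp$ci_low <= true_delta &&
                        true_delta <= cmp$ci_high)
  }
  expect_gte(cover / 100, 0.88)
  expect_lte(cover / 100, 1)
})

test_that("dependent comparison of a table with itself is exactly null", {
  set.seed(14)
  m <- sim_pairs(30, 0.1)
  cmp <- compare_cv_dependent(m, m, n_boot = 500, seed = 1)
  expect_equal(cmp$delta_cv, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$paired)
})

test_that("dependent comparison rejects mismatched subject sets", {
  t1 <- tibble::tibble(subject_id = c("a", "b", "c"), x1 = 1:3 + 10,
                       x2 = 1:3 + 11)
  t2 <- tibble::tibble(subject_id = c("a", "b", "d"), x1 = 1:3 + 10,
                       x2 = 1:3 + 11)
  expect_error(compare_cv_dependent(t1, t2), "only in A \\{c\\}")
  # same subjects in a different order are aligned by id
  t3 <- t1[c(3, 1, 2), ]
  cmp <- compare_cv_dependent(t1, t3, n_boot = 200, seed = 1)
  expect_equal(cmp$delta_cv, 0)
})

test_that("interval variability is detected against rescan (paired power)", {
  # rescan arms share the visit error (it cancels); the interval arm draws
  # an independent visit error, lifting the pair CV from 0.10 to 0.14
  set.seed(16)
  sv <- sqrt(0.14^2 - 0.10^2)
  hits <- 0
  for (r in 1:30) {
    n <- 74
    truth <- pmax(rnorm(n, 0.4, 0.1), 0.05)
    ev1 <- rnorm(n, 0, sv); ev2 <- rnorm(n, 0, sv)
    x1a <- truth * (1 + rnorm(n, 0, 0.10) + ev1)
    x1b <- truth * (1 + rnorm(n, 0, 0.10) + ev1)
    x2 <- truth * (1 + rnorm(n, 0, 0.10) + ev2)
    cmp <- compare_cv_dependent(cbind(x1a, x2), cbind(x1a, x1b),
                                n_boot = 1000, seed = r)
    hits <- hits + (cmp$p_value < 0.05 && cmp$delta_cv > 0)
  }
  expect_gt(hits / 30, 0.5)
})

test_that("joint resampling narrows the delta-CV CI under dependence", {
  set.seed(17)
  n <- 74
  truth <- pmax(rnorm(n, 0.4, 0.1), 0.05)
  x1 <- truth * (1 + rnorm(n, 0, 0.10))
  x2 <- truth * (1 + rnorm(n, 0, 0.10))
  a <- cbind(x1, x2)
  b <- cbind(x1, x2 * (1 + rnorm(n, 0, 0.04)))   # strongly correlated pairs
  dep <- compare_cv_dependent(a, b, n_boot = 4000, seed = 2)
  ind <- compare_cv_independent(a, b, n_boot = 4000, seed = 2)
  expect_lt(dep$ci_high - dep$ci_low, ind$ci_high - ind$ci_low)
})

test_that("Bland-Altman agreement matches hand calculations", {
  # identical pairs
  b0 <- bland_altman(data.frame(x1 = c(3, 5, 9), x2 = c(3, 5, 9)))
  expect_equal(b0$bias, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(0, 0))
  # diffs {-2, +2}: sd = 2.828, LoA = +/- 5.543
  b1 <- bland_altman(data.frame(x1 = c(0, 2), x2 = c(2, 0)))
  expect_equal(b1$bias, 0)
  expect_equal(b1$sd_diff, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(b1$loa_high, 5.543717, tolerance = 1e-6)
  # adding a constant to the second measurement shifts only the bias
  set.seed(18)
  m <- sim_pairs(30, 0.1)
  ba <- bland_altman(m)
  m2 <- m; m2[, 2] <- m2[, 2] + 1.5
  ba2 <- bland_altman(m2)
  expect_equal(ba2$bias, ba$bias - 1.5, tolerance = 1e-12)
  expect_equal(ba2$loa_high - ba2$loa_low, ba$loa_high - ba$loa_low,
               tolerance = 1e-12)
  expect_error(bland_altman(data.frame(x1 = 1, x2 = 2)), "n >= 2")
})

test_that("ICC(A,1) matches the explicit two-way ANOVA oracle", {
  set.seed(19)
  for (r in 1:10) {
    m <- matrix(rnorm(12, 10, 2), 6, 2)
    fit <- icc_two_way_mixed(m)
    df <- data.frame(y = as.vector(m), subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
    av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
    msr <- av["subj", "Mean Sq"]
    msc <- av["rater", "Mean Sq"]
    mse <- av["Residuals", "Mean Sq"]
    oracle <- (msr - mse) / (msr + mse + (2 / 6) * (msc - mse))
    expect_equal(fit$icc, oracle, tolerance = 1e-10)
    expect_true(fit$icc >= -1 && fit$icc <= 1)
  }
})

test_that("ICC distinguishes absolute agreement from consistency", {
  x <- c(4, 6, 8, 10, 12, 14)
  perfect <- icc_two_way_mixed(cbind(x, x))
  expect_equal(perfect$icc, 1)
  shifted <- icc_two_way_mixed(cbind(x, x + 3))
  expect_lt(shifted$icc, 1)   # consistency ICC would still be 1
  expect_gt(shifted$icc, 0)
})

test_that("ICC(A,1) approaches Pearson r on exchangeable tables", {
  # double-entered (symmetrised) tables have equal column means/variances;
  # the two statistics then differ only by O(1/n) finite-sample terms
  set.seed(20)
  for (n in c(50, 500)) {
    x <- rnorm(n, 10, 2)
    y <- x + rnorm(n, 0, 1.5)
    m <- rbind(cbind(x, y), cbind(y, x))
    gap <- abs(icc_two_way_mixed(m)$icc - stats::cor(c(x, y), c(y, x)))
    expect_lt(gap, 3 / n)
  }
})

test_that("ICC rejects incomplete or too-small tables", {
  expect_error(icc_two_way_mixed(cbind(c(1, 2), c(2, 3))), "at least 3")
  m <- cbind(c(1, 2, NA), c(2, 3, 4))
  expect_error(icc_two_way_mixed(m), "missing")
})

test_that("McNemar handles exact and asymptotic regimes", {
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  # one-sided discordance b = 10, c = 0: exact p = 2 * 0.5^10
  ex <- mcnemar_test(10, 0)
  expect_equal(ex$p_value, 2 * 0.5^10)
  expect_equal(round(ex$p_value, 5), 0.00195)
  expect_match(ex$method, "exact")
  # symmetric discordance: p = 1 under the exact test
  expect_equal(mcnemar_test(7, 7)$p_value, 1)
  # large counts: chi-square with continuity correction
  asy <- mcnemar_test(20, 10)
  expect_match(asy$method, "chi-square")
  expect_equal(asy$p_value,
               stats::pchisq((abs(20 - 10) - 1)^2 / 30, 1,
                             lower.tail = FALSE))
})

test_that("Pearson bootstrap handles exact linearity and independence", {
  x <- 1:20
  lin <- pearson_bootstrap(x, 2 * x, n_boot = 200, seed = 1)
  expect_equal(lin$r, 1)
  expect_equal(c(lin$ci_low, lin$ci_high), c(1, 1))
  expect_equal(pearson_bootstrap(x, -x, n_boot = 50, seed = 1)$r, -1)
  expect_error(pearson_bootstrap(x, rep(1, 20)), "zero variance")
  # coverage of zero under independence
  set.seed(21)
  cover <- 0
  for (r in 1:100) {
    xs <- rnorm(100); ys <- rnorm(100)
    ci <- pearson_bootstrap(xs, ys, n_boot = 300, seed = r)
    cover <- cover + (ci$ci_low <= 0 && 0 <= ci$ci_high)
  }
  expect_gte(cover / 100, 0.88)
})

test_that("stratified resampling preserves stratum sizes", {
  set.seed(22)
  x <- c(rnorm(40, 0), rnorm(10, 3))
  y <- x + rnorm(50, 0, 0.5)
  strata <- rep(c("SR", "AF"), c(40, 10))
  res <- pearson_bootstrap(x, y, strata = strata, n_boot = 200, seed = 5)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  expect_error(pearson_bootstrap(x[1:4], y[1:4],
                                 strata = c("a", "a", "a", "b")),
               "at least 3")
})

test_that("Spearman matches the rank oracle including ties", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  x <- c(1, 2, 2, 3, 3, 3, 4)
  y <- c(2, 1, 3, 3, 4, 3, 5)
  expect_equal(spearman_cor(x, y)$rho,
               stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_cor(x, y)$rho,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
})

test_that("Bonferroni adjustment caps at 1", {
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  expect_equal(bonferroni_adjust(0.03), 0.03)
  expect_error(bonferroni_adjust(c(0.1, 0)), "")
})

test_that("agreement power behaves at the boundary and monotonically", {
  # limit exactly at the expected upper LoA: essentially no power
  mu <- 0.01; s <- 0.05
  edge <- ba_agreement_power(74, mu, s, mu + stats::qnorm(0.975) * s + 1e-9)
  expect_lt(edge, 0.01)
  # monotone in n and in the agreement limit
  pw_n <- vapply(c(20, 40, 74, 150), ba_agreement_power,
                 numeric(1), mean_diff = 0.01, sd_diff = 0.05,
                 max_allowed_diff = 0.15)
  expect_true(all(diff(pw_n) > 0))
  pw_l <- vapply(c(0.12, 0.135, 0.15, 0.2), function(l)
    ba_agreement_power(74, 0.01, 0.05, l), numeric(1))
  expect_true(all(diff(pw_l) > 0))
  expect_error(ba_agreement_power(74, 0.2, 0.05, 0.15), "exceed")
  # inverse search returns the smallest sufficient n
  n_min <- ba_sample_size(0.9, 0.01, 0.05, 0.15)
  expect_gte(ba_agreement_power(n_min, 0.01, 0.05, 0.15), 0.9)
  expect_lt(ba_agreement_power(n_min - 1, 0.01, 0.05, 0.15), 0.9)
})

test_that("tidy methods return one-row tibbles with broom-style names", {
  set.seed(23)
  m <- sim_pairs(30, 0.1)
  td <- tidy(within_subject_cv(m, n_boot = 100, seed = 1))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "conf.low", "conf.high", "n.subjects",
                     "n.boot"))
  tc <- tidy(compare_cv_independent(m, m, n_boot = 100, seed = 1))
  expect_named(tc, c("estimate", "conf.low", "conf.high", "p.value",
                     "paired", "n.boot"))
  tb <- tidy(bland_altman(m))
  expect_named(tb, c("bias", "loa.low", "loa.high", "sd.diff", "n"))
  ti <- tidy(icc_two_way_mixed(m))
  expect_named(ti, c("estimate", "statistic", "p.value", "n", "k"))
  expect_named(glance(icc_two_way_mixed(m)),
               c("msr", "msc", "mse", "icc", "p.value"))
})
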