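test_that("paired contrast reproduces hand-computed t and Hedges' g", {
  a <- c(2, 3, 4, 5, 6); b <- c(1, 1, 1, 1, 1)
  res <- paired_contrast(a, b)
  d <- a - b
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$statistic, 4.242641, tolerance = 1e-6)
  J <- 1 - 3 / (4 * 4 - 1)
  expect_equal(res$effect_size, mean(d) / sd(d) * J, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(res$statistic), 4), tolerance = 1e-12)
})

test_that("degenerate inputs: exact null returns t = 0, other zero-variance errors", {
  a <- c(0.3, 0.5, 0.7)
  res <- paired_contrast(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$effect_size, 0)
  expect_error(paired_contrast(a + 1, a), "degenerate")
  expect_error(paired_contrast(1, 1), "at least 2")
  expect_error(paired_contrast(1:3, 1:4), "unequal")
})

test_that("one-sample test matches its arithmetic and symmetry anchors", {
  x <- c(0.1, 0.1, 0.1, 0.3)
  res <- one_sample_test(x)
  expect_equal(res$statistic, mean(x) / (sd(x) / 2), tolerance = 1e-12)
  expect_equal(res$effect_size, mean(x) / sd(x) * (1 - 3 / 11),
               tolerance = 1e-12)
  sym <- one_sample_test(c(-2, -1, 1, 2), mu0 = 0)
  expect_equal(sym$statistic, 0)
  expect_error(one_sample_test(rep(1, 5), mu0 = 0), "degenerate")
  expect_equal(one_sample_test(rep(0.2, 4), mu0 = 0.2)$p_value, 1)
})

test_that("Hedges' correction is below 1 and vanishes asymptotically", {
  ns <- c(5, 10, 50, 500, 5000)
  J <- vapply(ns, psyadapt:::hedges_j, 0)
  expect_true(all(J < 1))
  expect_true(all(diff(J) > 0))
  expect_lt(1 - J[length(J)], 1e-3)
})

test_that("2x2 repeated-measures effects equal squared contrast t tests", {
  # no effects at all
  cells <- matrix(0.3, nrow = 6, ncol = 4)
  res <- rm_anova_2x2(cells)
  expect_equal(res$factor_a$statistic, 0)
  expect_equal(res$interaction$statistic, 0)
  # additive construction (observer-specific main effects) has exactly zero
  # interaction
  set.seed(8)
  # exact (integer) arithmetic so the interaction contrast is identically 0
  base <- sample(0:20, 10, TRUE); ea <- sample(1:6, 10, TRUE)
  eb <- sample(1:4, 10, TRUE)
  add <- cbind(base + ea + eb, base + ea, base + eb, base)
  res_add <- rm_anova_2x2(add)
  expect_lt(res_add$interaction$statistic, 1e-10)
  expect_gt(res_add$factor_a$statistic, 1)
  # random cohort: F = t^2 against this package's own t machinery
  for (i in 1:10) {
    m <- matrix(rnorm(24 * 4), 24, 4)
    res_r <- rm_anova_2x2(m)
    t_a <- one_sample_test(as.vector(m %*% c(1, 1, -1, -1) / 2))
    t_x <- one_sample_test(as.vector(m %*% c(1, -1, -1, 1) / 2))
    expect_equal(res_r$factor_a$statistic, t_a$statistic^2, tolerance = 1e-8)
    expect_equal(res_r$interaction$statistic, t_x$statistic^2, tolerance = 1e-8)
    expect_equal(res_r$factor_a$p_value, t_a$p_value, tolerance = 1e-10)
  }
  expect_error(rm_anova_2x2(matrix(1, 3, 3)), "4 cells")
  expect_error(rm_anova_2x2(matrix(c(1, NA, 1, 1, 1, 1, 1, 1), 2, 4)),
               "incomplete")
})

test_that("2x2 contrasts agree with a classical aov decomposition", {
  set.seed(21)
  m <- matrix(rnorm(12 * 4, mean = rep(c(0.5, 0.2, 0, 0), each = 12)), 12, 4)
  res <- rm_anova_2x2(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:12, 4)),
                  A = factor(rep(c(1, 1, 2, 2), each = 12)),
                  B = factor(rep(c(1, 2, 1, 2), each = 12)))
  fit <- summary(aov(y ~ A * B + Error(subj / (A * B)), data = d))
  f_aov <- c(fit[["Error: subj:A"]][[1]]["A", "F value"],
             fit[["Error: subj:B"]][[1]]["B", "F value"],
             fit[["Error: subj:A:B"]][[1]]["A:B", "F value"])
  expect_equal(c(res$factor_a$statistic, res$factor_b$statistic,
                 res$interaction$statistic), f_aov, tolerance = 1e-8)
})

test_that("directional JZS Bayes factor matches the quadrature oracle", {
  # null data favour the null under a directional alternative
  expect_gt(jzs_bf01(0, 21), 1)
  cases <- list(c(1.2, 20), c(0.3, 24), c(-1.31, 21), c(2.1, 12), c(-0.8, 30))
  for (cs in cases) {
    mine <- jzs_bf01(cs[1], cs[2])
    oracle <- oracle_jzs_bf01(cs[1], cs[2])
    expect_equal(mine, oracle, tolerance = 1e-4)
  }
  # vanishing prior width: the alternative collapses onto the null
  expect_equal(jzs_bf01(1.7, 18, prior_scale = 1e-5), 1, tolerance = 1e-3)
  # direction is explicit: mirrored t flips to the mirrored alternative
  expect_equal(jzs_bf01(1.4, 22, alternative = "greater"),
               jzs_bf01(-1.4, 22, alternative = "less"), tolerance = 1e-9)
  expect_error(jzs_bf01(1, 1), "n >= 2")
  expect_error(jzs_bf01(1, 10, prior_scale = -1), "positive")
})

test_that("two one-sided JZS factors average to the published two-sided value", {
  # anchors computed with an independent reference implementation (pingouin)
  two_sided <- function(t, n)   # two-sided BF10
    0.5 * (1 / jzs_bf01(t, n, alternative = "greater") +
             1 / jzs_bf01(t, n, alternative = "less"))
  expect_equal(two_sided(1.2, 20), 0.4357932316, tolerance = 1e-6)
  expect_equal(two_sided(2.5, 15), 2.611153746, tolerance = 1e-6)
  expect_equal(two_sided(0, 24), 0.2146547988, tolerance = 1e-6)
})

test_that("robustness sweep finds the substantial-evidence boundary", {
  rb <- bf_robustness(0, 21, scales = c(0.2, 0.5, 0.707, 1))
  expect_true(all(diff(rb$bf01) > 0))  # BF01 grows with prior width at t = 0
  expect_equal(rb$min_scale_substantial, rb$scales[min(which(rb$bf01 >= 3))])
  for (i in seq_along(rb$scales))
    expect_equal(rb$bf01[i], jzs_bf01(0, 21, rb$scales[i]), tolerance = 1e-10)
  expect_error(bf_robustness(0, 21, scales = numeric(0)), "empty")
  expect_error(bf_robustness(0, 21, scales = c(0.5, 0.2)), "increasing")
  # a null-centred medium-n dataset keeps substantial evidence to low widths
  rb2 <- bf_robustness(-1.31, 21, scales = seq(0.1, 1.5, by = 0.05))
  expect_lt(rb2$min_scale_substantial, 0.25)
  expect_gt(1 / jzs_bf01(-1.31, 21, 0.707), 0.1)  # sanity: finite evidence
})

test_that("Pearson correlation with Bayes factor matches oracles", {
  x <- c(0.12, -0.5, 1.3, 0.7, -0.2, 0.05, 2.1, -1.4, 0.9, 0.33)
  y <- c(0.5, -0.1, 0.8, 1.1, 0.3, -0.4, 1.9, -0.6, 0.2, 0.45)
  res <- pearson_with_bf(x, y)
  expect_equal(res$r, cor(x, y))
  expect_equal(res$p_value, cor.test(x, y)$p.value)
  expect_equal(res$bf01, oracle_pearson_bf01(res$r, 10), tolerance = 1e-4)
  # perfect correlation
  res1 <- suppressWarnings(pearson_with_bf(1:10, 1:10 * 2))
  expect_equal(res1$r, 1)
  expect_equal(res1$bf01, 0)
  expect_error(pearson_with_bf(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(pearson_with_bf(1:3, 1:4), "unequal")
})

test_that("Pearson Bayes factors reproduce independent reference values", {
  # frozen anchors from an independent implementation (pingouin, exact
  # stretched-beta BF with width 1): BF10 values
  expect_equal(1 / psyadapt:::corr_bf01(0.3, 20), 0.599651569,
               tolerance = 1e-6)
  expect_equal(1 / psyadapt:::corr_bf01(0.6, 10), 1.713097027,
               tolerance = 1e-6)
  expect_equal(1 / psyadapt:::corr_bf01(0.05, 50), 0.1868533048,
               tolerance = 1e-6)
})

test_that("independent data give null-leaning correlation Bayes factors", {
  set.seed(4)
  hits <- 0
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(40)
    if (pearson_with_bf(x, y)$bf01 > 1) hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("Bonferroni utility caps at one and is off by default", {
  expect_equal(bonferroni(c(0.01, 0.4), m = 3), c(0.03, 1))
  expect_equal(bonferroni(0.2), 0.2)
})
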