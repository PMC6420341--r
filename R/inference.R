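#' @name group-tests
#' @title Group-level frequentist tests with small-sample effect sizes
#'
#' @description
#' `paired_contrast()` runs a two-sided paired t test on per-observer value
#' pairs and reports Hedges' g; `one_sample_test()` the one-sample analogue
#' (effect size g1). The effect-size denominator for paired data is the
#' standard deviation of the difference scores, with the small-sample
#' correction `J = 1 - 3 / (4(n - 1) - 1)`.
#'
#' When all differences (or all deviations from `mu0`) are exactly zero the
#' tests return `t = 0, p = 1, g = 0` (there is literally no effect);
#' otherwise a zero-variance input is a degenerate-variance error.
#'
#' @param a,b per-observer values (equal length, no missing pairs).
#' @param x per-observer values.
#' @param mu0 null value for the one-sample test.
#' @return object of class `"psy_test"`: `statistic` (t), `df`, `p_value`,
#'   `effect_size`, `effect_label`, `n`, `method`.
NULL

hedges_j <- function(n) 1 - 3 / (4 * (n - 1) - 1)

psy_test <- function(statistic, df, p_value, effect_size, effect_label,
                     n, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), effect_size = unname(effect_size),
                 effect_label = effect_label, n = n, method = method),
            class = "psy_test")
}

#' @export
print.psy_test <- function(x, ...) {
  stat <- if (length(x$df) == 2) sprintf("F(%g, %g) = %.3f", x$df[1], x$df[2],
                                         x$statistic)
  else sprintf("t(%g) = %.3f", x$df, x$statistic)
  cat(sprintf("%s: %s, p = %.4g, %s = %.3f\n", x$method, stat, x$p_value,
              x$effect_label, x$effect_size))
  invisible(x)
}

#' @rdname group-tests
#' @export
paired_contrast <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed", call. = FALSE)
  one_sample_core(a - b, 0, "paired t test", "Hedges g")
}

#' @rdname group-tests
#' @export
one_sample_test <- function(x, mu0 = 0) {
  one_sample_core(x, mu0, "one-sample t test", "g1")
}

one_sample_core <- function(d, mu0, method, label) {
  n <- length(d)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (all(d == mu0))
    return(psy_test(0, n - 1, 1, 0, label, n, method))
  if (sd(d) == 0)
    stop("degenerate variance: all values identical", call. = FALSE)
  tt <- t.test(d, mu = mu0)
  g <- (mean(d) - mu0) / sd(d) * hedges_j(n)
  psy_test(tt$statistic, tt$parameter, tt$p.value, g, label, n, method)
}

#' 2 x 2 repeated-measures ANOVA via within-subject contrasts
#'
#' For a fully within-subject 2 x 2 design (e.g. face present/absent by
#' disgusted/angry body posture), each effect is a one-sample t test on the
#' per-observer contrast scores `(+1,+1,-1,-1)/2`, `(+1,-1,+1,-1)/2` and
#' `(+1,-1,-1,+1)/2`; the reported `F = t^2` with `df = (1, n - 1)` is the
#' classical repeated-measures F for 1-df effects.
#'
#' @param cells matrix or data frame, one row per observer, columns in the
#'   order `A1B1, A1B2, A2B1, A2B2` (factor A varying slowest). Column names,
#'   if present, are kept in the output labels.
#' @return list of three `"psy_test"` objects: `factor_a`, `factor_b`,
#'   `interaction`, each carrying F, `df = c(1, n-1)`, p and the g1 effect
#'   size of the underlying contrast.
#' @export
rm_anova_2x2 <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4) stop("need exactly 4 cells per observer", call. = FALSE)
  if (anyNA(cells)) stop("incomplete cells: missing values", call. = FALSE)
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 observers", call. = FALSE)
  contrasts <- list(factor_a = c(1, 1, -1, -1) / 2,
                    factor_b = c(1, -1, 1, -1) / 2,
                    interaction = c(1, -1, -1, 1) / 2)
  lapply(contrasts, function(cc) {
    tt <- one_sample_core(as.vector(cells %*% cc), 0,
                          "repeated-measures ANOVA effect", "g1")
    psy_test(tt$statistic^2, c(1, n - 1),
             pf(tt$statistic^2, 1, n - 1, lower.tail = FALSE),
             tt$effect_size, "g1", n, "repeated-measures ANOVA effect (F = t^2)")
  })
}

#' Directional JZS Bayes factor for a (paired or one-sample) t statistic
#'
#' Evidence for the point null over a directional alternative placing a
#' half-Cauchy prior (scale `prior_scale`, default 0.707 as in standard
#' Bayesian t-test software) on the standardized effect size. The marginal
#' likelihood is evaluated by adaptive quadrature after the substitution
#' `delta = prior_scale * tan(pi u / 2)`, which maps the half-Cauchy prior
#' mass to the uniform measure on `(0, 1)`:
#' \deqn{BF_{10} = \frac{\int_0^1 T_{n-1}(t;\; \sqrt{n}\,s\tan(\pi u/2))\,du}
#'   {T_{n-1}(t;\,0)}, \qquad BF_{01} = 1/BF_{10}}
#' with `T` the noncentral-t density. The direction of the alternative is an
#' explicit argument and is never inferred from the data.
#'
#' @param t observed t statistic.
#' @param n number of (pairs of) observations, >= 2.
#' @param prior_scale Cauchy prior scale ("prior width") on the standardized
#'   effect size.
#' @param alternative direction of the alternative: `"greater"` (effect > 0)
#'   or `"less"`.
#' @return BF01 (> 1 favours the null).
#' @examples
#' jzs_bf01(t = -1.31, n = 21, alternative = "greater") # approx 9.1
#' @export
jzs_bf01 <- function(t, n, prior_scale = 0.707,
                     alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (prior_scale <= 0) stop("'prior_scale' must be positive", call. = FALSE)
  tt <- if (alternative == "less") -t else t
  df <- n - 1
  ## dt() warns about reduced tail precision at extreme noncentrality; those
  ## densities are effectively 0 and harmless to the quadrature
  marg <- tryCatch(
    integrate(function(u)
      suppressWarnings(dt(tt, df, ncp = sqrt(n) * prior_scale * tan(pi * u / 2))),
      0, 1, rel.tol = 1e-6, stop.on.error = TRUE),
    error = function(e)
      stop("Bayes factor quadrature failed (t = ", t, ", n = ", n,
           ", scale = ", prior_scale, "): ", conditionMessage(e), call. = FALSE))
  bf10 <- marg$value / dt(tt, df)
  1 / bf10
}

#' Bayes factor robustness over a grid of prior widths
#'
#' Evaluates [jzs_bf01()] at each prior scale and reports the smallest scale
#' at which the evidence for the null is still substantial (BF01 >= 3).
#'
#' @param t,n,alternative as in [jzs_bf01()].
#' @param scales strictly increasing positive prior scales.
#' @return object of class `"bf_robustness"`: `scales`, `bf01`,
#'   `min_scale_substantial` (`NA` if the threshold is never reached).
#' @export
bf_robustness <- function(t, n, scales = seq(0.1, 1.5, by = 0.05),
                          alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(scales) == 0) stop("empty prior-scale grid", call. = FALSE)
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("'scales' must be positive and strictly increasing", call. = FALSE)
  bf <- vapply(scales, function(s) jzs_bf01(t, n, s, alternative), 0)
  sub <- scales[bf >= 3]
  structure(list(scales = scales, bf01 = bf,
                 min_scale_substantial = if (length(sub)) min(sub) else NA_real_,
                 t = t, n = n, alternative = alternative),
            class = "bf_robustness")
}

#' @export
print.bf_robustness <- function(x, ...) {
  cat(sprintf("BF01 robustness (t = %.3f, n = %d, one-sided '%s')\n",
              x$t, x$n, x$alternative))
  cat(sprintf("  scales %.3g..%.3g: BF01 %.3g..%.3g\n", min(x$scales),
              max(x$scales), x$bf01[1], x$bf01[length(x$bf01)]))
  cat("  substantial null evidence (BF01 >= 3) down to scale:",
      if (is.na(x$min_scale_substantial)) "never"
      else format(x$min_scale_substantial, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.bf_robustness <- function(x, ...) {
  plot.default(x$scales, x$bf01, type = "b", log = "y",
               xlab = "Cauchy prior scale (width)", ylab = "BF01", ...)
  abline(h = 3, lty = 2)
  if (!is.na(x$min_scale_substantial))
    abline(v = x$min_scale_substantial, lty = 3)
  invisible(x)
}

## Gaussian hypergeometric 2F1 by its power series (converges for |z| < 1;
## here z = (1 + rho r)/2 < 1 and c - a - b = n - 3/2 > 0)
hyp2f1 <- function(a, b, cc, z) {
  vapply(z, function(zz) {
    term <- 1; s <- 1
    for (k in 0:100000) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * zz
      s <- s + term
      if (abs(term) < 1e-16 * abs(s)) return(s)
    }
    stop("hypergeometric series did not converge", call. = FALSE)
  }, 0)
}

## likelihood ratio f(r | rho, n) / f(r | 0, n) from the exact sampling
## density of the Pearson correlation coefficient
corr_lik_ratio <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
    hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2) /
    hyp2f1(0.5, 0.5, n - 0.5, 0.5)
}

## BF01 for an observed correlation r at sample size n under the
## stretched-Beta(1/w, 1/w) prior on rho
corr_bf01 <- function(r, n, width = 1) {
  bf10 <- integrate(function(rho)
    corr_lik_ratio(rho, r, n) * dbeta((rho + 1) / 2, 1 / width, 1 / width) / 2,
    -1, 1, rel.tol = 1e-6)$value
  1 / bf10
}

#' Pearson correlation with a Bayesian companion
#'
#' The product-moment correlation with its two-sided p value (via the t
#' transform), plus a Bayes factor for the null of no correlation against a
#' stretched-Beta prior on the correlation: `(rho + 1)/2 ~ Beta(1/w, 1/w)`
#' with prior width `w` (the standard width is 1, a uniform prior on
#' `(-1, 1)`). The marginal likelihood integrates the exact sampling density
#' of `r` over the prior by adaptive quadrature (relative tolerance 1e-6).
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @param beta_prior_width stretched-Beta prior width (> 0).
#' @return list with `r`, `p_value`, `bf01`, `n`, `prior_width`.
#' @export
pearson_with_bf <- function(x, y, beta_prior_width = 1) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (beta_prior_width <= 0) stop("'beta_prior_width' must be > 0", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  ct <- cor.test(x, y)
  r <- unname(ct$estimate)
  n <- length(x)
  if (abs(r) > 1 - 1e-12) {
    warning("|r| is numerically 1; BF01 set to 0")
    return(list(r = r, p_value = ct$p.value, bf01 = 0, n = n,
                prior_width = beta_prior_width))
  }
  list(r = r, p_value = ct$p.value,
       bf01 = corr_bf01(r, n, beta_prior_width), n = n,
       prior_width = beta_prior_width)
}

#' m-fold Bonferroni correction
#'
#' Optional utility (off by default throughout the pipeline, mirroring the
#' reporting convention of uncorrected per-comparison p values).
#'
#' @param p p value(s).
#' @param m number of comparisons.
#' @return corrected p values, capped at 1.
#' @export
bonferroni <- function(p, m = 1) pmin(1, p * m)
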