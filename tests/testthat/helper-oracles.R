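## Independent oracles: brute-force / alternative-route implementations used
## only to check the package's fast paths. They deliberately avoid the
## package's internal code paths.

## exhaustive grid search over (alpha, sigma) for the binomial MLE
oracle_fit_grid <- function(level, n, k, guess = 0, lapse = 0.03,
                            alpha_range = c(-0.5, 1.5),
                            sigma_range = c(0.01, 1), n_grid = 50) {
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_grid)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_grid))
  best <- list(ll = -Inf)
  for (a in alphas) for (s in sigmas) {
    p <- guess + (1 - guess - lapse) * pnorm((level - a) / s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(k * log(p) + (n - k) * log(1 - p))
    if (ll > best$ll) best <- list(ll = ll, alpha = a, sigma = s)
  }
  best
}

## brute-force Psi expected entropy: explicit loops over candidates, both
## responses and all grid cells
oracle_psi_select <- function(alpha_grid, sigma_grid, candidates, posterior,
                              guess = 0, lapse = 0.03) {
  g <- expand.grid(alpha = alpha_grid, sigma = sigma_grid)
  eh <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    x <- candidates[ci]
    p1 <- guess + (1 - guess - lapse) * pnorm((x - g$alpha) / g$sigma)
    p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
    total <- 0
    for (r in c(1, 0)) {
      lik <- if (r == 1) p1 else 1 - p1
      w <- posterior * lik
      pr <- sum(w)
      q <- w / pr
      H <- -sum(ifelse(q > 0, q * log(q), 0))
      total <- total + pr * H
    }
    eh[ci] <- total
  }
  list(x = candidates[which.min(round(eh, 12))], eh = eh)
}

## one-line recomputation of both bias indices straight from counts
oracle_bias <- function(counts, face) {
  con <- face
  incon <- setdiff(c("disgust", "anger"), face)
  p <- function(ctx) counts[ctx, face] / (counts[ctx, "disgust"] + counts[ctx, "anger"])
  N <- function(ctx) counts[ctx, "disgust"] + counts[ctx, "anger"]
  adj <- function(pp, nn) if (pp == 0) 1 / nn else if (pp == 1) 1 - 1 / nn else pp
  i1 <- if (p(incon) > 0) p(con) / p(incon) else NA_real_
  i2 <- qnorm(adj(p(con), N(con))) - qnorm(adj(p(incon), N(incon)))
  list(index1 = i1, index2 = i2)
}

## fixed-grid Simpson quadrature of the directional JZS marginal likelihood,
## integrating the Cauchy prior explicitly on the effect-size axis
oracle_jzs_bf01 <- function(t, n, scale = 0.707, alternative = "greater",
                            upper = 60, n_points = 40001) {
  tt <- if (alternative == "less") -t else t
  d <- seq(0, upper, length.out = n_points)
  h <- d[2] - d[1]
  f <- suppressWarnings(dt(tt, n - 1, ncp = d * sqrt(n))) * 2 * dcauchy(d, 0, scale)
  wts <- c(1, rep(c(4, 2), length.out = n_points - 2), 1)
  marg <- sum(wts * f) * h / 3
  dt(tt, n - 1) / marg
}

## Pearson-correlation Bayes factor oracle: Euler-integral hypergeometric
## (independent of the package's series implementation) + Simpson over rho
oracle_hyp2f1_euler <- function(a, b, cc, z) {
  gamma(cc) / (gamma(b) * gamma(cc - b)) *
    integrate(function(u) u^(b - 1) * (1 - u)^(cc - b - 1) * (1 - z * u)^(-a),
              0, 1, rel.tol = 1e-10)$value
}

oracle_pearson_bf01 <- function(r, n, width = 1, n_points = 2001) {
  lik <- function(rho)
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
    oracle_hyp2f1_euler(0.5, 0.5, n - 0.5, (rho * r + 1) / 2) /
    oracle_hyp2f1_euler(0.5, 0.5, n - 0.5, 0.5)
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_points)
  h <- rho[2] - rho[1]
  f <- vapply(rho, function(p) lik(p) * dbeta((p + 1) / 2, 1 / width, 1 / width) / 2, 0)
  wts <- c(1, rep(c(4, 2), length.out = n_points - 2), 1)
  1 / (sum(wts * f) * h / 3)
}

## expected categorization probabilities under the bias construction,
## recomputed independently of the package
oracle_context_probs <- function(base, face, context, kappa) {
  p <- base
  if (context != face) {
    frac <- if (context %in% c("disgust", "anger")) kappa else kappa / 2
    p[face] <- base[face] - frac * base[face]
    p[context] <- base[context] + frac * base[face]
  }
  p
}
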