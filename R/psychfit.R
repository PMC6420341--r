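#' Binned 2AFC responses
#'
#' Aggregated responses of one test session: for each morph level, the number
#' of trials shown and the number of target ("anger") responses. Duplicate
#' levels are merged and levels sorted increasingly on construction.
#'
#' @param level morph levels in `[0, 1]` (or the session's stimulus range).
#' @param n_trials trials presented per level (non-negative integers).
#' @param n_target target responses per level; `n_target <= n_trials`.
#' @return a `binned_responses` data frame with columns
#'   `level`, `n_trials`, `n_target`.
#' @seealso [bin_trials()] to aggregate trial-level records.
#' @export
binned_responses <- function(level, n_trials, n_target) {
  if (length(level) != length(n_trials) || length(level) != length(n_target))
    stop("'level', 'n_trials' and 'n_target' must have equal length", call. = FALSE)
  if (any(!is.finite(level))) stop("non-finite morph levels", call. = FALSE)
  if (any(n_trials < 0) || any(n_trials != round(n_trials)))
    stop("'n_trials' must be non-negative integers", call. = FALSE)
  if (any(n_target < 0) || any(n_target != round(n_target)))
    stop("'n_target' must be non-negative integers", call. = FALSE)
  if (any(n_target > n_trials))
    stop("'n_target' exceeds 'n_trials' at some level", call. = FALSE)
  d <- aggregate(cbind(n_trials, n_target) ~ level,
                 data = data.frame(level, n_trials, n_target), FUN = sum)
  d <- d[order(d$level), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("binned_responses", "data.frame")
  d
}

#' Aggregate trial-level 2AFC responses into binned counts
#'
#' @param stimulus_level per-trial morph levels.
#' @param response per-trial binary responses (1 = target/"anger", 0 = other).
#' @return a [binned_responses()] object.
#' @export
bin_trials <- function(stimulus_level, response) {
  if (!all(response %in% c(0, 1)))
    stop("'response' must be binary 0/1", call. = FALSE)
  binned_responses(stimulus_level, rep(1L, length(stimulus_level)),
                   as.integer(response))
}

#' Read / write binned-response CSV
#'
#' The dialect is `level,n_trials,n_target` with a header row, UTF-8 and '.'
#' as decimal mark.
#'
#' @param path file path.
#' @return `read_binned_csv` returns a [binned_responses()] object.
#' @export
read_binned_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "n_trials", "n_target")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("binned-response CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  binned_responses(d$level, d$n_trials, d$n_target)
}

#' @rdname read_binned_csv
#' @param data a [binned_responses()] object (or compatible data frame).
#' @export
write_binned_csv <- function(data, path) {
  write.csv(as.data.frame(data)[c("level", "n_trials", "n_target")],
            path, row.names = FALSE)
  invisible(path)
}

## binomial log-likelihood pieces with 0*log(0) := 0
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

loglik_saturated <- function(n, k) {
  p <- ifelse(n > 0, k / n, 0)
  sum(xlogy(k, p) + xlogy(n - k, 1 - p))
}

## negative binomial log-likelihood of a cumulative-Gaussian fit,
## parameterised as (alpha, log sigma); probabilities clamped for stability
nll_cg <- function(par, level, n, k, guess, lapse) {
  p <- guess + (1 - guess - lapse) * pnorm((level - par[1]) / exp(par[2]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

## coarse-grid log-likelihood scan; returns best (alpha, log sigma) start.
## PR/logs may be precomputed (bootstrap hot path).
grid_start <- function(level, n, k, grid) {
  ll <- as.vector(k %*% grid$logp + (n - k) %*% grid$log1mp)
  c(grid$alpha[which.max(ll)], grid$logsig[which.max(ll)])
}

make_fit_grid <- function(level, guess, lapse, alpha_bounds, sigma_bounds,
                          n_alpha = 10L, n_sigma = 10L) {
  a <- seq(alpha_bounds[1], alpha_bounds[2], length.out = n_alpha)
  ls <- seq(log(sigma_bounds[1]), log(sigma_bounds[2]), length.out = n_sigma)
  g <- expand.grid(alpha = a, logsig = ls)
  p <- vapply(seq_len(nrow(g)), function(i)
    guess + (1 - guess - lapse) * pnorm((level - g$alpha[i]) / exp(g$logsig[i])),
    numeric(length(level)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(alpha = g$alpha, logsig = g$logsig, logp = log(p), log1mp = log1p(-p))
}

## core fitter shared by psychfit() and the bootstrap; no user-facing checks
fit_cg_core <- function(level, n, k, guess, lapse, alpha_bounds, sigma_bounds,
                        grid = NULL) {
  if (is.null(grid))
    grid <- make_fit_grid(level, guess, lapse, alpha_bounds, sigma_bounds)
  start <- grid_start(level, n, k, grid)
  o <- optim(start, nll_cg, level = level, n = n, k = k,
             guess = guess, lapse = lapse, method = "L-BFGS-B",
             lower = c(alpha_bounds[1], log(sigma_bounds[1])),
             upper = c(alpha_bounds[2], log(sigma_bounds[2])))
  eps <- 1e-6
  at_bound <- o$par[1] <= alpha_bounds[1] + eps | o$par[1] >= alpha_bounds[2] - eps |
    o$par[2] <= log(sigma_bounds[1]) + eps | o$par[2] >= log(sigma_bounds[2]) - eps
  loglik <- -o$value
  dev <- 2 * (loglik_saturated(n, k) - loglik)
  if (dev < 0 && dev > -1e-9) dev <- 0
  list(pse = o$par[1], sigma = exp(o$par[2]), loglik = loglik,
       deviance = dev, converged = o$convergence == 0 && !at_bound)
}

#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Estimates the PSE (`pse`, the model's alpha) and spread (`sigma`; the
#' reported slope is `1/sigma`) of a cumulative-Gaussian psychometric function
#' from binned 2AFC responses, with the guess and lapse rates held fixed
#' (the study convention is guess 0, lapse 0.03). The binomial log-likelihood
#' is maximised by a bounded quasi-Newton search over `(pse, log sigma)`
#' started from the best point of a coarse 10 x 10 grid, which makes the fit
#' deterministic given the data. Deviance is reported against the saturated
#' model (observed per-level proportions).
#'
#' Bounds allow PSEs slightly outside the morph range without unbounded
#' drift; an optimum on a bound is flagged `converged = FALSE` with a
#' warning.
#'
#' @param data a [binned_responses()] object, a data frame with columns
#'   `level`, `n_trials`, `n_target`, or a path handled by
#'   [read_binned_csv()] is read first by the caller.
#' @param guess fixed guess rate (lower asymptote).
#' @param lapse fixed lapse rate (upper-asymptote miss rate).
#' @param alpha_bounds search interval for the PSE.
#' @param sigma_bounds search interval for the spread.
#' @return an object of class `"psychfit"` with components `coefficients`
#'   (`pse`, `sigma`), `guess`, `lapse`, `loglik`, `deviance`, `converged`,
#'   `gof_p` (`NA` until [gof_bootstrap()] is run), `excluded`, and `data`.
#' @examples
#' d <- binned_responses(seq(0.2, 0.8, length.out = 7),
#'                       rep(20, 7), c(0, 2, 6, 10, 15, 18, 19))
#' fit <- psychfit(d)
#' coef(fit)
#' @export
psychfit <- function(data, guess = 0, lapse = 0.03,
                     alpha_bounds = c(-0.5, 1.5), sigma_bounds = c(0.01, 1)) {
  check_psych_params(0.5, 1, guess, lapse)
  if (!inherits(data, "binned_responses"))
    data <- binned_responses(data$level, data$n_trials, data$n_target)
  d <- data[data$n_trials > 0, , drop = FALSE]
  if (nrow(d) < 2)
    stop("need at least 2 distinct morph levels with trials to fit", call. = FALSE)
  if (sum(d$n_target) == 0 || sum(d$n_target) == sum(d$n_trials))
    stop("non-identifiable data: all responses are identical (",
         if (sum(d$n_target) == 0) "no" else "only", " target responses)",
         call. = FALSE)
  if (sum(d$n_trials) < 20)
    warning("fewer than 20 trials in total; estimates will be unstable")
  f <- fit_cg_core(d$level, d$n_trials, d$n_target, guess, lapse,
                   alpha_bounds, sigma_bounds)
  if (!f$converged)
    warning("optimizer stopped on a parameter bound; fit flagged as not converged")
  structure(list(coefficients = c(pse = f$pse, sigma = f$sigma),
                 guess = guess, lapse = lapse,
                 loglik = f$loglik, deviance = f$deviance,
                 converged = f$converged, gof_p = NA_real_, excluded = NA,
                 data = data, alpha_bounds = alpha_bounds,
                 sigma_bounds = sigma_bounds),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit\n")
  cat(sprintf("  PSE %.4f, sigma %.4f (slope %.2f), guess %g, lapse %g\n",
              x$coefficients["pse"], x$coefficients["sigma"],
              1 / x$coefficients["sigma"], x$guess, x$lapse))
  cat(sprintf("  logLik %.3f, deviance %.3f%s\n", x$loglik, x$deviance,
              if (!x$converged) " [not converged]" else ""))
  if (!is.na(x$gof_p))
    cat(sprintf("  goodness of fit: p = %.4f%s\n", x$gof_p,
                if (isTRUE(x$excluded)) " -> excluded" else ""))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object, slope = 1 / object$coefficients["sigma"],
              n_levels = nrow(object$data),
              n_trials = sum(object$data$n_trials),
              max_abs_dev_resid = max(abs(res)))
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d levels, %d trials; max |deviance residual| %.3f\n",
              x$n_levels, x$n_trials, x$max_abs_dev_resid))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' @export
deviance.psychfit <- function(object, ...) object$deviance

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$level
  else if (is.numeric(newdata)) newdata
  else newdata$level
  psych_prob(x, object$coefficients["pse"], object$coefficients["sigma"],
             object$guess, object$lapse)
}

#' @export
residuals.psychfit <- function(object, ...) {
  d <- object$data
  p <- predict(object)
  li <- xlogy(d$n_target, ifelse(d$n_trials > 0, d$n_target / d$n_trials, 0)) +
    xlogy(d$n_trials - d$n_target,
          ifelse(d$n_trials > 0, 1 - d$n_target / d$n_trials, 0)) -
    (d$n_target * log(pmax(p, 1e-12)) +
       (d$n_trials - d$n_target) * log(pmax(1 - p, 1e-12)))
  sign(d$n_target / pmax(d$n_trials, 1) - p) * sqrt(pmax(2 * li, 0))
}

#' Simulate response counts from a fitted psychometric function
#'
#' Parametric simulation at the observed stimulus placements: each replicate
#' draws binomial target counts at the fitted probabilities with the observed
#' per-level trial numbers.
#'
#' @param object a [psychfit()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @param ... unused.
#' @return data frame with the levels and one `sim_*` count column per
#'   replicate.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  p <- predict(object)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) rbinom(nrow(d), d$n_trials, p),
           integer(nrow(d)))
  })
  out <- data.frame(level = d$level, n_trials = d$n_trials)
  sims <- matrix(sims, nrow = nrow(d))
  colnames(sims) <- paste0("sim_", seq_len(nsim))
  cbind(out, as.data.frame(sims))
}

#' Plot a psychometric fit
#'
#' Observed proportions (point size proportional to the number of trials, as
#' in the usual adaptation-study figures) with the fitted curve and the PSE
#' marked.
#'
#' @param x a [psychfit()] object.
#' @param ... passed to [plot.default()].
#' @export
plot.psychfit <- function(x, ...) {
  d <- x$data
  prop <- ifelse(d$n_trials > 0, d$n_target / d$n_trials, NA)
  xx <- seq(min(d$level), max(d$level), length.out = 200)
  plot.default(d$level, prop, ylim = c(0, 1),
               xlab = "morph level (0 = disgust, 1 = anger)",
               ylab = "P(respond anger)",
               cex = 0.6 + 1.6 * sqrt(d$n_trials / max(d$n_trials)), ...)
  lines(xx, predict(x, xx))
  abline(v = x$coefficients["pse"], lty = 2)
  abline(h = x$guess + (1 - x$guess - x$lapse) / 2, lty = 3)
  invisible(x)
}

#' Parametric-bootstrap goodness of fit of a psychometric fit
#'
#' Simulates `n_sim` datasets from the fitted function at the observed
#' stimulus placements, refits each, and compares the observed deviance with
#' the simulated deviance distribution. The p value uses the smoothed
#' estimator `p = (1 + #\{D_sim >= D_obs\}) / (n_kept + 1)` so it can never be
#' exactly zero. Fits with `p < 0.05` are flagged for exclusion (deviance too
#' large to be acceptable). Replicates whose refit fails (e.g. a simulated
#' dataset with all-identical responses) are dropped and counted; more than
#' 10% failures raises an error.
#'
#' @param object a converged [psychfit()] object.
#' @param n_sim number of simulations (the study convention is 400).
#' @param seed optional integer seed for bit-exact reproducibility.
#' @return `object` with `gof_p` and `excluded` filled in and an attribute
#'   `"gof"` holding `d_obs`, the simulated deviances and the failure count.
#' @export
gof_bootstrap <- function(object, n_sim = 400, seed = NULL) {
  stopifnot(inherits(object, "psychfit"))
  if (!object$converged)
    stop("goodness of fit requires a converged fit", call. = FALSE)
  if (n_sim < 1) stop("'n_sim' must be >= 1", call. = FALSE)
  d <- object$data[object$data$n_trials > 0, , drop = FALSE]
  p <- psych_prob(d$level, object$coefficients["pse"], object$coefficients["sigma"],
                  object$guess, object$lapse)
  grid <- make_fit_grid(d$level, object$guess, object$lapse,
                        object$alpha_bounds, object$sigma_bounds)
  K <- with_seed(seed, {
    matrix(rbinom(n_sim * nrow(d), rep(d$n_trials, each = n_sim),
                  rep(p, each = n_sim)), nrow = n_sim)
  })
  d_sim <- rep(NA_real_, n_sim)
  for (i in seq_len(n_sim)) {
    ki <- K[i, ]
    if (sum(ki) == 0 || sum(ki) == sum(d$n_trials)) next  # degenerate replicate
    f <- tryCatch(fit_cg_core(d$level, d$n_trials, ki, object$guess,
                              object$lapse, object$alpha_bounds,
                              object$sigma_bounds, grid = grid),
                  error = function(e) NULL)
    if (!is.null(f)) d_sim[i] <- f$deviance
  }
  n_failed <- sum(is.na(d_sim))
  if (n_failed > 0.1 * n_sim)
    stop(sprintf("goodness-of-fit bootstrap: %d of %d refits failed",
                 n_failed, n_sim), call. = FALSE)
  d_sim <- d_sim[!is.na(d_sim)]
  pval <- (1 + sum(d_sim >= object$deviance)) / (length(d_sim) + 1)
  object$gof_p <- pval
  object$excluded <- pval < 0.05
  attr(object, "gof") <- list(d_obs = object$deviance, d_sim = d_sim,
                              n_failed = n_failed)
  object
}

#' Adaptation aftereffect: PSE difference from baseline
#'
#' The aftereffect of an adapted condition is the difference score
#' `pse_baseline - pse_adapted` on the morph axis 0 = fully disgusted,
#' 1 = fully angry. Positive values indicate adaptation to disgust (ambiguous
#' targets perceived as more angry); negative values indicate adaptation to
#' anger. Fitted objects that failed the goodness-of-fit screen are refused.
#'
#' @param baseline baseline PSE: a number or a (non-excluded) [psychfit()].
#' @param adapted adapted PSE(s): numeric vector (possibly named by
#'   condition), a [psychfit()], or a list of them.
#' @return named numeric vector of signed aftereffects, in morph units.
#' @examples
#' aftereffect(0.50, c(disgust_context = 0.42, anger_context = 0.44))
#' @export
aftereffect <- function(baseline, adapted) {
  pse_of <- function(f, what) {
    if (inherits(f, "psychfit")) {
      if (isTRUE(f$excluded))
        stop(what, " fit was excluded by the goodness-of-fit screen (p = ",
             format(f$gof_p, digits = 3), ")", call. = FALSE)
      unname(f$coefficients["pse"])
    } else as.numeric(f)
  }
  b <- pse_of(baseline, "baseline")
  a <- if (inherits(adapted, "psychfit")) pse_of(adapted, "adapted")
  else if (is.list(adapted))
    vapply(adapted, pse_of, 0, what = "adapted")
  else adapted
  b - a
}

#' Serialize a psychometric fit to JSON
#'
#' Keys follow the interchange convention `alpha, sigma, gamma, lam, loglik,
#' deviance, gof_p, converged, excluded`.
#'
#' @param fit a [psychfit()] object.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "psychfit"))
  x <- list(alpha = unname(fit$coefficients["pse"]),
            sigma = unname(fit$coefficients["sigma"]),
            gamma = fit$guess, lam = fit$lapse,
            loglik = fit$loglik, deviance = fit$deviance,
            gof_p = if (is.na(fit$gof_p)) NULL else fit$gof_p,
            converged = fit$converged,
            excluded = if (is.na(fit$excluded)) NULL else fit$excluded)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
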