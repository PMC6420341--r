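#' Initialize the Psi adaptive procedure
#'
#' The Psi method places every test trial at the candidate morph level that
#' minimises the expected Shannon entropy of the posterior over a discrete
#' (PSE, sigma) parameter grid. The default grid covers PSEs on the full
#' morph axis and spreads on a log scale, with a uniform prior and fresh
#' state per session.
#'
#' @param alpha_grid PSE grid (morph units).
#' @param sigma_grid spread grid (morph units, > 0).
#' @param candidates candidate stimulus levels in `[0, 1]`.
#' @param guess,lapse fixed asymptote parameters of the 2AFC likelihood; the
#'   study convention (two response labels, no forced guessing asymmetry) is
#'   `guess = 0`, `lapse = 0.03`.
#' @param prior optional prior weights over the grid, in `alpha`-fastest
#'   order (length `length(alpha_grid) * length(sigma_grid)`); uniform if
#'   omitted. Weights must be non-negative and not all zero.
#' @return an object of class `"psi_state"`: the expanded grid (`alpha`,
#'   `sigma`), normalized `posterior`, `candidates`, cached per-candidate
#'   response likelihoods, and an empty trial `history`.
#' @export
psi_init <- function(alpha_grid = seq(0, 1, length.out = 41),
                     sigma_grid = exp(seq(log(0.02), log(0.5), length.out = 21)),
                     candidates = seq(0, 1, length.out = 41),
                     guess = 0, lapse = 0.03, prior = NULL) {
  if (length(alpha_grid) < 1 || length(sigma_grid) < 1 || length(candidates) < 1)
    stop("empty parameter grid or candidate set", call. = FALSE)
  if (any(sigma_grid <= 0)) stop("'sigma_grid' must be positive", call. = FALSE)
  if (any(candidates < 0 | candidates > 1))
    stop("'candidates' must lie in [0, 1]", call. = FALSE)
  check_psych_params(0.5, 1, guess, lapse)
  candidates <- sort(candidates)
  g <- expand.grid(alpha = alpha_grid, sigma = sigma_grid)
  G <- nrow(g)
  if (is.null(prior)) prior <- rep(1, G)
  if (length(prior) != G)
    stop("'prior' must have one weight per (alpha, sigma) pair", call. = FALSE)
  if (any(prior < 0) || sum(prior) <= 0)
    stop("'prior' must be non-negative and not all zero", call. = FALSE)
  lik <- psi_likelihoods(g$alpha, g$sigma, candidates, guess, lapse)
  structure(list(alpha = g$alpha, sigma = g$sigma,
                 alpha_grid = alpha_grid, sigma_grid = sigma_grid,
                 posterior = prior / sum(prior),
                 candidates = candidates, guess = guess, lapse = lapse,
                 lik = lik,
                 history = data.frame(x = numeric(0), response = integer(0))),
            class = "psi_state")
}

## per-candidate target-response probabilities on the grid, plus the cached
## products needed by the entropy computation (clamped away from 0/1 so the
## posterior can never collapse to all-zero weights)
psi_likelihoods <- function(alpha, sigma, candidates, guess, lapse) {
  P <- vapply(candidates, function(x)
    guess + (1 - guess - lapse) * pnorm((x - alpha) / sigma),
    numeric(length(alpha)))
  P <- matrix(pmin(pmax(P, 1e-12), 1 - 1e-12), nrow = length(alpha))
  list(P = P, PlogP = P * log(P), Q = 1 - P, QlogQ = (1 - P) * log1p(-P))
}

#' @export
print.psi_state <- function(x, ...) {
  est <- psi_estimate_quiet(x)
  cat(sprintf(paste0("Psi adaptive state: %d x %d grid, %d candidates, ",
                     "%d trials\n  posterior mean: PSE %.4f, sigma %.4f\n"),
              length(x$alpha_grid), length(x$sigma_grid),
              length(x$candidates), nrow(x$history), est[1], est[2]))
  invisible(x)
}

#' Expected posterior entropy per candidate level
#'
#' For each candidate stimulus `x`, the expectation over the two responses of
#' the Shannon entropy (natural log) of the correspondingly updated
#' posterior: `E[H](x) = sum_r p(r|x) H(posterior | x, r)` with
#' `p(r|x) = sum_par p(r|x, par) posterior(par)`.
#'
#' @param state a [psi_init()] state.
#' @return numeric vector of expected entropies, one per candidate.
#' @export
psi_expected_entropy <- function(state) {
  w <- state$posterior
  wlw <- ifelse(w > 0, w * log(w), 0)
  s1 <- as.vector(crossprod(state$lik$P, w))
  t1 <- as.vector(crossprod(state$lik$P, wlw)) +
    as.vector(crossprod(state$lik$PlogP, w))
  s0 <- as.vector(crossprod(state$lik$Q, w))
  t0 <- as.vector(crossprod(state$lik$Q, wlw)) +
    as.vector(crossprod(state$lik$QlogQ, w))
  ## H(normalized w * lik) = log s - (1/s) * sum(w lik log(w lik))
  s1 * (log(s1) - t1 / s1) + s0 * (log(s0) - t0 / s0)
}

#' Select the next stimulus level (Psi rule)
#'
#' Returns the candidate morph level minimising the expected posterior
#' entropy; ties are broken toward the lowest candidate, so the rule is
#' deterministic.
#'
#' @param state a [psi_init()] state.
#' @return a morph level from `state$candidates`.
#' @export
psi_select <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  eh <- psi_expected_entropy(state)
  state$candidates[which.min(round(eh, 12))]
}

#' Bayesian posterior update after one trial
#'
#' Multiplies the posterior by the response likelihood at the presented level
#' and renormalizes; the trial is appended to the state's history. Weights
#' are floored at `1e-300` against numerical underflow.
#'
#' @param state a [psi_init()] state.
#' @param x presented morph level (a warning is given if it is not one of
#'   the candidate levels).
#' @param response observed binary response (1 = target/"anger").
#' @return the updated `psi_state`.
#' @export
psi_update <- function(state, x, response) {
  stopifnot(inherits(state, "psi_state"))
  if (!response %in% c(0L, 1L)) stop("'response' must be 0 or 1", call. = FALSE)
  if (min(abs(state$candidates - x)) > 1e-9)
    warning("presented level is not in the candidate set")
  p1 <- psych_prob(x, state$alpha, state$sigma, state$guess, state$lapse)
  p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  w <- state$posterior * (if (response == 1) p1 else 1 - p1)
  w <- pmax(w, 1e-300)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("posterior underflow during Psi update", call. = FALSE)
  state$posterior <- w / tot
  state$history <- rbind(state$history,
                         data.frame(x = x, response = as.integer(response)))
  state
}

#' Posterior-mean parameter estimates
#'
#' Marginal posterior means of the PSE and spread. A warning is given when no
#' update has been applied yet (the estimate is then just the prior mean).
#'
#' @param state a [psi_init()] state.
#' @return named numeric vector `c(alpha = , sigma = )`.
#' @export
psi_estimate <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  if (nrow(state$history) == 0)
    warning("no trials observed yet; returning the prior mean")
  psi_estimate_quiet(state)
}

psi_estimate_quiet <- function(state)
  c(alpha = sum(state$posterior * state$alpha),
    sigma = sum(state$posterior * state$sigma))

#' Run a full Psi session against a response source
#'
#' Convenience loop: select, present, update, `n_trials` times. The response
#' source is either a function of the stimulus level returning 0/1, or a
#' vector of pre-drawn uniforms combined with a true psychometric function
#' (used by the synthetic-observer generator so that single and batched runs
#' are trial-for-trial identical).
#'
#' @param state a [psi_init()] state.
#' @param n_trials number of test trials (the study protocol uses 144).
#' @param respond function `(x) -> 0/1` giving the observer's response.
#' @return list with the final `state` and a `trace` data frame (one row per
#'   trial: `trial, stimulus_level, response, alpha_hat, sigma_hat,
#'   posterior_entropy`).
#' @export
psi_run <- function(state, n_trials, respond) {
  stopifnot(inherits(state, "psi_state"), is.function(respond))
  tr <- data.frame(trial = seq_len(n_trials), stimulus_level = NA_real_,
                   response = NA_integer_, alpha_hat = NA_real_,
                   sigma_hat = NA_real_, posterior_entropy = NA_real_)
  for (i in seq_len(n_trials)) {
    x <- psi_select(state)
    r <- respond(x)
    state <- psi_update(state, x, r)
    est <- psi_estimate_quiet(state)
    w <- state$posterior
    tr$stimulus_level[i] <- x
    tr$response[i] <- as.integer(r)
    tr$alpha_hat[i] <- est[1]
    tr$sigma_hat[i] <- est[2]
    tr$posterior_entropy[i] <- -sum(ifelse(w > 0, w * log(w), 0))
  }
  list(state = state, trace = tr)
}

#' Write a Psi trial trace to CSV
#'
#' One row per trial: `trial,stimulus_level,response,alpha_hat,sigma_hat,
#' posterior_entropy`.
#'
#' @param trace the `trace` component of [psi_run()].
#' @param path output file.
#' @export
write_psi_trace <- function(trace, path) {
  write.csv(trace[c("trial", "stimulus_level", "response", "alpha_hat",
                    "sigma_hat", "posterior_entropy")], path, row.names = FALSE)
  invisible(path)
}

## ---- batched Psi engine (internal) -----------------------------------------
## Same computation as psi_select/psi_update but with one posterior column per
## concurrently simulated session, sharing the likelihood cache. Responses
## come from pre-drawn uniforms (one column per session) compared against the
## session's true psychometric function, so results are identical to running
## psi_run() per session with the same uniform stream.

psi_engine <- function(alpha_grid = seq(0, 1, length.out = 41),
                       sigma_grid = exp(seq(log(0.02), log(0.5), length.out = 21)),
                       candidates = seq(0, 1, length.out = 41),
                       guess = 0, lapse = 0.03) {
  candidates <- sort(candidates)
  g <- expand.grid(alpha = alpha_grid, sigma = sigma_grid)
  c(list(alpha = g$alpha, sigma = g$sigma, candidates = candidates,
         guess = guess, lapse = lapse),
    psi_likelihoods(g$alpha, g$sigma, candidates, guess, lapse))
}

## U: n_trials x m uniforms; true_alpha, true_sigma, true_guess, true_lapse:
## per-session generative parameters (length m, recycled)
psi_run_batch <- function(engine, U, true_alpha, true_sigma,
                          true_guess = 0, true_lapse = 0.03,
                          track_cell = NULL) {
  n <- nrow(U); m <- ncol(U)
  true_alpha <- rep_len(true_alpha, m); true_sigma <- rep_len(true_sigma, m)
  true_guess <- rep_len(true_guess, m); true_lapse <- rep_len(true_lapse, m)
  G <- length(engine$alpha)
  W <- matrix(1 / G, G, m)
  X <- matrix(NA_real_, n, m); R <- matrix(NA_integer_, n, m)
  tracked <- if (!is.null(track_cell)) matrix(NA_real_, n, m)
  for (t in seq_len(n)) {
    LW <- W * log(pmax(W, 1e-300))
    S1 <- crossprod(engine$P, W)
    T1 <- crossprod(engine$P, LW) + crossprod(engine$PlogP, W)
    S0 <- crossprod(engine$Q, W)
    T0 <- crossprod(engine$Q, LW) + crossprod(engine$QlogQ, W)
    EH <- S1 * (log(S1) - T1 / S1) + S0 * (log(S0) - T0 / S0)
    j <- max.col(t(-round(EH, 12)), ties.method = "first")
    x <- engine$candidates[j]
    p <- true_guess + (1 - true_guess - true_lapse) *
      pnorm((x - true_alpha) / true_sigma)
    r <- as.integer(U[t, ] < p)
    L <- engine$P[, j, drop = FALSE]
    if (any(r == 0L)) L[, r == 0L] <- engine$Q[, j[r == 0L], drop = FALSE]
    W <- pmax(W * L, 1e-300)
    W <- sweep(W, 2, colSums(W), "/")
    X[t, ] <- x; R[t, ] <- r
    if (!is.null(track_cell)) tracked[t, ] <- W[track_cell, ]
  }
  list(X = X, R = R,
       alpha_hat = as.vector(crossprod(W, engine$alpha)),
       sigma_hat = as.vector(crossprod(W, engine$sigma)),
       posterior = W, tracked = tracked)
}
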