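#' Cumulative-Gaussian psychometric function
#'
#' Probability of the target response ("anger") at morph level `x` under a
#' cumulative-Gaussian psychometric function with guess and lapse rates:
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda)\,\Phi((x - \alpha)/\sigma)}
#' where `pse` is the point of subjective equality (alpha), `sigma` the
#' Gaussian spread in morph units (reported slope is `1/sigma`), `guess` the
#' lower asymptote (gamma) and `lapse` the upper-asymptote miss rate (lambda).
#'
#' @param x morph level(s); the conventional axis is 0 = fully disgusted,
#'   1 = fully angry.
#' @param pse point of subjective equality (morph units).
#' @param sigma spread of the underlying Gaussian (morph units, > 0).
#' @param guess guess rate in `[0, 1)`.
#' @param lapse lapse rate in `[0, 1)`; `guess + lapse` must be < 1.
#' @return numeric vector of response probabilities in `[guess, 1 - lapse]`.
#' @examples
#' psych_prob(0.5, pse = 0.5, sigma = 0.1, lapse = 0.03) # midpoint: 0.485
#' psych_prob(0.6, pse = 0.5, sigma = 0.1, lapse = 0.03) # 0.97 * pnorm(1)
#' @export
psych_prob <- function(x, pse, sigma, guess = 0, lapse = 0) {
  check_psych_params(pse, sigma, guess, lapse)
  guess + (1 - guess - lapse) * pnorm((x - pse) / sigma)
}

check_psych_params <- function(pse, sigma, guess, lapse) {
  if (!all(is.finite(pse)))
    stop("invalid psychometric parameters: 'pse' must be finite", call. = FALSE)
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("invalid psychometric parameters: 'sigma' must be > 0", call. = FALSE)
  if (any(guess < 0) || any(guess >= 1) || any(lapse < 0) || any(lapse >= 1) ||
      any(guess + lapse >= 1))
    stop("invalid psychometric parameters: need 0 <= guess, lapse and guess + lapse < 1",
         call. = FALSE)
  invisible(TRUE)
}
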