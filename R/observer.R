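#' A synthetic observer with known ground truth
#'
#' Generative model of one observer in the face-body paradigm: a true
#' cumulative-Gaussian psychometric function (`pse`, `sigma`, fixed `guess`
#' and `lapse`), an adaptation shift magnitude `delta` (morph units, the PSE
#' displacement a fully effective adaptor produces), a body-context bias
#' strength `kappa` in `[0, 1]` (the fraction of face-emotion categorization
#' probability mass an incongruent body captures), congruent-context
#' `base_rates` over the four response labels, and the integration
#' `hypothesis`:
#'
#' * `"late"`: face and body merge after the adapted stage, so the adaptation
#'   shift follows the physical facial expression regardless of context
#'   (`delta_eff = delta`).
#' * `"early"`: the adapted stage sees the context-biased percept; the shift
#'   is weighted by the percept balance, `delta_eff = delta * (2q - 1)` with
#'   `q` the probability that the adaptor face is categorized as its physical
#'   emotion in that context, so a full perceptual reversal (`q = 0`) gives
#'   an equal-magnitude opposite aftereffect.
#'
#' Body-only adaptors (`adaptor_face = "none"`) produce no shift under either
#' hypothesis.
#'
#' @param pse unadapted PSE (morph units).
#' @param sigma psychometric spread (> 0).
#' @param lapse,guess fixed asymptote rates.
#' @param delta adaptation shift magnitude (morph units, toward the adaptor's
#'   expression).
#' @param kappa context bias strength in `[0, 1]`.
#' @param face_emotion the physical facial expression used in the study.
#' @param base_rates named probabilities of the `disgust, anger, fear, sad`
#'   responses to the face in a congruent context; must sum to 1. Default:
#'   0.90 on the correct label.
#' @param hypothesis `"late"` or `"early"`.
#' @param seed integer seed for this observer's response streams.
#' @return object of class `"observer_model"`.
#' @export
observer_model <- function(pse = 0.5, sigma = 0.12, lapse = 0.03, guess = 0,
                           delta = 0.08, kappa = 1,
                           face_emotion = c("disgust", "anger"),
                           base_rates = NULL,
                           hypothesis = c("late", "early"), seed = 1L) {
  face_emotion <- match.arg(face_emotion)
  hypothesis <- match.arg(hypothesis)
  check_psych_params(pse, sigma, guess, lapse)
  if (kappa < 0 || kappa > 1) stop("'kappa' must be in [0, 1]", call. = FALSE)
  if (!is.finite(delta)) stop("'delta' must be finite", call. = FALSE)
  if (is.null(base_rates)) {
    base_rates <- c(disgust = 0.04, anger = 0.04, fear = 0.03, sad = 0.03)
    base_rates[face_emotion] <- 0.90
  }
  cats <- c("disgust", "anger", "fear", "sad")
  if (!setequal(names(base_rates), cats))
    stop("'base_rates' must be named disgust/anger/fear/sad", call. = FALSE)
  base_rates <- base_rates[cats]
  if (abs(sum(base_rates) - 1) > 1e-8 || any(base_rates < 0))
    stop("'base_rates' must be non-negative and sum to 1", call. = FALSE)
  structure(list(pse = pse, sigma = sigma, lapse = lapse, guess = guess,
                 delta = delta, kappa = kappa, face_emotion = face_emotion,
                 base_rates = base_rates, hypothesis = hypothesis,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(paste0("Synthetic observer (%s integration): PSE %.3f, sigma %.3f,",
                     " delta %.3f, kappa %.2f, %s face\n"),
              x$hypothesis, x$pse, x$sigma, x$delta, x$kappa, x$face_emotion))
  invisible(x)
}

## response-probability construction: an incongruent disgust/anger body
## captures a fraction kappa of the face-emotion mass; fear/sad bodies
## capture kappa/2 (weaker off-pair effects)
categorization_probs <- function(obs, context) {
  p <- obs$base_rates
  face <- obs$face_emotion
  if (!context %in% c("disgust", "anger", "fear", "sad"))
    stop("invalid context label '", context, "'", call. = FALSE)
  if (context != face) {
    frac <- if (context == other_of_pair(face)) obs$kappa else obs$kappa / 2
    shift <- frac * p[[face]]
    p[[face]] <- p[[face]] - shift
    p[[context]] <- p[[context]] + shift
  }
  p
}

#' Simulate 4-alternative categorization responses
#'
#' Draws multinomial response counts for one observer and body context under
#' the bias construction of [observer_model()] (deterministic for a given
#' observer seed and context).
#'
#' @param obs an [observer_model()].
#' @param context body context: disgust, anger, fear or sad.
#' @param n_trials number of categorization trials.
#' @return named integer counts over `disgust, anger, fear, sad,
#'   no_response` (the generator never produces no-responses; the column is
#'   kept for schema compatibility with real data).
#' @export
simulate_categorization <- function(obs, context, n_trials) {
  stopifnot(inherits(obs, "observer_model"))
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  p <- categorization_probs(obs, context)
  stream <- match(context, c("disgust", "anger", "fear", "sad"))
  k <- with_seed(substream_seed(obs$seed, 0L, stream),
                 rmultinom(1, n_trials, p)[, 1])
  c(k, no_response = 0L)
}

## effective PSE displacement of the adapted session; sign convention:
## adaptation to disgust raises P("anger"|x), i.e. lowers the PSE, giving a
## positive aftereffect (baseline - adapted)
effective_shift <- function(obs, adaptor_face, adaptor_context) {
  if (adaptor_face == "none") return(0)
  if (adaptor_face != obs$face_emotion)
    stop("the adaptor face must match the observer's study face emotion",
         call. = FALSE)
  delta_eff <- switch(obs$hypothesis,
    late = obs$delta,
    early = {
      q <- categorization_probs(obs, adaptor_context)[[adaptor_face]]
      obs$delta * (2 * q - 1)
    })
  s <- if (adaptor_face == "disgust") 1 else -1
  s * delta_eff
}

#' Simulate one Psi-driven adaptation (or baseline) test session
#'
#' Runs a fresh Psi procedure against the observer, whose responses are
#' Bernoulli draws from the true psychometric function with the session's
#' adapted PSE. Responses are generated from a pre-drawn per-session uniform
#' stream, so the session is reproducible and identical whether run singly or
#' inside a batched cohort simulation.
#'
#' @param obs an [observer_model()].
#' @param adaptor_face `"disgust"`, `"anger"`, `"none"` (body-only adaptor)
#'   or `"baseline"` (no adaptor at all).
#' @param adaptor_context body context of the adaptor: `"disgust"`,
#'   `"anger"`, or `"none"` for baseline sessions.
#' @param n_test number of Psi test trials (study protocol: 144).
#' @param stream integer distinguishing this session's response stream.
#' @param psi optional [psi_init()] state (defaults to the standard grids).
#' @return list with `trials` (data frame `trial, stimulus_level, response`),
#'   the Psi `trace`, posterior-mean `alpha_psi`/`sigma_psi`, the session's
#'   true `alpha_session` and the signed `shift` applied to the PSE.
#' @export
simulate_adaptation_session <- function(obs,
                                        adaptor_face = c("baseline", "disgust",
                                                         "anger", "none"),
                                        adaptor_context = c("none", "disgust",
                                                            "anger"),
                                        n_test = 144, stream = 10L, psi = NULL) {
  stopifnot(inherits(obs, "observer_model"))
  adaptor_face <- match.arg(adaptor_face)
  adaptor_context <- match.arg(adaptor_context)
  if (adaptor_face %in% c("disgust", "anger") && adaptor_context == "none")
    stop("face adaptors require a body context", call. = FALSE)
  shift <- if (adaptor_face == "baseline") 0
  else effective_shift(obs, adaptor_face, adaptor_context)
  alpha_session <- obs$pse - shift
  if (is.null(psi)) psi <- psi_init()
  u <- with_seed(substream_seed(obs$seed, 0L, stream), runif(n_test))
  i <- 0L
  respond <- function(x) {
    i <<- i + 1L
    as.integer(u[i] < psych_prob(x, alpha_session, obs$sigma,
                                 obs$guess, obs$lapse))
  }
  run <- psi_run(psi, n_test, respond)
  est <- psi_estimate_quiet(run$state)
  list(trials = data.frame(trial = seq_len(n_test),
                           stimulus_level = run$trace$stimulus_level,
                           response = run$trace$response),
       trace = run$trace,
       alpha_psi = unname(est["alpha"]), sigma_psi = unname(est["sigma"]),
       alpha_session = alpha_session, shift = shift)
}

#' Cohort configuration for the synthetic-data generator
#'
#' Study-level conditions: cohort size, the latent-parameter distributions
#' (truncated normals; a zero SD fixes the parameter), per-phase trial counts
#' matching the study protocol (144 test trials after 24 adaptation trials;
#' 144 baseline trials without top-up), and the adaptation conditions to run.
#'
#' @param n_observers cohort size.
#' @param face_emotion,hypothesis,lapse,guess,base_rates passed to
#'   [observer_model()].
#' @param pse_mean,pse_sd,pse_bounds unadapted-PSE distribution.
#' @param sigma_mean,sigma_sd,sigma_bounds spread distribution.
#' @param delta_mean,delta_sd,delta_bounds adaptation-shift distribution.
#' @param kappa_mean,kappa_sd context-bias distribution (bounded to `[0,1]`).
#' @param n_test,n_adapt,n_baseline per-phase trial counts.
#' @param n_categorization categorization trials per body context.
#' @param contexts body contexts of the categorization task.
#' @param conditions data frame with columns `adaptor_face`,
#'   `adaptor_context`; the default is the four-condition design (study face
#'   in both disgust/anger contexts, plus both body-only adaptors).
#' @param seed cohort master seed; per-observer substreams are derived from
#'   it by a counter scheme so partial regeneration is reproducible.
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_observers = 24,
                          face_emotion = "disgust", hypothesis = "late",
                          pse_mean = 0.5, pse_sd = 0.05, pse_bounds = c(0.2, 0.8),
                          sigma_mean = 0.12, sigma_sd = 0.03,
                          sigma_bounds = c(0.04, 0.3),
                          delta_mean = 0.08, delta_sd = 0.02,
                          delta_bounds = c(0, 0.2),
                          kappa_mean = 1, kappa_sd = 0,
                          lapse = 0.03, guess = 0, base_rates = NULL,
                          n_test = 144, n_adapt = 24, n_baseline = 144,
                          n_categorization = 48,
                          contexts = c("disgust", "anger", "fear", "sad"),
                          conditions = NULL, seed = 1L) {
  if (n_observers < 0) stop("'n_observers' must be >= 0", call. = FALSE)
  stopifnot(pse_sd >= 0, sigma_sd >= 0, delta_sd >= 0, kappa_sd >= 0,
            n_test >= 1, n_adapt >= 0, n_baseline >= 1, n_categorization >= 1)
  if (is.null(conditions))
    conditions <- data.frame(
      adaptor_face = c(face_emotion, face_emotion, "none", "none"),
      adaptor_context = c("disgust", "anger", "disgust", "anger"),
      stringsAsFactors = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

## inverse-CDF truncated-normal draws (deterministic given the RNG stream)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  lo <- pnorm((lower - mean) / sd)
  hi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, lo, hi)) * sd + mean
}

draw_observers <- function(config) {
  n <- config$n_observers
  lat <- with_seed(substream_seed(config$seed, 0L, 99L), {
    data.frame(observer_id = seq_len(n),
               pse = rtruncnorm(n, config$pse_mean, config$pse_sd,
                                config$pse_bounds[1], config$pse_bounds[2]),
               sigma = rtruncnorm(n, config$sigma_mean, config$sigma_sd,
                                  config$sigma_bounds[1], config$sigma_bounds[2]),
               delta = rtruncnorm(n, config$delta_mean, config$delta_sd,
                                  config$delta_bounds[1], config$delta_bounds[2]),
               kappa = rtruncnorm(n, config$kappa_mean, config$kappa_sd, 0, 1))
  })
  if (n == 0) return(list(latents = lat, observers = list()))
  obs <- lapply(seq_len(n), function(i)
    observer_model(pse = lat$pse[i], sigma = lat$sigma[i],
                   lapse = config$lapse, guess = config$guess,
                   delta = lat$delta[i], kappa = lat$kappa[i],
                   face_emotion = config$face_emotion,
                   base_rates = config$base_rates,
                   hypothesis = config$hypothesis,
                   seed = substream_seed(config$seed, i, 0L)))
  list(latents = lat, observers = obs)
}

## condition stream ids: baseline = 10, conditions 11, 12, ...
condition_streams <- function(n_conditions) 10L + seq_len(n_conditions)

#' Generate a full synthetic cohort
#'
#' Draws a cohort of synthetic observers and simulates their categorization
#' task and all Psi-driven adaptation/baseline sessions (batched internally;
#' trial-for-trial identical to running [simulate_adaptation_session()] per
#' observer). Optionally writes the trial CSVs and a ground-truth manifest.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; if given, writes
#'   `categorization.csv`, `adaptation.csv` and `ground_truth.json` there.
#' @return list with `latents` (data frame of true parameters), `observers`,
#'   trial-level `categorization` and `adaptation` data frames, the session
#'   ground truth (`sessions`: per observer and condition, the true adapted
#'   PSE and applied shift), and the `manifest` list.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  drawn <- draw_observers(config)
  n <- config$n_observers
  if (n == 0) {
    warning("empty cohort: no observers generated")
    empty_cat <- data.frame(observer_id = integer(0), context = character(0),
                            face_emotion = character(0), response = character(0))
    empty_ad <- data.frame(observer_id = integer(0), phase = character(0),
                           adaptor_face = character(0),
                           adaptor_context = character(0), trial = integer(0),
                           stimulus_level = numeric(0), response = integer(0))
    manifest <- list(seed = config$seed, hypothesis = config$hypothesis,
                     n_observers = 0L, observers = list())
    out <- list(latents = drawn$latents, observers = list(),
                categorization = empty_cat, adaptation = empty_ad,
                sessions = data.frame(), manifest = manifest)
    if (!is.null(dir)) write_cohort_files(out, dir)
    return(out)
  }
  observers <- drawn$observers

  ## categorization task: counts -> trial rows (deterministic order)
  cat_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(config$contexts, function(ctx) {
      k <- simulate_categorization(observers[[i]], ctx, config$n_categorization)
      resp <- rep(c(names(k)[1:4], "none"), k)
      data.frame(observer_id = i, context = ctx,
                 face_emotion = config$face_emotion, response = resp,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## adaptation phases, batched per condition across observers
  engine <- psi_engine(guess = config$guess, lapse = config$lapse)
  conds <- rbind(data.frame(adaptor_face = "baseline", adaptor_context = "none",
                            stringsAsFactors = FALSE),
                 config$conditions)
  streams <- c(10L, condition_streams(nrow(config$conditions)))
  sessions <- list(); trial_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    af <- conds$adaptor_face[ci]; ac <- conds$adaptor_context[ci]
    n_tr <- if (af == "baseline") config$n_baseline else config$n_test
    shifts <- vapply(observers, function(o)
      if (af == "baseline") 0 else effective_shift(o, af, ac), 0)
    alpha_true <- drawn$latents$pse - shifts
    U <- vapply(seq_len(n), function(i)
      with_seed(substream_seed(observers[[i]]$seed, 0L, streams[ci]),
                runif(n_tr)),
      numeric(n_tr))
    U <- matrix(U, nrow = n_tr)
    run <- psi_run_batch(engine, U, alpha_true, drawn$latents$sigma,
                         config$guess, config$lapse)
    sessions[[ci]] <- data.frame(observer_id = seq_len(n),
                                 adaptor_face = af, adaptor_context = ac,
                                 alpha_session = alpha_true, shift = shifts,
                                 alpha_psi = run$alpha_hat,
                                 sigma_psi = run$sigma_hat,
                                 stringsAsFactors = FALSE)
    phase <- if (af == "baseline") "baseline" else "test"
    trial_rows[[ci]] <- data.frame(
      observer_id = rep(seq_len(n), each = n_tr),
      phase = phase, adaptor_face = af, adaptor_context = ac,
      trial = rep(seq_len(n_tr), n),
      stimulus_level = as.vector(run$X), response = as.vector(run$R),
      stringsAsFactors = FALSE)
    if (af != "baseline" && config$n_adapt > 0) {
      ## top-up adaptation exposures carry no response data (the red-dot sham
      ## task is a placeholder only)
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        observer_id = rep(seq_len(n), each = config$n_adapt),
        phase = "adaptation", adaptor_face = af, adaptor_context = ac,
        trial = rep(seq_len(config$n_adapt), n),
        stimulus_level = NA_real_, response = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  adaptation <- do.call(rbind, trial_rows)
  sessions <- do.call(rbind, sessions)

  manifest <- list(
    seed = config$seed, hypothesis = config$hypothesis,
    face_emotion = config$face_emotion, n_observers = n,
    trials = list(n_test = config$n_test, n_adapt = config$n_adapt,
                  n_baseline = config$n_baseline,
                  n_categorization = config$n_categorization),
    observers = lapply(seq_len(n), function(i)
      c(as.list(drawn$latents[i, ]),
        list(lapse = config$lapse, guess = config$guess,
             seed = observers[[i]]$seed))))
  out <- list(latents = drawn$latents, observers = observers,
              categorization = cat_rows, adaptation = adaptation,
              sessions = sessions, manifest = manifest)
  if (!is.null(dir)) write_cohort_files(out, dir)
  out
}

write_cohort_files <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$categorization, file.path(dir, "categorization.csv"),
            row.names = FALSE)
  write.csv(cohort$adaptation, file.path(dir, "adaptation.csv"),
            row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
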