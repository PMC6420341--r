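## structured, level-filtered logging (one line per stage per observer)
log_msg <- function(level = c("info", "warn", "error"), ...) {
  level <- match.arg(level)
  threshold <- match(getOption("psyadapt.log_level", "warn"),
                     c("info", "warn", "error", "quiet"))
  if (match(level, c("info", "warn", "error")) >= threshold)
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

#' Study configuration
#'
#' Bundles the full configuration of a simulated study: the cohort generator
#' settings, the fitting stage (fixed guess/lapse, parameter bounds, number
#' of goodness-of-fit simulations; `n_sim_gof = 0` disables the screen), the
#' statistics stage (Bayes prior scale, robustness grid, direction of the
#' one-sided alternative, optional Bonferroni factor) and output paths.
#'
#' @param cohort a [cohort_config()].
#' @param fitting named list overriding any of `guess` (0), `lapse` (0.03),
#'   `n_sim_gof` (400), `alpha_bounds`, `sigma_bounds`.
#' @param stats named list overriding any of `prior_scale` (0.707),
#'   `robustness_scales`, `alternative` (`"auto"`: the direction predicted by
#'   early integration for the study's face emotion), `bonferroni_m` (1),
#'   `beta_prior_width` (1).
#' @param io named list with optional `out_dir`.
#' @param seed optional master seed overriding `cohort$seed`.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(cohort = cohort_config(), fitting = list(),
                         stats = list(), io = list(), seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  fit_def <- list(guess = 0, lapse = 0.03, n_sim_gof = 400,
                  alpha_bounds = c(-0.5, 1.5), sigma_bounds = c(0.01, 1))
  stat_def <- list(prior_scale = 0.707,
                   robustness_scales = seq(0.1, 1.5, by = 0.05),
                   alternative = "auto", bonferroni_m = 1,
                   beta_prior_width = 1)
  io_def <- list(out_dir = NULL)
  merge_cfg <- function(def, user, what) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      stop("unknown ", what, " setting(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    def[names(user)] <- user
    def
  }
  fitting <- merge_cfg(fit_def, fitting, "fitting")
  stats <- merge_cfg(stat_def, stats, "stats")
  io <- merge_cfg(io_def, io, "io")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, fitting = fitting, stats = stats, io = io),
            class = "study_config")
}

#' Read a YAML study configuration
#'
#' The file must carry `schema: psyadapt_study/1`. Unknown keys at any level
#' are errors, not warnings. Sub-sections `cohort`, `fitting`, `stats`, `io`
#' and a top-level `seed` are accepted; `cohort$conditions` is a list of
#' `{adaptor_face, adaptor_context}` records.
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema) || !identical(y$schema, "psyadapt_study/1"))
    stop("config must declare schema: psyadapt_study/1", call. = FALSE)
  unknown <- setdiff(names(y), c("schema", "cohort", "fitting", "stats",
                                 "io", "seed"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cargs <- y$cohort %||% list()
  ok <- names(formals(cohort_config))
  bad <- setdiff(names(cargs), ok)
  if (length(bad))
    stop("unknown cohort setting(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(cargs$conditions))
    cargs$conditions <- do.call(rbind, lapply(cargs$conditions, function(co)
      data.frame(adaptor_face = co$adaptor_face,
                 adaptor_context = co$adaptor_context,
                 stringsAsFactors = FALSE)))
  for (nm in c("pse_bounds", "sigma_bounds", "delta_bounds"))
    if (!is.null(cargs[[nm]])) cargs[[nm]] <- unlist(cargs[[nm]])
  cohort <- do.call(cohort_config, cargs)
  study_config(cohort = cohort, fitting = y$fitting %||% list(),
               stats = y$stats %||% list(), io = y$io %||% list(),
               seed = y$seed)
}

#' Read trial-level CSV files
#'
#' Validates the adaptation/baseline dialect
#' (`observer_id,phase,adaptor_face,adaptor_context,trial,stimulus_level,response`)
#' or the categorization dialect; malformed rows are reported with their line
#' number and column.
#'
#' @param path CSV path.
#' @param type `"adaptation"` or `"categorization"`.
#' @return validated data frame.
#' @export
read_trials <- function(path, type = c("adaptation", "categorization")) {
  type <- match.arg(type)
  if (type == "categorization") return(read_categorization_csv(path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "phase", "adaptor_face", "adaptor_context",
            "trial", "stimulus_level", "response")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("adaptation CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  check <- function(col, ok, allow_na = FALSE) {
    v <- d[[col]]
    bad <- which(!(v %in% ok | (allow_na & is.na(v))))
    if (length(bad))
      stop(sprintf("invalid '%s' value '%s' at line %d of %s",
                   col, v[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  check("phase", c("baseline", "test", "adaptation"))
  check("adaptor_face", c("disgust", "anger", "none", "baseline"))
  check("adaptor_context", c("disgust", "anger", "none"))
  check("response", c(0L, 1L), allow_na = TRUE)
  bad_lvl <- which(!is.na(d$stimulus_level) &
                     (d$stimulus_level < 0 | d$stimulus_level > 1))
  if (length(bad_lvl))
    stop(sprintf("invalid 'stimulus_level' value at line %d of %s",
                 bad_lvl[1] + 1L, path), call. = FALSE)
  d
}

## grid-replayed Psi posterior mean (uniform prior): identical to sequential
## psi_update() up to the underflow floor, but one matrix product per session
psi_posterior_mean <- function(levels, responses, guess = 0, lapse = 0.03,
                               engine = NULL) {
  if (is.null(engine)) engine <- psi_engine(guess = guess, lapse = lapse)
  b <- bin_trials(levels, responses)
  idx <- match(round(b$level, 9), round(engine$candidates, 9))
  if (anyNA(idx)) {
    lik <- psi_likelihoods(engine$alpha, engine$sigma, b$level, guess, lapse)
    P <- lik$P; Q <- lik$Q
  } else {
    P <- engine$P[, idx, drop = FALSE]; Q <- engine$Q[, idx, drop = FALSE]
  }
  lp <- as.vector(log(P) %*% b$n_target +
                    log(Q) %*% (b$n_trials - b$n_target))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(alpha = sum(w * engine$alpha), sigma = sum(w * engine$sigma))
}

#' Analyze trial-level study data
#'
#' The full analysis half of the pipeline, independent of how the data were
#' produced: per observer and condition, bin the 2AFC test responses, fit the
#' cumulative-Gaussian psychometric function by maximum likelihood (guess and
#' lapse fixed), record the Psi posterior-mean estimate alongside, screen the
#' fit by parametric-bootstrap goodness of fit, apply the exclusion rule (an
#' observer with `gof_p < 0.05` or a non-converged fit in any condition is
#' dropped from the adaptation analyses), score aftereffects against the
#' baseline PSE (mean of baseline sessions when several exist), compute both
#' categorization bias indices, and run the group statistics.
#'
#' @param adaptation adaptation/baseline trial data frame ([read_trials()]
#'   dialect).
#' @param categorization categorization trial data frame (may be `NULL`).
#' @param config a [study_config()] (its `cohort` settings are not used
#'   here, only `fitting` and `stats`).
#' @param face_emotion the study's physical face expression.
#' @param seed seed for the goodness-of-fit bootstraps.
#' @return a `"study_report"` object; see [run_study()].
#' @export
analyze_study <- function(adaptation, categorization = NULL,
                          config = study_config(),
                          face_emotion = c("disgust", "anger"), seed = 1L) {
  face_emotion <- match.arg(face_emotion)
  ft <- config$fitting; st <- config$stats
  ids <- sort(unique(adaptation$observer_id))
  test <- adaptation[adaptation$phase %in% c("baseline", "test") &
                       !is.na(adaptation$response), , drop = FALSE]
  conds <- unique(test[c("adaptor_face", "adaptor_context")])
  conds$label <- ifelse(conds$adaptor_face == "baseline", "baseline",
                        paste(conds$adaptor_face, conds$adaptor_context,
                              sep = "_"))
  engine <- psi_engine(guess = ft$guess, lapse = ft$lapse)

  per_obs <- list(); fits <- list(); exclusions <- list()
  for (oi in seq_along(ids)) {
    id <- ids[oi]
    row <- list(observer_id = id, excluded = FALSE, reason = "")
    ofits <- list()
    for (ci in seq_len(nrow(conds))) {
      lab <- conds$label[ci]
      tr <- test[test$observer_id == id &
                   test$adaptor_face == conds$adaptor_face[ci] &
                   test$adaptor_context == conds$adaptor_context[ci], ]
      if (nrow(tr) == 0) next
      fit <- tryCatch({
        b <- bin_trials(tr$stimulus_level, tr$response)
        suppressWarnings(psychfit(b, guess = ft$guess, lapse = ft$lapse,
                                  alpha_bounds = ft$alpha_bounds,
                                  sigma_bounds = ft$sigma_bounds))
      }, error = function(e)
        stop("fitting stage failed for observer ", id, " (", lab, "): ",
             conditionMessage(e), call. = FALSE))
      if (ft$n_sim_gof > 0)
        fit <- gof_bootstrap(fit, n_sim = ft$n_sim_gof,
                             seed = substream_seed(seed, id, 200L + ci))
      psi_est <- psi_posterior_mean(tr$stimulus_level, tr$response,
                                    ft$guess, ft$lapse, engine)
      attr(fit, "psi_posterior_mean") <- psi_est
      ofits[[lab]] <- fit
      row[[paste0("pse_", lab)]] <- unname(coef(fit)["pse"])
      row[[paste0("psi_alpha_", lab)]] <- unname(psi_est["alpha"])
      if (!fit$converged) {
        row$excluded <- TRUE
        row$reason <- paste0(row$reason, lab, ": not converged; ")
      } else if (isTRUE(fit$excluded)) {
        row$excluded <- TRUE
        row$reason <- paste0(row$reason, lab,
                             sprintf(": gof p = %.3f; ", fit$gof_p))
      }
      log_msg("info", "observer ", id, " fit ", lab, ": PSE ",
              round(coef(fit)["pse"], 4))
    }
    fits[[as.character(id)]] <- ofits
    ## aftereffects relative to (mean) baseline
    if (!is.null(ofits$baseline)) {
      base <- unname(coef(ofits$baseline)["pse"])
      for (lab in setdiff(names(ofits), "baseline"))
        row[[paste0("ae_", lab)]] <- base - unname(coef(ofits[[lab]])["pse"])
    }
    ## categorization bias indices
    if (!is.null(categorization)) {
      ctr <- categorization[categorization$observer_id == id, ]
      if (nrow(ctr)) {
        bi <- tryCatch(bias_indices(confusion_table(ctr, face_emotion)),
                       error = function(e) NULL)
        row$index1 <- if (is.null(bi)) NA_real_ else bi$index1
        row$index2 <- if (is.null(bi)) NA_real_ else bi$index2
      }
    }
    if (row$excluded)
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(observer_id = id, reason = trimws(row$reason))
    per_obs[[oi]] <- row
  }
  nm <- unique(unlist(lapply(per_obs, names)))
  observers <- do.call(rbind, lapply(per_obs, function(r) {
    r[setdiff(nm, names(r))] <- NA
    as.data.frame(r[nm], stringsAsFactors = FALSE)
  }))
  exclusion_log <- if (length(exclusions)) do.call(rbind, exclusions)
  else data.frame(observer_id = integer(0), reason = character(0))

  inc <- observers[!observers$excluded, , drop = FALSE]
  group <- group_statistics(inc, conds, face_emotion, st)
  structure(list(observers = observers, fits = fits,
                 exclusion_log = exclusion_log, group = group,
                 metadata = list(
                   face_emotion = face_emotion,
                   guess = ft$guess, lapse = ft$lapse,
                   n_sim_gof = ft$n_sim_gof,
                   prior_scale = st$prior_scale,
                   alternative = group$alternative %||% st$alternative,
                   baseline_aggregation = "single session (mean if several)",
                   adjustment_n = "disgust+anger responses per context",
                   n_simulated = length(ids), n_included = nrow(inc),
                   n_excluded = nrow(exclusion_log))),
            class = "study_report")
}

## group-level statistics over included observers
group_statistics <- function(inc, conds, face_emotion, st) {
  group <- list()
  ae_cols <- grep("^ae_", names(inc), value = TRUE)
  for (cl in ae_cols) {
    v <- inc[[cl]][!is.na(inc[[cl]])]
    if (length(v) >= 2)
      group$one_sample[[sub("^ae_", "", cl)]] <-
        tryCatch(one_sample_test(v), error = function(e) NULL)
  }
  con_lab <- paste(face_emotion, face_emotion, sep = "_")
  incon_lab <- paste(face_emotion, other_of_pair(face_emotion), sep = "_")
  alt <- st$alternative
  if (identical(alt, "auto"))
    alt <- if (face_emotion == "disgust") "greater" else "less"
  group$alternative <- alt
  ca <- inc[[paste0("ae_", con_lab)]]; ia <- inc[[paste0("ae_", incon_lab)]]
  if (!is.null(ca) && !is.null(ia)) {
    keep <- !is.na(ca) & !is.na(ia)
    if (sum(keep) >= 2) {
      pc <- paired_contrast(ca[keep], ia[keep])
      group$context_contrast <- pc
      group$context_bf01 <- jzs_bf01(pc$statistic, pc$n, st$prior_scale, alt)
      group$robustness <- bf_robustness(pc$statistic, pc$n,
                                        st$robustness_scales, alt)
      diff <- ca[keep] - ia[keep]
      for (ix in c("index1", "index2")) {
        if (!is.null(inc[[ix]])) {
          v <- inc[[ix]][keep]
          ok <- !is.na(v)
          if (sum(ok) >= 3 && sd(v[ok]) > 0 && sd(diff[ok]) > 0)
            group$correlation[[ix]] <-
              pearson_with_bf(v[ok], diff[ok], st$beta_prior_width)
        }
      }
    }
  }
  ## 2x2 face-present/absent x body-context ANOVA when all cells exist
  none_labs <- paste("none", c(face_emotion, other_of_pair(face_emotion)),
                     sep = "_")
  cells <- paste0("ae_", c(con_lab, incon_lab, none_labs))
  if (all(cells %in% names(inc))) {
    m <- as.matrix(inc[cells])
    keep <- complete.cases(m)
    if (sum(keep) >= 2)
      group$anova <- tryCatch(rm_anova_2x2(m[keep, , drop = FALSE]),
                              error = function(e) NULL)
  }
  group
}

#' @export
print.study_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Study report (%s face): %d observers, %d included, %d excluded\n",
              md$face_emotion, md$n_simulated, md$n_included, md$n_excluded))
  if (!is.null(x$group$context_contrast)) {
    print(x$group$context_contrast)
    cat(sprintf("  directional BF01 (scale %.3f, '%s'): %.3f\n",
                md$prior_scale, md$alternative, x$group$context_bf01))
  }
  invisible(x)
}

#' Run a complete simulated study
#'
#' Executes all pipeline stages in order: draw the synthetic cohort, simulate
#' the categorization task and every Psi-driven baseline/adaptation session,
#' fit and screen the psychometric functions, score aftereffects and bias
#' indices, and compute the group statistics. Fully deterministic for a given
#' configuration seed. When `config$io$out_dir` is set, all intermediate
#' CSVs, the ground-truth manifest and the report JSON are written there.
#'
#' @param config a [study_config()].
#' @return object of class `"study_report"`: per-observer estimates and
#'   exclusion flags (`observers`), the fitted objects (`fits`), the
#'   `exclusion_log`, the `group` statistics (one-sample tests per condition,
#'   the congruent-incongruent paired contrast with its directional BF01 and
#'   robustness sweep, the 2x2 ANOVA when body-only conditions exist, and
#'   bias-index/aftereffect correlations), the generating cohort ground truth
#'   (`truth`) and run `metadata`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$io$out_dir
  cohort <- generate_cohort(config$cohort, dir = out_dir)
  if (config$cohort$n_observers == 0) {
    rep0 <- structure(list(observers = data.frame(), fits = list(),
                           exclusion_log = data.frame(observer_id = integer(0),
                                                      reason = character(0)),
                           group = list(),
                           metadata = list(
                             face_emotion = config$cohort$face_emotion,
                             n_simulated = 0L, n_included = 0L,
                             n_excluded = 0L,
                             prior_scale = config$stats$prior_scale)),
                      class = "study_report")
    if (!is.null(out_dir)) write_report(rep0, file.path(out_dir, "report.json"))
    return(rep0)
  }
  report <- analyze_study(cohort$adaptation, cohort$categorization, config,
                          face_emotion = config$cohort$face_emotion,
                          seed = config$cohort$seed)
  report$truth <- list(latents = cohort$latents, sessions = cohort$sessions,
                       hypothesis = config$cohort$hypothesis)
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
    if (nrow(report$exclusion_log))
      write.csv(report$exclusion_log, file.path(out_dir, "exclusions.csv"),
                row.names = FALSE)
  }
  report
}

## strip classes/attributes so jsonlite serializes the report plainly
sanitize_for_json <- function(x) {
  if (inherits(x, "psy_test") || inherits(x, "bf_robustness"))
    return(lapply(unclass(x), sanitize_for_json))
  if (inherits(x, "psychfit"))
    return(jsonlite::parse_json(fit_to_json(x)))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, sanitize_for_json))
  x
}

#' Write a study report as JSON
#'
#' @param report a `"study_report"`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  js <- jsonlite::toJSON(sanitize_for_json(unclass(report)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
  writeLines(js, path)
  invisible(path)
}
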