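test_that("observer construction validates its generative parameters", {
  obs <- observer_model()
  expect_equal(sum(obs$base_rates), 1)
  expect_equal(unname(obs$base_rates["disgust"]), 0.90)
  anger_obs <- observer_model(face_emotion = "anger")
  expect_equal(unname(anger_obs$base_rates["anger"]), 0.90)
  expect_error(observer_model(kappa = 1.2), "kappa")
  expect_error(observer_model(sigma = -1), "sigma")
  expect_error(observer_model(base_rates = c(disgust = 0.5, anger = 0.6,
                                             fear = 0, sad = 0)), "sum to 1")
})

test_that("context bias construction moves the right probability mass", {
  obs <- observer_model(kappa = 0.6, seed = 3)
  for (ctx in c("disgust", "anger", "fear", "sad")) {
    got <- psyadapt:::categorization_probs(obs, ctx)
    want <- oracle_context_probs(obs$base_rates, "disgust", ctx, 0.6)
    expect_equal(got, want)
    expect_equal(sum(got), 1)
  }
  # kappa = 0: no context influence at all
  flat <- observer_model(kappa = 0)
  expect_equal(psyadapt:::categorization_probs(flat, "anger"),
               flat$base_rates)
  # kappa = 1, incongruent: the face emotion is never reported
  full <- observer_model(kappa = 1)
  p <- psyadapt:::categorization_probs(full, "anger")
  expect_equal(unname(p["disgust"]), 0)
  expect_equal(unname(p["anger"]),
               unname(full$base_rates["anger"] + full$base_rates["disgust"]))
})

test_that("simulated categorization is seeded and matches its construction", {
  obs <- observer_model(kappa = 0.6, seed = 12)
  k1 <- simulate_categorization(obs, "anger", 500)
  k2 <- simulate_categorization(obs, "anger", 500)
  expect_identical(k1, k2)
  expect_equal(sum(k1), 500)
  # large-sample proportions near the construction (3 binomial SEs)
  big <- simulate_categorization(obs, "anger", 10000)
  p <- psyadapt:::categorization_probs(obs, "anger")
  for (resp in names(p)) {
    se <- sqrt(p[[resp]] * (1 - p[[resp]]) / 10000)
    expect_lt(abs(big[[resp]] / 10000 - p[[resp]]), 3 * se + 1e-9)
  }
})

test_that("effective adaptation shift implements both hypotheses", {
  late <- observer_model(delta = 0.08, kappa = 1, hypothesis = "late")
  # late integration: the physical face drives adaptation in any context
  expect_equal(psyadapt:::effective_shift(late, "disgust", "disgust"), 0.08)
  expect_equal(psyadapt:::effective_shift(late, "disgust", "anger"), 0.08)
  expect_equal(psyadapt:::effective_shift(late, "none", "anger"), 0)
  early <- observer_model(delta = 0.08, kappa = 1, hypothesis = "early")
  # congruent: q = base rate of the correct response
  q_con <- early$base_rates[["disgust"]]
  expect_equal(psyadapt:::effective_shift(early, "disgust", "disgust"),
               0.08 * (2 * q_con - 1))
  # full reversal (q = 0): equal-magnitude opposite shift
  expect_equal(psyadapt:::effective_shift(early, "disgust", "anger"), -0.08)
  # balanced percept (q = 0.5) produces no net adaptation
  half <- observer_model(delta = 0.08, kappa = 1, hypothesis = "early",
                         base_rates = c(disgust = 0.5, anger = 0.3,
                                        fear = 0.1, sad = 0.1))
  expect_equal(psyadapt:::effective_shift(half, "disgust", "disgust"), 0)
  # anger adaptors shift the PSE the other way
  anger <- observer_model(face_emotion = "anger", delta = 0.08,
                          hypothesis = "late")
  expect_equal(psyadapt:::effective_shift(anger, "anger", "anger"), -0.08)
})

test_that("adaptation sessions are reproducible and shift the PSE correctly", {
  obs <- observer_model(pse = 0.5, delta = 0.08, hypothesis = "late",
                        seed = 42)
  s1 <- simulate_adaptation_session(obs, "disgust", "anger", n_test = 144,
                                    stream = 11L)
  s2 <- simulate_adaptation_session(obs, "disgust", "anger", n_test = 144,
                                    stream = 11L)
  expect_identical(s1$trials, s2$trials)
  expect_equal(s1$alpha_session, 0.42)
  expect_equal(s1$shift, 0.08)
  base <- simulate_adaptation_session(obs, "baseline", n_test = 144)
  expect_equal(base$alpha_session, 0.5)
  expect_error(simulate_adaptation_session(obs, "disgust", "none"),
               "body context")
  # the aftereffect estimated from the session pair points at the truth
  # (two 144-trial sessions leave a few hundredths of estimation noise)
  expect_lt(abs(aftereffect(base$alpha_psi, s1$alpha_psi) - 0.08), 0.05)
})

test_that("cohort generation is deterministic and writes valid files", {
  cfg <- cohort_config(n_observers = 3, n_test = 40, n_baseline = 40,
                       n_adapt = 5, n_categorization = 20,
                       conditions = data.frame(adaptor_face = "disgust",
                                               adaptor_context = "anger"),
                       seed = 77)
  dir1 <- file.path(tempdir(), "cohortA")
  dir2 <- file.path(tempdir(), "cohortB")
  c1 <- generate_cohort(cfg, dir1)
  c2 <- generate_cohort(cfg, dir2)
  expect_identical(c1$adaptation, c2$adaptation)
  expect_identical(readLines(file.path(dir1, "adaptation.csv")),
                   readLines(file.path(dir2, "adaptation.csv")))
  expect_identical(readLines(file.path(dir1, "ground_truth.json")),
                   readLines(file.path(dir2, "ground_truth.json")))
  # round trip through the validated readers
  ad <- read_trials(file.path(dir1, "adaptation.csv"))
  expect_equal(nrow(ad), nrow(c1$adaptation))
  expect_setequal(unique(ad$phase), c("baseline", "test", "adaptation"))
  expect_equal(sum(ad$phase == "adaptation"), 3 * 5)
  ct <- read_trials(file.path(dir1, "categorization.csv"), "categorization")
  expect_equal(nrow(ct), 3 * 4 * 20)
  # empty cohort: schema-valid empty output, with a warning
  expect_warning(c0 <- generate_cohort(cohort_config(n_observers = 0)),
                 "empty")
  expect_equal(nrow(c0$adaptation), 0)
  expect_length(c0$manifest$observers, 0)
})

test_that("cohort sessions equal individually simulated sessions", {
  cfg <- cohort_config(n_observers = 2, n_test = 50, n_baseline = 50,
                       n_adapt = 0, seed = 5,
                       conditions = data.frame(
                         adaptor_face = c("disgust", "disgust"),
                         adaptor_context = c("disgust", "anger")))
  cohort <- generate_cohort(cfg)
  for (i in 1:2) {
    obs <- cohort$observers[[i]]
    single <- simulate_adaptation_session(obs, "disgust", "anger",
                                          n_test = 50, stream = 12L)
    rows <- cohort$adaptation[cohort$adaptation$observer_id == i &
                                cohort$adaptation$adaptor_context == "anger" &
                                cohort$adaptation$phase == "test", ]
    expect_equal(rows$stimulus_level, single$trials$stimulus_level)
    expect_equal(rows$response, single$trials$response)
  }
})

test_that("zero-delta observers show no systematic aftereffect", {
  eng <- psyadapt:::psi_engine()
  set.seed(60)
  m <- 60
  U1 <- matrix(runif(80 * m), 80, m)
  U2 <- matrix(runif(80 * m), 80, m)
  base <- psyadapt:::psi_run_batch(eng, U1, 0.5, 0.12, 0, 0.03)
  adap <- psyadapt:::psi_run_batch(eng, U2, 0.5, 0.12, 0, 0.03)
  ae <- base$alpha_hat - adap$alpha_hat
  expect_lt(abs(mean(ae)), 2 * sd(ae) / sqrt(m))
})
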