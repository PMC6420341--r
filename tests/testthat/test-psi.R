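test_that("initialization normalizes priors and rejects degenerate ones", {
  st <- psi_init(alpha_grid = seq(0, 1, length.out = 21),
                 sigma_grid = seq(0.05, 0.3, length.out = 11))
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  expect_equal(unique(st$posterior), 1 / 231)
  st2 <- psi_init(alpha_grid = c(0.4, 0.6), sigma_grid = 0.1, prior = c(2, 2))
  expect_equal(st2$posterior, c(0.5, 0.5))
  expect_error(psi_init(alpha_grid = c(0.4, 0.6), sigma_grid = 0.1,
                        prior = c(0, 0)), "not all zero")
  expect_error(psi_init(alpha_grid = numeric(0)), "empty")
  expect_error(psi_init(candidates = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("stimulus selection matches brute-force expected-entropy enumeration", {
  set.seed(11)
  for (i in 1:25) {
    na <- sample(2:5, 1); ns <- sample(1:5, 1); nc <- sample(2:5, 1)
    ag <- sort(runif(na)); sg <- sort(runif(ns, 0.03, 0.4))
    cand <- sort(runif(nc))
    st <- psi_init(ag, sg, cand)
    st$posterior <- rgamma(na * ns, 1); st$posterior <- st$posterior / sum(st$posterior)
    oracle <- oracle_psi_select(ag, sg, cand, st$posterior,
                                guess = 0, lapse = 0.03)
    expect_identical(psi_select(st), oracle$x)
    expect_equal(psi_expected_entropy(st), oracle$eh, tolerance = 1e-10)
  }
})

test_that("point-mass posterior gives zero expected entropy and low tie-break", {
  st <- psi_init(alpha_grid = c(0.3, 0.5, 0.7), sigma_grid = c(0.1, 0.2),
                 candidates = c(0.2, 0.5, 0.8))
  st$posterior <- c(0, 0, 0, 0, 1, 0)
  eh <- psi_expected_entropy(st)
  expect_true(all(abs(eh) < 1e-9))
  expect_equal(psi_select(st), 0.2)
})

test_that("expected-entropy profile is symmetric for a symmetric problem", {
  st <- psi_init(alpha_grid = seq(0.2, 0.8, length.out = 13),
                 sigma_grid = c(0.08, 0.15),
                 candidates = seq(0.1, 0.9, length.out = 9),
                 guess = 0, lapse = 0)
  eh <- psi_expected_entropy(st)
  expect_equal(eh, rev(eh), tolerance = 1e-12)
})

test_that("Bayesian update reproduces the two-hypothesis posterior", {
  st <- psi_init(alpha_grid = c(0.4, 0.6), sigma_grid = 0.1,
                 candidates = c(0.5), guess = 0, lapse = 0.03)
  st <- psi_update(st, 0.5, 1)
  # 0.97 * pnorm(1) vs 0.97 * pnorm(-1); the common factor cancels
  expect_equal(st$posterior[1], pnorm(1) / (pnorm(1) + pnorm(-1)),
               tolerance = 1e-12)
  expect_equal(st$posterior[1], 0.8413447, tolerance = 1e-7)
  expect_equal(nrow(st$history), 1)
})

test_that("posterior stays normalized and point masses are absorbing", {
  set.seed(5)
  st <- psi_init(alpha_grid = seq(0, 1, 0.25), sigma_grid = c(0.1, 0.2))
  for (i in 1:30) {
    x <- sample(st$candidates, 1)
    st <- psi_update(st, x, rbinom(1, 1, 0.5))
    expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  }
  pm <- psi_init(alpha_grid = c(0.3, 0.6), sigma_grid = 0.1,
                 candidates = c(0.3, 0.6))
  pm$posterior <- c(1, 0)
  pm <- psi_update(pm, 0.3, 1)
  pm <- psi_update(pm, 0.6, 0)
  expect_equal(pm$posterior[1], 1, tolerance = 1e-250)
})

test_that("posterior-mean estimates respect symmetry and point masses", {
  st <- psi_init(alpha_grid = seq(0.3, 0.7, length.out = 9),
                 sigma_grid = c(0.1, 0.2))
  expect_warning(est <- psi_estimate(st), "no trials")
  expect_equal(unname(est["alpha"]), 0.5)
  pm <- psi_init(alpha_grid = c(0.45, 0.6), sigma_grid = c(0.12, 0.2))
  pm$posterior <- c(1, 0, 0, 0)
  pm$history <- data.frame(x = 0.5, response = 1L)
  expect_equal(psi_estimate(pm), c(alpha = 0.45, sigma = 0.12))
})

test_that("a full Psi session is deterministic and sharpens the posterior", {
  obs_p <- function(x) psych_prob(x, 0.5, 0.12, 0, 0.03)
  run_once <- function() {
    set.seed(123)
    psi_run(psi_init(), 80, function(x) rbinom(1, 1, obs_p(x)))
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$trace, r2$trace)
  # expected posterior entropy at the selected level never exceeds current
  set.seed(9)
  st <- psi_init()
  for (i in 1:40) {
    w <- st$posterior
    h_now <- -sum(ifelse(w > 0, w * log(w), 0))
    x <- psi_select(st)
    eh <- min(psi_expected_entropy(st))
    expect_lte(eh, h_now + 1e-12)
    st <- psi_update(st, x, rbinom(1, 1, obs_p(x)))
  }
  expect_lt(-sum(st$posterior * log(st$posterior)), log(length(st$posterior)))
})

test_that("psi trace exports the declared CSV columns", {
  set.seed(2)
  run <- psi_run(psi_init(), 10, function(x) rbinom(1, 1, 0.5))
  path <- tempfile(fileext = ".csv")
  write_psi_trace(run$trace, path)
  d <- read.csv(path)
  expect_named(d, c("trial", "stimulus_level", "response", "alpha_hat",
                    "sigma_hat", "posterior_entropy"))
  expect_equal(nrow(d), 10)
})

test_that("batched sessions are trial-identical to single-state sessions", {
  eng <- psyadapt:::psi_engine()
  set.seed(31)
  n <- 60; m <- 3
  U <- matrix(runif(n * m), n, m)
  alpha_t <- c(0.45, 0.5, 0.58); sigma_t <- c(0.1, 0.12, 0.15)
  batch <- psyadapt:::psi_run_batch(eng, U, alpha_t, sigma_t, 0, 0.03)
  for (j in 1:m) {
    i <- 0L
    st <- psi_init()
    run <- psi_run(st, n, function(x) {
      i <<- i + 1L
      as.integer(U[i, j] < psych_prob(x, alpha_t[j], sigma_t[j], 0, 0.03))
    })
    expect_equal(run$trace$stimulus_level, batch$X[, j])
    expect_equal(run$trace$response, batch$R[, j])
    est <- psi_estimate(run$state)
    expect_equal(unname(est["alpha"]), batch$alpha_hat[j], tolerance = 1e-10)
  }
})

test_that("posterior mass on the true cell grows over a session (median)", {
  eng <- psyadapt:::psi_engine()
  # observer drawn from the grid itself: the cell nearest (0.5, 0.12)
  cell <- which.min((eng$alpha - 0.5)^2 + (eng$sigma - 0.12)^2)
  set.seed(77)
  n <- 144; m <- 40
  U <- matrix(runif(n * m), n, m)
  run <- psyadapt:::psi_run_batch(eng, U, eng$alpha[cell], eng$sigma[cell],
                                  0, 0.03, track_cell = cell)
  med <- apply(run$tracked, 1, median)
  checkpoints <- med[c(1, 36, 72, 108, 144)]
  expect_true(all(diff(checkpoints) > -1e-12))
  expect_gt(checkpoints[5], checkpoints[1])
})
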