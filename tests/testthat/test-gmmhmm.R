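test_that("gaussian_pdf matches closed-form values", {
  expect_equal(gaussian_pdf(0, 0, matrix(1)), 1 / sqrt(2 * pi))
  expect_equal(gaussian_pdf(c(1, 0), c(0, 0), diag(2)),
               exp(-0.5) / (2 * pi))
  # even around the mean
  mu <- c(1, -2); S <- matrix(c(2, 0.5, 0.5, 1), 2)
  d <- c(0.3, -0.7)
  expect_equal(gaussian_pdf(mu + d, mu, S), gaussian_pdf(mu - d, mu, S))
  expect_error(gaussian_pdf(0, 0, matrix(0)), "singular|positive")
})

test_that("emission_prob is the mixture of its components", {
  m <- rand_model(2, 1, 2, seed = 1)
  x <- c(0.5, -0.2)
  expect_equal(emission_prob(x, m, 1),
               gaussian_pdf(x, m$mu[1, 1, ], m$sigma[1, 1, , ]))

  # two equally weighted unit-variance components at +/-1
  mu <- array(c(1, -1), c(1, 2, 1))
  sg <- array(1, c(1, 2, 1, 1))
  m2 <- gmmhmm(matrix(1), 1, matrix(0.5, 1, 2), mu, sg)
  expect_equal(emission_prob(0, m2, 1), stats::dnorm(1))

  # bounded below by every weighted component
  m3 <- rand_model(1, 3, 2, seed = 2)
  x <- rnorm(2)
  for (k in 1:3)
    expect_gte(emission_prob(x, m3, 1),
               m3$w[1, k] * gaussian_pdf(x, m3$mu[1, k, ],
                                         m3$sigma[1, k, , ]))
})

test_that("forward-backward collapses correctly for degenerate chains", {
  # Q = 1: gamma identically one, loglik the sum of log emissions
  m1 <- rand_model(1, 2, 2, seed = 3)
  X <- matrix(rnorm(10), 5, 2)
  ps <- forward_backward(m1, X)
  expect_true(all(ps$gamma == 1))
  ll <- sum(vapply(1:5, function(t)
    emission_prob(X[t, ], m1, 1, log = TRUE), numeric(1)))
  expect_equal(ps$loglik, ll, tolerance = 1e-10)

  # deterministic identity chain stays in its start state
  m_id <- rand_model(2, 1, 2, seed = 4)
  m_id$a <- diag(2); m_id$pi <- c(1, 0)
  ps_id <- forward_backward(m_id, X)
  expect_true(all(ps_id$gamma[, 1] == 1))

  expect_error(forward_backward(m1, matrix(0, 2, 3)), "dimension")
})

test_that("forward-backward equals exhaustive path enumeration", {
  for (s in 1:10) {
    set.seed(s)
    Q <- sample(1:3, 1); M <- sample(1:2, 1); Tn <- sample(1:6, 1)
    m <- rand_model(Q, M, 2)
    X <- matrix(rnorm(Tn * 2), Tn, 2)
    expect_equal(forward_backward(m, X)$loglik, brute_force_loglik(m, X),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to state relabelling", {
  m <- rand_model(3, 2, 2, seed = 5)
  X <- matrix(rnorm(60), 30, 2)
  perm <- c(3, 1, 2)
  mp <- m
  mp$a <- m$a[perm, perm]; mp$pi <- m$pi[perm]
  mp$w <- m$w[perm, , drop = FALSE]
  mp$mu <- m$mu[perm, , , drop = FALSE]
  mp$sigma <- m$sigma[perm, , , , drop = FALSE]
  expect_equal(forward_backward(mp, X)$loglik,
               forward_backward(m, X)$loglik, tolerance = 1e-10)
})

test_that("a single-state single-cluster fit is the closed-form MLE", {
  sim <- simulate_hmm_features(rand_model(1, 1, 2, seed = 6), 500, seed = 6)
  X <- sim$features$x
  fit <- em_fit(sim$features, 1, 1, seed = 1, n_restarts = 1,
                scale = FALSE, max_iter = 3)
  expect_equal(drop(fit$model$mu[1, 1, ]), unname(colMeans(X)),
               tolerance = 1e-10)
  mle_cov <- unname(var(X)) * (nrow(X) - 1) / nrow(X)
  floor_d <- diag(1e-6 * pmax(apply(X, 2, var), 1e-12), 2)
  expect_equal(matrix(fit$model$sigma[1, 1, , ], 2), mle_cov + floor_d,
               tolerance = 1e-8)
})

test_that("EM recovers a known two-state model and never decreases LL", {
  gen <- two_state_model()
  sim <- simulate_hmm_features(gen, 5000, seed = 21)
  fit <- em_fit(sim$features, 2, 1, seed = 21, n_restarts = 2,
                scale = FALSE)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  perm <- align_two_state(fit$model)
  expect_lt(max(abs(fit$model$a[perm, perm] - gen$a)), 0.05)
  expect_lt(max(abs(fit$model$mu[perm, 1, ] -
                      rbind(c(0, 0), c(3, 3)))), 0.1)

  # posterior decoding matches the generating path almost everywhere
  dec <- decode(fit$model, sim$features)
  acc <- max(mean(dec$states == sim$states),
             mean(perm[dec$states] == sim$states))
  expect_gte(acc, 0.99)
})

test_that("multi-sequence EM pools statistics across recordings", {
  gen <- two_state_model()
  sims <- lapply(1:3, function(s)
    simulate_hmm_features(gen, 800, seed = 30 + s)$features)
  fit <- em_fit(sims, 2, 1, seed = 7, n_restarts = 2, scale = FALSE)
  perm <- align_two_state(fit$model)
  expect_lt(max(abs(fit$model$a[perm, perm] - gen$a)), 0.07)
  expect_error(em_fit(matrix(rnorm(4), 2, 2), 2, 2, seed = 1), "windows")
})

test_that("feature standardization is stored and reapplied", {
  gen <- two_state_model()
  sim <- simulate_hmm_features(gen, 1500, seed = 41)
  X <- sim$features$x
  X[, 1] <- X[, 1] * 100  # wildly different scales
  fit <- em_fit(feature_matrix(X), 2, 1, seed = 1, n_restarts = 2)
  expect_false(is.null(fit$model$scaler))
  dec <- decode(fit$model, feature_matrix(X))
  acc <- max(mean(dec$states == sim$states),
             mean((3 - dec$states) == sim$states))
  expect_gte(acc, 0.98)
})

test_that("models round-trip through JSON bit-exactly", {
  gen <- three_state_model()
  sim <- simulate_hmm_features(gen, 400, seed = 51)
  fit <- em_fit(sim$features, 3, 2, seed = 1, n_restarts = 1, max_iter = 30)
  p <- withr::local_tempfile(fileext = ".json")
  write_gmmhmm(fit$model, p)
  back <- read_gmmhmm(p)
  expect_identical(back$a, fit$model$a)
  expect_identical(back$mu, fit$model$mu)
  expect_identical(back$sigma, fit$model$sigma)
  expect_identical(back$scaler, fit$model$scaler)
  expect_identical(decode(back, sim$features)$states,
                   decode(fit$model, sim$features)$states)
})
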