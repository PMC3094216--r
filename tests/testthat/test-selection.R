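test_that("mRMR ranks an informative feature first", {
  set.seed(1)
  n <- 200
  target <- rep(c(0, 1), each = n / 2)
  X <- cbind(target + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 6), n, 6))
  colnames(X) <- c("informative", paste0("noise", 1:6))
  r <- mrmr_rank(X, target)
  expect_equal(r$feature[1], "informative")
  expect_true(all(r$quotient >= 0) && all(is.finite(r$quotient)))
  expect_true(all(diff(r$quotient) <= 0))
})

test_that("duplicated informative features are penalized as redundant", {
  set.seed(2)
  n <- 300
  target <- rep(c(0, 1), each = n / 2)
  base <- target + rnorm(n, sd = 0.3)
  X <- cbind(dup1 = base, dup2 = base + rnorm(n, sd = 0.01),
             indep = target + rnorm(n, sd = 0.3))
  r <- mrmr_rank(X, target)
  wc <- setNames(r$wc, r$feature)
  expect_gt(wc["dup1"], wc["indep"])
  expect_gt(wc["dup2"], wc["indep"])
  expect_equal(r$feature[1], "indep")
})

test_that("mRMR handles degenerate candidates and inputs", {
  set.seed(3)
  n <- 50
  target <- rep(c(0, 1), each = n / 2)
  single <- matrix(target + rnorm(n, sd = 0.5), ncol = 1,
                   dimnames = list(NULL, "only"))
  r1 <- mrmr_rank(single, target)
  expect_equal(r1$wc, 1)

  X <- cbind(flat = rep(2, n), ok = target + rnorm(n, sd = 0.5))
  expect_warning(r2 <- mrmr_rank(X, target), "zero-variance")
  expect_equal(r2$feature[nrow(r2)], "flat")
  expect_equal(r2$quotient[r2$feature == "flat"], 0)

  expect_error(mrmr_rank(X, rep(0, n)), "classes")
  expect_error(mrmr_rank(X[1:5, ], target[1:5]), "10")
})

test_that("mRMR is invariant to affine feature rescaling", {
  set.seed(4)
  n <- 120
  target <- rep(c(0, 1), each = n / 2)
  X <- cbind(a = target + rnorm(n, sd = 0.4), b = rnorm(n), c = rnorm(n))
  r1 <- mrmr_rank(X, target)
  X2 <- X; X2[, "a"] <- 100 * X2[, "a"] - 7
  r2 <- mrmr_rank(X2, target)
  expect_equal(r1$feature, r2$feature)
  expect_equal(r1$quotient, r2$quotient, tolerance = 1e-10)
})

test_that("AICc applies the parameter count and small-sample correction", {
  expect_equal(n_parameters(5, 3), 70)
  expect_equal(n_parameters(3, 2), 27)
  K <- n_parameters(1, 3)  # 10
  expect_equal(aicc(-100, 1, 3, 100),
               200 + 2 * K + 2 * K * (K + 1) / (100 - K - 1))
  # the correction vanishes with n
  expect_equal(aicc(-100, 1, 3, 1e9), 200 + 2 * K, tolerance = 1e-4)
  expect_error(aicc(-100, 1, 3, K + 1), "too small")
})

test_that("topology selection takes the fewest parameters under threshold", {
  entries <- data.frame(Q = c(3, 5), M = c(2, 3),
                        K = c(n_parameters(3, 2), n_parameters(5, 3)),
                        loglik = c(-500, -490),
                        aicc = c(1060.1, 1060.0))
  entries$delta_aicc <- entries$aicc - min(entries$aicc)
  expect_equal(unname(select_topology(entries)), c(3, 2))
  expect_equal(unname(select_topology(entries[2, ])), c(5, 3))

  # invariant under adding a constant to every log-likelihood
  shifted <- entries
  shifted$aicc <- shifted$aicc - 2 * 123  # LL + 123 everywhere
  shifted$delta_aicc <- shifted$aicc - min(shifted$aicc)
  expect_equal(select_topology(shifted), select_topology(entries))
})

test_that("the AICc grid has coherent entries", {
  gen <- two_state_model()
  sim <- simulate_hmm_features(gen, 900, seed = 61)
  train <- feature_matrix(sim$features$x[1:600, ])
  ev <- feature_matrix(sim$features$x[601:900, ])
  g <- grid_search(train, ev, Q_range = 1:2, M_range = 1:2, seed = 1,
                   n_restarts = 2, max_iter = 50)
  e <- g$entries
  expect_equal(e$K, 3 * e$Q * e$M + e$Q^2)
  expect_equal(sum(e$delta_aicc == 0), 1L)
  expect_true(all(e$delta_aicc >= 0))
  expect_equal(g$n, 300)

  # one-cell grid is its own optimum
  g1 <- grid_search(train, ev, Q_range = 1, M_range = 1, seed = 1,
                    n_restarts = 1, max_iter = 20)
  expect_equal(g1$entries$delta_aicc, 0)
  expect_equal(unname(select_topology(g1)), c(1, 1))

  # a larger topology does not lose training likelihood on easy data
  ll_small <- g$fits[["1.1"]]$ll_trace[g$fits[["1.1"]]$n_iter]
  ll_big <- g$fits[["2.1"]]$ll_trace[g$fits[["2.1"]]$n_iter]
  expect_gte(ll_big, ll_small - 1e-6 * abs(ll_small))
})
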