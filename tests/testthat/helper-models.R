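# model generators and an independent brute-force likelihood oracle

# random valid mixture-emission HMM
rand_model <- function(Q, M, D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(runif(Q * Q, 0.1, 1), Q)
  a <- a / rowSums(a)
  pi <- runif(Q, 0.1, 1); pi <- pi / sum(pi)
  w <- matrix(runif(Q * M, 0.2, 1), Q, M); w <- w / rowSums(w)
  mu <- array(rnorm(Q * M * D, sd = 2), c(Q, M, D))
  sigma <- array(0, c(Q, M, D, D))
  for (j in seq_len(Q)) for (k in seq_len(M)) {
    A <- matrix(rnorm(D * D), D)
    sigma[j, k, , ] <- crossprod(A) + diag(0.5, D)
  }
  gmmhmm(a, pi, w, mu, sigma)
}

# two well-separated states, single Gaussian each (D = 2)
two_state_model <- function(a_diag = c(0.9, 0.8)) {
  a <- matrix(c(a_diag[1], 1 - a_diag[1],
                1 - a_diag[2], a_diag[2]), 2, byrow = TRUE)
  mu <- array(0, c(2, 1, 2)); mu[2, 1, ] <- c(3, 3)
  sg <- array(0, c(2, 1, 2, 2))
  sg[1, 1, , ] <- diag(2); sg[2, 1, , ] <- diag(2)
  gmmhmm(a, c(0.5, 0.5), matrix(1, 2, 1), mu, sg)
}

# three states with two well-separated clusters each (D = 2)
three_state_model <- function() {
  a <- matrix(c(0.90, 0.05, 0.05,
                0.05, 0.90, 0.05,
                0.05, 0.05, 0.90), 3, byrow = TRUE)
  mu <- array(0, c(3, 2, 2))
  mu[1, 1, ] <- c(0, 0); mu[1, 2, ] <- c(2, 0)
  mu[2, 1, ] <- c(5, 5); mu[2, 2, ] <- c(7, 5)
  mu[3, 1, ] <- c(0, 8); mu[3, 2, ] <- c(2, 8)
  sg <- array(0, c(3, 2, 2, 2))
  for (j in 1:3) for (k in 1:2) sg[j, k, , ] <- diag(0.3, 2)
  gmmhmm(a, rep(1 / 3, 3), matrix(0.5, 3, 2), mu, sg)
}

# exhaustive sum over all Q^T state paths (independent of the scaled
# forward recursion under test)
brute_force_loglik <- function(model, X) {
  Q <- model$Q; Tn <- nrow(X)
  logb <- sapply(seq_len(Q), function(j) sapply(seq_len(Tn), function(t)
    emission_prob(X[t, ], model, j, log = TRUE)))
  logb <- matrix(logb, Tn, Q)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Q)), Tn)))
  lp <- apply(paths, 1L, function(p) {
    v <- log(model$pi[p[1L]]) + logb[1L, p[1L]]
    if (Tn > 1L) for (t in 2:Tn)
      v <- v + log(model$a[p[t - 1L], p[t]]) + logb[t, p[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# align a fitted 2-state model with the generating one by mean proximity
align_two_state <- function(model, true_mu1 = c(0, 0)) {
  d1 <- sum((model$mu[1, 1, ] - true_mu1)^2)
  d2 <- sum((model$mu[2, 1, ] - true_mu1)^2)
  if (d1 <= d2) 1:2 else 2:1
}

# preprocessed pure-tone record (skips the notch chain deliberately:
# amplitude already in [-1, 1], mean 0)
tone_record <- function(freq_hz, dur_s = 10, fs_hz = 1000) {
  t <- seq(0, dur_s - 1 / fs_hz, by = 1 / fs_hz)
  signal_record(sin(2 * pi * freq_hz * t), fs_hz, preprocessed = TRUE)
}
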