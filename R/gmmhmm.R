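#' Gaussian-mixture-emission hidden Markov model
#'
#' Constructs and validates a Q-state HMM whose per-state emission
#' density is an M-component multivariate Gaussian mixture,
#' \eqn{b_j(x) = \sum_k w_{jk} N(x; \mu_{jk}, \Sigma_{jk})}.
#'
#' @param a Q x Q transition matrix; rows sum to 1.
#' @param pi length-Q initial state distribution.
#' @param w Q x M mixture weights; rows sum to 1.
#' @param mu Q x M x D array of component means.
#' @param sigma Q x M x D x D array of component covariances (symmetric
#'   positive-definite).
#' @param scaler optional per-dimension feature standardization,
#'   `list(center, scale)`, stored at training time and applied to any
#'   features the model is evaluated on.
#' @param band_labels optional length-D feature names.
#' @return An object of class `gmmhmm` with fields `Q`, `M`, `D`, `a`,
#'   `pi`, `w`, `mu`, `sigma`, `scaler`, `band_labels`.
#' @export
gmmhmm <- function(a, pi, w, mu, sigma, scaler = NULL, band_labels = NULL) {
  a <- as.matrix(a)
  Q <- nrow(a)
  if (is.vector(w)) w <- matrix(w, nrow = Q)
  M <- ncol(w)
  mu <- .as_array(mu, 3L); sigma <- .as_array(sigma, 4L)
  D <- dim(mu)[3L]
  m <- structure(list(Q = Q, M = M, D = D, a = a, pi = as.numeric(pi),
                      w = as.matrix(w), mu = mu, sigma = sigma,
                      scaler = scaler, band_labels = band_labels),
                 class = "gmmhmm")
  validate_gmmhmm(m)
  m
}

.as_array <- function(x, ndim) {
  if (is.array(x) && length(dim(x)) == ndim) return(x)
  stop(sprintf("expected a %d-dimensional array", ndim))
}

#' Validate a gmmhmm model
#'
#' Checks stochasticity of `a`, `pi` and `w`, array shapes and symmetric
#' positive-definiteness of every covariance.
#'
#' @param model a [gmmhmm()].
#' @return `model`, invisibly; errors on violation.
#' @export
validate_gmmhmm <- function(model) {
  if (!inherits(model, "gmmhmm")) stop("not a gmmhmm model")
  Q <- model$Q; M <- model$M; D <- model$D
  if (Q < 1) stop("Q must be >= 1")
  if (!all(dim(model$a) == c(Q, Q))) stop("'a' must be Q x Q")
  if (any(model$a < -1e-12) || any(abs(rowSums(model$a) - 1) > 1e-8))
    stop("rows of 'a' must be non-negative and sum to 1")
  if (length(model$pi) != Q || abs(sum(model$pi) - 1) > 1e-8 ||
      any(model$pi < -1e-12))
    stop("'pi' must be a length-Q distribution")
  if (!all(dim(model$w) == c(Q, M)) ||
      any(abs(rowSums(model$w) - 1) > 1e-8) || any(model$w < -1e-12))
    stop("rows of 'w' must be non-negative and sum to 1")
  if (!all(dim(model$mu) == c(Q, M, D))) stop("'mu' must be Q x M x D")
  if (!all(dim(model$sigma) == c(Q, M, D, D)))
    stop("'sigma' must be Q x M x D x D")
  for (j in seq_len(Q)) for (k in seq_len(M)) {
    s <- matrix(model$sigma[j, k, , ], D, D)
    if (max(abs(s - t(s))) > 1e-8 * (1 + max(abs(s))))
      stop("covariance (", j, ",", k, ") is not symmetric")
    ev <- tryCatch(min(eigen(s, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -Inf)
    if (ev <= 0) stop("covariance (", j, ",", k, ") is not positive-definite")
  }
  invisible(model)
}

#' @export
print.gmmhmm <- function(x, ...) {
  cat(sprintf("gmmhmm: Q = %d states, M = %d clusters, D = %d features\n",
              x$Q, x$M, x$D))
  if (!is.null(x$band_labels))
    cat("  features:", paste(x$band_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Multivariate Gaussian density
#'
#' @param x observation vector (length D).
#' @param mu mean vector (length D).
#' @param sigma D x D symmetric positive-definite covariance.
#' @param log return the log density?
#' @return The (log) density; computed in log space via the Cholesky
#'   factor.
#' @export
gaussian_pdf <- function(x, mu, sigma, log = FALSE) {
  sigma <- as.matrix(sigma)
  L <- tryCatch(chol(sigma), error = function(e)
    stop("'sigma' is singular or not positive-definite"))
  d <- length(x)
  z <- backsolve(L, x - mu, transpose = TRUE)
  ld <- -sum(z^2) / 2 - sum(log(diag(L))) - d * log(2 * pi) / 2
  if (log) ld else exp(ld)
}

# log N(x_t; mu, sigma) for all rows of X at once, via Cholesky
.log_mvnorm_rows <- function(X, mu, sigma) {
  L <- chol(sigma)
  Xc <- sweep(X, 2L, mu)
  z <- Xc %*% backsolve(L, diag(ncol(X)))
  -rowSums(z^2) / 2 - sum(log(diag(L))) - ncol(X) * log(2 * pi) / 2
}

# apply the model's stored feature standardization
.apply_scaler <- function(model, X) {
  if (is.null(model$scaler)) return(X)
  sweep(sweep(X, 2L, model$scaler$center), 2L, model$scaler$scale, `/`)
}

# T x Q x M array of log(w_jk) + log N_jk(x_t); X already scaled
.component_logdens <- function(model, X) {
  Tn <- nrow(X)
  out <- array(0, c(Tn, model$Q, model$M))
  for (j in seq_len(model$Q)) for (k in seq_len(model$M)) {
    s <- matrix(model$sigma[j, k, , ], model$D, model$D)
    out[, j, k] <- log(model$w[j, k]) +
      .log_mvnorm_rows(X, model$mu[j, k, ], s)
  }
  out
}

# T x Q matrix of log b_j(x_t)
.emission_logmat <- function(cl) {
  Tn <- dim(cl)[1L]; Q <- dim(cl)[2L]
  out <- matrix(0, Tn, Q)
  for (j in seq_len(Q))
    out[, j] <- .row_logsumexp(matrix(cl[, j, ], Tn))
  out
}

#' Emission probability of one observation in one state
#'
#' \eqn{b_j(x) = \sum_k w_{jk} N(x; \mu_{jk}, \Sigma_{jk})}, evaluated in
#' log space.  The model's stored feature scaler, if any, is applied to
#' `x` first.
#'
#' @param x observation vector (length D, on the original feature scale).
#' @param model a [gmmhmm()].
#' @param j state index in 1..Q.
#' @param log return the log emission probability?
#' @return The (log) mixture density.
#' @export
emission_prob <- function(x, model, j, log = FALSE) {
  validate_gmmhmm(model)
  j <- as.integer(j)
  if (j < 1L || j > model$Q) stop("state index out of range")
  xs <- drop(.apply_scaler(model, matrix(x, 1L)))
  terms <- vapply(seq_len(model$M), function(k)
    log(model$w[j, k]) +
      gaussian_pdf(xs, model$mu[j, k, ],
                   matrix(model$sigma[j, k, , ], model$D, model$D),
                   log = TRUE),
    numeric(1))
  lb <- .logsumexp(terms)
  if (log) lb else exp(lb)
}

#' Forward-backward inference
#'
#' Runs the scaled forward-backward recursions and returns the full
#' posterior set: log-scale forward (`log_alpha`) and backward
#' (`log_beta`) terms, state posteriors `gamma`, transition-pair
#' posteriors `zeta`, per-cluster responsibilities `resp` and the total
#' log-likelihood.
#'
#' @param model a [gmmhmm()].
#' @param f a [feature_matrix()] or T x D matrix on the original feature
#'   scale (the model's scaler is applied internally).
#' @return An object of class `posterior_set` with fields `log_alpha`,
#'   `log_beta` (T x Q), `gamma` (T x Q, rows sum to 1), `zeta`
#'   ((T-1) x Q x Q), `resp` (T x Q x M) and `loglik`.
#' @export
forward_backward <- function(model, f) {
  validate_gmmhmm(model)
  X <- .fm_matrix(f)
  if (ncol(X) != model$D)
    stop(sprintf("feature dimension %d does not match model D = %d",
                 ncol(X), model$D))
  Xs <- .apply_scaler(model, X)
  cl <- .component_logdens(model, Xs)
  logB <- .emission_logmat(cl)
  fb <- .fb_core(logB, model$a, model$pi)

  Tn <- nrow(X); Q <- model$Q; M <- model$M
  cum <- cumsum(fb$logc)
  log_alpha <- log(fb$alpha) + cum
  log_beta <- log(fb$beta) + (fb$loglik - cum)

  resp <- array(0, c(Tn, Q, M))
  for (j in seq_len(Q)) {
    pj <- exp(cl[, j, , drop = FALSE] -
              array(logB[, j], c(Tn, 1L, M)))
    pj <- matrix(pj, Tn, M)
    pj <- pj / rowSums(pj)
    resp[, j, ] <- pj * fb$gamma[, j]
  }

  zeta <- if (Tn > 1L) aperm(fb$zeta, c(3L, 1L, 2L))
          else array(0, c(0L, Q, Q))
  structure(list(log_alpha = log_alpha, log_beta = log_beta,
                 gamma = fb$gamma, zeta = zeta, resp = resp,
                 loglik = fb$loglik),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat(sprintf("posterior_set: T = %d windows, Q = %d states, loglik = %.4f\n",
              nrow(x$gamma), ncol(x$gamma), x$loglik))
  invisible(x)
}

#' Posterior state decoding
#'
#' Decodes the most probable state per window from the marginal posterior
#' \eqn{\gamma_i(t)} (not the Viterbi path); ties break to the lowest
#' state index.
#'
#' @param model a trained [gmmhmm()].
#' @param f features as in [forward_backward()].
#' @return A list with `states` (integer trace) and `posterior` (the
#'   [forward_backward()] result).
#' @export
decode <- function(model, f) {
  ps <- forward_backward(model, f)
  list(states = max.col(ps$gamma, ties.method = "first"), posterior = ps)
}

# ---- training ---------------------------------------------------------

# k-means++ seeding of n_centers rows from X
.kmeanspp_centers <- function(X, n_centers) {
  n <- nrow(X)
  centers <- matrix(0, n_centers, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (n_centers > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (c in 2L:n_centers) {
      p <- d2 / sum(d2)
      if (any(!is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      i <- sample.int(n, 1L, prob = p)
      centers[c, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[c, ])^2))
    }
  }
  centers
}

# hierarchical seeding: k-means++/Lloyd into Q state groups, then M
# k-means++ sub-centres within each group, so the initial mean layout
# respects the state/cluster hierarchy of the model
.init_params <- function(X, Q, M, cov_type) {
  D <- ncol(X)
  state_centers <- .kmeanspp_centers(X, Q)
  if (Q > 1L) {
    km <- tryCatch(
      suppressWarnings(kmeans(X, state_centers, iter.max = 20L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && !anyNA(km$centers)) {
      state_centers <- km$centers
      grp <- km$cluster
    } else {
      d2 <- vapply(seq_len(Q), function(j)
        rowSums(sweep(X, 2L, state_centers[j, ])^2), numeric(nrow(X)))
      grp <- max.col(-matrix(d2, nrow(X)), ties.method = "first")
    }
  } else grp <- rep(1L, nrow(X))
  gcov <- var(X) + diag(1e-6 * pmax(diag(var(X)), 1e-12), D)
  floor_d <- diag(1e-4 * pmax(diag(var(X)), 1e-12), D)
  mu <- array(0, c(Q, M, D))
  sigma <- array(0, c(Q, M, D, D))
  for (j in seq_len(Q)) {
    Xj <- X[grp == j, , drop = FALSE]
    if (nrow(Xj) < 2L * M) Xj <- X
    sub <- .kmeanspp_centers(Xj, M)
    # covariances from the k-means cells so components start tight
    # enough to keep distinct responsibilities
    d2 <- vapply(seq_len(M), function(k)
      rowSums(sweep(Xj, 2L, sub[k, ])^2), numeric(nrow(Xj)))
    cell <- max.col(-matrix(d2, nrow(Xj)), ties.method = "first")
    for (k in seq_len(M)) {
      mu[j, k, ] <- sub[k, ]
      Xk <- Xj[cell == k, , drop = FALSE]
      cv <- if (nrow(Xk) > D) var(Xk) else var(Xj)
      if (anyNA(cv)) cv <- gcov
      sigma[j, k, , ] <- (cv + t(cv)) / 2 + floor_d
    }
  }
  if (cov_type == "diag")
    for (j in seq_len(Q)) for (k in seq_len(M))
      sigma[j, k, , ] <- diag(diag(matrix(sigma[j, k, , ], D, D)), D)
  a <- matrix(1, Q, Q) + matrix(runif(Q * Q, 0, 0.1), Q, Q)
  a <- a / rowSums(a)
  w <- matrix(1 / M, Q, M)
  list(a = a, pi = rep(1 / Q, Q), w = w, mu = mu, sigma = sigma)
}

#' Fit a Gaussian-mixture HMM by Baum-Welch EM
#'
#' Runs expectation-maximization from `n_restarts` seeded k-means++
#' initializations and keeps the fit with the best log-likelihood.
#' Multiple observation sequences are supported (pass a list of feature
#' matrices); per-sequence sufficient statistics are summed in the
#' M-step.  Covariances receive a diagonal floor of `cov_floor` times the
#' per-dimension data variance each M-step; a mixture component whose
#' effective weight collapses is re-seeded from a random data point.
#'
#' @param f a [feature_matrix()], T x D matrix, or list of them
#'   (multi-sequence training).
#' @param Q number of states (1..10).
#' @param M clusters per state (1..5).
#' @param seed integer seed controlling initialization.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param n_restarts number of random restarts (best LL kept).
#' @param cov_type `"full"` or `"diag"` covariances; diagonal is more
#'   stable for high-dimensional features.
#' @param scale standardize features per dimension (z-score) before
#'   fitting?  The scaler is stored in the model and re-applied whenever
#'   the model is evaluated.
#' @param cov_floor relative diagonal covariance floor.
#' @param verbose print per-iteration log-likelihoods?
#' @return An object of class `gmmhmm_fit`: `model`, `ll_trace` (one LL
#'   per EM iteration, non-decreasing), `n_iter`, `converged`, `seed`.
#' @export
em_fit <- function(f, Q, M, seed = 1, max_iter = 200, tol = 1e-4,
                   n_restarts = 5, cov_type = c("full", "diag"),
                   scale = TRUE, cov_floor = 1e-6, verbose = FALSE) {
  cov_type <- match.arg(cov_type)
  seqs <- if (is.list(f) && !inherits(f, "feature_matrix")) f else list(f)
  Xs <- lapply(seqs, .fm_matrix)
  D <- ncol(Xs[[1L]])
  if (!all(vapply(Xs, ncol, integer(1)) == D))
    stop("all sequences must have the same feature dimension")
  Tn <- sum(vapply(Xs, nrow, integer(1)))
  if (Q < 1 || Q > 10) stop("Q must be in 1..10")
  if (M < 1 || M > 5) stop("M must be in 1..5")
  if (Tn < Q * M) stop("need at least Q*M windows to fit")
  labels <- colnames(Xs[[1L]])

  pooled <- do.call(rbind, Xs)
  scaler <- NULL
  if (scale) {
    ctr <- unname(colMeans(pooled))
    scl <- unname(apply(pooled, 2L, sd))
    scl[scl <= 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    Xs <- lapply(Xs, function(X)
      sweep(sweep(X, 2L, ctr), 2L, scl, `/`))
    pooled <- do.call(rbind, Xs)
  }
  dim_var <- pmax(apply(pooled, 2L, var), 1e-12)
  floor_mat <- diag(cov_floor * dim_var, D)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- tryCatch(
      .em_run(Xs, pooled, Q, M, cov_type, floor_mat, max_iter, tol,
              verbose),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed")

  model <- gmmhmm(best$a, best$pi, best$w, best$mu, best$sigma,
                  scaler = scaler, band_labels = labels)
  structure(list(model = model, ll_trace = best$ll_trace,
                 n_iter = length(best$ll_trace),
                 converged = best$converged, seed = seed),
            class = "gmmhmm_fit")
}

#' @export
print.gmmhmm_fit <- function(x, ...) {
  cat(sprintf("gmmhmm_fit: Q = %d, M = %d, loglik = %.4f after %d iteration(s)%s\n",
              x$model$Q, x$model$M, tail(x$ll_trace, 1L), x$n_iter,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

.em_run <- function(Xs, pooled, Q, M, cov_type, floor_mat, max_iter, tol,
                    verbose) {
  D <- ncol(pooled)
  par <- .init_params(pooled, Q, M, cov_type)
  ll_trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # E-step over all sequences, accumulating sufficient statistics
    ll <- 0
    pi_acc <- numeric(Q)
    zeta_acc <- matrix(0, Q, Q)
    gamma_nolast_acc <- numeric(Q)
    r_sum <- matrix(0, Q, M)               # sum_t resp
    r_x <- array(0, c(Q, M, D))            # sum_t resp * x
    r_list <- vector("list", length(Xs))   # per-seq resp for cov update
    for (s in seq_along(Xs)) {
      X <- Xs[[s]]
      cl <- .component_logdens_par(par, X)
      logB <- .emission_logmat(cl)
      if (any(!is.finite(logB))) stop("non-finite emission log-density")
      fb <- .fb_core(logB, par$a, par$pi)
      if (!is.finite(fb$loglik)) stop("non-finite log-likelihood")
      ll <- ll + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1L, ]
      if (nrow(X) > 1L) {
        zeta_acc <- zeta_acc + apply(fb$zeta, c(1L, 2L), sum)
        gamma_nolast_acc <- gamma_nolast_acc +
          colSums(fb$gamma[-nrow(X), , drop = FALSE])
      }
      resp <- .resp_from(cl, logB, fb$gamma)
      r_list[[s]] <- resp
      for (j in seq_len(Q)) {
        rj <- matrix(resp[, j, ], nrow(X), M)
        r_sum[j, ] <- r_sum[j, ] + colSums(rj)
        r_x[j, , ] <- r_x[j, , ] + t(rj) %*% X
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("  iter %3d  LL = %.6f", it, ll))
    if (it > 1L) {
      prev <- ll_trace[it - 1L]
      if ((ll - prev) / max(abs(prev), 1) < tol) { converged <- TRUE; break }
    }

    # M-step
    par$pi <- pi_acc / sum(pi_acc)
    if (any(gamma_nolast_acc > 0)) {
      a_new <- zeta_acc / pmax(gamma_nolast_acc, 1e-300)
      a_new[gamma_nolast_acc <= 0, ] <- 1 / Q
      par$a <- a_new / rowSums(a_new)
    }
    state_tot <- rowSums(r_sum)
    for (j in seq_len(Q)) {
      if (state_tot[j] <= 0) next
      par$w[j, ] <- pmax(r_sum[j, ], 1e-300) / sum(pmax(r_sum[j, ], 1e-300))
      for (k in seq_len(M)) {
        rs <- r_sum[j, k]
        if (rs < D * 1e-8) {              # collapsed component: re-seed
          i <- sample.int(nrow(pooled), 1L)
          par$mu[j, k, ] <- pooled[i, ]
          par$sigma[j, k, , ] <- var(pooled) + floor_mat
          message(sprintf("re-seeded empty cluster (state %d, component %d)",
                          j, k))
          next
        }
        mu_new <- r_x[j, k, ] / rs
        par$mu[j, k, ] <- mu_new
        cv <- matrix(0, D, D)
        for (s in seq_along(Xs)) {
          Xc <- sweep(Xs[[s]], 2L, mu_new)
          rr <- r_list[[s]][, j, k]
          cv <- cv + crossprod(Xc * rr, Xc)
        }
        cv <- cv / rs
        if (cov_type == "diag") cv <- diag(diag(cv), D)
        par$sigma[j, k, , ] <- (cv + t(cv)) / 2 + floor_mat
      }
    }
  }
  list(a = par$a, pi = par$pi, w = par$w, mu = par$mu, sigma = par$sigma,
       ll = tail(ll_trace, 1L), ll_trace = ll_trace, converged = converged)
}

# same as .component_logdens but on a bare parameter list
.component_logdens_par <- function(par, X) {
  Q <- nrow(par$a); M <- ncol(par$w); D <- ncol(X)
  out <- array(0, c(nrow(X), Q, M))
  for (j in seq_len(Q)) for (k in seq_len(M)) {
    s <- matrix(par$sigma[j, k, , ], D, D)
    out[, j, k] <- log(par$w[j, k]) + .log_mvnorm_rows(X, par$mu[j, k, ], s)
  }
  out
}

.resp_from <- function(cl, logB, gamma) {
  Tn <- dim(cl)[1L]; Q <- dim(cl)[2L]; M <- dim(cl)[3L]
  resp <- array(0, c(Tn, Q, M))
  for (j in seq_len(Q)) {
    pj <- exp(matrix(cl[, j, ], Tn, M) - logB[, j])
    pj <- pj / rowSums(pj)
    resp[, j, ] <- pj * gamma[, j]
  }
  resp
}

# ---- serialization ----------------------------------------------------

#' Write a model to JSON
#'
#' Parameters are stored flattened with explicit dimensions at full
#' double precision, so a write/read round trip reproduces the model
#' bit-exactly.
#'
#' @param model a [gmmhmm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmmhmm <- function(model, path) {
  validate_gmmhmm(model)
  pack <- function(x) list(data = as.numeric(x), dim = dim(x))
  obj <- list(Q = model$Q, M = model$M, D = model$D,
              a = pack(model$a), pi = as.numeric(model$pi),
              w = pack(model$w), mu = pack(model$mu),
              sigma = pack(model$sigma),
              scaler = if (is.null(model$scaler)) NULL else
                list(center = as.numeric(model$scaler$center),
                     scale = as.numeric(model$scaler$scale)),
              band_labels = model$band_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path a file written by [write_gmmhmm()].
#' @return A [gmmhmm()].
#' @export
read_gmmhmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(p) array(as.numeric(p$data), dim = as.integer(p$dim))
  scaler <- NULL
  if (!is.null(obj$scaler) && length(obj$scaler))
    scaler <- list(center = as.numeric(obj$scaler$center),
                   scale = as.numeric(obj$scaler$scale))
  gmmhmm(unpack(obj$a), as.numeric(obj$pi), unpack(obj$w),
         unpack(obj$mu), unpack(obj$sigma), scaler = scaler,
         band_labels = obj$band_labels)
}
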