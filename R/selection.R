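#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by the mutual-information quotient \eqn{V_F / W_c},
#' where relevance \eqn{V_F} is the one-way ANOVA F-statistic of the
#' feature grouped by the binary target state (chronic vs rest) and
#' redundancy \eqn{W_c} is the mean absolute Pearson correlation of the
#' feature with every other candidate (defined as 1 for a single
#' candidate).  The ranking is deterministic; ties keep input order.
#'
#' @param f a [feature_matrix()] or T x D matrix (T >= 10).
#' @param target logical or 0/1 vector of length T marking the chronic
#'   state; both classes must be present.
#' @return An object of class `mrmr_result`: a data frame with columns
#'   `feature`, `vf`, `wc`, `quotient`, sorted by quotient descending.
#' @export
mrmr_rank <- function(f, target) {
  X <- .fm_matrix(f)
  if (nrow(X) < 10L) stop("need at least 10 windows")
  g <- as.integer(as.logical(target))
  if (length(g) != nrow(X)) stop("'target' must have one entry per window")
  if (length(unique(g)) < 2L)
    stop("both target classes must be present")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  D <- ncol(X)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    warning("zero-variance feature(s) ranked last: ",
            paste(colnames(X)[sds == 0], collapse = ", "))

  vf <- wc <- numeric(D)
  cm <- suppressWarnings(abs(cor(X)))
  for (m in seq_len(D)) {
    if (sds[m] == 0) { vf[m] <- 0; wc[m] <- 1; next }
    vf[m] <- unname(oneway.test(X[, m] ~ g, var.equal = TRUE)$statistic)
    if (D > 1L) {
      others <- cm[m, -m]
      others <- others[is.finite(others)]   # zero-variance partners drop
      wc[m] <- if (length(others)) mean(others) else 1
    } else wc[m] <- 1
  }
  q <- ifelse(sds == 0 | wc == 0, 0, vf / wc)
  q[!is.finite(q)] <- 0
  res <- data.frame(feature = colnames(X), vf = vf, wc = wc, quotient = q,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$quotient), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mrmr_result", "data.frame")
  res
}

#' Number of free parameters of a (Q, M) topology
#'
#' @param Q number of states.
#' @param M clusters per state.
#' @return `K = 3 * Q * M + Q^2`.
#' @export
n_parameters <- function(Q, M) 3 * Q * M + Q^2

#' Corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2K + 2K(K + 1) / (n - K - 1)` with
#' `K = 3QM + Q^2`.  The small-sample correction is always applied; it
#' vanishes as `n` grows (and matters whenever `n / K < 40`).
#'
#' @param loglik model log-likelihood on the evaluation sequence.
#' @param Q,M topology.
#' @param n evaluation-sequence size in windows; must exceed `K + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, Q, M, n) {
  K <- n_parameters(Q, M)
  if (n <= K + 1) stop(sprintf("n = %d too small for K = %d (need n > K + 1)",
                               n, K))
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit an AICc grid over HMM topologies
#'
#' Fits [em_fit()] for every `(Q, M)` combination, evaluates the
#' log-likelihood on a held-out evaluation sequence and assembles the
#' AICc table rescaled to its minimum (`delta_aicc`).  Cells whose fit
#' fails or whose `n <= K + 1` are excluded with a warning.
#'
#' @param train training features ([feature_matrix()], matrix, or list of
#'   them for multi-sequence fitting).
#' @param eval held-out evaluation features; defaults to `train` (the
#'   correction then uses the training size).
#' @param Q_range,M_range topology grids (defaults 1..10 and 1..5).
#' @param seed integer seed passed to every fit.
#' @param n_restarts EM restarts per cell.
#' @param ... further arguments to [em_fit()] (e.g. `cov_type`,
#'   `max_iter`).
#' @param verbose print per-cell progress?
#' @return An object of class `aicc_grid`: list with `entries` (data
#'   frame `Q, M, K, loglik, aicc, delta_aicc`), `n` (evaluation size)
#'   and `fits` (the per-cell [em_fit()] results, named `"Q.M"`).
#' @export
grid_search <- function(train, eval = NULL, Q_range = 1:10, M_range = 1:5,
                        seed = 1, n_restarts = 2, ..., verbose = FALSE) {
  if (is.null(eval)) eval <- train
  n_eval <- nrow(.fm_matrix(eval))
  rows <- list(); fits <- list()
  for (Q in Q_range) for (M in M_range) {
    K <- n_parameters(Q, M)
    if (n_eval <= K + 1) {
      warning(sprintf("skipping Q = %d, M = %d: n = %d <= K + 1 = %d",
                      Q, M, n_eval, K + 1))
      next
    }
    fit <- tryCatch(
      em_fit(train, Q, M, seed = seed, n_restarts = n_restarts, ...),
      error = function(e) {
        warning(sprintf("fit failed for Q = %d, M = %d: %s", Q, M,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    ll <- forward_backward(fit$model, eval)$loglik
    rows[[length(rows) + 1L]] <-
      data.frame(Q = Q, M = M, K = K, loglik = ll,
                 aicc = aicc(ll, Q, M, n_eval))
    fits[[paste(Q, M, sep = ".")]] <- fit
    if (verbose)
      message(sprintf("Q = %d, M = %d: eval LL = %.2f, AICc = %.2f",
                      Q, M, ll, tail(rows, 1L)[[1L]]$aicc))
  }
  if (!length(rows)) stop("no grid cell could be fitted")
  entries <- do.call(rbind, rows)
  entries$delta_aicc <- entries$aicc - min(entries$aicc)
  structure(list(entries = entries, n = n_eval, fits = fits),
            class = "aicc_grid")
}

#' @export
print.aicc_grid <- function(x, ...) {
  cat(sprintf("aicc_grid: %d topologies, evaluation n = %d windows\n",
              nrow(x$entries), x$n))
  print.data.frame(x$entries, digits = 6)
  invisible(x)
}

#' Select the most parsimonious near-optimal topology
#'
#' Among grid entries with `delta_aicc < threshold`, returns the one with
#' the fewest parameters `K`; ties break to smaller `Q`, then smaller
#' `M`.  The minimum-AICc entry always qualifies, so a selection always
#' exists.
#'
#' @param grid an [grid_search()] result, or its `entries` data frame.
#' @param threshold the `delta_aicc` admission threshold (default 0.25).
#' @return Named numeric `c(Q, M)`.
#' @export
select_topology <- function(grid, threshold = 0.25) {
  entries <- if (inherits(grid, "aicc_grid")) grid$entries else grid
  if (!nrow(entries)) stop("empty grid")
  cand <- entries[entries$delta_aicc < threshold, , drop = FALSE]
  cand <- cand[order(cand$K, cand$Q, cand$M), , drop = FALSE]
  c(Q = cand$Q[1L], M = cand$M[1L])
}
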