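#' Short-time maximum Lyapunov exponent (Rosenstein estimator)
#'
#' Estimates the largest Lyapunov exponent per sliding window by the
#' nearest-neighbour divergence method: delay-embed the window, pair each
#' point with its nearest neighbour outside a temporal exclusion zone
#' (one mean period), track the mean log distance of the pairs over a
#' fixed horizon and fit the slope by least squares.
#'
#' To bound the cost of the neighbour search, at most `max_points`
#' embedded points per window are used (uniform stride); the divergence
#' step is then the stride, which the returned exponent accounts for.
#'
#' @param sig a [signal_record()].
#' @param window_s window length in seconds; `NULL` treats the whole
#'   signal as one window.
#' @param embed_dim embedding dimension (default 7, suited to ~1 kHz
#'   field potentials).
#' @param delay embedding delay in samples; `NULL` picks the first
#'   zero crossing of the autocorrelation.
#' @param horizon_s divergence-tracking horizon in seconds (default
#'   0.1 s).
#' @param theiler temporal exclusion zone in samples; `NULL` uses the
#'   mean period.
#' @param max_points cap on embedded points per window.
#' @return An object of class `lyapunov_trace`: list with `times_s`
#'   (window starts), `lam` (exponent per window, 1/s; `NaN` where a
#'   window had too few points) and `params`.
#' @export
rosenstein_lyapunov <- function(sig, window_s = NULL, embed_dim = 7,
                                delay = NULL, horizon_s = 0.1,
                                theiler = NULL, max_points = 400) {
  stopifnot(inherits(sig, "signal_record"))
  x <- sig$samples; fs <- sig$fs_hz
  n <- length(x)
  win_n <- if (is.null(window_s)) n else as.integer(round(window_s * fs))
  if (win_n < 2L) stop("window too short")
  if (is.null(window_s)) window_s <- n / fs

  if (is.null(delay)) delay <- .first_acf_zero(x)
  delay <- max(1L, as.integer(delay))
  if (win_n < 10 * embed_dim * delay)
    stop("window must span at least 10 * embed_dim * delay samples")
  if (is.null(theiler)) theiler <- .mean_period(x)

  starts <- seq(1L, n - win_n + 1L, by = win_n)
  lam <- vapply(starts, function(s0) {
    .rosenstein_window(x[s0:(s0 + win_n - 1L)], fs, embed_dim, delay,
                       horizon_s, theiler, max_points)
  }, numeric(1))
  if (anyNA(lam))
    warning(sum(is.na(lam)), " window(s) had too few embedded points")
  structure(list(times_s = (starts - 1L) / fs, lam = lam,
                 params = list(window_s = window_s, embed_dim = embed_dim,
                               delay = delay, horizon_s = horizon_s,
                               theiler = theiler)),
            class = "lyapunov_trace")
}

.first_acf_zero <- function(x) {
  a <- acf(x, lag.max = min(length(x) - 1L, 1000L), plot = FALSE)$acf[, 1, 1]
  i <- which(a <= 0)
  if (!length(i)) length(a) - 1L else i[1L] - 1L
}

# mean period in samples from the mean zero-crossing rate
.mean_period <- function(x) {
  xc <- x - mean(x)
  zc <- sum(diff(sign(xc)) != 0)
  if (zc < 2L) return(length(x))
  max(1L, as.integer(round(2 * length(x) / zc)))
}

.rosenstein_window <- function(xw, fs, m, delay, horizon_s, theiler,
                               max_points) {
  n_emb <- length(xw) - (m - 1L) * delay
  if (n_emb < 4L * m) return(NaN)
  stride <- max(1L, ceiling(n_emb / max_points))
  idx <- seq(1L, n_emb, by = stride)
  np <- length(idx)
  if (np < 10L) return(NaN)
  emb <- sapply(0:(m - 1L), function(d) xw[idx + d * delay])
  if (m == 1L) emb <- matrix(emb, ncol = 1L)

  d2 <- as.matrix(stats::dist(emb))^2
  excl <- ceiling(theiler / stride)
  mask <- abs(row(d2) - col(d2)) <= excl
  d2[mask] <- Inf

  k_max <- max(1L, as.integer(round(horizon_s * fs / stride)))
  nn <- apply(d2, 1L, which.min)
  valid <- is.finite(d2[cbind(seq_len(np), nn)])

  # distances are floored at a minute fraction of the signal scale so
  # that exactly recurrent orbits (distances at machine epsilon) yield a
  # flat divergence curve instead of rounding noise
  d2_floor <- (1e-7 * max(sd(xw), .Machine$double.eps))^2
  y <- numeric(k_max + 1L)
  cnt <- integer(k_max + 1L)
  for (k in 0:k_max) {
    i <- which(valid & seq_len(np) + k <= np & nn + k <= np)
    if (!length(i)) next
    dk <- pmax(rowSums((emb[i + k, , drop = FALSE] -
                        emb[nn[i] + k, , drop = FALSE])^2), d2_floor)
    y[k + 1L] <- mean(log(dk)) / 2
    cnt[k + 1L] <- length(dk)
  }
  use <- which(cnt > 0)
  if (length(use) < 2L) return(NaN)
  ks <- (use - 1L)
  slope <- coef(lm(y[use] ~ ks))[2L]
  unname(slope) * fs / stride
}

#' @export
print.lyapunov_trace <- function(x, ...) {
  cat(sprintf("lyapunov_trace: %d window(s) of %g s, lambda in [%.3g, %.3g] 1/s\n",
              length(x$lam), x$params$window_s,
              min(x$lam, na.rm = TRUE), max(x$lam, na.rm = TRUE)))
  invisible(x)
}

#' Mark the chronic seizure interval
#'
#' Either reads the chronic onset (EcSOT) and offset directly from a
#' ground-truth annotation, or detects them on a Lyapunov trace as the
#' first sustained excursion (at least `min_run` consecutive windows) of
#' the exponent beyond its own baseline quantile band; seizure onset is
#' by default a *drop* in the exponent, reflecting the lowered complexity
#' of synchronized ictal rhythms.
#'
#' @param trace a [rosenstein_lyapunov()] trace (used when `annotations`
#'   is `NULL`).
#' @param annotations a [ground_truth()] with a chronic interval.
#' @param direction `"drop"` (default) or `"rise"`: the sense of the
#'   exponent excursion at seizure onset.
#' @param baseline_quantile quantile of the trace defining the threshold
#'   (default 0.2).
#' @param min_run minimum number of consecutive windows beyond threshold.
#' @return Named numeric `c(ecsot_s, end_s)`.
#' @export
mark_chronic_interval <- function(trace = NULL, annotations = NULL,
                                  direction = c("drop", "rise"),
                                  baseline_quantile = 0.2, min_run = 5) {
  if (!is.null(annotations)) {
    ci <- chronic_interval(annotations)
    return(c(ecsot_s = unname(ci["start_s"]), end_s = unname(ci["end_s"])))
  }
  if (is.null(trace)) stop("provide a Lyapunov trace or annotations")
  direction <- match.arg(direction)
  stopifnot(inherits(trace, "lyapunov_trace"))
  lam <- trace$lam; times <- trace$times_s
  ok <- is.finite(lam)
  # crossing threshold: midpoint between the extreme baseline quantile
  # and the median, so the rule stays robust when the ictal excursion
  # occupies a sizeable fraction of the trace
  qq <- if (direction == "drop") baseline_quantile else 1 - baseline_quantile
  thr <- (quantile(lam[ok], qq) + quantile(lam[ok], 0.5)) / 2
  beyond <- if (direction == "drop") lam < thr else lam > thr
  beyond[!ok] <- FALSE

  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values & r$lengths >= min_run)
  if (!length(on))
    stop("no sustained crossing found; annotate the chronic interval manually")
  i_on <- starts[on[1L]]
  off <- which(!r$values & r$lengths >= min_run &
               seq_along(r$values) > on[1L])
  i_off <- if (length(off)) starts[off[1L]] else length(lam) + 1L
  win <- trace$params$window_s
  c(ecsot_s = times[i_on],
    end_s = if (i_off > length(lam)) times[length(lam)] + win
            else times[i_off])
}

#' Expert-guided assignment of HMM states to electrographic stages
#'
#' Anchors the chronic seizure on the given interval: the chronic state
#' is the one with the largest mean posterior \eqn{\gamma} inside it.
#' Walking backward in time through the decoded trace from chronic
#' onset, pre-chronic states are grouped into blocks (states whose runs
#' interleave share a block) and the blocks are labelled `late_tonic`,
#' then `early_tonic`, with the earliest block `interictal`; with only
#' two pre-chronic blocks there is no early/late split and the block
#' adjacent to the chronic onset is labelled `late_tonic`; a single
#' pre-chronic block is labelled generic `tonic`.  States first appearing
#' after chronic offset become `postictal`; states never visited inherit
#' the label of their strongest transition-matrix neighbour.
#'
#' @param model a trained [gmmhmm()] (its transition matrix labels
#'   unvisited states).
#' @param decoded a [decode()] result (or a list with `states` and
#'   `posterior`).
#' @param interval chronic interval `c(start_s, end_s)` from
#'   [mark_chronic_interval()].
#' @param times_s window start times (length T); defaults to 1-s windows
#'   starting at 0.
#' @param window_s window length used when `times_s` is derived.
#' @return An object of class `state_assignment`: `mapping` (character
#'   label per state index), `chronic_state`, `groups` (states per
#'   label).
#' @export
assign_states <- function(model, decoded, interval, times_s = NULL,
                          window_s = 1) {
  states <- decoded$states
  gamma <- decoded$posterior$gamma
  Q <- ncol(gamma)
  Tn <- length(states)
  if (is.null(times_s)) times_s <- (seq_len(Tn) - 1) * window_s
  on_s <- interval[[1L]]; off_s <- interval[[2L]]
  in_chronic <- times_s >= on_s & times_s < off_s
  if (!any(in_chronic)) stop("decoded trace does not cover the chronic interval")

  mean_gamma <- colMeans(gamma[in_chronic, , drop = FALSE])
  chronic_state <- which.max(mean_gamma)
  if (Q > 1L && max(mean_gamma) < 1 / Q + 0.05)
    warning("no clearly dominant state in the chronic interval")

  mapping <- rep(NA_character_, Q)
  mapping[chronic_state] <- "chronic"

  # ---- pre-chronic blocks, walking backward from onset ----
  pre <- states[times_s < on_s]
  pre <- pre[pre != chronic_state]
  if (length(pre)) {
    r <- rle(rev(pre))$values          # run states, nearest first
    runs_of <- split(seq_along(r), r)  # run positions per state
    st <- unique(r)
    span <- t(vapply(st, function(s)
      range(runs_of[[as.character(s)]]), numeric(2)))
    ord <- order(span[, 1L])
    st <- st[ord]; span <- span[ord, , drop = FALSE]
    block_id <- integer(length(st))
    cur <- 0L; cur_end <- -Inf
    for (i in seq_along(st)) {
      if (span[i, 1L] > cur_end) cur <- cur + 1L
      block_id[i] <- cur
      cur_end <- max(cur_end, span[i, 2L])
    }
    nb <- max(block_id)
    block_label <- if (nb == 1L) "tonic"
      else if (nb == 2L) c("late_tonic", "interictal")
      else c("late_tonic", rep("early_tonic", nb - 2L), "interictal")
    for (i in seq_along(st))
      if (is.na(mapping[st[i]])) mapping[st[i]] <- block_label[block_id[i]]
  }

  # ---- post-chronic: states first appearing after offset ----
  post <- states[times_s >= off_s]
  for (s in unique(post)) if (is.na(mapping[s])) mapping[s] <- "postictal"

  # ---- unvisited states: strongest transition-matrix neighbour ----
  while (anyNA(mapping)) {
    un <- which(is.na(mapping))
    lab <- which(!is.na(mapping))
    if (!length(lab)) { mapping[un] <- "chronic"; break }
    scores <- vapply(un, function(s)
      max(model$a[s, lab] + model$a[lab, s]), numeric(1))
    s <- un[which.max(scores)]
    j <- lab[which.max(model$a[s, lab] + model$a[lab, s])]
    mapping[s] <- mapping[j]
  }

  groups <- split(seq_len(Q), mapping)
  structure(list(mapping = mapping, chronic_state = chronic_state,
                 groups = groups),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("state_assignment:\n")
  for (s in seq_along(x$mapping))
    cat(sprintf("  S%d -> %s%s\n", s, x$mapping[s],
                if (s == x$chronic_state) "  (chronic anchor)" else ""))
  invisible(x)
}

#' Label a decoded state trace
#'
#' @param assignment a [assign_states()] result.
#' @param states integer decoded state trace.
#' @return Character vector of stage labels per window.
#' @export
label_windows <- function(assignment, states) {
  stopifnot(inherits(assignment, "state_assignment"))
  assignment$mapping[states]
}
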