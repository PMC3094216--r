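#' Stage specification for the seizure-like signal generator
#'
#' Describes one electrographic stage: its duration, the relative power in
#' each of the seven frequency bands, the rate of superimposed spike
#' transients and an overall amplitude scale.
#'
#' @param label one of `"interictal"`, `"early_tonic"`, `"late_tonic"`,
#'   `"chronic"`, `"postictal"`.
#' @param duration_s stage duration in seconds (> 0).
#' @param band_power seven non-negative weights over the bands of
#'   [default_bands()] (delta ... fast ripple).
#' @param spike_rate_hz mean rate of spike transients (Poisson, >= 0).
#' @param amplitude_scale overall amplitude multiplier (> 0).
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(label, duration_s, band_power, spike_rate_hz = 0,
                       amplitude_scale = 1) {
  label <- match.arg(label, .stage_labels)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("'duration_s' must be > 0")
  band_power <- as.numeric(band_power)
  if (length(band_power) != 7L || any(band_power < 0) || !any(band_power > 0))
    stop("'band_power' must be 7 non-negative weights, not all zero")
  if (spike_rate_hz < 0) stop("'spike_rate_hz' must be >= 0")
  if (amplitude_scale <= 0) stop("'amplitude_scale' must be > 0")
  structure(list(label = label, duration_s = duration_s,
                 band_power = band_power, spike_rate_hz = spike_rate_hz,
                 amplitude_scale = amplitude_scale),
            class = "stage_spec")
}

#' Default five-stage seizure-like event recipe
#'
#' Durations follow the scale of in vitro seizure-like events: chronic
#' discharges last about 74 s on average and the tonic phase about 50 s
#' (split 30 s early / 20 s late), flanked by a 60 s interictal baseline
#' and 30 s of postictal suppression, putting the chronic onset at 110 s.
#' Band-power profiles shift from delta-dominated baseline through
#' theta/alpha tonic firing to broadband beta/gamma chronic discharge and
#' low-amplitude postictal suppression.
#'
#' @return A list of five [stage_spec()] objects.
#' @export
default_stage_recipe <- function() {
  list(
    stage_spec("interictal", 60,
               c(1.0, 0.30, 0.15, 0.10, 0.05, 0.02, 0.01),
               spike_rate_hz = 0.2, amplitude_scale = 0.5),
    stage_spec("early_tonic", 30,
               c(0.50, 0.80, 0.50, 0.25, 0.10, 0.05, 0.02),
               spike_rate_hz = 2, amplitude_scale = 0.8),
    stage_spec("late_tonic", 20,
               c(0.30, 0.50, 1.00, 0.60, 0.20, 0.08, 0.03),
               spike_rate_hz = 5, amplitude_scale = 1.0),
    stage_spec("chronic", 74,
               c(0.20, 0.40, 0.80, 1.20, 0.80, 0.30, 0.10),
               spike_rate_hz = 12, amplitude_scale = 1.8),
    stage_spec("postictal", 30,
               c(0.80, 0.20, 0.10, 0.05, 0.02, 0.01, 0.005),
               spike_rate_hz = 0.05, amplitude_scale = 0.3))
}

#' Ground-truth stage annotation
#'
#' @param stage_intervals data frame with columns `label`, `start_s`,
#'   `end_s`; intervals must be contiguous, non-overlapping and
#'   time-ordered starting at 0.
#' @param ecsot_s electrographic chronic seizure onset time in seconds;
#'   must equal the start of the chronic interval when one is present.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(stage_intervals, ecsot_s = NA_real_) {
  stopifnot(is.data.frame(stage_intervals),
            all(c("label", "start_s", "end_s") %in% names(stage_intervals)))
  si <- stage_intervals
  if (any(si$end_s <= si$start_s)) stop("intervals must have end > start")
  if (nrow(si) > 1L &&
      any(abs(si$start_s[-1L] - si$end_s[-nrow(si)]) > 1e-9))
    stop("intervals must be contiguous and time-ordered")
  chronic <- si$label == "chronic"
  if (any(chronic) && !is.na(ecsot_s) &&
      abs(ecsot_s - si$start_s[which(chronic)[1L]]) > 1e-9)
    stop("'ecsot_s' must equal the start of the chronic interval")
  structure(list(stage_intervals = si, ecsot_s = ecsot_s),
            class = "ground_truth")
}

#' Chronic interval (start, end) recorded in a ground truth
#' @param truth a [ground_truth()].
#' @return Numeric `c(start_s, end_s)` of the first chronic interval.
#' @export
chronic_interval <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  i <- which(truth$stage_intervals$label == "chronic")
  if (!length(i)) stop("no chronic interval in ground truth")
  i <- i[1L]
  c(start_s = truth$stage_intervals$start_s[i],
    end_s = truth$stage_intervals$end_s[i])
}

#' Simulate a multistage seizure-like LFP
#'
#' Concatenates one segment per stage.  Each segment is a mixture of
#' band-limited Gaussian noise (white noise band-passed per band, scaled
#' to unit RMS, mixed by the stage's `band_power` weights) plus Poisson
#' spike transients modelled as short Gabor (Morlet-like) bursts of
#' 50-150 ms, all multiplied by the stage's `amplitude_scale`.
#'
#' @param stages list of [stage_spec()]; default [default_stage_recipe()].
#' @param fs_hz sampling rate; must be at least twice the highest band
#'   edge carrying power (>= 800 Hz recommended).
#' @param seed integer seed; the output is reproducible for a fixed seed.
#' @return A list with elements `signal` (a [signal_record()], ground
#'   truth attached) and `truth` (the [ground_truth()]).
#' @export
simulate_sle_lfp <- function(stages = default_stage_recipe(), fs_hz = 1000,
                             seed = 1) {
  if (!length(stages)) stop("at least one stage is required")
  stopifnot(all(vapply(stages, inherits, logical(1), "stage_spec")))
  bands <- default_bands()
  max_edge <- max(vapply(stages, function(s)
    max(bands$high_hz[s$band_power > 0]), numeric(1)))
  if (fs_hz < 2 * max_edge)
    stop(sprintf("fs_hz = %g is below Nyquist for the requested bands (need >= %g)",
                 fs_hz, 2 * max_edge))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  segs <- lapply(stages, .simulate_stage, fs_hz = fs_hz, bands = bands)
  x <- unlist(segs, use.names = FALSE)

  durs <- vapply(stages, `[[`, numeric(1), "duration_s")
  ends <- cumsum(durs)
  si <- data.frame(label = vapply(stages, `[[`, character(1), "label"),
                   start_s = c(0, head(ends, -1L)), end_s = ends)
  ec <- if (any(si$label == "chronic"))
    si$start_s[which(si$label == "chronic")[1L]] else NA_real_
  truth <- ground_truth(si, ec)
  list(signal = signal_record(x, fs_hz, ground_truth = truth),
       truth = truth)
}

.simulate_stage <- function(stage, fs_hz, bands) {
  n <- as.integer(round(stage$duration_s * fs_hz))
  pad <- as.integer(round(fs_hz))  # settle the filters away from edges
  x <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    wgt <- stage$band_power[b]
    if (wgt <= 0) next
    lo <- bands$low_hz[b] / (fs_hz / 2)
    hi <- min(bands$high_hz[b], 0.95 * fs_hz / 2) / (fs_hz / 2)
    bf <- signal::butter(3, c(lo, hi), type = "pass")
    w <- signal::filtfilt(bf, rnorm(n + 2L * pad))
    w <- w[(pad + 1L):(pad + n)]
    s <- sd(w)
    if (s > 0) x <- x + wgt * w / s
  }
  base_sd <- sd(x)
  n_spikes <- rpois(1L, stage$spike_rate_hz * stage$duration_s)
  if (n_spikes > 0 && base_sd > 0) {
    centers <- runif(n_spikes, 0, stage$duration_s)
    for (k in seq_len(n_spikes)) {
      dur <- runif(1, 0.05, 0.15)
      f0 <- runif(1, 5, 30)
      amp <- runif(1, 2, 4) * base_sd
      half <- as.integer(round(dur * fs_hz / 2))
      tau <- (-half:half) / fs_hz
      burst <- amp * cos(2 * pi * f0 * tau) * exp(-tau^2 / (2 * (dur / 6)^2))
      c0 <- as.integer(round(centers[k] * fs_hz))
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + burst[ok]
    }
  }
  stage$amplitude_scale * x
}

#' Simulate feature sequences from a known mixture-emission HMM
#'
#' Draws a hidden state path from the model's initial distribution and
#' transition matrix, then one observation per window from the active
#' state's Gaussian mixture.  Used as the generating oracle for
#' parameter-recovery and decoding tests.
#'
#' @param model a [gmmhmm()] model.
#' @param n_windows number of windows to draw (>= 1).
#' @param seed integer seed.
#' @return A list with elements `features` (a [feature_matrix()]) and
#'   `states` (the integer state path).
#' @export
simulate_hmm_features <- function(model, n_windows, seed = 1) {
  validate_gmmhmm(model)
  n_windows <- as.integer(n_windows)
  if (n_windows < 1L) stop("'n_windows' must be >= 1")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  Q <- model$Q; M <- model$M; D <- model$D
  states <- integer(n_windows)
  states[1L] <- sample.int(Q, 1L, prob = model$pi)
  for (t in seq_len(n_windows - 1L))
    states[t + 1L] <- sample.int(Q, 1L, prob = model$a[states[t], ])
  comps <- vapply(states, function(j)
    sample.int(M, 1L, prob = model$w[j, ]), integer(1))

  x <- matrix(0, n_windows, D)
  for (j in seq_len(Q)) for (k in seq_len(M)) {
    idx <- which(states == j & comps == k)
    if (!length(idx)) next
    L <- chol(model$sigma[j, k, , , drop = TRUE])
    if (D == 1L) L <- matrix(sqrt(model$sigma[j, k, 1, 1]), 1, 1)
    z <- matrix(rnorm(length(idx) * D), length(idx), D)
    x[idx, ] <- sweep(z %*% L, 2L, model$mu[j, k, ], `+`)
  }
  colnames(x) <- if (!is.null(model$band_labels) &&
                     length(model$band_labels) == D) model$band_labels
                 else paste0("f", seq_len(D))
  list(features = feature_matrix(x), states = states)
}
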