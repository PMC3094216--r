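#' End-to-end synthetic seizure detection benchmark
#'
#' Runs the complete pipeline on simulated seizure-like events: simulate
#' `n_events` recordings from `recipe`, preprocess each, compute the
#' 7-band wavelet features plus their rate of change (14-D), fit one
#' Gaussian-mixture HMM on all events jointly (multi-sequence EM), decode
#' every event, anchor the chronic interval from the ground-truth
#' annotations, map states to stages and score the detector.
#'
#' @param n_events number of simulated seizure-like events.
#' @param seed integer seed; event `i` is simulated with `seed + i`.
#' @param Q,M HMM topology (defaults Q = 5 states, M = 3 clusters).
#' @param recipe list of [stage_spec()]s (default
#'   [default_stage_recipe()]).
#' @param fs_hz sampling rate of the simulated signals.
#' @param use_rate_of_change extend features with their first difference?
#' @param cov_type covariance structure for [em_fit()]; diagonal is the
#'   default for the 14-D feature space.
#' @param n_restarts,max_iter passed to [em_fit()].
#' @return A list with `report` (a [evaluate_detection()] result), `fit`
#'   (the [em_fit()] result), `assignment` (the [assign_states()]
#'   mapping), `features`, `decoded` and `truths`.
#' @export
run_sle_benchmark <- function(n_events = 10, seed = 1, Q = 5, M = 3,
                              recipe = default_stage_recipe(),
                              fs_hz = 1000, use_rate_of_change = TRUE,
                              cov_type = "diag", n_restarts = 3,
                              max_iter = 100) {
  feats <- vector("list", n_events)
  truths <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    sim <- simulate_sle_lfp(recipe, fs_hz = fs_hz, seed = seed + i)
    sig <- preprocess(sim$signal)
    f <- cwt_band_features(sig)
    if (use_rate_of_change) f <- append_rate_of_change(f)
    feats[[i]] <- f
    truths[[i]] <- sim$truth
  }

  fit <- em_fit(feats, Q = Q, M = M, seed = seed, cov_type = cov_type,
                n_restarts = n_restarts, max_iter = max_iter)
  decoded <- lapply(feats, function(f) decode(fit$model, f))

  interval <- mark_chronic_interval(annotations = truths[[1L]])
  assignment <- assign_states(fit$model, decoded[[1L]], interval,
                              times_s = feats[[1L]]$times_s,
                              window_s = feats[[1L]]$window_s)

  labelled <- lapply(seq_len(n_events), function(i)
    list(labels = label_windows(assignment, decoded[[i]]$states),
         times_s = feats[[i]]$times_s))
  report <- evaluate_detection(labelled, truths,
                               window_s = feats[[1L]]$window_s)

  list(report = report, fit = fit, assignment = assignment,
       features = feats, decoded = decoded, truths = truths,
       labelled = labelled)
}
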