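#' Chronic-detection sensitivity
#'
#' An event counts as detected when any window labelled `"chronic"`
#' overlaps the interval `(EcSOT, EcSOT + horizon_s]`.
#'
#' @param labels character stage label per window.
#' @param times_s window start times.
#' @param events vector of EcSOT times (one per event present in the
#'   trace); must be non-empty.
#' @param horizon_s detection horizon after onset (default 30 s).
#' @param window_s window length.
#' @return Sensitivity (TP) as a percentage in \[0, 100\].
#' @export
detection_sensitivity <- function(labels, times_s, events, horizon_s = 30,
                                  window_s = 1) {
  if (!length(events)) stop("no events given")
  detected <- vapply(events, function(e) {
    any(labels == "chronic" & times_s < e + horizon_s &
          times_s + window_s > e)
  }, logical(1))
  100 * mean(detected)
}

#' Chronic-detection specificity
#'
#' Over all windows ending at least `lead_s` before every event onset
#' (for a seizure-free trace, `events = numeric(0)`, all windows
#' qualify), the fraction not labelled `"chronic"`.
#'
#' @inheritParams detection_sensitivity
#' @param lead_s minimum lead time before any onset (default 30 s).
#' @return Specificity (TN) as a percentage in \[0, 100\].
#' @export
detection_specificity <- function(labels, times_s, events, lead_s = 30,
                                  window_s = 1) {
  qual <- rep(TRUE, length(labels))
  for (e in events) qual <- qual & (times_s + window_s <= e - lead_s)
  if (!any(qual)) stop("no qualifying pre-event windows")
  100 * mean(labels[qual] != "chronic")
}

#' Detection delay of one event
#'
#' The approximated chronic seizure onset time (AcSOT) is the first
#' chronic-labelled window start inside the detection horizon of
#' `horizon_s` either side of the EcSOT (a 1-min window centred on the
#' onset by default); the delay is `EcSOT - AcSOT`, positive when
#' detection precedes the onset.
#'
#' @param labels character stage label per window.
#' @param times_s window start times.
#' @param ecsot_s the event's electrographic chronic onset time.
#' @param horizon_s half-width of the detection horizon (default 30 s).
#' @return A list with `acsot_s` and `delta_t_s` (both `NA` when no
#'   chronic label falls in the horizon); the attribute `truncated` marks
#'   horizons cut short by the recording edge.
#' @export
detection_delay <- function(labels, times_s, ecsot_s, horizon_s = 30) {
  lo <- ecsot_s - horizon_s; hi <- ecsot_s + horizon_s
  truncated <- min(times_s) > lo || max(times_s) < hi
  inh <- which(labels == "chronic" & times_s >= lo & times_s <= hi)
  out <- if (length(inh)) {
    ac <- times_s[inh[1L]]
    list(acsot_s = ac, delta_t_s = ecsot_s - ac)
  } else list(acsot_s = NA_real_, delta_t_s = NA_real_)
  attr(out, "truncated") <- truncated
  out
}

#' Optimality index
#'
#' Combines sensitivity, specificity and the detection delay into a
#' single score in \[0, 1\]: the mean of the accuracy term
#' `(tp + tn) / 2` and the delay term `1 - min(|delta_t|, d) / d`, where
#' `d` is the chronic seizure duration.  A missed detection
#' (`delta_t = NA`) contributes a delay term of 0.  Larger is better; a
#' perfect detector (tp = tn = 1, zero delay) scores 1.
#'
#' @param tp_frac sensitivity as a fraction in \[0, 1\].
#' @param tn_frac specificity as a fraction in \[0, 1\].
#' @param delta_t_s detection delay in seconds (may be `NA`).
#' @param d_s chronic seizure duration in seconds (> 0).
#' @return The optimality index.
#' @export
optimality_index <- function(tp_frac, tn_frac, delta_t_s, d_s) {
  stopifnot(tp_frac >= 0, tp_frac <= 1, tn_frac >= 0, tn_frac <= 1)
  if (d_s <= 0) stop("'d_s' must be > 0")
  delay_term <- if (is.na(delta_t_s)) 0
                else 1 - min(abs(delta_t_s), d_s) / d_s
  ((tp_frac + tn_frac) / 2 + delay_term) / 2
}

#' Score a set of labelled events
#'
#' Computes the full detection report for one or more events, each given
#' as a labelled decoded trace plus its ground truth.  Sensitivity and
#' specificity are pooled over events; the per-event optimality index
#' uses the pooled TP/TN fractions with the event's own delay and chronic
#' duration, and the aggregate `O` is their mean.
#'
#' @param labelled list (one element per event) of lists with `labels`
#'   (stage label per window), `times_s` (window starts).
#' @param truths list of [ground_truth()] objects, parallel to
#'   `labelled`.
#' @param horizon_s detection horizon (default 30 s).
#' @param window_s window length.
#' @return An object of class `detection_report`: `per_event` data frame
#'   (`event`, `tp`, `ecsot_s`, `acsot_s`, `delta_t_s`, `d_s`,
#'   `o_index`) and `aggregate` list (`tp_pct`, `tn_pct`,
#'   `mean_delta_t_s`, `mean_o`).
#' @export
evaluate_detection <- function(labelled, truths, horizon_s = 30,
                               window_s = 1) {
  stopifnot(length(labelled) == length(truths), length(labelled) > 0)
  n_ev <- length(labelled)

  tp_flags <- logical(n_ev)
  tn_num <- tn_den <- 0
  rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    lb <- labelled[[i]]$labels; ts <- labelled[[i]]$times_s
    tr <- truths[[i]]
    ci <- chronic_interval(tr)
    e <- tr$ecsot_s
    tp_flags[i] <- detection_sensitivity(lb, ts, e, horizon_s,
                                         window_s) == 100
    qual <- ts + window_s <= e - horizon_s
    tn_num <- tn_num + sum(lb[qual] != "chronic")
    tn_den <- tn_den + sum(qual)
    dd <- detection_delay(lb, ts, e, horizon_s)
    rows[[i]] <- data.frame(event = i, tp = as.integer(tp_flags[i]),
                            ecsot_s = e, acsot_s = dd$acsot_s,
                            delta_t_s = dd$delta_t_s,
                            d_s = unname(ci["end_s"] - ci["start_s"]))
  }
  if (tn_den == 0) stop("no qualifying pre-event windows in any event")
  tp_frac <- mean(tp_flags)
  tn_frac <- tn_num / tn_den

  per_event <- do.call(rbind, rows)
  per_event$o_index <- vapply(seq_len(n_ev), function(i)
    optimality_index(tp_frac, tn_frac, per_event$delta_t_s[i],
                     per_event$d_s[i]), numeric(1))

  aggregate <- list(
    tp_pct = 100 * tp_frac,
    tn_pct = 100 * tn_frac,
    mean_delta_t_s = mean(per_event$delta_t_s, na.rm = TRUE),
    mean_o = mean(per_event$o_index))
  structure(list(per_event = per_event, aggregate = aggregate),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(paste0("detection_report (%d event(s)):\n",
                     "  sensitivity (TP) = %.1f%%\n",
                     "  specificity (TN) = %.1f%%\n",
                     "  mean delay (dT)  = %.2f s\n",
                     "  mean optimality  = %.3f\n"),
              nrow(x$per_event), a$tp_pct, a$tn_pct, a$mean_delta_t_s,
              a$mean_o))
  invisible(x)
}
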