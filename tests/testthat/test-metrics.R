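# one labelled trace covering a single event
trace_for <- function(chronic_from, chronic_to, total = 214) {
  times <- 0:(total - 1)
  labels <- rep("interictal", total)
  labels[times >= chronic_from & times < chronic_to] <- "chronic"
  list(labels = labels, times_s = times)
}

test_that("sensitivity counts detections within the 30-s horizon", {
  tr <- trace_for(110, 184)
  expect_equal(detection_sensitivity(tr$labels, tr$times_s, 110), 100)

  # two events, one detected
  times <- 0:499
  labels <- rep("interictal", 500)
  labels[times >= 100 & times < 140] <- "chronic"
  expect_equal(detection_sensitivity(labels, times, c(100, 400)), 50)

  # first chronic call 31 s after onset is a miss
  late <- trace_for(141, 184)
  expect_equal(detection_sensitivity(late$labels, late$times_s, 110), 0)
  # ... 29 s after onset is a hit
  near <- trace_for(139, 184)
  expect_equal(detection_sensitivity(near$labels, near$times_s, 110), 100)
  expect_error(detection_sensitivity(tr$labels, tr$times_s, numeric(0)),
               "no events")
})

test_that("specificity scores windows well before any onset", {
  tr <- trace_for(110, 184)
  expect_equal(detection_specificity(tr$labels, tr$times_s, 110), 100)

  # 3 early false alarms among the 79 qualifying windows
  labels <- tr$labels
  labels[c(10, 20, 30)] <- "chronic"
  qualifying <- sum(tr$times_s + 1 <= 110 - 30)
  expect_equal(detection_specificity(labels, tr$times_s, 110),
               100 * (qualifying - 3) / qualifying)

  # a seizure-free recording counts every window
  free <- rep("interictal", 100)
  expect_equal(detection_specificity(free, 0:99, numeric(0)), 100)
  expect_error(detection_specificity(free[1:10], 0:9, 20), "qualifying")
})

test_that("detection delay uses the centred one-minute horizon", {
  tr <- trace_for(105, 184)  # first chronic call 5 s early
  dd <- detection_delay(tr$labels, tr$times_s, 110)
  expect_equal(dd$delta_t_s, 5)
  expect_equal(dd$acsot_s, 105)

  exact <- trace_for(110, 184)
  expect_equal(detection_delay(exact$labels, exact$times_s, 110)$delta_t_s, 0)

  # chronic labels only outside +/-30 s are not eligible
  far <- trace_for(145, 184)
  dd_far <- detection_delay(far$labels, far$times_s, 110)
  expect_true(is.na(dd_far$delta_t_s))

  short <- trace_for(50, 80, total = 100)
  expect_true(attr(detection_delay(short$labels, short$times_s, 95),
                   "truncated"))
})

test_that("the optimality index combines accuracy and delay", {
  expect_equal(optimality_index(1, 1, 0, 74), 1)
  expect_equal(optimality_index(1, 1, 74, 74), 0.5)
  expect_equal(optimality_index(1, 1, -74, 74), 0.5)
  expect_equal(optimality_index(1, 1, NA, 74), 0.5)
  expect_equal(optimality_index(0, 0, NA, 74), 0)
  # non-increasing in |delta T|
  o <- vapply(seq(0, 74, by = 5), function(d)
    optimality_index(0.9, 0.95, d, 74), numeric(1))
  expect_true(all(diff(o) <= 0))
  expect_true(all(o >= 0 & o <= 1))
  expect_error(optimality_index(1, 1, 0, 0), "d_s")
})

test_that("a perfect decoder scores a perfect report", {
  sim <- simulate_sle_lfp(seed = 9)
  si <- sim$truth$stage_intervals
  times <- 0:213
  labels <- as.character(cut(times, breaks = c(si$start_s, 214),
                             labels = si$label, right = FALSE))
  rep1 <- evaluate_detection(list(list(labels = labels, times_s = times)),
                             list(sim$truth))
  expect_equal(rep1$aggregate$tp_pct, 100)
  expect_equal(rep1$aggregate$tn_pct, 100)
  expect_equal(rep1$aggregate$mean_delta_t_s, 0)
  expect_equal(rep1$aggregate$mean_o, 1)
})

test_that("metrics are invariant to a common time offset", {
  tr <- trace_for(105, 184)
  dd0 <- detection_delay(tr$labels, tr$times_s, 110)
  dd1 <- detection_delay(tr$labels, tr$times_s + 1000, 1110)
  expect_equal(dd0$delta_t_s, dd1$delta_t_s)
  expect_equal(detection_sensitivity(tr$labels, tr$times_s, 110),
               detection_sensitivity(tr$labels, tr$times_s + 1000, 1110))
  expect_equal(detection_specificity(tr$labels, tr$times_s, 110),
               detection_specificity(tr$labels, tr$times_s + 1000, 1110))
})
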