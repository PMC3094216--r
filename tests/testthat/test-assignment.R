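# small helper: a decoded object from a hand-written state trace
fake_decoded <- function(states, Q) {
  gamma <- matrix(0, length(states), Q)
  gamma[cbind(seq_along(states), states)] <- 1
  list(states = states, posterior = list(gamma = gamma))
}

# minimal model stand-in: only the transition matrix is consulted
fake_model <- function(a) list(a = a)

test_that("periodic signals have a much smaller exponent than noise", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  lam_sine <- rosenstein_lyapunov(signal_record(sin(2 * pi * 8 * t), fs),
                                  window_s = 10)$lam
  set.seed(1)
  lam_noise <- rosenstein_lyapunov(signal_record(rnorm(length(t)), fs),
                                   window_s = 10)$lam
  expect_true(all(lam_noise > lam_sine))
  expect_true(all(abs(lam_sine) < 0.05 * max(lam_noise)))
})

test_that("chronic marking from annotations is a pass-through", {
  sim <- simulate_sle_lfp(seed = 5)
  iv <- mark_chronic_interval(annotations = sim$truth)
  expect_equal(unname(iv["ecsot_s"]), 110)
  expect_equal(unname(iv["end_s"]), 184)
})

test_that("chronic marking detects a sustained exponent drop", {
  # constructed trace: baseline ~1, drop to ~0.1 at 110-183 s (1-s windows)
  set.seed(2)
  lam <- c(1 + 0.05 * rnorm(110), 0.1 + 0.01 * rnorm(74),
           1 + 0.05 * rnorm(30))
  trace <- structure(list(times_s = 0:213, lam = lam,
                          params = list(window_s = 1)),
                     class = "lyapunov_trace")
  iv <- mark_chronic_interval(trace)
  expect_lte(abs(iv["ecsot_s"] - 110), 3)
  expect_lte(abs(iv["end_s"] - 184), 3)

  flat <- structure(list(times_s = 0:99, lam = rep(1, 100),
                         params = list(window_s = 1)),
                    class = "lyapunov_trace")
  expect_error(mark_chronic_interval(flat), "no sustained crossing")
})

test_that("reverse-order assignment labels the stage progression", {
  # blocks A -> B -> C with the chronic interval inside C
  states <- c(rep(1L, 40), rep(2L, 30), rep(3L, 50))
  a <- diag(3) * 0.9 + 0.05
  asg <- assign_states(fake_model(a), fake_decoded(states, 3),
                       c(75, 120))
  expect_equal(asg$chronic_state, 3L)
  expect_equal(asg$mapping, c("interictal", "late_tonic", "chronic"))

  # three pre-chronic blocks split early from late tonic
  states4 <- c(rep(1L, 30), rep(2L, 20), rep(3L, 20), rep(4L, 30))
  asg4 <- assign_states(fake_model(diag(4) * 0.9 + 0.025),
                        fake_decoded(states4, 4), c(72, 100))
  expect_equal(asg4$mapping,
               c("interictal", "early_tonic", "late_tonic", "chronic"))
})

test_that("a unidirectional chain consolidates the remaining states", {
  # progression S2 (interictal) -> S4 (tonic) -> S5 (chronic) -> S1, S3
  states <- c(rep(2L, 40), rep(4L, 30), rep(5L, 50), rep(1L, 15),
              rep(3L, 15))
  a <- matrix(0.02, 5, 5); diag(a) <- 0.92
  asg <- assign_states(fake_model(a), fake_decoded(states, 5),
                       c(72, 120))
  expect_equal(asg$chronic_state, 5L)
  expect_equal(asg$mapping[4], "late_tonic")
  expect_equal(asg$mapping[2], "interictal")
  expect_equal(unname(asg$mapping[c(1, 3)]), rep("postictal", 2))
})

test_that("interleaved pre-chronic states share a consolidated block", {
  states <- c(rep(1L, 30), rep(c(2L, 3L), times = 12), rep(4L, 40))
  asg <- assign_states(fake_model(diag(4) * 0.9 + 0.025),
                       fake_decoded(states, 4), c(55, 94))
  expect_equal(asg$mapping[2], asg$mapping[3])
  expect_equal(unname(asg$mapping[2]), "late_tonic")
  expect_equal(unname(asg$mapping[1]), "interictal")
})

test_that("a single state degenerates to chronic only", {
  asg <- assign_states(fake_model(matrix(1)), fake_decoded(rep(1L, 50), 1),
                       c(10, 40))
  expect_equal(asg$mapping, "chronic")
})

test_that("assignment is equivariant under state relabelling", {
  set.seed(6)
  states <- c(rep(1L, 30), rep(2L, 25), rep(3L, 40), rep(4L, 25))
  a <- diag(4) * 0.88 + 0.03
  dec <- fake_decoded(states, 4)
  asg <- assign_states(fake_model(a), dec, c(56, 95))
  lab <- label_windows(asg, states)

  perm <- c(3L, 1L, 4L, 2L)  # new index of former state i
  states_p <- perm[states]
  a_p <- a; a_p[perm, perm] <- a
  dec_p <- fake_decoded(states_p, 4)
  asg_p <- assign_states(fake_model(a_p), dec_p, c(56, 95))
  expect_equal(label_windows(asg_p, states_p), lab)
})
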