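test_that("spikes land in half-open bins with edge ties going right", {
  tr <- spike_train("u", c(0.105, 0.112))
  b <- bin_spikes(tr, 0, c(0, 0.2), 0.01)
  expect_equal(b$counts[1, 11], 1L)   # [0.10, 0.11)
  expect_equal(b$counts[1, 12], 1L)   # [0.11, 0.12)
  expect_equal(sum(b$counts), 2L)

  edge <- bin_spikes(spike_train("u", 0.1), 0, c(0, 0.2), 0.01)
  expect_equal(edge$counts[1, 11], 1L)
  expect_equal(edge$counts[1, 10], 0L)
})

test_that("binning conserves spike counts exactly per trial", {
  set.seed(42)
  tr <- poisson_train(20, 300)
  al <- seq(5, 290, by = 3)
  b <- bin_spikes(tr, al, c(-0.5, 1.5), 0.01)
  expected <- vapply(al, function(a) {
    sum(tr$spike_times >= a - 0.5 & tr$spike_times < a + 1.5)
  }, numeric(1))
  expect_identical(rowSums(b$counts), expected)
})

test_that("grand mean count of a homogeneous Poisson unit matches expectation", {
  set.seed(7)
  tr <- poisson_train(10, 1300)
  al <- seq(5, by = 6, length.out = 200)
  b <- bin_spikes(tr, al, c(0, 1), 0.01)
  m <- mean(b$counts)
  se <- stats::sd(as.vector(b$counts)) / sqrt(length(b$counts))
  expect_lt(abs(m - 0.1), 3 * se + 1e-12)
})

test_that("windows reaching before session start are flagged partial", {
  b <- bin_spikes(spike_train("u", c(0.2, 1)), c(0.1, 5), c(-0.5, 0.5), 0.01)
  expect_equal(b$partial, c(TRUE, FALSE))
})

test_that("causal exponential smoothing preserves constants, causality and mass", {
  cc <- matrix(3L, 5, 100)
  b <- structure(list(unit_id = "u", counts = cc, bin_starts = seq(0, 0.99, 0.01),
                      align_times = 1:5, window = c(0, 1), bin_width = 0.01,
                      partial = rep(FALSE, 5)),
                 class = "binned_response")
  sm <- smooth_psth(b)
  expect_lt(max(abs(sm$rate - 300)), 1e-9)
  expect_equal(sum(sm$kernel$weights), 1)

  imp <- matrix(0L, 1, 100); imp[1, 50] <- 1L
  bi <- structure(list(unit_id = "u", counts = imp, bin_starts = seq(0, 0.99, 0.01),
                       align_times = 0, window = c(0, 1), bin_width = 0.01,
                       partial = FALSE),
                  class = "binned_response")
  si <- smooth_psth(bi)
  expect_true(all(si$rate[1:49] == 0))                   # strictly causal
  expect_true(all(diff(si$rate[50:69]) < 0))             # monotone decay
  expect_lt(abs(sum(si$rate) * 0.01 - 1), 1e-9)          # mass conserved

  expect_error(smooth_psth(bi, tau = 0), "tau")
  expect_error(smooth_psth(bi, support = 0.001), "support")
})

test_that("baseline_rate implements spikes / duration for each epoch type", {
  ev <- event_table(c("session_start", "cue_on", "cue_off", "session_end"),
                    c(0, 10, 15, 40), c("", "sucrose", "sucrose", ""))
  trl <- trial_table(1L, "sucrose", list(2:3), TRUE, FALSE)
  tr <- spike_train("u", seq(0.1, 9.9, length.out = 50))  # 50 spikes pre-session
  s <- session("b", "r", "opioid_naive", "pavlovian", list(tr), ev, trl)
  expect_equal(baseline_rate(tr, s, "pre_session"), 5.0)

  quiet <- spike_train("q", 20)
  expect_equal(baseline_rate(quiet, s, "pre_session"), 0.0)

  expect_equal(baseline_rate(tr, s, "pre_event", event_type = "cue_on"),
               sum(tr$spike_times >= 9 & tr$spike_times < 10) / 1)

  # pooled intertrial epochs of a simulated stationary unit recover its rate
  set.seed(11)
  sim <- small_pav()
  u <- sim$session$spike_trains[[3]]  # inhibited: baseline 8 Hz outside cues
  r <- baseline_rate(u, sim$session, "intertrial")
  expect_lt(abs(r - 8) / 8, 0.15)
})

test_that("phasic response recovers planted modulation and obeys definitions", {
  # stationary unit: no modulation
  set.seed(13)
  tr <- poisson_train(6, 2300)
  al <- seq(5, by = 11, length.out = 200)
  pm <- phasic_response(tr, al)
  expect_lt(abs(pm$value), 3 * pm$sem)

  # planted +6 Hz box spanning exactly the response window
  ev <- event_table(c("session_start", rep("cue_on", 200), "session_end"),
                    c(0, al, 2300), c("", rep("sucrose", 200), ""))
  params <- list(baseline_hz = 5, gamma_shape = 1,
                 bumps = list(),
                 boxes = list(list(event = "cue_on", label = NA, amp = 6,
                                   from = 0.03, to = 0.5)),
                 pauses = list(), waveform = c(p1 = 40, n1 = -90, p2 = 45,
                                               t_n1 = 0.3, spread = 0.12))
  u <- simulate_unit("bump", "canonical_phasic", ev, 2300, seed = 17, params = params)
  pb <- phasic_response(u, al)
  expect_lt(abs(pb$value - 6), 3 * pb$sem)

  # linearity: doubling the amplitude doubles the recovered value
  params2 <- params
  params2$boxes[[1]]$amp <- 12
  u2 <- simulate_unit("bump2", "canonical_phasic", ev, 2300, seed = 17, params = params2)
  p2 <- phasic_response(u2, al)
  expect_lt(abs(p2$value - 2 * pb$value), 2 * sqrt(p2$sem^2 + 4 * pb$sem^2))

  # empty response window with a 4 Hz baseline
  reg <- spike_train("r", seq(-0.999, -0.001, by = 0.25) + 10)  # 4 Hz only pre-event
  pe <- phasic_response(reg, 10)
  expect_equal(pe$value, -4.0)

  expect_error(phasic_response(tr, numeric()), "empty")
  expect_error(phasic_response(tr, c(1, 2), baseline_times = 1), "equal length")
})

test_that("windowed responses vanish off the bump support and self-subtract", {
  set.seed(19)
  al <- seq(5, by = 11, length.out = 150)
  ev <- event_table(c("session_start", rep("cue_on", 150), "session_end"),
                    c(0, al, 1700), c("", rep("sucrose", 150), ""))
  params <- list(baseline_hz = 5, gamma_shape = 1, bumps = list(),
                 boxes = list(list(event = "cue_on", label = NA, amp = 8,
                                   from = 0.18, to = 0.5)),
                 pauses = list(), waveform = c(p1 = 40, n1 = -90, p2 = 45,
                                               t_n1 = 0.3, spread = 0.12))
  u <- simulate_unit("late", "canonical_phasic", ev, 1700, seed = 23, params = params)
  det <- windowed_response(u, al, c(0.03, 0.18))
  expect_lt(abs(det), 3 * attr(det, "sem"))
  val <- windowed_response(u, al, c(0.18, 0.5))
  expect_gt(val, 5)

  # window identical to baseline window on the same alignment: exactly zero
  z <- windowed_response(u, al, c(-1, 0))
  expect_identical(unclass(z)[1], 0)
})
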