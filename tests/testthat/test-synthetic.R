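test_that("identical config and seed reproduce byte-identical session files", {
  cfg <- generator_config("pavlovian",
                          n_trials = c(sucrose = 6, remifentanil = 0, neutral = 3),
                          roster = default_unit_roster(c(canonical_phasic = 1,
                                                         inhibited = 1)),
                          pre_session_s = 20, post_session_s = 10)
  s1 <- simulate_pavlovian_session(cfg, seed = 9)$session
  s2 <- simulate_pavlovian_session(cfg, seed = 9)$session
  expect_true(isTRUE(all.equal(s1, s2, tolerance = 0)))

  d <- withr::local_tempdir()
  write_session(s1, file.path(d, "a"))
  write_session(s2, file.path(d, "b"))
  fa <- list.files(file.path(d, "a"), recursive = TRUE)
  for (f in fa) {
    expect_identical(readLines(file.path(d, "a", f)), readLines(file.path(d, "b", f)))
  }

  s3 <- simulate_pavlovian_session(cfg, seed = 10)$session
  expect_false(isTRUE(all.equal(s1$spike_trains[[1]], s3$spike_trains[[1]])))
})

test_that("every generated session passes validation", {
  expect_equal(nrow(validate_session(small_pav()$session)), 0L)
  expect_equal(nrow(validate_session(small_op()$session)), 0L)
})

test_that("trial schedules respect ratios, omission and reward laws", {
  sim <- small_pav()
  trl <- sim$session$trials
  expect_equal(sort(unique(trl$trial_type)), c("neutral", "sucrose"))
  expect_equal(sum(trl$trial_type == "sucrose"), 12L)

  # omission 0: every sucrose trial carries a reward event
  cfg0 <- generator_config("pavlovian",
                           n_trials = c(sucrose = 10, remifentanil = 0, neutral = 5),
                           omission_fraction = 0,
                           roster = default_unit_roster(c(canonical_phasic = 1)),
                           pre_session_s = 10, post_session_s = 5)
  s0 <- simulate_pavlovian_session(cfg0, seed = 2)$session
  rows <- trial_event_rows(s0$trials)
  for (i in which(s0$trials$trial_type == "sucrose")) {
    expect_true("reward_delivery" %in% s0$events$event_type[rows[[i]]])
  }

  # default omission fraction: multinomial agreement at 10% over many trials
  cfg1 <- generator_config("pavlovian",
                           n_trials = c(sucrose = 200, remifentanil = 0, neutral = 0),
                           roster = default_unit_roster(c(inhibited = 1)),
                           pre_session_s = 5, post_session_s = 5)
  s1 <- simulate_pavlovian_session(cfg1, seed = 4)$session
  p <- mean(s1$trials$omission)
  expect_lt(abs(p - 0.10), 3 * sqrt(0.1 * 0.9 / 200))
})

test_that("ITIs are drawn inside the stated ranges", {
  cfg <- generator_config("pavlovian", "opioid_exposed",
                          n_trials = c(sucrose = 8, remifentanil = 8, neutral = 4),
                          roster = default_unit_roster(c(canonical_phasic = 1)),
                          pre_session_s = 10, post_session_s = 5)
  s <- simulate_pavlovian_session(cfg, seed = 6)$session
  trl <- s$trials
  rows <- trial_event_rows(trl)
  on_times <- vapply(rows, function(r) {
    ev <- s$events[r, ]; ev$time[ev$event_type == "cue_on"][1]
  }, numeric(1))
  ord <- order(on_times)
  iti <- diff(on_times[ord]) - cfg$cue_dur_s
  prev_type <- trl$trial_type[ord][-length(ord)]
  expect_true(all(iti[prev_type == "remifentanil"] >= 110 - 1e-6 &
                    iti[prev_type == "remifentanil"] <= 320 + 1e-6))
  expect_true(all(iti[prev_type != "remifentanil"] >= 11 - 1e-6 &
                    iti[prev_type != "remifentanil"] <= 150 + 1e-6))
})

test_that("a stationary simulated unit obeys the Poisson count law", {
  ev <- event_table(c("session_start", "session_end"), c(0, 600), c("", ""))
  params <- list(baseline_hz = 5, gamma_shape = 1, bumps = list(), boxes = list(),
                 pauses = list(), waveform = c(p1 = 40, n1 = -90, p2 = 45,
                                               t_n1 = 0.3, spread = 0.12))
  n <- length(simulate_unit("pois", "canonical_phasic", ev, 600, seed = 8,
                            params = params)$spike_times)
  expect_lt(abs(n - 3000), 3 * sqrt(3000))
})

test_that("the atypical class inflates ISI variability via gamma renewal", {
  ev <- event_table(c("session_start", "session_end"), c(0, 400), c("", ""))
  p <- unit_class_params()
  cvs <- sapply(c("canonical_phasic", "atypical"), function(cl) {
    pp <- p[[cl]]; pp$bumps <- list(); pp$pauses <- list()
    u <- simulate_unit(cl, cl, ev, 400, seed = 12, params = pp)
    isi <- diff(u$spike_times)
    sd(isi) / mean(isi)
  })
  expect_lt(cvs["canonical_phasic"], 1)         # shape 1.5 regularizes
  expect_gt(cvs["atypical"], 1.2)               # shape < 1 inflates
})

test_that("the exposed gain scales baseline firing multiplicatively", {
  ev <- event_table(c("session_start", "session_end"), c(0, 500), c("", ""))
  params <- list(baseline_hz = 5, gamma_shape = 1, bumps = list(), boxes = list(),
                 pauses = list(), waveform = c(p1 = 40, n1 = -90, p2 = 45,
                                               t_n1 = 0.3, spread = 0.12))
  n1 <- length(simulate_unit("g1", "canonical_phasic", ev, 500, seed = 14,
                             gain = 1, params = params)$spike_times)
  n15 <- length(simulate_unit("g2", "canonical_phasic", ev, 500, seed = 14,
                              gain = 1.5, params = params)$spike_times)
  expect_lt(abs(n15 / n1 - 1.5), 0.15)
})

test_that("group-level contrasts reproduce the planted gain direction", {
  base_cfg <- function(group) {
    generator_config("pavlovian", group,
                     n_trials = c(sucrose = 15,
                                  remifentanil = 0, neutral = 5),
                     roster = default_unit_roster(c(canonical_phasic = 6)),
                     pre_session_s = 20, post_session_s = 10)
  }
  ok_base <- ok_amp <- logical(10)
  for (k in 1:10) {
    sn <- simulate_pavlovian_session(base_cfg("opioid_naive"), seed = 300 + k)
    se <- simulate_pavlovian_session(base_cfg("opioid_exposed"), seed = 400 + k)
    mrate <- function(sim) mean(vapply(sim$session$spike_trains, function(tr) {
      baseline_rate(tr, sim$session, "intertrial")
    }, numeric(1)))
    resp <- function(sim) {
      ev <- sim$session$events
      cues <- ev$time[ev$event_type == "cue_on" & ev$label == "sucrose"]
      # peak window where the planted bump concentrates: the most sensitive
      # amplitude readout at small trial counts
      mean(vapply(sim$session$spike_trains, function(tr) {
        unclass(windowed_response(tr, cues, c(0.05, 0.15)))[1]
      }, numeric(1)))
    }
    ok_base[k] <- mrate(se) > mrate(sn)
    ok_amp[k] <- resp(se) > resp(sn)
  }
  expect_true(all(ok_base))
  expect_true(all(ok_amp))
})

test_that("operant sessions implement the trial cascade and block-2 omission", {
  sim <- small_op()
  s <- sim$session
  rows <- trial_event_rows(s$trials)
  gt <- sim$ground_truth$trials
  for (i in seq_len(nrow(s$trials))) {
    ev <- s$events[rows[[i]], ]
    # cascade order: light, +2 s lever extension, then (if pressed) press -> cue
    expect_equal(ev$event_type[1], "light_on")
    expect_equal(ev$event_type[2], "lever_extension")
    expect_equal(ev$time[2] - ev$time[1], 2)
    if (!is.na(gt$latency[i])) {
      # event times are stored at microsecond resolution
      expect_lt(abs(ev$time[ev$event_type == "lever_press"] - ev$time[2] -
                      gt$latency[i]), 2e-6)
      expect_lt(abs(ev$time[ev$event_type == "cue_on"] -
                      ev$time[ev$event_type == "lever_press"] - 1), 2e-6)
    }
    n_rew <- sum(ev$event_type == "reward_delivery")
    if (isTRUE(gt$correct[i])) {
      expect_equal(n_rew, if (gt$block2[i]) 1L else 2L)
    } else {
      expect_equal(n_rew, 0L)
    }
  }
})

test_that("planted hazard and congruence are recovered cross-module", {
  cfg <- generator_config("operant", n_trials = c(A = 60, B = 60, C = 10),
                          press_hazard = 0.4,
                          congruence = c(A = 0.80, B = 0.95),
                          roster = default_unit_roster(c(canonical_phasic = 1)),
                          pre_session_s = 10, post_session_s = 5)
  sim <- simulate_operant_session(cfg, seed = 21)
  m <- session_behavior_measures(sim$session)
  expect_lt(abs(m$mean_hazard_0_2s - 0.4), 0.1)
  n_corr <- sum(sim$ground_truth$trials$correct[sim$ground_truth$trials$trial_type == "B"],
                na.rm = TRUE)
  expect_lt(abs(m$first_entry_congruence_B - 0.95), 3 * sqrt(0.95 * 0.05 / n_corr) + 1e-9)
  expect_lt(abs(m$first_entry_congruence_A - 0.80), 3 * sqrt(0.8 * 0.2 / n_corr) + 1e-9)
})

test_that("generator configs validate their inputs", {
  expect_error(generator_config("pavlovian", omission_fraction = 1.5), "omission")
  expect_error(default_unit_roster(c(nonsense = 3)), "unknown unit class")
  expect_error(simulate_operant_session(generator_config("pavlovian")), "operant")
})
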