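test_that("response matrix has the mode-specific window arithmetic", {
  s <- small_pav()$session
  m <- response_matrix(s, "pavlovian")
  expect_equal(ncol(m), 600L)             # (0.5 + 5.5) / 0.01
  expect_equal(nrow(m), length(s$spike_trains))

  so <- small_op()$session
  mo <- response_matrix(so, "operant")
  expect_equal(ncol(mo), 125L + 75L)      # lever-extension + reward segments
  expect_equal(as.integer(table(attr(mo, "segment"))), c(125L, 75L))
})

test_that("functional clustering recovers planted archetypes and labels all three", {
  cfg <- generator_config("pavlovian",
                          n_trials = c(sucrose = 15, remifentanil = 0, neutral = 5),
                          roster = default_unit_roster(c(canonical_phasic = 15,
                                                         sustained_excited = 15,
                                                         inhibited = 15)),
                          pre_session_s = 30, post_session_s = 10)
  sim <- simulate_pavlovian_session(cfg, seed = 11)
  mat <- response_matrix(sim$session, "pavlovian")
  ca <- cluster_functional(mat)
  expect_setequal(ca$labels, c("phasic", "excited", "inhibited"))
  map <- c(canonical_phasic = "phasic", sustained_excited = "excited",
           inhibited = "inhibited")
  recovered <- mean(ca$labels[ca$cluster] == map[sim$ground_truth$units$class])
  expect_gte(recovered, 0.95)

  # duplicated rows always co-cluster
  dup <- rbind(mat, mat[3, , drop = FALSE])
  rownames(dup) <- c(rownames(mat), "dup")
  ca2 <- cluster_functional(dup)
  expect_equal(unname(ca2$cluster["dup"]), unname(ca2$cluster[rownames(mat)[3]]))

  expect_error(cluster_functional(matrix(0.5, 10, 50)), "degenerate")
})

test_that("inhibition index endpoints are exact", {
  expect_identical(inhibition_index(4, 4), 0)
  expect_identical(inhibition_index(0, 3), -1)
  expect_identical(inhibition_index(3, 0), 1)
  expect_identical(inhibition_index(0, 0), 0)
  expect_error(inhibition_index(-1, 2), "non-negative")
})

test_that("extract_features measures peak time, ISI CV and inhibition as defined", {
  sim <- small_pav()
  s <- sim$session
  f1 <- extract_features(s$spike_trains[[1]], s, "pavlovian")  # canonical, peak 100 ms
  expect_true(f1$peak_time >= 0.05 && f1$peak_time <= 1.0)
  expect_lte(abs(f1$peak_time - 0.1), 0.021)

  # a perfectly regular pacemaker has zero ISI CV
  toy <- toy_session()
  f2 <- extract_features(toy$spike_trains[[2]], toy, "pavlovian")
  expect_equal(f2$isi_cv, 0)

  # atypical unit: delayed peak, inflated CV, sustained reward inhibition
  f4 <- extract_features(s$spike_trains[[4]], s, "pavlovian")
  expect_gt(f4$peak_time, 0.3)
  expect_gt(f4$isi_cv, f1$isi_cv)
  expect_lt(f4$inhibition, -0.3)
})

test_that("k-means refinement separates planted atypical units deterministically", {
  set.seed(5)
  f <- data.frame(unit_id = sprintf("u%02d", 1:60),
                  peak_time = c(rnorm(30, 0.10, 0.02), rnorm(30, 0.60, 0.10)),
                  isi_cv = c(rnorm(30, 0.8, 0.1), rnorm(30, 2.0, 0.3)),
                  inhibition = c(rnorm(30, 0, 0.1), rnorm(30, -0.5, 0.1)))
  flags <- refine_phasic(f, seed = 3)
  expect_gte(mean(flags == rep(c(FALSE, TRUE), each = 30)), 0.90)

  # invariant to unit ordering
  p <- sample(60)
  flags_p <- refine_phasic(f[p, ], seed = 3)
  expect_identical(unname(flags_p[match(f$unit_id, f$unit_id[p])]), unname(flags))

  # identical feature vectors: refuse an arbitrary split
  same <- f[rep(1, 10), ]
  same$unit_id <- sprintf("s%02d", 1:10)
  expect_error(refine_phasic(same, seed = 1), "degenerate|identical")

  expect_error(refine_phasic(f[1:3, ], seed = 1), "at least")
})

test_that("the exclusion cascade telescopes exactly", {
  cc <- exclusion_cascade(165, 39, 21, 6)
  expect_identical(cc$n_putative,
                   cc$n_phasic - cc$n_high_baseline - cc$n_atypical - cc$n_manual)
  expect_error(exclusion_cascade(10, 20), "exceed")
})

test_that("the full cascade is deterministic and its counts telescope", {
  sim <- small_pav()
  r1 <- classify_units(sim$session, "pavlovian", seed = 7)
  r2 <- classify_units(sim$session, "pavlovian", seed = 7)
  expect_identical(r1$units, r2$units)
  expect_identical(r1$counts, r2$counts)

  with(r1$counts, {
    expect_identical(n_units, n_screened + n_not_responsive)
    expect_identical(n_screened, n_phasic + n_excited + n_inhibited)
    expect_identical(n_phasic, n_putative + n_high_baseline + n_atypical + n_manual)
  })
  tab <- table(r1$units$reason)
  expect_identical(sum(tab), nrow(r1$units))

  # manual exclusions are honored and bookkept
  put <- r1$units$unit_id[r1$units$putative_dopamine]
  r3 <- classify_units(sim$session, "pavlovian", manual_exclusions = put[1], seed = 7)
  expect_identical(r3$counts$n_manual, 1L)
  expect_identical(r3$counts$n_putative, r1$counts$n_putative - 1L)
  expect_identical(r3$units$reason[r3$units$unit_id == put[1]], "manual")
})

test_that("waveform features follow the peak-based definitions", {
  # pure peaks: P = 30 at sample 2, N = -90 at sample 4, next positive at 6
  w <- c(0, 30, 0, -90, 0, 10, 0)
  f <- waveform_features(w, dt_ms = 0.1)
  expect_equal(f$amplitude_ratio, (30 - 90) / (30 + 90))
  expect_equal(f$half_duration, 0.2)     # samples 4 -> 6 at 0.1 ms

  # starts negative: no preceding positive peak
  f2 <- waveform_features(c(-10, -90, -20, -5, -2, -1), dt_ms = 0.1)
  expect_equal(f2$amplitude_ratio, -1)

  # no positive peak after the trough: half duration runs to waveform end
  tt <- seq(0, 1.1, by = 0.025)
  w3 <- -90 * exp(-((tt - 0.3)^2) / (2 * 0.08^2))
  expect_equal(waveform_features(w3)$half_duration, 1.1 - 0.3, tolerance = 1e-9)

  expect_error(waveform_features(rep(1, 10)), "flat")
  expect_error(waveform_features(5), "2 samples")
})

test_that("waveform k-means separates planted populations and is order-invariant", {
  set.seed(41)
  f <- data.frame(amplitude_ratio = c(rnorm(20, -0.5, 0.08), rnorm(20, 0.3, 0.08)),
                  half_duration = c(rnorm(20, 0.8, 0.05), rnorm(20, 0.25, 0.05)))
  km <- kmeans_waveform(f, seed = 2)
  expect_gte(mean(km$is_dopamine == rep(c(TRUE, FALSE), each = 20)), 0.95)

  p <- sample(40)
  km_p <- kmeans_waveform(f[p, ], seed = 2)
  expect_identical(km_p$is_dopamine[order(p)], km$is_dopamine)

  blob <- data.frame(amplitude_ratio = rep(0.1, 10), half_duration = rep(0.5, 10))
  expect_warning(kmeans_waveform(blob, seed = 1), "degenerate")
})

test_that("burst statistics implement the 80/160 ms two-threshold rule", {
  b <- burst_stats(spike_train("u", c(0, 0.05, 0.1, 0.5)))
  expect_equal(b$burst_sizes, 3L)
  expect_equal(b$pct_spikes_in_bursts, 75)

  none <- burst_stats(spike_train("u", seq(0, 10, by = 0.2)))
  expect_equal(none$n_bursts, 0L)
  expect_equal(none$pct_spikes_in_bursts, 0)

  # halving all rates can only reduce burst membership: every burst spike of
  # the slowed train is a burst spike of the original (a long burst may split,
  # so the burst *count* is not monotone, but spikes in bursts are)
  set.seed(43)
  ts <- cumsum(rexp(500, 12))
  b1 <- burst_stats(spike_train("u", ts))
  b2 <- burst_stats(spike_train("u", ts * 2))
  expect_lte(sum(b2$burst_sizes), sum(b1$burst_sizes))
  expect_lte(b2$pct_spikes_in_bursts, b1$pct_spikes_in_bursts)

  expect_equal(burst_stats(spike_train("u", 1))$n_bursts, 0L)
})
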