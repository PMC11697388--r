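# Shared fixtures. Expensive simulations are built lazily once per test run
# and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# hand-built minimal Pavlovian-style session: 2 units, 3 trials
toy_session <- function() {
  ev <- event_table(
    event_type = c("session_start", "cue_on", "cue_off", "reward_delivery",
                   "cue_on", "cue_off", "reward_delivery",
                   "cue_on", "cue_off", "session_end"),
    time = c(0, 10, 15, 15, 40, 45, 45, 70, 75, 100),
    label = c("", "sucrose", "sucrose", "sucrose",
              "sucrose", "sucrose", "sucrose",
              "neutral", "neutral", ""))
  trl <- trial_table(trial_id = 1:3,
                     trial_type = c("sucrose", "sucrose", "neutral"),
                     event_rows = list(2:4, 5:7, 8:9),
                     rewarded = c(TRUE, TRUE, FALSE),
                     omission = c(FALSE, FALSE, FALSE))
  u1 <- spike_train("t01", sort(round(runif(300, 0, 100), 6)),
                    waveform = c(0, 5, 30, 5, -90, -40, 0, 10, 5, 0))
  u2 <- spike_train("t02", seq(0.5, 99.5, by = 0.2))  # 5 Hz pacemaker
  session("toy", "rat_toy", "opioid_naive", "pavlovian",
          spike_trains = list(u1, u2), events = ev, trials = trl)
}

# small Pavlovian simulation used across modules
small_pav <- function() cached("small_pav", {
  cfg <- generator_config("pavlovian",
                          n_trials = c(sucrose = 12, remifentanil = 0, neutral = 6),
                          roster = default_unit_roster(c(canonical_phasic = 2,
                                                         inhibited = 1, atypical = 1)),
                          pre_session_s = 30, post_session_s = 10)
  simulate_pavlovian_session(cfg, seed = 3)
})

# small operant simulation
small_op <- function() cached("small_op", {
  cfg <- generator_config("operant", "opioid_exposed",
                          n_trials = c(A = 12, B = 12, C = 6),
                          roster = default_unit_roster(c(canonical_phasic = 2,
                                                         sustained_excited = 1,
                                                         inhibited = 1)),
                          pre_session_s = 20, post_session_s = 10)
  simulate_operant_session(cfg, seed = 5)
})

# the default 200-unit roster session and its classification (the reference
# study conditions; fixed seed)
roster_sim <- function() cached("roster_sim", {
  simulate_pavlovian_session(generator_config("pavlovian"), seed = 101)
})

roster_report <- function() cached("roster_report", {
  classify_units(roster_sim()$session, "pavlovian", seed = 101)
})

# map a classification report row to the planted-class vocabulary
predicted_class <- function(units) {
  ifelse(units$reason == "none", "canonical_phasic",
  ifelse(units$reason == "high_baseline", "high_baseline",
  ifelse(units$reason == "atypical_kmeans", "atypical",
  ifelse(!is.na(units$cluster_label) & units$cluster_label == "excited", "sustained_excited",
  ifelse(!is.na(units$cluster_label) & units$cluster_label == "inhibited", "inhibited",
         "not_responsive")))))
}

balanced_accuracy <- function(planted, predicted) {
  mean(vapply(unique(planted), function(cl) {
    mean(predicted[planted == cl] == cl)
  }, numeric(1)))
}

# brute-force all-pairs auROC oracle
auroc_oracle <- function(test, base) {
  wins <- 0
  for (x in test) for (y in base) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  wins / (length(test) * length(base))
}

# homogeneous Poisson spike train on [0, t_end]
poisson_train <- function(rate, t_end, id = "p") {
  ts <- cumsum(rexp(ceiling(rate * t_end * 1.5) + 50, rate))
  spike_train(id, ts[ts < t_end])
}
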