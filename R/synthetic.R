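# Synthetic session generator with planted ground truth.
#
# Spiking is simulated as a time-rescaled gamma-renewal process on top of an
# inhomogeneous rate function: constant baseline plus additive event-locked
# Gaussian bumps and box kernels, and multiplicative pauses, floored at zero.
# Gamma shape 1 gives an inhomogeneous Poisson process; shape < 1 inflates
# the ISI CV (labile firing), shape > 1 regularizes it. Opioid-exposed gain
# multiplies baseline rates and bump amplitudes.

UNIT_CLASSES <- c("canonical_phasic", "sustained_excited", "inhibited",
                  "atypical", "high_baseline")

#' Default parameters for each planted unit class
#'
#' `bumps` are additive Gaussian rate kernels `(event_type, label, amp_hz,
#' latency_s, sd_s)`; `boxes` additive box kernels `(event_type, label,
#' amp_hz, from_s, to_s)`; `pauses` multiplicative `(event_type, label,
#' factor, from_s, to_s)`. A label of NA matches any event of the type.
#'
#' @return named list of per-class parameter lists.
#' @export
unit_class_params <- function() {
  g <- function(ev, lab, amp, lat, sd) list(event = ev, label = lab, amp = amp,
                                            latency = lat, sd = sd)
  bx <- function(ev, lab, amp, from, to) list(event = ev, label = lab, amp = amp,
                                              from = from, to = to)
  pz <- function(ev, lab, fac, from, to) list(event = ev, label = lab, factor = fac,
                                              from = from, to = to)
  phasic_bumps <- list(
    g("cue_on", "sucrose", 25, 0.10, 0.03),
    g("cue_on", "remifentanil", 25, 0.10, 0.03),
    g("cue_on", "neutral", 8, 0.10, 0.03),
    g("reward_delivery", NA, 20, 0.10, 0.05),
    g("lever_extension", NA, 25, 0.10, 0.03),
    g("cue_on", "A", 18, 0.10, 0.03),
    g("cue_on", "B", 18, 0.10, 0.03),
    g("cue_on", "C", 14, 0.10, 0.03),
    g("light_on", NA, 15, 0.10, 0.03))
  # high-baseline units carry canonical-shaped responses scaled up with
  # their tonic rate so they remain clearly cue-responsive
  hb_bumps <- lapply(phasic_bumps, function(k) { k$amp <- 1.4 * k$amp; k })
  list(
    canonical_phasic = list(baseline_hz = 5, gamma_shape = 1.5,
                            bumps = phasic_bumps, boxes = list(), pauses = list(),
                            waveform = c(p1 = 40, n1 = -90, p2 = 45, t_n1 = 0.30, spread = 0.12)),
    sustained_excited = list(baseline_hz = 6, gamma_shape = 1,
                             bumps = list(),
                             boxes = list(bx("cue_on", NA, 8, 0, 5),
                                          bx("lever_extension", NA, 8, 0, 1)),
                             pauses = list(),
                             waveform = c(p1 = 60, n1 = -80, p2 = 20, t_n1 = 0.15, spread = 0.05)),
    inhibited = list(baseline_hz = 8, gamma_shape = 1,
                     bumps = list(), boxes = list(),
                     pauses = list(pz("cue_on", NA, 0.15, 0, 5),
                                   pz("lever_extension", NA, 0.15, 0, 1)),
                     waveform = c(p1 = 70, n1 = -75, p2 = 15, t_n1 = 0.125, spread = 0.045)),
    atypical = list(baseline_hz = 5, gamma_shape = 0.45,
                    bumps = list(g("cue_on", NA, 15, 0.60, 0.25),
                                 g("lever_extension", NA, 15, 0.60, 0.25)),
                    boxes = list(),
                    pauses = list(pz("reward_delivery", NA, 0.15, 0, 2)),
                    waveform = c(p1 = 35, n1 = -85, p2 = 40, t_n1 = 0.30, spread = 0.12)),
    high_baseline = list(baseline_hz = 18, gamma_shape = 1,
                         bumps = hb_bumps, boxes = list(), pauses = list(),
                         waveform = c(p1 = 55, n1 = -85, p2 = 18, t_n1 = 0.15, spread = 0.05)))
}

#' Default unit roster
#'
#' The 200-unit reference population: 60 canonical phasic, 40 sustained
#' excited, 30 inhibited, 30 atypical, 40 high-baseline (canonical-shaped)
#' units.
#'
#' @param counts named integer vector over the unit classes.
#' @return data.frame `unit_id`, `class`.
#' @export
default_unit_roster <- function(counts = c(canonical_phasic = 60,
                                           sustained_excited = 40,
                                           inhibited = 30, atypical = 30,
                                           high_baseline = 40)) {
  bad <- setdiff(names(counts), UNIT_CLASSES)
  if (length(bad)) stop("unknown unit class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  cls <- rep(names(counts), counts)
  data.frame(unit_id = sprintf("u%03d", seq_along(cls)), class = cls,
             stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defaults mirror the task structure: Pavlovian sessions with three 5-s
#' cues in a 2:2:1 remifentanil:sucrose:neutral ratio, intertrial intervals
#' drawn uniformly from 11-150 s (post sucrose/neutral) or 110-320 s (post
#' remifentanil), and 10% reward omission; operant sessions with trial light
#' -> +2 s lever extension -> press (geometric latency over 100-ms bins,
#' censored at 10 s) -> +1 s auditory cue -> decision port entry -> light
#' cue -> dual water reward (single reward in block 2).
#'
#' @param experiment `"pavlovian"` or `"operant"`.
#' @param group `"opioid_naive"` or `"opioid_exposed"`.
#' @param n_trials named vector of trial counts per type. Pavlovian default
#'   `c(sucrose = 40, remifentanil = 40, neutral = 20)` (remifentanil trials
#'   are dropped for naive sessions); operant default `c(A = 24, B = 24,
#'   C = 12)`.
#' @param omission_fraction reward-omission probability (default 0.10).
#' @param roster data.frame `unit_id`, `class` (default [default_unit_roster()]).
#' @param gain_exposed multiplier on baseline rates and bump amplitudes for
#'   opioid-exposed sessions (default 1.3).
#' @param press_hazard per-100-ms lever-press hazard (default 0.35 exposed,
#'   0.20 naive).
#' @param congruence anticipatory (during-cue) entry congruence probability
#'   per cue; default exposed `c(A = 0.80, B = 0.95)`, naive
#'   `c(A = 0.85, B = 0.85)`.
#' @param decision_accuracy probability the post-cue decision entry is on the
#'   correct side; default exposed `c(A = 0.90, B = 0.95)`, naive
#'   `c(A = 0.90, B = 0.90)`.
#' @param block2_fraction fraction of trials run in block 2 (second reward
#'   omitted; default 0.5).
#' @param pre_session_s,post_session_s padding around the trial block.
#' @param cue_dur_s cue duration: 5 s Pavlovian, 2 s operant auditory cue.
#' @param unit_params per-class parameter overrides (see
#'   [unit_class_params()]).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(experiment = c("pavlovian", "operant"),
                             group = c("opioid_naive", "opioid_exposed"),
                             n_trials = NULL,
                             omission_fraction = 0.10,
                             roster = default_unit_roster(),
                             gain_exposed = 1.3,
                             press_hazard = NULL,
                             congruence = NULL,
                             decision_accuracy = NULL,
                             block2_fraction = 0.5,
                             pre_session_s = 120, post_session_s = 60,
                             cue_dur_s = NULL,
                             unit_params = unit_class_params()) {
  experiment <- match.arg(experiment)
  group <- match.arg(group)
  exposed <- group == "opioid_exposed"
  if (is.null(n_trials)) {
    n_trials <- if (experiment == "pavlovian") {
      c(sucrose = 40, remifentanil = if (exposed) 40 else 0, neutral = 20)
    } else c(A = 24, B = 24, C = 12)
  }
  if (omission_fraction < 0 || omission_fraction > 1) {
    stop("omission_fraction must be in [0, 1]", call. = FALSE)
  }
  cfg <- list(experiment = experiment, group = group, n_trials = n_trials,
              omission_fraction = omission_fraction, roster = roster,
              gain = if (exposed) gain_exposed else 1,
              press_hazard = press_hazard %||% (if (exposed) 0.35 else 0.20),
              congruence = congruence %||%
                (if (exposed) c(A = 0.80, B = 0.95) else c(A = 0.85, B = 0.85)),
              decision_accuracy = decision_accuracy %||%
                (if (exposed) c(A = 0.90, B = 0.95) else c(A = 0.90, B = 0.90)),
              block2_fraction = block2_fraction,
              pre_session_s = pre_session_s, post_session_s = post_session_s,
              cue_dur_s = cue_dur_s %||% (if (experiment == "pavlovian") 5 else 2),
              iti_short = c(11, 150), iti_drug = c(110, 320),
              unit_params = unit_params)
  class(cfg) <- "generator_config"
  cfg
}

# ---- spiking ----------------------------------------------------------------

# rate function on a regular grid from baseline + event kernels
build_rate <- function(params, events, t_end, gain = 1, dt = 0.005) {
  n <- as.integer(ceiling(t_end / dt)) + 1L
  tg <- (seq_len(n) - 1L) * dt
  rate <- rep(params$baseline_hz * gain, n)
  pick <- function(k) {
    sel <- events$event_type == k$event
    if (!is.na(k$label)) sel <- sel & events$label == k$label
    events$time[sel]
  }
  for (k in params$bumps) {
    for (e in pick(k)) {
      lo <- max(1L, as.integer(floor((e + k$latency - 4 * k$sd) / dt)) + 1L)
      hi <- min(n, as.integer(ceiling((e + k$latency + 4 * k$sd) / dt)) + 1L)
      if (hi < lo) next
      idx <- lo:hi
      rate[idx] <- rate[idx] + gain * k$amp * exp(-((tg[idx] - e - k$latency)^2) / (2 * k$sd^2))
    }
  }
  for (k in params$boxes) {
    for (e in pick(k)) {
      lo <- max(1L, as.integer(floor((e + k$from) / dt)) + 1L)
      hi <- min(n, as.integer(ceiling((e + k$to) / dt)) + 1L)
      if (hi >= lo) rate[lo:hi] <- rate[lo:hi] + gain * k$amp
    }
  }
  for (k in params$pauses) {
    for (e in pick(k)) {
      lo <- max(1L, as.integer(floor((e + k$from) / dt)) + 1L)
      hi <- min(n, as.integer(ceiling((e + k$to) / dt)) + 1L)
      if (hi >= lo) rate[lo:hi] <- rate[lo:hi] * k$factor
    }
  }
  neg <- rate < 0
  if (any(neg)) {
    warning("rate floored at 0 for ", sum(neg), " grid points")
    rate[neg] <- 0
  }
  list(t = tg, rate = pmax(rate, 1e-9), dt = dt)
}

# time-rescaled gamma-renewal spike times on [0, t_end]
sample_renewal <- function(rate_grid, gamma_shape) {
  r <- rate_grid$rate
  dt <- rate_grid$dt
  lam <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
  total <- lam[length(lam)]
  n_guess <- as.integer(ceiling(total + 4 * sqrt(total / gamma_shape) + 20))
  incr <- stats::rgamma(n_guess, shape = gamma_shape, rate = gamma_shape)
  targets <- cumsum(incr)
  while (targets[length(targets)] < total) {
    incr <- stats::rgamma(n_guess, shape = gamma_shape, rate = gamma_shape)
    targets <- c(targets, targets[length(targets)] + cumsum(incr))
  }
  targets <- targets[targets < total]
  if (!length(targets)) return(numeric())
  ts <- stats::approx(lam, rate_grid$t, xout = targets, ties = "ordered")$y
  ts <- round_us(ts)
  ts[c(TRUE, diff(ts) > 0)]
}

#' Simulate one unit's spike train
#'
#' @param unit_id unit identifier.
#' @param class one of the planted unit classes (see [unit_class_params()]).
#' @param events session event table driving the rate kernels.
#' @param t_end session end time (s).
#' @param seed integer seed (each unit derives its own stream).
#' @param gain group gain multiplier on baseline and bump amplitudes.
#' @param params optional parameter override for the class.
#' @return a [spike_train()] with a synthetic class-typical mean waveform.
#' @export
simulate_unit <- function(unit_id, class, events, t_end, seed = 1, gain = 1,
                          params = NULL) {
  class <- match.arg(class, UNIT_CLASSES)
  params <- params %||% unit_class_params()[[class]]
  set.seed(derive_seed(seed, unit_id))
  rg <- build_rate(params, events, t_end, gain)
  ts <- sample_renewal(rg, params$gamma_shape)
  ts <- ts[ts < t_end]   # the rate grid overhangs t_end by up to one step
  wf <- synth_waveform(params$waveform)
  spike_train(unit_id, ts, waveform = wf, wf_dt_ms = 0.025, channel_id = unit_id)
}

# parametric biphasic mean waveform (44 samples @ 25 us = 1.1 ms) with a
# touch of seeded jitter so units within a class are not identical
synth_waveform <- function(p, n = 44L, dt_ms = 0.025) {
  tt <- (seq_len(n) - 1L) * dt_ms
  jit <- stats::rnorm(4, 0, 0.03)
  t_n1 <- p[["t_n1"]] * (1 + jit[1])
  spread <- p[["spread"]] * (1 + jit[2])
  w <- p[["p1"]] * (1 + jit[3]) * exp(-((tt - t_n1 + 2 * spread)^2) / (2 * (0.6 * spread)^2)) +
    p[["n1"]] * exp(-((tt - t_n1)^2) / (2 * (0.8 * spread)^2)) +
    p[["p2"]] * (1 + jit[4]) * exp(-((tt - t_n1 - 2.5 * spread)^2) / (2 * (1.6 * spread)^2))
  round(w, 3)
}

# ---- Pavlovian sessions -----------------------------------------------------

#' Simulate a Pavlovian session with planted ground truth
#'
#' @param config a [generator_config()] with `experiment = "pavlovian"`.
#' @param seed integer seed; identical config + seed reproduce the session
#'   exactly (file-level determinism).
#' @return list: `session` (a [session()]), `ground_truth` (per-unit planted
#'   classes and parameters, per-trial planted draws, config echo).
#' @export
simulate_pavlovian_session <- function(config = generator_config("pavlovian"), seed = 1) {
  stopifnot(inherits(config, "generator_config"), config$experiment == "pavlovian")
  set.seed(derive_seed(seed, "schedule"))
  nt <- config$n_trials
  types <- sample(rep(names(nt), nt))
  cue_dur <- config$cue_dur_s

  ev <- list()
  push <- function(type, time, label = "") {
    ev[[length(ev) + 1L]] <<- list(event_type = type, time = round_us(time), label = label)
    length(ev)
  }
  push("session_start", 0)
  t <- config$pre_session_s
  trials <- list()
  occupancy <- list()   # collected (entry, exit) bouts, already sequential
  for (i in seq_along(types)) {
    ty <- types[i]
    rows <- integer()
    rows <- c(rows, push("cue_on", t, ty))
    omitted <- ty != "neutral" && stats::runif(1) < config$omission_fraction
    if (ty == "remifentanil" && !omitted) rows <- c(rows, push("infusion_on", t, ty))
    # anticipatory well entry during the cue
    p_entry <- c(sucrose = 0.9, remifentanil = 0.25, neutral = 0.2)[[ty]]
    entered <- stats::runif(1) < p_entry
    if (entered) {
      ent <- t + stats::runif(1, 0.3, cue_dur - 1)
      stay <- stats::runif(1, 0.8, min(2, cue_dur + 1))
      rows <- c(rows, push("port_entry", ent, "well"))
      rows <- c(rows, push("port_exit", ent + stay, "well"))
    }
    rows <- c(rows, push("cue_off", t + cue_dur, ty))
    if (ty == "sucrose" && !omitted) rows <- c(rows, push("reward_delivery", t + cue_dur, ty))
    # order trial event references by time
    times_of <- vapply(rows, function(r) ev[[r]]$time, numeric(1))
    rows <- rows[order(times_of)]
    trials[[i]] <- list(trial_id = i, trial_type = ty, event_rows = rows,
                        rewarded = ty != "neutral" && !omitted,
                        omission = omitted, entered = entered)
    iti <- if (ty == "remifentanil") stats::runif(1, config$iti_drug[1], config$iti_drug[2])
           else stats::runif(1, config$iti_short[1], config$iti_short[2])
    t <- t + cue_dur + iti
  }
  t_end <- t + config$post_session_s
  push("session_end", t_end)
  events <- event_table(vapply(ev, `[[`, "", "event_type"),
                        vapply(ev, `[[`, 0, "time"),
                        vapply(ev, `[[`, "", "label"))
  trl <- trial_table(trial_id = vapply(trials, `[[`, 0L, "trial_id"),
                     trial_type = vapply(trials, `[[`, "", "trial_type"),
                     event_rows = lapply(trials, `[[`, "event_rows"),
                     rewarded = vapply(trials, `[[`, FALSE, "rewarded"),
                     omission = vapply(trials, `[[`, FALSE, "omission"))
  trains <- lapply(seq_len(nrow(config$roster)), function(j) {
    simulate_unit(config$roster$unit_id[j], config$roster$class[j], events,
                  t_end, seed = seed, gain = config$gain,
                  params = config$unit_params[[config$roster$class[j]]])
  })
  ses <- session(session_id = sprintf("sim_pav_s%d", seed),
                 subject_id = sprintf("rat_sim%d", seed),
                 group = config$group, experiment = "pavlovian",
                 spike_trains = trains, events = events, trials = trl)
  gt <- list(units = cbind(config$roster, gain = config$gain),
             trials = data.frame(trial_id = trl$trial_id, trial_type = trl$trial_type,
                                 omission = trl$omission,
                                 entered = vapply(trials, `[[`, FALSE, "entered")),
             config = config, seed = seed)
  list(session = ses, ground_truth = gt)
}

# ---- operant sessions -------------------------------------------------------

# geometric press latency over 100-ms bins with hazard h, censored at 10 s
draw_press_latency <- function(h, censor = 10, bin = 0.1) {
  k <- stats::rgeom(1, h)   # number of failure bins before the press bin
  lat <- (k + stats::runif(1)) * bin
  if (lat >= censor) NA_real_ else lat
}

#' Simulate an operant session with planted ground truth
#'
#' Each trial: trial light, +2 s lever extension, press latency drawn from
#' the configured per-100-ms hazard (censored at 10 s: no-response trial),
#' +1 s one of three auditory cues (2:2:1 A:B:C), an anticipatory port entry
#' during the cue whose side follows the planted congruence probability, a
#' post-cue decision entry whose correctness follows the planted decision
#' accuracy, then light cue and dual water reward (the second reward omitted
#' in block-2 trials). Cue A pays at the left port, cue B at the right.
#'
#' @inheritParams simulate_pavlovian_session
#' @param config a [generator_config()] with `experiment = "operant"`.
#' @export
simulate_operant_session <- function(config = generator_config("operant"), seed = 1) {
  stopifnot(inherits(config, "generator_config"), config$experiment == "operant")
  set.seed(derive_seed(seed, "schedule"))
  nt <- config$n_trials
  types <- sample(rep(names(nt), nt))
  cue_dur <- config$cue_dur_s
  sides <- list(A = "left", B = "right")
  n_block1 <- as.integer(round(length(types) * (1 - config$block2_fraction)))

  ev <- list()
  push <- function(type, time, label = "") {
    ev[[length(ev) + 1L]] <<- list(event_type = type, time = round_us(time), label = label)
    length(ev)
  }
  push("session_start", 0)
  t <- config$pre_session_s
  trials <- list()
  for (i in seq_along(types)) {
    ty <- types[i]
    block2 <- i > n_block1
    rows <- c(push("light_on", t, "trial"))
    t_lever <- t + 2
    rows <- c(rows, push("lever_extension", t_lever))
    lat <- draw_press_latency(config$press_hazard)
    correct <- NA
    congruent <- NA
    rewarded <- FALSE
    if (is.na(lat)) {
      # no response: lever retracts, new trial after a short interval
      t_next <- t_lever + 10 + stats::runif(1, 5, 10)
      trials[[i]] <- list(trial_id = i, trial_type = ty, event_rows = rows,
                          rewarded = FALSE, omission = FALSE, correct = NA,
                          congruent = NA, latency = NA_real_, block2 = block2)
      t <- t_next
      next
    }
    t_press <- t_lever + lat
    rows <- c(rows, push("lever_press", t_press))
    t_cue <- t_press + 1
    rows <- c(rows, push("cue_on", t_cue, ty))
    rows <- c(rows, push("cue_off", t_cue + cue_dur, ty))
    t_after <- t_cue + cue_dur
    if (ty %in% c("A", "B")) {
      # anticipatory entry during the cue (inconsequential; measured for
      # first-entry congruence)
      congruent <- stats::runif(1) < config$congruence[[ty]]
      side_a <- if (congruent) sides[[ty]] else setdiff(unlist(sides), sides[[ty]])
      ent <- t_cue + stats::runif(1, 0.3, cue_dur - 0.3)
      rows <- c(rows, push("port_entry", ent, side_a))
      rows <- c(rows, push("port_exit", ent + 0.25, side_a))
      # decision entry after cue offset
      correct <- stats::runif(1) < config$decision_accuracy[[ty]]
      side_d <- if (correct) sides[[ty]] else setdiff(unlist(sides), sides[[ty]])
      t_dec <- t_after + min(stats::rexp(1, 2) + 0.2, 3)
      rows <- c(rows, push("port_entry", t_dec, side_d))
      if (correct) {
        t_light <- t_dec + 0.5
        rows <- c(rows, push("light_on", t_light, ty))
        t_r1 <- t_light + 1
        rows <- c(rows, push("reward_delivery", t_r1, ty))
        t_end_rw <- t_r1 + 2.5
        if (!block2) {
          t_r2 <- t_r1 + 4.0   # 2.5 s delivery + 1.5 s dipper retraction
          rows <- c(rows, push("reward_delivery", t_r2, ty))
          t_end_rw <- t_r2 + 2.5
        }
        rows <- c(rows, push("light_off", t_end_rw, ty))
        rows <- c(rows, push("port_exit", t_end_rw + 0.3, side_d))
        rewarded <- TRUE
        t_after <- t_end_rw + 0.3
        iti <- stats::runif(1, 30, 40)
      } else {
        rows <- c(rows, push("port_exit", t_dec + 0.5, side_d))
        t_after <- t_dec + 0.5
        iti <- stats::runif(1, 40, 60)
      }
    } else {
      iti <- stats::runif(1, 15, 25)
    }
    times_of <- vapply(rows, function(r) ev[[r]]$time, numeric(1))
    rows <- rows[order(times_of)]
    trials[[i]] <- list(trial_id = i, trial_type = ty, event_rows = rows,
                        rewarded = rewarded,
                        omission = block2 && rewarded,   # second reward omitted
                        correct = correct, congruent = congruent,
                        latency = lat, block2 = block2)
    t <- t_after + iti
  }
  t_end <- t + config$post_session_s
  push("session_end", t_end)
  events <- event_table(vapply(ev, `[[`, "", "event_type"),
                        vapply(ev, `[[`, 0, "time"),
                        vapply(ev, `[[`, "", "label"))
  # omission flag is reserved for rewarded-cue trial types
  omi <- vapply(trials, `[[`, FALSE, "omission") &
    vapply(trials, `[[`, "", "trial_type") %in% c("A", "B")
  trl <- trial_table(trial_id = vapply(trials, `[[`, 0L, "trial_id"),
                     trial_type = vapply(trials, `[[`, "", "trial_type"),
                     event_rows = lapply(trials, `[[`, "event_rows"),
                     rewarded = vapply(trials, `[[`, FALSE, "rewarded"),
                     omission = omi,
                     correct = vapply(trials, function(x) as.logical(x$correct), NA),
                     congruent_first_entry = vapply(trials, function(x) as.logical(x$congruent), NA))
  trains <- lapply(seq_len(nrow(config$roster)), function(j) {
    simulate_unit(config$roster$unit_id[j], config$roster$class[j], events,
                  t_end, seed = seed, gain = config$gain,
                  params = config$unit_params[[config$roster$class[j]]])
  })
  ses <- session(session_id = sprintf("sim_op_s%d", seed),
                 subject_id = sprintf("rat_sim%d", seed),
                 group = config$group, experiment = "operant",
                 spike_trains = trains, events = events, trials = trl,
                 metadata = list(cue_sides = list(A = "left", B = "right")))
  gt <- list(units = cbind(config$roster, gain = config$gain),
             trials = data.frame(trial_id = trl$trial_id, trial_type = trl$trial_type,
                                 latency = vapply(trials, `[[`, NA_real_, "latency"),
                                 correct = trl$correct,
                                 congruent = trl$congruent_first_entry,
                                 block2 = vapply(trials, `[[`, FALSE, "block2")),
             config = config, seed = seed)
  list(session = ses, ground_truth = gt)
}

#' Simulate a table of composite behavioral measures
#'
#' Small latent-factor generator for the case-control similarity analysis:
#' each row's four measures load positively on a single latent reactivity
#' axis, groups differ by a planted shift along it, and the target subject's
#' sessions sit at the naive (default) or exposed level. With
#' `group_shift = 0` the naive and exposed rows are exchangeable.
#'
#' @param n_naive,n_exposed,n_target rows per group (defaults 55, 37, 12,
#'   matching the session counts of the operant case-control comparison).
#' @param group_shift planted exposed-minus-naive shift on the latent axis
#'   (default 2).
#' @param target_affinity `"naive"` or `"exposed"`.
#' @param noise_sd measurement noise on each measure (default 0.6).
#' @param seed integer seed.
#' @return data.frame with `group` and four measure columns `m1..m4`.
#' @export
simulate_measure_table <- function(n_naive = 55, n_exposed = 37, n_target = 12,
                                   group_shift = 2, target_affinity = c("naive", "exposed"),
                                   noise_sd = 0.6, seed = 1) {
  target_affinity <- match.arg(target_affinity)
  set.seed(derive_seed(seed, "measures"))
  mu <- c(rep(0, n_naive), rep(group_shift, n_exposed),
          rep(if (target_affinity == "naive") 0 else group_shift, n_target))
  latent <- stats::rnorm(length(mu), mu, 1)
  load <- c(0.9, 0.8, 0.7, 0.6)
  m <- sapply(load, function(a) a * latent + stats::rnorm(length(latent), 0, noise_sd))
  colnames(m) <- paste0("m", 1:4)
  data.frame(group = c(rep("naive", n_naive), rep("exposed", n_exposed),
                       rep("target", n_target)),
             m, stringsAsFactors = FALSE)
}
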