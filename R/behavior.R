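# Behavioral cue-reactivity metrics: lever-press hazard rate, port occupancy,
# accuracy and congruence indices, cumulative congruent entries, and the
# progressive-ratio breakpoint.

#' Lever-press hazard curve
#'
#' Latency after lever extension is binned at 100 ms; the hazard in bin `j`
#' is the fraction of trials with a press in that bin among trials in which
#' no press has yet occurred, `P(LP = t | LP >= t)`. Censored trials (no
#' press) remain at risk until `censor_time`. Bins with zero trials at risk
#' report an undefined (NA) hazard, not zero. The cumulative press fraction
#' is derived as `1 - prod(1 - hazard)`, which on any input equals the
#' empirical cumulative fraction pressed.
#'
#' @param latencies numeric latencies in seconds (for censored trials, any
#'   value `>= censor_time` or NA).
#' @param censored logical per trial; NA latencies are treated as censored.
#' @param censor_time response deadline in seconds (default 10).
#' @param bin bin width in seconds (default 0.1).
#' @return Class `hazard_curve`: data.frame with `bin_start`, `bin_end`,
#'   `n_at_risk`, `n_events`, `hazard`, `cum_fraction`.
#' @export
hazard_curve <- function(latencies, censored = NULL, censor_time = 10, bin = 0.1) {
  latencies <- as.numeric(latencies)
  n <- length(latencies)
  if (is.null(censored)) censored <- rep(FALSE, n)
  censored <- censored | is.na(latencies) | latencies >= censor_time
  latencies[censored] <- censor_time
  if (any(latencies < 0, na.rm = TRUE)) stop("latencies must be >= 0", call. = FALSE)
  n_bins <- as.integer(ceiling(censor_time / bin - 1e-9))
  starts <- bin * (seq_len(n_bins) - 1L)
  ends <- starts + bin
  if (!n) {
    return(structure(data.frame(bin_start = numeric(), bin_end = numeric(),
                                n_at_risk = integer(), n_events = integer(),
                                hazard = numeric(), cum_fraction = numeric()),
                     class = c("hazard_curve", "data.frame")))
  }
  ev_bin <- ifelse(censored, NA_integer_, pmin(floor(latencies / bin + 1e-9), n_bins - 1L) + 1L)
  n_events <- tabulate(ev_bin[!is.na(ev_bin)], nbins = n_bins)
  at_risk <- integer(n_bins)
  risk <- n
  for (j in seq_len(n_bins)) {
    at_risk[j] <- risk
    risk <- risk - n_events[j]
  }
  hazard <- ifelse(at_risk > 0, n_events / at_risk, NA_real_)
  surv <- cumprod(ifelse(is.na(hazard), 1, 1 - hazard))
  structure(data.frame(bin_start = starts, bin_end = ends, n_at_risk = at_risk,
                       n_events = n_events, hazard = hazard,
                       cum_fraction = 1 - surv),
            class = c("hazard_curve", "data.frame"))
}

#' Mean hazard over the first seconds after lever extension
#'
#' Unweighted mean of the defined hazard bins with `bin_start` in
#' `[window[1], window[2])` (default the first two seconds).
#'
#' @param hc a [hazard_curve()].
#' @param window seconds (default `c(0, 2)`).
#' @export
mean_hazard <- function(hc, window = c(0, 2)) {
  sel <- hc$bin_start >= window[1] & hc$bin_start < window[2] & !is.na(hc$hazard)
  if (!any(sel)) return(NA_real_)
  mean(hc$hazard[sel])
}

# pair port_entry/port_exit events into occupancy intervals; an unmatched
# entry at session end is closed at session_end
occupancy_intervals <- function(events, session_end, side = NULL) {
  pe <- events[events$event_type %in% c("port_entry", "port_exit"), , drop = FALSE]
  if (!is.null(side)) pe <- pe[pe$label == side, , drop = FALSE]
  pe <- pe[order(pe$time), , drop = FALSE]
  ivals <- NULL
  open <- NA_real_
  for (i in seq_len(nrow(pe))) {
    if (pe$event_type[i] == "port_entry") {
      if (!is.na(open)) ivals <- rbind(ivals, c(open, pe$time[i]))  # double entry: close at next
      open <- pe$time[i]
    } else {
      if (is.na(open)) stop("unpaired port_exit at ", pe$time[i], call. = FALSE)
      ivals <- rbind(ivals, c(open, pe$time[i]))
      open <- NA_real_
    }
  }
  if (!is.na(open)) ivals <- rbind(ivals, c(open, session_end))
  if (is.null(ivals)) matrix(numeric(), ncol = 2) else ivals
}

#' Peri-event port-occupancy trace
#'
#' For each bin of the window, the fraction of trials during which the
#' subject is inside the port at the bin midpoint. Occupancy intervals are
#' reconstructed from paired `port_entry` / `port_exit` events; an entry
#' without a matching exit is closed at session end.
#'
#' @param session a [session()].
#' @param align_times alignment event times (s).
#' @param window `c(start, end)` relative seconds.
#' @param bin bin width in seconds (default 0.1).
#' @param side optional port side label to restrict to.
#' @return data.frame `bin_start`, `p_occupied`.
#' @export
occupancy_trace <- function(session, align_times, window, bin = 0.1, side = NULL) {
  check_window(window)
  span <- session_span(session)
  iv <- occupancy_intervals(session$events, span[2], side)
  n_bins <- as.integer(round((window[2] - window[1]) / bin))
  mids <- window[1] + bin * (seq_len(n_bins) - 0.5)
  occ <- function(t) {
    if (!nrow(iv)) return(FALSE)
    any(iv[, 1] <= t & t < iv[, 2])
  }
  p <- vapply(seq_len(n_bins), function(j) {
    mean(vapply(align_times, function(a) occ(a + mids[j]), logical(1)))
  }, numeric(1))
  data.frame(bin_start = window[1] + bin * (seq_len(n_bins) - 1L), p_occupied = p)
}

#' Relative trial-accuracy index
#'
#' (% correct Cue B trials) / (% correct Cue A trials) over trials whose
#' `correct` flag is defined. Values above 1 indicate a drug-cue (B) bias.
#'
#' @param session an operant [session()].
#' @param type_a,type_b trial-type labels (defaults `"A"`, `"B"`).
#' @return ratio, or NA (with a warning) if either denominator is empty or
#'   the Cue A accuracy is zero.
#' @export
trial_accuracy_index <- function(session, type_a = "A", type_b = "B") {
  trl <- session$trials
  pc <- function(tt) {
    sel <- trl$trial_type == tt & !is.na(trl$correct)
    if (!sum(sel)) return(NA_real_)
    mean(trl$correct[sel])
  }
  a <- pc(type_a); b <- pc(type_b)
  if (is.na(a) || is.na(b) || a == 0) {
    warning("trial_accuracy_index undefined (empty type or zero Cue A accuracy)")
    return(NA_real_)
  }
  b / a
}

# first feeder entry at/after cue onset per trial; returns per-trial logical
# congruence (NA when no entry)
first_entries <- function(session, cue_type) {
  ev <- session$events
  trl <- session$trials
  rows <- trial_event_rows(trl)
  sides <- session$metadata$cue_sides %||% list(A = "left", B = "right")
  out <- lapply(which(trl$trial_type == cue_type), function(i) {
    r <- rows[[i]]
    tev <- ev[r, , drop = FALSE]
    cue_on <- tev$time[tev$event_type == "cue_on"]
    if (!length(cue_on)) return(NULL)
    ent <- tev[tev$event_type == "port_entry" & tev$time >= cue_on[1], , drop = FALSE]
    list(trial = i, correct = trl$correct[i],
         congruent = if (nrow(ent)) ent$label[which.min(ent$time)] == sides[[cue_type]] else NA)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' First-entry congruence probability
#'
#' Among correct trials of the given cue type with at least one feeder entry
#' at/after cue onset, the fraction whose first entry is on the cue's
#' designated side (taken from `session$metadata$cue_sides`).
#'
#' @param session an operant [session()].
#' @param cue_type `"A"` or `"B"`.
#' @return probability in `[0, 1]`, or NA (with warning) if no qualifying
#'   trials exist.
#' @export
first_entry_congruence <- function(session, cue_type) {
  fe <- first_entries(session, cue_type)
  cong <- unlist(lapply(fe, function(x) if (isTRUE(x$correct)) x$congruent else NULL))
  cong <- cong[!is.na(cong)]
  if (!length(cong)) {
    warning("first_entry_congruence undefined: no qualifying trials")
    return(NA_real_)
  }
  mean(cong)
}

#' Cumulative congruent feeder entries after cue onset
#'
#' Session-summed step curve of congruent feeder entries as a function of
#' time from cue onset, over a window from cue onset to cue offset + 1 s by
#' default, with a least-squares slope fitted over the cue-presentation
#' segment. `reduce = "per_trial"` averages the curve across trials instead
#' of summing.
#'
#' @param session an operant [session()].
#' @param cue_type `"A"` or `"B"`.
#' @param post_offset_s seconds past cue offset to include (default 1).
#' @param reduce `"session_sum"` (default) or `"per_trial"`.
#' @return list: `curve` (data.frame `time`, `cum_entries`), `slope`
#'   (entries/s during cue presentation), `total` (congruent entries in the
#'   window), `n_trials`.
#' @export
cumulative_congruent_entries <- function(session, cue_type, post_offset_s = 1,
                                         reduce = c("session_sum", "per_trial")) {
  reduce <- match.arg(reduce)
  ev <- session$events
  trl <- session$trials
  rows <- trial_event_rows(trl)
  sides <- session$metadata$cue_sides %||% list(A = "left", B = "right")
  rel <- numeric()
  n_tr <- 0L
  cue_dur <- NA_real_
  for (i in which(trl$trial_type == cue_type)) {
    r <- rows[[i]]
    tev <- ev[r, , drop = FALSE]
    cue_on <- tev$time[tev$event_type == "cue_on"]
    cue_off <- tev$time[tev$event_type == "cue_off"]
    if (!length(cue_on) || !length(cue_off)) next
    n_tr <- n_tr + 1L
    cue_dur <- cue_off[1] - cue_on[1]
    ent <- tev[tev$event_type == "port_entry" & tev$label == sides[[cue_type]], , drop = FALSE]
    tt <- ent$time - cue_on[1]
    rel <- c(rel, tt[tt >= 0 & tt <= cue_dur + post_offset_s])
  }
  if (!n_tr) {
    return(list(curve = data.frame(time = 0, cum_entries = 0), slope = 0,
                total = 0L, n_trials = 0L))
  }
  rel <- sort(rel)
  denom <- if (reduce == "per_trial") n_tr else 1L
  curve <- data.frame(time = c(0, rel), cum_entries = (0:length(rel)) / denom)
  slope <- 0
  if (length(rel)) {
    # step-function value sampled on a fine grid over the cue segment
    grid <- seq(0, cue_dur, by = 0.05)
    y <- findInterval(grid, rel) / denom
    slope <- unname(stats::coef(stats::lm(y ~ grid))[2])
  }
  list(curve = curve, slope = slope, total = length(rel) / denom, n_trials = n_tr)
}

#' Ratio of total congruent feeder entries, Cue B / Cue A
#'
#' @param session an operant [session()].
#' @param post_offset_s seconds past cue offset to include (default 1).
#' @return ratio, NA (with warning) if the Cue A total is zero.
#' @export
congruent_entry_totals_ratio <- function(session, post_offset_s = 1) {
  a <- cumulative_congruent_entries(session, "A", post_offset_s)$total
  b <- cumulative_congruent_entries(session, "B", post_offset_s)$total
  if (a == 0) {
    warning("congruent entry ratio undefined: zero Cue A entries")
    return(NA_real_)
  }
  b / a
}

#' Progressive-ratio schedule
#'
#' The exponentially escalating response-requirement schedule used for
#' breakpoint testing.
#'
#' @return integer vector of 25 steps.
#' @export
pr_schedule <- function() {
  c(1L, 2L, 4L, 6L, 9L, 12L, 15L, 20L, 25L, 32L, 40L, 50L, 62L, 77L, 95L,
    118L, 145L, 178L, 219L, 268L, 328L, 402L, 492L, 603L, 737L)
}

#' Progressive-ratio breakpoint
#'
#' The last completed response requirement: `schedule[rewards_earned]`, or 0
#' when no reward was earned.
#'
#' @param rewards_earned non-negative integer count of rewards.
#' @param schedule strictly increasing positive integer steps (default
#'   [pr_schedule()]).
#' @export
pr_breakpoint <- function(rewards_earned, schedule = pr_schedule()) {
  if (rewards_earned < 0) stop("rewards_earned must be >= 0", call. = FALSE)
  if (any(diff(schedule) <= 0) || any(schedule <= 0)) {
    stop("schedule must be strictly increasing positive integers", call. = FALSE)
  }
  if (rewards_earned > length(schedule)) {
    stop("rewards_earned exceeds schedule length", call. = FALSE)
  }
  if (rewards_earned == 0) 0L else schedule[rewards_earned]
}

# lever-press latencies (s) per trial with censoring flags
press_latencies <- function(session) {
  ev <- session$events
  rows <- trial_event_rows(session$trials)
  lat <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)) {
    tev <- ev[rows[[i]], , drop = FALSE]
    le <- tev$time[tev$event_type == "lever_extension"]
    lp <- tev$time[tev$event_type == "lever_press"]
    if (length(le)) lat[i] <- if (length(lp)) lp[1] - le[1] else NA_real_
  }
  has_lever <- vapply(seq_along(rows), function(i) {
    any(ev$event_type[rows[[i]]] == "lever_extension")
  }, logical(1))
  list(latencies = lat[has_lever], censored = is.na(lat[has_lever]))
}

#' Per-session behavioral cue-reactivity measures
#'
#' One row of the composite measures used in the case-control similarity
#' analysis: relative trial accuracy index, first-entry congruence for each
#' cue, ratio of total congruent entries B/A, first-entry congruence ratio
#' B/A, and the mean lever-press hazard over 0-2 s.
#'
#' @param session an operant [session()].
#' @param censor_time response deadline (s) for the hazard curve.
#' @return one-row data.frame.
#' @export
session_behavior_measures <- function(session, censor_time = 10) {
  pl <- press_latencies(session)
  hc <- hazard_curve(pl$latencies, pl$censored, censor_time = censor_time)
  fa <- suppressWarnings(first_entry_congruence(session, "A"))
  fb <- suppressWarnings(first_entry_congruence(session, "B"))
  data.frame(session_id = session$session_id,
             subject_id = session$subject_id,
             group = session$group,
             trial_accuracy_index = suppressWarnings(trial_accuracy_index(session)),
             first_entry_congruence_A = fa,
             first_entry_congruence_B = fb,
             congruent_entry_ratio = if (!is.na(fa) && fa > 0) fb / fa else NA_real_,
             cumulative_entry_ratio_BA = suppressWarnings(congruent_entry_totals_ratio(session)),
             mean_hazard_0_2s = mean_hazard(hc),
             stringsAsFactors = FALSE)
}
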