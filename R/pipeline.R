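# Orchestration: run configuration with the standard analysis windows, and
# an end-to-end driver running classification, windowed responses, behavior
# measures and (when groups allow) the similarity analysis.
#
# The package's R functions are the intended interface; `run_full()` wires
# the stages together and records a manifest (configuration hash, seeds,
# stage counts) for reproducibility audits.

#' Run configuration with the standard analysis windows
#'
#' Windows are seconds relative to their alignment event: detection
#' 30-180 ms, valuation 180-500 ms, phasic 30-500 ms, omission periods 1
#' (0-200 ms) and 2 (200-1000 ms), reward 0-400 ms after cue offset. All
#' windows are validated (`end > start`) before any stage runs.
#'
#' @param windows named list of `c(start, end)` windows (s).
#' @param classify a [classify_config()].
#' @param seed integer seed for all randomized stages.
#' @param n_boot,n_null similarity-analysis settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(windows = list(detection = c(0.030, 0.180),
                                      valuation = c(0.180, 0.500),
                                      phasic = c(0.030, 0.500),
                                      omission_p1 = c(0, 0.200),
                                      omission_p2 = c(0.200, 1.000),
                                      reward = c(0, 0.400)),
                       classify = classify_config(),
                       seed = 1, n_boot = 2000, n_null = 50000) {
  for (nm in names(windows)) check_window(windows[[nm]], nm)
  structure(list(windows = windows, classify = classify, seed = seed,
                 n_boot = n_boot, n_null = n_null),
            class = "run_config")
}

# per-unit windowed responses to the session's cues for putative DA units
session_unit_responses <- function(session, report, config) {
  ev <- session$events
  put <- report$units$unit_id[report$units$putative_dopamine]
  trains <- session$spike_trains
  names(trains) <- vapply(trains, function(tr) tr$unit_id, character(1))
  win <- config$windows
  mode <- session$experiment
  rows <- lapply(put, function(u) {
    tr <- trains[[u]]
    out <- list(unit_id = u, session_id = session$session_id, group = session$group)
    if (mode == "pavlovian") {
      for (ct in intersect(unique(ev$label[ev$event_type == "cue_on"]),
                           c("sucrose", "remifentanil", "neutral"))) {
        cues <- ev$time[ev$event_type == "cue_on" & ev$label == ct]
        out[[paste0("cue_", ct)]] <- unclass(windowed_response(tr, cues, win$phasic))
        out[[paste0("detection_", ct)]] <- unclass(windowed_response(tr, cues, win$detection))
        out[[paste0("valuation_", ct)]] <- unclass(windowed_response(tr, cues, win$valuation))
      }
      rew_off <- ev$time[ev$event_type == "cue_off" & ev$label == "sucrose"]
      if (length(rew_off)) {
        out$reward <- unclass(windowed_response(tr, rew_off, win$reward))
      }
      omtr <- session$trials[session$trials$omission & session$trials$trial_type == "sucrose", ]
      if (nrow(omtr)) {
        rows_l <- trial_event_rows(omtr)
        offs <- vapply(rows_l, function(r) {
          tt <- ev[r, ]; tt$time[tt$event_type == "cue_off"][1]
        }, numeric(1))
        out$omission_p1 <- unclass(windowed_response(tr, offs, win$omission_p1))
        out$omission_p2 <- unclass(windowed_response(tr, offs, win$omission_p2))
      }
    } else {
      lev <- ev$time[ev$event_type == "lever_extension"]
      out$lever_extension <- unclass(windowed_response(tr, lev, win$phasic))
      for (ct in c("A", "B")) {
        cues <- ev$time[ev$event_type == "cue_on" & ev$label == ct]
        if (length(cues)) out[[paste0("cue_", ct)]] <- unclass(
          windowed_response(tr, cues, win$phasic,
                            baseline_times = closest_before(lev, cues)))
        lts <- ev$time[ev$event_type == "light_on" & ev$label == ct]
        if (length(lts)) out[[paste0("light_", ct)]] <- unclass(
          windowed_response(tr, lts, win$phasic))
        rws <- ev$time[ev$event_type == "reward_delivery" & ev$label == ct]
        if (length(rws)) out[[paste0("reward_", ct)]] <- unclass(
          windowed_response(tr, rws, win$phasic,
                            baseline_times = closest_before(
                              ev$time[ev$event_type == "light_on" & ev$label == ct], rws)))
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(NULL)
  nm <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] }))
}

# for each time in x, the closest reference time at or before it (the
# per-trial baseline event); falls back to the first reference
closest_before <- function(ref, x) {
  ref <- sort(ref)
  i <- findInterval(x, ref)
  ref[pmax(i, 1L)]
}

#' Run the full analysis pipeline over a set of sessions
#'
#' For each session: classify units, compute per-unit windowed responses for
#' the putative-dopamine population, and (operant sessions) behavioral
#' measures. If the behavior table contains naive, exposed and target groups
#' (`target_subject` given), the composite similarity analysis is run. A
#' manifest records the configuration hash, seed and stage counts.
#'
#' @param sessions list of [session()] objects (or paths loadable with
#'   [load_session()]).
#' @param config a [run_config()].
#' @param manual_exclusions named list: session id -> unit ids to exclude.
#' @param target_subject subject id treated as the similarity target.
#' @return list of class `run_result`: `classification` (reports by session),
#'   `responses`, `behavior`, `similarity` (or NULL), `manifest`.
#' @export
run_full <- function(sessions, config = run_config(),
                     manual_exclusions = list(), target_subject = NULL) {
  stopifnot(inherits(config, "run_config"))
  sessions <- lapply(sessions, function(s) {
    if (is.character(s)) load_session(s) else s
  })
  for (s in sessions) {
    rep <- validate_session(s)
    if (nrow(rep)) stop("stage validate: session ", s$session_id, ": ",
                        rep$message[1], call. = FALSE)
  }
  reports <- list()
  responses <- list()
  behavior <- list()
  for (s in sessions) {
    id <- s$session_id
    reports[[id]] <- classify_units(s, s$experiment,
                                    manual_exclusions = manual_exclusions[[id]] %||% character(),
                                    config = config$classify, seed = config$seed)
    responses[[id]] <- session_unit_responses(s, reports[[id]], config)
    if (s$experiment == "operant") behavior[[id]] <- session_behavior_measures(s)
  }
  behavior_df <- if (length(behavior)) do.call(rbind, behavior) else NULL
  similarity <- NULL
  if (!is.null(behavior_df) && !is.null(target_subject)) {
    grp <- ifelse(behavior_df$subject_id == target_subject, "target",
                  ifelse(behavior_df$group == "opioid_naive", "naive", "exposed"))
    meas <- c("cumulative_entry_ratio_BA", "trial_accuracy_index",
              "mean_hazard_0_2s", "congruent_entry_ratio")
    tbl <- cbind(behavior_df, sim_group = grp)
    ok <- stats::complete.cases(tbl[, meas])
    tbl <- tbl[ok, ]
    if (all(c("target", "naive", "exposed") %in% tbl$sim_group) && nrow(tbl) >= 6) {
      emb <- composite_embedding(tbl, meas, group_col = "sim_group")
      similarity <- null_distribution(emb, "target", "naive", "exposed",
                                      n_null = config$n_null, n_boot = config$n_boot,
                                      seed = config$seed)
    }
  }
  manifest <- list(config_hash = object_hash(config), seed = config$seed,
                   n_sessions = length(sessions),
                   stage_counts = lapply(reports, `[[`, "counts"))
  structure(list(classification = reports, responses = responses,
                 behavior = behavior_df, similarity = similarity,
                 manifest = manifest),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d session(s), config %s\n",
              x$manifest$n_sessions, x$manifest$config_hash))
  for (r in x$classification) print(r)
  if (!is.null(x$similarity)) print(x$similarity)
  invisible(x)
}

#' Export a smoothed PSTH as a tidy data.frame
#'
#' @param smoothed a [smooth_psth()] result.
#' @param align label for the alignment event.
#' @return data.frame `unit_id`, `align`, `bin_start_s`, `rate_hz`, `sem`.
#' @export
psth_table <- function(smoothed, align = "") {
  data.frame(unit_id = smoothed$unit_id, align = align,
             bin_start_s = smoothed$bin_starts, rate_hz = smoothed$rate,
             sem = smoothed$sem, stringsAsFactors = FALSE)
}
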