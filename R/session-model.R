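# Session data model: spike trains, events, trials, readers/writers, validation.
#
# All times are seconds from session start (floating point). Analysis windows
# quoted in milliseconds elsewhere in the package are converted to seconds at
# the interface. Times are stored on disk at microsecond resolution.

EVENT_TYPES <- c("cue_on", "cue_off", "reward_delivery", "lever_extension",
                 "lever_press", "port_entry", "port_exit", "infusion_on",
                 "light_on", "light_off", "session_start", "session_end")

GROUPS <- c("opioid_exposed", "opioid_naive")
EXPERIMENTS <- c("pavlovian", "operant")

#' Construct a spike train
#'
#' @param unit_id character scalar identifying the unit.
#' @param spike_times numeric vector of spike times in seconds from session
#'   start; must be non-negative and strictly increasing.
#' @param waveform optional numeric vector: mean waveform amplitude samples in
#'   microvolts.
#' @param wf_dt_ms sampling interval of the waveform in milliseconds
#'   (default 0.025 ms, i.e. 40 kHz).
#' @param channel_id optional recording channel identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, waveform = NULL,
                        wf_dt_ms = 0.025, channel_id = NA_character_) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L)
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike_times contains NA", call. = FALSE)
  if (length(spike_times) && any(spike_times < 0)) {
    stop(sprintf("unit '%s': spike times must be >= 0", unit_id), call. = FALSE)
  }
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0)) {
    stop(sprintf("unit '%s': spike times must be strictly increasing", unit_id),
         call. = FALSE)
  }
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 waveform = if (is.null(waveform)) NULL else as.numeric(waveform),
                 wf_dt_ms = wf_dt_ms, channel_id = channel_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes%s\n", x$unit_id,
              length(x$spike_times),
              if (is.null(x$waveform)) "" else
                sprintf(", waveform %d samples @ %g ms", length(x$waveform), x$wf_dt_ms)))
  invisible(x)
}

#' Construct an event table
#'
#' @param event_type character vector drawn from the event vocabulary
#'   (`cue_on`, `cue_off`, `reward_delivery`, `lever_extension`, `lever_press`,
#'   `port_entry`, `port_exit`, `infusion_on`, `light_on`, `light_off`,
#'   `session_start`, `session_end`).
#' @param time event times in seconds from session start.
#' @param label free-text label (cue identity, port side, ...).
#' @return A `data.frame` with columns `event_type`, `time`, `label`.
#' @export
event_table <- function(event_type = character(), time = numeric(),
                        label = character()) {
  if (length(label) == 0L && length(event_type) > 0L) label <- rep("", length(event_type))
  df <- data.frame(event_type = as.character(event_type),
                   time = as.numeric(time),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$event_type), EVENT_TYPES)
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' Construct a trial table
#'
#' @param trial_id integer trial identifiers.
#' @param trial_type character trial types (e.g. `sucrose`, `remifentanil`,
#'   `neutral`, `A`, `B`, `C`).
#' @param event_rows list of integer vectors referencing rows of the session
#'   event table belonging to each trial.
#' @param rewarded,omission logical flags.
#' @param correct logical or NA (defined only for operant trials).
#' @param congruent_first_entry logical or NA.
#' @return A `data.frame` with an `event_rows` character column holding
#'   semicolon-joined row indices.
#' @export
trial_table <- function(trial_id = integer(), trial_type = character(),
                        event_rows = list(), rewarded = logical(),
                        omission = logical(), correct = NA,
                        congruent_first_entry = NA) {
  n <- length(trial_id)
  rec <- function(x, default) if (length(x) == n) x else rep(default, n)
  data.frame(trial_id = as.integer(trial_id),
             trial_type = as.character(trial_type),
             event_rows = vapply(event_rows, function(r) paste(as.integer(r), collapse = ";"),
                                 character(1)),
             rewarded = as.logical(rec(rewarded, FALSE)),
             omission = as.logical(rec(omission, FALSE)),
             correct = as.logical(rec(correct, NA)),
             congruent_first_entry = as.logical(rec(congruent_first_entry, NA)),
             stringsAsFactors = FALSE)
}

#' Parse the event_rows column of a trial table into integer vectors
#' @param trials a trial table.
#' @return list of integer vectors, one per trial.
#' @export
trial_event_rows <- function(trials) {
  lapply(strsplit(trials$event_rows, ";", fixed = TRUE),
         function(x) as.integer(x[nzchar(x)]))
}

#' Construct a recording session
#'
#' A session bundles the spike trains, the event table and the trial table of
#' one recording, together with subject and group metadata. The event table
#' must contain one `session_start` and one `session_end` event.
#'
#' @param session_id,subject_id character identifiers.
#' @param group `"opioid_exposed"` or `"opioid_naive"`.
#' @param experiment `"pavlovian"` or `"operant"`.
#' @param spike_trains list of [spike_train()] objects.
#' @param events event table (see [event_table()]).
#' @param trials trial table (see [trial_table()]).
#' @param metadata optional named list (e.g. `cue_sides` mapping cue labels to
#'   designated port sides in the operant task).
#' @return An object of class `session`.
#' @export
session <- function(session_id, subject_id, group, experiment,
                    spike_trains = list(), events = event_table(),
                    trials = trial_table(), metadata = list()) {
  group <- match.arg(group, GROUPS)
  experiment <- match.arg(experiment, EXPERIMENTS)
  s <- structure(list(session_id = as.character(session_id),
                      subject_id = as.character(subject_id),
                      group = group, experiment = experiment,
                      spike_trains = spike_trains, events = events,
                      trials = trials, metadata = metadata),
                 class = "session")
  rep <- validate_session(s)
  if (nrow(rep)) {
    stop("invalid session: ", paste(utils::head(rep$message, 5), collapse = "; "),
         call. = FALSE)
  }
  s
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s (%s, %s, %s): %d units, %d events, %d trials\n",
              x$session_id, x$subject_id, x$group, x$experiment,
              length(x$spike_trains), nrow(x$events), nrow(x$trials)))
  invisible(x)
}

#' Session start/end times
#' @param session a session object.
#' @return numeric length-2 vector `c(start, end)`.
#' @export
session_span <- function(session) {
  st <- session$events$time[session$events$event_type == "session_start"]
  en <- session$events$time[session$events$event_type == "session_end"]
  c(if (length(st)) st[1] else NA_real_, if (length(en)) en[1] else NA_real_)
}

#' Validate a session, reporting every invariant violation
#'
#' Checks performed: declared group/experiment values, event vocabulary and
#' temporal bounds, strictly increasing non-negative spike times, trial event
#' references, omission implying a rewarded-cue trial type, and temporal
#' ordering of events within each trial. Validation reports rather than
#' raises: an empty report means the session is valid.
#'
#' @param session a (possibly malformed) session-like list.
#' @return data.frame with columns `scope`, `id`, `message`; zero rows iff valid.
#' @export
validate_session <- function(session) {
  viol <- list()
  add <- function(scope, id, message) {
    viol[[length(viol) + 1L]] <<- data.frame(scope = scope, id = as.character(id),
                                             message = message, stringsAsFactors = FALSE)
  }
  ev <- session$events
  if (!session$group %in% GROUPS) add("session", session$session_id, "unknown group")
  if (!session$experiment %in% EXPERIMENTS) add("session", session$session_id, "unknown experiment")

  span <- c(NA_real_, NA_real_)
  if (is.data.frame(ev)) {
    bad <- setdiff(unique(ev$event_type), EVENT_TYPES)
    if (length(bad)) add("events", "-", paste("unknown event type(s):", paste(bad, collapse = ", ")))
    st <- ev$time[ev$event_type == "session_start"]
    en <- ev$time[ev$event_type == "session_end"]
    if (length(st) != 1L) add("events", "-", "expected exactly one session_start event")
    if (length(en) != 1L) add("events", "-", "expected exactly one session_end event")
    if (length(st) == 1L && length(en) == 1L) {
      span <- c(st, en)
      out <- which(ev$time < st - 1e-9 | ev$time > en + 1e-9)
      for (i in out) add("events", i, sprintf("event at %.6f s outside [session_start, session_end]", ev$time[i]))
    }
  } else {
    add("events", "-", "events is not a data.frame")
  }

  for (tr in session$spike_trains) {
    ts <- tr$spike_times
    if (length(ts) && any(ts < 0)) add("spikes", tr$unit_id, "negative spike time")
    if (length(ts) > 1L && any(diff(ts) <= 0)) add("spikes", tr$unit_id, "spike times not strictly increasing")
    if (!is.na(span[2]) && length(ts) && any(ts > span[2] + 1e-9))
      add("spikes", tr$unit_id, "spike time after session_end")
  }

  trl <- session$trials
  if (is.data.frame(trl) && nrow(trl)) {
    rows <- trial_event_rows(trl)
    for (i in seq_len(nrow(trl))) {
      r <- rows[[i]]
      if (length(r) && (any(r < 1L) || any(r > nrow(ev)))) {
        add("trials", trl$trial_id[i], "trial references missing event row")
        next
      }
      if (length(r) > 1L && is.data.frame(ev) && is.unsorted(ev$time[r])) {
        add("trials", trl$trial_id[i], "trial events not temporally ordered")
      }
      if (isTRUE(trl$omission[i]) && trl$trial_type[i] %in% c("neutral", "C")) {
        add("trials", trl$trial_id[i], "omission flagged on a non-rewarded trial type")
      }
    }
  }

  if (length(viol)) do.call(rbind, viol) else
    data.frame(scope = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
}

# ---- I/O --------------------------------------------------------------------

fmt_time <- function(x) sprintf("%.6f", x)

#' Write a session to disk
#'
#' `csv_dir` layout: `session.json` (metadata), `events.csv`
#' (`event_type,time,label`), `trials.csv`, `spikes/<unit_id>.csv` (one column
#' `time`), `waveforms/<unit_id>.csv` (`sample_uv` plus the sampling interval
#' in the header row of `session.json`). `json` writes a single JSON document.
#' Times are written at microsecond resolution, so a session whose times are
#' already at that resolution round-trips exactly.
#'
#' @param session a valid session.
#' @param path directory (`csv_dir`) or file path (`json`).
#' @param format `"csv_dir"` or `"json"`.
#' @export
write_session <- function(session, path, format = c("csv_dir", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- session_to_list(session)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  meta <- list(session_id = session$session_id, subject_id = session$subject_id,
               group = session$group, experiment = session$experiment,
               units = vapply(session$spike_trains, function(tr) tr$unit_id, character(1)),
               wf_dt_ms = lapply(session$spike_trains, function(tr) tr$wf_dt_ms),
               channel_id = lapply(session$spike_trains, function(tr) tr$channel_id),
               metadata = session$metadata)
  jsonlite::write_json(meta, file.path(path, "session.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ev <- session$events
  ev$time <- fmt_time(ev$time)
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(path, "trials.csv"), row.names = FALSE)
  any_wf <- FALSE
  for (tr in session$spike_trains) {
    utils::write.csv(data.frame(time = fmt_time(tr$spike_times)),
                     file.path(path, "spikes", paste0(tr$unit_id, ".csv")),
                     row.names = FALSE)
    if (!is.null(tr$waveform)) any_wf <- TRUE
  }
  if (any_wf) {
    dir.create(file.path(path, "waveforms"), showWarnings = FALSE)
    for (tr in session$spike_trains) {
      if (is.null(tr$waveform)) next
      utils::write.csv(data.frame(sample_uv = tr$waveform),
                       file.path(path, "waveforms", paste0(tr$unit_id, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

session_to_list <- function(session) {
  list(session_id = session$session_id, subject_id = session$subject_id,
       group = session$group, experiment = session$experiment,
       metadata = session$metadata,
       events = session$events,
       trials = session$trials,
       spike_trains = lapply(session$spike_trains, function(tr) {
         list(unit_id = tr$unit_id, spike_times = round_us(tr$spike_times),
              waveform = tr$waveform, wf_dt_ms = tr$wf_dt_ms,
              channel_id = tr$channel_id)
       }))
}

session_from_list <- function(obj) {
  trains <- lapply(obj$spike_trains, function(tr) {
    # canonicalize through the microsecond decimal representation: JSON
    # number parsing can differ from R's by 1 ulp
    spike_train(tr$unit_id, round_us(as.numeric(unlist(tr$spike_times))),
                waveform = if (length(tr$waveform)) as.numeric(unlist(tr$waveform)) else NULL,
                wf_dt_ms = tr$wf_dt_ms %||% 0.025,
                channel_id = tr$channel_id %||% NA_character_)
  })
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  ev$time <- round_us(as.numeric(ev$time))
  trl <- as.data.frame(obj$trials, stringsAsFactors = FALSE)
  if (!nrow(trl)) trl <- trial_table()
  trl$trial_id <- as.integer(trl$trial_id)
  for (col in c("rewarded", "omission", "correct", "congruent_first_entry")) {
    # all-NA logical columns are dropped by the JSON writer; restore them
    if (!col %in% names(trl)) trl[[col]] <- NA
    trl[[col]] <- as.logical(trl[[col]])
  }
  trl <- trl[, c("trial_id", "trial_type", "event_rows", "rewarded", "omission",
                 "correct", "congruent_first_entry")]
  session(obj$session_id, obj$subject_id, obj$group, obj$experiment,
          spike_trains = trains, events = event_table(ev$event_type, ev$time, ev$label),
          trials = trl, metadata = obj$metadata %||% list())
}

#' Load a session from disk
#'
#' Inverse of [write_session()]. Parse and invariant violations raise
#' descriptive errors naming the offending file.
#'
#' @param path directory (`csv_dir`) or file (`json`).
#' @param format `"csv_dir"` or `"json"`.
#' @return a validated [session()].
#' @export
load_session <- function(path, format = c("csv_dir", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
    obj$spike_trains <- apply_rowwise_trains(obj$spike_trains)
    return(session_from_list(obj))
  }
  if (!dir.exists(path)) stop("no such session directory: ", path, call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  ev_raw <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE,
                            colClasses = c(time = "character"))
  ev <- tryCatch(event_table(ev_raw$event_type, as.numeric(ev_raw$time),
                             ifelse(is.na(ev_raw$label), "", ev_raw$label)),
                 error = function(e) stop("events.csv: ", conditionMessage(e), call. = FALSE))
  tf <- file.path(path, "trials.csv")
  trl <- utils::read.csv(tf, stringsAsFactors = FALSE,
                         colClasses = c(event_rows = "character"))
  if (!nrow(trl)) trl <- trial_table() else {
    trl$trial_id <- as.integer(trl$trial_id)
    for (col in c("rewarded", "omission", "correct", "congruent_first_entry"))
      trl[[col]] <- as.logical(trl[[col]])
  }
  units <- unlist(meta$units)
  wf_dt <- meta$wf_dt_ms
  chans <- meta$channel_id
  trains <- lapply(seq_along(units), function(i) {
    u <- units[i]
    sf <- file.path(path, "spikes", paste0(u, ".csv"))
    if (!file.exists(sf)) stop("missing spike file: ", sf, call. = FALSE)
    st <- utils::read.csv(sf, colClasses = "character")
    wf_file <- file.path(path, "waveforms", paste0(u, ".csv"))
    wf <- if (file.exists(wf_file)) utils::read.csv(wf_file)$sample_uv else NULL
    tryCatch(spike_train(u, as.numeric(st$time), waveform = wf,
                         wf_dt_ms = if (length(wf_dt) >= i) as.numeric(wf_dt[[i]]) else 0.025,
                         channel_id = if (length(chans) >= i && !is.null(chans[[i]])) as.character(chans[[i]]) else NA_character_),
             error = function(e) stop(sf, ": ", conditionMessage(e), call. = FALSE))
  })
  md <- meta$metadata
  if (is.null(md)) md <- list()
  session(meta$session_id, meta$subject_id, meta$group, meta$experiment,
          spike_trains = trains, events = ev, trials = trl,
          metadata = md)
}

# jsonlite may simplify the spike_trains list into a data.frame; normalize back
apply_rowwise_trains <- function(x) {
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]) |>
             lapply(function(v) if (is.list(v)) v[[1]] else v))
  } else x
}
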