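# Peri-event histograms: binning, causal-exponential smoothing, baselines,
# and windowed / baseline-subtracted response measures.
#
# Default bin width is 10 ms. Binning is half-open [left, right): a spike
# exactly on a bin edge is counted in the right-hand bin.

#' Bin spikes around alignment events
#'
#' @param train a [spike_train()].
#' @param align_times numeric vector of alignment event times (s).
#' @param window `c(start, end)` in seconds relative to each alignment time.
#' @param bin_width bin width in seconds (default 0.01).
#' @return An object of class `binned_response` with fields `counts`
#'   (trials x bins integer matrix), `bin_starts` (relative seconds),
#'   `align_times`, `window`, `bin_width`, `unit_id`, and `partial` (logical
#'   per trial: window extends before session start, i.e. before 0 s).
#' @export
bin_spikes <- function(train, align_times, window, bin_width = 0.01) {
  stopifnot(inherits(train, "spike_train"))
  check_window(window)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  align_times <- as.numeric(align_times)
  if (!length(align_times)) stop("align_times must be non-empty", call. = FALSE)
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  if (n_bins < 1L) stop("window shorter than one bin", call. = FALSE)
  ts <- train$spike_times
  counts <- matrix(0L, nrow = length(align_times), ncol = n_bins)
  for (i in seq_along(align_times)) {
    rel <- ts - align_times[i] - window[1]
    # half-open bins; +1e-9/bin_width nudge keeps edge spikes in the right bin
    j <- floor(rel / bin_width + 1e-9)
    j <- j[j >= 0 & j < n_bins]
    if (length(j)) counts[i, ] <- tabulate(j + 1L, nbins = n_bins)
  }
  structure(list(unit_id = train$unit_id, counts = counts,
                 bin_starts = window[1] + bin_width * (seq_len(n_bins) - 1L),
                 align_times = align_times, window = window,
                 bin_width = bin_width,
                 partial = align_times + window[1] < 0),
            class = "binned_response")
}

#' @export
print.binned_response <- function(x, ...) {
  cat(sprintf("<binned_response> unit %s: %d trials x %d bins (%g ms), window [%g, %g] s\n",
              x$unit_id, nrow(x$counts), ncol(x$counts), 1000 * x$bin_width,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Causal exponential smoothing of a binned response
#'
#' The trial-wise firing rate (counts / bin width) is convolved with a causal
#' exponential kernel `k(t) = exp(-t / tau)` truncated to `[0, support)` and
#' normalized to unit sum, so a constant-rate input is returned unchanged and
#' the smoothed value at bin `j` depends only on bins `<= j`.
#'
#' @param binned a [bin_spikes()] result.
#' @param support kernel support in seconds (default 0.2).
#' @param tau decay constant in seconds (default 0.05).
#' @return Class `smoothed_trace`: `rate` (trial-mean Hz per bin), `sem`
#'   (across trials), `bin_starts`, `kernel`.
#' @export
smooth_psth <- function(binned, support = 0.2, tau = 0.05) {
  stopifnot(inherits(binned, "binned_response"))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  bw <- binned$bin_width
  if (support < bw) stop("support must be >= bin_width", call. = FALSE)
  L <- max(1L, as.integer(floor(support / bw + 1e-9)))
  w <- exp(-(seq_len(L) - 1L) * bw / tau)
  w <- w / sum(w)
  # partial-kernel renormalization at the left edge keeps constant inputs
  # exactly invariant while preserving strict causality
  norm <- cumsum(w)
  norm <- c(norm, rep(1, max(0L, ncol(binned$counts) - L)))[seq_len(ncol(binned$counts))]
  rates <- binned$counts / bw
  sm <- t(apply(rates, 1L, function(r) {
    y <- stats::filter(c(rep(0, L - 1L), r), w, sides = 1L)[L:(L - 1L + length(r))]
    y / norm
  }))
  if (nrow(binned$counts) == 1L) sm <- matrix(sm, nrow = 1L)
  rate <- colMeans(sm)
  sem <- if (nrow(sm) > 1L) apply(sm, 2L, stats::sd) / sqrt(nrow(sm)) else rep(NA_real_, ncol(sm))
  structure(list(unit_id = binned$unit_id, rate = as.numeric(rate), sem = as.numeric(sem),
                 bin_starts = binned$bin_starts, bin_width = bw,
                 kernel = list(support = support, tau = tau, weights = w)),
            class = "smoothed_trace")
}

#' Baseline firing rate of a unit
#'
#' @param train a [spike_train()].
#' @param session the parent [session()].
#' @param method epoch definition: `pre_session` (session start to the first
#'   task event), `intertrial` (gaps between consecutive trials' event spans),
#'   or `pre_event` (a fixed window before each event of `event_type`, pooled).
#' @param event_type event type for `pre_event`.
#' @param window relative window for `pre_event` (default `c(-1, 0)` s).
#' @return rate in Hz (total spikes in the epoch(s) / total epoch duration).
#' @export
baseline_rate <- function(train, session,
                          method = c("intertrial", "pre_session", "pre_event"),
                          event_type = NULL, window = c(-1, 0)) {
  method <- match.arg(method)
  ep <- baseline_epochs(session, method, event_type, window)
  total <- sum(ep[, 2] - ep[, 1])
  if (total <= 0) stop("baseline epoch has zero total duration", call. = FALSE)
  n <- 0L
  ts <- train$spike_times
  for (k in seq_len(nrow(ep))) n <- n + sum(ts >= ep[k, 1] & ts < ep[k, 2])
  n / total
}

# epochs as a 2-column matrix [start, end)
baseline_epochs <- function(session, method, event_type = NULL, window = c(-1, 0)) {
  ev <- session$events
  span <- session_span(session)
  if (method == "pre_session") {
    task <- ev$time[!ev$event_type %in% c("session_start", "session_end")]
    end <- if (length(task)) min(task) else span[2]
    return(matrix(c(span[1], end), ncol = 2))
  }
  if (method == "pre_event") {
    if (is.null(event_type)) stop("pre_event baseline needs event_type", call. = FALSE)
    check_window(window)
    tt <- ev$time[ev$event_type == event_type]
    if (!length(tt)) stop("no events of type ", event_type, call. = FALSE)
    return(cbind(pmax(tt + window[1], span[1]), tt + window[2]))
  }
  # intertrial: gaps between consecutive trials' event spans
  rows <- trial_event_rows(session$trials)
  if (!length(rows)) stop("session has no trials for intertrial baseline", call. = FALSE)
  spans <- t(vapply(rows, function(r) range(ev$time[r]), numeric(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  gaps <- cbind(spans[-nrow(spans), 2], spans[-1, 1])
  gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
  if (!nrow(gaps)) stop("no positive-length intertrial gaps", call. = FALSE)
  gaps
}

# per-trial mean rates (Hz) in a window around alignment times
window_rates <- function(train, align_times, window) {
  check_window(window)
  ts <- train$spike_times
  vapply(align_times, function(a) {
    sum(ts >= a + window[1] & ts < a + window[2]) / (window[2] - window[1])
  }, numeric(1))
}

#' Baseline-subtracted phasic response
#'
#' Mean firing rate in `response_window` after each alignment event minus the
#' rate in `baseline_window` around the paired baseline event, averaged across
#' trials. With the defaults this is the 30-500 ms response minus the 0-1000 ms
#' pre-baseline-event rate. `align_times` and `baseline_times` must pair up
#' one-to-one (same trials); in the Pavlovian task both are cue onset, in the
#' operant task the baseline event differs by response type (lever extension
#' for lever/auditory-cue responses, pre-light-cue for light/reward responses).
#'
#' @param train a [spike_train()].
#' @param align_times response alignment times (s).
#' @param baseline_times baseline alignment times (s); same length.
#' @param response_window default `c(0.030, 0.500)` s.
#' @param baseline_window default `c(-1, 0)` s.
#' @return Class `phasic_measure`: `value` (Hz), `per_trial`, `sem`, windows.
#' @export
phasic_response <- function(train, align_times, baseline_times = align_times,
                            response_window = c(0.030, 0.500),
                            baseline_window = c(-1, 0)) {
  if (!length(align_times)) stop("empty trial set", call. = FALSE)
  if (length(align_times) != length(baseline_times)) {
    stop("align_times and baseline_times must have equal length (paired trials)",
         call. = FALSE)
  }
  resp <- window_rates(train, align_times, response_window)
  base <- window_rates(train, baseline_times, baseline_window)
  d <- resp - base
  structure(list(unit_id = train$unit_id, value = mean(d), per_trial = d,
                 sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
                 response_window = response_window, baseline_window = baseline_window),
            class = "phasic_measure")
}

#' @export
print.phasic_measure <- function(x, ...) {
  cat(sprintf("<phasic_measure> unit %s: %.3f Hz (sem %.3f, %d trials)\n",
              x$unit_id, x$value, x$sem, length(x$per_trial)))
  invisible(x)
}

#' Baseline-subtracted mean rate in an arbitrary window
#'
#' Generalization of [phasic_response()] used for the detection (30-180 ms)
#' and valuation (180-500 ms) cue phases, the reward-delivery response
#' (0-400 ms after cue offset), and the omission response periods
#' (0-200 / 200-1000 ms).
#'
#' @inheritParams phasic_response
#' @param window response window `c(start, end)` relative seconds.
#' @return numeric Hz; attributes `per_trial` and `sem`.
#' @export
windowed_response <- function(train, align_times, window,
                              baseline_times = align_times,
                              baseline_window = c(-1, 0)) {
  pm <- phasic_response(train, align_times, baseline_times,
                        response_window = window, baseline_window = baseline_window)
  structure(pm$value, per_trial = pm$per_trial, sem = pm$sem)
}
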