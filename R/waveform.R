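# Waveform features and burst statistics.

# local extrema of a numeric vector; returns indices of strict local maxima
# or minima (plateaus take their first index)
local_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  # carry the sign through flat runs so plateaus register once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L
  # endpoints: a rising start or falling end is not a peak
  idx[idx > 1L & idx < n | (idx == n & n > 1L)]
}

#' Waveform amplitude ratio and half duration
#'
#' The amplitude ratio is `(P - |N|) / (P + |N|)` where `N` is the amplitude
#' of the first negative peak and `P` the amplitude of the first positive
#' peak preceding it; if no positive peak precedes the first negative peak,
#' `P = 0` and the ratio is -1. The half duration is the time from the first
#' negative peak to the next positive peak, or to the end of the waveform
#' (1.1 ms from its start) if none follows.
#'
#' @param waveform numeric vector of amplitude samples (microvolts).
#' @param dt_ms sampling interval in milliseconds (default 0.025).
#' @param wf_end_ms nominal waveform end used when no positive peak follows
#'   (default 1.1 ms).
#' @return one-row data.frame: `amplitude_ratio` in `[-1, 1]`, `half_duration`
#'   in ms.
#' @export
waveform_features <- function(waveform, dt_ms = 0.025, wf_end_ms = 1.1) {
  w <- as.numeric(waveform)
  if (length(w) < 2L) stop("waveform needs at least 2 samples", call. = FALSE)
  if (max(w) - min(w) < 1e-12) stop("flat waveform", call. = FALSE)
  mins <- local_extrema(w, "min")
  mins <- mins[w[mins] < 0]
  if (!length(mins)) stop("waveform has no negative peak", call. = FALSE)
  n_idx <- mins[1]
  N <- w[n_idx]
  maxs <- local_extrema(w, "max")
  pre_pos <- maxs[maxs < n_idx & w[maxs] > 0]
  P <- if (length(pre_pos)) w[pre_pos[1]] else 0
  ratio <- (P - abs(N)) / (P + abs(N))
  post_pos <- maxs[maxs > n_idx & w[maxs] > 0]
  t_n <- (n_idx - 1L) * dt_ms
  half <- if (length(post_pos)) (post_pos[1] - n_idx) * dt_ms else wf_end_ms - t_n
  data.frame(amplitude_ratio = ratio, half_duration = half)
}

#' k-means clustering on waveform features
#'
#' z-scored (amplitude_ratio, half_duration) clustered with seeded k-means
#' (best of `replicates` initializations). The putative-dopamine cluster is
#' the one with the longer mean half duration. A degenerate input (all points
#' essentially identical) yields a warning and a single cluster.
#'
#' @param features data.frame with columns `amplitude_ratio`, `half_duration`
#'   (e.g. stacked [waveform_features()] rows), optionally `unit_id`.
#' @param k,replicates,seed k-means settings.
#' @return list: `cluster` (integer per unit), `is_dopamine` (logical),
#'   `centers` on the original scale.
#' @export
kmeans_waveform <- function(features, k = 2, replicates = 20, seed = 1) {
  x <- as.matrix(features[, c("amplitude_ratio", "half_duration")])
  if (nrow(x) < 2 * k) stop("need at least 2k units", call. = FALSE)
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (all(rng < 1e-9)) {
    warning("degenerate waveform feature set: single tight blob, no meaningful split")
    cl <- rep(1L, nrow(x))
    return(list(cluster = cl, is_dopamine = rep(TRUE, nrow(x)),
                centers = matrix(colMeans(x), nrow = 1,
                                 dimnames = list(NULL, colnames(x)))))
  }
  keep <- apply(x, 2, stats::sd) > 0
  z <- zscore_cols(x[, keep, drop = FALSE])
  km <- kmeans_replicated(z, k, replicates, seed)
  mean_hd <- vapply(seq_len(k), function(g) mean(x[km$cluster == g, "half_duration"]),
                    numeric(1))
  da <- which.max(mean_hd)
  centers <- t(vapply(seq_len(k), function(g) colMeans(x[km$cluster == g, , drop = FALSE]),
                      numeric(ncol(x))))
  list(cluster = km$cluster, is_dopamine = km$cluster == da, centers = centers)
}

#' Burst statistics of a spike train
#'
#' Classic two-threshold interspike-interval criterion applied greedily left
#' to right: a burst starts when an ISI drops to `burst_onset_isi` or below
#' and continues while ISIs stay at or below `burst_offset_isi`. Only bursts
#' of two or more spikes count.
#'
#' @param train a [spike_train()] (or numeric spike-time vector).
#' @param burst_onset_isi onset threshold in seconds (default 0.080).
#' @param burst_offset_isi offset threshold in seconds (default 0.160).
#' @param total_time observation time in seconds for the per-minute rate;
#'   defaults to the train's span.
#' @return list: `n_bursts`, `bursts_per_minute`, `pct_spikes_in_bursts`,
#'   `burst_sizes` (integer vector), `burst_size_histogram` (table).
#' @export
burst_stats <- function(train, burst_onset_isi = 0.080, burst_offset_isi = 0.160,
                        total_time = NULL) {
  ts <- if (inherits(train, "spike_train")) train$spike_times else as.numeric(train)
  if (length(ts) < 2L) {
    return(list(n_bursts = 0L, bursts_per_minute = 0,
                pct_spikes_in_bursts = 0, burst_sizes = integer(),
                burst_size_histogram = table(integer())))
  }
  isi <- diff(ts)
  sizes <- integer()
  in_burst <- FALSE
  cur <- 0L
  for (d in isi) {
    if (!in_burst) {
      if (d <= burst_onset_isi) { in_burst <- TRUE; cur <- 2L }
    } else {
      if (d <= burst_offset_isi) cur <- cur + 1L
      else { sizes <- c(sizes, cur); in_burst <- FALSE; cur <- 0L }
    }
  }
  if (in_burst) sizes <- c(sizes, cur)
  span <- total_time %||% (ts[length(ts)] - ts[1])
  list(n_bursts = length(sizes),
       bursts_per_minute = if (span > 0) length(sizes) / (span / 60) else 0,
       pct_spikes_in_bursts = 100 * sum(sizes) / length(ts),
       burst_sizes = sizes,
       burst_size_histogram = table(factor(sizes, levels = if (length(sizes)) seq(2L, max(sizes)) else integer())))
}
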