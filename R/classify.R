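# Putative-dopamine-neuron identification cascade.
#
# Stages: screen for cue responsiveness -> auROC response matrix -> PCA +
# Ward-linkage hierarchical clustering into excited / inhibited / phasic
# groups -> keep the phasic cluster -> exclude baseline > 12 Hz -> k-means
# refinement on (log peak time, log ISI CV, inhibition index) to remove the
# atypical delayed/labile subpopulation -> apply manual exclusions.

#' Default classification configuration
#'
#' @param bin_width auROC bin width (s).
#' @param screen_bounds auROC band considered unresponsive; a unit passes the
#'   screen if any bin in `screen_window` falls outside it.
#' @param screen_window post-event window (s) inspected by the screen.
#' @param screen_bin bin width (s) of the screening auROC trace. The screen
#'   uses coarser bins than the response matrix: at 10 ms single-bin counts
#'   are nearly binary and the auROC band cannot register moderate
#'   inhibition, so responsiveness is judged on 100-ms counts.
#' @param baseline_max_hz baseline-rate exclusion threshold (12 Hz).
#' @param baseline_method epoch definition passed to [baseline_rate()].
#' @param inhibition_window Pavlovian inhibition response window, seconds
#'   after reward delivery (1-2 s).
#' @param baseline_mode auROC baseline construction (see [auroc_trace()]).
#' @return named list of settings.
#' @export
classify_config <- function(bin_width = 0.01,
                            screen_bounds = c(0.35, 0.65),
                            screen_window = c(0, 0.5),
                            screen_bin = 0.1,
                            baseline_max_hz = 12,
                            baseline_method = "intertrial",
                            inhibition_window = c(1.0, 2.0),
                            baseline_mode = "pooled") {
  list(bin_width = bin_width, screen_bounds = screen_bounds,
       screen_window = screen_window, screen_bin = screen_bin,
       baseline_max_hz = baseline_max_hz,
       baseline_method = baseline_method, inhibition_window = inhibition_window,
       baseline_mode = baseline_mode)
}

# cue-responsiveness screen: TRUE when any screening-trace bin leaves the
# unresponsive band
screen_unit <- function(train, align_times, base_window, config) {
  b <- bin_spikes(train, align_times, config$screen_window, config$screen_bin)
  bb <- bin_spikes(train, align_times, base_window, config$screen_bin)
  v <- auroc_trace(b, bb, baseline_mode = config$baseline_mode)$values
  any(v < config$screen_bounds[1] | v > config$screen_bounds[2])
}

# alignment times used by each mode
mode_alignments <- function(session, mode) {
  ev <- session$events
  if (mode == "pavlovian") {
    list(primary = ev$time[ev$event_type == "cue_on" & ev$label == "sucrose"])
  } else {
    list(primary = ev$time[ev$event_type == "lever_extension"],
         reward = ev$time[ev$event_type == "reward_delivery"])
  }
}

#' Units x bins auROC response matrix
#'
#' Pavlovian mode: each row is the unit's auROC trace from 0.5 s before to
#' 5.5 s after sucrose cue onset (600 bins at 10 ms), normalized against the
#' pooled 0.5-s pre-cue counts. Operant mode: the trace around lever
#' extension (-250 to 1000 ms; 125 bins) concatenated with the trace around
#' reward delivery (-250 to 500 ms; 75 bins), each segment normalized against
#' its own 250-ms pre-event counts.
#'
#' @param session a [session()].
#' @param mode `"pavlovian"` or `"operant"`.
#' @param units optional character vector restricting the units.
#' @param config see [classify_config()].
#' @return numeric matrix with unit ids as row names; attributes `rel_time`
#'   (per-column time relative to its segment's event) and `segment`.
#' @export
response_matrix <- function(session, mode = c("pavlovian", "operant"),
                            units = NULL, config = classify_config()) {
  mode <- match.arg(mode)
  trains <- session$spike_trains
  if (!is.null(units)) {
    trains <- Filter(function(tr) tr$unit_id %in% units, trains)
  }
  if (!length(trains)) stop("no units to analyse", call. = FALSE)
  al <- mode_alignments(session, mode)
  segs <- if (mode == "pavlovian") {
    list(list(times = al$primary, window = c(-0.5, 5.5), base_window = c(-0.5, 0)))
  } else {
    list(list(times = al$primary, window = c(-0.25, 1.0), base_window = c(-0.25, 0)),
         list(times = al$reward, window = c(-0.25, 0.5), base_window = c(-0.25, 0)))
  }
  for (sg in segs) {
    if (!length(sg$times)) stop("session lacks alignment events for mode ", mode, call. = FALSE)
  }
  bw <- config$bin_width
  rows <- lapply(trains, function(tr) {
    unlist(lapply(segs, function(sg) {
      b <- bin_spikes(tr, sg$times, sg$window, bw)
      bb <- bin_spikes(tr, sg$times, sg$base_window, bw)
      auroc_trace(b, bb, baseline_mode = config$baseline_mode)$values
    }))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(trains, function(tr) tr$unit_id, character(1))
  rel <- unlist(lapply(segs, function(sg) {
    n <- round((sg$window[2] - sg$window[1]) / bw)
    sg$window[1] + bw * (seq_len(n) - 1L)
  }))
  seg_id <- rep(seq_along(segs), vapply(segs, function(sg)
    as.integer(round((sg$window[2] - sg$window[1]) / bw)), integer(1)))
  attr(mat, "rel_time") <- rel
  attr(mat, "segment") <- seg_id
  mat
}

#' Functional clustering of auROC response profiles
#'
#' Column-centered (unscaled) PCA of the response matrix, then agglomerative
#' clustering of the first `n_pcs` component scores with Ward linkage on
#' Euclidean distances, cut at `n_clusters`. Clusters are auto-labeled:
#' `inhibited` has the lowest mean auROC over the post-event region; of the
#' remaining two, `phasic` has the larger (early-peak minus late-mean)
#' contrast with "early" the first 250 ms post event; the third is `excited`.
#'
#' @param mat matrix from [response_matrix()] (needs its `rel_time`
#'   attribute; absent that, all columns count as post-event and "early" is
#'   the first 25 columns).
#' @param n_pcs number of principal components retained (default 3).
#' @param n_clusters number of clusters (default 3).
#' @return Class `cluster_assignment`: `cluster` (named integer vector),
#'   `labels` (cluster index -> functional label), `pc_scores`, `hclust`.
#' @export
cluster_functional <- function(mat, n_pcs = 3, n_clusters = 3) {
  if (nrow(mat) < n_clusters) stop("need at least n_clusters rows", call. = FALSE)
  if (all(apply(mat, 2, stats::sd) < 1e-12)) {
    stop("degenerate response matrix: zero variance in every bin", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  names(cl) <- rownames(mat)

  rel <- attr(mat, "rel_time")
  seg <- attr(mat, "segment") %||% rep(1L, ncol(mat))
  if (is.null(rel)) rel <- seq_len(ncol(mat)) * 0.01
  post <- rel >= 0
  early <- post & seg == 1L & rel < 0.25
  late <- post & !early
  cl_means <- t(vapply(seq_len(n_clusters), function(g) {
    colMeans(mat[cl == g, , drop = FALSE])
  }, numeric(ncol(mat))))
  post_mean <- rowMeans(cl_means[, post, drop = FALSE])
  labels <- rep(NA_character_, n_clusters)
  inhib <- which.min(post_mean)
  labels[inhib] <- "inhibited"
  rest <- setdiff(seq_len(n_clusters), inhib)
  contrast <- vapply(rest, function(g) {
    max(cl_means[g, early]) - mean(cl_means[g, late])
  }, numeric(1))
  phasic <- rest[which.max(contrast)]
  labels[phasic] <- "phasic"
  labels[setdiff(rest, phasic)] <- "excited"
  structure(list(cluster = cl, labels = labels,
                 pc_scores = scores, hclust = hc,
                 cluster_means = cl_means, var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "cluster_assignment")
}

#' Inhibition index (R - B) / (R + B)
#'
#' Bounded in `[-1, 1]`: 0 when the response rate equals baseline, -1 when
#' the unit is completely silenced.
#'
#' @param R response firing rate (Hz), >= 0.
#' @param B baseline firing rate (Hz), >= 0.
#' @export
inhibition_index <- function(R, B) {
  if (R < 0 || B < 0) stop("rates must be non-negative", call. = FALSE)
  if (R + B == 0) return(0)
  (R - B) / (R + B)
}

#' Per-unit classification features
#'
#' Peak firing time: time of highest trial-mean activity 50-1000 ms after
#' the reference event (sucrose cue onset in the Pavlovian task, lever
#' extension in the operant task), binned at 20 ms; earliest bin wins ties;
#' reported as the bin midpoint. ISI CV: coefficient of variation of all
#' session ISIs excluding any ISI with an endpoint inside (event, event +
#' 0.5 s] after a cue onset or reward delivery. Inhibition index: Pavlovian,
#' R = mean rate 1-2 s after reward delivery; operant, R = the lower of the
#' mean rate 0-1 s before vs. after reward delivery; B = session baseline.
#'
#' @param train a [spike_train()].
#' @param session the parent session.
#' @param mode `"pavlovian"` or `"operant"`.
#' @param config see [classify_config()].
#' @return one-row data.frame: `unit_id`, `peak_time` (s), `isi_cv`,
#'   `inhibition`, `baseline_hz`, `n_isi_used`.
#' @export
extract_features <- function(train, session, mode = c("pavlovian", "operant"),
                             config = classify_config()) {
  mode <- match.arg(mode)
  ev <- session$events
  al <- mode_alignments(session, mode)
  if (!length(al$primary)) stop("no reference events for feature extraction", call. = FALSE)

  b20 <- bin_spikes(train, al$primary, c(0.05, 1.0), 0.02)
  m <- colMeans(b20$counts)
  pk <- which.max(m)                       # which.max returns the earliest tie
  peak_time <- b20$bin_starts[pk] + 0.01   # bin midpoint

  ts <- train$spike_times
  excl_ev <- sort(ev$time[ev$event_type %in% c("cue_on", "reward_delivery")])
  cv <- NA_real_
  n_isi <- 0L
  if (length(ts) >= 3L) {
    inside <- function(x) {
      if (!length(excl_ev)) return(rep(FALSE, length(x)))
      i <- findInterval(x - 1e-12, excl_ev)   # last event strictly before x
      i > 0 & (x - excl_ev[pmax(i, 1L)]) <= 0.5
    }
    keep <- !(inside(ts[-length(ts)]) | inside(ts[-1L]))
    isi <- diff(ts)[keep]
    n_isi <- length(isi)
    if (n_isi >= 3L) cv <- stats::sd(isi) / mean(isi)
  }

  B <- baseline_rate(train, session, method = config$baseline_method)
  rew <- ev$time[ev$event_type == "reward_delivery"]
  inh <- NA_real_
  if (length(rew)) {
    if (mode == "pavlovian") {
      R <- mean(window_rates(train, rew, config$inhibition_window))
    } else {
      R <- min(mean(window_rates(train, rew, c(-1, 0))),
               mean(window_rates(train, rew, c(0, 1))))
    }
    inh <- inhibition_index(R, B)
  }
  data.frame(unit_id = train$unit_id, peak_time = peak_time, isi_cv = cv,
             inhibition = inh, baseline_hz = B, n_isi_used = n_isi,
             stringsAsFactors = FALSE)
}

# deterministic replicated k-means; rows are canonically ordered first so the
# result is invariant to input permutation
kmeans_replicated <- function(x, k, replicates, seed) {
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  best <- NULL
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, paste0("kmeans", r)))
    km <- tryCatch(stats::kmeans(xs, centers = k, iter.max = 100),
                   error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
  }
  if (is.null(best)) stop("k-means failed on all replicates", call. = FALSE)
  cl <- integer(nrow(x))
  cl[ord] <- best$cluster
  list(cluster = cl, centers = best$centers, tot.withinss = best$tot.withinss)
}

#' k-means refinement of the phasic cluster
#'
#' Separates the atypical subpopulation (delayed peak, labile firing,
#' sustained reward inhibition) from canonical dopamine-like units.
#' Features log(peak_time), log(isi_cv) and inhibition are z-scored, reduced
#' to the first two principal components and clustered with k-means (k = 2,
#' Euclidean distance, best of `replicates` seeded initializations by total
#' within-cluster sum of squares; ties broken by the lowest replicate index).
#' The atypical cluster is the one whose centroid has the larger mean
#' log(peak_time), ties broken by the more negative inhibition centroid.
#'
#' @param features data.frame from [extract_features()] rows (units with
#'   baseline <= 12 Hz only; high-baseline units are excluded upstream).
#' @param k,replicates k-means settings (defaults 2 and 20).
#' @param seed integer seed controlling all replicate initializations.
#' @return logical vector of atypical flags named by unit id.
#' @export
refine_phasic <- function(features, k = 2, replicates = 20, seed = 1) {
  if (nrow(features) < 2 * k) stop("need at least 2k units for refinement", call. = FALSE)
  if (any(features$peak_time <= 0) || any(features$isi_cv <= 0, na.rm = TRUE)) {
    stop("peak_time and isi_cv must be positive for log transform", call. = FALSE)
  }
  if (anyNA(features$isi_cv) || anyNA(features$inhibition)) {
    stop("features contain NA (units flagged upstream must be removed)", call. = FALSE)
  }
  x <- cbind(log_peak = log(features$peak_time),
             log_cv = log(features$isi_cv),
             inhibition = features$inhibition)
  if (all(apply(x, 2, stats::sd) < 1e-10)) {
    stop("degenerate feature set: all units identical; refusing arbitrary split",
         call. = FALSE)
  }
  keep <- apply(x, 2, stats::sd) > 0
  z <- zscore_cols(x[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  km <- kmeans_replicated(sc, k, replicates, seed)
  mean_logpeak <- vapply(seq_len(k), function(g) mean(x[km$cluster == g, "log_peak"]), numeric(1))
  mx <- max(mean_logpeak)
  cand <- which(mean_logpeak > mx - 1e-9)
  if (length(cand) > 1L) {
    mean_inh <- vapply(cand, function(g) mean(x[km$cluster == g, "inhibition"]), numeric(1))
    cand <- cand[which.min(mean_inh)]
  }
  flags <- km$cluster == cand[1]
  names(flags) <- features$unit_id
  flags
}

#' Exclusion-cascade bookkeeping
#'
#' Telescopes the stage counts of the identification cascade: starting from
#' the phasic cluster, units excluded for high baseline firing, atypical
#' k-means membership, and manual curation leave the putative-dopamine count.
#'
#' @param n_phasic units in the phasic cluster.
#' @param n_high_baseline excluded with baseline > 12 Hz.
#' @param n_atypical excluded by the k-means refinement.
#' @param n_manual manually excluded.
#' @return named list of all stage counts including `n_putative`.
#' @export
exclusion_cascade <- function(n_phasic, n_high_baseline = 0, n_atypical = 0,
                              n_manual = 0) {
  counts <- list(n_phasic = as.integer(n_phasic),
                 n_high_baseline = as.integer(n_high_baseline),
                 n_atypical = as.integer(n_atypical),
                 n_manual = as.integer(n_manual))
  counts$n_putative <- counts$n_phasic - counts$n_high_baseline -
    counts$n_atypical - counts$n_manual
  if (counts$n_putative < 0) stop("exclusions exceed phasic-cluster size", call. = FALSE)
  counts
}

#' Full putative-dopamine classification cascade
#'
#' Runs screen -> [response_matrix()] -> [cluster_functional()] -> keep the
#' phasic cluster -> exclude baseline > 12 Hz -> [refine_phasic()] -> apply
#' manual exclusions, and reports per-unit labels with full provenance. A
#' unit's final label is `putative_dopamine` iff its exclusion reason is
#' `none`.
#'
#' @param session a [session()].
#' @param mode `"pavlovian"` or `"operant"`.
#' @param manual_exclusions character vector of unit ids to remove at the end.
#' @param config see [classify_config()].
#' @param seed seed for the k-means replicates.
#' @return Class `classification_report`: `units` data.frame (unit_id,
#'   screened, cluster_label, baseline_hz, features, atypical, reason,
#'   putative_dopamine), `counts` (stage counts), `assignment`, `features`.
#' @export
classify_units <- function(session, mode = c("pavlovian", "operant"),
                           manual_exclusions = character(),
                           config = classify_config(), seed = 1) {
  mode <- match.arg(mode)
  mat <- response_matrix(session, mode, config = config)
  al <- mode_alignments(session, mode)
  base_win <- if (mode == "pavlovian") c(-0.5, 0) else c(-0.25, 0)
  trains0 <- session$spike_trains
  names(trains0) <- vapply(trains0, function(tr) tr$unit_id, character(1))
  screened <- vapply(rownames(mat), function(u) {
    screen_unit(trains0[[u]], al$primary, base_win, config)
  }, logical(1))
  all_ids <- rownames(mat)

  units <- data.frame(unit_id = all_ids, screened = screened,
                      cluster_label = NA_character_, baseline_hz = NA_real_,
                      peak_time = NA_real_, isi_cv = NA_real_,
                      inhibition = NA_real_, atypical = FALSE,
                      reason = "not_responsive", stringsAsFactors = FALSE)

  if (sum(screened) < 3) stop("stage screen: fewer than 3 cue-responsive units", call. = FALSE)
  assignment <- tryCatch(cluster_functional(mat[screened, , drop = FALSE]),
                         error = function(e) stop("stage cluster_functional: ",
                                                  conditionMessage(e), call. = FALSE))
  lab <- assignment$labels[assignment$cluster]
  units$cluster_label[match(names(assignment$cluster), units$unit_id)] <- lab
  units$reason[which(units$screened & units$cluster_label != "phasic")] <- "non_phasic_cluster"

  phasic_ids <- names(assignment$cluster)[lab == "phasic"]
  trains <- session$spike_trains
  names(trains) <- vapply(trains, function(tr) tr$unit_id, character(1))
  feats <- do.call(rbind, lapply(phasic_ids, function(u) {
    extract_features(trains[[u]], session, mode, config)
  }))
  idx <- match(feats$unit_id, units$unit_id)
  units$baseline_hz[idx] <- feats$baseline_hz
  units$peak_time[idx] <- feats$peak_time
  units$isi_cv[idx] <- feats$isi_cv
  units$inhibition[idx] <- feats$inhibition

  high <- feats$unit_id[feats$baseline_hz > config$baseline_max_hz]
  units$reason[units$unit_id %in% high] <- "high_baseline"
  keep <- feats[!feats$unit_id %in% high, , drop = FALSE]

  if (nrow(keep) >= 4) {
    flags <- tryCatch(refine_phasic(keep, seed = seed),
                      error = function(e) stop("stage refine_phasic: ",
                                               conditionMessage(e), call. = FALSE))
    atyp <- names(flags)[flags]
    units$atypical[units$unit_id %in% atyp] <- TRUE
    units$reason[units$unit_id %in% atyp] <- "atypical_kmeans"
  } else {
    atyp <- character()
  }

  remaining <- setdiff(keep$unit_id, atyp)
  man <- intersect(manual_exclusions, remaining)
  units$reason[units$unit_id %in% man] <- "manual"
  units$reason[units$unit_id %in% setdiff(remaining, man)] <- "none"
  units$putative_dopamine <- units$reason == "none"

  counts <- exclusion_cascade(length(phasic_ids), length(high), length(atyp), length(man))
  counts <- c(list(n_units = nrow(units), n_screened = sum(screened),
                   n_not_responsive = sum(!screened),
                   n_excited = sum(units$cluster_label == "excited", na.rm = TRUE),
                   n_inhibited = sum(units$cluster_label == "inhibited", na.rm = TRUE)),
              counts)
  structure(list(units = units, counts = counts, assignment = assignment,
                 features = feats, mode = mode, seed = seed,
                 session_id = session$session_id),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  with(x$counts, cat(sprintf(
    paste0("<classification_report> %s (%s): %d units; %d screened in; ",
           "%d phasic (%d excited, %d inhibited); excluded %d high-baseline, ",
           "%d atypical, %d manual -> %d putative dopamine\n"),
    x$session_id, x$mode, n_units, n_screened, n_phasic, n_excited,
    n_inhibited, n_high_baseline, n_atypical, n_manual, n_putative)))
  invisible(x)
}
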