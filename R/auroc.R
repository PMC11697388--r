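# auROC normalization of peri-event activity against a pre-event baseline.
#
# The per-bin statistic is the probability that a randomly drawn test-bin
# spike count exceeds a randomly drawn baseline count, ties counted 1/2 --
# the Mann-Whitney U statistic divided by n_test * n_baseline, identical to
# the area under the ROC curve swept over count thresholds. 0.5 means the two
# distributions are indistinguishable; > 0.5 excitation, < 0.5 inhibition.

#' Per-bin auROC value
#'
#' @param test_counts integer spike counts across trials in the test bin.
#' @param baseline_counts integer baseline spike counts.
#' @return value in `[0, 1]`.
#' @export
auroc_bin <- function(test_counts, baseline_counts) {
  nt <- length(test_counts); nb <- length(baseline_counts)
  if (!nt || !nb) stop("auroc_bin: both samples must be non-empty", call. = FALSE)
  r <- rank(c(test_counts, baseline_counts))
  u <- sum(r[seq_len(nt)]) - nt * (nt + 1) / 2
  u / (nt * nb)
}

# Fast path for repeated comparisons against the same baseline sample:
# precompute the sorted baseline, then each test count x contributes
# (#baseline < x) + (#baseline == x)/2 wins. Counts must be integers.
auroc_vs_sorted_baseline <- function(test_counts, sorted_baseline) {
  nb <- length(sorted_baseline)
  less <- findInterval(test_counts - 0.5, sorted_baseline)
  leq <- findInterval(test_counts + 0.5, sorted_baseline)
  mean(less + (leq - less) / 2) / nb
}

#' auROC trace of a binned response against a baseline response
#'
#' For each bin of `binned`, the across-trial count distribution is compared
#' to the baseline distribution. By default the baseline sample pools the
#' per-bin counts across all bins and trials of `baseline_binned` (the 0.5-s
#' pre-event window in the Pavlovian task); `baseline_mode = "per_bin"`
#' instead compares bin `j` against baseline bin `j %% n_baseline_bins`,
#' trial-matched pooling only across trials.
#'
#' @param binned test [bin_spikes()] result.
#' @param baseline_binned baseline [bin_spikes()] result; same unit and
#'   bin width.
#' @param baseline_mode `"pooled"` (default) or `"per_bin"`.
#' @return Class `auroc_trace`: `values` in `[0,1]` per bin, `bin_starts`,
#'   `bin_width`, `unit_id`, `baseline_window`.
#' @export
auroc_trace <- function(binned, baseline_binned, baseline_mode = c("pooled", "per_bin")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(inherits(binned, "binned_response"), inherits(baseline_binned, "binned_response"))
  if (abs(binned$bin_width - baseline_binned$bin_width) > 1e-12) {
    stop("mismatched bin widths between test and baseline responses", call. = FALSE)
  }
  if (!identical(binned$unit_id, baseline_binned$unit_id)) {
    stop("auroc_trace: test and baseline must come from the same unit", call. = FALSE)
  }
  vals <- if (baseline_mode == "pooled") {
    sb <- sort(as.vector(baseline_binned$counts))
    apply(binned$counts, 2L, auroc_vs_sorted_baseline, sorted_baseline = sb)
  } else {
    nbb <- ncol(baseline_binned$counts)
    vapply(seq_len(ncol(binned$counts)), function(j) {
      auroc_bin(binned$counts[, j], baseline_binned$counts[, ((j - 1L) %% nbb) + 1L])
    }, numeric(1))
  }
  structure(list(unit_id = binned$unit_id, values = as.numeric(vals),
                 bin_starts = binned$bin_starts, bin_width = binned$bin_width,
                 baseline_window = baseline_binned$window),
            class = "auroc_trace")
}

#' @export
print.auroc_trace <- function(x, ...) {
  cat(sprintf("<auroc_trace> unit %s: %d bins, range [%.3f, %.3f]\n",
              x$unit_id, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
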