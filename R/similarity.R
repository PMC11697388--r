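# Case-control similarity analysis: PCA composite of four measures, a
# bootstrapped centroid-distance similarity score, a shuffled-label null
# distribution, and a two-tailed 95% percentile test.
#
# Sign convention: score = mean distance(naive -> target centroid) minus
# mean distance(exposed -> target centroid), so negative values reflect
# greater similarity of the target to the naive group.

#' PCA composite embedding of session (or unit) measures
#'
#' The four measures are z-scored by default (they carry heterogeneous
#' units) and reduced by PCA; the first two component scores are retained.
#'
#' @param table data.frame with one row per session/unit.
#' @param measure_names character vector naming the 4 measure columns.
#' @param group_col name of the group-label column (default `"group"`).
#' @param scale z-score the measures before PCA (default TRUE).
#' @return Class `composite_embedding`: `scores` (rows x 2), `group`,
#'   `loadings`, `var_explained`, `measure_names`.
#' @export
composite_embedding <- function(table, measure_names, group_col = "group",
                                scale = TRUE) {
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  miss <- setdiff(c(measure_names, group_col), names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(table[, measure_names])
  if (!all(is.finite(x))) stop("measures must be finite in every retained row", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant measure column(s): ",
         paste(measure_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  structure(list(scores = pc$x[, 1:2, drop = FALSE],
                 group = as.character(table[[group_col]]),
                 loadings = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 measure_names = measure_names),
            class = "composite_embedding")
}

#' @export
print.composite_embedding <- function(x, ...) {
  cat(sprintf("<composite_embedding> %d rows; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), 100 * sum(x$var_explained[1:2])))
  invisible(x)
}

# Euclidean distance of each embedding row to the target-group centroid
distances_to_target <- function(embedding, target) {
  sc <- embedding$scores
  tc <- colMeans(sc[embedding$group == target, , drop = FALSE])
  sqrt(rowSums(sweep(sc, 2, tc)^2))
}

# bootstrap means of d over resamples of idx; RNG keyed by (seed, key) so a
# group's resampling stream depends on its label, not its role -- swapping
# the naive/exposed roles therefore flips the score sign exactly
boot_group_means <- function(d, idx, n_boot, seed, key) {
  set.seed(derive_seed(seed, key))
  m <- matrix(sample(d[idx], n_boot * length(idx), replace = TRUE), nrow = n_boot)
  rowMeans(m)
}

#' Bootstrapped centroid-distance similarity score
#'
#' The target centroid is the mean of the target rows in PC space. Each
#' bootstrap draw resamples the naive and exposed rows with replacement
#' (keeping group sizes) and computes the mean Euclidean distance of each
#' resampled group to the target centroid; the draw's score is
#' `mean_dist(naive) - mean_dist(exposed)` and the observed score is the
#' average over `n_boot` draws. Negative scores mean the target is closer
#' to the naive group.
#'
#' @param embedding a [composite_embedding()].
#' @param target,naive,exposed group labels present in the embedding.
#' @param n_boot number of bootstrap draws (default 2000).
#' @param seed integer seed.
#' @return list: `score`, `draws` (length `n_boot`), `n` per group.
#' @export
similarity_score <- function(embedding, target, naive, exposed,
                             n_boot = 2000, seed = 1) {
  g <- embedding$group
  for (lab in c(target, naive, exposed)) {
    if (!any(g == lab)) stop("empty group: ", lab, call. = FALSE)
  }
  d <- distances_to_target(embedding, target)
  mn <- boot_group_means(d, which(g == naive), n_boot, seed, naive)
  me <- boot_group_means(d, which(g == exposed), n_boot, seed, exposed)
  draws <- mn - me
  list(score = mean(draws), draws = draws,
       n = c(target = sum(g == target), naive = sum(g == naive),
             exposed = sum(g == exposed)))
}

#' Shuffled-label null distribution and percentile test
#'
#' Null scores are computed under random relabelings of the pooled naive +
#' exposed rows that preserve the group sizes. With `inner_mode = "direct"`
#' (default) each null score is the relabeled centroid-distance difference
#' itself; `inner_mode = "bootstrap"` additionally runs an inner bootstrap of
#' `n_boot` draws per relabeling (computationally heavy; intended for
#' fidelity checks at reduced `n_null`). Significance is two-tailed at 95%:
#' the observed score is significant iff its percentile within the null lies
#' outside [2.5, 97.5].
#'
#' @param embedding a [composite_embedding()].
#' @param target,naive,exposed group labels.
#' @param n_null number of relabeled scores (default 50000).
#' @param n_boot bootstrap draws for the observed score (default 2000).
#' @param inner_mode `"direct"` or `"bootstrap"`.
#' @param seed integer seed.
#' @return Class `similarity_result`: `observed`, `null_scores`,
#'   `percentile`, `significant`, `n_boot`, `n_null`, `seed`.
#' @export
null_distribution <- function(embedding, target, naive, exposed,
                              n_null = 50000, n_boot = 2000,
                              inner_mode = c("direct", "bootstrap"), seed = 1) {
  inner_mode <- match.arg(inner_mode)
  if (n_null < 100) warning("n_null < 100: percentile estimate will be unstable")
  obs <- similarity_score(embedding, target, naive, exposed, n_boot, seed)
  g <- embedding$group
  d <- distances_to_target(embedding, target)
  pool <- which(g %in% c(naive, exposed))
  n_naive <- sum(g == naive)
  set.seed(derive_seed(seed, "null"))
  null_scores <- if (inner_mode == "direct") {
    vapply(seq_len(n_null), function(b) {
      lab <- sample(pool)
      mean(d[lab[seq_len(n_naive)]]) - mean(d[lab[-seq_len(n_naive)]])
    }, numeric(1))
  } else {
    vapply(seq_len(n_null), function(b) {
      lab <- sample(pool)
      ni <- lab[seq_len(n_naive)]
      ei <- lab[-seq_len(n_naive)]
      mean(matrix(sample(d[ni], n_boot * length(ni), replace = TRUE),
                  nrow = n_boot) |> rowMeans()) -
        mean(matrix(sample(d[ei], n_boot * length(ei), replace = TRUE),
                    nrow = n_boot) |> rowMeans())
    }, numeric(1))
  }
  pct <- 100 * (sum(null_scores < obs$score) + 0.5 * sum(null_scores == obs$score)) / n_null
  structure(list(observed = obs$score, null_scores = null_scores,
                 percentile = pct, significant = pct < 2.5 || pct > 97.5,
                 n_boot = n_boot, n_null = n_null, seed = seed,
                 groups = obs$n),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(paste0("<similarity_result> observed score %.4f (%s the naive group), ",
                     "percentile %.2f of %d null scores%s\n"),
              x$observed, if (x$observed < 0) "closer to" else "farther from",
              x$percentile, x$n_null,
              if (x$significant) " [significant, two-tailed 95%]" else ""))
  invisible(x)
}

#' Rank correlation between behavioral and firing principal components
#'
#' Spearman rank correlation with a two-tailed test, delegated to
#' [stats::cor.test()]. Pairs with missing values are dropped and counted.
#'
#' @param behavior_pc1,firing_pc1 paired per-session values.
#' @return list: `rho`, `p_value`, `n_used`, `n_dropped`.
#' @export
pc_correlation <- function(behavior_pc1, firing_pc1) {
  if (length(behavior_pc1) != length(firing_pc1)) {
    stop("inputs must be paired (equal length)", call. = FALSE)
  }
  ok <- is.finite(behavior_pc1) & is.finite(firing_pc1)
  x <- behavior_pc1[ok]; y <- firing_pc1[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("all-tied input: correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n_used = length(x),
                n_dropped = sum(!ok)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_used = length(x), n_dropped = sum(!ok))
}
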