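test_that("composite embedding retains two components and reports variance", {
  set.seed(61)
  lat <- rnorm(30)
  tbl <- data.frame(group = rep(c("naive", "exposed", "target"), each = 10),
                    m1 = lat + rnorm(30, 0, 0.3), m2 = 2 * lat + rnorm(30, 0, 0.3),
                    m3 = -lat + rnorm(30, 0, 0.3), m4 = 0.5 * lat + rnorm(30, 0, 0.3))
  emb <- composite_embedding(tbl, paste0("m", 1:4))
  expect_equal(ncol(emb$scores), 2L)
  expect_equal(sum(emb$var_explained), 1)

  # exactly rank-2 measures: first two PCs explain everything
  tbl2 <- tbl
  tbl2$m3 <- 2 * tbl2$m1
  tbl2$m4 <- -tbl2$m2
  emb2 <- composite_embedding(tbl2, paste0("m", 1:4), scale = FALSE)
  expect_equal(sum(emb2$var_explained[1:2]), 1, tolerance = 1e-9)

  tbl3 <- tbl; tbl3$m2 <- 1
  expect_error(composite_embedding(tbl3, paste0("m", 1:4)), "m2")
  expect_error(composite_embedding(tbl[1:2, ], paste0("m", 1:4)), "at least 3")
})

test_that("orthonormal rotation of measures leaves PC-space distances unchanged", {
  set.seed(63)
  x <- matrix(rnorm(80), 20, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  t1 <- data.frame(group = "g", x); names(t1)[2:5] <- paste0("m", 1:4)
  t2 <- data.frame(group = "g", x %*% q); names(t2)[2:5] <- paste0("m", 1:4)
  e1 <- composite_embedding(t1, paste0("m", 1:4), scale = FALSE)
  e2 <- composite_embedding(t2, paste0("m", 1:4), scale = FALSE)
  expect_equal(as.matrix(dist(e1$scores)), as.matrix(dist(e2$scores)),
               tolerance = 1e-8)
})

test_that("similarity score is exact on degenerate geometry and flips sign on swap", {
  emb <- structure(list(scores = matrix(c(0, 0, 4, 4, 0)),
                        group = c("n", "n", "e", "e", "t")),
                   class = "composite_embedding")
  expect_equal(similarity_score(emb, "t", "n", "e", n_boot = 100, seed = 1)$score, -4)

  tbl <- simulate_measure_table(seed = 7)
  e <- composite_embedding(tbl, paste0("m", 1:4))
  s1 <- similarity_score(e, "target", "naive", "exposed", seed = 9)
  s2 <- similarity_score(e, "target", "exposed", "naive", seed = 9)
  expect_identical(s1$score, -s2$score)
  expect_identical(s1$draws, -s2$draws)
  expect_error(similarity_score(e, "target", "nope", "exposed"), "empty group")
})

test_that("exchangeable groups give a near-zero score and a centered null", {
  tbl <- simulate_measure_table(group_shift = 0, seed = 71)
  emb <- composite_embedding(tbl, paste0("m", 1:4))
  ss <- similarity_score(emb, "target", "naive", "exposed", seed = 3)
  expect_lt(abs(ss$score), 3 * stats::sd(ss$draws))

  r <- null_distribution(emb, "target", "naive", "exposed",
                         n_null = 4000, n_boot = 500, seed = 3)
  expect_lt(abs(mean(r$null_scores)), 3 * stats::sd(r$null_scores) / sqrt(4000))
  expect_true(r$percentile >= 0 && r$percentile <= 100)
  expect_identical(r$significant, r$percentile < 2.5 || r$percentile > 97.5)
  expect_warning(null_distribution(emb, "target", "naive", "exposed",
                                   n_null = 50, n_boot = 50, seed = 1), "unstable")
})

test_that("a planted target-naive affinity is detected with high power", {
  # the target centroid has finite-sample spread, so the claim is about
  # detection frequency across datasets, not any single draw
  res <- lapply(1:10, function(i) {
    tbl <- simulate_measure_table(seed = 500 + i)  # defaults: shift 2, naive affinity
    emb <- composite_embedding(tbl, paste0("m", 1:4))
    null_distribution(emb, "target", "naive", "exposed", n_null = 2000, seed = i)
  })
  obs <- vapply(res, `[[`, numeric(1), "observed")
  pct <- vapply(res, `[[`, numeric(1), "percentile")
  expect_true(all(obs < 0))
  expect_gte(mean(pct < 2.5), 0.8)
})

test_that("independent null 2.5/97.5 percentiles agree within Monte-Carlo error", {
  tbl <- simulate_measure_table(group_shift = 0, seed = 75)
  emb <- composite_embedding(tbl, paste0("m", 1:4))
  q1 <- quantile(null_distribution(emb, "target", "naive", "exposed",
                                   n_null = 10000, n_boot = 200, seed = 11)$null_scores,
                 c(0.025, 0.975))
  q2 <- quantile(null_distribution(emb, "target", "naive", "exposed",
                                   n_null = 10000, n_boot = 200, seed = 12)$null_scores,
                 c(0.025, 0.975))
  spread <- diff(range(q1, q2))
  expect_lt(max(abs(q1 - q2)), 0.15 * abs(diff(q1)) + 1e-9)
  expect_gt(spread, 0)
})

test_that("rank correlation delegates to the standard Spearman test", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(pc_correlation(x, x)$rho, 1)
  expect_equal(pc_correlation(x, -x)$rho, -1)
  set.seed(77)
  a <- rnorm(22); b <- rnorm(22)
  pc <- pc_correlation(a, b)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(pc$rho, unname(ref$estimate))
  expect_equal(pc$p_value, ref$p.value)

  a[3] <- NA
  expect_equal(pc_correlation(a, b)$n_dropped, 1L)
  expect_warning(out <- pc_correlation(rep(1, 6), 1:6), "tied")
  expect_true(is.na(out$rho))
  expect_error(pc_correlation(1:3, 1:3), "at least 4")
})
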