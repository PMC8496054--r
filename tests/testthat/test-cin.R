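test_that("CPM normalization conserves the per-sample million", {
  expect_equal(unname(cpm_normalize(matrix(25, 1, 1))[1, 1]), 1e6)
  two <- cpm_normalize(matrix(c(25, 75), ncol = 1))
  expect_equal(as.numeric(two), c(250000, 750000))

  set.seed(5)
  m <- matrix(rpois(600, 40), nrow = 30)
  cpm <- cpm_normalize(m)
  expect_equal(colSums(cpm), rep(1e6, ncol(m)), tolerance = 1e-9)
  # independent cross-check against the edgeR implementation
  expect_equal(unname(cpm), unname(edgeR::cpm(m)), tolerance = 1e-9)

  bad <- matrix(c(1, 2, 0, 0), nrow = 2,
    dimnames = list(NULL, c("s1", "s2")))
  expect_error(cpm_normalize(bad), "s2")
  expect_error(cpm_normalize(matrix(-1, 1, 1)), "non-negative")
})

test_that("signature scores match the hand-computed scaling oracle", {
  mat <- rbind(
    g1 = c(1, 2, 3, 4),
    g2 = c(2, 4, 8, 6),
    g3 = c(5, 5, 5, 9)
  )
  colnames(mat) <- paste0("s", 1:4)
  # per-gene SDs (n - 1): sqrt(5/3), sqrt(20/3), 2
  sd1 <- sqrt(5 / 3)
  sd2 <- sqrt(20 / 3)
  expected <- c(
    -1.5 / sd1 - 3 / sd2 - 0.5,
    -0.5 / sd1 - 1 / sd2 - 0.5,
    0.5 / sd1 + 3 / sd2 - 0.5,
    1.5 / sd1 + 1 / sd2 + 1.5
  )
  scores <- score_signature(mat, c("g1", "g2", "g3"))
  expect_equal(scores$score, expected, tolerance = 1e-12)
  expect_equal(sum(scores$score), 0, tolerance = 1e-12)
})

test_that("signature scoring handles degenerate and partial gene sets", {
  flat <- matrix(3, nrow = 2, ncol = 4,
    dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_warning(sc <- score_signature(flat, c("g1", "g2")), "zero-variance")
  expect_equal(sc$score, rep(0, 4))

  two <- matrix(c(1, 5), nrow = 1, dimnames = list("g1", c("s1", "s2")))
  sc <- score_signature(two, "g1")
  expect_equal(sc$score, c(-1, 1) / sqrt(2))

  m <- matrix(rnorm(20), nrow = 5,
    dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(sc <- score_signature(m, c("g1", "g2", "ABSENT")), "absent")
  expect_equal(attr(sc, "missing_genes"), "ABSENT")
  expect_error(score_signature(m, c("X", "Y")), "no signature genes")
})

test_that("scores sum to zero and are invariant to sample order", {
  cohort <- simulate_expression_cohort(expression_cohort_spec(seed = 13))
  logcpm <- cpm_normalize(cohort$counts, log2 = TRUE)
  scores <- score_signature(logcpm, cin25_genes())
  expect_equal(sum(scores$score), 0, tolerance = 1e-8)

  perm <- sample(ncol(logcpm))
  scores_perm <- score_signature(logcpm[, perm], cin25_genes())
  merged <- dplyr::inner_join(scores, scores_perm,
    by = "sample_id", suffix = c("", "_perm"))
  expect_equal(merged$score, merged$score_perm, tolerance = 1e-10)
})

test_that("k-means recovers planted blobs and degenerate optima", {
  set.seed(6)
  centers <- c(-5, 0, 5)
  truth <- rep(1:3, each = 10)
  mat <- sapply(truth, function(g) rnorm(8, mean = centers[g], sd = 0.3))
  rownames(mat) <- paste0("g", 1:8)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  cl <- kmeans_cluster(mat, k = 3, seed = 2)
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
  expect_equal(
    adjusted_rand_index(cl$cluster, truth),
    mclust::adjustedRandIndex(cl$cluster, truth)
  )

  one <- kmeans_cluster(mat, k = 1, seed = 2)
  expect_true(all(one$cluster == 1))
  pts <- t(scale_genes(mat))
  expect_equal(
    attr(one, "within_ss"),
    sum(sweep(pts, 2, colMeans(pts))^2),
    tolerance = 1e-8
  )

  profiles <- matrix(c(0, 0, 5, 5, 10, 10), nrow = 2)
  dup <- profiles[, rep(1:3, each = 4)]
  rownames(dup) <- c("g1", "g2")
  colnames(dup) <- paste0("s", 1:12)
  cl <- kmeans_cluster(dup, k = 3, seed = 3)
  expect_equal(attr(cl, "within_ss"), 0, tolerance = 1e-10)
  expect_equal(adjusted_rand_index(cl$cluster, rep(1:3, each = 4)), 1)

  expect_error(kmeans_cluster(mat[, 1:2], k = 3), "exceed")
})

test_that("median split sends ties low and is deterministic", {
  sc <- tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4))
  split <- median_split(sc)
  expect_equal(split$group, c("low", "low", "high", "high"))

  odd <- median_split(tibble::tibble(sample_id = letters[1:5], score = 1:5))
  expect_equal(odd$group[3], "low")

  expect_warning(
    split <- median_split(tibble::tibble(sample_id = letters[1:3],
      score = c(2, 2, 2))),
    "low group"
  )
  expect_true(all(split$group == "low"))
})

test_that("Kaplan-Meier curves match the hand-computed product-limit table", {
  none <- km_curve(tibble::tibble(
    time = c(3, 5, 7), event = c(FALSE, FALSE, FALSE), group = "all"
  ))
  expect_true(all(none$survival == 1))

  two <- km_curve(tibble::tibble(
    time = c(1, 2), event = c(TRUE, TRUE), group = "all"
  ))
  expect_equal(two$survival[two$time == 1], 0.5)
  expect_equal(two$survival[two$time == 2], 0)

  # 6 records, censoring at t = 2 and 5:
  # S(1) = 5/6, S(3) = 5/6 * 3/4, S(4) = that * 2/3, S(6) = 0
  mixed <- km_curve(tibble::tibble(
    time = 1:6, event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    group = "all"
  ))
  ev <- mixed[mixed$n_event == 1 & !is.na(mixed$n_risk), ]
  expect_equal(ev$survival, c(5 / 6, 5 / 8, 5 / 12, 0))
  expect_true(all(diff(mixed$survival) <= 1e-12))
  expect_error(km_curve(tibble::tibble(time = -1, event = TRUE)), "negative")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(8)
  t <- rexp(40, 0.1)
  curve <- km_curve(tibble::tibble(time = t, event = TRUE, group = "all"))
  pts <- curve[curve$time > 0, ]
  emp <- vapply(pts$time, function(u) mean(t > u), numeric(1))
  expect_equal(pts$survival, emp, tolerance = 1e-10)
})

test_that("log-rank test behaves at its boundary cases", {
  same <- tibble::tibble(
    time = rep(c(1, 2, 3, 4), 2), event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
    group = rep(c("a", "b"), each = 4)
  )
  res <- logrank_test(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  expect_error(
    logrank_test(tibble::tibble(time = 1:4, event = FALSE,
      group = rep(c("a", "b"), 2))),
    "without any events"
  )
  expect_error(
    logrank_test(tibble::tibble(time = 1:4, event = TRUE, group = "a")),
    "at least 2 groups"
  )
})

test_that("chi-square log-rank p matches a permutation oracle on a small cohort", {
  surv <- simulate_survival(
    n = c(a = 10, b = 10), hazard = c(a = 0.04, b = 0.08),
    censor_time = 40, seed = 19
  )
  res <- logrank_test(surv)
  obs <- res$statistic
  set.seed(20)
  perm_stats <- vapply(1:400, function(i) {
    shuffled <- surv
    shuffled$group <- sample(shuffled$group)
    logrank_test(shuffled)$statistic
  }, numeric(1))
  p_perm <- mean(perm_stats >= obs)
  expect_lt(abs(res$p_value - p_perm), 0.08)
})

test_that("planted high-CIN cluster is recovered from a synthetic cohort", {
  spec <- expression_cohort_spec(seed = 41)
  cohort <- simulate_expression_cohort(spec)
  logcpm <- cpm_normalize(cohort$counts, log2 = TRUE)
  scores <- score_signature(logcpm, spec$signature_genes)
  clusters <- kmeans_cluster(logcpm, genes = spec$signature_genes,
    k = 3, seed = 41)
  rec <- cluster_recovery(clusters, scores, cohort$samples)
  expect_gte(rec$ari, 0.9)
  expect_gte(rec$planted_capture, 0.9)
  expect_equal(rec$ari, mclust::adjustedRandIndex(
    clusters$cluster == rec$top_cluster,
    cohort$samples$planted
  ))
})
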