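test_that("window enrichment p-value matches closed-form binomial sums", {
  expect_equal(window_enrichment_p(5, 5, 10, 100), 1e-5)
  expect_equal(window_enrichment_p(0, 7, 10, 100), 1.0)
  expect_equal(window_enrichment_p(2, 10, 20, 100),
               1 - 0.8^10 - 10 * 0.2 * 0.8^9)
  expect_error(window_enrichment_p(1, 2, 10, 0), "positive")
  expect_error(window_enrichment_p(5, 2, 10, 100), "k_in")
})

test_that("fixed-window scan flags concentrated variants and not empty proteins", {
  # all variants inside one window-sized interval
  v <- variant_positions(200, c(40, 42, 45, 47, 50, 53), "case")
  hits <- scan_fixed_window(v, 20, 0.05)
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$start <= 40 & hits$end >= 53))
  expect_true(all(hits$p_raw < 0.05))
  # no variants -> no windows
  empty <- variant_positions(200, integer(), "case")
  expect_equal(nrow(scan_fixed_window(empty, 20)), 0)
  # uniform null: the share of raw-significant windows stays near alpha
  set.seed(71)
  frac <- replicate(100, {
    v <- variant_positions(300, sample.int(300, 12), "case")
    nrow(scan_fixed_window(v, 30, 0.05)) / (300 - 30 + 1)
  })
  expect_lt(mean(frac), 0.10)   # expectation <= 0.05, MC slack for correlation
})

test_that("clustering objective hits the documented extremes", {
  v <- variant_positions(100, c(10, 20, 30), "case")
  exact <- data.frame(start = c(10, 20, 30), end = c(10, 20, 30))
  expect_equal(clustering_objective(exact, v), 0)
  none <- data.frame(start = integer(), end = integer())
  expect_equal(clustering_objective(none, v), 1)
  whole <- data.frame(start = 1, end = 100)
  expect_equal(clustering_objective(whole, v), 1)
  # minimal windows: specificity = 1; maximal window: sensitivity = 1
  expect_equal(cluster_performance(exact, v)$specificity, 1)
  expect_equal(cluster_performance(whole, v)$sensitivity, 1)
  expect_equal(cluster_performance(none, v)$sensitivity, 0)
  expect_error(clustering_objective(none, variant_positions(100, integer(), "case")),
               "at least one cohort")
})

test_that("window-size search refines tenfold and tracks planted hotspot width", {
  sim <- simulate_positions(sim_spec(1000, 0.02,
                                     data.frame(start = 401, end = 600,
                                                fold_enrichment = 10),
                                     seed = 3))
  w <- optimize_window_size(sim$case)
  passes <- attr(w, "fractions_tested")
  expect_gte(length(passes), 2)
  expect_equal(min(diff(passes[[1]])), 0.05, tolerance = 1e-9)
  expect_equal(min(diff(passes[[2]])), 0.005, tolerance = 1e-9)
  expect_gte(attr(w, "avg_tests_per_residue"), 1)

  # across replicates the selected size tracks the planted width (200)
  # within a factor of two in the typical case
  sizes <- vapply(1:12, function(seed) {
    sim <- simulate_positions(sim_spec(1000, 0.02,
                                       data.frame(start = 401, end = 600,
                                                  fold_enrichment = 10),
                                       seed = seed))
    as.integer(optimize_window_size(sim$case))
  }, integer(1))
  expect_false(anyNA(sizes))
  expect_true(median(sizes) >= 100 && median(sizes) <= 400)

  # pure uniform noise: no clustering detected in nearly all replicates
  nas <- vapply(1:30, function(seed) {
    sim <- simulate_positions(sim_spec(1000, 0.02, NULL, seed = 500 + seed))
    is.na(optimize_window_size(sim$case))
  }, logical(1))
  expect_gte(sum(nas), 27)
})

test_that("multiple-testing correction scales and caps p-values", {
  w <- data.frame(start = 1, end = 10, p_raw = c(0.001, 0.5))
  out <- correct_p(w, 100)
  expect_equal(out$p_corrected, c(0.1, 1.0))
  # single window tested once over the whole protein: identity
  one <- correct_p(data.frame(start = 1, end = 50, p_raw = 0.03), 1)
  expect_equal(one$p_corrected, 0.03)
  expect_error(correct_p(w, 0.5), ">= 1")
})

test_that("significant windows merge into maximal intervals", {
  w <- data.frame(start = c(10, 25), end = c(30, 45), p_raw = c(0.01, 0.002))
  m <- merge_windows(w)
  expect_equal(m[, c("start", "end")], data.frame(start = 10, end = 45))
  expect_equal(m$p_raw, 0.002)
  w2 <- data.frame(start = c(10, 40), end = c(20, 50), p_raw = c(0.01, 0.02))
  expect_equal(nrow(merge_windows(w2)), 2)
  # touching windows merge
  w3 <- data.frame(start = c(10, 21), end = c(20, 30), p_raw = c(0.01, 0.02))
  expect_equal(merge_windows(w3)[, c("start", "end")],
               data.frame(start = 10, end = 30))
  expect_equal(nrow(merge_windows(w3[0, ])), 0)
})

test_that("boundary trimming removes depleted tails, is bounded and idempotent", {
  # all variants in the left half: right end trimmed towards the last variant
  set.seed(7)
  v <- variant_positions(200, sample.int(50, 30, replace = TRUE), "case")
  tr <- trim_cluster(list(start = 1, end = 100), v)
  expect_true(tr$trimmed_right)
  expect_false(tr$trimmed_left)
  expect_lte(abs(tr$end - max(v$positions)), 2)
  # perfectly uniform coverage: unchanged
  u <- variant_positions(100, seq(5, 95, by = 5), "case")
  tru <- trim_cluster(list(start = 1, end = 100), u)
  expect_false(tru$trimmed_left || tru$trimmed_right)
  expect_equal(c(tru$start, tru$end), c(1, 100))
  # idempotence and containment over random clusters
  set.seed(42)
  for (i in 1:60) {
    v <- variant_positions(300, sample.int(300, rpois(1, 25) + 1, replace = TRUE),
                           "case")
    c1 <- trim_cluster(list(start = 30, end = 270), v)
    c2 <- trim_cluster(c1, v)
    expect_equal(c(c1$start, c1$end), c(c2$start, c2$end))
    expect_gte(c1$start, 30)
    expect_lte(c1$end, 270)
    expect_lte(c1$start, c1$end)
  }
})

test_that("cluster detection recovers a planted enriched region", {
  sim <- simulate_positions(sim_spec(1000, 0.02,
                                     data.frame(start = 401, end = 600,
                                                fold_enrichment = 10),
                                     seed = 1))
  cl <- detect_clusters(sim$case, sim$control)
  case_cl <- cl[cl$cohort == "case", ]
  expect_gt(nrow(case_cl), 0)
  expect_gte(best_jaccard(case_cl, 401, 600), 0.7)
  # structural invariants: sorted, disjoint, inside the protein
  for (co in unique(cl$cohort)) {
    cc <- cl[cl$cohort == co, ]
    expect_true(all(cc$start <= cc$end))
    expect_true(all(cc$start >= 1 & cc$end <= 1000))
    if (nrow(cc) > 1) expect_true(all(cc$start[-1] > cc$end[-nrow(cc)]))
  }
  expect_true(all(cl$p_raw < 0.05))
})

test_that("cluster detection is a pure function of its inputs", {
  sim <- simulate_positions(sim_spec(600, 0.03,
                                     data.frame(start = 101, end = 200,
                                                fold_enrichment = 8),
                                     seed = 9))
  a <- detect_clusters(sim$case, sim$control)
  b <- detect_clusters(sim$case, sim$control)
  expect_identical(a, b)
  # identical variant sets give identical calls for both cohorts
  twin <- variant_positions(600, sim$case$positions, "control")
  both <- detect_clusters(sim$case, twin)
  case_cl <- both[both$cohort == "case", setdiff(names(both), "cohort")]
  ctrl_cl <- both[both$cohort == "control", setdiff(names(both), "cohort")]
  rownames(case_cl) <- rownames(ctrl_cl) <- NULL
  expect_equal(case_cl, ctrl_cl)
  # no variants in either cohort -> no clusters
  none <- detect_clusters(variant_positions(600, integer(), "case"),
                          variant_positions(600, integer(), "control"))
  expect_equal(nrow(none), 0)
  expect_error(detect_clusters(variant_positions(10, 3, "case")), ">= 20")
})

test_that("regional EF reduces to the gene-level burden and pools intervals", {
  case <- variant_positions(500, c(50, 60, 120, 130, 300), "case",
                            carriers = c(4, 2, 6, 1, 3))
  ctrl <- variant_positions(500, c(55, 200, 310, 420), "control",
                            carriers = c(1, 2, 5, 40))
  whole <- regional_ef(data.frame(start = 1, end = 500), case, ctrl, 5000, 60000)
  gene <- burden_estimate(sum(case$carriers), 5000, sum(ctrl$carriers), 60000)
  expect_equal(whole$inside$odds_ratio, gene$odds_ratio)
  expect_equal(whole$inside$ef_ci, gene$ef_ci)
  expect_null(whole$outside)
  # union of two intervals equals the burden estimate on pooled counts
  two <- regional_ef(data.frame(start = c(40, 115), end = c(70, 140)),
                     case, ctrl, 5000, 60000)
  pooled <- burden_estimate(4 + 2 + 6 + 1, 5000, 1, 60000)
  expect_equal(two$inside$odds_ratio, pooled$odds_ratio)
  expect_equal(two$inside$p_value, pooled$p_value)
  # region empty in cases, populated in controls: EF < 0 reported as-is
  neg <- regional_ef(data.frame(start = 415, end = 430), case, ctrl, 5000, 60000)
  expect_lt(neg$inside$ef, 0)
  expect_error(regional_ef(data.frame(start = 480, end = 490), case, ctrl,
                           5000, 60000), "undefined")
})

test_that("regional OR estimates cover a known within-region odds ratio", {
  # planted region with true carrier OR = 50; the estimate's own 95% CI
  # should cover the truth in >= 90% of seeds
  n_cases <- 5000; n_ref <- 60000
  p0 <- 0.002
  odds1 <- 50 * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    a <- rbinom(1, n_cases, p1)
    b <- rbinom(1, n_ref, p0)
    case <- variant_positions(1000, 150, "case", carriers = max(a, 1))
    ctrl <- variant_positions(1000, 160, "control", carriers = max(b, 1))
    est <- regional_ef(data.frame(start = 101, end = 200), case, ctrl,
                       n_cases, n_ref)$inside
    if (est$or_ci[[1]] <= 50 && 50 <= est$or_ci[[2]]) hits <- hits + 1
  }
  expect_gte(hits, 45)
})
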