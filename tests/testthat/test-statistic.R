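test_that("aggregation filters by threshold and sums weighted counts", {
  G <- matrix(c(2, 0, 1, 2, 1, 0), ncol = 2)
  q <- c(0.02, 0.2)
  # all variants above threshold -> zero scores
  expect_equal(aggregate_scores(G, c(1, 1), q, theta = 0.01), c(0, 0, 0))
  # single passing variant with unit weight is a passthrough
  expect_equal(aggregate_scores(G, c(1, 5), q, theta = 0.05), G[, 1])
  # opposite-direction weights cancel
  expect_equal(aggregate_scores(matrix(c(2, 2), 1), c(1, -1), c(0.1, 0.1), 0.5), 0)
  expect_error(aggregate_scores(G, 1, q), "per genotype column")
})

test_that("rank-sum summary uses midranks over the pooled sample", {
  # cases hold the two largest of four scores
  expect_equal(ranksum_summary(c(3, 4, 1, 2), c(1, 1, 0, 0)), 7)
  # complete ties -> n1 (n + 1) / 2
  expect_equal(ranksum_summary(rep(0, 6), c(1, 1, 1, 0, 0, 0)), 3 * 7 / 2)
  # hand-ranked example: case scores 0.3, 0.1; control 0.2, 0.0
  expect_equal(ranksum_summary(c(0.3, 0.1, 0.2, 0.0), c(1, 1, 0, 0)), 6)
})

test_that("t-sum summary is the absolute Welch statistic", {
  # cases (1,1,1,3), controls (0,0,0,0): 1.5 / sqrt(1/4) = 3
  expect_equal(tsum_summary(c(1, 1, 1, 3, 0, 0, 0, 0),
                            rep(c(1, 0), each = 4)), 3)
  # equal group means -> 0
  expect_equal(tsum_summary(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0)
  # label swap leaves the absolute statistic unchanged
  s <- c(0.2, 0.9, 0.1, 0.4, 0.5, 0.3)
  D <- c(1, 1, 1, 0, 0, 0)
  expect_equal(tsum_summary(s, D), tsum_summary(s, 1 - D))
  # degenerate: both variances zero with different means -> Inf
  expect_equal(tsum_summary(c(1, 1, 0, 0), c(1, 1, 0, 0)), Inf)
})

test_that("threshold sets follow the observed / grid / fixed policies", {
  expect_equal(threshold_set(c(0.001, 0.001, 0.03)), c(0.001, 0.03))
  expect_equal(threshold_set(c(0.2, 0.1), policy = 0.01), 0.01)
  q <- c(0.4, 0.1, 0.25)
  expect_length(threshold_set(q), 3)
  expect_error(threshold_set(numeric(0)), "nonempty")
  expect_error(threshold_set(q, policy = numeric(0)), "nonempty")
})

test_that("method registry matches the published taxonomy", {
  reg <- gwss_methods()
  expect_equal(nrow(reg), 10)
  m <- gwss_method("VDWSS-t")
  expect_equal(m[c("weight", "summary", "threshold")],
               list(weight = "DW", summary = "t-sum", threshold = "sup"))
  expect_equal(gwss_method("ORWSS")$summary, "rank-sum")
  expect_equal(gwss_method("DSS-t")$threshold, "fixed")
  expect_error(gwss_method("SKAT"), "unknown GWSS method")
  cust <- gwss_method(list(weight = "D", summary = "rank-sum", threshold = "sup"))
  expect_equal(cust$name, "custom")
})

test_that("observed statistics agree with the brute-force oracle for all methods", {
  set.seed(42)
  reg <- gwss_methods()
  for (i in 1:6) {
    G <- random_genotypes(30, 5, maf = runif(5, 0.02, 0.45))
    D <- sample(rep(c(1, 0), c(14, 16)))
    for (r in seq_len(nrow(reg))) {
      got <- gwss_statistic(G, D, reg$name[r])
      want <- oracle_gwss(G, D, reg$weight[r], reg$summary[r], reg$threshold[r])
      expect_equal(got$statistic, want$S, tolerance = 1e-10,
                   info = paste("method", reg$name[r], "instance", i))
      expect_equal(got$selected_theta, want$theta, tolerance = 1e-12,
                   info = paste("method", reg$name[r], "instance", i))
    }
  }
})

test_that("sup mode dominates every fixed threshold and breaks ties downward", {
  set.seed(43)
  for (i in 1:8) {
    G <- random_genotypes(40, 6)
    D <- sample(rep(c(1, 0), each = 20))
    sup <- gwss_statistic(G, D, "VDWSS-t")
    for (th in sup$thetas) {
      fixed <- gwss_statistic(G, D, "DWSS-t", theta = th)
      expect_gte(sup$statistic, fixed$statistic)
    }
    # selected threshold is the smallest achieving the max
    hits <- sup$thetas[sup$per_threshold_stats == sup$statistic]
    expect_equal(sup$selected_theta, min(hits))
  }
})

test_that("a degenerate threshold set collapses sup mode onto fixed mode", {
  set.seed(44)
  # all variants share one adjusted MAF -> |Theta| = 1
  G <- matrix(rep(c(1, 0, 0, 1, 0, 1, 1, 0), 3), ncol = 3)
  D <- rep(c(1, 0), 4)
  expect_equal(length(unique(adjusted_control_maf(G, D))), 1)
  sup <- gwss_statistic(G, D, "VWSS-t")
  fixed <- gwss_statistic(G, D, "WSS-t")
  expect_equal(sup$statistic, fixed$statistic)
})

test_that("WSS reproduces an independently coded Madsen-Browning statistic", {
  set.seed(45)
  for (i in 1:10) {
    # draw until the adjusted MAFs are all distinct: with tied MAFs two
    # distinct genotype rows can have mathematically equal scores, and the
    # two implementations may then break the rank tie differently in
    # floating point
    repeat {
      G <- random_genotypes(36, 5, maf = runif(5, 0.03, 0.3))
      D <- sample(rep(c(1, 0), each = 18))
      if (!anyDuplicated(adjusted_control_maf(G, D))) break
    }
    # the package's MAF weight differs from the Madsen-Browning score
    # denominator only by the constant sqrt(n / n0), which cannot change
    # any rank, so the rank-sum statistics must coincide exactly
    expect_equal(gwss_statistic(G, D, "WSS")$statistic,
                 oracle_madsen_browning(G, D))
  }
})

test_that("ORWSS matches a direct transcription of the log-OR weighted rank-sum", {
  set.seed(46)
  for (i in 1:10) {
    G <- random_genotypes(36, 5)
    D <- sample(rep(c(1, 0), each = 18))
    q <- oracle_q(G, D)
    w <- log(oracle_or(G, D))
    want <- sum(rank(as.vector(G %*% w))[D == 1])
    expect_equal(gwss_statistic(G, D, "ORWSS")$statistic, want,
                 tolerance = 1e-12)
  }
})
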