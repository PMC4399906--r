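# Independent oracle implementations: straight, slow transcriptions of the
# defining formulas, deliberately sharing no code with the package's
# vectorized evaluation paths.

oracle_q <- function(G, D) {
  n0 <- sum(D == 0)
  sapply(seq_len(ncol(G)), function(j) (sum(G[D == 0, j]) + 1) / (2 * n0 + 2))
}

oracle_or <- function(G, D) {
  n1 <- sum(D == 1); n0 <- sum(D == 0)
  sapply(seq_len(ncol(G)), function(j) {
    a <- sum(G[D == 1, j]); c_ <- sum(G[D == 0, j])
    b <- 2 * n1 - a; d <- 2 * n0 - c_
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  })
}

oracle_weight <- function(scheme, q, or, n0) {
  switch(scheme,
    MAF = 1 / sqrt(n0 * q * (1 - q)),
    OR  = log(or),
    D   = ifelse(or > 1, 1, ifelse(or < 1, -1, 0)),
    DW  = ifelse(or > 1, 1, ifelse(or < 1, -1, 0)) / sqrt(n0 * q * (1 - q)))
}

oracle_summary <- function(s, D, summary) {
  if (summary == "rank-sum") {
    sum(rank(s)[D == 1])
  } else {
    x <- s[D == 1]; y <- s[D == 0]
    num <- abs(mean(x) - mean(y))
    den <- sqrt(var(x) / length(x) + var(y) / length(y))
    if (den == 0) (if (num == 0) 0 else Inf) else num / den
  }
}

# Full observed GWSS statistic, one method, by brute force.
oracle_gwss <- function(G, D, scheme, summary, mode, theta = Inf) {
  q <- oracle_q(G, D)
  w <- oracle_weight(scheme, q, oracle_or(G, D), sum(D == 0))
  thetas <- if (mode == "sup") sort(unique(q)) else theta
  st <- sapply(thetas, function(th) {
    oracle_summary(as.vector(G %*% (w * (q <= th))), D, summary)
  })
  list(S = max(st), theta = thetas[which.max(st)], per_threshold = st)
}

# Madsen-Browning weighted-sum statistic, coded from its own recipe:
# control-based adjusted frequency, weight sqrt(n q (1-q)) dividing each
# variant's allele count, genetic score summed per subject, rank-sum of
# the case scores.
oracle_madsen_browning <- function(G, D) {
  n <- length(D); n0 <- sum(D == 0)
  gamma <- sapply(seq_len(ncol(G)), function(j) {
    m <- sum(G[D == 0, j])
    q <- (m + 1) / (2 * n0 + 2)
    sqrt(n * q * (1 - q))
  })
  score <- as.vector(G %*% (1 / gamma))
  sum(rank(score)[D == 1])
}

# All distinct 0/1 labelings with a fixed number of cases, as columns.
all_labelings <- function(n, n1) {
  combos <- combn(n, n1)
  apply(combos, 2, function(idx) { v <- numeric(n); v[idx] <- 1; v })
}

# Small random genotype matrix with a mix of rare and common columns and
# guaranteed polymorphism.
random_genotypes <- function(n, k, maf = NULL) {
  if (is.null(maf)) maf <- runif(k, 0.02, 0.4)
  repeat {
    G <- sapply(maf, function(m) rbinom(n, 2, m))
    if (all(colSums(G) > 0) && any(G > 0)) return(G)
  }
}
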