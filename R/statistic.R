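#' Aggregate weighted genotypes into per-subject burden scores
#'
#' Computes \eqn{G_i(\theta) = \sum_j w_j I(q_j \le \theta) G_{ij}}: the
#' weighted sum of each subject's minor-allele counts over the variants
#' whose adjusted control MAF passes the threshold.
#'
#' @param genotypes subjects x variants matrix of minor-allele counts.
#' @param weights per-variant weight vector (same variant order).
#' @param q per-variant adjusted control MAFs (same variant order).
#' @param theta MAF threshold; variants with `q > theta` contribute 0.
#'   `Inf` means no filter.
#' @return numeric per-subject score vector.
#' @export
aggregate_scores <- function(genotypes, weights, q, theta = Inf) {
  k <- ncol(genotypes)
  if (length(weights) != k || length(q) != k) {
    stop("weights and q must have one entry per genotype column")
  }
  w <- weights * (q <= theta)
  as.vector(genotypes %*% w)
}

#' Rank-sum summary of case versus control burden scores
#'
#' Sum of the ranks of the case subjects' aggregated scores within the
#' pooled sample (Wilcoxon-type; ties receive midranks). Large values
#' indicate that cases carry more weighted burden than controls.
#'
#' @param scores per-subject aggregated score vector.
#' @param phenotype 0/1 disease indicators, same length.
#' @return the rank-sum statistic (scalar).
#' @export
ranksum_summary <- function(scores, phenotype) {
  ph <- validate_phenotype(phenotype, length(scores))
  r <- rank(scores, ties.method = "average")
  sum(r[ph$labels == 1])
}

#' Welch t summary of case versus control burden scores
#'
#' Absolute two-sample t statistic with unpooled (Welch) variances:
#' \deqn{|\bar s_1 - \bar s_0| / \sqrt{V_1/n_1 + V_0/n_0}}
#' where \eqn{V_g} are unbiased sample variances within each phenotype
#' group. If both group variances are zero the statistic is 0 when the
#' means agree and `Inf` when they differ (degenerate inputs; `Inf`
#' compares coherently inside the permutation engine).
#'
#' @inheritParams ranksum_summary
#' @return the absolute Welch t statistic (scalar, possibly `Inf`).
#' @export
tsum_summary <- function(scores, phenotype) {
  ph <- validate_phenotype(phenotype, length(scores))
  if (ph$n1 < 2L || ph$n0 < 2L) {
    stop("t-sum needs at least two cases and two controls for variance estimation")
  }
  s1 <- scores[ph$labels == 1]
  s0 <- scores[ph$labels == 0]
  num <- abs(mean(s1) - mean(s0))
  den <- sqrt(stats::var(s1) / ph$n1 + stats::var(s0) / ph$n0)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Candidate threshold set for variable-threshold (sup) mode
#'
#' @param q per-variant adjusted control MAFs.
#' @param policy `"observed"` returns the sorted unique values of `q`
#'   (every observed adjusted MAF is a candidate cutoff -- the finest
#'   partition the data distinguish); a numeric vector is used as a
#'   user-supplied grid; a single number is a fixed threshold.
#' @return ordered numeric vector of candidate thresholds.
#' @export
threshold_set <- function(q, policy = "observed") {
  if (length(q) < 1L) stop("q must be nonempty")
  if (is.numeric(policy)) {
    if (length(policy) < 1L) stop("threshold grid must be nonempty")
    return(sort(unique(policy)))
  }
  policy <- match.arg(policy, "observed")
  sort(unique(q))
}

#' Observed GWSS statistic for one method
#'
#' Recomputes the per-variant statistics and weights from the given
#' labelling, aggregates genotypes at each candidate threshold, applies
#' the method's summary measure, and (in sup mode) maximises over the
#' threshold set. This is the statistic whose null distribution
#' [gwss_test()] obtains by label permutation.
#'
#' @inheritParams variant_stats
#' @param method a registry name (see [gwss_methods()]), a custom triple,
#'   or a `gwss_method` object.
#' @param theta,theta_set passed to [gwss_method()] when `method` is a name
#'   or a list.
#' @return list with `statistic` (observed S), `selected_theta` (the
#'   arg-max threshold in sup mode, smallest on ties; the fixed theta
#'   otherwise), `thetas` and `per_threshold_stats` (the statistic at each
#'   candidate threshold; in fixed mode a single value).
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200, 2, 0.05), 50, 4)
#' D <- rep(c(1, 0), 25)
#' gwss_statistic(G, D, "VDWSS-t")
#' @export
gwss_statistic <- function(genotypes, phenotype, method = "VDWSS-t",
                           theta = Inf, theta_set = "observed") {
  ctx <- gwss_context(genotypes, phenotype,
                      list(gwss_method(method, theta = theta, theta_set = theta_set)))
  ev <- gwss_eval(ctx, ctx$labels, detail = TRUE)
  list(statistic = ev$S[1],
       selected_theta = ev$theta[1],
       thetas = ev$detail[[1]]$thetas,
       per_threshold_stats = ev$detail[[1]]$stats)
}

# ---- shared evaluation core -------------------------------------------------
#
# One context object per dataset carries everything that does not depend on
# the labelling: the genotype matrix restricted to subjects carrying at
# least one minor allele (all-zero rows have aggregated score 0 at every
# threshold and only enter through the group counts), per-variant allele
# totals, and the resolved method list. gwss_eval() then computes every
# method's statistic for one labelling; the permutation engine calls it
# B + 1 times so that adjusted MAFs, odds ratios, weights and thresholds
# are all recomputed under each permuted labelling (required for the
# statistic to be exchangeable under the null).

gwss_context <- function(genotypes, phenotype, methods) {
  check_genotypes(genotypes)
  ph <- validate_phenotype(phenotype, nrow(genotypes))
  if (ph$n1 < 2L || ph$n0 < 2L) {
    stop("need at least two cases and two controls")
  }
  methods <- lapply(methods, gwss_method)
  k <- ncol(genotypes)
  nz <- which(rowSums(genotypes) > 0)
  list(
    G = genotypes,
    Gnz = genotypes[nz, , drop = FALSE],
    nz = nz,
    n = ph$n, n1 = ph$n1, n0 = ph$n0,
    k = k,
    tot = colSums(genotypes),
    Ut = upper.tri(diag(k), diag = TRUE) * 1,
    labels = ph$labels,
    methods = methods,
    names = vapply(methods, function(m) m$name, character(1))
  )
}

# Welch |t| for each column of a score matrix given case sums/sum-squares
# computed over the nonzero-row subset; zero rows contribute 0 to every sum.
welch_columns <- function(s1, ss1, s0, ss0, n1, n0) {
  v1 <- pmax((ss1 - s1^2 / n1) / (n1 - 1), 0)
  v0 <- pmax((ss0 - s0^2 / n0) / (n0 - 1), 0)
  den <- sqrt(v1 / n1 + v0 / n0)
  num <- abs(s1 / n1 - s0 / n0)
  tt <- num / den
  zero <- den == 0
  if (any(zero)) tt[zero] <- ifelse(num[zero] > 0, Inf, 0)
  tt
}

# Evaluate all methods in the context for one labelling.
# labels: full-length 0/1 vector. Returns list(S, theta, detail).
gwss_eval <- function(ctx, labels, detail = FALSE) {
  n1 <- ctx$n1; n0 <- ctx$n0; k <- ctx$k
  lnz <- labels[ctx$nz]
  nnz <- length(ctx$nz)

  a <- as.vector(crossprod(ctx$Gnz, lnz))   # minor alleles in cases
  m <- ctx$tot - a                          # minor alleles in controls
  q <- (m + 1) / (2 * n0 + 2)
  or_hat <- ((a + 0.5) * (2 * n0 - m + 0.5)) / ((2 * n1 - a + 0.5) * (m + 0.5))

  wMAF <- 1 / sqrt(n0 * q * (1 - q))
  weight_of <- function(scheme) switch(scheme,
    MAF = wMAF,
    OR  = log(or_hat),
    D   = (or_hat > 1) - (or_hat < 1),
    DW  = ((or_hat > 1) - (or_hat < 1)) * wMAF
  )

  ordq <- order(q)
  qs <- q[ordq]
  keep <- c(qs[-1] > qs[-k], TRUE)   # last index of each tied q block
  uq <- qs[keep]

  # cache of cumulative-threshold column stats per scheme (sup "observed")
  cum_cache <- list()
  sup_stats <- function(scheme) {
    hit <- cum_cache[[scheme]]
    if (!is.null(hit)) return(hit)
    w <- weight_of(scheme)
    cum <- (ctx$Gnz[, ordq, drop = FALSE] * rep(w[ordq], each = nnz)) %*% ctx$Ut
    Sc <- cum[, keep, drop = FALSE]
    Sc2 <- Sc * Sc
    s1 <- as.vector(crossprod(lnz, Sc))
    ss1 <- as.vector(crossprod(lnz, Sc2))
    s0 <- colSums(Sc) - s1
    ss0 <- colSums(Sc2) - ss1
    out <- list(Sc = Sc, t = welch_columns(s1, ss1, s0, ss0, n1, n0))
    cum_cache[[scheme]] <<- out
    out
  }

  score_at <- function(scheme, theta) {
    w <- weight_of(scheme) * (q <= theta)
    as.vector(ctx$Gnz %*% w)
  }
  ranksum_of <- function(snz) {
    full <- numeric(ctx$n)
    full[ctx$nz] <- snz
    r <- rank(full, ties.method = "average")
    sum(r[labels == 1])
  }
  tsum_of <- function(snz) {
    s1 <- sum(snz * lnz); ss1 <- sum(snz * snz * lnz)
    welch_columns(s1, ss1, sum(snz) - s1, sum(snz * snz) - ss1, n1, n0)
  }

  nm <- length(ctx$methods)
  S <- numeric(nm); th <- numeric(nm)
  det_list <- if (detail) vector("list", nm) else NULL

  for (i in seq_len(nm)) {
    mt <- ctx$methods[[i]]
    if (mt$threshold == "fixed") {
      # evaluate through the same cumulative-threshold path as sup mode
      # (j = number of unique adjusted MAFs passing theta), so that the
      # sup >= fixed dominance holds exactly, not just up to rounding
      j <- sum(uq <= mt$theta)
      if (mt$summary == "t-sum") {
        S[i] <- if (j == 0L) 0 else sup_stats(mt$weight)$t[j]
      } else {
        snz <- if (j == 0L) numeric(nnz) else sup_stats(mt$weight)$Sc[, j]
        S[i] <- ranksum_of(snz)
      }
      th[i] <- mt$theta
      if (detail) det_list[[i]] <- list(thetas = mt$theta, stats = S[i])
    } else {
      thetas <- if (is.numeric(mt$theta_set)) mt$theta_set else uq
      if (mt$summary == "t-sum" && !is.numeric(mt$theta_set)) {
        st <- sup_stats(mt$weight)$t
      } else {
        st <- vapply(thetas, function(tv) {
          snz <- score_at(mt$weight, tv)
          if (mt$summary == "t-sum") tsum_of(snz) else ranksum_of(snz)
        }, numeric(1))
      }
      j <- which.max(st)               # first max = smallest theta on ties
      S[i] <- st[j]
      th[i] <- thetas[j]
      if (detail) det_list[[i]] <- list(thetas = thetas, stats = st)
    }
  }
  list(S = S, theta = th, detail = det_list)
}
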