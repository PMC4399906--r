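#' Per-variant summary statistics for weighted-sum association tests
#'
#' Computes, for every variant in a genotype matrix, the control-group
#' adjusted minor-allele frequency and the continuity-corrected allelic
#' odds ratio, given a case/control labelling. These two quantities drive
#' all four weight schemes of the generalized weighted-sum statistic
#' (GWSS) family; see [gwss_weights()].
#'
#' The adjusted MAF follows the Madsen-Browning control-based pseudo-count
#' convention
#' \deqn{q_j = (m_j + 1) / (2 n_0 + 2)}
#' where \eqn{m_j} is the minor-allele count of variant \eqn{j} among the
#' \eqn{n_0} controls, so \eqn{0 < q_j < 1} strictly even for monomorphic
#' variants. The odds ratio is the cross-product ratio of the 2x2
#' allele-count table (minor/major x case/control) with 0.5 added to every
#' cell, which keeps it finite and positive for empty cells.
#'
#' @param genotypes numeric matrix of minor-allele counts, subjects in rows,
#'   variants in columns, entries 0/1/2 (missing values must be handled
#'   beforehand; see [impute_missing()]).
#' @param phenotype binary vector of disease indicators, 1 = case,
#'   0 = control, one per subject.
#' @return `variant_stats()` returns a data frame with one row per variant
#'   and columns `q` (adjusted control MAF) and `or_hat` (continuity-
#'   corrected odds ratio). `adjusted_control_maf()` and `estimate_or()`
#'   return the corresponding numeric vectors.
#' @examples
#' G <- matrix(c(0, 1, 1, 2, 0, 0, 0, 1), nrow = 4)
#' D <- c(1, 1, 0, 0)
#' variant_stats(G, D)
#' @export
variant_stats <- function(genotypes, phenotype) {
  ph <- validate_phenotype(phenotype, nrow(genotypes))
  check_genotypes(genotypes)
  data.frame(
    q = adjusted_control_maf(genotypes, phenotype),
    or_hat = estimate_or(genotypes, phenotype),
    row.names = colnames(genotypes)
  )
}

#' @rdname variant_stats
#' @export
adjusted_control_maf <- function(genotypes, phenotype) {
  ph <- validate_phenotype(phenotype, nrow(genotypes))
  if (ph$n0 < 1L) stop("at least one control is required to compute adjusted MAFs")
  m <- as.vector(crossprod(genotypes, 1 - ph$labels))
  (m + 1) / (2 * ph$n0 + 2)
}

#' @rdname variant_stats
#' @export
estimate_or <- function(genotypes, phenotype) {
  ph <- validate_phenotype(phenotype, nrow(genotypes))
  if (ph$n1 < 1L || ph$n0 < 1L) {
    stop("at least one case and one control are required to estimate odds ratios")
  }
  a <- as.vector(crossprod(genotypes, ph$labels)) # minor alleles in cases
  m <- as.vector(colSums(genotypes)) - a          # minor alleles in controls
  b <- 2 * ph$n1 - a                              # major alleles in cases
  d <- 2 * ph$n0 - m                              # major alleles in controls
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (m + 0.5))
}

#' GWSS per-variant weight schemes
#'
#' Maps per-variant summary statistics to the weight vector used when
#' aggregating genotypes into per-subject burden scores. Four schemes are
#' available:
#' \describe{
#'   \item{`"MAF"`}{inverse binomial standard deviation of the control
#'     allele count, \eqn{w_j = 1/\sqrt{n_0 q_j (1 - q_j)}}; up-weights
#'     rare variants, always positive.}
#'   \item{`"OR"`}{\eqn{w_j = \log(\widehat{OR}_j)}; carries both the
#'     direction and the (noisily estimated) strength of association.}
#'   \item{`"D"`}{\eqn{w_j = I(\widehat{OR}_j > 1) - I(\widehat{OR}_j < 1)},
#'     the direction only, in \{-1, 0, +1\}; a variant with
#'     \eqn{\widehat{OR}_j = 1} contributes nothing.}
#'   \item{`"DW"`}{the elementwise product of the D and MAF weights:
#'     direction from the odds ratio, strength proxied by rarity, which is
#'     more stable than the estimated odds ratio itself when counts are
#'     sparse.}
#' }
#'
#' @param scheme one of `"MAF"`, `"OR"`, `"D"`, `"DW"`.
#' @param stats data frame as returned by [variant_stats()] (columns `q`
#'   and `or_hat`), computed from the same labelling as `n0`.
#' @param n0 number of controls in the labelling that produced `stats`.
#' @return numeric weight vector, one entry per variant.
#' @examples
#' st <- data.frame(q = c(0.01, 0.5), or_hat = c(2, 0.5))
#' gwss_weights("DW", st, n0 = 500)
#' @export
gwss_weights <- function(scheme, stats, n0) {
  scheme <- match.arg(scheme, c("MAF", "OR", "D", "DW"))
  q <- stats$q
  or_hat <- stats$or_hat
  switch(scheme,
    MAF = 1 / sqrt(n0 * q * (1 - q)),
    OR  = log(or_hat),
    D   = (or_hat > 1) - (or_hat < 1),
    DW  = ((or_hat > 1) - (or_hat < 1)) / sqrt(n0 * q * (1 - q))
  )
}

#' Validate and summarise a case/control phenotype vector
#'
#' @param phenotype vector of 0/1 disease indicators.
#' @param n expected length (e.g. `nrow(genotypes)`); `NULL` to skip.
#' @return list with `labels` (numeric 0/1 vector), `n`, `n1` (cases),
#'   `n0` (controls).
#' @keywords internal
validate_phenotype <- function(phenotype, n = NULL) {
  labels <- as.numeric(phenotype)
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("phenotype must contain only 0 (control) and 1 (case)")
  }
  if (!is.null(n) && length(labels) != n) {
    stop("phenotype length (", length(labels),
         ") does not match the number of subjects (", n, ")")
  }
  n1 <- sum(labels)
  list(labels = labels, n = length(labels), n1 = as.integer(n1),
       n0 = as.integer(length(labels) - n1))
}

check_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes) || !is.numeric(genotypes)) {
    stop("genotypes must be a numeric matrix (subjects x variants)")
  }
  if (anyNA(genotypes)) {
    stop("genotypes contain missing values; run impute_missing() first")
  }
  if (!all(genotypes %in% c(0, 1, 2))) {
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  }
  invisible(genotypes)
}

#' Orient a genotype matrix to count the minor allele
#'
#' Recodes each column so that entries count the allele that is minor in
#' the full sample (cases and controls pooled), i.e. columns with pooled
#' allele frequency above 0.5 are flipped `G <- 2 - G`. Orientation is
#' decided once, before any testing, so it is stable across label
#' permutations. A column at exactly 0.5 keeps its input orientation.
#'
#' @param genotypes numeric subjects x variants matrix with entries 0/1/2.
#' @return matrix of the same shape counting minor alleles, with attribute
#'   `flipped` (logical per variant).
#' @export
orient_minor <- function(genotypes) {
  check_genotypes(genotypes)
  f <- colMeans(genotypes) / 2
  flip <- f > 0.5
  if (any(flip)) genotypes[, flip] <- 2 - genotypes[, flip, drop = FALSE]
  attr(genotypes, "flipped") <- flip
  genotypes
}

#' Impute missing genotypes to the homozygous major genotype
#'
#' Missing entries are set to 0 copies of the minor allele, which is
#' conservative under the null (it shrinks case/control contrasts toward
#' zero). Per-variant missingness is recorded; a variant missing more than
#' `warn_above` of its calls triggers a warning.
#'
#' @param genotypes numeric subjects x variants matrix, `NA` for missing.
#' @param warn_above missingness proportion above which to warn.
#' @return matrix with no `NA`s and attribute `missing_rate` per variant.
#' @export
impute_missing <- function(genotypes, warn_above = 0.2) {
  miss <- is.na(genotypes)
  rate <- colMeans(miss)
  if (any(rate > warn_above)) {
    bad <- which(rate > warn_above)
    warning(sprintf("%d variant(s) exceed %.0f%% missingness (max %.1f%%); imputed to 0 copies",
                    length(bad), 100 * warn_above, 100 * max(rate)))
  }
  genotypes[miss] <- 0
  attr(genotypes, "missing_rate") <- rate
  genotypes
}
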