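#' GWSS permutation test
#'
#' Runs one GWSS method on a genotype matrix and phenotype vector and
#' returns its empirical permutation p-value. The observed statistic is
#' compared against statistics recomputed under `B` uniform random
#' permutations of the case/control labels (case count preserved). Every
#' label-dependent quantity -- adjusted control MAFs, odds ratios, weights
#' and candidate thresholds -- is recomputed under each permuted labelling,
#' which is what makes the permutation distribution a valid null reference
#' for the fully data-driven statistic. The p-value uses the add-one
#' estimator
#' \deqn{p = (1 + \#\{S_{perm} \ge S_{obs}\}) / (B + 1),}
#' never exactly zero; both summaries reject for large values (the
#' rank-sum grows when cases carry more weighted burden; the t-sum is
#' absolute-valued), so the comparison is one-sided upper-tail.
#'
#' @inheritParams gwss_statistic
#' @param B number of random label permutations (default 1000).
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @param permutations optional n x B matrix of 0/1 labellings to use
#'   instead of random permutations (e.g. an exhaustive enumeration on
#'   tiny samples); each column must preserve the case count.
#' @param recode_minor recode columns so entries count the full-sample
#'   minor allele (see [orient_minor()]); decided once, before testing.
#' @param impute impute missing genotypes to 0 copies first
#'   (see [impute_missing()]).
#' @param return_null also return the vector of permuted statistics.
#' @return object of class `gwss_result`: list with `method`, `statistic`,
#'   `p_value`, `n_permutations`, `selected_theta` and (optionally)
#'   `null_statistics`.
#' @examples
#' set.seed(7)
#' G <- matrix(rbinom(400, 2, 0.05), 100, 4)
#' D <- rep(c(1, 0), each = 50)
#' gwss_test(G, D, "VDWSS-t", B = 99, seed = 1)
#' @export
gwss_test <- function(genotypes, phenotype, method = "VDWSS-t", B = 1000,
                      seed = NULL, theta = Inf, theta_set = "observed",
                      permutations = NULL, recode_minor = TRUE,
                      impute = TRUE, return_null = FALSE) {
  res <- gwss_test_set(genotypes, phenotype, methods = list(method),
                       B = B, seed = seed, theta = theta,
                       theta_set = theta_set, permutations = permutations,
                       recode_minor = recode_minor, impute = impute,
                       return_null = return_null)
  out <- list(method = res$method[1],
              statistic = res$statistic[1],
              p_value = res$p_value[1],
              n_permutations = res$n_permutations[1],
              selected_theta = res$selected_theta[1])
  if (return_null) out$null_statistics <- attr(res, "null_statistics")[1, ]
  class(out) <- "gwss_result"
  out
}

#' Run several GWSS methods on shared permutations
#'
#' Evaluates a set of methods on the same data and the same random
#' permutations (common random numbers), which both saves the dominant
#' cost -- the per-permutation recomputation of variant statistics is
#' shared -- and makes between-method comparisons less noisy.
#'
#' @inheritParams gwss_test
#' @param methods character vector of registry names and/or a list of
#'   method specifications (see [gwss_method()]).
#' @return data frame with one row per method: `method`, `statistic`,
#'   `selected_theta`, `n_permutations`, `p_value`. If `return_null`,
#'   the permuted statistics matrix (methods x B) is attached as
#'   attribute `"null_statistics"`.
#' @export
gwss_test_set <- function(genotypes, phenotype, methods, B = 1000,
                          seed = NULL, theta = Inf, theta_set = "observed",
                          permutations = NULL, recode_minor = TRUE,
                          impute = TRUE, return_null = FALSE) {
  if (impute && anyNA(genotypes)) genotypes <- impute_missing(genotypes)
  if (recode_minor) genotypes <- orient_minor(genotypes)
  if (is.character(methods)) methods <- as.list(methods)
  methods <- lapply(methods, gwss_method, theta = theta, theta_set = theta_set)
  ctx <- gwss_context(genotypes, phenotype, methods)

  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    if (nrow(permutations) != ctx$n) {
      stop("permutations must have one row per subject")
    }
    if (!all(colSums(permutations) == ctx$n1)) {
      stop("every permutation column must preserve the case count")
    }
    B <- ncol(permutations)
  }
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  obs <- gwss_eval(ctx, ctx$labels)
  nm <- length(ctx$methods)
  exceed <- integer(nm)
  null_mat <- if (return_null) matrix(NA_real_, nm, B) else NULL
  for (b in seq_len(B)) {
    lab <- if (is.null(permutations)) sample(ctx$labels) else permutations[, b]
    Sb <- gwss_eval(ctx, lab)$S
    exceed <- exceed + (Sb >= obs$S)
    if (return_null) null_mat[, b] <- Sb
  }
  out <- data.frame(method = ctx$names,
                    statistic = obs$S,
                    selected_theta = obs$theta,
                    n_permutations = B,
                    p_value = (1 + exceed) / (B + 1),
                    stringsAsFactors = FALSE)
  if (return_null) attr(out, "null_statistics") <- null_mat
  out
}

#' @export
print.gwss_result <- function(x, ...) {
  cat(sprintf("GWSS permutation test (%s)\n", x$method))
  cat(sprintf("  statistic S      = %g\n", x$statistic))
  cat(sprintf("  selected theta   = %g\n", x$selected_theta))
  cat(sprintf("  permutations     = %d\n", x$n_permutations))
  cat(sprintf("  empirical p      = %.4g\n", x$p_value))
  invisible(x)
}
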