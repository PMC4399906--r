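#' Estimate rejection rate (power or type-I error) for one scenario
#'
#' Monte-Carlo estimate of the probability that each GWSS method rejects
#' at level `alpha`: for each replicate a fresh case-control dataset is
#' simulated from `spec`, all methods are tested on it with shared
#' permutations (common random numbers, so method comparisons are made on
#' identical data), and the rejection proportion is returned with its
#' binomial Monte-Carlo standard error \eqn{\sqrt{\hat p (1-\hat p)/R}}.
#'
#' @param spec a [scenario_spec()]; with all odds ratios at 1 (or no
#'   signal variants) the estimate is the empirical type-I error.
#' @param methods character vector of GWSS method names (default: the full
#'   registry of [gwss_methods()]).
#' @param n_replicates number of simulated datasets (R).
#' @param B permutations per test.
#' @param alpha nominal significance level.
#' @param seed master seed; independent child seeds are spawned per
#'   replicate so any single replicate can be reproduced in isolation.
#' @param theta,theta_set passed to [gwss_test_set()].
#' @return data frame with one row per method: `method`, `power`, `se`,
#'   `n_replicates`, `alpha`, `B`. The full replicate x method matrix of
#'   p-values is attached as attribute `"p_values"` for auditing.
#' @examples
#' \donttest{
#' sp <- scenario_spec(n1 = 100, n0 = 100, n_signal_rv = 8)
#' estimate_power(sp, "VDWSS-t", n_replicates = 10, B = 50, seed = 1)
#' }
#' @export
estimate_power <- function(spec, methods = gwss_methods()$name,
                           n_replicates = 1000, B = 500, alpha = 0.05,
                           seed = NULL, theta = Inf, theta_set = "observed") {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max, n_replicates)
  pv <- matrix(NA_real_, n_replicates, length(methods),
               dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    set.seed(child[r])
    dat <- sample_case_control(spec)
    res <- gwss_test_set(dat$genotypes, dat$phenotype, methods = methods,
                         B = B, seed = NULL, theta = theta,
                         theta_set = theta_set, recode_minor = FALSE,
                         impute = FALSE)
    pv[r, ] <- res$p_value
  }
  p_hat <- colMeans(pv <= alpha)
  out <- data.frame(method = methods,
                    power = unname(p_hat),
                    se = unname(sqrt(p_hat * (1 - p_hat) / n_replicates)),
                    n_replicates = n_replicates, alpha = alpha, B = B,
                    stringsAsFactors = FALSE)
  attr(out, "p_values") <- pv
  out
}

#' Type-I error calibration under the null scenario
#'
#' Convenience wrapper around [estimate_power()] with a null
#' [scenario_spec()] (no signal variants: 8 noise rare variants and 8
#' noise common variants by default, so the genotype-generation structure
#' matches the signal scenarios while the disease prevalence is constant).
#'
#' @inheritParams estimate_power
#' @param spec null scenario; defaults to
#'   `scenario_spec(n_signal_rv = 0, n_noise_rv = 8, n_noise_cv = 8)`.
#' @return as [estimate_power()].
#' @export
null_calibration <- function(methods = gwss_methods()$name,
                             n_replicates = 1000, B = 500, alpha = 0.05,
                             seed = NULL,
                             spec = scenario_spec(n_signal_rv = 0,
                                                  n_noise_rv = 8,
                                                  n_noise_cv = 8)) {
  estimate_power(spec, methods = methods, n_replicates = n_replicates,
                 B = B, alpha = alpha, seed = seed)
}

#' Configure a power study over a scenario grid
#'
#' @param scenarios named list of [scenario_spec()] objects; the names
#'   label the columns of the resulting power table.
#' @param methods character vector of GWSS method names.
#' @param n_replicates simulated datasets per cell (the reference design
#'   uses 1000; 300 is a practical desk-scale preset).
#' @param n_permutations permutations per test (reference 500; desk 200).
#' @param alpha nominal level.
#' @param seed master seed; each (scenario, method-set) cell derives an
#'   independent child seed, and within a cell all methods share datasets
#'   and permutations.
#' @return object of class `study_config`.
#' @export
study_config <- function(scenarios, methods = gwss_methods()$name,
                         n_replicates = 1000, n_permutations = 500,
                         alpha = 0.05, seed = 1) {
  if (!is.list(scenarios) || is.null(names(scenarios)) ||
      any(names(scenarios) == "")) {
    stop("scenarios must be a named list of scenario_spec objects")
  }
  lapply(scenarios, function(s) stopifnot(inherits(s, "scenario_spec")))
  structure(list(scenarios = scenarios, methods = methods,
                 n_replicates = n_replicates,
                 n_permutations = n_permutations,
                 alpha = alpha, seed = seed),
            class = "study_config")
}

#' Run a power study and assemble the power table
#'
#' Executes [estimate_power()] for every scenario in the configuration and
#' binds the results into a long-format table (one row per scenario x
#' method) with Monte-Carlo standard errors. Deterministic given the
#' configuration seed. Completed cells can be cached to disk as delimited
#' text keyed by a hash of the cell configuration, so an interrupted grid
#' resumes without recomputation (and a changed configuration never reuses
#' a stale cell).
#'
#' @param config a [study_config()].
#' @param cache_dir optional directory for per-cell caches.
#' @param verbose print progress lines.
#' @return data frame with columns `scenario`, `method`, `power`, `se`,
#'   `n_replicates`, `alpha`, `B`.
#' @export
run_study <- function(config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cell_seed <- sample.int(.Machine$integer.max, length(config$scenarios))
  rows <- vector("list", length(config$scenarios))
  for (i in seq_along(config$scenarios)) {
    label <- names(config$scenarios)[i]
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0("cell-", label, "-",
                                  cell_hash(config$scenarios[[i]], config,
                                            cell_seed[i]), ".tsv"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cell <- utils::read.delim(cache_file, stringsAsFactors = FALSE)
      if (verbose) message("scenario '", label, "': cached")
    } else {
      if (verbose) message("scenario '", label, "': running ",
                           config$n_replicates, " replicates")
      cell <- estimate_power(config$scenarios[[i]], methods = config$methods,
                             n_replicates = config$n_replicates,
                             B = config$n_permutations,
                             alpha = config$alpha, seed = cell_seed[i])
      attr(cell, "p_values") <- NULL
      if (!is.null(cache_file)) {
        utils::write.table(cell, cache_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    rows[[i]] <- cbind(scenario = label, cell, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# content hash of one study cell: scenario, methods and sampling design
cell_hash <- function(spec, config, seed) {
  txt <- paste(utils::capture.output(utils::str(unclass(spec))), collapse = "|")
  txt <- paste(txt, paste(config$methods, collapse = ","),
               config$n_replicates, config$n_permutations, config$alpha,
               seed, sep = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  substr(unname(tools::md5sum(f)), 1, 10)
}
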