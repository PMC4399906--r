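#' Specify a case-control simulation scenario
#'
#' Describes one cell of the simulation study design: how many signal and
#' noise rare/common variants a region contains, the MAF spectrum each
#' class is drawn from, the linkage-disequilibrium index of the latent
#' AR(1) Gaussian model, and the effect sizes of the logistic liability
#' model.
#'
#' The disease model places the signal variants in two blocks. The first
#' (up to four) signal variants act additively on the log-odds scale with
#' per-allele odds ratio `or_rv` (a signal common variant, when present,
#' occupies one of these additive slots with odds ratio `or_cv`); the
#' remaining signal variants form an "any-carrier" block that multiplies
#' the disease odds by `or_carrier` when at least one of them carries a
#' minor allele, no matter how many:
#' \deqn{\mathrm{logit}\,\Pr(D_i = 1 \mid G) = \mathrm{logit}(0.05)
#'   + \sum_{j \in add} \log(OR_j) G_{ij}
#'   + \log(or_{carrier}) I\Big(\sum_{j \in carrier} G_{ij} > 0\Big).}
#' Setting all odds ratios to 1 (or all variant counts to noise classes)
#' gives the null model with constant prevalence.
#'
#' @param n1,n0 target numbers of cases and controls (default 500/500).
#' @param n_signal_rv,n_signal_cv,n_noise_rv,n_noise_cv variant counts per
#'   class. The standard grid uses (8,0,0,0), (8,0,8,0), (8,0,4,4),
#'   (7,1,8,0), (7,1,4,4) and, for the null, signal counts of zero.
#' @param or_rv per-allele odds ratio of each additive signal rare variant
#'   (2 harmful, 1/2 protective).
#' @param or_cv odds ratio of the signal common variant (1.5 or 1/1.5).
#' @param or_carrier joint odds ratio of the any-carrier block (3 harmful,
#'   1/3 protective).
#' @param rho latent AR(1) LD index in `[0, 1)`; adjacent variants' latent
#'   Gaussians correlate as `rho^|u - v|`.
#' @param maf_mode `"identical"` draws signal and noise rare-variant MAFs
#'   from the same Uniform(0.001, 0.01); `"different"` draws signal
#'   rare-variant MAFs from Uniform(0.001, 0.005) (rarer than the noise).
#' @param prevalence baseline disease prevalence for a zero genotype
#'   (default 0.05).
#' @param maf_signal_rv,maf_noise_rv,maf_cv optional `c(lo, hi)` overrides
#'   of the uniform MAF ranges; defaults follow `maf_mode`.
#' @return object of class `scenario_spec`.
#' @examples
#' scenario_spec(n_signal_rv = 8)                      # 8 harmful RVs
#' scenario_spec(n_signal_rv = 0, n_noise_rv = 8, n_noise_cv = 8)  # null
#' @export
scenario_spec <- function(n1 = 500, n0 = 500,
                          n_signal_rv = 8, n_signal_cv = 0,
                          n_noise_rv = 0, n_noise_cv = 0,
                          or_rv = 2, or_cv = 1.5, or_carrier = 3,
                          rho = 0, maf_mode = c("identical", "different"),
                          prevalence = 0.05,
                          maf_signal_rv = NULL, maf_noise_rv = NULL,
                          maf_cv = NULL) {
  maf_mode <- match.arg(maf_mode)
  k <- n_signal_rv + n_signal_cv + n_noise_rv + n_noise_cv
  if (k < 1) stop("the scenario must contain at least one variant")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (n1 < 1 || n0 < 1) stop("n1 and n0 must be positive")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  n_signal <- n_signal_rv + n_signal_cv
  n_additive <- min(4L, n_signal)
  if (n_signal_cv > n_additive) {
    stop("signal common variants occupy additive slots; at most ", n_additive,
         " allowed here")
  }
  if (is.null(maf_signal_rv)) {
    maf_signal_rv <- if (maf_mode == "identical") c(0.001, 0.01) else c(0.001, 0.005)
  }
  if (is.null(maf_noise_rv)) maf_noise_rv <- c(0.001, 0.01)
  if (is.null(maf_cv)) maf_cv <- c(0.01, 0.1)
  for (r in list(maf_signal_rv, maf_noise_rv, maf_cv)) {
    if (length(r) != 2 || any(r <= 0) || any(r >= 0.5) || r[1] > r[2]) {
      stop("MAF ranges must be c(lo, hi) within (0, 0.5)")
    }
  }
  structure(list(
    n1 = as.integer(n1), n0 = as.integer(n0),
    n_signal_rv = as.integer(n_signal_rv), n_signal_cv = as.integer(n_signal_cv),
    n_noise_rv = as.integer(n_noise_rv), n_noise_cv = as.integer(n_noise_cv),
    k = as.integer(k), n_additive = as.integer(n_additive),
    or_rv = or_rv, or_cv = or_cv, or_carrier = or_carrier,
    rho = rho, maf_mode = maf_mode, prevalence = prevalence,
    maf_signal_rv = maf_signal_rv, maf_noise_rv = maf_noise_rv,
    maf_cv = maf_cv
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d cases / %d controls, %d variants\n",
              x$n1, x$n0, x$k))
  cat(sprintf("  signal: %d RV + %d CV  (additive OR %.3g / CV OR %.3g / carrier OR %.3g)\n",
              x$n_signal_rv, x$n_signal_cv, x$or_rv, x$or_cv, x$or_carrier))
  cat(sprintf("  noise:  %d RV + %d CV\n", x$n_noise_rv, x$n_noise_cv))
  cat(sprintf("  LD rho = %g, MAF mode = %s, prevalence = %g\n",
              x$rho, x$maf_mode, x$prevalence))
  invisible(x)
}

#' Draw per-variant minor-allele frequencies and truth labels
#'
#' Each variant's MAF comes from the uniform range of its class (signal
#' rare variant, signal common variant, noise rare or common variant), and
#' the positions of the classes along the region are uniformly randomly
#' permuted. Uses the current RNG state.
#'
#' @param spec a [scenario_spec()].
#' @return data frame with columns `class` (one of `signal_rv_additive`,
#'   `signal_cv`, `signal_rv_carrier`, `noise_rv`, `noise_cv`) and `maf`,
#'   one row per variant in region order.
#' @export
draw_mafs <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  n_add_rv <- spec$n_additive - spec$n_signal_cv
  n_carrier <- spec$n_signal_rv + spec$n_signal_cv - spec$n_additive
  cls <- c(rep("signal_rv_additive", n_add_rv),
           rep("signal_cv", spec$n_signal_cv),
           rep("signal_rv_carrier", n_carrier),
           rep("noise_rv", spec$n_noise_rv),
           rep("noise_cv", spec$n_noise_cv))
  maf <- c(runif2(n_add_rv, spec$maf_signal_rv),
           runif2(spec$n_signal_cv, spec$maf_cv),
           runif2(n_carrier, spec$maf_signal_rv),
           runif2(spec$n_noise_rv, spec$maf_noise_rv),
           runif2(spec$n_noise_cv, spec$maf_cv))
  out <- data.frame(class = cls, maf = maf, stringsAsFactors = FALSE)
  out <- out[sample.int(spec$k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample genotypes from the latent AR(1) Gaussian LD model
#'
#' Each subject carries two independent haplotypes. For haplotype `l`, a
#' latent vector \eqn{Z^{(l)}} is multivariate normal with mean zero, unit
#' variances and \eqn{Cov(Z_u, Z_v) = \rho^{|u-v|}}; the haplotype carries
#' the minor allele at variant `j` iff \eqn{Z_j \le \Phi^{-1}(MAF_j)}.
#' Genotypes sum the two haplotype indicators, so marginally
#' \eqn{G_{ij} \sim Binomial(2, MAF_j)} while adjacent variants are
#' positively correlated for `rho > 0`. The AR(1) structure is generated
#' by the exact scalar recursion
#' \eqn{Z_u = \rho Z_{u-1} + \sqrt{1-\rho^2}\,\epsilon_u}, so no Cholesky
#' factorisation is needed.
#'
#' @param mafs per-variant minor-allele frequencies.
#' @param rho AR(1) correlation index in `[0, 1)`.
#' @param n number of subjects to draw.
#' @return n x k integer matrix of minor-allele counts.
#' @export
sample_genotypes <- function(mafs, rho, n) {
  k <- length(mafs)
  thr <- stats::qnorm(mafs)
  thr_mat <- matrix(thr, n, k, byrow = TRUE)
  one_haplotype <- function() {
    Z <- matrix(stats::rnorm(n * k), n, k)
    if (rho > 0 && k > 1) {
      sc <- sqrt(1 - rho^2)
      for (u in 2:k) Z[, u] <- rho * Z[, u - 1] + sc * Z[, u]
    }
    Z <= thr_mat
  }
  G <- one_haplotype() + one_haplotype()
  storage.mode(G) <- "double"
  G
}

#' Disease probability under the logistic liability model
#'
#' @param genotypes n x k matrix (or single row) of minor-allele counts,
#'   columns in the order of `truth`.
#' @param truth truth-label data frame from [draw_mafs()].
#' @param spec the [scenario_spec()] providing effect sizes.
#' @return vector of per-subject disease probabilities.
#' @export
disease_probability <- function(genotypes, truth, spec) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  if (ncol(genotypes) != nrow(truth)) {
    stop("genotype columns do not match the truth table")
  }
  eta <- rep(stats::qlogis(spec$prevalence), nrow(genotypes))
  add <- which(truth$class %in% c("signal_rv_additive", "signal_cv"))
  if (length(add)) {
    beta <- ifelse(truth$class[add] == "signal_cv", log(spec$or_cv), log(spec$or_rv))
    eta <- eta + as.vector(genotypes[, add, drop = FALSE] %*% beta)
  }
  car <- which(truth$class == "signal_rv_carrier")
  if (length(car)) {
    any_car <- rowSums(genotypes[, car, drop = FALSE]) > 0
    eta <- eta + log(spec$or_carrier) * any_car
  }
  stats::plogis(eta)
}

#' Simulate a case-control dataset for one scenario
#'
#' Draws subjects from the population model (genotypes from
#' [sample_genotypes()], disease status Bernoulli with probability from
#' [disease_probability()]) in batches until exactly `n1` cases and `n0`
#' controls are accumulated; excess subjects of a filled stratum are
#' discarded (standard rejection sampling for a case-control design under
#' a prospective liability model). Variant positions are re-randomised on
#' every call.
#'
#' @param spec a [scenario_spec()].
#' @param max_draws safety cap on the number of population draws before
#'   giving up (guards against pathological specs whose case or control
#'   stratum is essentially unreachable).
#' @return list of class `gwss_sim` with `genotypes` (n x k minor-allele
#'   counts, cases first), `phenotype` (0/1 vector), `truth` (per-variant
#'   class and drawn MAF), `spec`.
#' @export
sample_case_control <- function(spec, max_draws = 2e6) {
  stopifnot(inherits(spec, "scenario_spec"))
  truth <- draw_mafs(spec)
  need1 <- spec$n1; need0 <- spec$n0
  cases <- list(); controls <- list()
  got1 <- 0L; got0 <- 0L; drawn <- 0L
  batch <- max(2000L, ceiling((need1 + need0) / 2))
  while (got1 < need1 || got0 < need0) {
    if (drawn >= max_draws) {
      stop(sprintf(
        "gave up after %d population draws (have %d/%d cases, %d/%d controls); the scenario makes one stratum essentially unreachable",
        drawn, got1, need1, got0, need0))
    }
    G <- sample_genotypes(truth$maf, spec$rho, batch)
    p <- disease_probability(G, truth, spec)
    D <- stats::rbinom(batch, 1, p)
    drawn <- drawn + batch
    if (got1 < need1 && any(D == 1)) {
      take <- which(D == 1)[seq_len(min(need1 - got1, sum(D == 1)))]
      cases[[length(cases) + 1L]] <- G[take, , drop = FALSE]
      got1 <- got1 + length(take)
    }
    if (got0 < need0 && any(D == 0)) {
      take <- which(D == 0)[seq_len(min(need0 - got0, sum(D == 0)))]
      controls[[length(controls) + 1L]] <- G[take, , drop = FALSE]
      got0 <- got0 + length(take)
    }
  }
  G <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  colnames(G) <- sprintf("v%02d", seq_len(spec$k))
  structure(list(genotypes = G,
                 phenotype = rep(c(1, 0), c(need1, need0)),
                 truth = truth,
                 spec = spec),
            class = "gwss_sim")
}

#' @export
print.gwss_sim <- function(x, ...) {
  cat(sprintf("Simulated case-control dataset: %d cases, %d controls, %d variants\n",
              sum(x$phenotype == 1), sum(x$phenotype == 0), ncol(x$genotypes)))
  print(table(x$truth$class))
  invisible(x)
}
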