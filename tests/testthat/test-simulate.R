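test_that("scenario validation enforces the design constraints", {
  expect_error(scenario_spec(n_signal_rv = 0), "at least one variant")
  expect_error(scenario_spec(rho = 1), "rho")
  expect_error(scenario_spec(prevalence = 0), "prevalence")
  expect_error(scenario_spec(maf_cv = c(0.2, 0.1)), "MAF ranges")
  sp <- scenario_spec(n_signal_rv = 7, n_signal_cv = 1, n_noise_rv = 8)
  expect_equal(sp$k, 16L)
  expect_equal(sp$n_additive, 4L)
})

test_that("MAF draws respect the class-specific uniform ranges", {
  set.seed(61)
  sp <- scenario_spec(n_signal_rv = 7, n_signal_cv = 1, n_noise_rv = 8,
                      n_noise_cv = 4, maf_mode = "identical")
  draws <- do.call(rbind, replicate(60, draw_mafs(sp), simplify = FALSE))
  rv <- draws$maf[grepl("rv", draws$class)]
  expect_true(all(rv > 0.001 & rv < 0.01))
  cv <- draws$maf[grepl("cv", draws$class)]
  expect_true(all(cv > 0.01 & cv < 0.1))

  spd <- scenario_spec(n_signal_rv = 8, n_noise_rv = 8, maf_mode = "different")
  dd <- do.call(rbind, replicate(60, draw_mafs(spd), simplify = FALSE))
  expect_true(all(dd$maf[startsWith(dd$class, "signal")] < 0.005))
  expect_true(all(dd$maf[startsWith(dd$class, "noise")] < 0.01))

  # class composition: one CV in an additive slot, four carrier-block RVs
  one <- draw_mafs(sp)
  expect_equal(sum(one$class == "signal_cv"), 1)
  expect_equal(sum(one$class == "signal_rv_additive"), 3)
  expect_equal(sum(one$class == "signal_rv_carrier"), 4)

  # mean of the common-variant spectrum ~ (0.01 + 0.1) / 2
  set.seed(62)
  spc <- scenario_spec(n_signal_rv = 0, n_noise_rv = 1, n_noise_cv = 15)
  big <- do.call(rbind, replicate(400, draw_mafs(spc), simplify = FALSE))
  cvs <- big$maf[big$class == "noise_cv"]
  expect_equal(mean(cvs), 0.055, tolerance = 3 * sd(cvs) / sqrt(length(cvs)) / 0.055)
})

test_that("genotypes recover the target marginal MAFs", {
  set.seed(63)
  mafs <- c(0.003, 0.008, 0.05, 0.2)
  for (rho in c(0, 0.7)) {
    G <- sample_genotypes(mafs, rho, n = 1e5)
    emp <- colMeans(G) / 2
    se <- sqrt(mafs * (1 - mafs) / (2 * 1e5))
    expect_true(all(abs(emp - mafs) < 3 * se), info = paste("rho =", rho))
  }
  # vanishing MAF -> essentially empty column
  expect_equal(sum(sample_genotypes(c(1e-9), 0, 1e4)), 0)
})

test_that("AR(1) latent correlation induces the expected genotype correlation", {
  skip_if_not_installed("mvtnorm")
  set.seed(64)
  maf <- 0.2; rho <- 0.7
  G <- sample_genotypes(c(maf, maf), rho, n = 2e5)
  # per-haplotype indicators are Bernoulli(maf) with joint orthant
  # probability from the bivariate normal; genotype correlation equals the
  # haplotype indicator correlation
  t_ <- qnorm(maf)
  p11 <- mvtnorm::pmvnorm(upper = c(t_, t_),
                          corr = matrix(c(1, rho, rho, 1), 2))[1]
  rho_ind <- (p11 - maf^2) / (maf * (1 - maf))
  expect_equal(cor(G[, 1], G[, 2]), rho_ind, tolerance = 0.05)
  # and independence at rho = 0
  G0 <- sample_genotypes(c(maf, maf), 0, n = 2e5)
  expect_lt(abs(cor(G0[, 1], G0[, 2])), 0.01)
})

test_that("disease probabilities follow the logistic liability model", {
  sp <- scenario_spec(n_signal_rv = 8)
  truth <- data.frame(
    class = c(rep("signal_rv_additive", 4), rep("signal_rv_carrier", 4)),
    maf = rep(0.005, 8))
  zero <- rep(0, 8)
  expect_equal(disease_probability(zero, truth, sp), 0.05)
  # one copy at one additive RV with OR 2 doubles the odds
  one <- c(1, rep(0, 7))
  expect_equal(disease_probability(one, truth, sp),
               (0.05 / 0.95 * 2) / (1 + 0.05 / 0.95 * 2))
  # carrier block: any mutation multiplies odds by 3, regardless of count
  carrier1 <- c(rep(0, 4), 1, 0, 0, 0)
  carrier3 <- c(rep(0, 4), 2, 1, 0, 2)
  p3 <- (0.05 / 0.95 * 3) / (1 + 0.05 / 0.95 * 3)
  expect_equal(disease_probability(carrier1, truth, sp), p3)
  expect_equal(disease_probability(carrier3, truth, sp), p3)
  # signal CV slot uses its own odds ratio
  spcv <- scenario_spec(n_signal_rv = 7, n_signal_cv = 1)
  truth_cv <- truth; truth_cv$class[1] <- "signal_cv"
  expect_equal(disease_probability(one, truth_cv, spcv),
               (0.05 / 0.95 * 1.5) / (1 + 0.05 / 0.95 * 1.5))
  expect_error(disease_probability(zero[-1], truth, sp), "truth table")
})

test_that("null model keeps population prevalence at the baseline", {
  set.seed(65)
  sp <- scenario_spec(n_signal_rv = 0, n_noise_rv = 8, n_noise_cv = 8)
  truth <- draw_mafs(sp)
  G <- sample_genotypes(truth$maf, 0, 5e4)
  p <- disease_probability(G, truth, sp)
  expect_true(all(abs(p - 0.05) < 1e-12))
})

test_that("case-control sampling fills both strata exactly and reproducibly", {
  sp <- scenario_spec(n1 = 120, n0 = 80, n_signal_rv = 8)
  set.seed(66)
  d <- sample_case_control(sp)
  expect_equal(sum(d$phenotype == 1), 120)
  expect_equal(sum(d$phenotype == 0), 80)
  expect_equal(dim(d$genotypes), c(200L, 8L))
  expect_setequal(unique(as.vector(d$genotypes)), intersect(unique(as.vector(d$genotypes)), c(0, 1, 2)))
  set.seed(66)
  d2 <- sample_case_control(sp)
  expect_identical(d, d2)
  # unreachable stratum errors out with a diagnostic
  tiny <- scenario_spec(n1 = 50, n0 = 50, n_signal_rv = 0, n_noise_rv = 1,
                        prevalence = 1e-6)
  set.seed(67)
  expect_error(sample_case_control(tiny, max_draws = 5000), "unreachable")
})

test_that("signal variants are enriched in cases at scale", {
  set.seed(68)
  sp <- scenario_spec(n1 = 800, n0 = 800, n_signal_rv = 8, n_noise_rv = 8)
  d <- sample_case_control(sp)
  sig <- startsWith(d$truth$class, "signal")
  maf_case <- colMeans(d$genotypes[d$phenotype == 1, sig]) / 2
  maf_ctrl <- colMeans(d$genotypes[d$phenotype == 0, sig]) / 2
  # aggregate enrichment across the eight harmful signal variants
  expect_gt(mean(maf_case), mean(maf_ctrl))
})
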