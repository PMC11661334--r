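test_that("the generator is a pure function of its configuration", {
  cfg <- sim_config(n1 = 100, n2 = 150, p = 12, seed = 50)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$panel1$dosages, d2$panel1$dosages)
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$gwas$z, d2$gwas$z)
  expect_identical(d1$truth, d2$truth)
})

test_that("simulated dosages match their binomial moments", {
  panel <- simulate_genotypes(10000, 5, c(0.5, 0.5), seed = 51)
  expect_true(all(abs(colMeans(panel$dosages) - 1) < 0.03))
  panel2 <- simulate_genotypes(2000, 50, c(0.05, 0.05), seed = 52)
  emp_maf <- colMeans(panel2$dosages) / 2
  expect_true(all(emp_maf > 0.02 & emp_maf < 0.08))
})

test_that("the two panels never share sample ids", {
  ds <- simulate_dataset(sim_config(n1 = 50, n2 = 60, p = 5, seed = 53))
  expect_length(intersect(ds$panel1$sample_ids, ds$panel2$sample_ids), 0)
})

test_that("residual correlation follows the tanh link", {
  # eta = 0, eta0 = 0: residuals uncorrelated
  p0 <- simulate_genotypes(5000, 10, seed = 54)
  cfg0 <- sim_config(n1 = 5000, p = 10, eta0 = 0, eta_scale = 0, seed = 54)
  e0 <- simulate_expression_pair(p0, cfg0)
  expect_true(all(e0$truth$rho == 0))
  expect_lt(abs(cor(e0$truth$eps_a, e0$truth$eps_b)), 3 / sqrt(5000))

  # large baseline eta0: residual correlation saturates near tanh(3)
  cfg1 <- sim_config(n1 = 5000, p = 10, eta0 = 3, eta_scale = 0, seed = 54)
  e1 <- simulate_expression_pair(p0, cfg1)
  expect_gt(cor(e1$truth$eps_a, e1$truth$eps_b), 0.9)
})

test_that("no genetic effect leaves expression at unit variance", {
  panel <- simulate_genotypes(4000, 10, seed = 55)
  cfg <- sim_config(n1 = 4000, p = 10, effect_a = 0, effect_b = 0, seed = 55)
  e <- simulate_expression_pair(panel, cfg)
  expect_true(all(e$truth$beta_a == 0))
  expect_equal(var(e$expr$values[, "P1"]), 1, tolerance = 0.1)
})

test_that("the expected residual product given genotype equals rho", {
  panel <- simulate_genotypes(50000, 8, seed = 56)
  cfg <- sim_config(n1 = 50000, p = 8, eta0 = 0.2, eta_scale = 0.3,
                    k_co = 3, seed = 56)
  e <- simulate_expression_pair(panel, cfg)
  prod <- e$truth$eps_a * e$truth$eps_b
  slope <- coef(lm(prod ~ e$truth$rho))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("null trait effects give standard-normal marginal z scores", {
  ds <- simulate_dataset(sim_config(n1 = 50, n2 = 2000, p = 500,
                                    theta = c(0, 0, 0), seed = 57))
  expect_gt(mean(abs(ds$gwas$z)), 0.70)   # E|z| = sqrt(2/pi) ~ 0.798
  expect_lt(mean(abs(ds$gwas$z)), 0.90)
})

test_that("strong direct effects surface in the causal variants' z scores", {
  cfg <- sim_config(n1 = 50, n2 = 20000, p = 50, k_a = 5,
                    effect_a = 0.1, effect_b = 0.1,
                    theta = c(0.5, 0, 0), noise_sd = 1, seed = 58)
  ds <- simulate_dataset(cfg)
  z_causal <- abs(ds$gwas$z[ds$truth$idx_a])
  expect_gt(mean(z_causal), 5)
})

test_that("overwhelming trait noise drowns every association", {
  cfg <- sim_config(n1 = 50, n2 = 2000, p = 100, noise_sd = 1000, seed = 59)
  ds <- simulate_dataset(cfg)
  expect_lt(max(abs(ds$gwas$z)), 6)
  expect_lt(mean(abs(ds$gwas$z)), 1.0)
})

test_that("impossible heritability and MAF ranges are refused", {
  expect_error(sim_config(h2_a = 1), "heritability")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(k_a = 100, p = 50), "causal")
})

test_that("block-correlated mode induces within-block LD", {
  panel <- simulate_genotypes(3000, 20, c(0.2, 0.5), seed = 60,
                              phi = 0.8, block = 10)
  ld <- compute_ld(panel)
  within <- ld[1, 2]          # adjacent, same block
  across <- abs(ld[5, 15])    # different blocks
  expect_gt(within, 0.3)
  expect_lt(across, 0.1)
})

test_that("missing-data and covariate modes produce usable inputs", {
  cfg <- sim_config(n1 = 300, n2 = 100, p = 10, missing_rate = 0.1,
                    n_covariates = 3, seed = 61)
  ds <- simulate_dataset(cfg)
  expect_gt(sum(is.na(ds$expr$values)), 0)
  expect_equal(ncol(ds$covariates), 3)
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  expect_lt(length(adj$samples), 300)
  expect_equal(sd(adj$a_adj), 1)
})
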