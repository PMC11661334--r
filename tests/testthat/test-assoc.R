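panel_vars <- function(a1, a2, ids = paste0("rs", seq_along(a1))) {
  data.frame(id = ids, chrom = "1", pos = seq_along(a1) * 100L,
             a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

test_that("harmonization aligns, flips, complements and drops correctly", {
  pv <- panel_vars(c("A", "C", "G", "A", "A"),
                   c("G", "T", "A", "C", "C"))
  g <- gwas_summary(id = paste0("rs", 1:5),
                    a1 = c("A", "T", "C", "G", "A"),
                    a2 = c("G", "C", "T", "T", "G"),
                    z = c(-1.3, 2.0, 1.1, 0.7, 0.5), n = rep(1000, 5))
  h <- harmonize(g, pv)
  # rs1 identical -> unchanged; rs2 swapped -> negated;
  # rs3 strand complement of the same orientation (C/T ~ G/A) -> unchanged;
  # rs4 strand complement of the swapped orientation (G/T ~ C/A) -> negated;
  # rs5 shares one allele only (A/G vs A/C) -> dropped
  expect_identical(h$ids, c("rs1", "rs2", "rs3", "rs4"))
  expect_equal(h$z, c(-1.3, -2.0, 1.1, -0.7))
  expect_equal(h$n_dropped, 1L)
})

test_that("flipping alleles twice restores the aligned z vector exactly", {
  pv <- panel_vars(c("A", "C"), c("G", "T"))
  g <- gwas_summary(c("rs1", "rs2"), c("G", "T"), c("A", "C"),
                    z = c(1.5, -0.4), n = c(500, 500))
  h1 <- harmonize(g, pv)
  flipped <- gwas_summary(g$id, g$a2, g$a1, -g$z, g$n)
  h2 <- harmonize(flipped, pv)
  expect_identical(h2$z, h1$z)
})

test_that("harmonization with no overlap is a hard error", {
  pv <- panel_vars("A", "G", ids = "rsX")
  g <- gwas_summary("rsY", "A", "G", 1, 100)
  expect_error(harmonize(g, pv), "no overlap")
})

test_that("LD matrices behave on duplicated, independent and degenerate input", {
  panel <- simulate_genotypes(10000, 8, c(0.2, 0.5), seed = 40)
  ld <- compute_ld(panel)
  expect_equal(diag(ld), rep(1, 8), ignore_attr = TRUE)
  expect_lt(max(abs(ld[upper.tri(ld)])), 0.05)   # independent variants

  v <- rbind(panel$variants,
             data.frame(id = "dup", chrom = "1", pos = 1L, a1 = "A", a2 = "G"))
  p2 <- genotype_panel(panel$sample_ids, v,
                       cbind(panel$dosages, panel$dosages[, 1]))
  ld2 <- compute_ld(p2, c("v1", "dup"))
  expect_equal(ld2["v1", "dup"], 1)

  # 2 samples, 2 variants: rank deficiency forces |r| = 1
  p3 <- genotype_panel(c("s1", "s2"), panel_vars(c("A", "C"), c("G", "T")),
                       matrix(c(0, 2, 1, 0), 2, 2))
  ld3 <- compute_ld(p3)
  expect_equal(abs(ld3[1, 2]), 1)

  p4 <- subset_panel(panel, samples = panel$sample_ids[1:50])
  p4$dosages[, 3] <- 1
  expect_error(compute_ld(p4), "v3")
})

test_that("z_to_beta inverts the simple-regression t statistic", {
  expect_equal(z_to_beta(0, 100), 0)
  expect_equal(z_to_beta(3, 102), 3 / sqrt(109))
  expect_error(z_to_beta(1, 2), "exceed 2")
  set.seed(41)
  n <- 200
  x <- as.numeric(scale(rnorm(n))); y <- as.numeric(scale(x + rnorm(n)))
  sm <- summary(lm(y ~ x))
  z <- sm$coefficients["x", "t value"]
  expect_equal(z_to_beta(z, n), cor(x, y), tolerance = 1e-10)
})

test_that("Wald p-values match the chi-square tail", {
  expect_equal(wald_pvalue(0, 1), 1)
  expect_equal(wald_pvalue(1.959964, 1), 0.05, tolerance = 1e-4)
  expect_lt(wald_pvalue(10, 1), 1e-22)
  expect_error(wald_pvalue(1, 0), "positive")
})

test_that("summary and individual estimators agree with in-sample LD", {
  ds <- small_sim(seed = 42)
  ws <- random_weight_set(ds$panel2, seed = 42)
  ld <- compute_ld(ds$panel2)
  fs <- stage2_summary(ds$gwas, ld, ws)
  fi <- stage2_individual(ds$panel2, ds$y, ws)
  expect_lt(max(abs(fs$theta - fi$theta)), 1e-6)
  expect_lt(abs(fs$p_global - fi$p_global), 1e-4)
  expect_equal(fs$se, fi$se, tolerance = 1e-6)
})

test_that("null summary input yields exactly null estimates", {
  ds <- small_sim(seed = 43)
  ws <- random_weight_set(ds$panel2, seed = 43)
  ld <- compute_ld(ds$panel2)
  g0 <- gwas_summary(ds$gwas$id, ds$gwas$a1, ds$gwas$a2,
                     rep(0, nrow(ds$gwas)), ds$gwas$n)
  f <- stage2_summary(g0, ld, ws)
  expect_equal(unname(f$theta), c(0, 0, 0))
  expect_equal(f$f_stat, 0)
  expect_equal(f$p_global, 1)
})

test_that("the global F statistic has the documented closed form", {
  ft <- global_ftest(rss = 51.5, rss_null = 103, n2 = 104)
  expect_equal(ft$f, 100 / 3, tolerance = 1e-12)
})

test_that("a constant imputed predictor flags the fit as collinear", {
  ds <- small_sim(seed = 44)
  ws <- random_weight_set(ds$panel2, seed = 44)
  ws$w_co <- rep(0, length(ws$w_co))   # C* identically zero
  f <- stage2_individual(ds$panel2, ds$y, ws)
  expect_identical(f$status, "collinear")
  expect_true(all(is.na(f$theta)))
})

test_that("p-values are invariant to rescaling a weight column", {
  ds <- small_sim(seed = 45)
  ws <- random_weight_set(ds$panel2, seed = 45)
  ld <- compute_ld(ds$panel2)
  f1 <- stage2_summary(ds$gwas, ld, ws)
  ws2 <- ws; ws2$w_a <- 7 * ws2$w_a
  f2 <- stage2_summary(ds$gwas, ld, ws2)
  expect_equal(f2$p, f1$p, tolerance = 1e-9)
  expect_equal(f2$theta[["A"]], f1$theta[["A"]] / 7, tolerance = 1e-9)
  expect_equal(f2$f_stat, f1$f_stat, tolerance = 1e-9)
})

test_that("an ill-conditioned design is ridge-stabilized and flagged", {
  ds <- small_sim(seed = 47)
  ws <- random_weight_set(ds$panel2, seed = 47)
  ws$w_co <- ws$w_a * (1 + 1e-10)   # co column nearly collinear with A
  ld <- compute_ld(ds$panel2)
  f <- stage2_summary(ds$gwas, ld, ws)
  expect_true(f$status %in% c("regularized", "failed"))
  if (f$status == "regularized") {
    expect_true(all(is.finite(f$theta)))
    expect_true(all(f$se > 0))
  }
})

test_that("PWAS reduces to the documented marginal formulas", {
  # single variant, unit LD: theta equals the standardized marginal effect
  pv <- panel_vars("A", "G", ids = "rs1")
  z <- 0.1 * sqrt(9998) / sqrt(1 - 0.01)  # b = 0.1 at n = 10000
  g <- gwas_summary("rs1", "A", "G", z, 10000)
  f <- pwas_summary(g, matrix(1, 1, 1, dimnames = list("rs1", "rs1")),
                    pv, w = 1)
  expect_equal(f$theta, 0.1, tolerance = 1e-10)

  # multi-variant case agrees with the explicit algebra
  ds <- small_sim(seed = 46)
  ws <- random_weight_set(ds$panel2, seed = 46)
  ld <- compute_ld(ds$panel2)
  f2 <- pwas_summary(ds$gwas, ld, ws$variants, ws$w_a)
  b <- z_to_beta(ds$gwas$z, ds$gwas$n)
  m <- match(ws$variants$id, ds$gwas$id)
  s <- as.numeric(t(ws$w_a) %*% ld %*% ws$w_a)
  expect_equal(f2$theta, sum(ws$w_a * b[m]) / s, tolerance = 1e-12)
})

test_that("Bonferroni thresholds count only tested pairs", {
  bc <- bonferroni(runif(613), alpha = 0.05)
  expect_equal(bc$threshold, 0.05 / 613)
  expect_equal(bc$threshold, 8.157e-5, tolerance = 1e-3)
  expect_equal(bonferroni(0.04, alpha = 0.05)$threshold, 0.05)
  bc2 <- bonferroni(c(0.001, NA, 0.5), alpha = 0.05)
  expect_equal(bc2$m, 2L)
  expect_identical(bc2$significant, c(TRUE, FALSE, FALSE))
})
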