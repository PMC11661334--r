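test_that("HWE p-value matches closed forms and the chi-square tail", {
  expect_equal(hwe_pvalue(25, 50, 25), 1)
  # expected counts 25/50/25 -> statistic 4
  stat <- sum((c(30, 40, 30) - c(25, 50, 25))^2 / c(25, 50, 25))
  expect_equal(stat, 4)
  expect_equal(hwe_pvalue(30, 40, 30), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hwe_pvalue(30, 40, 30), 0.0455, tolerance = 1e-3)
  expect_lt(hwe_pvalue(10, 0, 10), 1e-4)  # statistic 20
  expect_equal(hwe_pvalue(50, 0, 0), 1)   # monomorphic
})

test_that("variant filters fire on the documented thresholds", {
  # one clean variant, one palindromic, one too missing, one rare
  variants <- data.frame(id = paste0("rs", 1:4), chrom = "1",
                         pos = (1:4) * 100L,
                         a1 = c("A", "A", "C", "G"),
                         a2 = c("G", "T", "T", "A"),
                         stringsAsFactors = FALSE)
  n <- 10
  d <- cbind(c(0, 0, 1, 2, rep(1, 6)),      # MAF 0.55 -> 0.45, fine
             c(0, 1, 1, 0, rep(1, 6)),      # fine but A/T palindromic
             c(NA, NA, NA, rep(1, 7)),      # 30% missing
             rep(0, 10))                    # monomorphic: MAF 0
  panel <- genotype_panel(paste0("s", 1:n), variants, d)
  res <- qc_variants(panel, max_missing = 0.10, min_mac = 1, min_maf = 0.01)
  expect_identical(res$report$surviving, "rs1")
  expect_equal(res$report$removed[["palindromic"]], 1L)
  expect_equal(res$report$removed[["missingness"]], 1L)
  # rs4 is monomorphic: caught by MAC first (MAC = 0 < 1), not MAF
  expect_equal(res$report$removed[["mac"]], 1L)
})

test_that("MAF is computed from mean dosage over non-missing samples", {
  variants <- data.frame(id = "rs1", chrom = "1", pos = 1L, a1 = "A",
                         a2 = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(paste0("s", 1:4), variants,
                          matrix(c(0, 0, 1, 2), ncol = 1))
  # f = mean/2 = 0.375 -> survives a 1% MAF filter
  res <- qc_variants(panel, min_mac = 1, min_maf = 0.01)
  expect_identical(res$report$surviving, "rs1")
  res2 <- qc_variants(panel, min_mac = 1, min_maf = 0.40)
  expect_equal(res2$report$removed[["maf"]], 1L)
})

test_that("QC counts reconcile and HWE is skipped on fractional dosages", {
  for (seed in 1:3) {
    panel <- simulate_genotypes(80, 40, c(0.02, 0.5), seed = seed)
    res <- qc_variants(panel, min_mac = 2, min_maf = 0.05)
    expect_equal(sum(res$report$removed) + length(res$report$surviving),
                 res$report$input)
    expect_false(res$report$hwe_skipped)
  }
  panel <- simulate_genotypes(50, 5, c(0.3, 0.5), seed = 1)
  panel$dosages[1, 1] <- 0.5
  res <- qc_variants(panel, min_mac = 1, min_maf = 0.01)
  expect_true(res$report$hwe_skipped)
  expect_equal(res$report$removed[["hwe"]], 0L)
})

test_that("a variant failing HWE hard is removed", {
  variants <- data.frame(id = "rs1", chrom = "1", pos = 1L, a1 = "A",
                         a2 = "G", stringsAsFactors = FALSE)
  # no heterozygotes at all: extreme HWE violation
  d <- matrix(rep(c(0, 2), each = 50), ncol = 1)
  panel <- genotype_panel(paste0("s", 1:100), variants, d)
  res <- qc_variants(panel, min_mac = 1, min_maf = 0.01, hwe_p_min = 1e-10)
  expect_equal(res$report$removed[["hwe"]], 1L)
})

test_that("greedy LD pruning removes duplicated variants only", {
  panel <- simulate_genotypes(200, 10, c(0.2, 0.5), seed = 3)
  # append an exact copy of variant 1
  v <- rbind(panel$variants,
             data.frame(id = "dup", chrom = "1", pos = 99999999L,
                        a1 = "A", a2 = "G"))
  d <- cbind(panel$dosages, panel$dosages[, 1])
  panel2 <- genotype_panel(panel$sample_ids, v, d)
  kept <- ld_prune(panel2, r2_max = 0.8, window = 20, step = 5)
  expect_false("dup" %in% kept)
  expect_true(all(panel$variants$id %in% kept))
})
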