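test_that("Blom transform matches the normal-quantile definition", {
  x <- c(5, 1, 9)
  out <- blom_transform(x)
  expect_equal(out[1], 0)                               # median rank
  expect_equal(out[2], qnorm((1 - 0.375) / 3.25))       # rank 1
  expect_equal(out[2], -0.8694, tolerance = 1e-4)
  expect_equal(out[3], qnorm((3 - 0.375) / 3.25))

  # independent oracle on random data: explicit averaged ranks + qnorm
  set.seed(11)
  y <- rnorm(50)
  y[sample(50, 5)] <- y[1]  # force ties
  r <- rank(y, ties.method = "average")
  oracle <- qnorm((r - 0.375) / (50 + 1 - 0.75))
  expect_equal(blom_transform(y), oracle, tolerance = 1e-12)
})

test_that("Blom transform handles ties, missing and constant input", {
  expect_equal(blom_transform(c(2, 2)), c(0, 0))
  out <- blom_transform(c(1, NA, 3, 2))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3, 4)], blom_transform(c(1, 3, 2)))  # NA out of n
  expect_equal(blom_transform(c(7, 7, 7)), c(0, 0, 0))
  expect_error(blom_transform(c(1, NA, NA)), "at least 2")
})

test_that("Blom output is monotone with near-zero mean and unit variance", {
  set.seed(5)
  x <- rexp(10000)
  out <- blom_transform(x)
  expect_identical(order(out), order(x))
  expect_lt(abs(mean(out)), 0.01)
  expect_equal(var(out), 1, tolerance = 0.01)
})

test_that("adjustment restricts to the pair's non-missing intersection", {
  set.seed(2)
  n <- 60
  vals <- cbind(P1 = rnorm(n), P2 = rnorm(n))
  vals[3, "P2"] <- NA           # sample s3 missing protein B
  vals[10, "P1"] <- NA
  expr <- expression_table(paste0("s", 1:n), c("P1", "P2"), vals)
  pair <- pair_spec("P1", "P2")
  adj <- adjust_pair(expr, NULL, pair)
  expect_false("s3" %in% adj$samples)
  expect_false("s10" %in% adj$samples)
  expect_length(adj$a_adj, n - 2)
  expect_equal(sd(adj$a_adj), 1)
  expect_equal(mean(adj$b_adj), 0)
})

test_that("covariates orthogonal to expression leave residuals unchanged", {
  set.seed(3)
  n <- 100
  vals <- cbind(P1 = rnorm(n), P2 = rnorm(n))
  expr <- expression_table(paste0("s", 1:n), c("P1", "P2"), vals)
  pair <- pair_spec("P1", "P2")
  plain <- adjust_pair(expr, NULL, pair)
  # build a covariate orthogonal to both transformed phenotypes
  raw <- rnorm(n)
  cv <- lsfit(cbind(plain$a_adj, plain$b_adj), raw)$residuals
  adj <- adjust_pair(expr, matrix(cv, ncol = 1), pair)
  expect_equal(adj$a_adj, plain$a_adj, tolerance = 1e-10)
  expect_equal(adj$b_adj, plain$b_adj, tolerance = 1e-10)
})

test_that("degenerate adjustments are refused", {
  set.seed(4)
  n <- 50
  vals <- cbind(P1 = rnorm(n), P2 = rnorm(n))
  expr <- expression_table(paste0("s", 1:n), c("P1", "P2"), vals)
  pair <- pair_spec("P1", "P2")
  # covariate equal to the transformed expression itself -> zero residuals
  cv <- matrix(blom_transform(vals[, "P1"]), ncol = 1)
  expect_error(adjust_pair(expr, cv, pair), "zero variance")
  # intersection too small relative to covariate count
  vals2 <- vals; vals2[1:45, "P2"] <- NA
  expr2 <- expression_table(paste0("s", 1:n), c("P1", "P2"), vals2)
  expect_error(adjust_pair(expr2, NULL, pair), "at least")
})
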