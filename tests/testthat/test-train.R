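test_that("co-expression targets follow their definitions", {
  a <- c(1, -1, 0.5); b <- c(0.2, 0.3, -0.1)
  # perfect imputation of A -> residual-mode target identically zero
  t0 <- build_coexpression_target(a, b, a_hat = a, b_hat = rep(0, 3))
  expect_equal(as.numeric(t0), c(0, 0, 0))
  # product mode with identical exposures -> elementwise square
  tp <- build_coexpression_target(a, a, mode = "product")
  expect_equal(as.numeric(tp), a^2)
  expect_error(build_coexpression_target(a, b[1:2]), "length")

  # independent standard-normal residuals: mean within 3/sqrt(n) of zero
  set.seed(30)
  n <- 10000
  tt <- build_coexpression_target(rnorm(n), rnorm(n), rep(0, n), rep(0, n))
  expect_lt(abs(mean(tt)), 3 / sqrt(n))
})

test_that("weights are padded onto the union with zeros, preserving imputations", {
  ds <- small_sim(seed = 31)
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  sub <- subset_panel(ds$panel1, samples = adj$samples)
  ids_a <- ds$panel1$variants$id[1:10]
  ids_b <- ds$panel1$variants$id[6:15]
  ws <- train_pair(sub, adj$a_adj, adj$b_adj, ids_a, ids_b, seed = 31)
  expect_identical(ws$variants$id, ds$panel1$variants$id[1:15])
  # zero where a variant is not in the model's feature set
  expect_true(all(ws$w_a[11:15] == 0))
  expect_true(all(ws$w_b[1:5] == 0))

  # imputation from padded union weights == imputation from per-model weights
  Z <- scale(sub$dosages[, ws$variants$id])
  a_hat_union <- as.numeric(Z %*% ws$w_a)
  a_hat_own <- as.numeric(Z[, ids_a] %*% ws$w_a[1:10])
  expect_identical(a_hat_union, a_hat_own)
})

test_that("evaluation is deterministic and filters on the 0.03 rule", {
  ds <- small_sim(seed = 32)
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  sub <- subset_panel(ds$panel1, samples = adj$samples)
  ids <- ds$panel1$variants$id
  m1 <- evaluate_pair(sub, adj$a_adj, adj$b_adj, ids, ids, seed = 5)
  m2 <- evaluate_pair(sub, adj$a_adj, adj$b_adj, ids, ids, seed = 5)
  expect_identical(m1, m2)
  expect_equal(m1$n_train + m1$n_test, length(adj$samples))

  # the pass flag is a strict > 0.03 rule on all three correlations
  fake <- m1; fake$r_co <- 0.02; fake$r_a <- fake$r_b <- 0.5
  expect_false(all(c(fake$r_a, fake$r_b, fake$r_co) > 0.03))
})

test_that("fully heritable exposures are imputed almost perfectly", {
  ds <- simulate_dataset(sim_config(n1 = 500, n2 = 200, p = 20,
                                    h2_a = 0.999, h2_b = 0.999,
                                    eta0 = 0, eta_scale = 0, seed = 33))
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  sub <- subset_panel(ds$panel1, samples = adj$samples)
  ids <- ds$panel1$variants$id
  m <- evaluate_pair(sub, adj$a_adj, adj$b_adj, ids, ids, seed = 33)
  expect_gt(m$r_a, 0.99)
  expect_gt(m$r_b, 0.99)
})

test_that("co-expression imputation has signal only when coQTLs exist", {
  # no coQTL effect: out-of-sample r_co scatters around zero
  r_null <- vapply(1:4, function(s) {
    ds <- simulate_dataset(sim_config(n1 = 700, n2 = 200, p = 25,
                                      eta0 = 0.3, eta_scale = 0, seed = s))
    adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
    sub <- subset_panel(ds$panel1, samples = adj$samples)
    ids <- ds$panel1$variants$id
    evaluate_pair(sub, adj$a_adj, adj$b_adj, ids, ids, seed = s)$r_co
  }, numeric(1))
  expect_lt(abs(mean(r_null)), 0.15)

  # strong coQTL effect at n1 = 2000: mean r_co clearly positive
  r_alt <- vapply(1:3, function(s) {
    ds <- simulate_dataset(sim_config(n1 = 2000, n2 = 200, p = 25,
                                      eta0 = 0.2, eta_scale = 0.4,
                                      seed = 100 + s))
    adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
    sub <- subset_panel(ds$panel1, samples = adj$samples)
    ids <- ds$panel1$variants$id
    evaluate_pair(sub, adj$a_adj, adj$b_adj, ids, ids, seed = s)$r_co
  }, numeric(1))
  expect_gt(mean(r_alt), 0.1)
})

test_that("residual targets are orthogonal to OLS imputations in training", {
  ds <- small_sim(seed = 35)
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  sub <- subset_panel(ds$panel1, samples = adj$samples)
  ids <- ds$panel1$variants$id
  X <- scale(sub$dosages)
  fa <- fit_penalized(X, adj$a_adj, lambda = 0)
  fb <- fit_penalized(X, adj$b_adj, lambda = 0)
  a_hat <- predict(fa, X); b_hat <- predict(fb, X)
  n <- length(a_hat)
  expect_lt(abs(cor(adj$a_adj - a_hat, a_hat)), 3 / sqrt(n))
  expect_lt(abs(cor(adj$b_adj - b_hat, b_hat)), 3 / sqrt(n))
})

test_that("product mode trains and evaluates against the observed product", {
  ds <- small_sim(seed = 37)
  ws <- cowas_train(ds$panel1, ds$expr, ds$covariates, ds$pair,
                    mode = "product", seed = 37)
  expect_identical(ws$mode, "product")
  expect_false(is.null(ws$metrics))
  # in product mode the co-expression weights predict a * b directly;
  # with a shared baseline correlation (eta0 > 0) that target has genetic
  # signal from both exposures' pQTLs, so training succeeds
  expect_true(ws$status %in% c("ok", "non_imputable"))
})

test_that("lasso training recovers the coQTL architecture at scale", {
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(n1 = 5000, n2 = 100, p = 50, seed = 500 + s)
    ds <- simulate_dataset(cfg)
    adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
    sub <- subset_panel(ds$panel1, samples = adj$samples)
    ids <- sub$variants$id
    ws <- train_pair(sub, adj$a_adj, adj$b_adj, ids, ids,
                     penalty = "lasso", seed = s)
    # imputed genetic co-expression tracks the true one
    Z <- scale(sub$dosages)
    c_hat <- as.numeric(Z %*% ws$w_co)
    cor(c_hat, ds$truth$rho[match(adj$samples, ds$panel1$sample_ids)])
  }, numeric(1))
  expect_true(all(hits > 0.5))
})

test_that("end-to-end training returns a well-formed weight set", {
  ds <- small_sim(seed = 36)
  ws <- cowas_train(ds$panel1, ds$expr, ds$covariates, ds$pair, seed = 36)
  expect_s3_class(ws, "cowas_weights")
  expect_equal(length(ws$w_a), nrow(ws$variants))
  expect_true(ws$status %in% c("ok", "non_imputable"))
  expect_false(is.null(ws$metrics))
  # cis windows span the simulated region, so screening keeps <= top_k
  expect_lte(nrow(ws$variants), 2 * 100)
})
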