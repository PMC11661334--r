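# Reproducible simulation experiments: calibration, recovery and
# summary-vs-individual agreement.  These drive the package's own
# validation and are exposed so that studies can be re-run at any size.

train_and_test_once <- function(cfg, penalty = "lasso") {
  ds <- simulate_dataset(cfg)
  adj <- adjust_pair(ds$expr, ds$covariates, ds$pair)
  sub <- subset_panel(ds$panel1, samples = adj$samples)
  qtl_a <- map_pqtls(sub, adj$a_adj, protein = "P1")
  qtl_b <- map_pqtls(sub, adj$b_adj, protein = "P2")
  ids_a <- screen_variants(qtl_a, mode = "effect", k = 100)
  ids_b <- screen_variants(qtl_b, mode = "effect", k = 100)
  ws <- train_pair(sub, adj$a_adj, adj$b_adj, ids_a, ids_b,
                   penalty = penalty, seed = cfg$seed)
  ld <- compute_ld(ds$panel2, ws$variants$id)
  fit <- stage2_summary(ds$gwas, ld, ws)
  list(ds = ds, adj = adj, sub = sub, ids_a = ids_a, ids_b = ids_b,
       ws = ws, fit = fit)
}

#' Type-I-error calibration study under a null trait
#'
#' Repeatedly simulates a dataset with no trait effects
#' (\code{theta = 0}), runs the full train-and-test pipeline on each
#' replicate (lasso stage-1 models, summary-level stage 2 with LD from
#' the GWAS cohort), and tallies rejections of the interaction and global
#' tests at level \code{alpha}.  Also returns the replicate F statistics
#' and a Kolmogorov-Smirnov p-value against their theoretical
#' F(3, n2 - 4) null distribution.
#'
#' @param n_rep number of null replicates.
#' @param n1,n2,p study dimensions per replicate.
#' @param alpha test level (default 0.05).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return list with rejection rates, F statistics, p-value vectors and
#'   the KS p-value.
#' @export
calibration_experiment <- function(n_rep = 1000, n1 = 500, n2 = 2000,
                                   p = 50, alpha = 0.05, seed = 1) {
  p_co <- p_glob <- f_stat <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n1 = n1, n2 = n2, p = p, theta = c(0, 0, 0),
                      seed = seed + r)
    fit <- train_and_test_once(cfg)$fit
    if (fit$status %in% c("collinear", "failed")) next
    p_co[r] <- fit$p[["co"]]
    p_glob[r] <- fit$p_global
    f_stat[r] <- fit$f_stat
  }
  ok <- !is.na(f_stat)
  ks <- stats::ks.test(f_stat[ok], stats::pf, 3, n2 - 4)
  list(n_rep = n_rep, n_used = sum(ok),
       reject_interaction = mean(p_co[ok] < alpha),
       reject_global = mean(p_glob[ok] < alpha),
       f_stat = f_stat[ok], p_co = p_co[ok], p_global = p_glob[ok],
       ks_p = ks$p.value)
}

#' Effect-recovery study with strong instruments
#'
#' Repeatedly simulates a well-powered two-sample dataset with nonzero
#' trait effects, estimates the co-expression effect with the
#' summary-level pipeline, and compares against a brute-force two-stage
#' ordinary-least-squares oracle run on the same data (stage-1 weights by
#' unpenalized regression on the same screened variants, stage 2 on the
#' individual-level GWAS cohort).
#'
#' @param n_rep number of replicates.
#' @param n1,n2,p study dimensions per replicate.
#' @param theta true trait effects (direct A, direct B, co-expression).
#' @param effect per-variant exposure effect size.
#' @param k causal variants per component.
#' @param penalty stage-1 model class for the package estimate.  The
#'   default \code{"ols"} matches the oracle's model class, so the
#'   comparison isolates the two-sample summary-statistic machinery;
#'   shrinkage penalties scale the imputed co-expression predictor and
#'   thus shift the stage-2 slope relative to the OLS oracle.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return list with the per-replicate estimates (\code{theta_co},
#'   \code{theta_co_oracle}), the sign agreement rate with the true
#'   effect, and both means.
#' @export
recovery_experiment <- function(n_rep = 200, n1 = 5000, n2 = 20000,
                                p = 50, theta = c(0.1, -0.1, 0.2),
                                effect = 0.3, k = 5, penalty = "ols",
                                seed = 1) {
  est <- oracle <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n1 = n1, n2 = n2, p = p, theta = theta,
                      k_a = k, k_b = k, k_co = k, effect_a = effect,
                      effect_b = effect, seed = seed + r)
    run <- train_and_test_once(cfg, penalty = penalty)
    if (!run$fit$status %in% c("collinear", "failed")) {
      est[r] <- run$fit$theta[["co"]]
    }
    ws_ols <- ols_weight_set(run)
    fit_o <- stage2_individual(run$ds$panel2, run$ds$y, ws_ols)
    if (!fit_o$status %in% c("collinear", "failed")) {
      oracle[r] <- fit_o$theta[["co"]]
    }
  }
  ok <- !is.na(est) & !is.na(oracle)
  list(n_rep = n_rep, n_used = sum(ok), theta_co = est[ok],
       theta_co_oracle = oracle[ok],
       sign_rate = mean(sign(est[ok]) == sign(theta[3])),
       mean_theta_co = mean(est[ok]),
       mean_theta_co_oracle = mean(oracle[ok]))
}

# two-stage OLS weights on the same screened variants and samples
ols_weight_set <- function(run) {
  sub <- run$sub
  union_ids <- c(run$ids_a, setdiff(run$ids_b, run$ids_a))
  X <- standardize_dosages(sub$dosages[, union_ids, drop = FALSE])$x
  fa <- fit_penalized(X[, run$ids_a, drop = FALSE], run$adj$a_adj, lambda = 0)
  fb <- fit_penalized(X[, run$ids_b, drop = FALSE], run$adj$b_adj, lambda = 0)
  a_hat <- predict(fa, X[, run$ids_a, drop = FALSE])
  b_hat <- predict(fb, X[, run$ids_b, drop = FALSE])
  target <- build_coexpression_target(run$adj$a_adj, run$adj$b_adj,
                                      a_hat, b_hat, "residual")
  fco <- fit_penalized(X, as.numeric(target), lambda = 0)
  vmeta <- sub$variants[match(union_ids, sub$variants$id), , drop = FALSE]
  weight_set(paste0(run$ws$pair_id, "_ols"), vmeta,
             pad_weights(fa, union_ids), pad_weights(fb, union_ids),
             pad_weights(fco, union_ids), mode = "residual")
}

#' Summary-level versus individual-level agreement study
#'
#' For each replicate, simulates a GWAS cohort, forms an arbitrary weight
#' set, and runs stage 2 both ways: on the individual-level data, and on
#' the marginal summary statistics with in-sample LD.  Because the
#' summary statistics encode the exact marginal correlations, the two
#' estimators are algebraically identical; this study measures the
#' numerical gap.
#'
#' @param n_rep number of replicates.
#' @param n2,p GWAS cohort dimensions.
#' @param seed base seed.
#' @return list with the maximum elementwise effect difference and the
#'   maximum global-test p-value difference across replicates.
#' @export
equivalence_experiment <- function(n_rep = 50, n2 = 2000, p = 50, seed = 1) {
  d_theta <- d_pglob <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n1 = 50, n2 = n2, p = p, seed = seed + r)
    ds <- simulate_dataset(cfg)
    ws <- weight_set("eq", ds$panel2$variants,
                     with_seed(seed + r, stats::rnorm(p)),
                     with_seed(seed + 7L * r, stats::rnorm(p)),
                     with_seed(seed + 13L * r, stats::rnorm(p)))
    ld <- compute_ld(ds$panel2)
    fs <- stage2_summary(ds$gwas, ld, ws)
    fi <- stage2_individual(ds$panel2, ds$y, ws)
    d_theta[r] <- max(abs(fs$theta - fi$theta))
    d_pglob[r] <- abs(fs$p_global - fi$p_global)
  }
  list(n_rep = n_rep, max_theta_diff = max(d_theta),
       max_p_global_diff = max(d_pglob))
}
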