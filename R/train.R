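#' Build the co-expression model target
#'
#' In residual mode the target is the elementwise product of the two
#' exposures' expression residuals, \code{(a - a_hat) * (b - b_hat)}: the
#' interaction left after removing each exposure's genetically regulated
#' mean.  In product mode the target is simply \code{a * b} of the
#' (already centered) adjusted expression values, which resembles a
#' conventional interaction term.
#'
#' @param a_adj,b_adj adjusted (standardized) expression vectors.
#' @param a_hat,b_hat in-sample genetic imputations of each exposure;
#'   required in residual mode, ignored in product mode.
#' @param mode \code{"residual"} or \code{"product"}.
#' @return numeric target vector with attribute \code{"mode"}.
#' @export
build_coexpression_target <- function(a_adj, b_adj, a_hat = NULL,
                                      b_hat = NULL,
                                      mode = c("residual", "product")) {
  mode <- match.arg(mode)
  if (length(a_adj) != length(b_adj)) stop("exposure vectors differ in length")
  if (mode == "residual") {
    if (is.null(a_hat) || is.null(b_hat)) {
      stop("residual mode needs in-sample imputations a_hat and b_hat")
    }
    if (length(a_hat) != length(a_adj) || length(b_hat) != length(b_adj)) {
      stop("imputation vectors differ in length from expression vectors")
    }
    target <- (a_adj - a_hat) * (b_adj - b_hat)
  } else {
    target <- a_adj * b_adj
  }
  attr(target, "mode") <- mode
  target
}

# Fit the three models (A, B, co) on given samples.  X columns must
# already be standardized; ids_a/ids_b index into colnames(X).
fit_three_models <- function(X, a_adj, b_adj, ids_a, ids_b, union_ids,
                             penalty, mode, n_folds, seed) {
  fit_a <- fit_penalized(X[, ids_a, drop = FALSE], a_adj, penalty = penalty,
                         n_folds = n_folds, seed = seed)
  fit_b <- fit_penalized(X[, ids_b, drop = FALSE], b_adj, penalty = penalty,
                         n_folds = n_folds, seed = seed + 1L)
  a_hat <- predict(fit_a, X[, ids_a, drop = FALSE])
  b_hat <- predict(fit_b, X[, ids_b, drop = FALSE])
  target <- build_coexpression_target(a_adj, b_adj, a_hat, b_hat, mode)
  fit_co <- fit_penalized(X[, union_ids, drop = FALSE], as.numeric(target),
                          penalty = penalty, n_folds = n_folds,
                          seed = seed + 2L)
  list(fit_a = fit_a, fit_b = fit_b, fit_co = fit_co,
       a_hat = a_hat, b_hat = b_hat, target = as.numeric(target))
}

pad_weights <- function(fit, union_ids) {
  w <- stats::setNames(rep(0, length(union_ids)), union_ids)
  w[fit$variant_ids] <- fit$weights
  unname(w)
}

#' Train the three stage-1 models for one exposure pair
#'
#' Fits the exposure-A model on its screened variant set, the exposure-B
#' model on its own set, imputes both exposures in-sample, builds the
#' co-expression target, and fits the co-expression model on the union of
#' the two screened sets.  All three weight vectors are embedded into the
#' union variant order with zeros where a variant is not in that model's
#' feature set.
#'
#' @param panel a \code{\link{genotype_panel}} restricted to the pair's
#'   sample subset (same order as the adjusted expression vectors).
#' @param a_adj,b_adj adjusted expression from \code{\link{adjust_pair}}.
#' @param ids_a,ids_b screened variant ids for each exposure, from
#'   \code{\link{screen_variants}}.
#' @param pair_id identifier stored on the result.
#' @param penalty,mode,n_folds,seed passed to the model fits.
#' @param metrics optional \code{pair_metrics} to embed.
#' @return a \code{\link{weight_set}}; its \code{status} field is
#'   \code{"ok"} or \code{"non_imputable"} when any model has an all-zero
#'   weight vector (zero-variance prediction).
#' @export
train_pair <- function(panel, a_adj, b_adj, ids_a, ids_b, pair_id = "pair",
                       penalty = "lasso", mode = "residual", n_folds = 10,
                       seed = 1, metrics = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  union_ids <- c(ids_a, setdiff(ids_b, ids_a))
  std <- standardize_dosages(panel$dosages[, union_ids, drop = FALSE])
  X <- std$x
  fits <- fit_three_models(X, a_adj, b_adj, ids_a, ids_b, union_ids,
                           penalty, mode, n_folds, seed)
  vmeta <- panel$variants[match(union_ids, panel$variants$id), , drop = FALSE]
  ws <- weight_set(pair_id, vmeta,
                   pad_weights(fits$fit_a, union_ids),
                   pad_weights(fits$fit_b, union_ids),
                   pad_weights(fits$fit_co, union_ids),
                   mode = mode, metrics = metrics)
  all_zero <- c(A = all(ws$w_a == 0), B = all(ws$w_b == 0),
                co = all(ws$w_co == 0))
  ws$status <- if (any(all_zero)) "non_imputable" else "ok"
  ws
}

#' Out-of-sample evaluation of a pair's imputation models
#'
#' Randomly assigns \code{split} of the samples to training and the rest
#' to testing, then measures Pearson correlations between measured and
#' imputed expression on the test split for each exposure.  The
#' co-expression model is scored as the test-split correlation between
#' its prediction (from models trained only on the training split) and
#' the target recomputed on the test split -- in residual mode using
#' single-exposure models trained on ALL samples, in product mode using
#' the observed product of adjusted expression.  A pair passes when all
#' three correlations exceed \code{min_corr}.
#'
#' @inheritParams train_pair
#' @param split training fraction (default 0.8).
#' @param min_corr pass threshold on each correlation (default 0.03).
#' @param min_test smallest acceptable test split (default 30 samples).
#' @return a \code{pair_metrics} list: \code{r_a}, \code{r_b},
#'   \code{r_co}, squared versions, split sizes, \code{pass} and a
#'   \code{reason} when a correlation is undefined.
#' @export
evaluate_pair <- function(panel, a_adj, b_adj, ids_a, ids_b,
                          penalty = "lasso", mode = "residual",
                          split = 0.8, min_corr = 0.03, n_folds = 10,
                          seed = 1, min_test = 30) {
  n <- length(panel$sample_ids)
  n_test <- n - floor(split * n)
  if (n_test < min_test) {
    stop("test split would have ", n_test, " samples; need at least ",
         min_test)
  }
  union_ids <- c(ids_a, setdiff(ids_b, ids_a))
  train_idx <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sort(sample(n, floor(split * n)))
  })
  test_idx <- setdiff(seq_len(n), train_idx)

  d_union <- panel$dosages[, union_ids, drop = FALSE]
  std_tr <- standardize_dosages(d_union[train_idx, , drop = FALSE])
  X_tr <- std_tr$x
  # test dosages standardized with training-set statistics
  X_te <- standardize_dosages(d_union[test_idx, , drop = FALSE],
                              center = std_tr$center,
                              scale = std_tr$scale)$x

  fits80 <- fit_three_models(X_tr, a_adj[train_idx], b_adj[train_idx],
                             ids_a, ids_b, union_ids, penalty, mode,
                             n_folds, seed)
  a_hat_te <- predict(fits80$fit_a, X_te[, ids_a, drop = FALSE])
  b_hat_te <- predict(fits80$fit_b, X_te[, ids_b, drop = FALSE])
  c_hat_te <- predict(fits80$fit_co, X_te)

  if (mode == "residual") {
    # test-split target uses single-exposure models trained on all samples
    std_all <- standardize_dosages(d_union)
    fit_a_full <- fit_penalized(std_all$x[, ids_a, drop = FALSE], a_adj,
                                penalty = penalty, n_folds = n_folds,
                                seed = seed)
    fit_b_full <- fit_penalized(std_all$x[, ids_b, drop = FALSE], b_adj,
                                penalty = penalty, n_folds = n_folds,
                                seed = seed + 1L)
    a_hat_full <- predict(fit_a_full, std_all$x[, ids_a, drop = FALSE])
    b_hat_full <- predict(fit_b_full, std_all$x[, ids_b, drop = FALSE])
    c_tilde_te <- (a_adj[test_idx] - a_hat_full[test_idx]) *
      (b_adj[test_idx] - b_hat_full[test_idx])
  } else {
    c_tilde_te <- a_adj[test_idx] * b_adj[test_idx]
  }

  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }
  r_a <- safe_cor(a_adj[test_idx], a_hat_te)
  r_b <- safe_cor(b_adj[test_idx], b_hat_te)
  r_co <- safe_cor(c_tilde_te, c_hat_te)
  rs <- c(r_a, r_b, r_co)
  reason <- NULL
  if (anyNA(rs)) {
    reason <- "zero-variance prediction on test split"
    pass <- FALSE
  } else {
    pass <- all(rs > min_corr)
  }
  structure(list(r_a = r_a, r_b = r_b, r_co = r_co,
                 r2_a = r_a^2, r2_b = r_b^2, r2_co = r_co^2,
                 n_train = length(train_idx), n_test = length(test_idx),
                 pass = pass, reason = reason),
            class = "pair_metrics")
}

#' @export
#' @method print pair_metrics
print.pair_metrics <- function(x, ...) {
  cat(sprintf("Out-of-sample performance (train %d / test %d)\n",
              x$n_train, x$n_test))
  cat(sprintf("  r(A) = %.4f, r(B) = %.4f, r(co) = %.4f; pass = %s\n",
              x$r_a, x$r_b, x$r_co, x$pass))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Train imputation models for one exposure pair, end to end
#'
#' The main stage-1 entry point: normalizes and covariate-adjusts the two
#' exposures on their shared non-missing sample intersection, maps
#' marginal QTLs, screens variants (optionally to each gene's cis
#' window), evaluates out-of-sample imputation performance on a random
#' train/test split, and finally re-trains all three models on the full
#' dataset to produce the weight set used in stage 2.
#'
#' @param panel a \code{\link{genotype_panel}} (already quality
#'   controlled).
#' @param expr an \code{\link{expression_table}} containing both
#'   proteins.
#' @param covariates covariate matrix or \code{NULL}.
#' @param pair a \code{\link{pair_spec}}.
#' @param penalty \code{"elastic_net"}, \code{"lasso"} or \code{"ridge"}.
#' @param screen \code{"pvalue"} or \code{"effect"} ranking for sure
#'   independence screening.
#' @param top_k variants kept per exposure by screening (default 100).
#' @param cis_only restrict screening to each gene's cis window.
#' @param flank cis flank in bp (default 500000).
#' @param mode co-expression target mode.
#' @param split,min_corr,min_test evaluation protocol parameters.
#' @param n_folds CV folds for the penalized fits.
#' @param seed integer seed controlling the split and CV folds.
#' @param evaluate set FALSE to skip the held-out evaluation.
#' @return a \code{\link{weight_set}} with embedded \code{pair_metrics}.
#' @export
cowas_train <- function(panel, expr, covariates = NULL, pair,
                        penalty = c("lasso", "elastic_net", "ridge", "ols"),
                        screen = c("effect", "pvalue"), top_k = 100,
                        cis_only = FALSE, flank = 500000,
                        mode = c("residual", "product"), split = 0.8,
                        min_corr = 0.03, min_test = 30, n_folds = 10,
                        seed = 1, evaluate = TRUE) {
  penalty <- match.arg(penalty)
  screen <- match.arg(screen)
  mode <- match.arg(mode)
  adj <- adjust_pair(expr, covariates, pair)
  sub <- subset_panel(panel, samples = adj$samples)
  qtl_a <- map_pqtls(sub, adj$a_adj, protein = pair$protein_a)
  qtl_b <- map_pqtls(sub, adj$b_adj, protein = pair$protein_b)
  win_a <- if (cis_only) cis_window(pair$window_a, flank) else NULL
  win_b <- if (cis_only) cis_window(pair$window_b, flank) else NULL
  ids_a <- screen_variants(qtl_a, mode = screen, k = top_k,
                           cis_only = cis_only, window = win_a)
  ids_b <- screen_variants(qtl_b, mode = screen, k = top_k,
                           cis_only = cis_only, window = win_b)
  metrics <- if (evaluate) {
    evaluate_pair(sub, adj$a_adj, adj$b_adj, ids_a, ids_b,
                  penalty = penalty, mode = mode, split = split,
                  min_corr = min_corr, n_folds = n_folds, seed = seed,
                  min_test = min_test)
  } else NULL
  pair_id <- paste(pair$protein_a, pair$protein_b, sep = "_")
  ws <- train_pair(sub, adj$a_adj, adj$b_adj, ids_a, ids_b,
                   pair_id = pair_id, penalty = penalty, mode = mode,
                   n_folds = n_folds, seed = seed, metrics = metrics)
  ws$samples <- adj$samples
  ws
}
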