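#' Rank-based inverse-normal (Blom) transform
#'
#' Maps values to normal quantiles of their fractional ranks:
#' \code{qnorm((rank - offset) / (n + 1 - 2 * offset))}, with ties broken
#' by averaging ranks.  Missing values stay missing and are excluded from
#' \code{n}.  If all non-missing values are identical every output is 0.
#'
#' @param values numeric vector; \code{NA} allowed.
#' @param offset rank offset (default 0.375, the Blom constant).
#' @return numeric vector of the same length.
#' @export
blom_transform <- function(values, offset = 0.375) {
  out <- rep(NA_real_, length(values))
  obs <- which(!is.na(values))
  n <- length(obs)
  if (n < 2L) stop("need at least 2 non-missing values")
  x <- values[obs]
  if (max(x) == min(x)) {
    out[obs] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  out[obs] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Normalize and covariate-adjust one exposure pair
#'
#' Restricts to the samples with non-missing measurements for BOTH
#' proteins (missing values are never imputed), Blom-transforms each
#' protein on that intersection, regresses each transformed vector on the
#' standardized covariates plus an intercept, and returns the least-squares
#' residuals re-centered and scaled to unit variance.  These adjusted
#' vectors are the phenotypes used for QTL mapping and stage-1 training.
#'
#' @param expr an \code{\link{expression_table}}.
#' @param covariates numeric matrix with one row per \code{expr} sample
#'   (rownames matching sample ids, or assumed in the same order), or
#'   \code{NULL} for no adjustment beyond normalization.
#' @param pair a \code{\link{pair_spec}}.
#' @return list with \code{a_adj}, \code{b_adj} (unit-variance adjusted
#'   phenotypes) and \code{samples} (the intersection, in input order).
#' @export
adjust_pair <- function(expr, covariates, pair) {
  stopifnot(inherits(expr, "expression_table"), inherits(pair, "pair_spec"))
  for (pr in c(pair$protein_a, pair$protein_b)) {
    if (!pr %in% expr$protein_ids) stop("protein not in expression table: ", pr)
  }
  a_raw <- expr$values[, pair$protein_a]
  b_raw <- expr$values[, pair$protein_b]
  keep <- !is.na(a_raw) & !is.na(b_raw)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (sum(keep) < n_cov + 10L) {
    stop("only ", sum(keep), " samples have both proteins measured; ",
         "need at least ", n_cov + 10L, " for a stable adjustment")
  }
  samples <- expr$sample_ids[keep]
  a_t <- blom_transform(a_raw[keep])
  b_t <- blom_transform(b_raw[keep])
  if (is.null(covariates)) {
    a_res <- a_t - mean(a_t)
    b_res <- b_t - mean(b_t)
  } else {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) {
      m <- match(samples, rownames(cv))
      if (anyNA(m)) stop("covariates missing for sample: ", samples[is.na(m)][1L])
      cv <- cv[m, , drop = FALSE]
    } else {
      if (nrow(cv) != length(expr$sample_ids)) {
        stop("covariate matrix must have one row per expression sample")
      }
      cv <- cv[keep, , drop = FALSE]
    }
    cv <- scale(cv)
    cv[is.nan(cv)] <- 0  # constant covariate column: absorbed by intercept
    X <- cbind(1, cv)
    if (qr(X)$rank < ncol(X)) {
      stop("covariate matrix is rank deficient on the pair's samples")
    }
    a_res <- stats::lsfit(cv, a_t, intercept = TRUE)$residuals
    b_res <- stats::lsfit(cv, b_t, intercept = TRUE)$residuals
  }
  finish <- function(r, label) {
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-10) {
      stop("adjusted expression for protein ", label,
           " has (near) zero variance after covariate regression")
    }
    as.numeric((r - mean(r)) / s)
  }
  list(a_adj = finish(a_res, pair$protein_a),
       b_adj = finish(b_res, pair$protein_b),
       samples = samples)
}
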