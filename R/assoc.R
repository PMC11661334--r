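#' Harmonize GWAS summary statistics to a variant panel's orientation
#'
#' Intersects on variant id and aligns each Z score to the panel's effect
#' allele: identical allele pairs keep their sign, swapped pairs are
#' negated, and strand complements of either orientation are treated as
#' that orientation (palindromic variants are assumed removed upstream by
#' QC, so complements are unambiguous).  Variants whose alleles match no
#' orientation are dropped and counted.
#'
#' @param gwas a \code{\link{gwas_summary}}.
#' @param panel_variants data frame of panel variants (\code{id},
#'   \code{a1}, \code{a2}, ...).
#' @return list with \code{z} and \code{n} aligned in panel order
#'   (restricted to kept variants), \code{ids}, and \code{n_dropped}.
#' @export
harmonize <- function(gwas, panel_variants) {
  pv <- as.data.frame(panel_variants, stringsAsFactors = FALSE)
  if (nrow(pv) == 0L || nrow(gwas) == 0L) stop("empty harmonization input")
  m <- match(pv$id, gwas$id)
  keep_rows <- which(!is.na(m))
  if (length(keep_rows) == 0L) {
    stop("no overlap between GWAS variants and panel variants")
  }
  comp <- function(a) chartr("ACGT", "TGCA", a)
  z <- numeric(0); n <- numeric(0); ids <- character(0)
  n_dropped <- 0L
  for (i in keep_rows) {
    g <- gwas[m[i], ]
    p1 <- toupper(pv$a1[i]); p2 <- toupper(pv$a2[i])
    g1 <- toupper(g$a1); g2 <- toupper(g$a2)
    sgn <- if (g1 == p1 && g2 == p2) 1
      else if (g1 == p2 && g2 == p1) -1
      else if (comp(g1) == p1 && comp(g2) == p2) 1
      else if (comp(g1) == p2 && comp(g2) == p1) -1
      else NA_real_
    if (is.na(sgn)) {
      n_dropped <- n_dropped + 1L
      next
    }
    z <- c(z, sgn * g$z); n <- c(n, g$n); ids <- c(ids, pv$id[i])
  }
  if (length(ids) == 0L) stop("no GWAS variant could be allele-aligned")
  list(z = z, n = n, ids = ids, n_dropped = n_dropped)
}

#' Compute an LD matrix from a reference genotype panel
#'
#' Pearson correlation of mean-imputed, standardized dosage columns; the
#' result is symmetrized and its diagonal set exactly to 1.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param variant_ids variants to include, in the desired order; defaults
#'   to every panel variant.
#' @return correlation matrix with variant ids as dimnames.
#' @export
compute_ld <- function(panel, variant_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$sample_ids) < 2L) stop("need at least 2 samples for LD")
  if (is.null(variant_ids)) variant_ids <- panel$variants$id
  sub <- subset_panel(panel, variants = variant_ids)
  std <- standardize_dosages(sub$dosages)
  if (any(std$zero_var)) {
    stop("zero-variance variant in LD panel: ",
         variant_ids[std$zero_var][1L])
  }
  r <- stats::cor(std$x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  r
}

#' Convert a marginal GWAS Z score to a standardized effect
#'
#' Exact inversion of the simple-regression t statistic on standardized
#' variables: \code{b = z / sqrt(n - 2 + z^2)}, the marginal correlation
#' between the variant's standardized dosage and the standardized trait.
#'
#' @param z Z score(s).
#' @param n GWAS sample size(s), greater than 2.
#' @return standardized marginal effect(s).
#' @export
z_to_beta <- function(z, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  z / sqrt(n - 2 + z^2)
}

#' Wald chi-square p-value
#'
#' Upper tail of the 1-df chi-square distribution at \code{(theta/se)^2}.
#'
#' @param theta effect estimate.
#' @param se its standard error (positive).
#' @return two-sided p-value.
#' @export
wald_pvalue <- function(theta, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  stats::pchisq((theta / se)^2, df = 1, lower.tail = FALSE)
}

#' Global F test against an intercept-only model
#'
#' \code{F = (n2 - 4) / 3 * (rss_null - rss) / rss}, compared to an
#' F(3, n2 - 4) distribution: the test of whether the three imputed
#' predictors jointly improve on the intercept-only fit.  For a
#' standardized outcome \code{rss_null = n2 - 1}.
#'
#' @param rss residual sum of squares of the three-predictor model.
#' @param rss_null residual sum of squares of the intercept-only model.
#' @param n2 outcome sample size.
#' @return list with \code{f} and \code{p}.
#' @export
global_ftest <- function(rss, rss_null, n2) {
  f <- (n2 - 4) / 3 * (rss_null - rss) / rss
  list(f = f, p = stats::pf(f, 3, n2 - 4, lower.tail = FALSE))
}

new_cowas_fit <- function(pair_id, theta, se, p, f_stat, p_global, r2, n2,
                          mode, status, vcov = NULL) {
  structure(list(pair_id = pair_id, theta = theta, se = se, p = p,
                 f_stat = f_stat, p_global = p_global, r2 = r2, n2 = n2,
                 mode = mode, status = status, vcov = vcov),
            class = "cowas_fit")
}

cowas_fit_failed <- function(pair_id, n2, mode, status) {
  nm <- c("A", "B", "co")
  na3 <- stats::setNames(rep(NA_real_, 3L), nm)
  new_cowas_fit(pair_id, na3, na3, na3, NA_real_, NA_real_, NA_real_, n2,
                mode, status)
}

#' Stage-2 association test from individual-level data
#'
#' Imputes both exposures and their co-expression for the outcome cohort
#' from the stage-1 weights (\code{A* = Z* wA}, \code{B* = Z* wB},
#' \code{C* = Z* wco} on standardized dosages), then fits an ordinary
#' least-squares regression of the standardized trait on the three
#' imputed predictors plus an intercept.  Each coefficient gets a Wald
#' chi-square test; the global test compares the fitted model to an
#' intercept-only model with an F(3, n2 - 4) statistic.
#'
#' @param panel2 outcome-cohort \code{\link{genotype_panel}} covering the
#'   weight set's union variants.
#' @param y outcome trait values, one per \code{panel2} sample
#'   (standardized internally).
#' @param weights a \code{\link{weight_set}}.
#' @return a \code{cowas_fit}; \code{status} is \code{"collinear"} with
#'   \code{NA} estimates when the imputed predictors are rank deficient.
#' @export
stage2_individual <- function(panel2, y, weights) {
  stopifnot(inherits(panel2, "genotype_panel"),
            inherits(weights, "cowas_weights"))
  n2 <- length(panel2$sample_ids)
  if (length(y) != n2) stop("y length must equal panel2 sample count")
  if (!is.null(weights$samples) &&
      length(intersect(panel2$sample_ids, weights$samples)) > 0L) {
    warning("outcome cohort shares sample ids with the training cohort; ",
            "two-sample estimates may be biased")
  }
  sub <- subset_panel(panel2, variants = weights$variants$id)
  Z <- standardize_dosages(sub$dosages)$x
  W <- cbind(A = weights$w_a, B = weights$w_b, co = weights$w_co)
  X <- Z %*% W
  y_std <- as.numeric(scale(y))
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < 4L) {
    return(cowas_fit_failed(weights$pair_id, n2, "individual", "collinear"))
  }
  fit <- stats::lm.fit(Xd, y_std)
  rss <- sum(fit$residuals^2)
  rss_null <- sum((y_std - mean(y_std))^2)  # n2 - 1 for standardized y
  sigma2 <- rss / (n2 - 4)
  XtX_inv <- chol2inv(chol(crossprod(Xd)))
  vc <- sigma2 * XtX_inv
  theta <- stats::setNames(fit$coefficients[-1L], c("A", "B", "co"))
  se <- stats::setNames(sqrt(diag(vc))[-1L], c("A", "B", "co"))
  p <- wald_pvalue(theta, se)
  ft <- global_ftest(rss, rss_null, n2)
  new_cowas_fit(weights$pair_id, theta, se, p, ft$f, ft$p,
                r2 = 1 - rss / rss_null, n2 = n2, mode = "individual",
                status = "ok", vcov = vc[-1L, -1L, drop = FALSE])
}

#' Stage-2 association test from GWAS summary statistics
#'
#' Summary-level counterpart of \code{\link{stage2_individual}}, requiring
#' only per-variant GWAS Z scores and an LD reference.  With \code{W} the
#' p-by-3 padded weight matrix, \code{b} the standardized marginal effect
#' vector recovered from the Z scores, \code{S = W' LD W} and
#' \code{v = W' b}, the joint estimates are \code{theta = solve(S, v)},
#' the model R-squared is \code{theta' v} (clipped to \code{[0, 0.999]}),
#' and \code{Var(theta) = (1 - R2) / (n2 - 4) * solve(S)}.  When in-sample
#' LD and exact marginal correlations are supplied this reproduces the
#' individual-level estimator exactly.
#'
#' An ill-conditioned \code{S} (condition number above 1e8) is ridge
#' inflated by \code{1e-6 * trace(S) / 3} on the diagonal and the fit
#' flagged \code{"regularized"}; if still singular the fit fails.
#'
#' @param gwas a \code{\link{gwas_summary}} (harmonized internally to the
#'   weight set's alleles).
#' @param ld LD matrix over (at least) the weight set's union variants.
#' @param weights a \code{\link{weight_set}}.
#' @param n2 GWAS sample size for the degrees of freedom; defaults to the
#'   median per-variant N over kept variants.
#' @return a \code{cowas_fit}.
#' @export
stage2_summary <- function(gwas, ld, weights, n2 = NULL) {
  stopifnot(inherits(weights, "cowas_weights"))
  h <- harmonize(gwas, weights$variants)
  keep <- match(h$ids, weights$variants$id)
  W <- cbind(A = weights$w_a, B = weights$w_b, co = weights$w_co)
  W <- W[keep, , drop = FALSE]
  if (is.null(dimnames(ld))) {
    if (nrow(ld) != nrow(weights$variants)) {
      stop("unnamed LD matrix must cover exactly the union variants")
    }
    sigma <- ld[keep, keep, drop = FALSE]
  } else {
    m <- match(h$ids, rownames(ld))
    if (anyNA(m)) stop("LD matrix is missing variant: ", h$ids[is.na(m)][1L])
    sigma <- ld[m, m, drop = FALSE]
  }
  if (is.null(n2)) n2 <- stats::median(h$n)
  b <- z_to_beta(h$z, h$n)
  S <- crossprod(W, sigma %*% W)
  S <- (S + t(S)) / 2
  v <- as.numeric(crossprod(W, b))
  status <- "ok"
  if (!all(is.finite(S)) || kappa(S, exact = TRUE) > 1e8) {
    S <- S + diag(1e-6 * sum(diag(S)) / 3, 3L)
    status <- "regularized"
  }
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    return(cowas_fit_failed(weights$pair_id, n2, "summary", "failed"))
  }
  theta <- as.numeric(Sinv %*% v)
  r2_raw <- sum(theta * v)
  r2 <- min(max(r2_raw, 0), 0.999)
  if (r2_raw < 0 || r2_raw > 0.999) {
    status <- if (status == "ok") "r2_clipped" else status
  }
  vc <- (1 - r2) / (n2 - 4) * Sinv
  theta <- stats::setNames(theta, c("A", "B", "co"))
  se <- stats::setNames(sqrt(diag(vc)), c("A", "B", "co"))
  p <- wald_pvalue(theta, se)
  # algebraically the F test above with RSS = (n2 - 1) (1 - R2)
  ft <- global_ftest((n2 - 1) * (1 - r2), n2 - 1, n2)
  dimnames(vc) <- list(c("A", "B", "co"), c("A", "B", "co"))
  new_cowas_fit(weights$pair_id, theta, se, p, ft$f, ft$p, r2, n2,
                mode = "summary", status = status, vcov = vc)
}

#' Joint association test for one exposure pair
#'
#' The main stage-2 entry point.  Supply either an outcome-cohort
#' genotype panel with individual trait values, or GWAS summary
#' statistics with an LD reference; the corresponding estimator is
#' dispatched automatically.
#'
#' @param weights a \code{\link{weight_set}} from \code{\link{cowas_train}}.
#' @param panel,y individual-level inputs (see
#'   \code{\link{stage2_individual}}).
#' @param gwas,ld,n2 summary-level inputs (see
#'   \code{\link{stage2_summary}}).
#' @return a \code{cowas_fit} with elements \code{theta}, \code{se},
#'   \code{p} (per-coefficient Wald tests; \code{p["co"]} is the
#'   interaction test), \code{f_stat} and \code{p_global} (global test).
#' @export
cowas <- function(weights, panel = NULL, y = NULL, gwas = NULL, ld = NULL,
                  n2 = NULL) {
  if (!is.null(panel) && !is.null(y)) {
    stage2_individual(panel, y, weights)
  } else if (!is.null(gwas) && !is.null(ld)) {
    stage2_summary(gwas, ld, weights, n2 = n2)
  } else {
    stop("supply either (panel, y) or (gwas, ld)")
  }
}

#' Standard PWAS test from GWAS summary statistics
#'
#' Single-exposure special case of \code{\link{stage2_summary}}: the
#' marginal association between one protein's imputed expression and the
#' trait, with \code{theta = (w' LD w)^{-1} w' b} and variance
#' \code{(1 - R2) / (n2 - 2) * (w' LD w)^{-1}}.
#'
#' @param gwas a \code{\link{gwas_summary}}.
#' @param ld LD matrix covering the model's variants.
#' @param variants data frame of the model's variants (id and alleles).
#' @param w weight vector, one entry per variant.
#' @param n2 GWAS sample size; defaults to the median per-variant N.
#' @param protein label for the result.
#' @return a \code{pwas_fit} list: \code{theta}, \code{se}, \code{p},
#'   \code{r2}, \code{n2}, \code{status}.
#' @export
pwas_summary <- function(gwas, ld, variants, w, n2 = NULL,
                         protein = "protein") {
  h <- harmonize(gwas, variants)
  keep <- match(h$ids, variants$id)
  w <- w[keep]
  if (is.null(dimnames(ld))) {
    sigma <- ld[keep, keep, drop = FALSE]
  } else {
    m <- match(h$ids, rownames(ld))
    if (anyNA(m)) stop("LD matrix is missing variant: ", h$ids[is.na(m)][1L])
    sigma <- ld[m, m, drop = FALSE]
  }
  if (is.null(n2)) n2 <- stats::median(h$n)
  b <- z_to_beta(h$z, h$n)
  s <- as.numeric(crossprod(w, sigma %*% w))
  if (!is.finite(s) || s <= 0) {
    return(structure(list(protein = protein, theta = NA_real_,
                          se = NA_real_, p = NA_real_, r2 = NA_real_,
                          n2 = n2, status = "failed"),
                     class = "pwas_fit"))
  }
  v <- sum(w * b)
  theta <- v / s
  r2 <- min(max(theta * v, 0), 0.999)
  se <- sqrt((1 - r2) / (n2 - 2) / s)
  structure(list(protein = protein, theta = theta, se = se,
                 p = wald_pvalue(theta, se), r2 = r2, n2 = n2,
                 status = "ok"),
            class = "pwas_fit")
}

#' @export
#' @method print pwas_fit
print.pwas_fit <- function(x, ...) {
  cat("PWAS marginal test for '", x$protein, "' (n2 = ", x$n2, ")\n",
      sep = "")
  if (x$status == "ok") {
    cat(sprintf("  theta = %.4g (se %.4g), p = %.3g\n", x$theta, x$se, x$p))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}

#' Bonferroni correction over tested pairs
#'
#' @param pvalues vector of p-values; \code{NA} entries (failed pairs) are
#'   excluded from the tested count.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with the \code{threshold} (\code{alpha / m} over the
#'   \code{m} tested entries) and logical \code{significant} flags.
#' @export
bonferroni <- function(pvalues, alpha = 0.05) {
  m <- sum(!is.na(pvalues))
  if (m < 1L) stop("no tested p-values")
  threshold <- alpha / m
  list(threshold = threshold, m = m,
       significant = !is.na(pvalues) & pvalues <= threshold)
}
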