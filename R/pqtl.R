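#' Marginal QTL mapping for one adjusted phenotype
#'
#' Regresses the adjusted phenotype on each variant's standardized dosage
#' in turn (simple linear regression with intercept; missing dosages are
#' mean-imputed per variant before standardization).  With both sides
#' standardized the slope equals the Pearson correlation.  Two-sided
#' p-values come from the t distribution with n - 2 degrees of freedom.
#' Variants with zero dosage variance after imputation are flagged
#' \code{excluded} and carry \code{NA} estimates.
#'
#' @param panel a \code{\link{genotype_panel}} already restricted to the
#'   pair's sample subset, in the same sample order as \code{y_adj}.
#' @param y_adj standardized adjusted phenotype (one value per panel
#'   sample).
#' @param protein label stored on the result.
#' @return a \code{qtl_result}: data frame with columns \code{id},
#'   \code{chrom}, \code{pos}, \code{beta}, \code{se}, \code{p},
#'   \code{excluded}.
#' @export
map_pqtls <- function(panel, y_adj, protein = "protein") {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  if (length(y_adj) != n) stop("y_adj length must equal panel sample count")
  if (n < 4L) stop("need at least 4 samples for marginal QTL mapping")
  std <- standardize_dosages(panel$dosages)
  y <- (y_adj - mean(y_adj)) / stats::sd(y_adj)
  r <- as.numeric(crossprod(std$x, y)) / (n - 1)
  r <- pmin(1, pmax(-1, r))
  se <- sqrt(pmax(1 - r^2, 0) / (n - 2))
  tstat <- ifelse(se > 0, r / se, Inf * sign(r))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  beta <- r
  beta[std$zero_var] <- NA_real_
  se[std$zero_var] <- NA_real_
  p[std$zero_var] <- NA_real_
  out <- data.frame(id = panel$variants$id, chrom = panel$variants$chrom,
                    pos = panel$variants$pos, beta = beta, se = se, p = p,
                    excluded = std$zero_var, stringsAsFactors = FALSE)
  attr(out, "protein") <- protein
  class(out) <- c("qtl_result", "data.frame")
  out
}

#' Expand a gene window into its cis region
#'
#' The cis region runs from \code{flank} bp upstream of the transcription
#' start to \code{flank} bp downstream of the transcription end, clamped at
#' position 1; intervals are 1-based and closed.
#'
#' @param gene_window list or vector \code{(chrom, start, end)}.
#' @param flank flank size in bp (default 500000).
#' @return list \code{(chrom, lo, hi)}.
#' @export
cis_window <- function(gene_window, flank = 500000) {
  w <- as.list(gene_window)
  chrom <- as.character(w[[1L]])
  start <- as.numeric(w[[2L]]); end <- as.numeric(w[[3L]])
  if (start > end) stop("gene window start exceeds end")
  list(chrom = chrom, lo = max(1, start - flank), hi = end + flank)
}

#' Sure independence screening of QTL-mapped variants
#'
#' Ranks variants by marginal association strength and keeps the top
#' \code{k}: ascending p-value in \code{"pvalue"} mode, descending
#' absolute effect size in \code{"effect"} mode.  Ties are broken
#' deterministically by (chrom, pos, id), which also makes the output
#' invariant to input row order.  Flagged (zero-variance) variants are
#' never selected.
#'
#' @param qtl a \code{qtl_result} from \code{\link{map_pqtls}}.
#' @param mode \code{"pvalue"} or \code{"effect"}.
#' @param k number of variants to keep (default 100).
#' @param cis_only restrict to a cis window first.
#' @param window a \code{(chrom, lo, hi)} region as returned by
#'   \code{\link{cis_window}}; required when \code{cis_only} is TRUE.
#' @return character vector of up to \code{k} variant ids, in rank order.
#' @export
screen_variants <- function(qtl, mode = c("pvalue", "effect"), k = 100,
                            cis_only = FALSE, window = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(qtl)
  df <- df[!df$excluded & !is.na(df$beta), , drop = FALSE]
  if (cis_only) {
    if (is.null(window)) stop("cis_only screening needs a window")
    df <- df[df$chrom == window$chrom & df$pos >= window$lo &
               df$pos <= window$hi, , drop = FALSE]
    if (nrow(df) == 0L) {
      stop("no variants inside cis window ", window$chrom, ":",
           window$lo, "-", window$hi)
    }
  }
  if (nrow(df) == 0L) stop("no mappable variants to screen")
  key <- if (mode == "pvalue") df$p else -abs(df$beta)
  ord <- order(key, df$chrom, df$pos, df$id)
  utils::head(df$id[ord], k)
}
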