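#' Hardy-Weinberg equilibrium goodness-of-fit p-value
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the counts expected under Hardy-Weinberg proportions at the
#' estimated allele frequency.  Monomorphic input returns 1.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes.
#' @return the upper-tail chi-square p-value.
#' @export
hwe_pvalue <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("total genotype count must be positive")
  q <- (2 * n_aa + n_ab) / (2 * n)
  if (q == 0 || q == 1) return(1)
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Variant quality control
#'
#' Applies the standard pre-training variant filters, in this fixed order:
#' missingness rate, minor allele count (MAC), minor allele frequency
#' (MAF), Hardy-Weinberg equilibrium, missing variant id, palindromic
#' alleles.  A variant removed by one filter is not re-counted by a later
#' one, so the per-filter counts in the report always sum, together with
#' the survivors, to the input count.
#'
#' MAF is computed from the mean dosage over non-missing samples as
#' \code{min(f, 1 - f)} with \code{f = mean/2}; MAC uses the summed dosage
#' analogously.  The HWE test runs only when every non-missing dosage is
#' integral (hard calls); on fractional dosages it is skipped and noted in
#' the report.  Palindromic variants (allele pair A/T or C/G) are
#' strand-ambiguous and removed so that GWAS harmonization can rely on
#' allele complements.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param max_missing maximum tolerated missingness rate (default 0.10).
#' @param min_mac minimum minor allele count (default 100).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param hwe_p_min variants with HWE p below this are removed
#'   (default 1e-15).
#' @param drop_palindromic remove A/T and C/G variants (default TRUE).
#' @return a list with the filtered \code{panel} and a \code{qc_report}
#'   (per-filter removal counts, surviving ids, whether HWE was skipped).
#' @export
qc_variants <- function(panel, max_missing = 0.10, min_mac = 100,
                        min_maf = 0.01, hwe_p_min = 1e-15,
                        drop_palindromic = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- nrow(panel$variants)
  if (p == 0L || length(panel$sample_ids) == 0L) stop("empty genotype panel")
  d <- panel$dosages
  alive <- rep(TRUE, p)
  removed <- c(missingness = 0L, mac = 0L, maf = 0L, hwe = 0L,
               no_id = 0L, palindromic = 0L)

  miss_rate <- colMeans(is.na(d))
  drop <- alive & miss_rate > max_missing
  removed["missingness"] <- sum(drop); alive <- alive & !drop

  n_obs <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  mac <- pmin(alt, 2 * n_obs - alt)
  drop <- alive & mac < min_mac
  removed["mac"] <- sum(drop); alive <- alive & !drop

  f <- alt / (2 * n_obs)
  maf <- pmin(f, 1 - f)
  drop <- alive & maf < min_maf
  removed["maf"] <- sum(drop); alive <- alive & !drop

  hard_called <- all(is.na(d) | d == round(d))
  if (hard_called) {
    hwe_p <- vapply(which(alive), function(j) {
      x <- d[, j]; x <- x[!is.na(x)]
      hwe_pvalue(sum(x == 2), sum(x == 1), sum(x == 0))
    }, numeric(1L))
    drop_idx <- which(alive)[hwe_p < hwe_p_min]
    removed["hwe"] <- length(drop_idx); alive[drop_idx] <- FALSE
  }

  id <- panel$variants$id
  drop <- alive & (is.na(id) | id == "" | id == ".")
  removed["no_id"] <- sum(drop); alive <- alive & !drop

  if (drop_palindromic) {
    drop <- alive & is_palindromic(toupper(panel$variants$a1),
                                   toupper(panel$variants$a2))
    removed["palindromic"] <- sum(drop); alive <- alive & !drop
  }

  surviving <- panel$variants$id[alive]
  report <- structure(list(input = p, removed = removed,
                           surviving = surviving,
                           hwe_skipped = !hard_called),
                      class = "qc_report")
  out <- if (any(alive)) subset_panel(panel, variants = surviving) else {
    genotype_panel(panel$sample_ids, panel$variants[alive, , drop = FALSE],
                   panel$dosages[, alive, drop = FALSE])
  }
  list(panel = out, report = report)
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("Variant QC: ", x$input, " in, ", length(x$surviving), " out\n",
      sep = "")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-12s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  if (x$hwe_skipped) cat("  note: HWE skipped (fractional dosages)\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a \code{qc_report}.
#' @param path output path.
#' @return invisibly, \code{report}.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(filter = c(names(report$removed), "surviving", "input"),
                   count = c(unname(report$removed),
                             length(report$surviving), report$input))
  write_tsv_base(df, path)
  invisible(report)
}

#' Greedy LD pruning
#'
#' Walks variants in panel order with a sliding window and removes, within
#' each window, any variant whose squared correlation with a retained
#' earlier variant exceeds \code{r2_max}.  The window and step can be
#' expressed in variant counts or in base pairs.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param r2_max squared-correlation threshold (default 0.8).
#' @param window window size (default 1000).
#' @param step step size (default 100).
#' @param units \code{"count"} (variant counts, the default) or
#'   \code{"bp"}.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(panel, r2_max = 0.8, window = 1000, step = 100,
                     units = c("count", "bp")) {
  units <- match.arg(units)
  v <- panel$variants
  ord <- order(v$chrom, v$pos, v$id)
  X <- standardize_dosages(panel$dosages[, ord, drop = FALSE])$x
  keep <- rep(TRUE, ncol(X))
  pos <- v$pos[ord]; chrom <- v$chrom[ord]
  p <- ncol(X)
  start <- 1L
  while (start <= p) {
    if (units == "count") {
      idx <- start:min(p, start + window - 1L)
    } else {
      idx <- which(chrom == chrom[start] & pos >= pos[start] &
                     pos <= pos[start] + window)
      idx <- idx[idx >= start]
    }
    idx <- idx[keep[idx] & chrom[idx] == chrom[start]]
    if (length(idx) > 1L) {
      r2 <- stats::cor(X[, idx, drop = FALSE])^2
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        later <- which(keep[idx] & seq_along(idx) > a & r2[a, ] > r2_max)
        keep[idx[later]] <- FALSE
      }
    }
    start <- start + step
  }
  v$id[ord][keep]
}

# Mean-impute missing dosages per variant, then center and scale each
# column.  Columns with zero variance after imputation get scale 1 and are
# flagged.  Optionally reuse centers/scales estimated elsewhere (training
# set statistics applied to a test set).
standardize_dosages <- function(d, center = NULL, scale = NULL) {
  d <- as.matrix(d)
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  if (is.null(center)) center <- colMeans(d)
  if (is.null(scale)) {
    scale <- apply(d, 2L, stats::sd)
  }
  zero_var <- !is.finite(scale) | scale <= 0
  scale[zero_var] <- 1
  x <- sweep(sweep(d, 2L, center, "-"), 2L, scale, "/")
  list(x = x, center = center, scale = scale, zero_var = zero_var)
}
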