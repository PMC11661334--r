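#' Construct a genotype panel
#'
#' A genotype panel holds per-sample alternate-allele dosages together with
#' variant metadata (chromosome, position and the two alleles).  Dosages are
#' on the usual 0--2 scale and may contain missing values; allele metadata is
#' what allows stage-2 testing to harmonize external GWAS summary statistics
#' to the panel's orientation.
#'
#' @param sample_ids character vector of sample identifiers (row order).
#' @param variants data frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}.  \code{a1} is the counted (effect)
#'   allele of the dosage column.
#' @param dosages numeric matrix, samples by variants, entries in
#'   \code{[0, 2]} or \code{NA}.
#' @return an object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(sample_ids, variants, dosages) {
  sample_ids <- as.character(sample_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(needed %in% names(variants))) {
    stop("variant metadata must have columns: ", paste(needed, collapse = ", "))
  }
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosage matrix has ", nrow(dosages), " rows but ",
         length(sample_ids), " sample ids")
  }
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage matrix has ", ncol(dosages), " columns but ",
         nrow(variants), " variants")
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicated variant id: ", variants$id[duplicated(variants$id)][1L])
  }
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("dosage outside [0, 2] at sample '", sample_ids[bad[1L, 1L]],
         "', variant '", variants$id[bad[1L, 2L]], "'")
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages),
            class = "genotype_panel")
}

#' @export
#' @method print genotype_panel
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel: ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat("  missing dosage rate: ", format(round(miss, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by samples and/or variants
#'
#' @param panel a \code{genotype_panel}.
#' @param samples character vector of sample ids to keep (in the given
#'   order), or \code{NULL} to keep all.
#' @param variants character vector of variant ids to keep (in the given
#'   order), or \code{NULL} to keep all.
#' @return a \code{genotype_panel}.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(samples)) seq_along(panel$sample_ids) else {
    m <- match(samples, panel$sample_ids)
    if (anyNA(m)) stop("sample not in panel: ", samples[is.na(m)][1L])
    m
  }
  vi <- if (is.null(variants)) seq_len(nrow(panel$variants)) else {
    m <- match(variants, panel$variants$id)
    if (anyNA(m)) stop("variant not in panel: ", variants[is.na(m)][1L])
    m
  }
  genotype_panel(panel$sample_ids[si], panel$variants[vi, , drop = FALSE],
                 panel$dosages[si, vi, drop = FALSE])
}

#' Construct an expression table
#'
#' @param sample_ids character vector of sample identifiers.
#' @param protein_ids character vector of protein (or gene) identifiers.
#' @param values numeric matrix, samples by proteins; \code{NA} allowed.
#' @return an object of class \code{expression_table}.
#' @export
expression_table <- function(sample_ids, protein_ids, values) {
  sample_ids <- as.character(sample_ids)
  protein_ids <- as.character(protein_ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(protein_ids)) stop("duplicated protein id")
  if (nrow(values) != length(sample_ids) || ncol(values) != length(protein_ids)) {
    stop("expression matrix dimensions do not match identifiers")
  }
  dimnames(values) <- list(sample_ids, protein_ids)
  structure(list(sample_ids = sample_ids, protein_ids = protein_ids,
                 values = values),
            class = "expression_table")
}

#' @export
#' @method print expression_table
print.expression_table <- function(x, ...) {
  cat("Expression table: ", length(x$sample_ids), " samples x ",
      length(x$protein_ids), " proteins\n", sep = "")
  invisible(x)
}

#' Specify an exposure pair
#'
#' Carries the two protein identifiers and the genomic windows of their
#' coding genes (1-based, closed intervals), used to build cis windows for
#' variant screening.
#'
#' @param protein_a,protein_b protein identifiers; must differ.
#' @param window_a,window_b lists or vectors \code{(chrom, start, end)} for
#'   the coding gene of each protein.
#' @return an object of class \code{pair_spec}.
#' @export
pair_spec <- function(protein_a, protein_b, window_a = NULL, window_b = NULL) {
  if (identical(protein_a, protein_b)) stop("the two proteins must differ")
  norm_win <- function(w) {
    if (is.null(w)) return(NULL)
    w <- as.list(w)
    out <- list(chrom = as.character(w[[1L]]), start = as.numeric(w[[2L]]),
                end = as.numeric(w[[3L]]))
    if (out$start > out$end) stop("gene window start exceeds end")
    out
  }
  structure(list(protein_a = as.character(protein_a),
                 protein_b = as.character(protein_b),
                 window_a = norm_win(window_a), window_b = norm_win(window_b)),
            class = "pair_spec")
}

#' @export
#' @method print pair_spec
print.pair_spec <- function(x, ...) {
  cat("Exposure pair: ", x$protein_a, " -- ", x$protein_b, "\n", sep = "")
  invisible(x)
}

#' Construct a GWAS summary-statistics object
#'
#' @param id variant identifiers (unique).
#' @param a1,a2 effect and other allele for each variant.
#' @param z per-variant Z score (effect size divided by its standard error).
#' @param n per-variant GWAS sample size (at least 5).
#' @param trait optional trait label.
#' @return an object of class \code{gwas_summary}: a data frame with
#'   columns \code{id}, \code{a1}, \code{a2}, \code{z}, \code{n}.
#' @export
gwas_summary <- function(id, a1, a2, z, n, trait = "trait") {
  df <- data.frame(id = as.character(id), a1 = toupper(as.character(a1)),
                   a2 = toupper(as.character(a2)), z = as.numeric(z),
                   n = as.numeric(n), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicated variant id in GWAS summary")
  if (any(!is.finite(df$z))) stop("non-finite Z score in GWAS summary")
  if (any(df$n < 5)) stop("per-variant N below 5 in GWAS summary")
  attr(df, "trait") <- trait
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' @export
#' @method print gwas_summary
print.gwas_summary <- function(x, ...) {
  cat("GWAS summary statistics for '", attr(x, "trait"), "': ",
      nrow(x), " variants, median N = ", stats::median(x$n), "\n", sep = "")
  invisible(x)
}

#' Construct a weight set
#'
#' A weight set stores the fitted variant weights of the three stage-1
#' models of one exposure pair -- exposure A, exposure B and their
#' co-expression -- embedded into a common union variant list.  A weight is
#' zero wherever a variant was not part of that model's screened feature
#' set, so that all three imputations can be computed from one genotype
#' matrix over the union variants.
#'
#' @param pair_id identifier of the exposure pair.
#' @param variants data frame of union variants (\code{id}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}), in model feature order.
#' @param w_a,w_b,w_co numeric weight vectors, one entry per union variant,
#'   on the standardized-dosage scale.
#' @param mode \code{"residual"} or \code{"product"} co-expression target.
#' @param metrics optional \code{pair_metrics} from out-of-sample
#'   evaluation.
#' @return an object of class \code{cowas_weights}.
#' @export
weight_set <- function(pair_id, variants, w_a, w_b, w_co,
                       mode = c("residual", "product"), metrics = NULL) {
  mode <- match.arg(mode)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  p <- nrow(variants)
  if (length(w_a) != p || length(w_b) != p || length(w_co) != p) {
    stop("weight vectors must all have one entry per union variant")
  }
  structure(list(pair_id = as.character(pair_id), variants = variants,
                 w_a = as.numeric(w_a), w_b = as.numeric(w_b),
                 w_co = as.numeric(w_co), mode = mode, metrics = metrics),
            class = "cowas_weights")
}

#' @export
#' @method print cowas_weights
print.cowas_weights <- function(x, ...) {
  cat("Stage-1 weight set for pair '", x$pair_id, "' (", x$mode,
      " mode)\n", sep = "")
  cat("  union variants: ", nrow(x$variants),
      "; nonzero weights A/B/co: ", sum(x$w_a != 0), "/", sum(x$w_b != 0),
      "/", sum(x$w_co != 0), "\n", sep = "")
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  out-of-sample r (A, B, co): %.3f, %.3f, %.3f; pass = %s\n",
                m$r_a, m$r_b, m$r_co, m$pass))
  }
  invisible(x)
}
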