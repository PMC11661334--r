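# Tab-delimited readers/writers for every on-disk artifact.  All files are
# UTF-8 TSV with a header row; missing values are written as "NA".

read_tsv_base <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
}

#' Read a genotype panel from dosage and variant-metadata files
#'
#' The dosage file is a TSV whose first column is \code{sample_id} and whose
#' remaining columns are one variant each, holding numeric alternate-allele
#' dosages in \code{[0, 2]} (\code{NA} for missing).  The metadata file has
#' columns \code{id}, \code{chrom}, \code{pos}, \code{a1}, \code{a2}.  The
#' returned panel orders variants as in the metadata file and samples as in
#' the dosage file.
#'
#' @param dosage_path path to the dosage TSV.
#' @param variant_meta_path path to the variant metadata TSV.
#' @return a \code{\link{genotype_panel}}.
#' @export
read_genotype_panel <- function(dosage_path, variant_meta_path) {
  dos <- read_tsv_base(dosage_path)
  meta <- read_tsv_base(variant_meta_path)
  if (names(dos)[1L] != "sample_id") {
    stop("first column of the dosage file must be 'sample_id'")
  }
  vids_dos <- names(dos)[-1L]
  missing_in_dos <- setdiff(meta$id, vids_dos)
  if (length(missing_in_dos) > 0L) {
    stop("variant in metadata but not in dosage file: ", missing_in_dos[1L])
  }
  extra_in_dos <- setdiff(vids_dos, meta$id)
  if (length(extra_in_dos) > 0L) {
    stop("variant in dosage file but not in metadata: ", extra_in_dos[1L])
  }
  dosages <- as.matrix(dos[, meta$id, drop = FALSE])
  genotype_panel(dos$sample_id, meta, dosages)
}

#' Write a genotype panel to dosage and variant-metadata files
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param dosage_path,variant_meta_path output paths.
#' @return invisibly, \code{panel}.
#' @export
write_genotype_panel <- function(panel, dosage_path, variant_meta_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(sample_id = panel$sample_ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(panel$dosages, check.names = FALSE))
  write_tsv_base(df, dosage_path)
  write_tsv_base(panel$variants, variant_meta_path)
  invisible(panel)
}

#' Read an expression table
#'
#' TSV with first column \code{sample_id} and one column per protein.
#'
#' @param path input path.
#' @return an \code{\link{expression_table}}.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_base(path)
  if (names(df)[1L] != "sample_id") {
    stop("first column of the expression file must be 'sample_id'")
  }
  expression_table(df$sample_id, names(df)[-1L],
                   as.matrix(df[, -1L, drop = FALSE]))
}

#' Write an expression table
#'
#' @param expr an \code{\link{expression_table}}.
#' @param path output path.
#' @return invisibly, \code{expr}.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(sample_id = expr$sample_ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(expr$values, check.names = FALSE))
  write_tsv_base(df, path)
  invisible(expr)
}

#' Read GWAS summary statistics
#'
#' Expects a TSV with columns \code{id}, \code{a1}, \code{a2}, \code{n} and
#' either a \code{z} column or a \code{beta} plus \code{se} pair, in which
#' case Z scores are computed as \code{beta / se}.  Records with missing
#' fields or a non-positive standard error are dropped; the number of
#' dropped records is attached as attribute \code{"n_dropped"}.
#'
#' @param path input path.
#' @param z_mode \code{"auto"} uses \code{z} when present, otherwise
#'   \code{beta}/\code{se}; \code{"z"} and \code{"beta_se"} force one.
#' @param trait trait label attached to the result.
#' @return a \code{\link{gwas_summary}} with attribute \code{n_dropped}.
#' @export
read_gwas_summary <- function(path, z_mode = c("auto", "z", "beta_se"),
                              trait = "trait") {
  z_mode <- match.arg(z_mode)
  df <- read_tsv_base(path)
  has_z <- "z" %in% names(df)
  has_bse <- all(c("beta", "se") %in% names(df))
  if (z_mode == "auto") z_mode <- if (has_z) "z" else "beta_se"
  if (z_mode == "z" && !has_z) stop("no 'z' column in GWAS file")
  if (z_mode == "beta_se" && !has_bse) {
    stop("GWAS file provides neither z nor beta+se columns")
  }
  if (!all(c("id", "a1", "a2", "n") %in% names(df))) {
    stop("GWAS file must have columns id, a1, a2, n")
  }
  if (z_mode == "z") {
    z <- df$z
    ok <- !is.na(df$id) & !is.na(df$a1) & !is.na(df$a2) & !is.na(z) &
      !is.na(df$n)
  } else {
    ok <- !is.na(df$id) & !is.na(df$a1) & !is.na(df$a2) & !is.na(df$beta) &
      !is.na(df$se) & !is.na(df$n) & df$se > 0
    z <- ifelse(ok, df$beta / df$se, NA_real_)
  }
  n_dropped <- sum(!ok)
  out <- gwas_summary(df$id[ok], df$a1[ok], df$a2[ok], z[ok], df$n[ok],
                      trait = trait)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GWAS summary statistics
#'
#' @param gwas a \code{\link{gwas_summary}}.
#' @param path output path.
#' @return invisibly, \code{gwas}.
#' @export
write_gwas_summary <- function(gwas, path) {
  stopifnot(inherits(gwas, "gwas_summary"))
  write_tsv_base(as.data.frame(gwas), path)
  invisible(gwas)
}

#' Write a weight set (long-format TSV plus metrics sidecar)
#'
#' Weights are written one row per (model, variant) in union variant order,
#' with columns \code{pair_id}, \code{model} (A, B or co), \code{variant_id},
#' \code{chrom}, \code{pos}, \code{a1}, \code{a2}, \code{weight}.  Weights
#' are serialized with 17 significant digits so the round trip is lossless
#' to within 1e-15 absolute.  Evaluation metrics, if present, go to a
#' sidecar TSV.
#'
#' @param ws a \code{\link{weight_set}}.
#' @param path output path for the weights.
#' @param metrics_path output path for the metrics sidecar; defaults to
#'   \code{path} with a \code{_metrics.tsv} suffix.
#' @return invisibly, \code{ws}.
#' @export
write_weight_set <- function(ws, path,
                             metrics_path = default_metrics_path(path)) {
  stopifnot(inherits(ws, "cowas_weights"))
  v <- ws$variants
  one <- function(model, w) {
    data.frame(pair_id = ws$pair_id, model = model, variant_id = v$id,
               chrom = v$chrom, pos = v$pos, a1 = v$a1, a2 = v$a2,
               weight = sprintf("%.17g", w), mode = ws$mode,
               stringsAsFactors = FALSE)
  }
  df <- rbind(one("A", ws$w_a), one("B", ws$w_b), one("co", ws$w_co))
  write_tsv_base(df, path)
  if (!is.null(ws$metrics)) {
    m <- ws$metrics
    md <- data.frame(pair_id = ws$pair_id, r_a = m$r_a, r_b = m$r_b,
                     r_co = m$r_co, r2_a = m$r2_a, r2_b = m$r2_b,
                     r2_co = m$r2_co, n_train = m$n_train, n_test = m$n_test,
                     pass = m$pass, stringsAsFactors = FALSE)
    write_tsv_base(md, metrics_path)
  }
  invisible(ws)
}

default_metrics_path <- function(path) {
  paste0(sub("\\.tsv$", "", path), "_metrics.tsv")
}

#' Read a weight set written by \code{\link{write_weight_set}}
#'
#' @param path weights TSV path.
#' @param metrics_path metrics sidecar path; read if the file exists.
#' @return a \code{\link{weight_set}}.
#' @export
read_weight_set <- function(path,
                            metrics_path = default_metrics_path(path)) {
  df <- read_tsv_base(path)
  bad <- setdiff(unique(df$model), c("A", "B", "co"))
  if (length(bad) > 0L) stop("unknown model label in weight file: ", bad[1L])
  a <- df[df$model == "A", , drop = FALSE]
  b <- df[df$model == "B", , drop = FALSE]
  co <- df[df$model == "co", , drop = FALSE]
  if (!identical(a$variant_id, b$variant_id) ||
      !identical(a$variant_id, co$variant_id)) {
    stop("the three models must share one union variant order")
  }
  variants <- data.frame(id = a$variant_id, chrom = as.character(a$chrom),
                         pos = a$pos, a1 = a$a1, a2 = a$a2,
                         stringsAsFactors = FALSE)
  metrics <- NULL
  if (file.exists(metrics_path)) {
    md <- read_tsv_base(metrics_path)
    metrics <- as.list(md[1L, ])
  }
  weight_set(df$pair_id[1L], variants, as.numeric(a$weight),
             as.numeric(b$weight), as.numeric(co$weight),
             mode = df$mode[1L], metrics = metrics)
}
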