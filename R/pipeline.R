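#' Assemble a full pipeline configuration
#'
#' Collects every tunable of the simulate / preprocess / train / test
#' stages with defaults matching the method's standard settings: top-100
#' variant screening, 500 kb cis flank, 0.03 out-of-sample correlation
#' filter, 80/20 evaluation split, lasso penalty, and the usual variant QC
#' thresholds (10% missingness, MAC 100, MAF 1%, HWE p 1e-15, palindromic
#' variants removed).
#'
#' Inputs are given either as in-memory objects (a \code{sim} config, or
#' panel/expression/GWAS objects) or as file paths to the package's TSV
#' formats; in-memory objects win when both are present.
#'
#' @param out_dir results directory (created if absent).
#' @param sim optional \code{\link{sim_config}}; when set, the pipeline
#'   starts by generating a synthetic dataset and ignores input paths.
#' @param panel,expr,covariates,pairs,gwas,ld_panel in-memory inputs:
#'   a \code{\link{genotype_panel}}, an \code{\link{expression_table}},
#'   a covariate matrix or NULL, a list of \code{\link{pair_spec}}, a
#'   \code{\link{gwas_summary}}, and a reference panel for LD.
#' @param dosage_path,variant_path,expression_path,gwas_path input file
#'   paths, used when the corresponding object is NULL.
#' @param penalty,screen,top_k,cis_only,flank,mode,min_corr,split,n_folds
#'   training-stage settings (see \code{\link{cowas_train}}).
#' @param max_missing,min_mac,min_maf,hwe_p_min,drop_palindromic variant
#'   QC thresholds (see \code{\link{qc_variants}}).
#' @param n2 GWAS sample size override for stage 2 (NULL = per-variant
#'   median).
#' @param alpha family-wise error rate for the Bonferroni correction.
#' @param min_test smallest acceptable evaluation test split.
#' @param seed integer seed for every random choice in the run.
#' @return a \code{cowas_config} list.
#' @export
cowas_config <- function(out_dir, sim = NULL, panel = NULL, expr = NULL,
                         covariates = NULL, pairs = NULL, gwas = NULL,
                         ld_panel = NULL, dosage_path = NULL,
                         variant_path = NULL, expression_path = NULL,
                         gwas_path = NULL,
                         penalty = "lasso", screen = "effect", top_k = 100,
                         cis_only = FALSE, flank = 500000,
                         mode = "residual", min_corr = 0.03, split = 0.8,
                         n_folds = 10, max_missing = 0.10, min_mac = 100,
                         min_maf = 0.01, hwe_p_min = 1e-15,
                         drop_palindromic = TRUE, n2 = NULL, alpha = 0.05,
                         min_test = 30, seed = 1) {
  structure(as.list(environment()), class = "cowas_config")
}

manifest_of <- function(config) {
  keep <- !vapply(config, function(x) {
    is.null(x) ||
      inherits(x, c("genotype_panel", "expression_table", "gwas_summary"))
  }, logical(1L))
  cfg <- unclass(config)[keep]
  cfg$out_dir <- NULL  # run location, not part of the reproducible config
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  if (!is.null(cfg$pairs)) {
    cfg$pairs <- lapply(cfg$pairs, function(p) {
      list(protein_a = p$protein_a, protein_b = p$protein_b,
           window_a = p$window_a, window_b = p$window_b)
    })
  }
  cfg$covariates <- NULL
  cfg$ld_panel <- NULL
  list(config = cfg,
       package = "coexwas",
       version = as.character(utils::packageVersion("coexwas")))
}

#' Run the full pipeline
#'
#' Orchestrates simulate (optional), variant QC, per-pair training and
#' evaluation, the 0.03 imputation filter, summary-level association
#' testing against the GWAS with LD from the reference panel, a standard
#' PWAS baseline for every distinct protein, and Bonferroni correction.
#' All outputs are plain TSV/JSON in \code{config$out_dir}: a QC report,
#' per-pair weight and metrics files, a results table (one row per
#' trained pair), a PWAS table, a significant-pair edge list, and a run
#' manifest holding the full configuration.  Given the same configuration
#' and seed the output files are byte-identical across runs; zero passing
#' pairs still yields a complete (header-only) results table and exit
#' without error.
#'
#' Any stage failure aborts with a stage-named message and leaves a
#' \code{FAILED} marker file next to the partial outputs.
#'
#' @param config a \code{\link{cowas_config}}.
#' @return invisibly, a list with the trained weight sets, metrics,
#'   the results and PWAS tables, and the Bonferroni thresholds.
#' @export
cowas_run <- function(config) {
  stopifnot(inherits(config, "cowas_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  stage <- "setup"
  log_line <- function(...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  result <- tryCatch({
    if (!is.null(config$sim)) {
      stage <- "simulate"
      log_line("generating synthetic dataset (seed %d)", config$sim$seed)
      ds <- simulate_dataset(config$sim)
      panel <- ds$panel1; expr <- ds$expr; covariates <- ds$covariates
      pairs <- list(ds$pair); gwas <- ds$gwas; ld_panel <- ds$panel2
    } else {
      stage <- "read"
      panel <- if (!is.null(config$panel)) config$panel else
        read_genotype_panel(config$dosage_path, config$variant_path)
      expr <- if (!is.null(config$expr)) config$expr else
        read_expression_table(config$expression_path)
      covariates <- config$covariates
      pairs <- config$pairs
      gwas <- if (!is.null(config$gwas)) config$gwas else
        read_gwas_summary(config$gwas_path)
      ld_panel <- if (!is.null(config$ld_panel)) config$ld_panel else panel
      if (is.null(pairs)) stop("no exposure pairs configured")
    }

    stage <- "preprocess"
    qc <- qc_variants(panel, max_missing = config$max_missing,
                      min_mac = config$min_mac, min_maf = config$min_maf,
                      hwe_p_min = config$hwe_p_min,
                      drop_palindromic = config$drop_palindromic)
    write_qc_report(qc$report, file.path(config$out_dir, "qc_report.tsv"))
    log_line("QC kept %d of %d variants", length(qc$report$surviving),
             qc$report$input)
    panel <- qc$panel

    stage <- "train"
    pair_ids <- vapply(pairs, function(p)
      paste(p$protein_a, p$protein_b, sep = "_"), character(1L))
    ord <- order(pair_ids)
    pairs <- pairs[ord]; pair_ids <- pair_ids[ord]
    weight_sets <- vector("list", length(pairs))
    names(weight_sets) <- pair_ids
    metrics_rows <- list()
    for (i in seq_along(pairs)) {
      ws <- tryCatch(
        cowas_train(panel, expr, covariates, pairs[[i]],
                    penalty = config$penalty, screen = config$screen,
                    top_k = config$top_k, cis_only = config$cis_only,
                    flank = config$flank, mode = config$mode,
                    split = config$split, min_corr = config$min_corr,
                    min_test = config$min_test, n_folds = config$n_folds,
                    seed = config$seed),
        error = function(e) e)
      if (inherits(ws, "error")) {
        log_line("pair %s training failed: %s", pair_ids[i],
                 conditionMessage(ws))
        metrics_rows[[i]] <- data.frame(pair_id = pair_ids[i],
                                        r_a = NA_real_, r_b = NA_real_,
                                        r_co = NA_real_, pass = FALSE,
                                        status = "train_error",
                                        stringsAsFactors = FALSE)
        next
      }
      weight_sets[[i]] <- ws
      write_weight_set(ws, file.path(config$out_dir,
                                     paste0("weights_", pair_ids[i], ".tsv")))
      m <- ws$metrics
      metrics_rows[[i]] <- data.frame(pair_id = pair_ids[i], r_a = m$r_a,
                                      r_b = m$r_b, r_co = m$r_co,
                                      pass = m$pass, status = ws$status,
                                      stringsAsFactors = FALSE)
      log_line("pair %s trained: r = (%.3f, %.3f, %.3f), pass = %s",
               pair_ids[i], m$r_a, m$r_b, m$r_co, m$pass)
    }
    metrics <- do.call(rbind, metrics_rows)
    write_tsv_base(metrics, file.path(config$out_dir, "pair_metrics.tsv"))

    stage <- "test"
    tested <- list()
    pwas_rows <- list()
    for (i in seq_along(pairs)) {
      ws <- weight_sets[[i]]
      if (is.null(ws) || ws$status != "ok" || !isTRUE(ws$metrics$pass)) next
      ld <- compute_ld(ld_panel, ws$variants$id)
      fit <- stage2_summary(gwas, ld, ws, n2 = config$n2)
      tested[[ws$pair_id]] <- fit
      for (side in c("a", "b")) {
        protein <- if (side == "a") pairs[[i]]$protein_a else
          pairs[[i]]$protein_b
        w <- if (side == "a") ws$w_a else ws$w_b
        pw <- pwas_summary(gwas, ld, ws$variants, w, n2 = config$n2,
                           protein = protein)
        pwas_rows[[paste(ws$pair_id, side)]] <-
          data.frame(protein = protein, pair_id = ws$pair_id,
                     theta = pw$theta, se = pw$se, p = pw$p,
                     status = pw$status, stringsAsFactors = FALSE)
      }
    }
    results <- if (length(tested) > 0L) cowas_results_table(tested) else
      cowas_results_table(list())
    if (is.null(results)) {
      results <- data.frame(pair_id = character(0), theta_a = numeric(0),
                            theta_b = numeric(0), theta_co = numeric(0),
                            se_a = numeric(0), se_b = numeric(0),
                            se_co = numeric(0), p_a = numeric(0),
                            p_b = numeric(0), p_co = numeric(0),
                            f_stat = numeric(0), p_global = numeric(0),
                            r2 = numeric(0), n2 = numeric(0),
                            mode = character(0), status = character(0))
    }
    write_tsv_base(results, file.path(config$out_dir, "results.tsv"))
    pwas_tab <- if (length(pwas_rows) > 0L) do.call(rbind, pwas_rows) else
      data.frame(protein = character(0), pair_id = character(0),
                 theta = numeric(0), se = numeric(0), p = numeric(0),
                 status = character(0))
    rownames(pwas_tab) <- NULL
    write_tsv_base(pwas_tab, file.path(config$out_dir, "pwas.tsv"))

    stage <- "correct"
    edges <- data.frame(pair_id = character(0), test = character(0),
                        p = numeric(0))
    corr <- NULL
    if (nrow(results) > 0L) {
      corr <- list(global = bonferroni(results$p_global, config$alpha),
                   interaction = bonferroni(results$p_co, config$alpha))
      sig_g <- which(corr$global$significant)
      sig_i <- which(corr$interaction$significant)
      edges <- rbind(
        data.frame(pair_id = results$pair_id[sig_g],
                   test = rep("global", length(sig_g)),
                   p = results$p_global[sig_g], stringsAsFactors = FALSE),
        data.frame(pair_id = results$pair_id[sig_i],
                   test = rep("interaction", length(sig_i)),
                   p = results$p_co[sig_i], stringsAsFactors = FALSE))
      log_line("%d significant pair-tests at alpha = %g", nrow(edges),
               config$alpha)
    } else {
      log_line("zero pairs passed the imputation filter")
    }
    write_tsv_base(edges, file.path(config$out_dir, "significant_pairs.tsv"))

    stage <- "manifest"
    jsonlite::write_json(manifest_of(config),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    list(weight_sets = weight_sets, metrics = metrics, results = results,
         pwas = pwas_tab, edges = edges, correction = corr)
  }, error = function(e) {
    writeLines(paste0("stage '", stage, "': ", conditionMessage(e)),
               failed_marker)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
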