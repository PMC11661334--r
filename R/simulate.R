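#' Configuration for the synthetic two-sample generator
#'
#' Bundles every latent parameter of the generative model: a sparse
#' cis-pQTL architecture for two exposures, a genotype-modulated residual
#' correlation (the coQTL effect), and a downstream quantitative trait
#' built from the genetically regulated expression and co-expression of
#' the pair.  The defaults describe a well-powered two-sample design:
#' 5,000 expression samples, 20,000 GWAS samples, 50 independent variants,
#' five causal variants per component with effect scale 0.3, and trait
#' effects (0.1, -0.1, 0.2) for (direct A, direct B, co-expression).
#'
#' @param n1 expression-cohort sample size.
#' @param n2 GWAS-cohort sample size.
#' @param p number of variants.
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param k_a,k_b,k_co causal-variant counts for exposure A, exposure B
#'   and the residual-correlation (coQTL) component.
#' @param effect_a,effect_b per-variant absolute effect size on each
#'   exposure (signs random).
#' @param eta0 baseline residual correlation on the link scale.
#' @param eta_scale per-coQTL absolute effect on the link scale.
#' @param theta length-3 trait effects (direct A, direct B,
#'   co-expression).
#' @param noise_sd trait residual standard deviation.
#' @param h2_a,h2_b optional exposure heritabilities in [0, 1); when set,
#'   per-variant effects become \code{sqrt(h2/k)} and residual variance
#'   \code{1 - h2}, so each exposure has unit total variance.
#' @param missing_rate fraction of expression entries set missing.
#' @param n_covariates number of standard-normal covariates with known
#'   loadings added to both exposures (0 disables).
#' @param cov_effect covariate loading magnitude.
#' @param ld_phi AR(1) correlation of latent haplotypes within blocks of
#'   \code{ld_block} variants (0 = independent variants).
#' @param ld_block block size for the AR(1) LD mode.
#' @param seed integer seed; the whole dataset is a pure function of this
#'   configuration.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n1 = 5000, n2 = 20000, p = 50,
                       maf_range = c(0.05, 0.5), k_a = 5, k_b = 5,
                       k_co = 5, effect_a = 0.3, effect_b = 0.3,
                       eta0 = 0.2, eta_scale = 0.3,
                       theta = c(0.1, -0.1, 0.2), noise_sd = 1,
                       h2_a = NULL, h2_b = NULL, missing_rate = 0,
                       n_covariates = 0, cov_effect = 0.5, ld_phi = 0,
                       ld_block = 10, seed = 1) {
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
        maf_range[2] <= 0.5)) {
    stop("maf_range must satisfy 0 < lo <= hi <= 0.5")
  }
  if (max(k_a, k_b, k_co) > p) stop("causal counts cannot exceed p")
  for (h2 in list(h2_a, h2_b)) {
    if (!is.null(h2) && h2 >= 1) stop("requested heritability must be < 1")
  }
  if (length(theta) != 3L) stop("theta must have length 3")
  structure(list(n1 = n1, n2 = n2, p = p, maf_range = maf_range,
                 k_a = k_a, k_b = k_b, k_co = k_co, effect_a = effect_a,
                 effect_b = effect_b, eta0 = eta0, eta_scale = eta_scale,
                 theta = stats::setNames(as.numeric(theta),
                                         c("A", "B", "co")),
                 noise_sd = noise_sd, h2_a = h2_a, h2_b = h2_b,
                 missing_rate = missing_rate,
                 n_covariates = n_covariates, cov_effect = cov_effect,
                 ld_phi = ld_phi, ld_block = ld_block,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named trait-effect presets
#'
#' @param scenario one of \code{"null"} (no trait effects),
#'   \code{"direct-only"}, \code{"coqtl-only"} or \code{"full"}.
#' @param ... further arguments to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
sim_preset <- function(scenario = c("full", "null", "direct-only",
                                    "coqtl-only"), ...) {
  scenario <- match.arg(scenario)
  theta <- switch(scenario, null = c(0, 0, 0),
                  `direct-only` = c(0.1, -0.1, 0),
                  `coqtl-only` = c(0, 0, 0.2), full = c(0.1, -0.1, 0.2))
  sim_config(theta = theta, ...)
}

# non-palindromic allele pairs only, so QC never removes simulated variants
allele_pairs <- function() {
  rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
        c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Simulate a hard-called genotype panel
#'
#' Per-variant minor allele frequencies are drawn uniformly from
#' \code{maf_range}; dosages are Binomial(2, MAF).  With \code{phi > 0},
#' latent haplotype indicators follow an AR(1) copula within blocks of
#' \code{block} variants, inducing block-diagonal LD.
#'
#' @param n,p sample and variant counts.
#' @param maf_range MAF range.
#' @param seed integer seed.
#' @param phi AR(1) latent correlation (0 = independent).
#' @param block block size for correlated mode.
#' @param sample_prefix prefix for generated sample ids.
#' @return a \code{\link{genotype_panel}} of hard calls.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), seed = 1,
                               phi = 0, block = 10, sample_prefix = "s") {
  stopifnot(n >= 1, p >= 1)
  with_seed(seed, {
    maf <- stats::runif(p, maf_range[1], maf_range[2])
    if (phi == 0) {
      d <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    } else {
      hap <- function() {
        lat <- matrix(stats::rnorm(n * p), n, p)
        for (j in seq(2L, p)) {
          if ((j - 1L) %% block != 0L) {
            lat[, j] <- phi * lat[, j - 1L] +
              sqrt(1 - phi^2) * lat[, j]
          }
        }
        sweep(stats::pnorm(lat), 2L, maf, "<") * 1L
      }
      d <- hap() + hap()
    }
    ap <- allele_pairs()
    ai <- sample(nrow(ap), p, replace = TRUE)
    variants <- data.frame(id = paste0("v", seq_len(p)), chrom = "1",
                           pos = 1000000L + (seq_len(p) - 1L) * 5000L,
                           a1 = ap[ai, 1L], a2 = ap[ai, 2L],
                           stringsAsFactors = FALSE)
    panel <- genotype_panel(paste0(sample_prefix, seq_len(n)), variants, d)
    attr(panel, "maf") <- maf
    panel
  })
}

#' Simulate an exposure pair with a genotype-modulated correlation
#'
#' Exposure values follow sparse linear genetic architectures on
#' standardized dosages, \code{A = Z_A beta_A + eps_A} and likewise for B.
#' The residual pair is bivariate normal with per-sample correlation
#' \code{rho_i = tanh(eta0 + Z_co,i' eta)}: the tanh link keeps the
#' correlation inside (-1, 1) while staying locally linear in the
#' small-effect regime, so a linear model for the residual product is the
#' matched analysis.  Causal index sets are drawn without replacement and
#' may overlap between components.
#'
#' @param panel a \code{\link{genotype_panel}} (no missing dosages).
#' @param cfg a \code{\link{sim_config}}.
#' @return list with an \code{\link{expression_table}} (\code{expr},
#'   proteins "P1" and "P2"), optional \code{covariates}, and a
#'   \code{truth} record holding every latent quantity (causal indices,
#'   effect vectors, per-sample \code{rho} and residuals).
#' @export
simulate_expression_pair <- function(panel, cfg) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(cfg, "sim_config"))
  n <- length(panel$sample_ids)
  with_seed(cfg$seed + 101L, {
    Z <- standardize_dosages(panel$dosages)$x
    p <- ncol(Z)
    idx_a <- sort(sample(p, cfg$k_a))
    idx_b <- sort(sample(p, cfg$k_b))
    idx_co <- sort(sample(p, cfg$k_co))
    eff <- function(k, scale) scale * sample(c(-1, 1), k, replace = TRUE)
    sd_a <- sd_b <- 1
    effect_a <- cfg$effect_a; effect_b <- cfg$effect_b
    if (!is.null(cfg$h2_a)) {
      effect_a <- sqrt(cfg$h2_a / cfg$k_a); sd_a <- sqrt(1 - cfg$h2_a)
    }
    if (!is.null(cfg$h2_b)) {
      effect_b <- sqrt(cfg$h2_b / cfg$k_b); sd_b <- sqrt(1 - cfg$h2_b)
    }
    beta_a <- eff(cfg$k_a, effect_a)
    beta_b <- eff(cfg$k_b, effect_b)
    eta <- eff(cfg$k_co, cfg$eta_scale)
    g_a <- as.numeric(Z[, idx_a, drop = FALSE] %*% beta_a)
    g_b <- as.numeric(Z[, idx_b, drop = FALSE] %*% beta_b)
    rho <- tanh(cfg$eta0 +
                  as.numeric(Z[, idx_co, drop = FALSE] %*% eta))
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    eps_a <- x1
    eps_b <- rho * x1 + sqrt(1 - rho^2) * x2
    a <- g_a + sd_a * eps_a
    b <- g_b + sd_b * eps_b
    covariates <- NULL
    load_a <- load_b <- NULL
    if (cfg$n_covariates > 0) {
      covariates <- matrix(stats::rnorm(n * cfg$n_covariates), n,
                           cfg$n_covariates,
                           dimnames = list(panel$sample_ids,
                                           paste0("c", seq_len(cfg$n_covariates))))
      load_a <- eff(cfg$n_covariates, cfg$cov_effect)
      load_b <- eff(cfg$n_covariates, cfg$cov_effect)
      a <- a + as.numeric(covariates %*% load_a)
      b <- b + as.numeric(covariates %*% load_b)
    }
    vals <- cbind(P1 = a, P2 = b)
    if (cfg$missing_rate > 0) {
      nas <- which(stats::runif(length(vals)) < cfg$missing_rate)
      vals[nas] <- NA_real_
    }
    truth <- list(idx_a = idx_a, idx_b = idx_b, idx_co = idx_co,
                  beta_a = beta_a, beta_b = beta_b, eta = eta,
                  eta0 = cfg$eta0, rho = rho,
                  eps_a = sd_a * eps_a, eps_b = sd_b * eps_b,
                  g_a = g_a, g_b = g_b, sd_a = sd_a, sd_b = sd_b,
                  load_a = load_a, load_b = load_b)
    list(expr = expression_table(panel$sample_ids, c("P1", "P2"), vals),
         covariates = covariates, truth = truth)
  })
}

#' Simulate the outcome trait and its marginal GWAS
#'
#' The trait is a linear combination of the genetically regulated
#' expression of both exposures and their genetically regulated
#' co-expression (which, with unit residual variances, is the per-sample
#' residual correlation \code{rho}):
#' \code{y = theta_A g_A + theta_B g_B + theta_co rho + e}.  The trait is
#' standardized, and per-variant marginal summary statistics are computed
#' by simple regression of \code{y} on each standardized dosage, giving
#' \code{z = beta/se} with \code{n = n2} for every variant.
#'
#' @param panel2 GWAS-cohort \code{\link{genotype_panel}} (same variants
#'   as the training panel).
#' @param cfg a \code{\link{sim_config}}.
#' @param truth truth record from \code{\link{simulate_expression_pair}}
#'   (the same latent parameters applied to the new genotypes).
#' @return list with \code{y} (standardized trait) and \code{gwas}
#'   (a \code{\link{gwas_summary}}).
#' @export
simulate_outcome_and_gwas <- function(panel2, cfg, truth) {
  stopifnot(inherits(panel2, "genotype_panel"), inherits(cfg, "sim_config"))
  n2 <- length(panel2$sample_ids)
  with_seed(cfg$seed + 202L, {
    Z <- standardize_dosages(panel2$dosages)$x
    g_a <- as.numeric(Z[, truth$idx_a, drop = FALSE] %*% truth$beta_a)
    g_b <- as.numeric(Z[, truth$idx_b, drop = FALSE] %*% truth$beta_b)
    rho <- tanh(truth$eta0 +
                  as.numeric(Z[, truth$idx_co, drop = FALSE] %*% truth$eta))
    y <- cfg$theta[["A"]] * g_a + cfg$theta[["B"]] * g_b +
      cfg$theta[["co"]] * rho + stats::rnorm(n2, 0, cfg$noise_sd)
    y <- as.numeric(scale(y))
    r <- as.numeric(crossprod(Z, y)) / (n2 - 1)
    r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
    z <- r * sqrt((n2 - 2) / (1 - r^2))
    gwas <- gwas_summary(panel2$variants$id, panel2$variants$a1,
                         panel2$variants$a2, z, rep(n2, ncol(Z)),
                         trait = "simulated_trait")
    list(y = y, gwas = gwas)
  })
}

#' Simulate a complete two-sample dataset
#'
#' Generates a training panel with expression for both exposures, a
#' disjoint GWAS panel with the outcome trait and its marginal summary
#' statistics, and a truth record sufficient to recompute every latent
#' quantity.  Sample ids never overlap between the two panels (prefixes
#' "s" and "t"), honouring the two-sample design.  The pair's gene
#' windows are set to span the full simulated region, so cis screening
#' keeps every variant.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{panel1}, \code{expr}, \code{covariates},
#'   \code{pair}, \code{panel2}, \code{y}, \code{gwas}, \code{truth} and
#'   the \code{config} itself.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  panel1 <- simulate_genotypes(cfg$n1, cfg$p, cfg$maf_range,
                               seed = cfg$seed, phi = cfg$ld_phi,
                               block = cfg$ld_block, sample_prefix = "s")
  # GWAS cohort: same variants and frequencies, fresh disjoint samples
  panel2 <- with_seed(cfg$seed + 303L, {
    maf <- attr(panel1, "maf")
    if (cfg$ld_phi == 0) {
      d <- matrix(stats::rbinom(cfg$n2 * cfg$p, 2L, rep(maf, each = cfg$n2)),
                  cfg$n2, cfg$p)
    } else {
      hap <- function() {
        lat <- matrix(stats::rnorm(cfg$n2 * cfg$p), cfg$n2, cfg$p)
        for (j in seq(2L, cfg$p)) {
          if ((j - 1L) %% cfg$ld_block != 0L) {
            lat[, j] <- cfg$ld_phi * lat[, j - 1L] +
              sqrt(1 - cfg$ld_phi^2) * lat[, j]
          }
        }
        sweep(stats::pnorm(lat), 2L, maf, "<") * 1L
      }
      d <- hap() + hap()
    }
    genotype_panel(paste0("t", seq_len(cfg$n2)), panel1$variants, d)
  })
  ep <- simulate_expression_pair(panel1, cfg)
  og <- simulate_outcome_and_gwas(panel2, cfg, ep$truth)
  pair <- pair_spec("P1", "P2",
                    window_a = list("1", 1, max(panel1$variants$pos)),
                    window_b = list("1", 1, max(panel1$variants$pos)))
  list(panel1 = panel1, expr = ep$expr, covariates = ep$covariates,
       pair = pair, panel2 = panel2, y = og$y, gwas = og$gwas,
       truth = ep$truth, config = cfg)
}
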