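#' @export
#' @method print cowas_fit
print.cowas_fit <- function(x, ...) {
  cat("Joint association fit for pair '", x$pair_id, "' (", x$mode,
      " data, n2 = ", x$n2, ")\n", sep = "")
  if (x$status %in% c("collinear", "failed")) {
    cat("  status:", x$status, "- no estimates\n")
    return(invisible(x))
  }
  est <- data.frame(theta = x$theta, se = x$se, p = x$p)
  rownames(est) <- c("direct A", "direct B", "co-expression")
  print(format(est, digits = 4))
  cat(sprintf("Global test: F = %.4f on (3, %d) df, p = %.3g\n",
              x$f_stat, as.integer(x$n2 - 4), x$p_global))
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' @export
coef.cowas_fit <- function(object, ...) object$theta

#' @export
vcov.cowas_fit <- function(object, ...) object$vcov

#' @export
confint.cowas_fit <- function(object, parm = c("A", "B", "co"),
                              level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(lower = object$theta[parm] - zq * object$se[parm],
               upper = object$theta[parm] + zq * object$se[parm])
  rownames(out) <- parm
  out
}

#' @export
#' @method summary cowas_fit
summary.cowas_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cowas_fit")
}

#' @export
#' @method print summary.cowas_fit
print.summary.cowas_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!f$status %in% c("collinear", "failed")) {
    cat("\nInteraction test (co-expression effect): W = ",
        format((f$theta["co"] / f$se["co"])^2, digits = 4),
        ", p = ", format(f$p["co"], digits = 3), "\n", sep = "")
    cat("Stage-2 model R-squared: ", format(f$r2, digits = 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Collect several fits into a results table
#'
#' @param fits list of \code{cowas_fit} objects.
#' @return data frame with one row per pair: estimates, standard errors,
#'   Wald p-values, the global F test and status.
#' @export
cowas_results_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(pair_id = f$pair_id, theta_a = f$theta[["A"]],
               theta_b = f$theta[["B"]], theta_co = f$theta[["co"]],
               se_a = f$se[["A"]], se_b = f$se[["B"]], se_co = f$se[["co"]],
               p_a = f$p[["A"]], p_b = f$p[["B"]], p_co = f$p[["co"]],
               f_stat = f$f_stat, p_global = f$p_global, r2 = f$r2,
               n2 = f$n2, mode = f$mode, status = f$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
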