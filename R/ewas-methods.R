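# Methods for the classed EWAS fit objects.

#' @export
print.ewas_fit <- function(x, ...) {
  cat("EWAS fit:", x$model, "\n")
  cat("  ", nrow(x$records), "units tested, n =", x$n, ";",
      sum(x$records$significant), "significant at FDR <",
      x$thresholds["fdr"], "and |delta-beta| >", x$thresholds["delta"], "\n")
  invisible(x)
}

#' @export
summary.ewas_fit <- function(object, n_top = 10, ...) {
  rec <- object$records
  ord <- order(rec$fdr_q, -abs(rec$delta_beta))
  out <- list(model = object$model, n = object$n,
              n_tested = nrow(rec),
              n_significant = sum(rec$significant),
              thresholds = object$thresholds,
              top = utils::head(rec[ord, ], n_top))
  class(out) <- "summary.ewas_fit"
  out
}

#' @export
print.summary.ewas_fit <- function(x, ...) {
  cat("EWAS fit:", x$model, " (n =", x$n, ")\n")
  cat(x$n_significant, "of", x$n_tested, "units significant at FDR <",
      x$thresholds["fdr"], "and |delta-beta| >", x$thresholds["delta"], "\n")
  cat("Top units:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ewas_fit <- function(object, ...) {
  stats::setNames(object$records$coefficient, object$records$probe_id)
}

#' @export
as.data.frame.ewas_fit <- function(x, ...) x$records

#' Volcano plot of an EWAS fit
#'
#' Delta-beta against -log10 of the p-value used for the significance call
#' (inflation-corrected when available), with the FDR and delta-beta
#' thresholds drawn as dashed lines.
#'
#' @param x An \code{"ewas_fit"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.ewas_fit <- function(x, ...) {
  rec <- x$records
  p <- if (all(is.na(rec$p_bacon))) rec$p_raw else rec$p_bacon
  graphics::plot(rec$delta_beta, -log10(p),
                 xlab = expression(Delta * beta),
                 ylab = expression(-log[10](p)),
                 pch = 16, cex = 0.5,
                 col = ifelse(rec$significant, "firebrick", "grey50"), ...)
  graphics::abline(v = c(-1, 1) * x$thresholds["delta"], lty = 2)
  if (any(rec$significant)) {
    pcut <- max(p[rec$fdr_q < x$thresholds["fdr"]])
    graphics::abline(h = -log10(pcut), lty = 2)
  }
  invisible(x)
}

#' Write EWAS records as TSV
#'
#' Fixed column order: probe, coef, se, t, df, p_raw, p_bacon, fdr_q,
#' delta_beta, significant.
#'
#' @param fit An \code{"ewas_fit"}.
#' @param path Output file.
#' @export
write_ewas_tsv <- function(fit, path) {
  cols <- c("probe_id", "coefficient", "std_error", "t_statistic", "df",
            "p_raw", "p_bacon", "fdr_q", "delta_beta", "significant")
  extra <- setdiff(names(fit$records), cols)
  utils::write.table(fit$records[, c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
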