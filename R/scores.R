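# Surrogate and composite scores: the allostatic-load index, the
# methylation-derived IL-6 score, and the contribution analysis that asks
# how much of each CpG's gestational-age coefficient a psychosocial or
# biological variable accounts for.

#' Allostatic-load composite score
#'
#' Cortisol is first adjusted for draw time (minutes from midnight) and
#' gestational week by least squares: adjusted = observed - predicted +
#' cohort mean, so both upward and downward departures from the expected
#' value register as dysregulation. The six mediators (adjusted cortisol,
#' HbA1c, CRP, total cholesterol, systolic and diastolic blood pressure)
#' are z-standardized (mean 0, variance 1) and averaged.
#'
#' @param panel Data frame with one row per woman: \code{cortisol},
#'   \code{hba1c}, \code{crp}, \code{cholesterol}, \code{sbp}, \code{dbp},
#'   \code{cortisol_draw_min}, \code{gest_week_at_draw}.
#' @return Named numeric vector of scores (cohort mean 0 by construction);
#'   names taken from \code{panel$woman_id} when present.
#' @export
allostatic_load <- function(panel) {
  if (nrow(panel) < 3) stop("at least 3 women are required to standardize mediators")
  fit <- stats::lm(cortisol ~ cortisol_draw_min + gest_week_at_draw, data = panel)
  adj_cortisol <- panel$cortisol - stats::fitted(fit) + mean(panel$cortisol)
  meds <- cbind(cortisol = adj_cortisol, hba1c = panel$hba1c, crp = panel$crp,
                cholesterol = panel$cholesterol, sbp = panel$sbp, dbp = panel$dbp)
  zs <- apply(meds, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero-variance mediator; its z-score is set to 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  })
  out <- rowMeans(zs)
  names(out) <- panel$woman_id %||% rownames(panel)
  out
}

#' Methylation-derived IL-6 surrogate score
#'
#' Weighted average over the predictor CpGs available in the matrix:
#' score = mean over available probes of (weight x beta). Probes absent
#' from the matrix are dropped and the divisor is the count of available
#' probes, so partially covered arrays remain comparable.
#'
#' @param betas Beta matrix (probes x arrays).
#' @param weights Data frame with \code{probe_id} and \code{weight} columns
#'   (or a named numeric vector).
#' @return Named numeric vector of per-array scores, with the availability
#'   count attached as attribute \code{"n_available"}.
#' @export
il6_score <- function(betas, weights) {
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$weight, weights$probe_id)
  } else w <- weights
  avail <- intersect(names(w), rownames(betas))
  if (length(avail) == 0) stop("no IL-6 predictor probes present in the beta matrix")
  if (length(avail) < length(w))
    message("il6_score: ", length(avail), " of ", length(w),
            " predictor CpGs available")
  sc <- colMeans(betas[avail, , drop = FALSE] * w[avail])
  attr(sc, "n_available") <- length(avail)
  sc
}

#' Contribution of a covariate to CpG-gestational age associations
#'
#' For each (probe, variable) pair, compares the gestational-age
#' coefficient of the base GA model (as in \code{\link{fit_ga_ewas}}) with
#' the coefficient after adding the variable:
#' contribution (\%) = 100 x (beta_base - beta_adjusted) / beta_base. The
#' variable's own two-sided p in the adjusted model is BH-adjusted across
#' the full (probe, variable) grid; by convention only records at
#' FDR < \code{fdr_threshold} are flagged as reported. The signed base
#' coefficient is the denominator, so suppressors can yield negative or
#' >100\% contributions; they are reported as computed.
#'
#' @param betas Beta matrix (probes x arrays) at one timepoint.
#' @param sheet Sample sheet (as in \code{\link{fit_ga_ewas}}).
#' @param pcs Compositional PCs for the arrays.
#' @param probes CpGs to test (typically the timepoint's significant EWAS
#'   set).
#' @param variables Named list of per-array covariate vectors (named by
#'   array id, or in column order of \code{betas}); z-scored upstream where
#'   convention requires.
#' @param fdr_threshold Reporting threshold (default 0.1).
#' @param k_huber Huber tuning constant (default 1.345).
#' @return Data frame with one row per (probe, variable):
#'   \code{beta_base}, \code{beta_adjusted}, \code{contribution_pct},
#'   \code{variable_p}, \code{variable_fdr}, \code{reported}. Pairs with a
#'   zero base coefficient are suppressed with a warning.
#' @export
contribution_analysis <- function(betas, sheet, pcs, probes, variables,
                                  fdr_threshold = 0.1, k_huber = 1.345) {
  scores <- if (inherits(pcs, "composition_pcs")) pcs$pc_scores else as.matrix(pcs)
  idx <- match(colnames(betas), sheet$array_id)
  if (anyNA(idx)) stop("arrays missing from the sample sheet")
  meta <- sheet[idx, ]
  if (!all(meta$term)) {
    keep <- meta$term
    betas <- betas[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  sc <- scores[match(colnames(betas), rownames(scores)), 1:2, drop = FALSE]
  Xb <- cbind(intercept = 1, ga = meta$ga_weeks, maternal_age = meta$maternal_age,
              PC1 = sc[, 1], PC2 = sc[, 2])
  n <- nrow(Xb)
  rows <- list()
  for (pb in probes) {
    y <- betas[pb, ]
    base <- MASS::rlm(Xb, y, psi = MASS::psi.huber, k = k_huber, maxit = 50)
    b_base <- base$coefficients["ga"]
    for (vn in names(variables)) {
      v <- variables[[vn]]
      if (!is.null(names(v))) v <- v[colnames(betas)]
      if (anyNA(v)) stop("variable ", vn, " missing values for some arrays")
      Xa <- cbind(Xb, variable = v)
      adj <- MASS::rlm(Xa, y, psi = MASS::psi.huber, k = k_huber, maxit = 50)
      b_adj <- adj$coefficients["ga"]
      se_v <- rlm_se(adj, Xa)[ncol(Xa)]
      tv <- adj$coefficients["variable"] / se_v
      pv <- 2 * stats::pt(-abs(tv), n - ncol(Xa))
      if (b_base == 0) {
        warning("zero base GA coefficient for ", pb, "; contribution undefined")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pb, variable = vn,
        beta_base = unname(b_base), beta_adjusted = unname(b_adj),
        contribution_pct = contribution_pct(b_base, b_adj),
        variable_p = unname(pv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$variable_fdr <- stats::p.adjust(out$variable_p, method = "BH")
  out$reported <- out$variable_fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' Contribution percentage from base and adjusted coefficients
#'
#' @param beta_base GA coefficient without the variable.
#' @param beta_adjusted GA coefficient with the variable added.
#' @return 100 x (beta_base - beta_adjusted) / beta_base.
#' @export
contribution_pct <- function(beta_base, beta_adjusted) {
  100 * (beta_base - beta_adjusted) / beta_base
}
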