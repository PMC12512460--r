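# Per-CpG association models: the longitudinal timepoint model (random
# intercept per woman, REML, with an outer Huber-reweighting loop), the
# per-timepoint robust gestational-age EWAS (Huber M-estimation via
# MASS::rlm), empirical-null inflation correction of the test statistics,
# BH false-discovery control, beta-scale effect sizes, candidate testing at
# the other timepoint and the term/preterm contrast.

new_ewas_fit <- function(records, model, n, thresholds, subclass = character()) {
  structure(list(records = records, model = model, n = n,
                 thresholds = thresholds),
            class = c(subclass, "ewas_fit"))
}

# ---------------------------------------------------------------------------
# Random-intercept REML with fixed per-observation error weights.
# V_i = sigma^2 (diag(1/w_i) + lambda * 1 1'); lambda = tau^2 / sigma^2 is
# profiled by direct search. All group sums are computed with rowsum so a
# single evaluation is a handful of matrix products.
reml_gls <- function(y, X, group, w, lambda) {
  wX <- X * w
  s_i <- rowsum(w, group)                       # per-group sum of weights
  t_i <- rowsum(wX, group)                      # per-group X' W 1  (rows = groups)
  ty <- rowsum(w * y, group)                    # per-group 1' W y
  shrink <- lambda / (1 + lambda * drop(s_i))   # per-group factor
  A <- crossprod(X, wX) - crossprod(t_i * sqrt(shrink))
  b1 <- crossprod(wX, y) - crossprod(t_i, shrink * ty)
  bhat <- solve(A, b1)
  r <- y - drop(X %*% bhat)
  wr <- rowsum(w * r, group)
  rss <- sum(w * r^2) - sum(shrink * wr^2)
  list(coef = drop(bhat), A = A, rss = rss,
       logdetV = -sum(log(w)) + sum(log1p(lambda * s_i)))
}

reml_crit <- function(lambda, y, X, group, w) {
  p <- ncol(X)
  n <- length(y)
  g <- reml_gls(y, X, group, w, lambda)
  s2 <- g$rss / (n - p)
  (n - p) * log(s2) + g$logdetV + determinant(g$A, logarithm = TRUE)$modulus
}

# One probe: REML random-intercept fit with an outer Huber loop on the
# marginal residuals. Lambda is profiled by direct search, then held fixed
# while the Huber weights iterate; the profile/IRLS blocks alternate until
# both lambda and the coefficients stabilize. Returns the fixed-effect
# vector, its covariance, the converged weights and a convergence flag.
fit_rlmm_probe <- function(y, X, group, k_huber = 1.345, tol = 1e-8,
                           max_iter = 50) {
  profile_lambda <- function(w) {
    opt <- stats::optimize(function(ll) reml_crit(exp(ll), y, X, group, w),
                           interval = log(c(1e-8, 1e4)), tol = 1e-6)
    exp(opt$minimum)
  }
  w <- rep(1, length(y))
  converged <- FALSE
  lambda <- profile_lambda(w)
  g <- reml_gls(y, X, group, w, lambda)
  iters_left <- max_iter
  for (block in 1:6) {
    # inner IRLS at fixed lambda
    repeat {
      if (iters_left <= 0L) break
      iters_left <- iters_left - 1L
      r <- y - drop(X %*% g$coef)
      s <- stats::mad(r)
      if (s < 1e-12) { converged <- TRUE; break }   # perfect fit
      w <- huber_weight(r / s, k_huber)
      g_new <- reml_gls(y, X, group, w, lambda)
      done <- max(abs(g_new$coef - g$coef)) < tol
      g <- g_new
      if (done) break
    }
    if (converged) break
    lambda_new <- profile_lambda(w)
    g_new <- reml_gls(y, X, group, w, lambda_new)
    # the profile step moves lambda by up to its search tolerance, so the
    # cross-block coefficient stability check is necessarily looser than
    # the inner IRLS tolerance
    stable <- abs(log(lambda_new + 1e-12) - log(lambda + 1e-12)) < 1e-3 &&
      max(abs(g_new$coef - g$coef)) < max(tol, 1e-6)
    lambda <- lambda_new
    g <- g_new
    if (stable) { converged <- TRUE; break }
    if (iters_left <= 0L) break
  }
  if (!converged) {                               # fall back to unweighted REML
    w <- rep(1, length(y))
    lambda <- profile_lambda(w)
    g <- reml_gls(y, X, group, w, lambda)
  }
  s2 <- g$rss / (length(y) - ncol(X))
  list(coef = g$coef, vcov = s2 * solve(g$A), converged = converged,
       lambda = lambda, weights = w)
}

#' Longitudinal timepoint model across the methylome
#'
#' Per CpG, a random-intercept (per woman) linear model of beta on
#' timepoint, maternal age and the five between-timepoint cell-proportion
#' differences, fitted by REML with an outer Huber-reweighting loop for
#' robustness to outlying residuals. The timepoint t statistic is referred
#' to a t distribution with \code{n_women - 1} degrees of freedom; the
#' statistics are then recalibrated against an empirical null
#' (\code{\link{bacon_correct}}) before BH false-discovery control. The
#' effect size is the late-minus-early beta difference averaged over women.
#'
#' @param early,late Beta matrices (probes x arrays) for matched pairs; the
#'   i-th column of each must belong to the same woman.
#' @param sheet Sample sheet containing \code{woman_id} and
#'   \code{maternal_age} for the early arrays (matched by \code{array_id}
#'   to \code{colnames(early)}).
#' @param cell_diffs Women x 5 matrix of late-minus-early estimated
#'   proportions (Bmem, CD4mem, CD8mem, Neu, NK), rows in the same woman
#'   order as the columns of \code{early}.
#' @param fdr_threshold,delta_threshold Significance thresholds
#'   (defaults 0.1 and 0.03).
#' @param k_huber Huber tuning constant (default 1.345).
#' @return An \code{"ewas_fit"} of subclass \code{"timepoint_ewas"}. The
#'   records table has one row per probe with coefficient, SE, t, df, raw /
#'   inflation-corrected / FDR-adjusted p, delta_beta and the significance
#'   call; the inflation fit is attached as \code{$inflation}.
#' @export
fit_timepoint_model <- function(early, late, sheet, cell_diffs,
                                fdr_threshold = 0.1, delta_threshold = 0.03,
                                k_huber = 1.345) {
  if (!identical(rownames(early), rownames(late)))
    stop("early and late matrices must cover the same probes")
  if (ncol(early) != ncol(late))
    stop("early and late must contain one array per woman each (matched pairs only)")
  idx <- match(colnames(early), sheet$array_id)
  if (anyNA(idx)) stop("early arrays missing from the sample sheet")
  women <- sheet$woman_id[idx]
  age <- sheet$maternal_age[idx]
  n <- length(women)
  cell_diffs <- as.matrix(cell_diffs)
  if (nrow(cell_diffs) != n) stop("cell_diffs must have one row per woman")

  # observation order: (early_1..early_n, late_1..late_n)
  tp <- rep(c(0, 1), each = n)
  X <- cbind(intercept = 1, timepoint = tp,
             maternal_age = rep(age, 2),
             rbind(cell_diffs, cell_diffs))
  group <- rep(seq_len(n), 2)
  probes <- rownames(early)

  coefs <- ses <- numeric(length(probes))
  flagged <- logical(length(probes))
  for (i in seq_along(probes)) {
    y <- c(early[i, ], late[i, ])
    fit <- fit_rlmm_probe(y, X, group, k_huber = k_huber)
    coefs[i] <- fit$coef["timepoint"]
    ses[i] <- sqrt(fit$vcov["timepoint", "timepoint"])
    flagged[i] <- !fit$converged
  }
  tstat <- coefs / ses
  df <- n - 1
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  delta <- rowMeans(late) - rowMeans(early)

  inflation <- bacon_correct(tstat, df)
  p_bacon <- inflation$p_corrected
  fdr_q <- stats::p.adjust(p_bacon, method = "BH")
  records <- data.frame(
    probe_id = probes, coefficient = coefs, std_error = ses,
    t_statistic = tstat, df = df, p_raw = p_raw, p_bacon = p_bacon,
    fdr_q = fdr_q, delta_beta = delta,
    significant = fdr_q < fdr_threshold & abs(delta) > delta_threshold,
    fallback_fit = flagged,
    stringsAsFactors = FALSE
  )
  out <- new_ewas_fit(records,
                      model = "beta ~ timepoint + maternal_age + 5 cell diffs + (1 | woman)",
                      n = n,
                      thresholds = c(fdr = fdr_threshold, delta = delta_threshold),
                      subclass = "timepoint_ewas")
  out$inflation <- inflation
  out
}

# ---------------------------------------------------------------------------

#' Empirical-null recalibration of test statistics
#'
#' Transforms t statistics to z scores through their tail probabilities and
#' fits a three-component normal mixture (a central null plus two tail
#' components) by EM. The null component's mean and SD rescale the z scores,
#' removing bias and inflation; corrected two-sided p-values follow. If the
#' EM degenerates, a median/MAD empirical null is used and flagged.
#'
#' @param t_stats Numeric vector of t statistics (a warning is issued below
#'   1000, where the mixture fit is poorly determined).
#' @param df Degrees of freedom of the t statistics.
#' @return A list of class \code{"inflation_fit"}: \code{null_mean},
#'   \code{null_sd}, \code{proportion_null}, \code{corrected_z},
#'   \code{p_corrected}, and \code{method} ("em" or "median_mad").
#' @export
bacon_correct <- function(t_stats, df) {
  if (length(t_stats) < 1000)
    warning("fewer than 1000 statistics; the empirical-null fit may be unstable")
  if (stats::sd(t_stats) == 0)
    stop("constant test statistics: the null mixture is degenerate")
  # probability-scale transform to z, numerically stable in the tails
  z <- ifelse(t_stats < 0,
              stats::qnorm(stats::pt(t_stats, df, log.p = TRUE), log.p = TRUE),
              -stats::qnorm(stats::pt(-t_stats, df, log.p = TRUE), log.p = TRUE))

  em <- fit_normal_mixture3(z)
  if (is.null(em)) {
    method <- "median_mad"
    null_mean <- stats::median(z)
    null_sd <- stats::mad(z)
    prop0 <- 1
  } else {
    method <- "em"
    null_mean <- em$mu[em$null]
    null_sd <- em$sd[em$null]
    prop0 <- em$p[em$null]
  }
  if (null_sd <= 0) stop("estimated null SD is not positive")
  cz <- (z - null_mean) / null_sd
  structure(list(null_mean = null_mean, null_sd = null_sd,
                 proportion_null = prop0, corrected_z = cz,
                 p_corrected = 2 * stats::pnorm(-abs(cz)),
                 method = method),
            class = "inflation_fit")
}

#' @export
print.inflation_fit <- function(x, ...) {
  cat(sprintf("Empirical null (%s): mean %.4f, sd %.4f, null proportion %.3f\n",
              x$method, x$null_mean, x$null_sd, x$proportion_null))
  invisible(x)
}

# Three-component normal mixture EM; returns NULL on degeneracy so the
# caller can fall back. The null is the dominant central component. For the
# mixture to be identifiable when most statistics are null, the effect
# components are constrained to be displaced (at least 1.5 null-SDs from
# the null mean) and over-dispersed (at least twice the null SD): without
# this, narrow tail components absorb the genuine tails of the null and
# the null SD is under-estimated on perfectly calibrated input.
fit_normal_mixture3 <- function(z, max_iter = 500, tol = 1e-8) {
  m <- stats::median(z)
  s <- stats::mad(z)
  if (s <= 0) return(NULL)
  mu <- c(m, m - 2.5 * s, m + 2.5 * s)
  sd <- c(s, 2 * s, 2 * s)
  p <- c(0.9, 0.05, 0.05)
  ll_old <- -Inf
  n <- length(z)
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(j) p[j] * stats::dnorm(z, mu[j], sd[j]),
                   numeric(n))
    tot <- rowSums(dens)
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {
      # a tail component emptied out: treat the data as pure null
      nk <- pmax(nk, 1e-8)
    }
    p <- nk / n
    mu <- colSums(resp * z) / nk
    sd <- sqrt(colSums(resp * (outer(z, mu, "-")^2)) / nk)
    sd <- pmax(sd, 1e-6)
    # identifiability: component 1 central, 2 left-displaced, 3
    # right-displaced, both wider than the null
    sd[2:3] <- pmax(sd[2:3], 2 * sd[1])
    mu[2] <- min(mu[2], mu[1] - 1.5 * sd[1])
    mu[3] <- max(mu[3], mu[1] + 1.5 * sd[1])
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (!is.finite(ll)) return(NULL)
  list(mu = mu, sd = sd, p = p, null = 1L, loglik = ll)
}

# ---------------------------------------------------------------------------

# Robust SE for MASS::rlm from the weighted information matrix:
# cov(b) = s^2 (X' W X)^{-1}, s the converged robust scale, W the final
# IRLS weights.
rlm_se <- function(fit, X) {
  XtWX <- crossprod(X * fit$w, X)
  sqrt(diag(fit$s^2 * solve(XtWX)))
}

#' Gestational-age EWAS at one timepoint
#'
#' Per CpG, a Huber M-estimator regression (\code{MASS::rlm}) of beta on
#' gestational age at birth, maternal age, and the first two compositional
#' cell-type PCs. t is the GA coefficient over its robust SE (weighted
#' information matrix), p from a t distribution with \code{n - p} df
#' (p = number of fitted coefficients), BH FDR over the probes tested, and
#' delta-beta = coefficient x (GA at the 95th minus GA at the 5th
#' percentile, linear-interpolation quantiles). A CpG is called significant
#' at FDR < \code{fdr_threshold} and |delta-beta| > \code{delta_threshold}.
#'
#' @param betas Beta matrix (probes x arrays), one timepoint.
#' @param sheet Sample sheet with \code{array_id}, \code{ga_weeks},
#'   \code{maternal_age} and \code{term}; non-term arrays are dropped with a
#'   message (the model is defined for term pregnancies).
#' @param pcs A \code{"composition_pcs"} for the same arrays, or a matrix
#'   of PC scores with array rownames.
#' @param fdr_threshold,delta_threshold Significance thresholds
#'   (defaults 0.1, 0.03).
#' @param quantiles GA quantile pair for the delta-beta range
#'   (default 0.05, 0.95).
#' @param k_huber Huber tuning constant (default 1.345).
#' @param max_iter IRLS iteration cap (default 50).
#' @param inflation_correct Recalibrate the t statistics against an
#'   empirical null (\code{\link{bacon_correct}}) before the FDR step.
#'   Residual cell-composition variation beyond the two PC covariates
#'   inflates test statistics genome-wide, so correction is the default
#'   whenever enough statistics are available to estimate the null
#'   (\code{NULL}, the default, enables it at 200+ probes); without it the
#'   FDR is not controlled on composition-driven probes. When disabled,
#'   \code{p_bacon} is \code{NA} and the FDR runs on the raw p-values.
#' @return An \code{"ewas_fit"} of subclass \code{"ga_ewas"} with a
#'   per-probe records table (and an \code{$inflation} fit when corrected).
#' @export
fit_ga_ewas <- function(betas, sheet, pcs,
                        fdr_threshold = 0.1, delta_threshold = 0.03,
                        quantiles = c(0.05, 0.95), k_huber = 1.345,
                        max_iter = 50, inflation_correct = NULL) {
  scores <- if (inherits(pcs, "composition_pcs")) pcs$pc_scores else as.matrix(pcs)
  idx <- match(colnames(betas), sheet$array_id)
  if (anyNA(idx)) stop("arrays missing from the sample sheet")
  meta <- sheet[idx, ]
  if (!all(meta$term)) {
    message("dropping ", sum(!meta$term), " non-term arrays from the GA EWAS")
    keep <- meta$term
    betas <- betas[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  ga <- meta$ga_weeks
  if (stats::sd(ga) == 0) stop("gestational age is constant; the model is undefined")
  sc <- scores[match(colnames(betas), rownames(scores)), 1:2, drop = FALSE]
  if (anyNA(sc)) stop("PC scores missing for some arrays")
  X <- cbind(intercept = 1, ga = ga, maternal_age = meta$maternal_age,
             PC1 = sc[, 1], PC2 = sc[, 2])
  n <- nrow(X)
  if (n <= ncol(X) + 1) stop("too few arrays for the number of covariates")
  ga_range <- diff(lin_quantile(ga, quantiles))
  df <- n - ncol(X)

  probes <- rownames(betas)
  coefs <- ses <- numeric(length(probes))
  for (i in seq_along(probes)) {
    fit <- MASS::rlm(X, betas[i, ], psi = MASS::psi.huber, k = k_huber,
                     maxit = max_iter)
    coefs[i] <- fit$coefficients["ga"]
    ses[i] <- rlm_se(fit, X)[2]
  }
  tstat <- coefs / ses
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  if (is.null(inflation_correct)) inflation_correct <- length(probes) >= 200
  if (inflation_correct) {
    infl <- bacon_correct(tstat, df = df)
    p_bacon <- infl$p_corrected
  } else {
    infl <- NULL
    p_bacon <- rep(NA_real_, length(probes))
  }
  fdr_q <- stats::p.adjust(if (inflation_correct) p_bacon else p_raw,
                           method = "BH")
  delta <- coefs * ga_range
  records <- data.frame(
    probe_id = probes, coefficient = coefs, std_error = ses,
    t_statistic = tstat, df = df, p_raw = p_raw, p_bacon = p_bacon,
    fdr_q = fdr_q, delta_beta = delta,
    significant = fdr_q < fdr_threshold & abs(delta) > delta_threshold,
    stringsAsFactors = FALSE
  )
  out <- new_ewas_fit(records,
                      model = "beta ~ gestational_age + maternal_age + PC1 + PC2",
                      n = n,
                      thresholds = c(fdr = fdr_threshold, delta = delta_threshold),
                      subclass = "ga_ewas")
  out$ga_range <- ga_range
  out$inflation <- infl
  out
}

#' Test discovery CpGs as candidates at the other timepoint
#'
#' Refits the GA model at the other timepoint restricted to the candidate
#' probes. Reports both the FDR call within the candidate set (same
#' thresholds as discovery) and a relaxed nominal p < \code{nominal_p} call.
#'
#' @param candidates Character vector of candidate probe ids (typically the
#'   significant probes of a discovery \code{"ga_ewas"}).
#' @param betas Beta matrix of the other timepoint.
#' @param sheet,pcs,... Passed to \code{\link{fit_ga_ewas}}.
#' @param nominal_p Relaxed nominal threshold (default 0.01).
#' @return A \code{"ga_ewas"} restricted to the candidates, whose records
#'   gain a \code{significant_nominal} column.
#' @export
test_candidates <- function(candidates, betas, sheet, pcs, nominal_p = 0.01, ...) {
  if (length(candidates) == 0) {
    out <- new_ewas_fit(records = data.frame(), model = "candidates", n = 0,
                        thresholds = c(fdr = 0.1, delta = 0.03),
                        subclass = "ga_ewas")
    return(out)
  }
  missing <- setdiff(candidates, rownames(betas))
  if (length(missing)) stop("candidate probes absent from the beta matrix: ",
                            paste(missing, collapse = ", "))
  out <- fit_ga_ewas(betas[candidates, , drop = FALSE], sheet, pcs, ...)
  out$records$significant_nominal <- out$records$p_raw < nominal_p &
    abs(out$records$delta_beta) > out$thresholds["delta"]
  out
}

#' Term versus preterm contrast at listed CpGs
#'
#' Per probe, a Welch two-sample t-test between the term and preterm
#' groups' beta values; delta-beta is the term-minus-preterm difference in
#' group means; BH FDR over the probe list.
#'
#' @param term_betas,preterm_betas Beta matrices (probes x arrays) for the
#'   two groups, restricted to the probes of interest (or superset).
#' @param probes Probe ids to test.
#' @return Data frame with \code{probe_id}, \code{mean_diff}, \code{p},
#'   \code{fdr_q} and a \code{flagged} column for degenerate probes
#'   (zero-variance group with n = 2, where p is undefined).
#' @export
preterm_contrast <- function(term_betas, preterm_betas, probes) {
  if (ncol(term_betas) < 2 || ncol(preterm_betas) < 2)
    stop("at least 2 samples per group are required")
  res <- lapply(probes, function(pb) {
    x <- term_betas[pb, ]
    y <- preterm_betas[pb, ]
    md <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (md == 0) return(data.frame(probe_id = pb, mean_diff = 0, p = 1,
                                     flagged = FALSE))
      return(data.frame(probe_id = pb, mean_diff = md, p = NA_real_,
                        flagged = TRUE))
    }
    tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    if (is.null(tt))
      return(data.frame(probe_id = pb, mean_diff = md, p = NA_real_,
                        flagged = TRUE))
    data.frame(probe_id = pb, mean_diff = md, p = tt$p.value, flagged = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
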