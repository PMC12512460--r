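# Reference-based leukocyte deconvolution, paired timepoint comparison of
# the estimated proportions, and compositional (ilr) principal components
# used as cell-composition covariates in the EWAS models.

# Constrained least squares: minimize ||y - A p||^2 subject to sum(p) = 1,
# p >= 0. Active-set method on the KKT system; at most 12 variables so the
# dense solves are trivial.
solve_mixture <- function(A, y, tol = 1e-10, max_iter = 200) {
  k <- ncol(A)
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  active <- rep(FALSE, k)          # clamped at zero
  for (iter in seq_len(max_iter)) {
    free <- which(!active)
    nf <- length(free)
    kkt <- rbind(cbind(2 * AtA[free, free, drop = FALSE], 1),
                 c(rep(1, nf), 0))
    rhs <- c(2 * Aty[free], 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) stop("deconvolution: singular KKT system; reference may be rank-deficient")
    p <- numeric(k)
    p[free] <- sol[seq_len(nf)]
    lambda <- sol[nf + 1L]
    if (any(p[free] < -tol)) {
      worst <- free[which.min(p[free])]
      active[worst] <- TRUE
      next
    }
    # dual feasibility: gradient of active (zero) coordinates must be >= 0
    grad <- 2 * (AtA %*% p - Aty) + lambda
    viol <- which(active & grad < -tol)
    if (length(viol)) {
      active[viol[which.min(grad[viol])]] <- FALSE
      next
    }
    p[p < 0] <- 0
    return(p / sum(p))
  }
  stop("deconvolution: active-set iteration did not converge")
}

#' Estimate leukocyte proportions by constrained projection
#'
#' Per array, finds the cell-type proportion vector minimizing the squared
#' error between observed betas and the reference-weighted mixture, subject
#' to non-negativity and sum-to-one (full-composition convention, so the
#' result feeds the ilr step directly).
#'
#' @param betas Beta matrix (probes x arrays).
#' @param reference A \code{"cell_reference"} (or list with
#'   \code{probe_ids}, \code{cell_types}, \code{betas}).
#' @param probes Optional probe subset for the fit; defaults to the
#'   reference's discriminating probes present in \code{betas}, else all
#'   shared probes.
#' @return A list of class \code{"proportion_table"}: \code{proportions}
#'   (arrays x 12 matrix, rows summing to 1) and \code{probes_used}.
#' @export
deconvolve <- function(betas, reference, probes = NULL) {
  if (is.null(probes)) {
    probes <- intersect(reference$discriminating %||% reference$probe_ids,
                        rownames(betas))
    if (length(probes) < length(reference$cell_types))
      probes <- intersect(reference$probe_ids, rownames(betas))
  }
  shared <- intersect(probes, intersect(reference$probe_ids, rownames(betas)))
  k <- length(reference$cell_types)
  if (length(shared) < k)
    stop("deconvolution requires at least ", k, " shared probes")
  A <- reference$betas[shared, , drop = FALSE]
  if (qr(A)$rank < k)
    stop("reference is rank-deficient on the shared probes (rank ",
         qr(A)$rank, " < ", k, "); deconvolution is not identifiable")
  Y <- betas[shared, , drop = FALSE]
  props <- t(apply(Y, 2, function(y) solve_mixture(A, y)))
  dimnames(props) <- list(colnames(betas), reference$cell_types)
  stopifnot(all(abs(rowSums(props) - 1) < 1e-6), all(props >= 0))
  structure(list(proportions = props, probes_used = shared),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, ...) {
  cat("Estimated cell proportions:", nrow(x$proportions), "arrays x",
      ncol(x$proportions), "cell types (",
      length(x$probes_used), "probes used )\n")
  print(round(colMeans(x$proportions), 4))
  invisible(x)
}

#' Paired comparison of cell proportions between timepoints
#'
#' Per cell type, a paired t-test on late-minus-early differences with
#' Bonferroni correction over the 12 cell types and a paired Cohen's d
#' (mean difference over the SD of differences, equivalently t / sqrt(n)).
#'
#' @param props A \code{"proportion_table"} covering both timepoints'
#'   arrays.
#' @param pairing A \code{"pairing_result"} (timepoint-1 array, timepoint-2
#'   array per pair), or a two-column data frame/matrix of array ids.
#' @return Data frame of class \code{"cell_shift_result"} with one row per
#'   cell type: \code{mean_diff}, \code{t_statistic}, \code{df},
#'   \code{p_raw}, \code{p_bonferroni}, \code{cohens_d}, \code{effect_class}.
#' @export
compare_timepoints <- function(props, pairing) {
  pr <- props$proportions
  if (inherits(pairing, "pairing_result")) pairing <- pairing$matched_pairs
  a1 <- as.character(pairing[[1]]); a2 <- as.character(pairing[[2]])
  if (length(a1) < 3) stop("at least 3 matched pairs are required")
  if (!all(c(a1, a2) %in% rownames(pr)))
    stop("pairing refers to arrays absent from the proportion table")
  diffs <- pr[a2, , drop = FALSE] - pr[a1, , drop = FALSE]
  n <- nrow(diffs)
  k <- ncol(diffs)
  res <- lapply(seq_len(k), function(j) {
    d <- diffs[, j]
    sdd <- stats::sd(d)
    if (sdd == 0) {
      if (mean(d) == 0) {
        return(data.frame(mean_diff = 0, t_statistic = 0, df = n - 1,
                          p_raw = 1, cohens_d = 0))
      }
      stop("zero variance of non-zero paired differences for ",
           colnames(diffs)[j], "; t statistic undefined")
    }
    tt <- stats::t.test(d)
    data.frame(mean_diff = mean(d), t_statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               cohens_d = mean(d) / sdd)
  })
  out <- do.call(rbind, res)
  out <- cbind(cell_type = colnames(diffs), out, stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, k * out$p_raw)
  out$effect_class <- effect_size_class(out$cohens_d)
  rownames(out) <- NULL
  class(out) <- c("cell_shift_result", "data.frame")
  out
}

#' Classify a Cohen's d effect size
#'
#' Conventional benchmarks: |d| below 0.2 is "negligible", 0.2-0.49
#' "small", 0.5-0.79 "medium", 0.8 and above "large".
#'
#' @param d Numeric vector of standardized effect sizes.
#' @return Character vector of labels.
#' @export
effect_size_class <- function(d) {
  a <- abs(d)
  ifelse(a >= 0.8, "large",
         ifelse(a >= 0.5, "medium",
                ifelse(a >= 0.2, "small", "negligible")))
}

#' Compositional principal components of cell proportions
#'
#' Replaces zeros by a small detection-limit value with multiplicative
#' renormalization, maps compositions to ilr coordinates on a fixed basis
#' (set by the cell-label order), and runs a robust PCA: coordinates are
#' centred on their medians (optionally an MCD covariance via
#' \code{MASS::cov.rob}) before the eigendecomposition.
#'
#' @param props A \code{"proportion_table"} or a plain arrays x parts
#'   matrix.
#' @param k Number of component scores to return (default 2; at most
#'   parts - 1).
#' @param robust Either \code{"median"} (median-centred classical PCA,
#'   default) or \code{"mcd"} (minimum covariance determinant).
#' @param zero_replace Detection-limit value substituted for zeros
#'   (default 1e-5).
#' @return A list of class \code{"composition_pcs"}: \code{ilr_coordinates}
#'   (arrays x parts-1), \code{pc_scores} (arrays x k),
#'   \code{variance_explained} (all parts-1 shares, non-increasing) and the
#'   \code{rotation}.
#' @export
ilr_pca <- function(props, k = 2, robust = c("median", "mcd"),
                    zero_replace = 1e-5) {
  robust <- match.arg(robust)
  pr <- if (inherits(props, "proportion_table")) props$proportions else as.matrix(props)
  d <- ncol(pr)
  if (k > d - 1) stop("k must be at most ", d - 1, " for a ", d, "-part composition")
  pr[pr < zero_replace] <- zero_replace
  pr <- sweep(pr, 1, rowSums(pr), "/")
  z <- ilr(pr)
  if (robust == "mcd" && nrow(z) > ncol(z) + 1) {
    rob <- MASS::cov.rob(z, method = "mcd")
    center <- rob$center
    covm <- rob$cov
  } else {
    center <- apply(z, 2, stats::median)
    zc <- sweep(z, 2, center)
    covm <- crossprod(zc) / (nrow(zc) - 1)
  }
  total <- sum(diag(covm))
  if (total < 1e-24) {
    warning("all compositions identical; returning zero scores")
    return(structure(list(
      ilr_coordinates = z,
      pc_scores = matrix(0, nrow(z), k,
                         dimnames = list(rownames(pr), paste0("PC", seq_len(k)))),
      variance_explained = rep(0, d - 1),
      rotation = diag(d - 1)[, seq_len(k), drop = FALSE]
    ), class = "composition_pcs"))
  }
  eg <- eigen(covm, symmetric = TRUE)
  scores <- sweep(z, 2, center) %*% eg$vectors[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(pr), paste0("PC", seq_len(k)))
  structure(list(
    ilr_coordinates = z,
    pc_scores = scores,
    variance_explained = pmax(eg$values, 0) / sum(pmax(eg$values, 0)),
    rotation = eg$vectors[, seq_len(k), drop = FALSE]
  ), class = "composition_pcs")
}

#' @export
print.composition_pcs <- function(x, ...) {
  ve <- x$variance_explained
  cat("Compositional PCA:", ncol(x$pc_scores), "scores returned;",
      "cumulative variance PC1-2:",
      sprintf("%.1f%%", 100 * sum(ve[1:min(2, length(ve))])), "\n")
  invisible(x)
}
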