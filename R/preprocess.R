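# Sample identity matching on SNP fingerprint probes, and the two-step
# probe variability filter applied to normalized beta values.

#' Match arrays across timepoints by SNP fingerprint correlation
#'
#' Arrays from the same woman share a genotype fingerprint, so their beta
#' values at SNP probes are near-perfectly correlated while unrelated pairs
#' are not. Pairs are formed greedily, highest Pearson correlation first,
#' and accepted only when the correlation reaches \code{threshold};
#' remaining arrays are reported unmatched. Exact ties are broken by
#' lexicographic array-id order and noted via a message.
#'
#' @param snp_t1,snp_t2 Beta matrices restricted to the same SNP probes, in
#'   the same probe order (timepoint 1 and 2 arrays in columns).
#' @param threshold Minimum Pearson correlation to accept a pair
#'   (default 0.90; genotype clusters at 0.05/0.5/0.95 put same-person
#'   correlations near 1 and unrelated near 0).
#' @return A list of class \code{"pairing_result"}: \code{matched_pairs}
#'   (data frame array_t1, array_t2, correlation), \code{unmatched}
#'   (character), and the full \code{correlation_matrix}.
#' @export
match_samples <- function(snp_t1, snp_t2, threshold = 0.90) {
  if (nrow(snp_t1) < 2 || nrow(snp_t2) < 2)
    stop("at least 2 SNP probes are required for a genetic fingerprint")
  if (!identical(rownames(snp_t1), rownames(snp_t2)))
    stop("SNP matrices must cover the same probes in the same order")
  cm <- stats::cor(snp_t1, snp_t2)
  avail1 <- colnames(snp_t1)
  avail2 <- colnames(snp_t2)
  pairs <- list()
  work <- cm
  while (length(avail1) && length(avail2)) {
    best <- max(work[avail1, avail2, drop = FALSE])
    if (!is.finite(best) || best < threshold) break
    hits <- which(work[avail1, avail2, drop = FALSE] == best, arr.ind = TRUE)
    if (nrow(hits) > 1) {
      o <- order(avail1[hits[, 1]], avail2[hits[, 2]])
      hits <- hits[o, , drop = FALSE]
      message("match_samples: tie at correlation ", signif(best, 6),
              "; broken by array-id order")
    }
    a1 <- avail1[hits[1, 1]]; a2 <- avail2[hits[1, 2]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      array_t1 = a1, array_t2 = a2, correlation = best,
      stringsAsFactors = FALSE)
    avail1 <- setdiff(avail1, a1)
    avail2 <- setdiff(avail2, a2)
  }
  matched <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(array_t1 = character(), array_t2 = character(),
               correlation = numeric(), stringsAsFactors = FALSE)
  structure(list(
    matched_pairs = matched,
    unmatched = c(avail1, avail2),
    correlation_matrix = cm
  ), class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat("Sample pairing:", nrow(x$matched_pairs), "matched pairs,",
      length(x$unmatched), "unmatched arrays\n")
  if (nrow(x$matched_pairs))
    cat("  correlation range:",
        paste(signif(range(x$matched_pairs$correlation), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Two-step probe variability filter
#'
#' Excludes probes previously reported as non-variable, then retains probes
#' whose interquantile range of beta values (hi_q minus lo_q quantile,
#' linear-interpolation quantiles) reaches \code{min_range}. SNP fingerprint
#' probes are always excluded from the analysis universe.
#'
#' @param betas Beta matrix (probes x arrays); typically arrays from both
#'   timepoints pooled, so one probe universe serves all models.
#' @param nonvariable_list Character vector of probes to drop a priori.
#' @param snp_probes Character vector of SNP-flagged probes (always dropped).
#' @param lo_q,hi_q Quantile pair (defaults 0.10 and 0.90).
#' @param min_range Minimum interquantile range on the beta scale
#'   (default 0.05).
#' @return Character vector of retained probe ids (in input order).
#' @export
variability_filter <- function(betas, nonvariable_list = character(),
                               snp_probes = character(),
                               lo_q = 0.10, hi_q = 0.90, min_range = 0.05) {
  stopifnot(lo_q >= 0, hi_q <= 1, lo_q < hi_q)
  if (nrow(betas) == 0 || ncol(betas) == 0) {
    warning("empty beta matrix; returning an empty probe set")
    return(character())
  }
  keep <- !(rownames(betas) %in% c(nonvariable_list, snp_probes))
  b <- betas[keep, , drop = FALSE]
  q <- t(apply(b, 1, lin_quantile, probs = c(lo_q, hi_q)))
  rownames(b)[(q[, 2] - q[, 1]) >= min_range]
}
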