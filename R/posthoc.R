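# Post-hoc characterization: modality-based mQTL flagging from the shape
# of a CpG's beta distribution, and chromatin-state overrepresentation of
# EWAS hits against the filtered probe universe.

#' Count modes of a beta distribution
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) evaluated
#' on [0, 1]; local maxima with height at least \code{min_height} of the
#' global maximum and pairwise separation at least \code{min_separation}
#' are counted as modes. Two or three well-separated modes typically betray
#' genotype control of the CpG (mQTL).
#'
#' @param beta_values Numeric vector in [0, 1] (at least 10 values).
#' @param min_separation Minimum distance between mode positions
#'   (default 0.1).
#' @param min_height Minimum relative peak height (default 0.05).
#' @return A list of class \code{"modality_call"}: \code{n_modes},
#'   \code{mode_positions}, \code{mqtl_candidate} (n_modes >= 2) and a
#'   \code{degenerate} flag for constant input.
#' @export
count_modes <- function(beta_values, min_separation = 0.1, min_height = 0.05) {
  if (length(beta_values) < 10) stop("at least 10 values are required")
  if (any(beta_values < 0 | beta_values > 1)) stop("beta values must lie in [0, 1]")
  if (stats::sd(beta_values) == 0) {
    return(structure(list(n_modes = 1L, mode_positions = beta_values[1],
                          mqtl_candidate = FALSE, degenerate = TRUE),
                     class = "modality_call"))
  }
  d <- stats::density(beta_values, bw = "nrd0", from = 0, to = 1, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  # boundary maxima count too
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  if (y[length(y)] > y[length(y) - 1]) peaks <- c(peaks, length(y))
  peaks <- peaks[y[peaks] >= min_height * max(y)]
  # greedy: keep highest peaks first, enforce pairwise separation
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  kept <- numeric(0)
  for (p in peaks) {
    if (!length(kept) || all(abs(d$x[p] - kept) >= min_separation))
      kept <- c(kept, d$x[p])
  }
  kept <- sort(kept)
  structure(list(n_modes = length(kept), mode_positions = kept,
                 mqtl_candidate = length(kept) >= 2, degenerate = FALSE),
            class = "modality_call")
}

#' @export
print.modality_call <- function(x, ...) {
  cat("Modality:", x$n_modes, "mode(s) at",
      paste(signif(x$mode_positions, 3), collapse = ", "),
      if (x$mqtl_candidate) "- mQTL candidate" else "", "\n")
  invisible(x)
}

#' Chromatin-state overrepresentation of EWAS hits
#'
#' Per state, a 2x2 table of hit / non-hit against in-state / out-of-state
#' probes (background = the filtered probe universe the hits were
#' discovered in), a two-sided Fisher exact test with conditional
#' odds-ratio estimate, and BH FDR across the states. States are declared
#' enriched at FDR < 0.1.
#'
#' @param hit_probes Character vector of hit probe ids (must be contained
#'   in the background).
#' @param background_probes Character vector of the probe universe.
#' @param state_labels Named character vector probe -> state (or a data
#'   frame with \code{probe_id} and \code{chrom_state}); unlabeled
#'   background probes become "unassigned".
#' @return Data frame with one row per state: counts, \code{odds_ratio},
#'   \code{p_fisher}, \code{fdr_q}, \code{enriched}.
#' @export
chromstate_enrichment <- function(hit_probes, background_probes, state_labels) {
  if (length(hit_probes) == 0) stop("no hit probes supplied")
  if (!all(hit_probes %in% background_probes))
    stop("hits must be a subset of the background universe")
  if (is.data.frame(state_labels)) {
    state_labels <- stats::setNames(
      state_labels[[setdiff(names(state_labels), "probe_id")[1]]],
      state_labels$probe_id)
  }
  st <- state_labels[background_probes]
  st[is.na(st)] <- "unassigned"
  names(st) <- background_probes
  is_hit <- background_probes %in% hit_probes
  states <- sort(unique(st))
  rows <- lapply(states, function(s) {
    in_state <- st == s
    a <- sum(is_hit & in_state)      # hits in state
    b <- sum(is_hit & !in_state)
    c_ <- sum(!is_hit & in_state)
    d <- sum(!is_hit & !in_state)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- (a * d) / (b * c_)          # cross-product (sample) odds ratio
    if (!is.finite(or)) or <- NA_real_
    data.frame(state = s, hits_in_state = a, hits_total = a + b,
               background_in_state = a + c_,
               background_total = length(background_probes),
               odds_ratio = or, p_fisher = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_fisher, method = "BH")
  out$enriched <- out$fdr_q < 0.1
  rownames(out) <- NULL
  out
}
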