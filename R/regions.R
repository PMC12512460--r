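# Co-methylated regions: chains of adjacent, correlated CpGs treated as
# one analytic unit, and their region-level gestational-age association.

#' Build co-methylated regions by correlation chaining
#'
#' Probes are sorted per chromosome by position; a probe joins the current
#' chain when its distance to the previous probe is at most \code{max_gap}
#' base pairs and the Spearman correlation of their beta values reaches
#' \code{min_corr}; otherwise the chain breaks. Singleton chains are
#' discarded. Regions partition the probes: no probe belongs to two
#' regions.
#'
#' @param betas Beta matrix (probes x arrays) on the filtered universe.
#' @param manifest Data frame with \code{probe_id}, \code{chrom},
#'   \code{pos} (1-based); probes missing positions are excluded with a
#'   warning.
#' @param max_gap Maximum distance between consecutive members in bp
#'   (default 1000).
#' @param min_corr Minimum Spearman correlation between consecutive members
#'   (default 0.3).
#' @return Data frame of class \code{"cmr_set"}: one row per region with
#'   \code{region_id}, \code{chrom}, \code{start}, \code{end} (1-based
#'   member positions), \code{n_probes}, \code{mean_pairwise_corr} and a
#'   list-column \code{members}.
#' @export
build_cmrs <- function(betas, manifest, max_gap = 1000, min_corr = 0.3) {
  m <- manifest[match(rownames(betas), manifest$probe_id), ]
  drop <- is.na(m$pos) | is.na(m$chrom)
  if (any(drop)) {
    warning(sum(drop), " probes missing positions; excluded from CMR construction")
    betas <- betas[!drop, , drop = FALSE]
    m <- m[!drop, ]
  }
  regions <- list()
  for (ch in unique(m$chrom)) {
    on_ch <- which(m$chrom == ch)
    on_ch <- on_ch[order(m$pos[on_ch])]
    if (length(on_ch) < 2) next
    chain <- on_ch[1]
    flush <- function(chain) {
      if (length(chain) >= 2) {
        member_ids <- m$probe_id[chain]
        cors <- stats::cor(t(betas[member_ids, , drop = FALSE]),
                           method = "spearman")
        regions[[length(regions) + 1L]] <<- data.frame(
          chrom = ch, start = min(m$pos[chain]), end = max(m$pos[chain]),
          n_probes = length(chain),
          mean_pairwise_corr = mean(cors[upper.tri(cors)]),
          members = I(list(member_ids)), stringsAsFactors = FALSE)
      }
    }
    for (i in on_ch[-1]) {
      prev <- chain[length(chain)]
      gap <- m$pos[i] - m$pos[prev]
      rho <- stats::cor(betas[m$probe_id[i], ], betas[m$probe_id[prev], ],
                        method = "spearman")
      if (gap <= max_gap && !is.na(rho) && rho >= min_corr) {
        chain <- c(chain, i)
      } else {
        flush(chain)
        chain <- i
      }
    }
    flush(chain)
  }
  if (!length(regions)) {
    out <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_probes = integer(),
                      mean_pairwise_corr = numeric(), stringsAsFactors = FALSE)
    out$members <- list()
  } else {
    out <- do.call(rbind, regions)
    out <- cbind(region_id = sprintf("CMR%05d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("cmr_set", "data.frame")
  out
}

#' Region-level gestational-age EWAS
#'
#' Summarizes each region as the unweighted mean beta of its member probes
#' per array and applies the single-CpG GA model
#' (\code{\link{fit_ga_ewas}}) to the summaries, with the same FDR and
#' delta-beta significance rule.
#'
#' @param cmrs A \code{"cmr_set"}.
#' @param betas Beta matrix covering the member probes.
#' @param sheet,pcs,... Passed to \code{\link{fit_ga_ewas}}.
#' @return A \code{"ga_ewas"} whose records are regions (probe_id holds the
#'   region_id).
#' @export
cmr_ewas <- function(cmrs, betas, sheet, pcs, ...) {
  if (nrow(cmrs) == 0) stop("no regions to test")
  summaries <- t(vapply(cmrs$members, function(ids) {
    colMeans(betas[ids, , drop = FALSE])
  }, numeric(ncol(betas))))
  rownames(summaries) <- cmrs$region_id
  fit_ga_ewas(summaries, sheet, pcs, ...)
}

#' Overlap two CMR sets by shared member probes
#'
#' Two regions overlap when they share at least one member probe.
#'
#' @param set_t1,set_t2 \code{"cmr_set"} data frames.
#' @return List with \code{shared} (data frame region_t1, region_t2),
#'   \code{unique_t1} and \code{unique_t2} (region ids with no partner).
#' @export
overlap_cmrs <- function(set_t1, set_t2) {
  map2 <- rep(set_t2$region_id, lengths(set_t2$members))
  probe2 <- unlist(set_t2$members)
  shared <- list()
  matched2 <- character()
  for (i in seq_len(nrow(set_t1))) {
    hits <- unique(map2[probe2 %in% set_t1$members[[i]]])
    for (h in hits) {
      shared[[length(shared) + 1L]] <- data.frame(
        region_t1 = set_t1$region_id[i], region_t2 = h,
        stringsAsFactors = FALSE)
    }
    matched2 <- c(matched2, hits)
  }
  shared_df <- if (length(shared)) do.call(rbind, shared) else
    data.frame(region_t1 = character(), region_t2 = character(),
               stringsAsFactors = FALSE)
  list(shared = shared_df,
       unique_t1 = setdiff(set_t1$region_id, shared_df$region_t1),
       unique_t2 = setdiff(set_t2$region_id, matched2))
}

#' Export CMRs as BED
#'
#' 0-based half-open spans from the first to the last member position.
#'
#' @param cmrs A \code{"cmr_set"}.
#' @param path Output BED file.
#' @export
write_cmr_bed <- function(cmrs, path) {
  bed <- data.frame(cmrs$chrom, cmrs$start - 1L, cmrs$end, cmrs$region_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
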