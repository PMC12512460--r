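# Plain-text readers/writers for the pipeline's artifact formats:
# beta matrices as TSV (probe rows, array columns), probe lists as
# one-per-line text, and BED export of probe positions.

#' Write a beta matrix as TSV
#'
#' Probe rows, array columns; first column \code{probe_id}. Values are
#' written at full precision so tables round-trip.
#'
#' @param betas Numeric matrix with probe rownames and array colnames.
#' @param path Output file.
#' @export
write_beta_tsv <- function(betas, path) {
  df <- data.frame(probe_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta matrix written by \code{write_beta_tsv}
#'
#' @param path TSV file with a \code{probe_id} column.
#' @return Numeric matrix, probes in rows.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stop("beta matrix must be finite and within [0, 1]")
  m
}

#' Read a one-probe-per-line list
#' @param path Text file, one probe id per line.
#' @return Character vector of probe ids.
#' @export
read_probe_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Write probes as a 1-bp BED track
#'
#' 0-based half-open convention: a probe at 1-based position p becomes the
#' interval [p-1, p).
#'
#' @param probes Probe ids to export.
#' @param manifest Data frame with \code{probe_id}, \code{chrom}, \code{pos}.
#' @param path Output BED file.
#' @export
write_probe_bed <- function(probes, manifest, path) {
  m <- manifest[match(probes, manifest$probe_id), ]
  if (anyNA(m$pos)) stop("probes missing from manifest: ",
                         paste(probes[is.na(m$pos)], collapse = ", "))
  bed <- data.frame(m$chrom, m$pos - 1L, m$pos, m$probe_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
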