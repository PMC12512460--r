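# End-to-end orchestration: simulate (optional) -> preprocess -> cell types
# -> EWAS (timepoint + both GA EWAS + candidates + preterm) -> scores ->
# regions -> post-hoc, writing every intermediate artifact, a JSON run
# summary and a log with versions, seed and config hash.

#' Assemble a pipeline configuration
#'
#' @param sim A \code{\link{sim_config}} (or list of its fields) describing
#'   the cohort to simulate; alternatively supply \code{inputs}, a list of
#'   paths (betas_early, betas_late, sample_sheet, manifest, il6_weights)
#'   to consume pre-existing artifacts.
#' @param inputs Optional list of artifact paths (see \code{sim}).
#' @param fdr_threshold,delta_beta_threshold EWAS significance thresholds
#'   (defaults 0.1 and 0.03).
#' @param delta_quantiles GA quantile pair for delta-beta (default
#'   0.05, 0.95).
#' @param filter Variability-filter settings: \code{lo_q}, \code{hi_q},
#'   \code{min_range}, \code{pool_timepoints}.
#' @param cmr CMR settings: \code{max_gap}, \code{min_corr}.
#' @param match_threshold SNP-fingerprint correlation threshold.
#' @param seed Integer seed forwarded to the simulation.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL,
                            fdr_threshold = 0.1, delta_beta_threshold = 0.03,
                            delta_quantiles = c(0.05, 0.95),
                            filter = list(lo_q = 0.10, hi_q = 0.90,
                                          min_range = 0.05,
                                          pool_timepoints = TRUE),
                            cmr = list(max_gap = 1000, min_corr = 0.3),
                            match_threshold = 0.90,
                            seed = 1) {
  if (is.list(delta_quantiles)) delta_quantiles <- unlist(delta_quantiles)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            delta_beta_threshold > 0, delta_beta_threshold < 1)
  if (is.null(sim) && is.null(inputs)) sim <- list()
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, utils::modifyList(sim, list(seed = seed)))
  cfg <- list(sim = sim, inputs = inputs, fdr_threshold = fdr_threshold,
              delta_beta_threshold = delta_beta_threshold,
              delta_quantiles = delta_quantiles, filter = filter, cmr = cmr,
              match_threshold = match_threshold, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror \code{\link{pipeline_config}}.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_error <- function(stage, e) {
  stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                 list(message = sprintf("[stage:%s] %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all artifacts beneath
#' \code{out}. Identical configuration and seed give byte-identical run
#' summaries. A stage failure aborts with an error condition of class
#' \code{"pipeline_stage_error"} naming the stage.
#'
#' @param config A \code{"pipeline_config"} or path to its YAML form.
#' @param out Output directory (created).
#' @return Invisibly, the run summary list; artifacts and
#'   \code{run_summary.json} are written to \code{out}.
#' @export
run_pipeline <- function(config, out) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("gestewas ", as.character(utils::packageVersion("gestewas")),
           " | R ", paste(R.version$major, R.version$minor, sep = "."))
  log_line("seed: ", config$seed)
  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), cfg_file)
  log_line("config md5: ", unname(tools::md5sum(cfg_file)))
  summary <- list(seed = config$seed)

  ## simulate -----------------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      for (f in unlist(inp)) if (!file.exists(f)) stop("missing input: ", f)
      list(betas_early = read_beta_tsv(inp$betas_early),
           betas_late = read_beta_tsv(inp$betas_late),
           sample_sheet = utils::read.csv(inp$sample_sheet, stringsAsFactors = FALSE),
           manifest = utils::read.delim(inp$manifest, stringsAsFactors = FALSE),
           il6_weights = utils::read.csv(inp$il6_weights, stringsAsFactors = FALSE),
           reference = NULL, truth = NULL)
    } else {
      co <- simulate_cohort(config$sim)
      write_cohort(co, file.path(out, "simulated"))
      co
    }
  }, error = function(e) stage_error("simulate", e))
  log_line("simulate: ", ncol(cohort$betas_early), " arrays/timepoint x ",
           nrow(cohort$betas_early), " probes")

  ## preprocess ----------------------------------------------------------------
  pp <- tryCatch({
    snp <- cohort$manifest$probe_id[cohort$manifest$snp_probe]
    pairing <- match_samples(cohort$betas_early[snp, , drop = FALSE],
                             cohort$betas_late[snp, , drop = FALSE],
                             threshold = config$match_threshold)
    pooled <- if (isTRUE(config$filter$pool_timepoints))
      cbind(cohort$betas_early, cohort$betas_late) else cohort$betas_early
    kept <- variability_filter(pooled, snp_probes = snp,
                               lo_q = config$filter$lo_q,
                               hi_q = config$filter$hi_q,
                               min_range = config$filter$min_range)
    writeLines(kept, file.path(out, "kept_probes.txt"))
    utils::write.csv(pairing$matched_pairs, file.path(out, "pairing.csv"),
                     row.names = FALSE)
    list(pairing = pairing, kept = kept, snp = snp)
  }, error = function(e) stage_error("preprocess", e))
  log_line("preprocess: ", length(pp$kept), " probes retained; ",
           nrow(pp$pairing$matched_pairs), " pairs matched")
  summary$n_probes_retained <- length(pp$kept)
  summary$n_pairs_matched <- nrow(pp$pairing$matched_pairs)

  ## celltypes ------------------------------------------------------------------
  ct <- tryCatch({
    if (is.null(cohort$reference)) stop("no cell-type reference available")
    props_e <- deconvolve(cohort$betas_early, cohort$reference)
    props_l <- deconvolve(cohort$betas_late, cohort$reference)
    props_all <- structure(list(
      proportions = rbind(props_e$proportions, props_l$proportions),
      probes_used = props_e$probes_used), class = "proportion_table")
    shifts <- compare_timepoints(props_all, pp$pairing)
    pcs_e <- ilr_pca(props_e)
    pcs_l <- ilr_pca(props_l)
    utils::write.csv(data.frame(array_id = rownames(props_all$proportions),
                                props_all$proportions),
                     file.path(out, "cell_proportions.csv"), row.names = FALSE)
    utils::write.csv(shifts, file.path(out, "cell_shifts.csv"), row.names = FALSE)
    list(props_e = props_e, props_l = props_l, shifts = shifts,
         pcs_e = pcs_e, pcs_l = pcs_l)
  }, error = function(e) stage_error("celltypes", e))
  summary$n_cell_shifts_significant <- sum(ct$shifts$p_bonferroni < 0.05)

  ## ewas ------------------------------------------------------------------------
  sheet <- cohort$sample_sheet
  ew <- tryCatch({
    pairs <- pp$pairing$matched_pairs
    term_of <- sheet$term[match(pairs$array_t1, sheet$array_id)]
    tp_pairs <- pairs[term_of, ]
    kept_e <- cohort$betas_early[pp$kept, tp_pairs$array_t1, drop = FALSE]
    kept_l <- cohort$betas_late[pp$kept, tp_pairs$array_t2, drop = FALSE]
    five <- c("Bmem", "CD4mem", "CD8mem", "Neu", "NK")
    diffs <- ct$props_l$proportions[tp_pairs$array_t2, five] -
      ct$props_e$proportions[tp_pairs$array_t1, five]
    tp_fit <- fit_timepoint_model(kept_e, kept_l, sheet, diffs,
                                  fdr_threshold = config$fdr_threshold,
                                  delta_threshold = config$delta_beta_threshold)

    term_arrays_e <- sheet$array_id[sheet$timepoint == "early" & sheet$term]
    term_arrays_l <- sheet$array_id[sheet$timepoint == "late" & sheet$term]
    ga_e <- fit_ga_ewas(cohort$betas_early[pp$kept, term_arrays_e, drop = FALSE],
                        sheet, ct$pcs_e,
                        fdr_threshold = config$fdr_threshold,
                        delta_threshold = config$delta_beta_threshold,
                        quantiles = config$delta_quantiles)
    ga_l <- fit_ga_ewas(cohort$betas_late[pp$kept, term_arrays_l, drop = FALSE],
                        sheet, ct$pcs_l,
                        fdr_threshold = config$fdr_threshold,
                        delta_threshold = config$delta_beta_threshold,
                        quantiles = config$delta_quantiles)
    sig_e <- ga_e$records$probe_id[ga_e$records$significant]
    sig_l <- ga_l$records$probe_id[ga_l$records$significant]
    cand_l <- test_candidates(sig_e, cohort$betas_late[, term_arrays_l, drop = FALSE],
                              sheet, ct$pcs_l)
    cand_e <- test_candidates(sig_l, cohort$betas_early[, term_arrays_e, drop = FALSE],
                              sheet, ct$pcs_e)
    pre <- NULL
    pre_arrays <- sheet$array_id[sheet$timepoint == "early" & !sheet$term]
    if (length(pre_arrays) >= 2 && length(sig_e)) {
      pre <- preterm_contrast(cohort$betas_early[, term_arrays_e, drop = FALSE],
                              cohort$betas_early[, pre_arrays, drop = FALSE],
                              sig_e)
      utils::write.csv(pre, file.path(out, "preterm_contrast.csv"),
                       row.names = FALSE)
    }
    write_ewas_tsv(tp_fit, file.path(out, "ewas_timepoint.tsv"))
    write_ewas_tsv(ga_e, file.path(out, "ewas_ga_early.tsv"))
    write_ewas_tsv(ga_l, file.path(out, "ewas_ga_late.tsv"))
    if (length(sig_e))
      write_probe_bed(sig_e, cohort$manifest,
                      file.path(out, "significant_early.bed"))
    list(tp = tp_fit, ga_e = ga_e, ga_l = ga_l, sig_e = sig_e, sig_l = sig_l,
         cand_e = cand_e, cand_l = cand_l, pre = pre)
  }, error = function(e) stage_error("ewas", e))
  summary$n_timepoint_cpgs_significant <- sum(ew$tp$records$significant)
  summary$n_ga_cpgs_early <- length(ew$sig_e)
  summary$n_ga_cpgs_late <- length(ew$sig_l)

  ## scores -----------------------------------------------------------------------
  scs <- tryCatch({
    early_rows <- sheet[sheet$timepoint == "early", ]
    al <- allostatic_load(early_rows)
    il6_e <- il6_score(cohort$betas_early, cohort$il6_weights)
    il6_l <- il6_score(cohort$betas_late, cohort$il6_weights)
    utils::write.csv(data.frame(woman_id = names(al), allostatic_load = al,
                                row.names = NULL),
                     file.path(out, "allostatic_load.csv"), row.names = FALSE)
    contrib <- NULL
    if (length(ew$sig_e)) {
      term_e <- sheet$array_id[sheet$timepoint == "early" & sheet$term]
      vars <- list(
        ses_z = stats::setNames(early_rows$ses_z, early_rows$array_id),
        anxiety_z = stats::setNames(early_rows$anxiety_z, early_rows$array_id),
        depression_z = stats::setNames(early_rows$depression_z, early_rows$array_id),
        allostatic_load = stats::setNames(al[early_rows$woman_id], early_rows$array_id),
        il6_score = il6_e[early_rows$array_id])
      contrib <- contribution_analysis(
        cohort$betas_early[, term_e, drop = FALSE], sheet, ct$pcs_e,
        ew$sig_e, vars, fdr_threshold = config$fdr_threshold)
      utils::write.csv(contrib, file.path(out, "contributions.csv"),
                       row.names = FALSE)
    }
    list(al = al, il6_e = il6_e, il6_l = il6_l, contrib = contrib)
  }, error = function(e) stage_error("scores", e))
  summary$n_contributions_reported <-
    if (is.null(scs$contrib)) 0L else sum(scs$contrib$reported)

  ## regions ----------------------------------------------------------------------
  rg <- tryCatch({
    term_e <- sheet$array_id[sheet$timepoint == "early" & sheet$term]
    term_l <- sheet$array_id[sheet$timepoint == "late" & sheet$term]
    cmr_e <- build_cmrs(cohort$betas_early[pp$kept, term_e, drop = FALSE],
                        cohort$manifest,
                        max_gap = config$cmr$max_gap,
                        min_corr = config$cmr$min_corr)
    cmr_l <- build_cmrs(cohort$betas_late[pp$kept, term_l, drop = FALSE],
                        cohort$manifest,
                        max_gap = config$cmr$max_gap,
                        min_corr = config$cmr$min_corr)
    ov <- overlap_cmrs(cmr_e, cmr_l)
    hit_cmrs <- cmr_e[vapply(cmr_e$members,
                             function(mm) any(mm %in% ew$sig_e), logical(1)), ]
    cmr_fit <- NULL
    if (nrow(hit_cmrs))
      cmr_fit <- cmr_ewas(hit_cmrs, cohort$betas_early[, term_e, drop = FALSE],
                          sheet, ct$pcs_e,
                          fdr_threshold = config$fdr_threshold,
                          delta_threshold = config$delta_beta_threshold,
                          quantiles = config$delta_quantiles)
    if (nrow(cmr_e)) write_cmr_bed(cmr_e, file.path(out, "cmrs_early.bed"))
    list(cmr_e = cmr_e, cmr_l = cmr_l, overlap = ov, cmr_fit = cmr_fit)
  }, error = function(e) stage_error("regions", e))
  summary$n_cmrs_early <- nrow(rg$cmr_e)
  summary$n_cmrs_late <- nrow(rg$cmr_l)
  summary$n_cmrs_shared <- nrow(rg$overlap$shared)
  summary$n_cmrs_significant <-
    if (is.null(rg$cmr_fit)) 0L else sum(rg$cmr_fit$records$significant)

  ## posthoc ----------------------------------------------------------------------
  ph <- tryCatch({
    mq <- 0L
    enr <- NULL
    if (length(ew$sig_e)) {
      term_e <- sheet$array_id[sheet$timepoint == "early" & sheet$term]
      calls <- lapply(ew$sig_e, function(pb)
        count_modes(cohort$betas_early[pb, term_e]))
      mq <- sum(vapply(calls, function(x) x$mqtl_candidate, logical(1)))
      enr <- chromstate_enrichment(ew$sig_e, pp$kept,
                                   stats::setNames(cohort$manifest$chrom_state,
                                                   cohort$manifest$probe_id))
      utils::write.csv(enr, file.path(out, "chromstate_enrichment.csv"),
                       row.names = FALSE)
    }
    list(n_mqtl = mq, enr = enr)
  }, error = function(e) stage_error("posthoc", e))
  summary$n_mqtl_candidates <- ph$n_mqtl
  summary$n_states_enriched <- if (is.null(ph$enr)) 0L else sum(ph$enr$enriched)

  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("done")
  invisible(summary)
}
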