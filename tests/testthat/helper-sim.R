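# Shared fixtures, computed once per test run and memoized so the simulated
# cohort and its deconvolution are reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small but fully featured cohort: all planted effects present, 5
# co-methylated blocks, fixed seed.
small_cfg <- function(...) sim_config(n_probes = 1200, n_regions = 5, seed = 7, ...)

shared_cohort <- function() fixture("cohort", function() simulate_cohort(small_cfg()))

early_arrays <- function(co = shared_cohort())
  co$sample_sheet$array_id[co$sample_sheet$timepoint == "early"]
late_arrays <- function(co = shared_cohort())
  co$sample_sheet$array_id[co$sample_sheet$timepoint == "late"]

shared_props <- function() fixture("props", function() {
  co <- shared_cohort()
  list(early = deconvolve(co$betas_early, co$reference),
       late = deconvolve(co$betas_late, co$reference))
})

shared_pcs <- function() fixture("pcs", function() {
  pr <- shared_props()
  list(early = ilr_pca(pr$early), late = ilr_pca(pr$late))
})

# Women x 5 late-minus-early estimated memory/Neu/NK differences, in the
# woman order of the early arrays.
shared_cell_diffs <- function() fixture("cell_diffs", function() {
  co <- shared_cohort()
  pr <- shared_props()
  five <- c("Bmem", "CD4mem", "CD8mem", "Neu", "NK")
  ea <- early_arrays(co)
  la <- sub("_T1$", "_T2", ea)
  pr$late$proportions[la, five] - pr$early$proportions[ea, five]
})

term_early_arrays <- function(co = shared_cohort())
  co$sample_sheet$array_id[co$sample_sheet$timepoint == "early" & co$sample_sheet$term]
term_late_arrays <- function(co = shared_cohort())
  co$sample_sheet$array_id[co$sample_sheet$timepoint == "late" & co$sample_sheet$term]

# Cohort at the all-default configuration (used by the acceptance suite).
default_cohort <- function() fixture("default_cohort", function()
  simulate_cohort(sim_config()))

# GA EWAS on the full small cohort (early timepoint, term women).
shared_ga_fit <- function() fixture("ga_fit", function() {
  co <- shared_cohort()
  suppressWarnings(suppressMessages(
    fit_ga_ewas(co$betas_early[, term_early_arrays(co)], co$sample_sheet,
                shared_pcs()$early)))
})
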