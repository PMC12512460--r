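# Generator: configuration validation, determinism, planted structure.

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_probes = 10))                  # fewer than SNP probes
  expect_error(sim_config(preterm_fraction = 1.5))
  expect_error(sim_config(noise_sd = -0.1))
  expect_error(sim_config(timepoint_shift = c(Neu = 0.06)))  # must cover 12 cells
})

test_that("defaults encode the study design", {
  cfg <- sim_config()
  expect_equal(cfg$n_women, 26)
  expect_equal(round(cfg$n_women * (1 - cfg$preterm_fraction)), 22)
  expect_equal(cfg$n_snp_probes, 59)
  expect_equal(cfg$n_ga_cpgs_early, 37)
  expect_equal(cfg$n_ga_cpgs_late, 4)
  expect_equal(cfg$n_timepoint_cpgs, 21)
  expect_equal(cfg$ga_range, c(37, 40.5))
  expect_equal(cfg$preterm_ga_range, c(32, 36.9))
  expect_equal(cfg$maternal_age_mean, 26.09)
  expect_equal(cfg$maternal_age_sd, 4.05)
  expect_length(blood_cell_types(), 12)
  expect_equal(sum(cfg$timepoint_shift), 0, tolerance = 1e-12)
  expect_gt(cfg$timepoint_shift["Neu"], 0)
  expect_lt(cfg$timepoint_shift["CD4mem"], 0)
})

test_that("the same seed reproduces the cohort and different seeds differ", {
  cfg <- small_cfg()
  co1 <- shared_cohort()
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$betas_early, co2$betas_early)
  expect_identical(co1$sample_sheet, co2$sample_sheet)
  co3 <- simulate_cohort(sim_config(n_probes = 1200, n_regions = 5, seed = 8))
  expect_false(identical(co1$betas_early, co3$betas_early))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(seed_streams(123, 5))
  expect_identical(before, .Random.seed)
})

test_that("betas have the right shape and range", {
  co <- shared_cohort()
  expect_equal(dim(co$betas_early), c(1200, 26))
  expect_equal(dim(co$betas_late), c(1200, 26))
  expect_true(all(co$betas_early >= 0 & co$betas_early <= 1))
  expect_true(all(co$betas_late >= 0 & co$betas_late <= 1))
  expect_identical(rownames(co$betas_early), rownames(co$betas_late))
})

test_that("the sample sheet reflects the cohort design", {
  co <- shared_cohort()
  sheet <- co$sample_sheet
  expect_equal(nrow(sheet), 52)
  expect_equal(sum(sheet$timepoint == "early"), 26)
  per_woman <- sheet[sheet$timepoint == "early", ]
  expect_equal(sum(per_woman$term), 22)
  expect_true(all(per_woman$ga_weeks[per_woman$term] >= 37 &
                    per_woman$ga_weeks[per_woman$term] <= 40.5))
  expect_true(all(per_woman$ga_weeks[!per_woman$term] >= 32 &
                    per_woman$ga_weeks[!per_woman$term] <= 36.9))
  expect_true(all(c("maternal_age", "ses_z", "anxiety_z", "depression_z",
                    "cortisol", "hba1c", "crp", "cholesterol", "sbp", "dbp",
                    "cortisol_draw_min", "gest_week_at_draw") %in% names(sheet)))
})

test_that("planted probe roles are disjoint and sized as configured", {
  co <- shared_cohort()
  tr <- co$truth
  ga <- tr$ga_effect_probes
  expect_equal(sum(ga$timepoint == "early"), 37)
  expect_equal(sum(ga$timepoint == "late"), 4)
  expect_equal(nrow(tr$timepoint_effect_probes), 21)
  expect_length(tr$snp_probes, 59)
  roles <- list(ga$probe_id, tr$timepoint_effect_probes$probe_id,
                tr$mediated_probes$probe_id, tr$snp_probes, tr$il6_probes,
                unlist(tr$region_members))
  all_ids <- unlist(roles)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(all(all_ids %in% rownames(co$betas_early)))
})

test_that("true compositions are on the simplex", {
  tp <- shared_cohort()$truth$true_proportions
  expect_equal(dim(tp), c(52, 12))
  expect_equal(unname(rowSums(tp)), rep(1, 52), tolerance = 1e-9)
  expect_true(all(tp > 0))
  # neutrophils dominate, as in whole blood
  expect_true(all(colMeans(tp)["Neu"] > colMeans(tp)[colnames(tp) != "Neu"]))
})

test_that("SNP fingerprint probes cluster at genotype levels", {
  co <- shared_cohort()
  snp <- co$betas_early[co$truth$snp_probes, ]
  dist_to_cluster <- pmin(abs(snp - 0.05), abs(snp - 0.5), abs(snp - 0.95))
  expect_lt(stats::quantile(dist_to_cluster, 0.99), 0.1)
  expect_true(all(co$manifest$snp_probe[match(co$truth$snp_probes,
                                              co$manifest$probe_id)]))
})

test_that("planted timepoint effects appear in the raw data", {
  co <- shared_cohort()
  tp <- co$truth$timepoint_effect_probes$probe_id
  d <- rowMeans(co$betas_late[tp, ]) - rowMeans(co$betas_early[tp, ])
  # the raw marginal difference carries a small composition-mediated drift
  # on top of the planted delta, so compare on an absolute scale
  expect_lt(abs(mean(d) + 0.05), 0.005)
})

test_that("planted GA slopes leave a marginal trace of the right sign", {
  co <- shared_cohort()
  sheet <- co$sample_sheet
  ea <- term_early_arrays(co)
  ga <- sheet$ga_weeks[match(ea, sheet$array_id)]
  pl <- co$truth$ga_effect_probes[co$truth$ga_effect_probes$timepoint == "early", ]
  slopes <- apply(co$betas_early[pl$probe_id, ea], 1,
                  function(y) stats::coef(stats::lm(y ~ ga))[2])
  expect_gt(mean(sign(slopes) == sign(pl$slope)), 0.9)
})

test_that("co-methylated blocks are adjacent and correlated", {
  co <- shared_cohort()
  man <- co$manifest
  for (members in co$truth$region_members) {
    rows <- match(members, man$probe_id)
    expect_equal(length(unique(man$chrom[rows])), 1L)
    gaps <- diff(sort(man$pos[rows]))
    expect_true(all(gaps <= 1000))
    cors <- stats::cor(t(co$betas_early[members, ]), method = "spearman")
    expect_gt(min(cors[upper.tri(cors)]), 0.3)
  }
})

test_that("manifest spacing outside blocks never chains by distance", {
  co <- shared_cohort()
  man <- co$manifest
  in_block <- man$probe_id %in% unlist(co$truth$region_members)
  for (ch in unique(man$chrom)) {
    rows <- which(man$chrom == ch)
    rows <- rows[order(man$pos[rows])]
    gaps <- diff(man$pos[rows])
    pairs_in_block <- in_block[rows][-1] & in_block[rows][-length(rows)]
    expect_true(all(gaps[!pairs_in_block] > 1000))
  }
})

test_that("cohort artifacts round-trip through disk", {
  co <- shared_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_beta_tsv(paths$betas_early)
  expect_equal(back, co$betas_early, tolerance = 1e-12)
  sheet <- utils::read.csv(paths$sample_sheet, stringsAsFactors = FALSE)
  expect_equal(sheet$array_id, co$sample_sheet$array_id)
})

test_that("YAML configuration round-trips", {
  cfg <- small_cfg()
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(rapply(unclass(cfg), unclass, how = "replace")), f)
  cfg2 <- read_sim_config(f)
  expect_s3_class(cfg2, "sim_config")
  expect_equal(cfg2$n_probes, cfg$n_probes)
  expect_equal(cfg2$timepoint_shift, cfg$timepoint_shift)
})

test_that("beta TSV reader rejects out-of-range values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(0.5, 1.2), 1, 2, dimnames = list("cg1", c("a", "b")))
  utils::write.table(m, f, sep = "\t", quote = FALSE)
  expect_error(read_beta_tsv(f), "\\[0, 1\\]|range|beta")
})
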