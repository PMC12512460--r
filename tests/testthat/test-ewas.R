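# Per-CpG models: the GA EWAS, the random-intercept timepoint model, the
# empirical-null recalibration and the term/preterm contrast.

test_that("fit_ga_ewas recovers planted gestational-age effects", {
  co <- shared_cohort()
  fit <- shared_ga_fit()
  expect_s3_class(fit, "ga_ewas")
  expect_s3_class(fit, "ewas_fit")
  expect_equal(fit$n, 22)
  rec <- fit$records
  expect_equal(unique(rec$df), 22 - 5)   # intercept, GA, age, PC1, PC2
  planted <- co$truth$ga_effect_probes
  planted <- planted[planted$timepoint == "early", ]
  rows <- match(planted$probe_id, rec$probe_id)
  expect_gt(mean(rec$significant[rows]), 0.9)
  # signed slope estimates track the planted value without gross bias
  est <- rec$coefficient[rows] * sign(planted$slope)
  expect_lt(abs(mean(est) - 0.02), 0.005)
})

test_that("delta-beta is the slope times the GA interquantile range", {
  co <- shared_cohort()
  fit <- shared_ga_fit()
  sheet <- co$sample_sheet
  ga <- sheet$ga_weeks[match(term_early_arrays(co), sheet$array_id)]
  span <- diff(stats::quantile(ga, c(0.05, 0.95), type = 7, names = FALSE))
  expect_equal(fit$records$delta_beta, fit$records$coefficient * span,
               tolerance = 1e-12)
})

test_that("significance needs both FDR < 0.1 and |delta-beta| > 0.03", {
  rec <- shared_ga_fit()$records
  expect_identical(rec$significant,
                   rec$fdr_q < 0.1 & abs(rec$delta_beta) > 0.03)
})

test_that("non-term arrays are dropped with a message", {
  co <- shared_cohort()
  all_early <- early_arrays(co)
  sub <- co$betas_early[1:50, all_early]
  expect_message(
    fit <- suppressWarnings(fit_ga_ewas(sub, co$sample_sheet, shared_pcs()$early)),
    "term")
  expect_equal(fit$n, 22)
})

test_that("Huber regression tends to OLS as the tuning constant grows", {
  co <- shared_cohort()
  sheet <- co$sample_sheet
  ea <- term_early_arrays(co)
  pcs <- shared_pcs()$early
  sub <- co$betas_early[1:30, ea]
  fit_huge <- suppressWarnings(fit_ga_ewas(sub, sheet, pcs, k_huber = 1e6))
  sc <- pcs$pc_scores[ea, ]
  meta <- sheet[match(ea, sheet$array_id), ]
  ols <- apply(sub, 1, function(y)
    stats::coef(stats::lm(y ~ meta$ga_weeks + meta$maternal_age +
                            sc[, 1] + sc[, 2]))[2])
  expect_equal(unname(fit_huge$records$coefficient), unname(ols),
               tolerance = 1e-6)
})

test_that("the timepoint model recovers planted deltas", {
  co <- shared_cohort()
  tp <- co$truth$timepoint_effect_probes$probe_id
  set.seed(31)
  nulls <- sample(setdiff(rownames(co$betas_early),
                          unlist(lapply(co$truth, function(x)
                            if (is.data.frame(x)) x$probe_id else x))), 80)
  sel <- c(tp, nulls)
  fit <- suppressWarnings(fit_timepoint_model(
    co$betas_early[sel, early_arrays(co)],
    co$betas_late[sel, late_arrays(co)],
    co$sample_sheet, shared_cell_diffs()))
  expect_s3_class(fit, "timepoint_ewas")
  rec <- fit$records
  expect_equal(unique(rec$df), 26 - 1)
  rows <- match(tp, rec$probe_id)
  expect_lt(abs(mean(rec$delta_beta[rows]) + 0.05), 0.01)
  expect_gt(mean(rec$significant[rows]), 0.8)
  # delta-beta is the observed mean late-minus-early difference
  manual <- rowMeans(co$betas_late[sel, late_arrays(co)]) -
    rowMeans(co$betas_early[sel, early_arrays(co)])
  expect_equal(rec$delta_beta, unname(manual), tolerance = 1e-12)
  expect_s3_class(fit$inflation, "inflation_fit")
})

test_that("the timepoint model validates its inputs", {
  co <- shared_cohort()
  e <- co$betas_early[1:5, early_arrays(co)]
  l <- co$betas_late[6:10, late_arrays(co)]
  expect_error(suppressWarnings(
    fit_timepoint_model(e, l, co$sample_sheet, shared_cell_diffs())),
    "same probes")
  l2 <- co$betas_late[1:5, late_arrays(co)[1:10]]
  expect_error(suppressWarnings(
    fit_timepoint_model(e, l2, co$sample_sheet, shared_cell_diffs())),
    "matched pairs")
})

test_that("random-intercept GLS at lambda 0 matches weighted least squares", {
  set.seed(41)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(0.5, 0.2, -0.1)) + rnorm(n, 0, 0.05)
  w <- runif(n, 0.5, 1.5)
  g <- gestewas:::reml_gls(y, X, group = rep(1:15, 2), w = w, lambda = 0)
  wls <- stats::lm.wfit(X, y, w)
  expect_equal(g$coef, unname(wls$coefficients), tolerance = 1e-9)
})

test_that("a strong woman effect yields a large variance ratio", {
  set.seed(43)
  n <- 26
  u <- rnorm(n, 0, 0.2)
  X <- cbind(1, rep(c(0, 1), each = n))
  y <- 0.5 + rep(u, 2) + rnorm(2 * n, 0, 0.01)
  fit <- gestewas:::fit_rlmm_probe(y, X, group = rep(1:n, 2))
  expect_gt(fit$lambda, 10)
  y2 <- 0.5 + rnorm(2 * n, 0, 0.05)
  fit2 <- gestewas:::fit_rlmm_probe(y2, X, group = rep(1:n, 2))
  expect_lt(fit2$lambda, 1)
})

test_that("bacon recalibration recovers a clean null", {
  set.seed(47)
  t0 <- stats::rt(20000, df = 25)
  suppressWarnings(b <- bacon_correct(t0, df = 25))
  expect_s3_class(b, "inflation_fit")
  expect_equal(b$null_mean, 0, tolerance = 0.03)
  expect_equal(b$null_sd, 1, tolerance = 0.03)
  expect_gt(b$proportion_null, 0.9)
})

test_that("bacon undoes scale inflation and location bias", {
  set.seed(53)
  z <- rnorm(20000, 0.5, 1.6)
  t_inflated <- stats::qt(stats::pnorm(z), df = 40)   # t stats with that z law
  suppressWarnings(b <- bacon_correct(t_inflated, df = 40))
  expect_equal(b$null_mean, 0.5, tolerance = 0.1)
  expect_equal(b$null_sd, 1.6, tolerance = 0.1)
  # corrected statistics are calibrated: roughly uniform p-values
  expect_lt(abs(mean(b$p_corrected < 0.05) - 0.05), 0.02)
})

test_that("bacon guards degenerate input and warns when underpowered", {
  expect_error(suppressWarnings(bacon_correct(rep(1.3, 50), df = 10)),
               "constant|variance")
  expect_warning(bacon_correct(rnorm(100), df = 10), "1000|few")
})

test_that("candidate testing reports nominal significance at the other timepoint", {
  co <- shared_cohort()
  fit <- shared_ga_fit()
  sig <- fit$records$probe_id[fit$records$significant][1:10]
  res <- suppressWarnings(test_candidates(
    sig, co$betas_late[, term_late_arrays(co)], co$sample_sheet,
    shared_pcs()$late))
  rec <- res$records
  expect_setequal(rec$probe_id, sig)
  expect_identical(unname(rec$significant_nominal),
                   rec$p_raw < 0.01 & abs(rec$delta_beta) > 0.03)
  expect_error(suppressWarnings(test_candidates(
    "not_a_probe", co$betas_late[, term_late_arrays(co)], co$sample_sheet,
    shared_pcs()$late)))
})

test_that("the preterm contrast flags planted differences and degenerate rows", {
  set.seed(59)
  term_b <- matrix(runif(20 * 22, 0.4, 0.6), 20, 22,
                   dimnames = list(sprintf("cg%02d", 1:20), paste0("t", 1:22)))
  pre_b <- matrix(runif(20 * 4, 0.4, 0.6), 20, 4,
                  dimnames = list(sprintf("cg%02d", 1:20), paste0("p", 1:4)))
  pre_b[1:3, ] <- pre_b[1:3, ] + 0.3
  res <- preterm_contrast(term_b, pre_b, rownames(term_b))
  expect_equal(res$mean_diff[1:3],
               rowMeans(term_b[1:3, ]) - rowMeans(pre_b[1:3, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(res$fdr_q[1:3] < 0.1))
  pre_c <- pre_b
  pre_c[5, ] <- 0.6
  term_c <- term_b
  term_c[5, ] <- 0.5
  res2 <- preterm_contrast(term_c, pre_c, rownames(term_c))
  expect_true(res2$flagged[5])
  expect_true(is.na(res2$p[5]))
  term_c[6, ] <- 0.5
  pre_c[6, ] <- 0.5
  res3 <- preterm_contrast(term_c, pre_c, rownames(term_c))
  expect_false(res3$flagged[6])
  expect_equal(res3$p[6], 1)
})

test_that("ewas_fit methods print, summarize, extract and plot", {
  fit <- shared_ga_fit()
  expect_output(print(fit), "EWAS fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.ewas_fit")
  expect_output(print(s), "Top units")
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf), fit$records$coefficient)
  expect_identical(as.data.frame(fit), fit$records)
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ewas_tsv(fit, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(names(back)[1:10],
               c("probe_id", "coefficient", "std_error", "t_statistic", "df",
                 "p_raw", "p_bacon", "fdr_q", "delta_beta", "significant"))
  expect_equal(nrow(back), nrow(fit$records))
})
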