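# Deconvolution, paired cell-shift tests, effect-size labels and the
# compositional (ilr) PCA.

test_that("noiseless mixtures are recovered exactly", {
  ref <- make_reference(400, seed = 3)
  set.seed(5)
  k <- 12
  true <- matrix(rgamma(8 * k, 2), 8, k)
  true <- true / rowSums(true)
  mix <- ref$betas %*% t(true)
  colnames(mix) <- paste0("s", 1:8)
  est <- deconvolve(mix, ref)
  expect_lt(max(abs(est$proportions - true)), 1e-6)
})

test_that("pure cell types deconvolve to unit proportions", {
  ref <- make_reference(400, seed = 3)
  mix <- ref$betas
  colnames(mix) <- paste0("pure_", ref$cell_types)
  est <- deconvolve(mix, ref)
  expect_equal(unname(diag(est$proportions)), rep(1, 12), tolerance = 1e-8)
})

test_that("the active-set solution satisfies the KKT optimality conditions", {
  set.seed(9)
  for (i in 1:20) {
    A <- matrix(runif(40 * 6), 40, 6)
    y <- runif(40)
    p <- gestewas:::solve_mixture(A, y)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    # stationarity: gradient equal on the support, >= elsewhere
    g <- drop(2 * (crossprod(A) %*% p - crossprod(A, y)))
    on_support <- p > 1e-9
    mu <- mean(g[on_support])
    expect_lt(max(abs(g[on_support] - mu)), 1e-6)
    if (any(!on_support)) expect_gt(min(g[!on_support]) - mu, -1e-6)
  }
})

test_that("cohort deconvolution tracks the true proportions", {
  co <- shared_cohort()
  est <- shared_props()$early$proportions
  true <- co$truth$true_proportions[rownames(est), ]
  rmse <- sqrt(mean((est - true)^2))
  expect_lt(rmse, 0.02)
})

test_that("deconvolution insists on an identifiable reference", {
  ref <- make_reference(400, seed = 3)
  flat <- ref
  flat$betas[] <- 0.5
  mix <- ref$betas %*% rep(1 / 12, 12)
  mix <- cbind(s1 = drop(mix))
  rownames(mix) <- ref$probe_ids
  expect_error(deconvolve(mix, flat), "rank")
  expect_error(deconvolve(mix[1:5, , drop = FALSE], ref), "at least 12")
})

test_that("compare_timepoints recovers the planted composition shifts", {
  co <- shared_cohort()
  pr <- shared_props()
  all_props <- structure(list(
    proportions = rbind(pr$early$proportions, pr$late$proportions),
    probes_used = pr$early$probes_used), class = "proportion_table")
  pairing <- data.frame(array_t1 = early_arrays(co),
                        array_t2 = late_arrays(co))
  res <- compare_timepoints(all_props, pairing)
  expect_s3_class(res, "cell_shift_result")
  expect_equal(nrow(res), 12)
  expect_equal(unique(res$df), 25)
  neu <- res[res$cell_type == "Neu", ]
  expect_gt(neu$mean_diff, 0)
  expect_lt(neu$p_bonferroni, 0.05)
  expect_lt(res$mean_diff[res$cell_type == "CD4mem"], 0)
})

test_that("paired Cohen's d equals t over sqrt(n) and Bonferroni is x12", {
  co <- shared_cohort()
  pr <- shared_props()
  all_props <- structure(list(
    proportions = rbind(pr$early$proportions, pr$late$proportions),
    probes_used = pr$early$probes_used), class = "proportion_table")
  pairing <- data.frame(array_t1 = early_arrays(co), array_t2 = late_arrays(co))
  res <- compare_timepoints(all_props, pairing)
  n <- nrow(pairing)
  expect_equal(res$cohens_d, res$t_statistic / sqrt(n), tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, 12 * res$p_raw), tolerance = 1e-12)
})

test_that("effect-size labels follow the conventional cut points", {
  expect_equal(effect_size_class(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, -0.9)),
               c("negligible", "negligible", "small", "small",
                 "medium", "medium", "large", "large"))
})

test_that("compare_timepoints validates its pairing", {
  pr <- shared_props()$early
  expect_error(compare_timepoints(pr, data.frame(a = "x", b = "y")),
               "3 matched pairs")
  bad <- data.frame(a = rownames(pr$proportions)[1:3], b = c("no1", "no2", "no3"))
  expect_error(compare_timepoints(pr, bad), "absent")
})

test_that("the ilr basis is orthonormal and the map round-trips", {
  V <- ilr_basis(12)
  expect_equal(crossprod(V), diag(11), tolerance = 1e-12)
  # each basis vector lives in the clr plane (orthogonal to the 1 vector)
  expect_equal(unname(colSums(V)), rep(0, 11), tolerance = 1e-12)
  set.seed(13)
  x <- matrix(rgamma(50 * 12, 2), 50, 12)
  x <- x / rowSums(x)
  expect_lt(max(abs(ilr_inv(ilr(x)) - x)), 1e-9)
})

test_that("ilr_pca returns ordered shares that sum to one", {
  pcs <- shared_pcs()$early
  expect_s3_class(pcs, "composition_pcs")
  ve <- pcs$variance_explained
  expect_length(ve, 11)
  expect_equal(sum(ve), 1, tolerance = 1e-9)
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(dim(pcs$pc_scores), c(26, 2))
  expect_gt(sum(ve[1:2]), 0.5)
})

test_that("median and MCD centring agree on clean low-rank data", {
  co <- shared_cohort()
  true <- co$truth$true_proportions[early_arrays(co), ]
  a <- ilr_pca(true, robust = "median")
  b <- ilr_pca(true, robust = "mcd")
  expect_gt(sum(a$variance_explained[1:2]), 0.9)
  expect_gt(sum(b$variance_explained[1:2]), 0.9)
})

test_that("zeros are replaced and degenerate input is flagged", {
  comp <- matrix(rep(c(0.5, 0.5, 0, rep(0.1 / 9 * 0, 0), rep(0, 9)), 5),
                 5, 12, byrow = TRUE)
  comp <- comp / rowSums(comp)
  colnames(comp) <- blood_cell_types()
  expect_warning(pcs <- ilr_pca(comp), "identical")
  expect_true(all(pcs$pc_scores == 0))
  expect_true(all(is.finite(pcs$ilr_coordinates)))
})

test_that("ilr_pca rejects too many components", {
  comp <- matrix(1 / 12, 3, 12)
  expect_error(ilr_pca(comp, k = 12), "at most")
})
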