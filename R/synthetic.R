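# Synthetic paired-timepoint methylome cohorts with recorded ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: convex cell-type mixtures with a timepoint shift in composition,
# planted gestational-age and timepoint effects on the beta scale,
# heavy-tailed (contaminated Gaussian) measurement noise, SNP fingerprint
# probes, co-methylated probe blocks, and a partially mediated SES / IL-6
# covariate structure for the contribution analysis.

#' Default twelve leukocyte subtype labels
#' @export
blood_cell_types <- function() {
  c("Neu", "Eos", "Bas", "Mono", "Bnv", "Bmem",
    "CD4nv", "CD4mem", "CD8nv", "CD8mem", "NK", "Treg")
}

#' Simulation configuration for a paired-timepoint cohort
#'
#' Defaults emulate the study design the pipeline targets: 26 women sampled
#' at two pregnancy timepoints, of whom 4 deliver preterm (22 term pairs
#' enter the EWAS), 59 SNP fingerprint probes, 37 early / 4 late-mid planted
#' gestational-age CpGs with slope 0.02 beta/week, 21 planted timepoint CpGs
#' at delta -0.05, term gestational ages uniform on 37-40.5 weeks and
#' maternal age around 26.1 (SD 4.05) years.
#'
#' Cell compositions are logistic-normal around the normalized
#' \code{dirichlet_base} mean with two dominant latent factors (a
#' granulocyte-versus-lymphocyte balance and a memory-versus-naive balance)
#' plus small isotropic ilr jitter, so composition variation is effectively
#' two-dimensional, as observed in whole blood.
#'
#' @param n_women Number of women (each contributes one early and one late
#'   array).
#' @param n_probes Number of probes on the synthetic array.
#' @param n_snp_probes Number of SNP fingerprint probes (default 59).
#' @param cell_types Twelve distinct cell-type labels.
#' @param dirichlet_base Twelve positive weights; their normalization is the
#'   mean cell composition.
#' @param timepoint_shift Signed late-minus-early change per cell type;
#'   must sum to zero.
#' @param granulocyte_sd,memory_sd SDs of the two latent composition
#'   factors on the ilr scale.
#' @param ilr_jitter_sd Isotropic ilr-coordinate jitter SD (residual
#'   composition noise per array).
#' @param woman_intercept_sd Per-(woman, probe) random methylation offset SD
#'   on the beta scale, shared across timepoints.
#' @param n_ga_cpgs_early,n_ga_cpgs_late Planted gestational-age CpG counts.
#' @param ga_slope Magnitude of the planted slope, beta per week.
#' @param ga_negative_fraction Fraction of planted GA CpGs with negative
#'   slope (methylation loss with longer gestation predominates).
#' @param n_timepoint_cpgs Planted timepoint-effect CpG count.
#' @param timepoint_delta Planted late-minus-early beta change.
#' @param ga_range Term gestational age range in weeks (uniform draw).
#' @param preterm_ga_range Preterm gestational age range in weeks.
#' @param preterm_fraction Fraction of women delivering preterm.
#' @param maternal_age_mean,maternal_age_sd Maternal age distribution (years).
#' @param noise_sd Beta-scale measurement noise SD.
#' @param contamination_rate Fraction of residuals drawn from the inflated
#'   (\code{contamination_scale} times wider) component.
#' @param contamination_scale SD multiplier of the contaminating component.
#' @param n_mediated Number of planted partially mediated GA CpGs (early
#'   timepoint).
#' @param mediation_fraction Fraction of each mediated CpG's marginal GA
#'   effect routed through the SES path.
#' @param ses_ga_cor Correlation between the SES score and gestational age.
#' @param n_il6_cpgs Number of IL-6 predictor CpGs with planted loading.
#' @param il6_effect Beta change per unit latent IL-6 per unit weight.
#' @param n_regions,region_size,region_gap,region_sd Co-methylated block
#'   layout: number of blocks, probes per block, within-block spacing in bp,
#'   and the SD of the shared per-array latent signal.
#' @param seed Integer seed; one seed drives explicit sub-streams for the
#'   design, compositions, fingerprints, planting, noise and biomarkers.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_women = 26,
                       n_probes = 5000,
                       n_snp_probes = 59,
                       cell_types = blood_cell_types(),
                       dirichlet_base = c(58, 2.5, 0.5, 8, 2.5, 1, 8, 6, 5, 3, 4, 1.5),
                       timepoint_shift = stats::setNames(
                         c(0.06, 0, 0, 0, 0, -0.005, -0.005, -0.02,
                           -0.005, -0.01, -0.015, 0), cell_types),
                       granulocyte_sd = 0.5,
                       memory_sd = 0.25,
                       ilr_jitter_sd = 0.03,
                       woman_intercept_sd = 0.01,
                       n_ga_cpgs_early = 37,
                       n_ga_cpgs_late = 4,
                       ga_slope = 0.02,
                       ga_negative_fraction = 0.85,
                       n_timepoint_cpgs = 21,
                       timepoint_delta = -0.05,
                       ga_range = c(37, 40.5),
                       preterm_ga_range = c(32, 36.9),
                       preterm_fraction = 4 / 26,
                       maternal_age_mean = 26.09,
                       maternal_age_sd = 4.05,
                       noise_sd = 0.01,
                       contamination_rate = 0.05,
                       contamination_scale = 5,
                       n_mediated = 5,
                       mediation_fraction = 0.30,
                       ses_ga_cor = 0.4,
                       n_il6_cpgs = 35,
                       il6_effect = 0.02,
                       n_regions = 40,
                       region_size = 3,
                       region_gap = 200,
                       region_sd = 0.04,
                       seed = 1) {
  cfg <- as.list(environment())
  # YAML readers deliver named vectors as lists; flatten them back
  for (v in c("cell_types", "dirichlet_base", "timepoint_shift",
              "ga_range", "preterm_ga_range")) {
    if (is.list(cfg[[v]])) cfg[[v]] <- unlist(cfg[[v]])
  }
  # an unnamed shift (e.g. read back from YAML, which drops vector names)
  # is taken to be in cell-type order; a named one is aligned to it
  if (is.null(names(cfg$timepoint_shift)) &&
      length(cfg$timepoint_shift) == length(cfg$cell_types))
    names(cfg$timepoint_shift) <- cfg$cell_types
  if (!is.null(names(cfg$timepoint_shift)))
    cfg$timepoint_shift <- cfg$timepoint_shift[cfg$cell_types]
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$cell_types) == 12, !anyDuplicated(cfg$cell_types),
    length(cfg$dirichlet_base) == 12, all(cfg$dirichlet_base > 0),
    length(cfg$timepoint_shift) == 12, !anyNA(cfg$timepoint_shift),
    cfg$n_snp_probes <= cfg$n_probes,
    cfg$preterm_fraction >= 0, cfg$preterm_fraction <= 1,
    cfg$contamination_rate >= 0, cfg$contamination_rate <= 1,
    cfg$mediation_fraction >= 0, cfg$mediation_fraction <= 1,
    cfg$noise_sd >= 0, cfg$ga_range[1] < cfg$ga_range[2]
  )
  if (abs(sum(cfg$timepoint_shift)) > 1e-9)
    stop("timepoint_shift must sum to zero so compositions remain on the simplex")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' The YAML schema mirrors the \code{\link{sim_config}} arguments
#' field-for-field; absent fields take the defaults.
#'
#' @param path YAML file path.
#' @return A \code{"sim_config"} object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Generate a cell-type reference beta matrix
#'
#' Builds a probes x 12 matrix of expected methylation levels. A designated
#' subset of probes is strongly cell-discriminating (between-type beta range
#' at least 0.5), mirroring an IDOL-style optimized library, so constrained
#' deconvolution is identifiable; remaining probes share a common baseline
#' with small cell-specific deviations.
#'
#' @param n_probes Number of probes (>= 12).
#' @param cell_types Twelve or more distinct labels (exactly 12 expected by
#'   the rest of the pipeline).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class \code{"cell_reference"} with \code{probe_ids},
#'   \code{cell_types}, the \code{betas} matrix and the ids of the
#'   discriminating probes.
#' @export
make_reference <- function(n_probes, cell_types = blood_cell_types(), seed = 1) {
  if (length(cell_types) < 12) stop("a 12-cell-type reference requires at least 12 labels")
  if (anyDuplicated(cell_types)) stop("cell-type labels must be distinct")
  if (n_probes < 12) stop("n_probes must be at least 12")
  k <- length(cell_types)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  probe_ids <- sprintf("cg%07d", seq_len(n_probes))
  n_disc <- min(n_probes, 25L * k)
  betas <- matrix(0, n_probes, k, dimnames = list(probe_ids, cell_types))

  # Discriminating probes: one target type high, the rest low (round robin).
  target <- rep_len(seq_len(k), n_disc)
  for (i in seq_len(n_disc)) {
    lo <- stats::runif(k, 0.05, 0.30)
    lo[target[i]] <- stats::runif(1, 0.85, 0.95)
    betas[i, ] <- lo
  }
  # Remaining probes: shared baseline, mild cell-specific deviation.
  if (n_disc < n_probes) {
    idx <- (n_disc + 1L):n_probes
    base <- stats::runif(length(idx), 0.05, 0.95)
    dev <- matrix(stats::rnorm(length(idx) * k, 0, 0.03), length(idx), k)
    betas[idx, ] <- clip01(base + dev)
  }
  structure(list(probe_ids = probe_ids, cell_types = cell_types,
                 betas = betas, discriminating = probe_ids[seq_len(n_disc)]),
            class = "cell_reference")
}

#' @export
print.cell_reference <- function(x, ...) {
  cat("Cell-type reference:", length(x$probe_ids), "probes x",
      length(x$cell_types), "cell types;",
      length(x$discriminating), "discriminating probes\n")
  invisible(x)
}

# Latent composition factor directions on the ilr scale, unit norm.
composition_factors <- function(cell_types, basis) {
  grans <- cell_types %in% c("Neu", "Eos", "Bas")
  mem <- cell_types %in% c("Bmem", "CD4mem", "CD8mem")
  naiv <- cell_types %in% c("Bnv", "CD4nv", "CD8nv")
  clr1 <- ifelse(grans, 1 / sum(grans), -1 / sum(!grans))
  clr2 <- ifelse(mem, 1 / sum(mem), ifelse(naiv, -1 / sum(naiv), 0))
  v1 <- drop(clr1 %*% basis); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- drop(clr2 %*% basis); v2 <- v2 / sqrt(sum(v2^2))
  list(v1 = v1, v2 = v2)
}

#' Simulate a paired-timepoint methylation cohort
#'
#' Per array, beta values are the convex reference mixture for that array's
#' cell composition, plus planted gestational-age / timepoint / mediated /
#' IL-6 / co-methylated-block effects, a per-(woman, probe) random offset,
#' and contaminated Gaussian noise, clipped to [0, 1]. SNP probes carry
#' woman-specific genotype fingerprints near 0.05 / 0.5 / 0.95 identical at
#' both timepoints. All randomness derives from \code{cfg$seed} through
#' named sub-streams, so sub-structures are independently reproducible.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param reference A \code{\link{make_reference}} result with at least
#'   \code{cfg$n_probes} probes.
#' @return A list of class \code{"sim_cohort"}: \code{betas_early} and
#'   \code{betas_late} (probe x array matrices), \code{sample_sheet},
#'   \code{manifest}, \code{truth} (ground-truth record), \code{il6_weights}
#'   and the \code{reference} and \code{config} used.
#' @export
simulate_cohort <- function(cfg, reference = NULL) {
  validate_sim_config(cfg)
  if (is.null(reference)) {
    reference <- make_reference(cfg$n_probes, cfg$cell_types,
                                seed = seed_streams(cfg$seed, 9)[9])
  }
  if (length(reference$probe_ids) < cfg$n_probes)
    stop("reference has fewer probes than cfg$n_probes")
  streams <- seed_streams(cfg$seed, 8)
  probes <- reference$probe_ids[seq_len(cfg$n_probes)]
  ref <- reference$betas[probes, , drop = FALSE]
  k <- length(cfg$cell_types)
  n <- cfg$n_women

  ## --- design stream: women, gestational ages, covariates -----------------
  set.seed(streams[1])
  woman_ids <- sprintf("W%02d", seq_len(n))
  n_pre <- round(cfg$preterm_fraction * n)
  term <- rep(TRUE, n)
  if (n_pre > 0) term[sample.int(n, n_pre)] <- FALSE
  ga <- numeric(n)
  ga[term] <- stats::runif(sum(term), cfg$ga_range[1], cfg$ga_range[2])
  ga[!term] <- stats::runif(sum(!term), cfg$preterm_ga_range[1], cfg$preterm_ga_range[2])
  age <- stats::rnorm(n, cfg$maternal_age_mean, cfg$maternal_age_sd)
  # SES correlates with gestational age among term women (the EWAS cohort);
  # calibrated on the empirical term-GA scale so the planted mediation
  # fraction holds in-sample
  rho <- cfg$ses_ga_cor
  ses <- stats::rnorm(n)
  ses[term] <- rho * as.numeric(scale(ga[term])) +
    sqrt(1 - rho^2) * stats::rnorm(sum(term))
  anx_e <- stats::rnorm(n); anx_l <- stats::rnorm(n)
  dep_e <- stats::rnorm(n); dep_l <- stats::rnorm(n)
  il6_e <- stats::rnorm(n)
  il6_l <- 0.44 * il6_e + sqrt(1 - 0.44^2) * stats::rnorm(n) + 0.5

  ## --- biomarker stream ----------------------------------------------------
  set.seed(streams[8])
  draw_min <- stats::runif(n, 660, 840)           # 11:00-14:00
  gw_draw <- stats::runif(n, 10, 19)
  cortisol <- pmax(0.5, 12 - 0.008 * (draw_min - 660) + 0.1 * (gw_draw - 14) +
                     stats::rnorm(n, 0, 1.5))
  panel <- data.frame(
    woman_id = woman_ids,
    cortisol = cortisol,
    hba1c = stats::rnorm(n, 5.2, 0.35),
    crp = stats::rlnorm(n, log(0.4), 0.6),
    cholesterol = stats::rnorm(n, 180, 25),
    sbp = stats::rnorm(n, 110, 10),
    dbp = stats::rnorm(n, 70, 8),
    cortisol_draw_min = draw_min,
    gest_week_at_draw = gw_draw,
    stringsAsFactors = FALSE
  )

  ## --- composition stream --------------------------------------------------
  set.seed(streams[2])
  basis <- ilr_basis(k)
  m <- cfg$dirichlet_base / sum(cfg$dirichlet_base)
  mu <- drop(ilr(m, basis))
  fac <- composition_factors(cfg$cell_types, basis)
  f1 <- stats::rnorm(n, 0, cfg$granulocyte_sd)
  f2 <- stats::rnorm(n, 0, cfg$memory_sd)
  eps_e <- matrix(stats::rnorm(n * (k - 1), 0, cfg$ilr_jitter_sd), n)
  eps_l <- matrix(stats::rnorm(n * (k - 1), 0, cfg$ilr_jitter_sd), n)
  z0 <- matrix(mu, n, k - 1, byrow = TRUE) +
    outer(f1, fac$v1) + outer(f2, fac$v2)      # woman latent composition
  prop_e <- ilr_inv(z0 + eps_e, basis)
  shifted <- sweep(ilr_inv(z0, basis), 2, cfg$timepoint_shift, "+")
  shifted[shifted < 1e-4] <- 1e-4
  shifted <- sweep(shifted, 1, rowSums(shifted), "/")
  prop_l <- ilr_inv(ilr(shifted, basis) + eps_l, basis)
  dimnames(prop_e) <- dimnames(prop_l) <- list(woman_ids, cfg$cell_types)

  ## --- planting stream: probe roles ---------------------------------------
  set.seed(streams[4])
  disc_idx <- match(intersect(reference$discriminating, probes), probes)
  # probes laid out per chromosome in contiguous index blocks, so runs of
  # consecutive indices share a chromosome (used for co-methylated blocks)
  chrom <- paste0("chr", rep(1:22, each = ceiling(cfg$n_probes / 22))[seq_len(cfg$n_probes)])
  rs <- cfg$region_size
  run_ok <- vapply(seq_len(cfg$n_probes - rs + 1L), function(i) {
    idx <- i:(i + rs - 1L)
    chrom[i] == chrom[i + rs - 1L] && !any(idx %in% disc_idx)
  }, logical(1))
  starts <- integer(0)
  cand <- sample(which(run_ok))
  for (s in cand) {
    if (length(starts) >= cfg$n_regions) break
    if (!any(abs(starts - s) < rs)) starts <- c(starts, s)
  }
  if (length(starts) < cfg$n_regions)
    stop("n_probes too small to place all co-methylated blocks")
  reg_runs <- lapply(starts, function(s) s:(s + rs - 1L))
  reg_idx <- unlist(reg_runs)
  region_of <- integer(cfg$n_probes)
  for (r in seq_along(reg_runs)) region_of[reg_runs[[r]]] <- r

  eligible <- setdiff(seq_len(cfg$n_probes), c(disc_idx, reg_idx))
  take <- function(nn, from) {
    if (nn > length(from)) stop("not enough probes to plant all effects")
    from[seq_len(nn)]
  }
  shuffled <- sample(eligible)
  snp_idx <- take(cfg$n_snp_probes, shuffled); shuffled <- setdiff(shuffled, snp_idx)
  gae_idx <- take(cfg$n_ga_cpgs_early, shuffled); shuffled <- setdiff(shuffled, gae_idx)
  gal_idx <- take(cfg$n_ga_cpgs_late, shuffled); shuffled <- setdiff(shuffled, gal_idx)
  tp_idx <- take(cfg$n_timepoint_cpgs, shuffled); shuffled <- setdiff(shuffled, tp_idx)
  med_idx <- take(cfg$n_mediated, shuffled); shuffled <- setdiff(shuffled, med_idx)
  il6_idx <- take(cfg$n_il6_cpgs, shuffled)

  slope_sign <- ifelse(stats::runif(cfg$n_ga_cpgs_early) < cfg$ga_negative_fraction, -1, 1)
  slopes_e <- slope_sign * cfg$ga_slope
  slope_sign_l <- ifelse(stats::runif(cfg$n_ga_cpgs_late) < cfg$ga_negative_fraction, -1, 1)
  slopes_l <- slope_sign_l * cfg$ga_slope
  il6_w <- stats::runif(cfg$n_il6_cpgs, 0.5, 1.5) * sample(c(-1, 1), cfg$n_il6_cpgs, TRUE)

  ## --- manifest stream ------------------------------------------------------
  set.seed(streams[7])
  pos <- integer(cfg$n_probes)
  # block members placed region_gap apart; all other consecutive probes
  # spaced > 1000 bp so they never chain by distance alone
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    p <- 10000L
    last_region <- 0L
    for (i in on_ch) {
      if (region_of[i] != 0L && region_of[i] == last_region) {
        p <- p + cfg$region_gap
      } else {
        p <- p + as.integer(stats::runif(1, 1500, 6000))
      }
      pos[i] <- p
      last_region <- region_of[i]
    }
  }
  states <- c("TSS", "Enh", "Tx", "ReprPC", "Quies")
  manifest <- data.frame(
    probe_id = probes,
    chrom = chrom,
    pos = pos,
    gene = ifelse(stats::runif(cfg$n_probes) < 0.6,
                  sprintf("GENE%04d", sample.int(2000, cfg$n_probes, TRUE)), ""),
    chrom_state = sample(states, cfg$n_probes, TRUE,
                         prob = c(0.1, 0.12, 0.2, 0.13, 0.45)),
    snp_probe = seq_len(cfg$n_probes) %in% snp_idx,
    stringsAsFactors = FALSE
  )

  ## --- expected betas -------------------------------------------------------
  arrays_e <- paste0(woman_ids, "_T1")
  arrays_l <- paste0(woman_ids, "_T2")
  mix_e <- ref %*% t(prop_e)    # probes x women
  mix_l <- ref %*% t(prop_l)
  colnames(mix_e) <- arrays_e
  colnames(mix_l) <- arrays_l

  ga_c <- ga - mean(cfg$ga_range)       # centred so planted betas stay in range
  add_slope <- function(mat, idx, slopes) {
    mat[idx, ] <- mat[idx, , drop = FALSE] + outer(slopes, ga_c)
    mat
  }
  mix_e <- add_slope(mix_e, gae_idx, slopes_e)
  mix_l <- add_slope(mix_l, gal_idx, slopes_l)
  mix_l[tp_idx, ] <- mix_l[tp_idx, , drop = FALSE] + cfg$timepoint_delta

  # mediated probes (early): marginal GA slope ga_slope, a fraction of which
  # flows through SES. direct = (1-f) * slope; SES loading chosen so the
  # SES path contributes f * slope to the marginal regression on GA.
  f <- cfg$mediation_fraction
  sd_ga <- stats::sd(ga[term])
  med_slope <- -cfg$ga_slope            # mediated CpGs lose methylation with GA
  c_ses <- if (f > 0) f * med_slope * sd_ga / rho else 0
  mix_e[med_idx, ] <- mix_e[med_idx, , drop = FALSE] +
    rep(1, cfg$n_mediated) %o% ((1 - f) * med_slope * ga_c + c_ses * ses)

  # IL-6 predictor probes: loading proportional to the predictor weight
  mix_e[il6_idx, ] <- mix_e[il6_idx, , drop = FALSE] +
    cfg$il6_effect * (il6_w %o% il6_e)
  mix_l[il6_idx, ] <- mix_l[il6_idx, , drop = FALSE] +
    cfg$il6_effect * (il6_w %o% il6_l)

  ## --- co-methylated blocks stream -----------------------------------------
  set.seed(streams[6])
  for (r in seq_len(cfg$n_regions)) {
    g_e <- stats::rnorm(n, 0, cfg$region_sd)
    g_l <- stats::rnorm(n, 0, cfg$region_sd)
    mix_e[reg_runs[[r]], ] <- mix_e[reg_runs[[r]], , drop = FALSE] +
      rep(1, cfg$region_size) %o% g_e
    mix_l[reg_runs[[r]], ] <- mix_l[reg_runs[[r]], , drop = FALSE] +
      rep(1, cfg$region_size) %o% g_l
  }

  bad <- which(mix_e < 0 | mix_e > 1 | mix_l < 0 | mix_l > 1)
  truncated <- probes[unique(((bad - 1L) %% cfg$n_probes) + 1L)]
  mix_e <- clip01(mix_e); mix_l <- clip01(mix_l)

  ## --- noise stream ---------------------------------------------------------
  set.seed(streams[5])
  u <- matrix(stats::rnorm(cfg$n_probes * n, 0, cfg$woman_intercept_sd),
              cfg$n_probes, n)
  noise <- function() {
    sds <- matrix(cfg$noise_sd, cfg$n_probes, n)
    contam <- matrix(stats::runif(cfg$n_probes * n) < cfg$contamination_rate,
                     cfg$n_probes, n)
    sds[contam] <- cfg$noise_sd * cfg$contamination_scale
    matrix(stats::rnorm(cfg$n_probes * n, 0, sds), cfg$n_probes, n)
  }
  betas_e <- clip01(mix_e + u + noise())
  betas_l <- clip01(mix_l + u + noise())

  ## --- SNP fingerprints stream ----------------------------------------------
  set.seed(streams[3])
  maf <- stats::runif(cfg$n_snp_probes, 0.1, 0.5)
  geno_means <- c(0.05, 0.5, 0.95)
  geno <- matrix(0L, cfg$n_snp_probes, n)
  for (j in seq_len(cfg$n_snp_probes)) {
    p <- maf[j]
    geno[j, ] <- sample(0:2, n, TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  snp_mu <- matrix(geno_means[geno + 1L], cfg$n_snp_probes, n)
  betas_e[snp_idx, ] <- clip01(snp_mu + stats::rnorm(length(snp_mu), 0, 0.02))
  betas_l[snp_idx, ] <- clip01(snp_mu + stats::rnorm(length(snp_mu), 0, 0.02))

  rownames(betas_e) <- rownames(betas_l) <- probes

  ## --- outputs ---------------------------------------------------------------
  sheet <- rbind(
    data.frame(array_id = arrays_e, woman_id = woman_ids, timepoint = "early",
               stringsAsFactors = FALSE),
    data.frame(array_id = arrays_l, woman_id = woman_ids, timepoint = "late",
               stringsAsFactors = FALSE)
  )
  per_woman <- data.frame(
    woman_id = woman_ids, ga_weeks = ga, maternal_age = age, term = term,
    ses_z = ses, stringsAsFactors = FALSE
  )
  sheet <- merge(sheet, per_woman, by = "woman_id", sort = FALSE)
  sheet$anxiety_z <- ifelse(sheet$timepoint == "early", anx_e[match(sheet$woman_id, woman_ids)],
                            anx_l[match(sheet$woman_id, woman_ids)])
  sheet$depression_z <- ifelse(sheet$timepoint == "early", dep_e[match(sheet$woman_id, woman_ids)],
                               dep_l[match(sheet$woman_id, woman_ids)])
  sheet$il6_true <- ifelse(sheet$timepoint == "early", il6_e[match(sheet$woman_id, woman_ids)],
                           il6_l[match(sheet$woman_id, woman_ids)])
  sheet <- merge(sheet, panel, by = "woman_id", sort = FALSE)
  sheet <- sheet[order(sheet$timepoint, sheet$array_id),
                 c("array_id", setdiff(names(sheet), "array_id"))]
  rownames(sheet) <- NULL

  true_props <- rbind(prop_e, prop_l)
  rownames(true_props) <- c(arrays_e, arrays_l)

  truth <- structure(list(
    true_proportions = true_props,
    ga_effect_probes = rbind(
      data.frame(probe_id = probes[gae_idx],
                 timepoint = rep("early", length(gae_idx)),
                 slope = slopes_e, stringsAsFactors = FALSE),
      data.frame(probe_id = probes[gal_idx],
                 timepoint = rep("late", length(gal_idx)),
                 slope = slopes_l, stringsAsFactors = FALSE)
    ),
    timepoint_effect_probes = data.frame(
      probe_id = probes[tp_idx],
      delta = rep(cfg$timepoint_delta, length(tp_idx)),
      stringsAsFactors = FALSE),
    mediated_probes = data.frame(
      probe_id = probes[med_idx],
      mediator = rep("ses_z", length(med_idx)),
      contribution_pct = rep(100 * f, length(med_idx)),
      marginal_slope = rep(med_slope, length(med_idx)),
      stringsAsFactors = FALSE),
    true_pairing = data.frame(array_id = c(arrays_e, arrays_l),
                              woman_id = rep(woman_ids, 2),
                              stringsAsFactors = FALSE),
    term_flag = stats::setNames(term, woman_ids),
    snp_probes = probes[snp_idx],
    il6_probes = probes[il6_idx],
    region_members = lapply(reg_runs, function(i) probes[i]),
    truncated_probes = truncated
  ), class = "truth_table")
  stopifnot(all(abs(rowSums(true_props) - 1) < 1e-9))

  structure(list(
    betas_early = betas_e, betas_late = betas_l,
    sample_sheet = sheet, manifest = manifest, truth = truth,
    il6_weights = data.frame(probe_id = probes[il6_idx], weight = il6_w,
                             stringsAsFactors = FALSE),
    reference = reference, config = cfg
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic paired cohort:", x$config$n_women, "women x 2 timepoints,",
      x$config$n_probes, "probes\n")
  cat("  planted GA CpGs:", x$config$n_ga_cpgs_early, "early /",
      x$config$n_ga_cpgs_late, "late;",
      x$config$n_timepoint_cpgs, "timepoint CpGs;",
      x$config$n_mediated, "mediated\n")
  invisible(x)
}

#' Write a simulated cohort's artifacts to disk
#'
#' Betas as TSV (probe rows, array columns), sample sheet as CSV, manifest
#' as TSV, ground truth as JSON, IL-6 weights as CSV.
#'
#' @param cohort A \code{"sim_cohort"}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    betas_early = file.path(dir, "betas_early.tsv"),
    betas_late = file.path(dir, "betas_late.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    manifest = file.path(dir, "manifest.tsv"),
    truth = file.path(dir, "truth.json"),
    il6_weights = file.path(dir, "il6_weights.csv")
  )
  write_beta_tsv(cohort$betas_early, files["betas_early"])
  write_beta_tsv(cohort$betas_late, files["betas_late"])
  utils::write.csv(cohort$sample_sheet, files["sample_sheet"], row.names = FALSE)
  utils::write.table(cohort$manifest, files["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_proportions <- as.data.frame(truth$true_proportions)
  truth$region_members <- unname(truth$region_members)
  jsonlite::write_json(unclass(truth), files["truth"], dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  utils::write.csv(cohort$il6_weights, files["il6_weights"], row.names = FALSE)
  invisible(as.list(files))
}
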