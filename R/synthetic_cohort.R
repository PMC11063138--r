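#' Simulation configuration for a synthetic CSF cohort
#'
#' Defines the data-generating conditions for [generate_cohort()]: a cohort of
#' participants whose NPX-style (log2 relative abundance) protein values are
#' driven by a latent per-participant concentration ("dilution") factor `d`,
#' correlated amyloid/tau pathology burdens, per-cluster protein loadings on
#' `d`, disease effects restricted to designated biomarker proteins, and
#' below-LOD censoring.
#'
#' The latent factor is
#' `d_i = age_effect * z(age_i) + sex_effect * sex_i + ventricle_effect * z(ventricle_i) + N(0, dilution_sd^2)`
#' with age and ventricular volume standardized internally and sex coded
#' 0/1 (1 = male). Protein `j` for participant `i` is
#' `mu_j + lambda_j d_i + beta_j^A a_i + beta_j^T t_i + eps_ij`,
#' `eps ~ N(0, noise_sd^2)`.
#'
#' @param n_participants,n_proteins,n_clusters cohort and panel dimensions;
#'   `n_clusters` must be at least 3 (one reference cluster plus the two
#'   clusters that host the designated tau- and amyloid-biomarker proteins).
#' @param cluster_sizes integer vector of per-cluster protein counts summing to
#'   `n_proteins`; defaults to a near-even split.
#' @param dilution_sd standard deviation of the residual (covariate-free) part
#'   of the latent dilution factor.
#' @param loading_by_cluster per-cluster mean loading on `d`; the cluster with
#'   the largest loading is the planted reference cluster (zero disease
#'   effects). Defaults to a decreasing grid from 1 to 0.05.
#' @param loading_jitter_sd within-cluster spread of loadings.
#' @param noise_sd per-protein residual SD in NPX log2 units.
#' @param amyloid_prevalence,tau_prevalence fractions in (0, 1) of PET-positive
#'   participants.
#' @param effect_amyloid,effect_tau disease effect sizes (NPX units per unit
#'   latent burden) applied to the designated biomarker proteins; the amyloid
#'   effect enters with a negative sign (CSF A-beta-42 falls with plaque load).
#' @param burden_correlation coupling of the tau burden to the standardized
#'   supra-threshold amyloid excess (default 0.95); tau pathology is modeled
#'   downstream of amyloid, so genuinely tau-positive amyloid-negative
#'   participants are rare, as in AD cohorts.
#' @param age_effect,sex_effect,ventricle_effect covariate coefficients on `d`.
#' @param pet_noise_sd noise added to latent burdens before thresholding into
#'   PET positivity.
#' @param biomarker_noise_sd measurement noise of the concentration-scale
#'   (immunoassay-style) biomarker columns; smaller than `noise_sd` because
#'   the clinical assays are more precise than the multiplexed panel.
#' @param pathway_sd SD of the biomarker-specific pathway factors shared
#'   between each main biomarker and its designated specific reference
#'   protein (the A-beta-42/A-beta-40 co-secretion analogue).
#' @param lod_quantile fraction of each protein's values censored (set missing)
#'   below its empirical quantile; 0 disables censoring.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @seealso [generate_cohort()], [fixture_config()]
#' @export
sim_config <- function(n_participants = 658L,
                       n_proteins = 500L,
                       n_clusters = 10L,
                       cluster_sizes = NULL,
                       dilution_sd = 1.8,
                       loading_by_cluster = NULL,
                       loading_jitter_sd = 0.05,
                       noise_sd = 0.8,
                       amyloid_prevalence = 0.33,
                       tau_prevalence = 0.27,
                       effect_amyloid = 3.0,
                       effect_tau = 1.8,
                       burden_correlation = 0.95,
                       age_effect = 0.3,
                       sex_effect = 0.3,
                       ventricle_effect = -0.3,
                       pet_noise_sd = 0.25,
                       biomarker_noise_sd = 0.4,
                       pathway_sd = 0.8,
                       lod_quantile = 0,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_proteins = as.integer(n_proteins),
    n_clusters = as.integer(n_clusters),
    cluster_sizes = cluster_sizes,
    dilution_sd = dilution_sd,
    loading_by_cluster = loading_by_cluster,
    loading_jitter_sd = loading_jitter_sd,
    noise_sd = noise_sd,
    amyloid_prevalence = amyloid_prevalence,
    tau_prevalence = tau_prevalence,
    effect_amyloid = effect_amyloid,
    effect_tau = effect_tau,
    burden_correlation = burden_correlation,
    age_effect = age_effect,
    sex_effect = sex_effect,
    ventricle_effect = ventricle_effect,
    pet_noise_sd = pet_noise_sd,
    biomarker_noise_sd = biomarker_noise_sd,
    pathway_sd = pathway_sd,
    lod_quantile = lod_quantile,
    seed = as.integer(seed)
  )
  if (is.null(cfg$cluster_sizes)) {
    base <- cfg$n_proteins %/% cfg$n_clusters
    sizes <- rep(base, cfg$n_clusters)
    rem <- cfg$n_proteins - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    cfg$cluster_sizes <- as.integer(sizes)
  } else {
    cfg$cluster_sizes <- as.integer(cfg$cluster_sizes)
  }
  if (is.null(cfg$loading_by_cluster)) {
    cfg$loading_by_cluster <- seq(1, 0.05, length.out = cfg$n_clusters)
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_participants < 2) bad("n_participants", "must be >= 2")
  if (cfg$n_proteins < 1) bad("n_proteins", "must be >= 1")
  if (cfg$n_clusters < 3) bad("n_clusters", "must be >= 3")
  if (length(cfg$cluster_sizes) != cfg$n_clusters)
    bad("cluster_sizes", "must have one entry per cluster")
  if (sum(cfg$cluster_sizes) != cfg$n_proteins)
    bad("cluster_sizes", "must sum to n_proteins")
  if (any(cfg$cluster_sizes < 1)) bad("cluster_sizes", "must all be >= 1")
  if (length(cfg$loading_by_cluster) != cfg$n_clusters)
    bad("loading_by_cluster", "must have one entry per cluster")
  for (f in c("dilution_sd", "loading_jitter_sd", "noise_sd", "pet_noise_sd",
              "biomarker_noise_sd", "pathway_sd"))
    if (cfg[[f]] < 0) bad(f, "must be >= 0")
  for (f in c("amyloid_prevalence", "tau_prevalence"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) bad(f, "must lie in (0, 1)")
  if (cfg$burden_correlation < -1 || cfg$burden_correlation > 1)
    bad("burden_correlation", "must lie in [-1, 1]")
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1)
    bad("lod_quantile", "must lie in [0, 1)")
  invisible(cfg)
}

# Designated biomarker roles. The reference cluster is the one with the
# largest mean loading; the tau- and amyloid-biomarker proteins sit in the
# next two clusters (by loading) so they carry a substantial but not maximal
# dilution loading, as CSF P-tau181 and A-beta-42 do.
.assign_roles <- function(cluster_label, ids, loading_by_cluster) {
  ord <- order(loading_by_cluster, decreasing = TRUE)
  ref_cluster <- ord[1]
  tau_cluster <- ord[2]
  ab_cluster <- ord[3]
  first2 <- function(cl) ids[which(cluster_label == cl)[1:2]]
  list(
    ptau181 = first2(tau_cluster)[1],
    tau_partner = first2(tau_cluster)[2],
    abeta42 = first2(ab_cluster)[1],
    amyloid_partner = first2(ab_cluster)[2],
    abeta40 = ids[which(cluster_label == ref_cluster)[1]],
    ptau_reference = ids[which(cluster_label == ref_cluster)[2]],
    reference = ids[cluster_label == ref_cluster],
    reference_cluster = ref_cluster,
    tau_cluster = tau_cluster,
    amyloid_cluster = ab_cluster
  )
}

#' Generate a synthetic CSF cohort with full ground truth
#'
#' Draws a cohort under the data-generating model described in [sim_config()]:
#' covariates, a latent dilution factor, correlated amyloid/tau burdens,
#' a participants-by-proteins NPX matrix with planted cluster structure, PET
#' positivity and conversion outcomes coupled to the latent burdens, and
#' optional below-LOD missingness.
#'
#' Concentration-scale biomarker columns (pg/ml, ratio, SUVR, centiloid) are
#' monotone transforms of the designated proteins' NPX values, calibrated so
#' the conventional cutoffs (P-tau181 21.8 pg/ml, A-beta ratio 0.08, SUVR 1.36,
#' centiloid 20) fall at the configured prevalence quantiles of the synthetic
#' marginals.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `csf_cohort` with elements `cohort` (a participant
#'   covariate/outcome data.frame), `matrix` (a [protein_matrix()]), and
#'   `truth` (latent `d`, `a`, `t`, loadings, disease effects, cluster labels
#'   and designated roles).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  p <- config$n_proteins

  participant_id <- sprintf("subj_%04d", seq_len(n))
  age <- rnorm(n, 68, 12)
  sex <- rbinom(n, 1, 0.5)
  education <- pmax(round(rnorm(n, 12.4, 3.8)), 6)
  icv <- rnorm(n, 1450, 130)
  gm_volume <- rnorm(n, 600, 55)
  ventricle_volume <- exp(rnorm(n, log(35), 0.45))

  zs <- function(v) as.numeric(scale(v))
  d <- config$age_effect * zs(age) + config$sex_effect * sex +
    config$ventricle_effect * zs(ventricle_volume) +
    rnorm(n, 0, config$dilution_sd)

  # Tau burden is modeled downstream of supra-threshold amyloid: tau-PET
  # positivity virtually requires amyloid positivity in AD cohorts, so the
  # tau driver is the standardized amyloid excess over the positivity
  # quantile, blended with independent noise by burden_correlation.
  rho <- config$burden_correlation
  # Amyloid burden is bimodal (accumulators vs non-accumulators), as amyloid
  # PET is in AD cohorts; standardized to unit variance.
  accum <- rbinom(n, 1, config$amyloid_prevalence)
  a <- 2.2 * accum + rnorm(n, 0, 0.6)
  a <- (a - mean(a)) / sd(a)
  a_excess <- pmax(a - quantile(a, 1 - config$amyloid_prevalence,
                                names = FALSE), 0)
  a_excess <- (a_excess - mean(a_excess)) / sd(a_excess)
  t_burden <- rho * a_excess + sqrt(1 - rho^2) * rnorm(n)

  lambda <- rep(config$loading_by_cluster, config$cluster_sizes) +
    rnorm(p, 0, config$loading_jitter_sd)
  cluster_label <- rep(seq_len(config$n_clusters), config$cluster_sizes)
  ids <- sprintf("prot_%04d", seq_len(p))
  roles <- .assign_roles(cluster_label, ids, config$loading_by_cluster)

  beta_a <- numeric(p)
  beta_t <- numeric(p)
  beta_t[match(c(roles$ptau181, roles$tau_partner), ids)] <- config$effect_tau
  beta_a[match(c(roles$abeta42, roles$amyloid_partner), ids)] <-
    -config$effect_amyloid

  mu <- rnorm(p, 5, 1.5)
  values <- matrix(mu, n, p, byrow = TRUE) +
    d %o% lambda + a %o% beta_a + t_burden %o% beta_t +
    matrix(rnorm(n * p, 0, config$noise_sd), n, p)
  dimnames(values) <- list(participant_id, ids)

  # Biomarker-specific pathway factors: each main biomarker shares extra
  # non-disease covariation with its specific reference (as A-beta-42 and
  # A-beta-40 share the APP secretion pathway), which is what lets a single
  # well-chosen reference outperform the panel-wide mean level.
  ps <- config$pathway_sd
  w_tau <- rnorm(n)
  w_amy <- rnorm(n)
  values[, roles$ptau181] <- values[, roles$ptau181] + ps * w_tau
  values[, roles$ptau_reference] <- values[, roles$ptau_reference] +
    ps * w_tau
  values[, roles$abeta42] <- values[, roles$abeta42] + ps * w_amy
  values[, roles$abeta40] <- values[, roles$abeta40] + ps * w_amy

  # PET positivity: noisy burden thresholded at the prevalence quantile, then
  # mapped to the conventional scale so the standard clinical cutoff
  # reproduces the planted labels exactly.
  s_t <- t_burden + rnorm(n, 0, config$pet_noise_sd)
  thr_t <- quantile(s_t, 1 - config$tau_prevalence, names = FALSE)
  tau_pet_suvr <- 1.36 + 0.45 * (s_t - thr_t)
  s_a <- a + rnorm(n, 0, config$pet_noise_sd)
  thr_a <- quantile(s_a, 1 - config$amyloid_prevalence, names = FALSE)
  amyloid_centiloid <- 20 + 35 * (s_a - thr_a)
  s_c <- t_burden + rnorm(n, 0, 1.5 * config$pet_noise_sd)
  add_conversion <- as.integer(
    s_c > quantile(s_c, 1 - config$tau_prevalence / 2, names = FALSE))

  # Concentration-scale biomarkers (immunoassay-style) share the designated
  # proteins' latent structure but carry their own, smaller measurement noise:
  # the clinical assays are far more precise than the multiplexed panel.
  bn <- config$biomarker_noise_sd
  lam_pt <- lambda[match(roles$ptau181, ids)]
  lam40 <- lambda[match(roles$abeta40, ids)]
  x_pt <- lam_pt * d + config$effect_tau * t_burden + ps * w_tau +
    rnorm(n, 0, bn)
  # The two amyloid peptides are co-secreted products of the same precursor:
  # dilution scales their concentrations identically, so their ratio is
  # dilution-free by construction.
  x42 <- lam40 * d - config$effect_amyloid * a + ps * w_amy + rnorm(n, 0, bn)
  x40 <- lam40 * d + ps * w_amy + rnorm(n, 0, bn)
  ptau181 <- 21.8 *
    2^(0.5 * (x_pt - quantile(x_pt, 1 - config$tau_prevalence, names = FALSE)))
  abeta42 <- 1400 * 2^(0.35 * x42)
  abeta40 <- 15000 * 2^(0.35 * x40)
  lr <- x42 - x40
  abeta_ratio <- 0.08 *
    2^(0.5 * (lr - quantile(lr, config$amyloid_prevalence, names = FALSE)))

  sev <- a + t_burden + 0.5 * rnorm(n)
  diagnosis <- cut(sev, quantile(sev, c(0, 0.32, 0.45, 0.68, 0.94, 1)),
                   labels = c("NC", "SCD", "MCI", "Dementia", "Other"),
                   include.lowest = TRUE)
  diagnosis <- as.character(diagnosis)

  if (config$lod_quantile > 0) {
    for (j in seq_len(p)) {
      cut_j <- quantile(values[, j], config$lod_quantile, names = FALSE)
      values[values[, j] < cut_j, j] <- NA_real_
    }
  }

  cohort <- data.frame(
    participant_id = participant_id,
    age = age, sex = sex, education = education, diagnosis = diagnosis,
    icv = icv, gm_volume = gm_volume, ventricle_volume = ventricle_volume,
    ptau181 = ptau181, abeta42 = abeta42, abeta40 = abeta40,
    abeta_ratio = abeta_ratio,
    tau_pet_suvr = tau_pet_suvr, amyloid_centiloid = amyloid_centiloid,
    add_conversion = add_conversion,
    stringsAsFactors = FALSE
  )

  panel <- paste0("panel_", ((seq_len(p) - 1L) %/% max(1L, ceiling(p / 4))) + 1L)
  names(panel) <- ids
  pm <- protein_matrix(values, panel = panel)

  truth <- structure(
    list(d = d, a = a, t = t_burden,
         lambda = lambda, beta_a = beta_a, beta_t = beta_t,
         cluster_label = cluster_label, roles = roles),
    class = "synthetic_truth")
  names(truth$d) <- names(truth$a) <- names(truth$t) <- participant_id
  names(truth$lambda) <- names(truth$beta_a) <- names(truth$beta_t) <- ids
  names(truth$cluster_label) <- ids

  structure(list(cohort = cohort, matrix = pm, truth = truth,
                 config = config),
            class = "csf_cohort")
}

#' Canned fixture configurations
#'
#' Three desk-scale study conditions used throughout the test suite:
#' `"null"` (no dilution loadings, no disease effects), `"dilution"` (planted
#' dilution structure, no disease), and `"dilution_disease"` (both). All three
#' use 400 participants, 150 proteins and 6 clusters of 25.
#'
#' @param name one of `"null"`, `"dilution"`, `"dilution_disease"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @export
fixture_config <- function(name = c("dilution_disease", "dilution", "null"),
                           seed = 1L, ...) {
  name <- match.arg(name)
  loadings <- c(1, 0.8, 0.6, 0.4, 0.2, 0.05)
  base <- list(
    n_participants = 400L, n_proteins = 150L, n_clusters = 6L,
    cluster_sizes = rep(25L, 6), loading_by_cluster = loadings,
    seed = seed
  )
  over <- switch(name,
    null = list(loading_by_cluster = rep(0, 6), loading_jitter_sd = 0,
                effect_amyloid = 0, effect_tau = 0,
                age_effect = 0, sex_effect = 0, ventricle_effect = 0),
    dilution = list(effect_amyloid = 0, effect_tau = 0),
    dilution_disease = list()
  )
  args <- utils::modifyList(base, over)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

#' Write the ground truth of a synthetic cohort as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- lapply(unclass(truth), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(payload, path, digits = 10, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
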