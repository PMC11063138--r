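#' Configure an end-to-end reference-protein pipeline run
#'
#' Bundles the simulation (or ingestion) settings, stage toggles, seeds for
#' every stochastic stage, and analysis parameters for [run_pipeline()].
#' Every stochastic stage has its own explicit seed so runs are exactly
#' reproducible.
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `cohort_path`/`matrix_path` are given.
#' @param cohort_path,matrix_path optional paths to ingest instead of
#'   simulating.
#' @param test_fraction held-out fraction for the train/test split.
#' @param max_missing detectability-filter threshold (strict `<`).
#' @param perplexity,K,merge_overrides embedding and clustering controls.
#' @param n_candidates number of top reference candidates carried forward.
#' @param folds,n_iter cross-validation folds and bootstrap iterations.
#' @param seeds named list of integer seeds: `split`, `folds`, `embedding`,
#'   `bootstrap`.
#' @param atn an [atn_config()].
#' @param stages named list of logical toggles: `embedding`, `reference`,
#'   `atn`, `associations`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cohort_path = NULL, matrix_path = NULL,
                            test_fraction = 0.2,
                            max_missing = 0.75,
                            perplexity = 30, K = 20, merge_overrides = NULL,
                            n_candidates = 3,
                            folds = 10, n_iter = 2000,
                            seeds = list(split = 101L, folds = 202L,
                                         embedding = 303L, bootstrap = 404L),
                            atn = atn_config(),
                            stages = list(embedding = TRUE, reference = TRUE,
                                          atn = TRUE, associations = TRUE)) {
  need <- c("split", "folds", "embedding", "bootstrap")
  miss <- setdiff(need, names(seeds))
  if (length(miss) > 0)
    stop("seeds must name every stochastic stage; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(sim = sim, cohort_path = cohort_path,
                 matrix_path = matrix_path,
                 test_fraction = test_fraction, max_missing = max_missing,
                 perplexity = perplexity, K = K,
                 merge_overrides = merge_overrides,
                 n_candidates = n_candidates, folds = folds, n_iter = n_iter,
                 seeds = lapply(seeds, as.integer), atn = atn,
                 stages = utils::modifyList(
                   list(embedding = TRUE, reference = TRUE, atn = TRUE,
                        associations = TRUE), stages)),
            class = "pipeline_config")
}

.stage_log <- function(name, ...) {
  message(sprintf("[%s] %s", name, sprintf(...)))
}

#' Run the reference-protein search and evaluation pipeline
#'
#' Executes the full sequence: simulate (or ingest) a cohort, filter
#' low-detectability proteins, split into training/test, fit standardization
#' on the training set only, compute the mean standardized CSF level, embed
#' and cluster the proteins, compute metric maps and the per-cluster AUC
#' summary, select reference candidates, evaluate the reference grid on
#' held-out data (plus the validation-only conversion model on the training
#' set), derive a reference-adjusted AT(N) boundary and its PET concordance,
#' and compute paired partial-correlation matrices. Results are written to
#' `outdir` as TSV tables plus a machine-readable `summary.json`; two runs
#' with the same configuration produce byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- config$seeds
  summary <- list(seeds = seeds)

  # --- simulate or ingest -------------------------------------------------
  truth <- NULL
  if (!is.null(config$cohort_path)) {
    .stage_log("ingest", "reading %s", config$cohort_path)
    cohort <- read_cohort(config$cohort_path)
    pm <- read_matrix(config$matrix_path)
  } else {
    .stage_log("simulate", "n = %d, p = %d, seed = %d",
               config$sim$n_participants, config$sim$n_proteins,
               config$sim$seed)
    gen <- generate_cohort(config$sim)
    cohort <- gen$cohort
    pm <- gen$matrix
    truth <- gen$truth
    write_cohort(cohort, file.path(outdir, "cohort.tsv"))
    write_matrix(pm, file.path(outdir, "matrix.tsv"))
    write_truth(truth, file.path(outdir, "truth.json"))
  }
  summary$n_participants <- nrow(cohort)
  summary$n_proteins_input <- ncol(pm$values)

  # --- detectability filter ----------------------------------------------
  pm <- detectability_filter(pm, config$max_missing)
  summary$n_proteins_retained <- ncol(pm$values)
  .stage_log("filter", "%d proteins retained (max_missing = %g)",
             ncol(pm$values), config$max_missing)

  # --- split --------------------------------------------------------------
  sp <- train_test_split(cohort, pm, config$test_fraction, seeds$split)
  summary$n_train <- nrow(sp$train$cohort)
  summary$n_test <- nrow(sp$test$cohort)
  .stage_log("split", "train %d / test %d (seed %d)",
             summary$n_train, summary$n_test, seeds$split)

  # --- standardization and mean level (fitted on training only) ----------
  std <- fit_standardization(sp$train$matrix)
  utils::write.table(std, file.path(outdir, "standardization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  z_train <- apply_standardization(std, sp$train$matrix)
  z_test <- apply_standardization(std, sp$test$matrix)
  lvl_train <- mean_csf_level(z_train)
  lvl_test <- mean_csf_level(z_test)
  utils::write.table(lvl_train, file.path(outdir, "mean_level_train.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$mean_level_train_mean <- mean(lvl_train$level, na.rm = TRUE)
  cv_model <- level_covariate_model(lvl_train, sp$train$cohort)
  summary$level_covariates <- stats::setNames(
    as.list(cv_model$beta), cv_model$term)

  # --- embedding + clustering --------------------------------------------
  clusters <- NULL
  if (config$stages$embedding) {
    .stage_log("embed", "t-SNE over %d proteins (seed %d)",
               ncol(z_train$values), seeds$embedding)
    coords <- embed_proteins(z_train, perplexity = config$perplexity,
                             seed = seeds$embedding)
    K <- min(config$K, nrow(coords))
    clusters <- cluster_embedding(coords, K = K, seed = seeds$embedding,
                                  merge_overrides = config$merge_overrides)
    utils::write.table(
      data.frame(protein_id = rownames(coords), coords,
                 cluster = clusters$labels[rownames(coords)]),
      file.path(outdir, "embedding.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_clusters <- clusters$K
  }

  # --- metric maps, cluster summary, candidate selection ------------------
  maps <- metric_maps(z_train, lvl_train, sp$train$cohort, config$atn,
                      folds = config$folds, fold_seed = seeds$folds)
  utils::write.table(maps, file.path(outdir, "metric_maps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  baseline <- attr(maps, "baseline_auc")
  summary$baseline_auc <- as.list(baseline)

  candidates <- NULL
  references <- list(none = NULL, mean_level = "mean_level")
  if (!is.null(clusters)) {
    cs <- cluster_auc_summary(clusters, maps)
    utils::write.table(cs, file.path(outdir, "cluster_auc_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    candidates <- select_candidates(clusters, maps,
                                    panel_ids = maps$protein_id)
    utils::write.table(candidates, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$selected_cluster <- attr(candidates, "cluster")
    top <- utils::head(candidates$protein_id, config$n_candidates)
    if (length(top) < config$n_candidates) {
      # pad from the nominated cluster, ranked by combined AUC as reference
      cl_ids <- names(clusters$labels)[
        clusters$labels == attr(candidates, "cluster")]
      extra <- setdiff(cl_ids, top)
      gains <- (maps$auc_as_reference_tau_model +
                  maps$auc_as_reference_abeta_model)[
                    match(extra, maps$protein_id)]
      extra <- extra[order(-gains)]
      top <- c(top, utils::head(extra, config$n_candidates - length(top)))
      .stage_log("select", "padded candidate list from cluster %d to %d",
                 attr(candidates, "cluster"), length(top))
    }
    summary$candidates <- as.list(top)
    .stage_log("select", "cluster %d, %d candidate(s): %s",
               attr(candidates, "cluster"), length(top),
               paste(top, collapse = ", "))
    if (config$stages$reference && length(top) > 0) {
      for (id in top) references[[id]] <- id
      if (length(top) >= 2) references$svd_composite <- top
    }
  }
  if (!config$stages$reference) references <- list(none = NULL)

  # --- reference evaluation grid ------------------------------------------
  specs <- list(model_spec("ptau_taupet"), model_spec("abeta_abpet"))
  grid <- suppressMessages(evaluate_reference_grid(
    specs, references, sp$train$cohort, z_train, lvl_train,
    scheme = "holdout",
    test_cohort = sp$test$cohort, test_zmat = z_test, test_level = lvl_test,
    folds = config$folds, n_iter = config$n_iter, seed = seeds$bootstrap,
    atn = config$atn))
  # validation-only conversion model, cross-validated on the training set
  grid_conv <- suppressMessages(evaluate_reference_grid(
    list(model_spec("ptau_addconv")), references, sp$train$cohort, z_train,
    lvl_train, scheme = "cv", folds = config$folds, n_iter = config$n_iter,
    seed = seeds$bootstrap, atn = config$atn))
  grid <- rbind(grid, grid_conv)
  utils::write.table(grid, file.path(outdir, "reference_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$reference_grid <- lapply(seq_len(nrow(grid)), function(i) {
    list(model = grid$model[i], reference = grid$reference[i],
         auc = grid$auc[i], p_vs_none = grid$p_vs_none[i])
  })

  # --- AT(N) concordance ---------------------------------------------------
  if (config$stages$atn && !is.null(candidates) &&
      nrow(candidates) > 0) {
    co <- sp$train$cohort
    ref_id <- candidates$protein_id[1]
    ref_z <- z_train$values[, ref_id]
    pet_t <- as.integer(co$tau_pet_suvr > config$atn$tau_pet_suvr_cutoff)
    bnd <- derive_adjusted_boundary(co$ptau181, ref_z, pet_t,
                                    config = config$atn)
    atn_adj <- atn_config(
      abeta_ratio_cutoff = config$atn$abeta_ratio_cutoff,
      ptau_cutoff_pgml = config$atn$ptau_cutoff_pgml,
      tau_pet_suvr_cutoff = config$atn$tau_pet_suvr_cutoff,
      amyloid_centiloid_cutoff = config$atn$amyloid_centiloid_cutoff,
      boundary_intercept = bnd$intercept, boundary_slope = bnd$slope)
    a_csf <- classify_A(co$abeta_ratio, config$atn)
    t_unadj <- classify_T_csf(co$ptau181, config = config$atn)
    t_adj <- classify_T_csf(co$ptau181, ref_z, atn_adj, adjusted = TRUE)
    t_pet <- classify_T_pet(co$tau_pet_suvr, config$atn)
    pet_groups <- atn_group(a_csf, t_pet)
    conc_unadj <- concordance(atn_group(a_csf, t_unadj), pet_groups)
    conc_adj <- concordance(atn_group(a_csf, t_adj), pet_groups)
    summary$atn <- list(
      reference = ref_id,
      boundary_intercept = bnd$intercept, boundary_slope = bnd$slope,
      accuracy_unadjusted = conc_unadj$accuracy,
      accuracy_adjusted = conc_adj$accuracy,
      a_neg_t_pos_unadjusted = sum(atn_group(a_csf, t_unadj) == "A-T+"),
      a_neg_t_pos_adjusted = sum(atn_group(a_csf, t_adj) == "A-T+"))
    .stage_log("atn", "concordance %.1f%% -> %.1f%%",
               100 * conc_unadj$accuracy, 100 * conc_adj$accuracy)
  }

  # --- association analyses ------------------------------------------------
  if (config$stages$associations && !is.null(candidates) &&
      nrow(candidates) > 0) {
    co <- sp$train$cohort
    ordv <- order_by_level_association(z_train, lvl_train, co)
    top_assoc <- utils::tail(ordv$protein_id, 8)
    ref_ids <- utils::head(candidates$protein_id, config$n_candidates)
    ref_vec <- if (length(ref_ids) >= 2)
      svd_composite(z_train$values[, ref_ids, drop = FALSE])
    else z_train$values[, ref_ids]
    stat <- stats::setNames(ordv$abs_beta, ordv$protein_id)
    pcm <- partial_correlation_matrix(
      z_train$values[, top_assoc, drop = FALSE],
      data.frame(age = co$age, sex = co$sex),
      reference = ref_vec, order_by = stat)
    utils::write.table(pcm$without,
                       file.path(outdir, "partial_cor_without.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(pcm$with, file.path(outdir, "partial_cor_with.tsv"),
                       sep = "\t", quote = FALSE)
    off <- upper.tri(pcm$without)
    summary$associations <- list(
      mean_abs_partial_cor_without = mean(abs(pcm$without[off])),
      mean_abs_partial_cor_with = mean(abs(pcm$with[off])))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       digits = 10, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
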