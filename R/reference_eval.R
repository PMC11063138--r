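#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted 1/2:
#' `AUC = U / (n_pos * n_neg)`.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 (or logical) outcome labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  ok <- !(is.na(scores) | is.na(labels))
  scores <- scores[ok]
  labels <- labels[ok]
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Specify a biomarker model
#'
#' The three logistic models of the pipeline: `ptau_taupet` (CSF P-tau181
#' predicting tau-PET positivity), `abeta_abpet` (CSF A-beta-42 predicting
#' amyloid-PET positivity), and `ptau_addconv` (CSF P-tau181 predicting
#' conversion to AD dementia). The name fixes the main predictor and outcome;
#' all models adjust for age and sex, and a reference covariate can be added
#' at evaluation time. The first two are search models; `ptau_addconv` is
#' validation-only.
#'
#' @param name one of `"ptau_taupet"`, `"abeta_abpet"`, `"ptau_addconv"`.
#' @param covariates cohort columns entering as covariates.
#' @param predictor_protein optional protein id underlying the main predictor;
#'   used to reject the degenerate reference-equals-predictor case.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("ptau_taupet", "abeta_abpet", "ptau_addconv"),
                       covariates = c("age", "sex"),
                       predictor_protein = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    ptau_taupet = list(predictor = "ptau181", outcome = "tau_pet_pos"),
    abeta_abpet = list(predictor = "abeta42", outcome = "amyloid_pet_pos"),
    ptau_addconv = list(predictor = "ptau181", outcome = "add_conversion"))
  structure(list(name = name, predictor = def$predictor,
                 outcome = def$outcome, covariates = covariates,
                 predictor_protein = predictor_protein),
            class = "model_spec")
}

# outcome labels implied by a model_spec
.spec_outcome <- function(spec, cohort, atn) {
  switch(spec$outcome,
    tau_pet_pos = as.integer(cohort$tau_pet_suvr > atn$tau_pet_suvr_cutoff),
    amyloid_pet_pos =
      as.integer(cohort$amyloid_centiloid > atn$amyloid_centiloid_cutoff),
    add_conversion = as.integer(cohort$add_conversion),
    stop("unknown outcome: ", spec$outcome))
}

# Resolve a reference descriptor to a per-participant numeric vector (or NULL).
# Descriptors: NULL/"none", "mean_level", a single protein id, a character
# vector of protein ids (first SVD component), or a numeric vector.
.resolve_reference <- function(reference, spec, zmat, level, n) {
  if (is.null(reference) || identical(reference, "none")) return(NULL)
  if (is.numeric(reference)) {
    if (length(reference) != n)
      stop("numeric reference must have one value per participant",
           call. = FALSE)
    return(reference)
  }
  if (identical(reference, "mean_level")) {
    if (is.null(level)) stop("mean_level reference requires 'level'",
                             call. = FALSE)
    return(level$level)
  }
  if (!is.character(reference))
    stop("unsupported reference descriptor", call. = FALSE)
  if (!is.null(spec$predictor_protein) &&
      spec$predictor_protein %in% reference)
    stop("degenerate model: reference equals the main predictor",
         call. = FALSE)
  if (is.null(zmat)) stop("protein reference requires 'zmat'", call. = FALSE)
  miss <- setdiff(reference, colnames(zmat$values))
  if (length(miss) > 0)
    stop("reference protein(s) not in matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(reference) == 1) return(zmat$values[, reference])
  svd_composite(zmat$values[, reference, drop = FALSE])
}

# model data for one spec + reference; listwise complete cases
.build_model_data <- function(spec, cohort, zmat = NULL, level = NULL,
                              reference = NULL, atn = atn_config()) {
  n <- nrow(cohort)
  y <- .spec_outcome(spec, cohort, atn)
  ref <- .resolve_reference(reference, spec, zmat, level, n)
  X <- data.frame(pred = cohort[[spec$predictor]])
  if (!is.null(ref)) X$ref <- ref
  for (cv in spec$covariates) X[[cv]] <- cohort[[cv]]
  keep <- stats::complete.cases(cbind(X, y))
  if (sum(!keep) > 0)
    message(sprintf("%s: %d incomplete case(s) dropped", spec$name,
                    sum(!keep)))
  list(X = as.matrix(X[keep, , drop = FALSE]), y = y[keep],
       participant_id = cohort$participant_id[keep])
}

# stratified-on-demand fold assignment: plain random folds first; if any
# training fold lacks a class, re-draw stratified by outcome
.make_folds <- function(y, k, seed) {
  n <- length(y)
  k <- min(k, n)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))
  ok <- all(vapply(seq_len(k), function(f) {
    yt <- y[fold_of != f]
    length(unique(yt)) == 2
  }, logical(1)))
  if (!ok) {
    fold_of <- integer(n)
    for (cls in unique(y)) {
      ix <- which(y == cls)
      fold_of[ix] <- sample(rep(seq_len(k), length.out = length(ix)))
    }
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

# unpenalized ML logistic fit; rank-deficient columns get zero weight
.logit_fit <- function(X, y) {
  Xd <- cbind(1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

.logit_predict <- function(cf, X) {
  as.numeric(stats::plogis(cbind(1, X) %*% cf))
}

# center/scale columns by training statistics (sd 0 guarded)
.fold_standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sc <- apply(Xtr, 2, sd)
  sc[sc <= 0] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sc, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sc, "/"))
}

# out-of-fold logistic AUC; X numeric matrix/data.frame, folds a list of
# test-index vectors
.cv_logistic_auc <- function(X, y, folds) {
  X <- as.matrix(X)
  oof <- rep(NA_real_, length(y))
  fold_auc <- rep(NA_real_, length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_along(y), te)
    std <- .fold_standardize(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    cf <- .logit_fit(std$tr, y[tr])
    oof[te] <- .logit_predict(cf, std$te)
    if (length(unique(y[te])) == 2) fold_auc[f] <- auc(oof[te], y[te])
  }
  list(auc = auc(oof, y), oof = oof, fold_auc = fold_auc)
}

#' Cross-validated AUC of a (reference-adjusted) biomarker model
#'
#' Fits `outcome ~ predictor + reference + age + sex` (reference omitted when
#' none) by unpenalized logistic regression with k-fold cross-validation;
#' out-of-fold predicted probabilities are pooled into a single AUC.
#' Predictors are standardized within training folds. Folds are re-drawn
#' stratified by outcome if a plain random draw leaves a training fold with
#' one class.
#'
#' @param spec a [model_spec()].
#' @param cohort participant table.
#' @param zmat standardized [protein_matrix()] (needed for protein
#'   references).
#' @param level a [mean_csf_level()] result (needed for the mean-level
#'   reference).
#' @param reference reference descriptor: `NULL`/`"none"`, `"mean_level"`, a
#'   protein id, several protein ids (first SVD component), or a numeric
#'   vector.
#' @param folds number of folds (default 10).
#' @param seed fold seed.
#' @param atn an [atn_config()] supplying PET positivity cutoffs.
#' @return A list of class `cv_auc`: `auc`, `fold_auc`, `scores`
#'   (out-of-fold probabilities), `y`, `participant_id`.
#' @export
cv_auc <- function(spec, cohort, zmat = NULL, level = NULL, reference = NULL,
                   folds = 10, seed = 1L, atn = atn_config()) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- .build_model_data(spec, cohort, zmat, level, reference, atn)
  fold_list <- .make_folds(dat$y, folds, seed)
  res <- .cv_logistic_auc(dat$X, dat$y, fold_list)
  structure(list(auc = res$auc, fold_auc = res$fold_auc, scores = res$oof,
                 y = dat$y, participant_id = dat$participant_id,
                 reference = reference, model = spec$name),
            class = "cv_auc")
}

#' Out-of-bag bootstrap evaluation
#'
#' Per iteration, the cohort is resampled with replacement to full size, the
#' model refit on the resample, and evaluated on the participants never
#' selected (on average a fraction `exp(-1) ~ 0.368`). Iterations whose
#' validation set lacks an outcome class are skipped and counted.
#'
#' @inheritParams cv_auc
#' @param n_iter bootstrap iterations (default 2000).
#' @param seed resampling seed; fixed seed reproduces the resamples exactly,
#'   so runs with different references share resamples and are paired.
#' @return A list of class `oob_eval`: `auc` (mean over iterations), `aucs`
#'   (per-iteration values, NA where skipped), `oob_fraction`, `n_skipped`.
#' @export
oob_bootstrap_eval <- function(spec, cohort, zmat = NULL, level = NULL,
                               reference = NULL, n_iter = 2000, seed = 1L,
                               atn = atn_config()) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- .build_model_data(spec, cohort, zmat, level, reference, atn)
  n <- length(dat$y)
  set.seed(seed)
  aucs <- rep(NA_real_, n_iter)
  oob_frac <- rep(NA_real_, n_iter)
  for (b in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- which(tabulate(idx, n) == 0L)
    oob_frac[b] <- length(oob) / n
    if (length(unique(dat$y[idx])) < 2 || length(unique(dat$y[oob])) < 2)
      next
    std <- .fold_standardize(dat$X[idx, , drop = FALSE],
                             dat$X[oob, , drop = FALSE])
    cf <- .logit_fit(std$tr, dat$y[idx])
    aucs[b] <- auc(.logit_predict(cf, std$te), dat$y[oob])
  }
  n_skipped <- sum(is.na(aucs))
  if (n_skipped > 0)
    message(sprintf("oob_bootstrap_eval: %d iteration(s) skipped", n_skipped))
  structure(list(auc = mean(aucs, na.rm = TRUE), aucs = aucs,
                 oob_fraction = mean(oob_frac), n_skipped = n_skipped,
                 reference = reference, model = spec$name),
            class = "oob_eval")
}

#' One-sided bootstrap ROC test
#'
#' Tests whether scores `b` discriminate better than scores `a` on the same
#' participants: participants are resampled with replacement, both AUCs are
#' recomputed, and `p = (k + 1) / (n_used + 1)` where `k` counts iterations
#' with `AUC(b) - AUC(a) <= 0`. The +1 small-sample correction keeps p away
#' from 0; identical score vectors give p = 1 by the `<= 0` convention.
#' Resamples with a single outcome class are skipped.
#'
#' @param scores_a,scores_b paired score vectors on identical participants.
#' @param labels 0/1 outcome labels.
#' @param n_iter bootstrap iterations (default 2000).
#' @param seed resampling seed.
#' @return One-sided p-value for "b better than a".
#' @export
bootstrap_roc_test <- function(scores_a, scores_b, labels, n_iter = 2000,
                               seed = 1L) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length", call. = FALSE)
  ok <- stats::complete.cases(scores_a, scores_b, labels)
  scores_a <- scores_a[ok]
  scores_b <- scores_b[ok]
  labels <- as.integer(labels[ok])
  n <- length(labels)
  set.seed(seed)
  k <- 0L
  used <- 0L
  for (b in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    yl <- labels[idx]
    s <- sum(yl)
    if (s == 0L || s == n) next
    used <- used + 1L
    if (auc(scores_b[idx], yl) - auc(scores_a[idx], yl) <= 0) k <- k + 1L
  }
  (k + 1) / (used + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' First-SVD-component composite of candidate references
#'
#' Column-standardizes the candidate block (complete cases), projects onto the
#' first right-singular direction, and fixes the sign so the composite
#' correlates positively with the candidates' mean. Rows with missing values
#' get a missing composite.
#'
#' @param x matrix or data.frame of candidate z-score columns.
#' @return Per-participant composite score.
#' @export
svd_composite <- function(x) {
  X <- as.matrix(x)
  if (ncol(X) < 1) stop("at least one candidate column required", call. = FALSE)
  cc <- stats::complete.cases(X)
  Xc <- X[cc, , drop = FALSE]
  sds <- apply(Xc, 2, sd)
  if (any(sds == 0))
    stop("zero-variance candidate column(s)", call. = FALSE)
  Xs <- scale(Xc)
  sv <- svd(Xs, nu = 0, nv = 1)
  score <- as.numeric(Xs %*% sv$v[, 1])
  if (stats::cor(score, rowMeans(Xs)) < 0) score <- -score
  out <- rep(NA_real_, nrow(X))
  out[cc] <- score
  out
}

#' Evaluate a grid of models and references
#'
#' Computes the AUC of every (model, reference) combination under one of
#' three schemes: `"cv"` (k-fold cross-validation), `"holdout"` (refit on the
#' full training data, evaluate once on a held-out set), `"oob"` (out-of-bag
#' bootstrap). Each with-reference row is compared against the no-reference
#' model and the mean-level reference with one-sided bootstrap ROC tests
#' (paired on the same participants; for `"oob"`, paired over shared
#' resamples), and all p-values are BH-adjusted within the grid.
#'
#' @param specs list of [model_spec()] objects.
#' @param references named list of reference descriptors (see [cv_auc()]);
#'   a `"none"` and a `"mean_level"` entry are added if absent.
#' @param cohort,zmat,level training data.
#' @param scheme evaluation scheme.
#' @param test_cohort,test_zmat,test_level held-out data (scheme
#'   `"holdout"`).
#' @param folds,n_iter,seed resampling controls.
#' @param atn an [atn_config()].
#' @return A data.frame of class `reference_eval_result`: one row per (model,
#'   reference) with `auc`, `n`, `p_vs_none`, `p_vs_mean_level` and their
#'   BH-adjusted `q_*` versions.
#' @export
evaluate_reference_grid <- function(specs, references, cohort, zmat = NULL,
                                    level = NULL,
                                    scheme = c("cv", "holdout", "oob"),
                                    test_cohort = NULL, test_zmat = NULL,
                                    test_level = NULL,
                                    folds = 10, n_iter = 2000, seed = 1L,
                                    atn = atn_config()) {
  scheme <- match.arg(scheme)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (!"none" %in% names(references))
    references <- c(list(none = NULL), references)
  has_ml <- any(vapply(references, identical, logical(1), "mean_level"))

  eval_one <- function(spec, ref) {
    if (scheme == "cv") {
      r <- cv_auc(spec, cohort, zmat, level, ref, folds = folds, seed = seed,
                  atn = atn)
      list(auc = r$auc, scores = r$scores, y = r$y, aucs = NULL)
    } else if (scheme == "holdout") {
      if (is.null(test_cohort))
        stop("holdout scheme requires test data", call. = FALSE)
      tr <- .build_model_data(spec, cohort, zmat, level, ref, atn)
      # the held-out reference must be computed with the training-fitted
      # standardization already applied upstream; descriptors are re-resolved
      # on the test tables
      te <- .build_model_data(spec, test_cohort, test_zmat, test_level, ref,
                              atn)
      std <- .fold_standardize(tr$X, te$X)
      cf <- .logit_fit(std$tr, tr$y)
      sc <- .logit_predict(cf, std$te)
      list(auc = auc(sc, te$y), scores = sc, y = te$y, aucs = NULL)
    } else {
      r <- oob_bootstrap_eval(spec, cohort, zmat, level, ref,
                              n_iter = n_iter, seed = seed, atn = atn)
      list(auc = r$auc, scores = NULL, y = NULL, aucs = r$aucs)
    }
  }

  rows <- list()
  for (spec in specs) {
    n_spec <- length(suppressMessages(
      .build_model_data(spec, cohort, zmat, level, NULL, atn))$y)
    base <- eval_one(spec, NULL)
    ml <- if (has_ml) eval_one(spec, "mean_level") else NULL
    per_ref <- lapply(references, function(ref) {
      if (is.null(ref)) return(base)
      if (identical(ref, "mean_level")) return(ml)
      eval_one(spec, ref)
    })
    paired_p <- function(res, other) {
      if (scheme == "oob") {
        d <- res$aucs - other$aucs
        d <- d[!is.na(d)]
        (sum(d <= 0) + 1) / (length(d) + 1)
      } else {
        bootstrap_roc_test(other$scores, res$scores, res$y,
                           n_iter = n_iter, seed = seed)
      }
    }
    for (nm in names(references)) {
      res <- per_ref[[nm]]
      is_none <- is.null(references[[nm]])
      is_ml <- identical(references[[nm]], "mean_level")
      rows[[length(rows) + 1L]] <- data.frame(
        model = spec$name, reference = nm, auc = res$auc,
        n = if (!is.null(res$y)) length(res$y) else n_spec,
        p_vs_none = if (is_none) NA_real_ else paired_p(res, base),
        p_vs_mean_level = if (is_none || is_ml || !has_ml) NA_real_ else
          paired_p(res, ml),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  all_p <- c(out$p_vs_none, out$p_vs_mean_level)
  all_q <- rep(NA_real_, length(all_p))
  all_q[!is.na(all_p)] <- bh_adjust(all_p[!is.na(all_p)])
  out$q_vs_none <- all_q[seq_len(nrow(out))]
  out$q_vs_mean_level <- all_q[nrow(out) + seq_len(nrow(out))]
  class(out) <- c("reference_eval_result", "data.frame")
  out
}

#' Select reference-protein candidates
#'
#' Applies the three-point selection rule: the protein (1) belongs to the
#' nominated cluster, (2) increases the AUC of both search models when used
#' as the reference, and (3) is measured in the validation panel. Survivors
#' are ranked by mean AUC gain across the two models (ties broken by id).
#'
#' @param clusters an [cluster_embedding()] result (or a named label vector).
#' @param maps a [metric_maps()] result (per-protein reference AUCs); its
#'   `baseline_auc` attribute supplies the no-reference AUCs unless
#'   `baseline` is given.
#' @param panel_ids protein ids measured in the validation cohort.
#' @param cluster the nominated cluster label; defaults to the cluster with
#'   the best mean AUC across the two models (via [cluster_auc_summary()]).
#' @param baseline optional named numeric `c(tau = , abeta = )` overriding the
#'   attribute.
#' @param min_cluster_size smallest cluster eligible for the automatic
#'   nomination (default 5); tiny clusters have unstable mean AUCs.
#' @return A data.frame of candidates: `protein_id`, `cluster`,
#'   `auc_tau`, `auc_abeta`, `gain`, ranked by decreasing gain; empty (with a
#'   warning) when the panel intersection is empty.
#' @export
select_candidates <- function(clusters, maps, panel_ids, cluster = NULL,
                              baseline = NULL, min_cluster_size = 5) {
  labels <- if (inherits(clusters, "embedding_clusters")) clusters$labels
            else clusters
  if (is.null(baseline)) baseline <- attr(maps, "baseline_auc")
  if (is.null(baseline) || !all(c("tau", "abeta") %in% names(baseline)))
    stop("baseline AUCs (tau, abeta) are required", call. = FALSE)
  if (is.null(cluster)) {
    if (!inherits(clusters, "embedding_clusters"))
      stop("cluster must be given when 'clusters' is a plain label vector",
           call. = FALSE)
    cs <- cluster_auc_summary(clusters, maps)
    eligible <- cs$n_proteins >= min_cluster_size
    if (!any(eligible)) eligible <- rep(TRUE, nrow(cs))
    cs <- cs[eligible, , drop = FALSE]
    cluster <- cs$cluster[which.max((cs$mean_auc_tau + cs$mean_auc_abeta) / 2)]
  }
  lab <- labels[maps$protein_id]
  in_panel <- maps$protein_id %in% panel_ids
  if (!any(in_panel)) warning("no protein overlaps the validation panel")
  keep <- !is.na(lab) & lab == cluster &
    maps$auc_as_reference_tau_model > baseline[["tau"]] &
    maps$auc_as_reference_abeta_model > baseline[["abeta"]] &
    in_panel
  out <- data.frame(
    protein_id = maps$protein_id[keep],
    cluster = unname(lab[keep]),
    auc_tau = maps$auc_as_reference_tau_model[keep],
    auc_abeta = maps$auc_as_reference_abeta_model[keep],
    stringsAsFactors = FALSE)
  out$gain <- (out$auc_tau - baseline[["tau"]] +
                 out$auc_abeta - baseline[["abeta"]]) / 2
  out <- out[order(-out$gain, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cluster") <- cluster
  attr(out, "baseline_auc") <- baseline
  out
}
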