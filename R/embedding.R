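# Exact (O(n^2)) t-SNE. Standard algorithm: per-point precision calibrated by
# binary search to a target perplexity, symmetrized affinities, gradient
# descent with early exaggeration, momentum and adaptive gains. Deterministic
# given the seed (PCA initialization plus seeded jitter).
.tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- D2[i, -i]
    for (k in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { w <- rep(1e-12, length(di)); sw <- sum(w) }
      H <- log(sw) + beta * sum(di * w) / sw
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / sw
  }
  P
}

.tsne <- function(X, perplexity = 30, seed = 1L, max_iter = 500,
                  eta = 200, exaggeration = 4, stop_lying = 100,
                  momentum_init = 0.5, momentum_final = 0.8,
                  mom_switch = 250) {
  n <- nrow(X)
  if (perplexity >= n)
    stop("perplexity must be smaller than the number of points", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  pc <- stats::prcomp(X, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  Y <- scale(pc, scale = FALSE)
  Y <- Y / max(stats::sd(as.vector(Y)), 1e-12) * 1e-4
  Y <- Y + matrix(rnorm(n * 2, sd = 1e-5), n, 2)

  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= stop_lying) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < mom_switch) momentum_init else momentum_final
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(X), c("dim1", "dim2"))
  Y
}

#' Embed proteins as points in participant space
#'
#' Each protein is one point whose coordinates are its standardized values
#' across participants; t-SNE reduces that high-dimensional space to two
#' dimensions so that similarly expressed proteins land close together.
#' Missing z-scores are imputed as 0 (the training mean) for the embedding
#' only, with the imputed count reported.
#'
#' @param standardized a [protein_matrix()] of z-scores.
#' @param perplexity t-SNE perplexity (default 30); must be smaller than the
#'   number of proteins.
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @param max_iter gradient-descent iterations.
#' @return A proteins x 2 matrix of coordinates, row-named by protein id.
#' @export
embed_proteins <- function(standardized, perplexity = 30, seed = 1L,
                           max_iter = 500) {
  stopifnot(inherits(standardized, "protein_matrix"))
  X <- t(standardized$values)
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    message(sprintf("embed_proteins: %d missing z-score(s) imputed as 0", n_imp))
    X[is.na(X)] <- 0
  }
  .tsne(X, perplexity = perplexity, seed = seed, max_iter = max_iter)
}

#' Cluster a protein embedding with K-means
#'
#' K-means on the 2-D embedding coordinates. The "semi-supervised" manual
#' adjustment of this kind of analysis (joining visually overlapping regions)
#' is operationalized as `merge_overrides`: an explicit, reproducible list of
#' label pairs to collapse, recorded in the result instead of interactive
#' tuning.
#'
#' @param coordinates proteins x 2 coordinate matrix (see [embed_proteins()]).
#' @param K number of clusters (default 20); must not exceed the number of
#'   proteins.
#' @param seed integer seed for the K-means initialization.
#' @param merge_overrides optional list of length-2 integer vectors; each pair
#'   of labels is merged. Labels are relabelled to a consecutive `1..K_eff`.
#' @param nstart K-means restarts.
#' @return An object of class `embedding_clusters`: list with `coordinates`,
#'   `labels` (named by protein id), `K` (effective count), `seed`,
#'   `merge_overrides`.
#' @export
cluster_embedding <- function(coordinates, K = 20, seed = 1L,
                              merge_overrides = NULL, nstart = 10) {
  coordinates <- as.matrix(coordinates)
  if (K > nrow(coordinates))
    stop("K must not exceed the number of proteins", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(coordinates, centers = K, nstart = nstart,
                      iter.max = 100)
  labels <- km$cluster
  if (!is.null(merge_overrides)) {
    parent <- seq_len(K)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (pr in merge_overrides) {
      pr <- as.integer(pr)
      if (length(pr) != 2 || any(!pr %in% seq_len(K)))
        stop("merge_overrides must be pairs of existing labels", call. = FALSE)
      parent[find(pr[2])] <- find(pr[1])
    }
    roots <- vapply(seq_len(K), find, integer(1))
    labels <- match(roots, sort(unique(roots)))[labels]
  } else {
    labels <- match(labels, sort(unique(labels)))
  }
  names(labels) <- rownames(coordinates)
  structure(list(coordinates = coordinates, labels = labels,
                 K = length(unique(labels)), seed = seed,
                 merge_overrides = merge_overrides),
            class = "embedding_clusters")
}

#' @export
print.embedding_clusters <- function(x, ...) {
  cat(sprintf("embedding_clusters: %d proteins in %d clusters (seed %d)\n",
              length(x$labels), x$K, x$seed))
  invisible(x)
}

.minmax <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("constant metric map; min-max scaled map set to all zero")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Metric maps for reference-protein nomination
#'
#' Computes, for every protein, the six criteria used to screen the embedding
#' for reference-protein regions: absolute standardized association (adjusted
#' for age and sex) with (1) the mean standardized CSF level and (2)
#' ventricular volume; absolute association with (3) P-tau181 and (4)
#' A-beta-42 among cognitively unimpaired A-beta-negative participants
#' (diagnosis NC/SCD with A-beta ratio at or above the positivity cutoff); and
#' the cross-validated AUC when the protein serves as the reference covariate
#' in (5) the P-tau181 to tau-PET model and (6) the A-beta-42 to amyloid-PET
#' model. Each map is also min-max scaled to \[0, 1\].
#'
#' The two AUC maps share one fold assignment (fixed by `fold_seed`) so
#' per-protein AUC differences are paired. Missing z-scores are imputed as 0
#' for these maps.
#'
#' @param standardized a [protein_matrix()] of z-scores.
#' @param level a [mean_csf_level()] result.
#' @param cohort participant table with biomarker, PET and volumetric columns.
#' @param atn an [atn_config()] providing the positivity cutoffs.
#' @param folds,fold_seed cross-validation folds for the AUC maps.
#' @return A data.frame of class `metric_maps`: `protein_id`, the six raw
#'   maps, and `scaled_*` versions. The no-reference baseline AUCs are in
#'   attribute `baseline_auc` (named `tau`, `abeta`).
#' @export
metric_maps <- function(standardized, level, cohort, atn = atn_config(),
                        folds = 10, fold_seed = 1L) {
  stopifnot(inherits(standardized, "protein_matrix"))
  z <- standardized$values
  co <- cohort[match(rownames(z), cohort$participant_id), , drop = FALSE]
  y <- level$level[match(rownames(z), level$participant_id)]
  covars <- data.frame(age = co$age, sex = co$sex)

  cu_abneg <- co$diagnosis %in% c("NC", "SCD") &
    !is.na(co$abeta_ratio) & co$abeta_ratio >= atn$abeta_ratio_cutoff
  if (!any(cu_abneg))
    stop("empty cognitively unimpaired A-beta-negative subset", call. = FALSE)

  p <- ncol(z)
  assoc <- function(target, subset = rep(TRUE, nrow(z))) {
    vapply(seq_len(p), function(j) {
      abs(.assoc_beta(z[subset, j], target[subset], covars[subset, ,
                                                           drop = FALSE])[["beta"]])
    }, numeric(1))
  }
  assoc_mean_level <- assoc(y)
  assoc_ventricle <- assoc(co$ventricle_volume)
  assoc_ptau <- assoc(co$ptau181, cu_abneg)
  assoc_abeta42 <- assoc(co$abeta42, cu_abneg)

  zi <- z
  zi[is.na(zi)] <- 0

  tau_y <- as.integer(co$tau_pet_suvr > atn$tau_pet_suvr_cutoff)
  ab_y <- as.integer(co$amyloid_centiloid > atn$amyloid_centiloid_cutoff)

  auc_map <- function(pred, yout) {
    keep <- !is.na(pred) & !is.na(yout) & !is.na(co$age) & !is.na(co$sex)
    fold_list <- .make_folds(yout[keep], folds, fold_seed)
    base <- .cv_logistic_auc(cbind(pred = pred[keep], covars[keep, ,
                                                             drop = FALSE]),
                             yout[keep], fold_list)$auc
    aucs <- vapply(seq_len(p), function(j) {
      X <- cbind(pred = pred[keep], ref = zi[keep, j],
                 covars[keep, , drop = FALSE])
      .cv_logistic_auc(X, yout[keep], fold_list)$auc
    }, numeric(1))
    list(baseline = base, aucs = aucs)
  }
  tau_res <- auc_map(co$ptau181, tau_y)
  ab_res <- auc_map(co$abeta42, ab_y)

  out <- data.frame(
    protein_id = standardized$protein_ids,
    assoc_mean_level = assoc_mean_level,
    assoc_ventricle = assoc_ventricle,
    assoc_ptau_cu_abneg = assoc_ptau,
    assoc_abeta42_cu_abneg = assoc_abeta42,
    auc_as_reference_tau_model = tau_res$aucs,
    auc_as_reference_abeta_model = ab_res$aucs,
    stringsAsFactors = FALSE
  )
  for (cl in names(out)[-1]) out[[paste0("scaled_", cl)]] <- .minmax(out[[cl]])
  attr(out, "baseline_auc") <- c(tau = tau_res$baseline,
                                 abeta = ab_res$baseline)
  class(out) <- c("metric_maps", "data.frame")
  out
}

#' Per-cluster summary of reference-model AUC
#'
#' Mean and SD, per embedding cluster, of the per-protein AUC obtained when
#' each cluster member serves as the reference in the two search models; the
#' no-reference baseline AUCs ride along as an attribute for comparison lines.
#'
#' @param clusters an [cluster_embedding()] result.
#' @param maps a [metric_maps()] result.
#' @return A data.frame with one row per cluster: `cluster`, `n_proteins`,
#'   `mean_auc_tau`, `sd_auc_tau`, `mean_auc_abeta`, `sd_auc_abeta`;
#'   attribute `baseline_auc` copied from `maps`.
#' @export
cluster_auc_summary <- function(clusters, maps) {
  stopifnot(inherits(clusters, "embedding_clusters"),
            inherits(maps, "metric_maps"))
  lab <- clusters$labels[maps$protein_id]
  if (anyNA(lab))
    stop("cluster labels do not cover all proteins in the metric maps",
         call. = FALSE)
  sd0 <- function(v) if (length(v) <= 1) 0 else sd(v)
  agg <- lapply(split(seq_along(lab), lab), function(ix) {
    data.frame(
      n_proteins = length(ix),
      mean_auc_tau = mean(maps$auc_as_reference_tau_model[ix]),
      sd_auc_tau = sd0(maps$auc_as_reference_tau_model[ix]),
      mean_auc_abeta = mean(maps$auc_as_reference_abeta_model[ix]),
      sd_auc_abeta = sd0(maps$auc_as_reference_abeta_model[ix])
    )
  })
  out <- cbind(cluster = as.integer(names(agg)), do.call(rbind, agg))
  rownames(out) <- NULL
  attr(out, "baseline_auc") <- attr(maps, "baseline_auc")
  out
}
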