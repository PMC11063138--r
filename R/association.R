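#' Partial Pearson correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression of each on the covariates (complete cases). With no covariates
#' this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame (or vector) of covariates.
#' @return Partial correlation coefficient; missing (with a warning) when a
#'   residual vector is constant.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 3) stop("too few complete cases", call. = FALSE)
    return(stats::cor(x[keep], y[keep]))
  }
  covariates <- as.data.frame(covariates)
  keep <- stats::complete.cases(x, y, covariates)
  if (sum(keep) < ncol(covariates) + 3)
    stop("too few complete cases for the covariate count", call. = FALSE)
  X <- stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
  rx <- stats::lm.fit(X, x[keep])$residuals
  ry <- stats::lm.fit(X, y[keep])$residuals
  tol_x <- 1e-10 * max(sd(x[keep]), 1)
  tol_y <- 1e-10 * max(sd(y[keep]), 1)
  if (sd(rx) <= tol_x || sd(ry) <= tol_y) {
    warning("constant residuals; partial correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Paired partial-correlation matrices with and without a reference
#'
#' Computes the matrix of pairwise partial Pearson correlations over a
#' protein set, always adjusting for the covariates (typically age and sex),
#' and again with the reference added to the covariate set. Observations are
#' listwise-complete across the whole block. Rows/columns can be ordered by a
#' supplied statistic (typically decreasing association with the mean
#' standardized CSF level).
#'
#' @param proteins numeric matrix of protein z-score columns (named).
#' @param covariates data.frame of covariates.
#' @param reference optional numeric vector (reference z-scores or composite).
#' @param order_by optional named numeric; columns are sorted by decreasing
#'   value of this statistic.
#' @return A list of class `partial_correlation_matrix` with `without` (and
#'   `with` when a reference is given), each a symmetric matrix with unit
#'   diagonal, plus `covariates` (names) and `n` used.
#' @export
partial_correlation_matrix <- function(proteins, covariates,
                                       reference = NULL, order_by = NULL) {
  P <- as.matrix(proteins)
  if (is.null(colnames(P))) stop("protein columns must be named", call. = FALSE)
  if (!is.null(order_by)) {
    ord <- order(-order_by[colnames(P)])
    P <- P[, ord, drop = FALSE]
  }
  covariates <- as.data.frame(covariates)
  blocks <- if (is.null(reference)) list(P, covariates)
            else list(P, covariates, reference)
  keep <- stats::complete.cases(do.call(cbind, lapply(blocks, as.data.frame)))
  n <- sum(keep)
  if (n < ncol(covariates) + 3 + !is.null(reference))
    stop("too few listwise-complete cases", call. = FALSE)

  pc_mat <- function(covdf) {
    X <- stats::model.matrix(~ ., data = covdf)
    R <- apply(P[keep, , drop = FALSE], 2,
               function(v) stats::lm.fit(X, v)$residuals)
    M <- stats::cor(R)
    diag(M) <- 1
    M
  }
  out <- list(without = pc_mat(covariates[keep, , drop = FALSE]))
  if (!is.null(reference)) {
    covref <- cbind(covariates[keep, , drop = FALSE],
                    .reference = reference[keep])
    out$with <- pc_mat(covref)
  }
  out$covariates <- names(covariates)
  out$n <- n
  class(out) <- "partial_correlation_matrix"
  out
}

#' ANCOVA comparison of biomarker levels across groups
#'
#' One-way ANCOVA: `protein ~ group + age + sex`. Reports per-group
#' covariate-adjusted means and SDs and all pairwise group contrasts (from
#' the model's pooled residual variance), BH-adjusted across the contrasts.
#'
#' @param values protein concentrations or z-scores.
#' @param group group labels (e.g. AT groups); at least 2 groups with n >= 3
#'   each.
#' @param age,sex covariates.
#' @return A list of class `group_comparison`: `groups` (data.frame with
#'   `group`, `n`, `adj_mean`, `adj_sd`), `contrasts` (data.frame with
#'   `group_a`, `group_b`, `estimate`, `se`, `p`, `q`), `n`.
#' @export
ancova_group_compare <- function(values, group, age, sex) {
  keep <- stats::complete.cases(values, group, age, sex)
  dat <- data.frame(y = values[keep], group = factor(group[keep]),
                    age = age[keep], sex = sex[keep])
  tab <- table(dat$group)
  if (length(tab) < 2) stop("at least two groups required", call. = FALSE)
  if (any(tab < 3)) stop("each group needs n >= 3", call. = FALSE)
  # cell-means coding: group coefficients are directly comparable
  fit <- stats::lm(y ~ 0 + group + age + sex, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("singular design in ANCOVA", call. = FALSE)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  gl <- levels(dat$group)
  gidx <- match(paste0("group", gl), names(cf))
  # covariate-adjusted values: remove age/sex effects around their means
  adj <- dat$y - cf["age"] * (dat$age - mean(dat$age)) -
    cf["sex"] * (dat$sex - mean(dat$sex))
  groups <- data.frame(
    group = gl,
    n = as.integer(tab[gl]),
    adj_mean = vapply(gl, function(g) mean(adj[dat$group == g]), numeric(1)),
    adj_sd = vapply(gl, function(g) sd(adj[dat$group == g]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(gl), 2)
  df_res <- fit$df.residual
  contrasts <- do.call(rbind, apply(pairs, 2, function(pr) {
    i <- gidx[pr[1]]; j <- gidx[pr[2]]
    est <- cf[i] - cf[j]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    data.frame(group_a = gl[pr[1]], group_b = gl[pr[2]],
               estimate = unname(est), se = unname(se),
               p = unname(2 * stats::pt(-abs(est / se), df_res)),
               stringsAsFactors = FALSE)
  }))
  contrasts$q <- bh_adjust(contrasts$p)
  structure(list(groups = groups, contrasts = contrasts, n = nrow(dat)),
            class = "group_comparison")
}

#' pQTL association with and without reference adjustment
#'
#' Linear model of a protein on a genotype dosage plus covariates, refit with
#' the reference added, returning both dosage coefficient sets. Attenuation
#' of the dosage coefficient on adding the reference indicates the variant
#' acts on the protein through the shared concentration factor rather than
#' directly.
#'
#' @param protein protein values (z-scores or NPX).
#' @param dosage genotype dosage in `{0, 1, 2}` (or continuous in \[0, 2\]).
#' @param covariates data.frame of covariates (e.g. age, sex, diagnosis,
#'   genetic principal components).
#' @param reference optional reference vector.
#' @return A data.frame with rows `without_reference` and (when given)
#'   `with_reference`: `beta`, `se`, `p`, `n` for the dosage term.
#' @export
pqtl_assoc <- function(protein, dosage, covariates, reference = NULL) {
  if (length(unique(stats::na.omit(dosage))) < 2)
    stop("monomorphic genotype", call. = FALSE)
  covariates <- as.data.frame(covariates)
  fit_one <- function(extra) {
    dat <- cbind(data.frame(protein = protein, dosage = dosage), covariates)
    if (!is.null(extra)) dat$.reference <- extra
    keep <- stats::complete.cases(dat)
    fit <- stats::lm(protein ~ ., data = dat[keep, , drop = FALSE])
    sm <- summary(fit)$coefficients
    data.frame(beta = sm["dosage", 1], se = sm["dosage", 2],
               p = sm["dosage", 4], n = sum(keep))
  }
  out <- fit_one(NULL)
  rownames(out) <- "without_reference"
  if (!is.null(reference)) {
    out <- rbind(out, with_reference = fit_one(reference))
  }
  out
}

#' Bootstrap enrichment test for a protein subset
#'
#' Compares per-feature mean proportions (e.g. cell-type expression fractions)
#' of a protein subset against random equal-size draws from the background.
#' Two-sided p-values count null draws at least as far from the null center as
#' the observed subset mean, with the (k+1)/(n+1) correction; BH adjustment
#' across features.
#'
#' @param subset_ids protein ids of the subset (strict subset of background).
#' @param background_ids background protein ids.
#' @param features numeric matrix of nonnegative per-protein proportions,
#'   rows named by protein id.
#' @param n_boot number of random draws (default 10000).
#' @param seed draw seed.
#' @return A data.frame: `feature`, `observed`, `null_mean`, `p`, `q`.
#' @export
bootstrap_enrichment_test <- function(subset_ids, background_ids, features,
                                      n_boot = 10000, seed = 1L) {
  feat <- as.matrix(features)
  if (is.null(rownames(feat))) stop("feature rows must be named", call. = FALSE)
  if (!all(subset_ids %in% background_ids))
    stop("subset must be contained in the background", call. = FALSE)
  k <- length(subset_ids)
  N <- length(background_ids)
  if (k == 0 || k >= N)
    stop("subset size must be in [1, background size - 1]", call. = FALSE)
  obs <- colMeans(feat[subset_ids, , drop = FALSE])
  set.seed(seed)
  null <- matrix(NA_real_, n_boot, ncol(feat))
  for (b in seq_len(n_boot)) {
    null[b, ] <- colMeans(feat[sample(background_ids, k), , drop = FALSE])
  }
  center <- colMeans(null)
  p <- vapply(seq_len(ncol(feat)), function(f) {
    (sum(abs(null[, f] - center[f]) >= abs(obs[f] - center[f])) + 1) /
      (n_boot + 1)
  }, numeric(1))
  data.frame(feature = colnames(feat), observed = unname(obs),
             null_mean = unname(center), p = p, q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
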