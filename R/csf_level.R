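#' Fit a per-protein standardization model on training data
#'
#' Stores each protein's location (mean) and scale (sample SD, ddof = 1) over
#' the non-missing training values. Standardization is always fitted on
#' training participants and then applied unchanged to any other data, so no
#' information leaks from test sets.
#'
#' @param train a [protein_matrix()] of training participants.
#' @return An object of class `standardization_model`: a data.frame with
#'   `protein_id`, `location`, `scale`.
#' @export
fit_standardization <- function(train) {
  stopifnot(inherits(train, "protein_matrix"))
  v <- train$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2))
    stop(sprintf("fewer than 2 non-missing training values for: %s",
                 paste(train$protein_ids[n_obs < 2], collapse = ", ")),
         call. = FALSE)
  loc <- colMeans(v, na.rm = TRUE)
  sc <- apply(v, 2, sd, na.rm = TRUE)
  if (any(sc == 0))
    stop(sprintf("zero-variance protein(s): %s",
                 paste(train$protein_ids[sc == 0], collapse = ", ")),
         call. = FALSE)
  structure(
    data.frame(protein_id = train$protein_ids, location = unname(loc),
               scale = unname(sc), stringsAsFactors = FALSE),
    class = c("standardization_model", "data.frame"))
}

#' Apply a standardization model
#'
#' Elementwise `(value - location) / scale` per protein; missing values stay
#' missing. Every protein in `matrix` must be covered by the model.
#'
#' @param model a [fit_standardization()] result.
#' @param matrix a [protein_matrix()].
#' @return A [protein_matrix()] of z-scores.
#' @export
apply_standardization <- function(model, matrix) {
  stopifnot(inherits(model, "standardization_model"),
            inherits(matrix, "protein_matrix"))
  idx <- match(matrix$protein_ids, model$protein_id)
  if (anyNA(idx))
    stop(sprintf("proteins not covered by the standardization model: %s",
                 paste(matrix$protein_ids[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  z <- sweep(matrix$values, 2, model$location[idx], "-")
  z <- sweep(z, 2, model$scale[idx], "/")
  protein_matrix(z, matrix$protein_ids, matrix$panel)
}

#' Mean standardized CSF protein level
#'
#' For each participant, the average z-score over all contributing
#' (non-missing) proteins:
#' `y_i = (1 / n_proteins) * sum_j z_ij`.
#' This scalar summarizes non-disease inter-individual differences in overall
#' CSF protein concentration. Missing z-scores are excluded from the average
#' (count-weighted mean) rather than imputed; participants with no
#' contributing proteins get a missing level with a warning.
#'
#' @param standardized a [protein_matrix()] of z-scores (see
#'   [apply_standardization()]).
#' @return A data.frame of class `mean_csf_level` with `participant_id`,
#'   `level`, `n_contributing`; the panel size used is in attribute
#'   `n_proteins`.
#' @export
mean_csf_level <- function(standardized) {
  stopifnot(inherits(standardized, "protein_matrix"))
  z <- standardized$values
  n_contrib <- rowSums(!is.na(z))
  y <- rowMeans(z, na.rm = TRUE)
  if (any(n_contrib == 0)) {
    warning(sprintf("%d participant(s) with no contributing proteins",
                    sum(n_contrib == 0)))
    y[n_contrib == 0] <- NA_real_
  }
  out <- data.frame(participant_id = rownames(z), level = unname(y),
                    n_contributing = unname(n_contrib),
                    stringsAsFactors = FALSE)
  attr(out, "n_proteins") <- ncol(z)
  class(out) <- c("mean_csf_level", "data.frame")
  out
}

# Standardized coefficient of `predictor` in lm(response ~ predictor + covars)
# on complete cases; response, predictor and continuous covariates are
# z-scored, binary covariates left as coded. Returns c(beta, se, p, n).
.assoc_beta <- function(response, predictor, covars) {
  dat <- cbind(response = response, predictor = predictor, covars)
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  if (n < ncol(dat) + 2) return(c(beta = NA, se = NA, p = NA, n = n))
  zcol <- function(v) {
    if (length(unique(v)) <= 2) return(v)
    s <- sd(v)
    if (s == 0) v else (v - mean(v)) / s
  }
  X <- cbind(1, vapply(dat[, -1, drop = FALSE], zcol, numeric(n)))
  yv <- zcol(dat$response)
  fit <- stats::lm.fit(X, yv)
  df_res <- n - fit$rank
  sigma2 <- sum(fit$residuals^2) / df_res
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  Rm <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  vc <- chol2inv(Rm) * sigma2
  se_all <- rep(NA_real_, ncol(X))
  se_all[piv] <- sqrt(diag(vc))
  beta <- fit$coefficients[2]
  se2 <- se_all[2]
  p <- 2 * stats::pt(-abs(beta / se2), df_res)
  c(beta = unname(beta), se = unname(se2), p = unname(p), n = n)
}

#' Order proteins by association with the mean standardized CSF level
#'
#' For each protein, the absolute standardized coefficient of its z-score on
#' the mean standardized CSF level, adjusted for age and sex; proteins are
#' returned sorted by increasing `abs_beta` (ties broken by protein id).
#'
#' @param standardized a [protein_matrix()] of z-scores.
#' @param level a [mean_csf_level()] result aligned to the same participants.
#' @param cohort participant table providing `age` and `sex`.
#' @return A data.frame with `protein_id`, `beta`, `abs_beta`, sorted
#'   ascending.
#' @export
order_by_level_association <- function(standardized, level, cohort) {
  stopifnot(inherits(standardized, "protein_matrix"))
  z <- standardized$values
  y <- level$level[match(rownames(z), level$participant_id)]
  co <- cohort[match(rownames(z), cohort$participant_id), , drop = FALSE]
  covars <- data.frame(y = y, age = co$age, sex = co$sex)
  res <- t(vapply(seq_len(ncol(z)), function(j) {
    .assoc_beta(z[, j], covars$y,
                data.frame(age = covars$age, sex = covars$sex))
  }, numeric(4)))
  out <- data.frame(protein_id = standardized$protein_ids,
                    beta = res[, "beta"], abs_beta = abs(res[, "beta"]),
                    stringsAsFactors = FALSE)
  out[order(out$abs_beta, out$protein_id), , drop = FALSE]
}

#' Covariate model for the mean standardized CSF level
#'
#' Multiple linear regression of the (standardized) mean CSF level on age,
#' sex, education and brain volumetrics, with continuous terms z-scored so
#' coefficients are standardized. Listwise deletion on the included terms,
#' with the dropped count reported.
#'
#' @param level a [mean_csf_level()] result.
#' @param cohort participant table.
#' @param terms covariates to include (cohort column names).
#' @return A data.frame of class `association_result` with `term`, `beta`,
#'   `se`, `p`.
#' @export
level_covariate_model <- function(level, cohort,
                                  terms = c("age", "sex", "education", "icv",
                                            "gm_volume", "ventricle_volume")) {
  co <- cohort[match(level$participant_id, cohort$participant_id), ,
               drop = FALSE]
  .require_columns(co, terms, "cohort table")
  dat <- data.frame(y = level$level, co[, terms, drop = FALSE])
  keep <- stats::complete.cases(dat)
  if (sum(!keep) > 0)
    message(sprintf("level_covariate_model: %d incomplete case(s) dropped",
                    sum(!keep)))
  dat <- dat[keep, , drop = FALSE]
  zcol <- function(v) {
    if (length(unique(v)) <= 2) return(v)
    (v - mean(v)) / sd(v)
  }
  dat[] <- lapply(dat, zcol)
  X <- stats::model.matrix(~ ., data = dat[, terms, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("collinear design; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  out <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                    p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(dat)
  attr(out, "model") <- paste("level ~", paste(terms, collapse = " + "))
  class(out) <- c("association_result", "data.frame")
  out
}
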