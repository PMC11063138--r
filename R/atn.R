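#' AT(N) classification configuration
#'
#' Cutoffs for amyloid (A) and tau (T) positivity by CSF and PET, plus the
#' parameters of the reference-adjusted linear T boundary. Defaults are the
#' established clinical values: A+ when CSF A-beta-42/A-beta-40 < 0.08; T+
#' when CSF P-tau181 > 21.8 pg/ml (unadjusted) or, with reference adjustment,
#' when P-tau181 exceeds `boundary_intercept + boundary_slope * reference_z`
#' (default 39.0 + 10.1 z); tau-PET positive when Braak I-IV SUVR > 1.36;
#' amyloid-PET positive when centiloid > 20.
#'
#' @param abeta_ratio_cutoff A-beta-42/40 ratio cutoff (A+ strictly below).
#' @param ptau_cutoff_pgml unadjusted CSF P-tau181 cutoff, pg/ml (T+ strictly
#'   above).
#' @param tau_pet_suvr_cutoff tau-PET SUVR cutoff (strictly above).
#' @param amyloid_centiloid_cutoff amyloid-PET centiloid cutoff (strictly
#'   above).
#' @param boundary_intercept,boundary_slope reference-adjusted T boundary:
#'   intercept in pg/ml, slope in pg/ml per reference z-unit.
#' @return An object of class `atn_config`.
#' @export
atn_config <- function(abeta_ratio_cutoff = 0.08,
                       ptau_cutoff_pgml = 21.8,
                       tau_pet_suvr_cutoff = 1.36,
                       amyloid_centiloid_cutoff = 20,
                       boundary_intercept = 39.0,
                       boundary_slope = 10.1) {
  cfg <- list(abeta_ratio_cutoff = abeta_ratio_cutoff,
              ptau_cutoff_pgml = ptau_cutoff_pgml,
              tau_pet_suvr_cutoff = tau_pet_suvr_cutoff,
              amyloid_centiloid_cutoff = amyloid_centiloid_cutoff,
              boundary_intercept = boundary_intercept,
              boundary_slope = boundary_slope)
  for (f in c("abeta_ratio_cutoff", "ptau_cutoff_pgml",
              "tau_pet_suvr_cutoff", "amyloid_centiloid_cutoff"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("atn_config: '%s' must be positive", f), call. = FALSE)
  structure(cfg, class = "atn_config")
}

.pm_label <- function(pos, neg_lab, pos_lab) {
  out <- ifelse(pos, pos_lab, neg_lab)
  out[is.na(pos)] <- NA_character_
  out
}

#' Amyloid and tau positivity labels
#'
#' `classify_A()` labels A+ when the CSF A-beta-42/40 ratio is strictly below
#' the cutoff; `classify_T_csf()` labels T+ when CSF P-tau181 exceeds the
#' unadjusted cutoff or, with `adjusted = TRUE`, the reference-adjusted linear
#' boundary `intercept + slope * reference_z`. `classify_T_pet()` and
#' `classify_A_pet()` use strict `>` comparisons on SUVR and centiloid.
#' Missing inputs give missing labels.
#'
#' @param abeta_ratio CSF A-beta-42/40 ratio (positive).
#' @param config an [atn_config()].
#' @return Character vector of labels (`"A+"`/`"A-"` or `"T+"`/`"T-"`).
#' @export
classify_A <- function(abeta_ratio, config = atn_config()) {
  .pm_label(abeta_ratio < config$abeta_ratio_cutoff, "A-", "A+")
}

#' @rdname classify_A
#' @param ptau CSF P-tau181 in pg/ml.
#' @param reference_z reference-protein z-scores (required when `adjusted`).
#' @param adjusted use the reference-adjusted boundary?
#' @export
classify_T_csf <- function(ptau, reference_z = NULL, config = atn_config(),
                           adjusted = FALSE) {
  if (adjusted) {
    if (is.null(reference_z))
      stop("adjusted classification requires reference_z", call. = FALSE)
    thr <- config$boundary_intercept + config$boundary_slope * reference_z
  } else {
    thr <- config$ptau_cutoff_pgml
  }
  .pm_label(ptau > thr, "T-", "T+")
}

#' @rdname classify_A
#' @param suvr tau-PET Braak I-IV composite SUVR.
#' @export
classify_T_pet <- function(suvr, config = atn_config()) {
  .pm_label(suvr > config$tau_pet_suvr_cutoff, "T-", "T+")
}

#' @rdname classify_A
#' @param centiloid amyloid-PET centiloid value.
#' @export
classify_A_pet <- function(centiloid, config = atn_config()) {
  .pm_label(centiloid > config$amyloid_centiloid_cutoff, "A-", "A+")
}

#' Combine A and T labels into AT groups
#'
#' @param a_label,t_label labels from the `classify_*` functions.
#' @return Character vector in `{"A-T-", "A-T+", "A+T-", "A+T+"}`.
#' @export
atn_group <- function(a_label, t_label) {
  out <- paste0(a_label, t_label)
  out[is.na(a_label) | is.na(t_label)] <- NA_character_
  out
}

#' Derive a reference-adjusted T boundary from a logistic model
#'
#' Fits `pet_positive ~ ptau + reference_z` by logistic regression and returns
#' the straight line of constant predicted probability as a P-tau181 cutoff
#' that depends linearly on the reference: `ptau > a + b * reference_z`. The
#' operating point is chosen by `rule`: `"prob_half"` (default) uses the
#' standard 0.5-predicted-probability decision boundary of the logistic
#' model; `"match_specificity"` places the line so its specificity on the
#' derivation set equals that of the unadjusted pg/ml cutoff; `"youden"`
#' maximizes sensitivity + specificity.
#'
#' @param ptau CSF P-tau181 in pg/ml.
#' @param reference_z reference-protein z-scores.
#' @param pet_positive 0/1 tau-PET positivity labels.
#' @param rule operating rule.
#' @param config an [atn_config()] (supplies the unadjusted cutoff for
#'   `"match_specificity"`).
#' @return A list of class `adjusted_boundary`: `intercept` (a, pg/ml),
#'   `slope` (b, pg/ml per z-unit), `threshold_prob` (the operating predicted
#'   probability), and the fitted coefficients. A warning (not an error) is
#'   issued when the P-tau181 coefficient is not significant.
#' @export
derive_adjusted_boundary <- function(ptau, reference_z, pet_positive,
                                     rule = c("prob_half",
                                              "match_specificity", "youden"),
                                     config = atn_config()) {
  rule <- match.arg(rule)
  keep <- stats::complete.cases(ptau, reference_z, pet_positive)
  ptau <- ptau[keep]
  reference_z <- reference_z[keep]
  y <- as.integer(pet_positive[keep])
  if (length(unique(y)) < 2)
    stop("both PET classes must be present", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ptau + reference_z, family = stats::binomial()))
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  if ("ptau" %in% rownames(sm) && sm["ptau", 4] > 0.05)
    warning("P-tau181 coefficient not significant; boundary still returned")
  if (is.na(cf["reference_z"])) cf["reference_z"] <- 0
  if (!is.finite(cf["ptau"]) || cf["ptau"] == 0)
    stop("degenerate fit: zero P-tau181 coefficient", call. = FALSE)
  score <- cf[1] + cf["ptau"] * ptau + cf["reference_z"] * reference_z
  thr_logit <- switch(rule,
    match_specificity = {
      spec_unadj <- mean(ptau[y == 0] <= config$ptau_cutoff_pgml)
      quantile(score[y == 0], spec_unadj, names = FALSE)
    },
    prob_half = 0,
    youden = {
      cand <- sort(unique(score))
      cuts <- c(cand - 1e-9, max(cand) + 1e-9)
      j <- vapply(cuts, function(ct) {
        mean(score[y == 1] > ct) + mean(score[y == 0] <= ct) - 1
      }, numeric(1))
      cuts[which.max(j)]
    })
  a <- (thr_logit - cf[1]) / cf["ptau"]
  b <- -cf["reference_z"] / cf["ptau"]
  structure(list(intercept = unname(a), slope = unname(b),
                 threshold_prob = unname(stats::plogis(thr_logit)),
                 coefficients = cf, rule = rule, n = length(y)),
            class = "adjusted_boundary")
}

#' @export
print.adjusted_boundary <- function(x, ...) {
  cat(sprintf(
    "adjusted T boundary: P-tau181 > %.1f + %.1f * reference_z (%s, n = %d)\n",
    x$intercept, x$slope, x$rule, x$n))
  invisible(x)
}

#' Concordance of CSF- and PET-based AT grouping
#'
#' Cross-tabulates paired AT group labels (CSF rows, PET columns) over the
#' four groups and reports accuracy = trace / n.
#'
#' @param csf_labels,pet_labels paired labels in
#'   `{"A-T-", "A-T+", "A+T-", "A+T+"}`, no missing values.
#' @return An object of class `concordance_matrix`: `counts` (4 x 4),
#'   `accuracy`, `n`.
#' @export
concordance <- function(csf_labels, pet_labels) {
  groups <- c("A-T-", "A-T+", "A+T-", "A+T+")
  if (length(csf_labels) != length(pet_labels))
    stop("label vectors must be paired", call. = FALSE)
  if (anyNA(csf_labels) || anyNA(pet_labels))
    stop("labels must not be missing", call. = FALSE)
  bad <- setdiff(unique(c(csf_labels, pet_labels)), groups)
  if (length(bad) > 0)
    stop("labels outside the four AT groups: ",
         paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(csf_labels, groups), factor(pet_labels, groups))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("csf", "pet")
  structure(list(counts = counts,
                 accuracy = sum(diag(counts)) / length(csf_labels),
                 n = length(csf_labels)),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("AT concordance (CSF rows vs PET columns), accuracy %.1f%%:\n",
              100 * x$accuracy))
  print(x$counts)
  invisible(x)
}
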