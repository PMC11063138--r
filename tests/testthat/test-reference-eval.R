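test_that("auc equals exhaustive pairwise counting on random instances", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_pairwise(scores, labels),
                 tolerance = 1e-10)
  }
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(rnorm(5), rep(1, 5)), "both outcome classes")
})

test_that("auc agrees with an independent ROC implementation", {
  set.seed(1)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.3)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("cross-validated AUC behaves at the extremes and is reproducible", {
  g <- fixture_cohort()
  fs <- fixture_standardized()
  spec <- model_spec("ptau_taupet")
  r1 <- cv_auc(spec, g$cohort, fs$z, fs$level, seed = 3)
  r2 <- cv_auc(spec, g$cohort, fs$z, fs$level, seed = 3)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$scores, r2$scores)
  # a monotone perfectly separating predictor gives AUC 1
  co <- g$cohort
  co$ptau181 <- co$tau_pet_suvr * 10 + 5
  # age/sex stay in the model, so saturation can leave a borderline pair
  expect_gte(cv_auc(spec, co, seed = 1)$auc, 0.999)
  # permuted outcomes give chance performance
  aucs <- vapply(1:3, function(s) {
    co2 <- g$cohort
    set.seed(s)
    co2$tau_pet_suvr <- sample(co2$tau_pet_suvr)
    cv_auc(spec, co2, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("out-of-bag bootstrap leaves the expected fraction unselected", {
  g <- fixture_cohort()
  spec <- model_spec("ptau_taupet")
  r <- oob_bootstrap_eval(spec, g$cohort, n_iter = 100, seed = 2)
  expect_lt(abs(r$oob_fraction - exp(-1)), 0.02)
  r2 <- oob_bootstrap_eval(spec, g$cohort, n_iter = 100, seed = 2)
  expect_identical(r$aucs, r2$aucs)
  # perfectly separating predictor: every iteration AUC is 1
  co <- g$cohort
  co$ptau181 <- co$tau_pet_suvr * 3
  rp <- oob_bootstrap_eval(spec, co, n_iter = 50, seed = 2)
  expect_gte(min(rp$aucs, na.rm = TRUE), 0.98)
  expect_gte(mean(rp$aucs, na.rm = TRUE), 0.999)
})

test_that("bootstrap ROC test follows its stated conventions", {
  set.seed(5)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  s <- rnorm(n) + y
  expect_equal(bootstrap_roc_test(s, s, y, n_iter = 200, seed = 1), 1)
  expect_error(bootstrap_roc_test(s[-1], s, y), "equal length")
  # a planted large improvement is detected in most seeds
  det <- vapply(1:10, function(sd) {
    set.seed(sd)
    sig <- rnorm(400)
    y2 <- rbinom(400, 1, plogis(2 * sig))
    worse <- sig + 2.5 * rnorm(400)
    better <- sig + 0.4 * rnorm(400)
    bootstrap_roc_test(worse, better, y2, n_iter = 300, seed = sd) < 0.05
  }, logical(1))
  expect_gte(sum(det), 9)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("SVD composite reduces to its inputs in the degenerate cases", {
  set.seed(2)
  z1 <- as.numeric(scale(rnorm(50)))
  expect_equal(svd_composite(cbind(a = z1)), z1, tolerance = 1e-10)
  two <- cbind(a = z1, b = z1)
  comp <- svd_composite(two)
  expect_equal(cor(comp, z1), 1, tolerance = 1e-10)
  expect_error(svd_composite(cbind(a = rep(1, 10))), "zero-variance")
})

test_that("SVD composite matches an eigen-decomposition oracle up to the sign rule", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4) + rnorm(50)
  colnames(X) <- letters[1:4]
  comp <- svd_composite(X)
  Xs <- scale(X)
  ev <- eigen(crossprod(Xs))$vectors[, 1]
  oracle <- as.numeric(Xs %*% ev)
  if (cor(oracle, rowMeans(Xs)) < 0) oracle <- -oracle
  expect_equal(comp, oracle, tolerance = 1e-8)
  # negating one input column leaves the composite invariant up to sign rule
  X2 <- X
  X2[, 2] <- -X2[, 2]
  expect_equal(abs(cor(svd_composite(X2), comp)), 1, tolerance = 1e-8)
})

test_that("dilution-loaded references improve the tau model over no reference", {
  g <- fixture_cohort()
  fs <- fixture_standardized()
  refs <- list(ref_a = g$truth$roles$reference[3],
               ref_b = g$truth$roles$reference[4],
               composite = g$truth$roles$reference[3:7])
  grid <- suppressMessages(evaluate_reference_grid(
    model_spec("ptau_taupet"), refs, g$cohort, fs$z, fs$level,
    scheme = "cv", folds = 10, n_iter = 200, seed = 9))
  base_auc <- grid$auc[grid$reference == "none"]
  with_ref <- grid[!grid$reference %in% "none", ]
  expect_true(all(with_ref$auc > base_auc))
  expect_true(all(grid$q_vs_none >= grid$p_vs_none, na.rm = TRUE))
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))
})

test_that("a pathway-sharing reference outperforms the mean level on average", {
  diffs <- vapply(1:5, function(s) {
    g <- fixture_cohort(seed = s)
    std <- fit_standardization(g$matrix)
    z <- apply_standardization(std, g$matrix)
    lvl <- mean_csf_level(z)
    spec <- model_spec("ptau_taupet")
    cv_auc(spec, g$cohort, z, lvl, g$truth$roles$ptau_reference,
           seed = 5)$auc -
      cv_auc(spec, g$cohort, z, lvl, "mean_level", seed = 5)$auc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the degenerate reference-equals-predictor model is rejected", {
  g <- fixture_cohort()
  fs <- fixture_standardized()
  spec <- model_spec("ptau_taupet",
                     predictor_protein = g$truth$roles$ptau181)
  expect_error(cv_auc(spec, g$cohort, fs$z, fs$level,
                      reference = g$truth$roles$ptau181),
               "degenerate")
})

test_that("AUC-gain from adjustment is monotone in the dilution loading", {
  # controlled two-model comparison: identical disease signal and noise,
  # only the biomarker's dilution loading differs
  gain_at <- function(lam, seed) {
    set.seed(seed)
    n <- 500
    d <- rnorm(n, 0, 1.8)
    t <- rnorm(n)
    y <- as.integer(t + 0.3 * rnorm(n) > quantile(t, 0.7))
    pred <- lam * d + 1.8 * t + 0.5 * rnorm(n)
    ref <- d + 0.5 * rnorm(n)
    co <- data.frame(participant_id = as.character(1:n),
                     age = rnorm(n, 68, 10), sex = rbinom(n, 1, 0.5),
                     ptau181 = pred,
                     tau_pet_suvr = 1.36 + (y - 0.5))
    spec <- model_spec("ptau_taupet")
    suppressMessages(
      cv_auc(spec, co, reference = ref, seed = seed)$auc -
        cv_auc(spec, co, seed = seed)$auc)
  }
  for (pair in list(c(1.2, 0.6), c(0.9, 0.3), c(1.5, 0.9))) {
    gains <- rowMeans(vapply(1:4, function(s)
      c(gain_at(pair[1], s), gain_at(pair[2], s)), numeric(2)))
    expect_gt(gains[1], gains[2])
  }
})

test_that("candidate selection applies the three criteria and ranks by gain", {
  maps <- data.frame(
    protein_id = paste0("p", 1:5),
    auc_as_reference_tau_model = c(0.90, 0.80, 0.88, 0.93, 0.91),
    auc_as_reference_abeta_model = c(0.95, 0.96, 0.91, 0.97, 0.96),
    stringsAsFactors = FALSE)
  class(maps) <- c("metric_maps", "data.frame")
  labels <- setNames(c(1, 1, 2, 1, 1), maps$protein_id)
  baseline <- c(tau = 0.85, abeta = 0.92)
  # p1: in cluster, gains, in panel -> keep; p2: tau below baseline;
  # p3: wrong cluster; p4: not in panel; p5: keep
  cand <- select_candidates(labels, maps, panel_ids = c("p1", "p2", "p3", "p5"),
                            cluster = 1, baseline = baseline)
  expect_identical(cand$protein_id, c("p5", "p1"))
  expect_true(all(diff(cand$gain) <= 0))
  expect_warning(
    empty <- select_candidates(labels, maps, panel_ids = character(0),
                               cluster = 1, baseline = baseline),
    "panel")
  expect_equal(nrow(empty), 0)
})
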