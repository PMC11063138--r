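make_pm <- function(v) {
  if (is.null(dimnames(v)))
    dimnames(v) <- list(sprintf("s%03d", seq_len(nrow(v))),
                        sprintf("p%03d", seq_len(ncol(v))))
  protein_matrix(v)
}

test_that("standardization uses training mean and sample SD", {
  pm <- make_pm(matrix(c(1, 3, 10, 20), 2, 2))
  m <- fit_standardization(pm)
  expect_equal(m$location, c(2, 15))
  expect_equal(m$scale, c(sqrt(2), sd(c(10, 20))))
  # train {1,3}, test value 5 -> (5 - 2)/sqrt(2)
  test_pm <- make_pm(matrix(c(5, 15), 1, 2))
  z <- apply_standardization(m, test_pm)
  expect_equal(z$values[1, 1], 3 / sqrt(2), tolerance = 1e-12)
})

test_that("standardized training data has mean 0 and SD 1 per protein", {
  g <- fixture_cohort("dilution", seed = 5)
  m <- fit_standardization(g$matrix)
  z <- apply_standardization(m, g$matrix)
  expect_true(all(abs(colMeans(z$values)) < 1e-10))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-10))
})

test_that("degenerate proteins are rejected with ids named", {
  v <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("s%02d", 1:10), c("ok", "flat")))
  v[, 2] <- 7
  expect_error(fit_standardization(protein_matrix(v)), "flat")
  v[, 2] <- c(1, rep(NA, 9))
  expect_error(fit_standardization(protein_matrix(v)), "flat")
})

test_that("standardization is invariant to affine transforms and rejects unknown proteins", {
  set.seed(1)
  v <- matrix(rnorm(60), 20, 3)
  pm <- make_pm(v)
  pm2 <- make_pm(sweep(sweep(v, 2, c(2, 3, 0.5), "*"), 2, c(1, -4, 10), "+"))
  z1 <- apply_standardization(fit_standardization(pm), pm)
  z2 <- apply_standardization(fit_standardization(pm2), pm2)
  expect_equal(z1$values, z2$values, tolerance = 1e-10)
  odd <- make_pm(matrix(rnorm(20), 10, 2))
  colnames(odd$values) <- odd$protein_ids <- c("p001", "novel")
  expect_error(apply_standardization(fit_standardization(pm), odd), "novel")
})

test_that("mean standardized level averages contributing z-scores", {
  z <- make_pm(matrix(c(1, 0, 1, 2, 1, -2), 2, 3))
  lvl <- mean_csf_level(z)
  expect_equal(lvl$level, c(1, 0))
  expect_equal(lvl$n_contributing, c(3L, 3L))
  # all z equal to c gives c
  zc <- make_pm(matrix(0.7, 4, 5))
  expect_equal(mean_csf_level(zc)$level, rep(0.7, 4))
  # zero contributing proteins: missing with warning
  v <- matrix(rnorm(8), 2, 4)
  v[2, ] <- NA
  expect_warning(lvl2 <- mean_csf_level(make_pm(v)), "no contributing")
  expect_true(is.na(lvl2$level[2]))
  expect_equal(lvl2$level[1], mean(v[1, ]))
})

test_that("mean level equals the explicit loop implementation (oracle)", {
  set.seed(42)
  for (k in 1:5) {
    v <- matrix(rnorm(12 * 7), 12, 7)
    v[sample(length(v), 10)] <- NA
    lvl <- suppressWarnings(mean_csf_level(make_pm(v)))
    expect_equal(lvl$level, mean_level_loop(v), tolerance = 1e-12)
  }
})

test_that("training-population mean of the level is zero when complete", {
  fs <- fixture_standardized("dilution", 5)
  expect_lt(abs(mean(fs$level$level)), 1e-10)
})

test_that("a protein identical to the level ranks last in the level ordering", {
  fs <- fixture_standardized("dilution", 5)
  z <- fs$z
  zv <- z$values
  zv <- cbind(zv, self = as.numeric(scale(fs$level$level)))
  colnames(zv)[ncol(zv)] <- "self_level"
  zpm <- protein_matrix(zv)
  ord <- order_by_level_association(zpm, fs$level, fs$g$cohort)
  expect_identical(ord$protein_id[nrow(ord)], "self_level")
  expect_setequal(ord$protein_id, zpm$protein_ids)
})

test_that("level from a protein subset correlates highly with the full-panel level", {
  fs <- fixture_standardized("dilution", 5)
  set.seed(3)
  sub <- sample(fs$z$protein_ids, 50)
  z_sub <- apply_standardization(fs$model,
                                 protein_matrix(fs$g$matrix$values[, sub]))
  lvl_sub <- mean_csf_level(z_sub)
  expect_gt(cor(lvl_sub$level, fs$level$level), 0.9)
})

test_that("covariate model recovers the planted sign pattern", {
  fs <- fixture_standardized("dilution", 5)
  res <- level_covariate_model(fs$level, fs$g$cohort)
  beta <- setNames(res$beta, res$term)
  expect_gt(beta[["age"]], 0)
  expect_gt(beta[["sex"]], 0)
  expect_lt(beta[["ventricle_volume"]], 0)
  expect_lt(res$p[res$term == "age"], 0.05)
  expect_lt(res$p[res$term == "ventricle_volume"], 0.01)
})

test_that("covariate model: null covariates give small effects, unit changes do not matter", {
  g <- fixture_cohort("null", seed = 2)
  fs <- fit_standardization(g$matrix)
  lvl <- mean_csf_level(apply_standardization(fs, g$matrix))
  res <- level_covariate_model(lvl, g$cohort)
  # no planted effects: every coefficient is within sampling error of zero
  expect_true(all(abs(res$beta) < 4 * res$se))
  # rescaling a covariate leaves its standardized coefficient unchanged
  co2 <- g$cohort
  co2$icv <- co2$icv * 1000
  res2 <- level_covariate_model(lvl, co2)
  expect_equal(res2$beta[res2$term == "icv"],
               res$beta[res$term == "icv"], tolerance = 1e-10)
})

test_that("collinear designs are rejected with the aliased term named", {
  g <- fixture_cohort("dilution", seed = 5)
  fs <- fit_standardization(g$matrix)
  lvl <- mean_csf_level(apply_standardization(fs, g$matrix))
  co <- g$cohort
  co$gm_volume <- co$icv   # exact alias after z-scoring
  expect_error(level_covariate_model(lvl, co), "gm_volume|icv")
})
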