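test_that("partial correlation reduces to plain Pearson and removes shared covariates", {
  set.seed(4)
  x <- rnorm(100)
  y <- 0.5 * x + rnorm(100)
  expect_equal(partial_correlation(x, y), cor(x, y), tolerance = 1e-12)
  cov1 <- rnorm(100)
  expect_equal(partial_correlation(x, x, data.frame(c1 = cov1)), 1,
               tolerance = 1e-10)
  # x and y related only through a covariate: coefficient goes to 0
  set.seed(5)
  n <- 4000
  zc <- rnorm(n)
  x2 <- zc + rnorm(n)
  y2 <- zc + rnorm(n)
  expect_gt(cor(x2, y2), 0.4)
  expect_lt(abs(partial_correlation(x2, y2, data.frame(z = zc))), 0.05)
  expect_warning(
    out <- partial_correlation(cov1, rnorm(100), data.frame(c1 = cov1)),
    "constant")
  expect_true(is.na(out))
})

test_that("residual method equals the precision-matrix formula (two oracles)", {
  set.seed(6)
  for (k in 1:20) {
    n <- sample(30:120, 1)
    ncov <- sample(1:3, 1)
    covs <- matrix(rnorm(n * ncov), n, ncov)
    x <- covs %*% runif(ncov) + rnorm(n)
    y <- covs %*% runif(ncov) + rnorm(n)
    got <- partial_correlation(as.numeric(x), as.numeric(y),
                               as.data.frame(covs))
    expect_equal(got, pcor_precision(x, y, covs), tolerance = 1e-10)
  }
})

test_that("paired matrices are symmetric with unit diagonal; dilution correlations attenuate", {
  g <- fixture_cohort()
  fs <- fixture_standardized()
  tr <- g$truth
  ref <- svd_composite(fs$z$values[, tr$roles$reference[3:7]])
  covs <- data.frame(age = g$cohort$age, sex = g$cohort$sex)
  dil <- fs$z$values[, tr$roles$reference[8:9]]
  dis <- fs$z$values[, c(tr$roles$ptau181, tr$roles$tau_partner)]
  pcm_dil <- partial_correlation_matrix(dil, covs, reference = ref)
  pcm_dis <- partial_correlation_matrix(dis, covs, reference = ref)
  for (m in list(pcm_dil$without, pcm_dil$with, pcm_dis$with)) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 2))
    expect_true(all(m >= -1 & m <= 1))
  }
  # dilution-driven pair: large unadjusted, near the planted zero adjusted
  expect_gt(pcm_dil$without[1, 2], 0.5)
  expect_lt(abs(pcm_dil$with[1, 2]), 0.3)
  # disease-driven pair persists
  expect_gt(pcm_dis$with[1, 2], 0.4)
  expect_gt(pcm_dis$with[1, 2], 0.5 * pcm_dis$without[1, 2])
})

test_that("an independent-noise covariate barely moves coefficients", {
  set.seed(8)
  n <- 2000
  f <- rnorm(n)
  x <- f + rnorm(n)
  y <- f + rnorm(n)
  covs <- data.frame(age = rnorm(n))
  base <- partial_correlation(x, y, covs)
  covs$junk <- rnorm(n)
  expect_lt(abs(partial_correlation(x, y, covs) - base), 0.05)
})

test_that("ANCOVA group comparison is calibrated under the null and powered under a shift", {
  set.seed(9)
  rejections <- vapply(1:300, function(k) {
    n <- 120
    grp <- rep(c("g1", "g2", "g3"), each = n / 3)
    age <- rnorm(n, 65, 8)
    sex <- rbinom(n, 1, 0.5)
    vals <- 0.02 * age + 0.1 * sex + rnorm(n)
    res <- ancova_group_compare(vals, grp, age, sex)
    min(res$contrasts$p) < 0.05 / 1  # smallest raw pairwise p
  }, logical(1))
  # three correlated contrasts: family-wise rate above 5% but bounded
  expect_lt(mean(rejections), 0.18)
  expect_gt(mean(rejections), 0.02)
  # planted 1 SD shift: detected after BH essentially always
  hits <- vapply(1:20, function(k) {
    set.seed(100 + k)
    n <- 200
    grp <- rep(c("g1", "g2"), each = 100)
    age <- rnorm(n, 65, 8)
    sex <- rbinom(n, 1, 0.5)
    vals <- rnorm(n) + (grp == "g2")
    res <- ancova_group_compare(vals, grp, age, sex)
    all(res$contrasts$q < 0.05)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("ANCOVA validates its inputs and reports adjusted means", {
  set.seed(10)
  n <- 90
  grp <- rep(c("a", "b", "c"), each = 30)
  age <- rnorm(n, 70, 5)
  sex <- rbinom(n, 1, 0.5)
  vals <- 2 * (grp == "b") + 0.05 * age + rnorm(n)
  res <- ancova_group_compare(vals, grp, age, sex)
  expect_equal(nrow(res$contrasts), 3)
  expect_gt(res$groups$adj_mean[res$groups$group == "b"],
            res$groups$adj_mean[res$groups$group == "a"] + 1)
  expect_error(ancova_group_compare(vals, rep("a", n), age, sex),
               "two groups")
  expect_error(ancova_group_compare(vals[1:5], c("a", "a", "a", "b", "b"),
                                    age[1:5], sex[1:5]), "n >= 3")
})

test_that("pQTL associations attenuate only when the variant acts through dilution", {
  set.seed(12)
  n <- 1500
  maf <- 0.3
  dosage <- rbinom(n, 2, maf)
  covs <- data.frame(age = rnorm(n, 68, 10), sex = rbinom(n, 1, 0.5))
  d <- 0.5 * dosage + rnorm(n)          # variant shifts the dilution factor
  ref <- d + 0.3 * rnorm(n)             # good dilution proxy
  prot_indirect <- d + 0.5 * rnorm(n)
  res_i <- pqtl_assoc(prot_indirect, dosage, covs, reference = ref)
  expect_lt(abs(res_i["with_reference", "beta"]),
            0.4 * abs(res_i["without_reference", "beta"]))
  # direct effect independent of dilution is preserved
  prot_direct <- 0.5 * dosage + rnorm(n) + d * 0
  res_d <- pqtl_assoc(prot_direct, dosage, covs, reference = ref)
  expect_gt(abs(res_d["with_reference", "beta"]),
            0.8 * abs(res_d["without_reference", "beta"]))
  expect_lt(abs(res_d["with_reference", "beta"] - 0.5), 0.1)
  # null variant
  prot_null <- rnorm(n)
  res_n <- pqtl_assoc(prot_null, dosage, covs, reference = ref)
  expect_lt(abs(res_n["without_reference", "beta"]), 0.1)
  expect_error(pqtl_assoc(prot_null, rep(1, n), covs), "monomorphic")
})

test_that("bootstrap enrichment detects a planted shift and respects the draw space", {
  set.seed(13)
  nprot <- 200
  feat <- matrix(runif(nprot * 3, 0, 0.5), nprot, 3,
                 dimnames = list(sprintf("pr%03d", 1:nprot),
                                 c("f1", "f2", "f3")))
  subset_ids <- rownames(feat)[1:25]
  feat[subset_ids, 2] <- feat[subset_ids, 2] + 3 * sd(feat[, 2])
  res <- bootstrap_enrichment_test(subset_ids, rownames(feat), feat,
                                   n_boot = 1000, seed = 3)
  expect_lt(res$q[res$feature == "f2"], 0.05)
  expect_gt(min(res$p), 0)
  # near-degenerate draw space: subset = background minus one element
  # near-degenerate draw space (draws differ by one protein): the statistic
  # reduces to the rank of the excluded protein, so p is roughly uniform and
  # nothing survives adjustment
  feat0 <- matrix(runif(nprot * 3, 0, 0.5), nprot, 3,
                  dimnames = dimnames(feat))
  res2 <- bootstrap_enrichment_test(rownames(feat0)[-1], rownames(feat0),
                                    feat0, n_boot = 200, seed = 3)
  expect_true(all(res2$q > 0.05))
  expect_gt(min(res2$p), 1 / 201)
  expect_error(bootstrap_enrichment_test(rownames(feat), rownames(feat), feat),
               "subset size")
  expect_error(bootstrap_enrichment_test("nope", rownames(feat), feat),
               "contained")
})
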