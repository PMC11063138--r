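# Shared fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_cohort <- function(name = "dilution_disease", seed = 7L, ...) {
  if (...length() > 0) {
    # overridden conditions are not cached
    return(generate_cohort(fixture_config(name, seed = seed, ...)))
  }
  key <- paste0("cohort_", name, "_", seed)
  cached(key, generate_cohort(fixture_config(name, seed = seed)))
}

# standardized matrix + mean level for a fixture, fitted on all participants
fixture_standardized <- function(name = "dilution_disease", seed = 7L) {
  key <- paste0("std_", name, "_", seed)
  cached(key, {
    g <- fixture_cohort(name, seed)
    std <- fit_standardization(g$matrix)
    z <- apply_standardization(std, g$matrix)
    list(g = g, model = std, z = z, level = mean_csf_level(z))
  })
}

# metric maps are the most expensive fixture; computed once
fixture_maps <- function(seed = 7L) {
  cached(paste0("maps_", seed), {
    fs <- fixture_standardized("dilution_disease", seed)
    metric_maps(fs$z, fs$level, fs$g$cohort, folds = 10, fold_seed = 2L)
  })
}

# brute-force oracles -------------------------------------------------------

# AUC by exhaustive pairwise comparison with ties counted 1/2
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# BH step-up from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# partial correlation via the precision matrix of (x, y, covariates)
pcor_precision <- function(x, y, covs) {
  m <- cbind(x, y, covs)
  pm <- solve(stats::cov(m))
  -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
}

# Eq-style mean standardized level by explicit loops
mean_level_loop <- function(z) {
  n <- nrow(z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    k <- 0
    for (j in seq_len(ncol(z))) {
      if (!is.na(z[i, j])) {
        s <- s + z[i, j]
        k <- k + 1
      }
    }
    out[i] <- if (k > 0) s / k else NA_real_
  }
  out
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
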