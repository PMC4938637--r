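# Synthetic-data generator: genotypes, phenotypes, field trials.

test_that("simulated genotypes are valid, deterministic, and honour the missing rate", {
  g1 <- simulate_genotypes(80, 400, n_groups = 3, divergence = 0.2,
                           missing_rate = 0.1, seed = 42)
  g2 <- simulate_genotypes(80, 400, n_groups = 3, divergence = 0.2,
                           missing_rate = 0.1, seed = 42)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$group_labels, g2$group_labels)
  vals <- g1$dosage[!is.na(g1$dosage)]
  expect_true(all(vals %in% c(0, 1, 2)))
  expect_false(anyDuplicated(g1$accession_ids) > 0)
  # observed missingness within +-2 percentage points at p = 1000
  g3 <- simulate_genotypes(100, 1000, missing_rate = 0.1, seed = 7)
  expect_lt(abs(mean(is.na(g3$dosage)) - 0.1), 0.02)
  expect_error(simulate_genotypes(0, 10), "n_accessions")
  expect_error(simulate_genotypes(10, 10, missing_rate = 1), "missing_rate")
  expect_error(simulate_genotypes(10, 10, divergence = 1), "divergence")
})

test_that("group divergence creates GRM structure that separates true labels", {
  qq <- quick_grm(200, 1000, seed = 7, n_groups = 5, divergence = 0.3)
  dec <- eigen_grm(qq$grm, k = 5)
  lab <- qq$geno$group_labels
  # mean silhouette of the truth labels in the 5-eigenvector space > 0
  X <- dec$vectors
  Dm <- as.matrix(dist(X))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(Dm[i, lab == lab[i]][-1])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(gl) mean(Dm[i, lab == gl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("divergence 0 leaves group labels uninformative about the GRM", {
  # permutation test on between- vs within-group mean relationship
  hits <- vapply(1:10, function(s) {
    qq <- quick_grm(60, 300, seed = 100 + s, n_groups = 3, divergence = 0)
    G <- qq$grm$matrix
    lab <- qq$geno$group_labels
    same <- outer(lab, lab, "==") & upper.tri(G)
    stat <- mean(G[same]) - mean(G[!same & upper.tri(G)])
    perm <- vapply(1:99, function(b) {
      pl <- sample(lab)
      ps <- outer(pl, pl, "==") & upper.tri(G)
      mean(G[ps]) - mean(G[!ps & upper.tri(G)])
    }, numeric(1))
    mean(abs(perm) >= abs(stat)) >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("phenotype terms realize their requested variances", {
  g <- simulate_genotypes(600, 800, seed = 3)
  vc <- c(E = 0.6, A = 0.1, G = 0.5, AxE = 0.1, GxE = 0.3, resid = 0.2)
  sim <- simulate_phenotypes(g, vc, n_envs = 2, seed = 9)
  gv <- sim$truth$true_genetic_values
  n <- nrow(gv)
  # main genomic variance = covariance of the two env columns; +-3 SE
  se_g <- sqrt(2 / n) * vc["G"] * 2    # generous MC band
  expect_lt(abs(cov(gv[, 1], gv[, 2]) - vc["G"]), 3 * se_g)
  # per-env total genetic variance ~ G + GxE
  expect_lt(abs(var(gv[, 1]) - (vc["G"] + vc["GxE"])), 3 * sqrt(2 / n) * 0.8 * 2)
  expect_lt(abs(var(sim$truth$accession_effects) - vc["A"]), 3 * sqrt(2 / n) * vc["A"] * 2)
})

test_that("noiseless single-environment phenotypes equal mu + genetic value", {
  g <- simulate_genotypes(40, 200, seed = 5)
  sim <- simulate_phenotypes(g, c(E = 0, A = 0, G = 1, AxE = 0, GxE = 0, resid = 0),
                             n_envs = 1, mu = 3, seed = 6)
  expect_equal(sim$trait$value,
               3 + sim$truth$true_genetic_values[sim$trait$accession, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero genetic variance gives predictions uncorrelated with phenotype", {
  g <- simulate_genotypes(150, 300, seed = 11)
  G <- compute_grm(prepare_markers(g, maf_min = 0.02))
  sim <- simulate_phenotypes(g, c(E = 0, A = 0, G = 0, AxE = 0, GxE = 0, resid = 1),
                             n_envs = 1, seed = 12)
  spec <- model_spec("SE-GBLUP", method = "fixed", components = c(G = 0.2, resid = 0.8))
  parts <- make_partitions(g$accession_ids, "random-single-env", 0.5, 3, seed = 2)
  rep <- evaluate(sim$trait, G, spec, parts)
  expect_lt(abs(rep$mean), 3 / sqrt(75))
})

test_that("field trials carry the requested AR1xAR1 spatial signal", {
  g <- simulate_genotypes(1540, 20, seed = 21)
  sim <- simulate_phenotypes(g, c(E = 0, A = 0, G = 0.2, AxE = 0, GxE = 0, resid = 0.1),
                             n_envs = 1, seed = 22)
  # sigma_spatial = 0: raw values equal inputs exactly
  tr0 <- simulate_field_trial(sim$trait, 40, 40, 0.6, 0.4, sigma_spatial = 0, seed = 23)
  expect_equal(tr0$value, attr(tr0, "truth")$base, tolerance = 1e-12)
  # checks appear in >= 2 rows and columns
  expect_gte(length(unique(tr0$row[tr0$is_check])), 2)
  expect_gte(length(unique(tr0$col[tr0$is_check])), 2)
  expect_false(anyDuplicated(tr0[, c("row", "col")]) > 0)
  # lag-1 autocorrelation of the surface near truth
  lag1 <- function(trial, dir = c("row", "col")) {
    dir <- match.arg(dir)
    s <- attr(trial, "truth")$surface
    M <- matrix(NA_real_, max(trial$row), max(trial$col))
    M[cbind(trial$row, trial$col)] <- s
    if (dir == "row") cor(as.vector(M[-1, ]), as.vector(M[-nrow(M), ]))
    else cor(as.vector(M[, -1]), as.vector(M[, -ncol(M)]))
  }
  tr1 <- simulate_field_trial(sim$trait, 40, 40, 0, 0, sigma_spatial = 1, seed = 24)
  expect_lt(abs(lag1(tr1, "row")), 0.1)
  expect_lt(abs(lag1(tr1, "col")), 0.1)
  tr2 <- simulate_field_trial(sim$trait, 40, 40, 0.6, 0.4, sigma_spatial = 1, seed = 25)
  expect_lt(abs(lag1(tr2, "row") - 0.6), 0.1)
  expect_lt(abs(lag1(tr2, "col") - 0.4), 0.1)
})
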