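# Core selection: MRD, diversity cores, reliability, prediction cores,
# diversity indices.

test_that("modified Rogers distances match hand values and a brute-force loop", {
  # identical accessions; opposite fixation; single heterozygous difference
  g <- toy_geno(rbind(c(0, 0, 0), c(0, 0, 0), c(2, 2, 2)))
  D <- mrd_matrix(g)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  g1 <- toy_geno(rbind(0, 1))
  expect_equal(mrd_matrix(g1)[1, 2], 0.5)
  # brute force at n = 30
  qq <- quick_grm(30, 80, seed = 61)
  D2 <- mrd_matrix(qq$geno)
  X <- qq$geno$dosage / 2
  m <- ncol(X)
  BF <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30)
    BF[i, j] <- sqrt(sum(2 * (X[i, ] - X[j, ])^2) / (2 * m))
  expect_lt(max(abs(unname(D2) - BF)), 1e-10)
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_equal(unname(diag(D2)), rep(0, 30))
  # triangle inequality on sampled triples
  set.seed(1)
  for (b in 1:50) {
    ijk <- sample(30, 3)
    expect_lte(D2[ijk[1], ijk[2]],
               D2[ijk[1], ijk[3]] + D2[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("diversity cores maximize candidate mean MRD and represent all clusters", {
  qq <- quick_grm(150, 300, seed = 62, n_groups = 5, divergence = 0.3)
  core <- diversity_core(qq$geno, 0.2, n_candidates = 200, seed = 63)
  expect_equal(length(core$selected_ids), 30)
  expect_false(anyDuplicated(core$selected_ids) > 0)
  # argmax by construction (exact)
  expect_equal(core$diagnostics$best_mean_mrd, max(core$diagnostics$candidate_means))
  D <- mrd_matrix(qq$geno)
  idx <- match(core$selected_ids, qq$geno$accession_ids)
  expect_equal(sum(D[idx, idx]) / (30 * 29), core$diagnostics$best_mean_mrd,
               tolerance = 1e-12)
  expect_true(all(core$diagnostics$allocation >= 1))
  # order invariance: permuting accessions, same ids selected
  oa <- sample(150)
  gperm <- new_genotypes(qq$geno$dosage[oa, ], qq$geno$accession_ids[oa],
                         qq$geno$marker_ids)
  core2 <- diversity_core(gperm, 0.2, n_candidates = 200, seed = 63)
  expect_setequal(core2$selected_ids, core$selected_ids)
  # both fractions give the announced sizes
  core10 <- diversity_core(qq$geno, 0.1, n_candidates = 50, seed = 64)
  expect_equal(length(core10$selected_ids), 15)
})

test_that("diversity cores beat simple random subsets of equal size", {
  wins <- vapply(1:5, function(s) {
    qq <- quick_grm(120, 200, seed = 70 + s, n_groups = 5, divergence = 0.3)
    D <- mrd_matrix(qq$geno)
    core <- diversity_core(qq$geno, 0.2, n_candidates = 300, seed = s)
    m <- length(core$selected_ids)
    rnd <- replicate(300, {
      idx <- sample(120, m)
      sum(D[idx, idx]) / (m * (m - 1))
    })
    mean(core$diagnostics$best_mean_mrd >= rnd)
  }, numeric(1))
  expect_gte(mean(wins >= 0.95), 0.8)
})

test_that("reliability matches brute-force dense inversion and its limits", {
  K <- random_psd(6, seed = 65)
  g11 <- K[1:4, 1:4]; g21 <- K[5:6, 1:4]
  r <- reliability(g11, g21, h2 = 0.5)
  BF <- g21 %*% solve(g11 + diag(1, 4)) %*% t(g21)
  expect_lt(max(abs(r$values - diag(BF))), 1e-10)
  # zero cross-relationships: zero reliability
  expect_equal(reliability(g11, matrix(0, 2, 4), 0.5)$values, c(0, 0))
  # h2 -> 1: shrinkage vanishes
  r1 <- reliability(g11, g21, h2 = 1 - 1e-12)
  expect_lt(max(abs(r1$values - diag(g21 %*% solve(g11) %*% t(g21)))), 1e-6)
  # monotone nondecreasing in h2 on random PSD instances
  for (s in 1:5) {
    K <- random_psd(10, seed = 80 + s)
    g11 <- K[1:7, 1:7]; g21 <- K[8:10, 1:7]
    ms <- vapply(c(0.2, 0.4, 0.6, 0.8), function(h2)
      reliability(g11, g21, h2)$mean, numeric(1))
    expect_true(all(diff(ms) >= -1e-12))
  }
})

test_that("prediction cores honour the PC default, optimality and determinism", {
  qq <- quick_grm(150, 600, seed = 66, n_groups = 5, divergence = 0.2)
  pc <- prediction_core(qq$grm, 0.2, h2 = 0.5, seed = 67)
  expect_equal(pc$diagnostics$n_pcs, 100)  # min(100, n-1) honoured
  expect_equal(length(pc$selected_ids), 30)
  pc2 <- prediction_core(qq$grm, 0.2, h2 = 0.5, seed = 67)
  expect_identical(pc$selected_ids, pc2$selected_ids)
  # order invariance of the selected set
  oa <- sample(150)
  gperm <- structure(list(matrix = qq$grm$matrix[oa, oa],
                          accession_ids = qq$grm$accession_ids[oa],
                          freqs = qq$grm$freqs,
                          n_markers_used = qq$grm$n_markers_used), class = "grm")
  pc3 <- prediction_core(gperm, 0.2, h2 = 0.5, seed = 67)
  expect_setequal(pc3$selected_ids, pc$selected_ids)
  # full-coverage fraction returns everything
  pcall <- prediction_core(qq$grm, 1, h2 = 0.5, seed = 1)
  expect_setequal(pcall$selected_ids, qq$grm$accession_ids)
  # selected core beats random cores on the exact reliability objective
  rnd <- replicate(100, core_reliability(qq$grm,
    sample(qq$grm$accession_ids, 30), 0.5)$mean)
  ex <- core_reliability(qq$grm, pc$selected_ids, 0.5)$mean
  expect_gte(mean(ex >= rnd), 0.95)
})

test_that("diversity indices hit their closed forms and biallelic maxima", {
  # all loci at p = 0.5
  g <- toy_geno(rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0)))
  di <- diversity_indices(g)
  expect_equal(di$expected_heterozygosity, 0.5)
  expect_equal(di$effective_alleles, 2)
  expect_equal(di$shannon, log(2))
  # monomorphic loci
  g0 <- toy_geno(rbind(c(0, 2), c(0, 2)))
  di0 <- diversity_indices(g0)
  expect_equal(di0$expected_heterozygosity, 0)
  expect_equal(di0$effective_alleles, 1)
  expect_equal(di0$shannon, 0)
  # p = 0.2 locus closed forms (4 counted alleles among 20)
  g2 <- toy_geno(cbind(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)))
  di2 <- diversity_indices(g2)
  expect_equal(di2$expected_heterozygosity, 0.32, tolerance = 1e-12)
  expect_equal(di2$effective_alleles, 1 / 0.68, tolerance = 1e-12)
  expect_equal(di2$shannon, -(0.2 * log(0.2) + 0.8 * log(0.8)), tolerance = 1e-12)
  expect_error(diversity_indices(g2, character(0)), "empty")
  # subsetting uses subset frequencies
  dsub <- diversity_indices(g2, paste0("a", 1:2))
  expect_equal(dsub$expected_heterozygosity, 0.5)
})
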