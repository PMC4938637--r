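# Mixed models: interaction covariances, fixed-component MME solutions vs
# direct GLS oracles, sampler behaviour, variance decomposition.

direct_gls_predictions <- function(trait, grm, components, targets) {
  # independent oracle: V = sum_t s_t K_t + s_e I, mu by GLS,
  # prediction = mu + sum_t s_t K_t(target, obs) V^-1 (y - mu)
  acc <- as.character(trait$accession); env <- as.character(trait$environment)
  y <- trait$value
  n <- length(y)
  idx <- match(acc, grm$accession_ids)
  Ks <- list()
  if ("E" %in% names(components)) Ks$E <- outer(env, env, "==") + 0
  if ("A" %in% names(components)) Ks$A <- outer(acc, acc, "==") + 0
  if ("G" %in% names(components)) Ks$G <- grm$matrix[idx, idx]
  if ("GxE" %in% names(components)) Ks$GxE <- grm$matrix[idx, idx] * (outer(env, env, "==") + 0)
  if ("AxE" %in% names(components)) Ks$AxE <- (outer(acc, acc, "==") & outer(env, env, "==")) + 0
  V <- components[["resid"]] * diag(n)
  for (t in names(Ks)) V <- V + components[[t]] * Ks[[t]]
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  r <- Vi %*% (y - mu)
  tacc <- as.character(targets$accession); tenv <- as.character(targets$environment)
  tidx <- match(tacc, grm$accession_ids)
  pred <- rep(mu, nrow(targets))
  for (t in names(Ks)) {
    Kt <- switch(t,
      E = outer(tenv, env, "==") + 0,
      A = outer(tacc, acc, "==") + 0,
      G = grm$matrix[tidx, idx, drop = FALSE],
      GxE = grm$matrix[tidx, idx, drop = FALSE] * (outer(tenv, env, "==") + 0),
      AxE = (outer(tacc, acc, "==") & outer(tenv, env, "==")) + 0)
    pred <- pred + components[[t]] * drop(Kt %*% r)
  }
  pred
}

test_that("model term sets follow the M1-M4 hierarchy", {
  expect_equal(model_spec("M1")$terms, c("E", "A"))
  expect_equal(model_spec("M2")$terms, c("E", "A", "G"))
  expect_equal(model_spec("M3")$terms, c("E", "A", "G", "GxE"))
  expect_equal(model_spec("M4")$terms, c("E", "A", "G", "GxE", "AxE"))
  expect_error(model_spec("M2", method = "fixed", components = c(G = 1, resid = 1)),
               "components named")
})

test_that("interaction covariance is the Hadamard of genetic and environment blocks", {
  qq <- quick_grm(3, 40, seed = 31)
  G <- qq$grm
  ids <- G$accession_ids
  acc <- rep(ids, each = 2); env <- rep(c("D", "H"), 3)
  K <- build_interaction_covariance(G, acc, env, "GRM")
  # cross-environment entries exactly zero; same-environment equal G
  expect_identical(K[1, 2], 0)
  expect_equal(K[1, 3], G$matrix[ids[1], ids[2]])
  idx <- match(acc, ids)
  BF <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    BF[i, j] <- G$matrix[idx[i], idx[j]] * (env[i] == env[j])
  expect_lt(max(abs(K - BF)), 1e-12)
  KI <- build_interaction_covariance(G, acc, env, "IID")
  BFI <- outer(idx, idx, "==") * outer(env, env, "==")
  expect_lt(max(abs(KI - BFI)), 1e-12)
  expect_error(build_interaction_covariance(G, c("nope"), c("D")), "unknown accession")
})

test_that("fixed-component SE-GBLUP equals the closed-form BLUP solve", {
  qq <- quick_grm(50, 200, seed = 32)
  sim <- simulate_phenotypes(qq$geno, c(E = 0, A = 0, G = 0.6, AxE = 0, GxE = 0, resid = 0.4),
                             n_envs = 1, seed = 33)
  comps <- c(G = 0.6, resid = 0.4)
  spec <- model_spec("SE-GBLUP", method = "fixed", components = comps)
  fit <- fit_model(sim$trait, qq$grm, spec, standardize = FALSE)
  pred <- predict(fit, sim$trait[, c("accession", "environment")])
  oracle <- direct_gls_predictions(sim$trait, qq$grm, comps,
                                   sim$trait[, c("accession", "environment")])
  expect_lt(max(abs(pred$predicted - oracle)), 1e-8)
})

test_that("GBLUP predictions equal marker ridge regression with the dual variance", {
  qq <- quick_grm(40, 150, seed = 34)
  sim <- simulate_phenotypes(qq$geno, c(E = 0, A = 0, G = 0.5, AxE = 0, GxE = 0, resid = 0.5),
                             n_envs = 1, seed = 35)
  y <- sim$trait$value
  comps <- c(G = 0.5, resid = 0.5)
  fit <- fit_model(sim$trait, qq$grm, model_spec("SE-GBLUP", method = "fixed",
                                                 components = comps),
                   standardize = FALSE)
  pred <- predict(fit, sim$trait[, c("accession", "environment")])
  # ridge on centered markers, sigma_beta^2 = sigma_g^2 / sum 2p(1-p)
  X <- qq$geno$dosage[sim$trait$accession, ]
  p <- allele_frequencies(qq$geno)
  Xc <- sweep(X, 2, 2 * p)
  sb2 <- comps["G"] / sum(2 * p * (1 - p))
  V <- sb2 * tcrossprod(Xc) + comps["resid"] * diag(length(y))
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  beta <- sb2 * crossprod(Xc, Vi %*% (y - mu))
  ridge_pred <- mu + drop(Xc %*% beta)
  expect_lt(max(abs(pred$predicted - ridge_pred)), 1e-6)
})

test_that("fixed-component reaction-norm fits match the direct GLS oracle incl. unobserved targets", {
  qq <- quick_grm(30, 120, seed = 36)
  sim <- simulate_phenotypes(qq$geno, c(E = 0.5, A = 0.1, G = 0.4, AxE = 0.1,
                                        GxE = 0.3, resid = 0.3), n_envs = 2, seed = 37)
  trait <- sim$trait
  # hold 5 accessions out entirely (never phenotyped)
  held <- qq$grm$accession_ids[1:5]
  obs <- trait[!trait$accession %in% held, ]
  for (mod in c("M2", "M3", "M4")) {
    comps <- c(E = 0.5, A = 0.1, G = 0.4, GxE = 0.3, AxE = 0.1, resid = 0.3)
    comps <- comps[c(model_spec(mod)$terms, "resid")]
    fit <- fit_model(obs, qq$grm, model_spec(mod, method = "fixed", components = comps),
                     standardize = FALSE)
    targets <- expand.grid(accession = qq$grm$accession_ids,
                           environment = c("D", "H"), stringsAsFactors = FALSE)
    pred <- predict(fit, targets)
    oracle <- direct_gls_predictions(obs, qq$grm, comps, targets)
    expect_lt(max(abs(pred$predicted - oracle)), 1e-8)
  }
})

test_that("duplicate genotypes and zero genomic variance behave as limits require", {
  qq <- quick_grm(20, 80, seed = 38)
  X <- qq$geno$dosage
  X[2, ] <- X[1, ]
  g2 <- toy_geno(X)
  G2 <- compute_grm(g2)
  sim <- simulate_phenotypes(g2, c(E = 0, A = 0, G = 0.5, AxE = 0, GxE = 0, resid = 0.5),
                             n_envs = 1, seed = 39)
  fit <- fit_model(sim$trait, G2, model_spec("SE-GBLUP", method = "fixed",
                                             components = c(G = 0.5, resid = 0.5)),
                   standardize = FALSE)
  pr <- predict(fit, data.frame(accession = c("a1", "a2"), environment = "OPT"))
  expect_lt(abs(pr$predicted[1] - pr$predicted[2]), 1e-8)
  # sigma_g^2 = 0: predictions collapse to mu (+ E)
  fit0 <- fit_model(sim$trait, G2, model_spec("SE-GBLUP", method = "fixed",
                                              components = c(G = 0, resid = 1)),
                    standardize = FALSE)
  expect_lt(max(abs(fit0$predictions$predicted - fit0$mu)), 1e-10)
  expect_equal(fit0$predictions$genetic, rep(0, 20))
})

test_that("the sampler is deterministic given a seed and reports a full decomposition", {
  qq <- quick_grm(60, 150, seed = 40)
  sim <- simulate_phenotypes(qq$geno, n_envs = 2, seed = 41)
  spec <- model_spec("M4", iterations = 300, burnin = 100, thin = 2, seed = 7)
  f1 <- fit_model(sim$trait, qq$grm, spec)
  f2 <- fit_model(sim$trait, qq$grm, spec)
  expect_identical(f1$variance_components, f2$variance_components)
  expect_identical(f1$predictions$predicted, f2$predictions$predicted)
  expect_true(all(f1$variance_components >= 0))
  expect_lt(abs(sum(f1$within_env_percentages) - 100), 0.1)
  expect_error(fit_model(sim$trait, qq$grm, model_spec("SE-GBLUP")), "exactly 1")
  one_env <- sim$trait[sim$trait$environment == "D", ]
  expect_error(fit_model(one_env, qq$grm, model_spec("M2")), ">= 2")
})

test_that("an M1 fit on genetics-free data predicts nothing", {
  g <- simulate_genotypes(80, 100, seed = 42)
  G <- compute_grm(prepare_markers(g, maf_min = 0.02))
  set.seed(43)
  trait <- data.frame(accession = rep(g$accession_ids, 2),
                      environment = rep(c("D", "H"), each = 80),
                      value = rep(c(0, 2), each = 80) + rnorm(160))
  spec <- model_spec("M1", iterations = 600, burnin = 200, seed = 3)
  parts <- make_partitions(g$accession_ids, "CV1-two-env", 0.5, 3, seed = 4)
  rep <- evaluate(trait, G, spec, parts)
  expect_lt(abs(rep$mean), 3 / sqrt(80))
})

test_that("within-environment percentages match hand-computed reference rows", {
  # two-component model: (A = 0.025, resid = 0.038)
  pct1 <- variance_decomposition(c(E = 1.137, A = 0.025, resid = 0.038))
  expect_equal(unname(pct1["A"]), 100 * 0.025 / 0.063, tolerance = 1e-10)
  expect_lt(abs(pct1[["A"]] - 39.43), 0.5)
  expect_lt(abs(pct1[["resid"]] - 60.56), 0.5)
  # five-component model row
  pct4 <- variance_decomposition(c(E = 0.635, A = 0.006, G = 0.014, AxE = 0.005,
                                   GxE = 0.012, resid = 0.012))
  printed <- c(A = 12.06, G = 28.15, AxE = 10.80, GxE = 23.85, resid = 25.12)
  expect_true(all(abs(pct4[names(printed)] - printed) < 1.5))
  expect_equal(unname(variance_decomposition(c(G = 0.7, resid = 0))["G"]), 100)
  expect_error(variance_decomposition(c(E = 1, A = 0, resid = 0)), "zero")
})
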