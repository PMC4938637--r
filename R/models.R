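# GBLUP and reaction-norm mixed models.
#
# Model family (random-effect terms, all mutually independent):
#   SE-GBLUP : y = mu + g + eps                     (single environment)
#   M1       : y = mu + E + A + eps
#   M2       : y = mu + E + A + g + eps
#   M3       : M2 + GxE   (Hadamard of ZGZ' with the environment block)
#   M4       : M3 + AxE   (Hadamard of ZIZ' with the environment block)
#
# Every random term u_t ~ N(0, K_t sigma_t^2) is re-parameterized in the
# orthonormal eigenbasis of its record-level covariance K_t = Q_t L_t Q_t',
# u_t = Q_t w_t with w_t ~ N(0, L_t sigma_t^2). Because Q_t'Q_t = I the full
# conditional of w_t in a Gibbs sweep is diagonal, so one update costs two
# dense matrix-vector products. The eigenbasis is obtained from
# accession-level (or per-environment-block) eigendecompositions, never from
# the raw record-level matrix.

MODEL_TERMS <- list(
  "SE-GBLUP" = c("G"),
  "M1" = c("E", "A"),
  "M2" = c("E", "A", "G"),
  "M3" = c("E", "A", "G", "GxE"),
  "M4" = c("E", "A", "G", "GxE", "AxE")
)

#' Specify a genomic prediction model
#'
#' @param name one of `"SE-GBLUP"`, `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param method `"gibbs"` (variance components estimated by a Gibbs
#'   sampler with scaled-inverse-chi-squared priors) or `"fixed"` (exact
#'   mixed-model-equation solutions at user-supplied components).
#' @param components for `method = "fixed"`: named variance components, one
#'   per model term plus `resid` (e.g. `c(E=..., A=..., G=..., resid=...)`).
#' @param iterations,burnin,thin Gibbs chain settings.
#' @param seed integer seed driving the sampler.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("SE-GBLUP", "M1", "M2", "M3", "M4"),
                       method = c("gibbs", "fixed"), components = NULL,
                       iterations = 6000, burnin = 1000, thin = 5, seed = 1) {
  name <- match.arg(name)
  method <- match.arg(method)
  terms <- MODEL_TERMS[[name]]
  if (method == "fixed") {
    need <- c(terms, "resid")
    if (is.null(components) || !all(need %in% names(components)))
      stop_genpred("method='fixed' requires components named: %s",
                   paste(need, collapse = ", "))
    components <- components[need]
    if (any(components < 0)) stop_genpred("variance components must be >= 0")
    if (components["resid"] <= 0) stop_genpred("resid component must be > 0")
  }
  structure(list(name = name, terms = terms, method = method,
                 components = components, iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Record-level interaction covariance (Hadamard structure)
#'
#' Builds `(Z K Z') o (Z_E Z_E')` for a set of records: entries are
#' `K[acc_i, acc_j]` when two records share an environment and exactly 0
#' otherwise, with `K = G` (`kind = "GRM"`) or the identity (`kind = "IID"`).
#'
#' @param grm a [compute_grm()] object.
#' @param accessions,environments per-record accession and environment labels.
#' @param kind `"GRM"` or `"IID"`.
#' @return A dense `n_records x n_records` covariance matrix.
#' @export
build_interaction_covariance <- function(grm, accessions, environments,
                                         kind = c("GRM", "IID")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grm, "grm"), length(accessions) == length(environments))
  idx <- match(as.character(accessions), grm$accession_ids)
  if (anyNA(idx))
    stop_genpred("unknown accession(s): %s",
                 paste(utils::head(unique(accessions[is.na(idx)]), 5), collapse = ", "))
  K <- if (kind == "GRM") grm$matrix[idx, idx, drop = FALSE]
       else (outer(idx, idx, "==") + 0)
  same_env <- outer(as.character(environments), as.character(environments), "==")
  K * same_env
}

# ---- internal: term factorizations -----------------------------------------

EIG_TOL <- 1e-9

# Orthonormal factor Q (n_rec x r) and eigenvalues lambda for one term.
# Returns prediction metadata alongside.
factor_term <- function(term, acc, env, grm) {
  n <- length(acc)
  if (term %in% c("E", "A", "AxE")) {
    f <- switch(term, E = env, A = acc, AxE = paste(acc, env, sep = "\r"))
    f <- factor(f)
    d <- as.numeric(table(f))
    L <- nlevels(f)
    Q <- matrix(0, n, L)
    Q[cbind(seq_len(n), as.integer(f))] <- 1 / sqrt(d[as.integer(f)])
    return(list(term = term, Q = Q, lambda = d, levels = levels(f),
                kind = "level"))
  }
  if (term == "G") {
    f <- factor(acc)
    d <- as.numeric(table(f))
    lev <- levels(f)
    Gs <- grm$matrix[match(lev, grm$accession_ids), match(lev, grm$accession_ids), drop = FALSE]
    sq <- sqrt(d)
    M <- Gs * tcrossprod(sq)
    ed <- eigen(M, symmetric = TRUE)
    keep <- ed$values > EIG_TOL * max(ed$values, 1)
    V <- ed$vectors[, keep, drop = FALSE] / sq  # rows scaled by 1/sqrt(d)
    Q <- V[as.integer(f), , drop = FALSE]
    return(list(term = term, Q = Q, lambda = ed$values[keep], levels = lev,
                kind = "grm", f = as.integer(f)))
  }
  if (term == "GxE") {
    envs <- unique(env)
    Qs <- vector("list", length(envs)); lams <- vector("list", length(envs))
    blocks <- vector("list", length(envs))
    total_r <- 0
    for (b in seq_along(envs)) {
      rows <- which(env == envs[b])
      f <- factor(acc[rows])
      d <- as.numeric(table(f))
      lev <- levels(f)
      Gs <- grm$matrix[match(lev, grm$accession_ids), match(lev, grm$accession_ids), drop = FALSE]
      sq <- sqrt(d)
      M <- Gs * tcrossprod(sq)
      ed <- eigen(M, symmetric = TRUE)
      keep <- ed$values > EIG_TOL * max(ed$values, 1)
      V <- ed$vectors[, keep, drop = FALSE] / sq
      Qs[[b]] <- V[as.integer(f), , drop = FALSE]
      lams[[b]] <- ed$values[keep]
      blocks[[b]] <- list(rows = rows, levels = lev, f = as.integer(f),
                          cols = total_r + seq_len(sum(keep)))
      total_r <- total_r + sum(keep)
    }
    Q <- matrix(0, n, total_r)
    for (b in seq_along(envs)) Q[blocks[[b]]$rows, blocks[[b]]$cols] <- Qs[[b]]
    return(list(term = term, Q = Q, lambda = unlist(lams), levels = NULL,
                kind = "grm_env", envs = envs, blocks = blocks))
  }
  stop_genpred("unknown term '%s'", term)
}

# From posterior-mean w for one term, build what predict() needs.
term_predictor <- function(fac, w_mean) {
  if (fac$kind == "level") {
    u_level <- w_mean / sqrt(fac$lambda)
    return(list(term = fac$term, kind = "level", levels = fac$levels,
                u_level = u_level))
  }
  if (fac$kind == "grm") {
    # alpha over accession levels: u_new(a) = G[a, levels] %*% alpha
    v <- drop(fac$Q %*% (w_mean / fac$lambda))        # per-record
    alpha <- as.numeric(rowsum(v, fac$f))             # aggregated per level
    return(list(term = fac$term, kind = "grm", levels = fac$levels,
                alpha = alpha))
  }
  if (fac$kind == "grm_env") {
    per_env <- lapply(seq_along(fac$envs), function(b) {
      bl <- fac$blocks[[b]]
      wb <- w_mean[bl$cols]
      lb <- fac$lambda[bl$cols]
      Qb <- fac$Q[bl$rows, bl$cols, drop = FALSE]
      v <- drop(Qb %*% (wb / lb))
      list(env = fac$envs[b], levels = bl$levels,
           alpha = as.numeric(rowsum(v, bl$f)))
    })
    return(list(term = fac$term, kind = "grm_env", per_env = per_env))
  }
}

# ---- internal: samplers / solvers ------------------------------------------

# Single-site-blocked Gibbs sampler in the per-term eigenbases.
gibbs_fit <- function(y, facs, spec) {
  n <- length(y)
  n_terms <- length(facs)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) vy <- 1
  # Symmetric weakly-informative scaled-inv-chi2 priors: every variance
  # component (including the residual) gets df = 5 with its mode at 2% of the
  # phenotypic variance, so attribution among competing covariance structures
  # (iid accession vs GRM, GxE vs residual) is decided by the likelihood
  # rather than by prior allocation. Asymmetric equal-share priors measurably
  # inflate weakly identified components at desk-scale n.
  df0 <- 5
  mode_t <- 0.02 * vy
  S0 <- vapply(facs, function(f) mode_t * (df0 + 2) / df0, numeric(1))
  S0e <- mode_t * (df0 + 2) / df0
  set.seed(spec$seed)
  sig2 <- rep(0.05 * vy, n_terms)
  sig2e <- 0.5 * vy
  mu <- mean(y)
  w <- lapply(facs, function(f) numeric(length(f$lambda)))
  e <- y - mu
  n_iter <- spec$iterations
  keep <- seq.int(spec$burnin + 1L, n_iter, by = spec$thin)
  keep_flag <- logical(n_iter); keep_flag[keep] <- TRUE
  n_keep <- length(keep)
  if (n_keep < 2) stop_genpred("chain settings leave fewer than 2 kept samples")
  vc_samp <- matrix(NA_real_, n_keep, n_terms + 1L)
  mu_samp <- numeric(n_keep)
  w_sum <- lapply(facs, function(f) numeric(length(f$lambda)))
  k_out <- 0L
  for (it in seq_len(n_iter)) {
    for (t in seq_len(n_terms)) {
      Q <- facs[[t]]$Q; lam <- facs[[t]]$lambda
      r <- drop(crossprod(Q, e)) + w[[t]]           # Q'Q = I
      v_post <- 1 / (1 / sig2e + 1 / (lam * sig2[t]))
      m_post <- v_post * r / sig2e
      w_new <- stats::rnorm(length(lam), m_post, sqrt(v_post))
      e <- e - drop(Q %*% (w_new - w[[t]]))
      w[[t]] <- w_new
      ss <- sum(w_new^2 / lam)
      sig2[t] <- (df0 * S0[t] + ss) / stats::rchisq(1, df0 + length(lam))
    }
    # intercept (flat prior)
    e <- e + mu
    mu <- stats::rnorm(1, mean(e), sqrt(sig2e / n))
    e <- e - mu
    sig2e <- (df0 * S0e + sum(e^2)) / stats::rchisq(1, df0 + n)
    if (keep_flag[it]) {
      k_out <- k_out + 1L
      vc_samp[k_out, ] <- c(sig2, sig2e)
      mu_samp[k_out] <- mu
      for (t in seq_len(n_terms)) w_sum[[t]] <- w_sum[[t]] + w[[t]]
    }
  }
  w_mean <- lapply(w_sum, function(s) s / n_keep)
  colnames(vc_samp) <- c(vapply(facs, `[[`, "", "term"), "resid")
  list(mu = mean(mu_samp), w_mean = w_mean,
       vc = colMeans(vc_samp), vc_sd = apply(vc_samp, 2, stats::sd),
       vc_samples = vc_samp)
}

# Exact Henderson mixed-model-equation solve at fixed variance components,
# in the same reduced eigenbases as the sampler.
mme_fit <- function(y, facs, components) {
  sig2e <- components[["resid"]]
  W <- do.call(cbind, lapply(facs, `[[`, "Q"))
  dp <- unlist(lapply(facs, function(f) f$lambda * components[[f$term]]))
  n <- length(y)
  ridge <- ifelse(dp > 0, sig2e / dp, Inf)
  finite <- is.finite(ridge)
  if (!all(finite)) {  # zero-variance terms drop out
    W <- W[, finite, drop = FALSE]
    ridge <- ridge[finite]
  }
  C <- rbind(cbind(n, t(colSums(W))),
             cbind(colSums(W), crossprod(W) + diag(ridge, length(ridge))))
  rhs <- c(sum(y), drop(crossprod(W, y)))
  coef <- solve(C, rhs)
  w_all <- numeric(length(finite))
  w_all[finite] <- coef[-1]
  sizes <- vapply(facs, function(f) length(f$lambda), integer(1))
  splits <- factor(rep(seq_along(facs), sizes), levels = seq_along(facs))
  vc <- vapply(facs, function(f) components[[f$term]], numeric(1))
  names(vc) <- vapply(facs, `[[`, "", "term")
  list(mu = coef[1], w_mean = split(w_all, splits),
       vc = c(vc, resid = sig2e),
       vc_sd = c(vc, resid = sig2e) * NA_real_, vc_samples = NULL)
}

# ---- public fitting interface ----------------------------------------------

#' Fit a genomic prediction mixed model
#'
#' Fits one of the SE-GBLUP / M1-M4 models to long-format phenotype records,
#' estimating variance components by Gibbs sampling (default) or solving the
#' mixed-model equations exactly at supplied components. Records with missing
#' `value` are dropped from the likelihood and handled as prediction targets.
#' Accessions present in the GRM but never phenotyped are predicted through
#' the genomic coupling of the G (and GxE) random effects.
#'
#' @param trait data.frame with `accession`, `environment`, `value`.
#' @param grm a [compute_grm()] object covering (at least) every phenotyped
#'   accession.
#' @param spec a [model_spec()].
#' @param standardize standardize the response to mean 0 / variance 1 before
#'   fitting (components are reported on that scale); default `TRUE`.
#' @return An object of class `genpred_fit`: variance components (posterior
#'   means and SDs), intercept, within-environment variance percentages,
#'   per-term effect predictors, and a `predictions` data.frame covering all
#'   GRM accessions in all observed environments.
#' @export
fit_model <- function(trait, grm, spec, standardize = TRUE) {
  stopifnot(is.data.frame(trait), inherits(grm, "grm"), inherits(spec, "model_spec"))
  obs <- trait[!is.na(trait$value), , drop = FALSE]
  if (nrow(obs) < 3) stop_genpred("fewer than 3 observed records")
  env_levels <- sort(unique(as.character(obs$environment)))
  n_env <- length(env_levels)
  if (spec$name == "SE-GBLUP" && n_env != 1)
    stop_genpred("SE-GBLUP requires exactly 1 environment, got %d", n_env)
  if (spec$name != "SE-GBLUP" && n_env < 2)
    stop_genpred("%s requires >= 2 environments, got %d", spec$name, n_env)
  acc <- as.character(obs$accession)
  if (!all(acc %in% grm$accession_ids))
    stop_genpred("phenotyped accession(s) missing from the GRM")
  env <- as.character(obs$environment)
  y_raw <- obs$value
  center <- 0; scale <- 1
  if (standardize) {
    center <- mean(y_raw)
    scale <- stats::sd(y_raw)
    if (!is.finite(scale) || scale == 0) scale <- 1
  }
  y <- (y_raw - center) / scale
  facs <- lapply(spec$terms, factor_term, acc = acc, env = env, grm = grm)
  fit <- if (spec$method == "gibbs") gibbs_fit(y, facs, spec)
         else mme_fit(y, facs, spec$components)
  predictors <- mapply(term_predictor, facs, fit$w_mean, SIMPLIFY = FALSE)
  out <- structure(list(
    model = spec$name, method = spec$method, spec = spec,
    mu = fit$mu, variance_components = fit$vc, vc_sd = fit$vc_sd,
    vc_samples = fit$vc_samples,
    predictors = predictors, grm = grm, env_levels = env_levels,
    center = center, scale = scale,
    n_records = nrow(obs)), class = "genpred_fit")
  out$within_env_percentages <- variance_decomposition(out)
  targets <- expand.grid(accession = grm$accession_ids, environment = env_levels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$predictions <- predict(out, targets)
  out
}

#' Predict accession values in environments
#'
#' Posterior-mean `mu + E_i + A_j + g_j + Eg_ij + EA_ij` (terms as present in
#' the fitted model) for arbitrary (accession, environment) targets. Genetic
#' effects of never-phenotyped accessions flow through the GRM; iid effects
#' of unobserved levels are 0.
#'
#' @param object a [fit_model()] result.
#' @param targets data.frame with `accession` and `environment`.
#' @param ... unused.
#' @return `targets` with columns `predicted` (total value, original scale)
#'   and `genetic` (G + GxE contribution, model scale).
#' @export
predict.genpred_fit <- function(object, targets, ...) {
  stopifnot(is.data.frame(targets),
            all(c("accession", "environment") %in% names(targets)))
  acc <- as.character(targets$accession)
  env <- as.character(targets$environment)
  if (!all(acc %in% object$grm$accession_ids))
    stop_genpred("target accession(s) absent from the GRM")
  G <- object$grm$matrix
  gid <- object$grm$accession_ids
  total <- rep(object$mu, nrow(targets))
  genetic <- numeric(nrow(targets))
  for (pr in object$predictors) {
    if (pr$kind == "level") {
      key <- switch(pr$term, E = env, A = acc, AxE = paste(acc, env, sep = "\r"))
      m <- match(key, pr$levels)
      contrib <- ifelse(is.na(m), 0, pr$u_level[m])
      total <- total + contrib
    } else if (pr$kind == "grm") {
      Gx <- G[match(acc, gid), match(pr$levels, gid), drop = FALSE]
      contrib <- drop(Gx %*% pr$alpha)
      total <- total + contrib
      genetic <- genetic + contrib
    } else if (pr$kind == "grm_env") {
      contrib <- numeric(nrow(targets))
      for (pe in pr$per_env) {
        rows <- which(env == pe$env)
        if (!length(rows)) next
        Gx <- G[match(acc[rows], gid), match(pe$levels, gid), drop = FALSE]
        contrib[rows] <- drop(Gx %*% pe$alpha)
      }
      total <- total + contrib
      genetic <- genetic + contrib
    }
  }
  out <- targets
  out$predicted <- total * object$scale + object$center
  out$genetic <- genetic
  out
}

#' Within-environment variance decomposition
#'
#' Expresses each non-environment variance component (accession, genomic,
#' interactions, residual) as a percentage of the total variance after
#' removing the environment main effect:
#' `100 * sigma_t^2 / sum_{t != E} sigma_t^2`.
#'
#' @param fit a [fit_model()] result, or a named numeric vector of variance
#'   components (an `E` element, if present, is excluded from the total).
#' @return Named percentage vector summing to 100.
#' @export
variance_decomposition <- function(fit) {
  vc <- if (inherits(fit, "genpred_fit")) fit$variance_components
        else if (is.numeric(fit) && !is.null(names(fit))) fit
        else stop_genpred("fit must be a genpred_fit or a named numeric vector")
  vc <- vc[setdiff(names(vc), "E")]
  tot <- sum(vc)
  if (tot <= 0) stop_genpred("all non-environment variance components are zero")
  100 * vc / tot
}

#' @export
print.genpred_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s), %d records, mu = %.4f\n",
              x$model, x$method, x$n_records, x$mu))
  print(round(x$variance_components, 5))
  invisible(x)
}
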