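# Synthetic-data generators emulating structured gene-bank landrace
# collections: admixture-free subpopulations with Balding-Nichols allele
# frequency dispersion, additive marker effects with environment-specific
# deviations, and augmented field trials with separable AR1xAR1 plot error.

#' Construct a genotype object
#'
#' Container for an accessions x markers dosage matrix (biallelic SNPs coded
#' 0/1/2, `NA` for missing) with aligned accession and marker identifiers and
#' optional subpopulation labels (simulation truth).
#'
#' @param dosage numeric matrix, entries in \{0, 1, 2\} or `NA`.
#' @param accession_ids unique character vector, one per row.
#' @param marker_ids unique character vector, one per column.
#' @param group_labels optional per-accession subpopulation label.
#' @return An object of class `genotypes`.
#' @export
new_genotypes <- function(dosage, accession_ids = rownames(dosage),
                          marker_ids = colnames(dosage), group_labels = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(nrow(dosage)))
  if (is.null(marker_ids)) marker_ids <- paste0("mk", seq_len(ncol(dosage)))
  accession_ids <- as.character(accession_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(accession_ids)) stop_genpred("accession_ids must be unique")
  if (anyDuplicated(marker_ids)) stop_genpred("marker_ids must be unique")
  if (length(accession_ids) != nrow(dosage) || length(marker_ids) != ncol(dosage))
    stop_genpred("identifier lengths do not match the dosage matrix dimensions")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop_genpred("non-missing dosages must be 0, 1 or 2")
  dimnames(dosage) <- list(accession_ids, marker_ids)
  if (!is.null(group_labels)) {
    if (length(group_labels) != nrow(dosage))
      stop_genpred("group_labels must have one entry per accession")
    group_labels <- as.character(group_labels)
  }
  structure(list(dosage = dosage, accession_ids = accession_ids,
                 marker_ids = marker_ids, group_labels = group_labels),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d accessions x %d markers (%.1f%% missing)%s\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$group_labels)) ""
              else sprintf(", %d groups", length(unique(x$group_labels)))))
  invisible(x)
}

#' Simulate genotypes for a structured collection
#'
#' Draws biallelic dosages for `n_groups` subpopulations under a
#' Balding-Nichols model: each marker has an ancestral frequency drawn
#' uniformly from `maf_range`; group frequencies are Beta-dispersed around it
#' with variance `divergence * p * (1 - p)`. `divergence = 0` gives an
#' unstructured collection. Missingness is completely at random per entry.
#'
#' @param n_accessions,n_markers positive dimensions.
#' @param n_groups number of subpopulations (accessions split evenly).
#' @param divergence Wright's F_ST-like dispersion, in `[0, 1)`.
#' @param maf_range ancestral minor-allele frequency range, within `(0, 0.5]`.
#' @param missing_rate per-entry missingness probability, in `[0, 1)`.
#' @param seed integer seed; identical seeds reproduce the matrix exactly.
#' @return A [new_genotypes()] object with `group_labels` populated.
#' @export
simulate_genotypes <- function(n_accessions, n_markers, n_groups = 1,
                               divergence = 0, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1) {
  check_scalar(n_accessions, "n_accessions", lower = 1)
  check_scalar(n_markers, "n_markers", lower = 1)
  check_scalar(n_groups, "n_groups", lower = 1)
  check_scalar(divergence, "divergence", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 1, strict_upper = TRUE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_genpred("maf_range must be an increasing pair within (0, 0.5]")
  n <- as.integer(n_accessions); p <- as.integer(n_markers)
  k <- as.integer(n_groups)
  set.seed(as.integer(seed))
  anc <- stats::runif(p, maf_range[1], maf_range[2])
  groups <- rep_len(paste0("grp", seq_len(k)), n)
  groups <- groups[order(rep_len(seq_len(k), n))]  # contiguous, balanced
  # group-specific frequencies: Beta with mean anc, variance F*p*(1-p)
  gf <- matrix(anc, nrow = k, ncol = p, byrow = TRUE)
  if (divergence > 0 && k > 1) {
    a <- anc * (1 - divergence) / divergence
    b <- (1 - anc) * (1 - divergence) / divergence
    for (g in seq_len(k))
      gf[g, ] <- stats::rbeta(p, a, b)
  }
  gidx <- match(groups, paste0("grp", seq_len(k)))
  dosage <- matrix(stats::rbinom(n * p, size = 2L, prob = gf[gidx, , drop = FALSE]),
                   nrow = n, ncol = p)
  if (missing_rate > 0) {
    miss <- stats::runif(n * p) < missing_rate
    dosage[miss] <- NA_real_
  }
  new_genotypes(dosage,
                accession_ids = sprintf("acc%04d", seq_len(n)),
                marker_ids = sprintf("mk%05d", seq_len(p)),
                group_labels = groups)
}

#' Default variance components of the phenotype generator
#'
#' Magnitudes on the standardized-phenotype scale typical of a two-environment
#' days-to-heading analysis of a large landrace collection: a dominant
#' environment main effect and within-environment shares of roughly 12%
#' accession, 28% genomic, 11% accession-by-environment, 24%
#' genomic-by-environment, and 25% residual.
#'
#' @return Named numeric vector with elements `E`, `A`, `G`, `AxE`, `GxE`,
#'   `resid`.
#' @export
default_variance_components <- function() {
  c(E = 0.635, A = 0.006, G = 0.014, AxE = 0.005, GxE = 0.012, resid = 0.012)
}

#' Simulate phenotypes with additive genomic and G x E effects
#'
#' Builds records `y_ij = mu + E_i + A_j + g_j + EA_ij + Eg_ij + eps_ij` where
#' `g_j = sum_k (x_jk - 2 p_k) beta_k` is the additive genomic value and
#' `Eg_ij` arises from environment-specific marker-effect deviations
#' `delta_k,i` with variance calibrated so that `Var(Eg)` matches the
#' requested `GxE` component. With `n_envs = 1` the environment and
#' interaction terms are omitted and the single-environment genomic
#' heritability is `G / (G + resid)`.
#'
#' @param geno a [new_genotypes()] object (missing entries are mean-imputed
#'   internally when computing genetic values).
#' @param variance_components named vector with elements `E`, `A`, `G`,
#'   `AxE`, `GxE`, `resid` (all >= 0); see [default_variance_components()].
#' @param n_envs 1 or 2 environments (labelled `"D"`, `"H"` when 2).
#' @param mu grand mean.
#' @param seed integer seed.
#' @return A list with `trait` (data.frame `accession`, `environment`,
#'   `value`) and `truth` (marker effects, realized variance components,
#'   per accession x environment true genetic values, and the seed).
#' @export
simulate_phenotypes <- function(geno, variance_components = default_variance_components(),
                                n_envs = 2, mu = 0, seed = 1) {
  stopifnot(inherits(geno, "genotypes"))
  if (!n_envs %in% c(1, 2)) stop_genpred("n_envs must be 1 or 2")
  vc <- variance_components
  need <- c("E", "A", "G", "AxE", "GxE", "resid")
  if (!all(need %in% names(vc)))
    stop_genpred("variance_components must be named with %s", paste(need, collapse = ", "))
  vc <- vc[need]
  if (any(vc < 0)) stop_genpred("variance components must be >= 0")
  X <- geno$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * p[j]
  }
  Xc <- sweep(X, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop_genpred("all markers are monomorphic; no genetic signal possible")
  n <- nrow(X)
  envs <- if (n_envs == 2) c("D", "H") else "OPT"
  set.seed(as.integer(seed))
  beta <- stats::rnorm(ncol(X), 0, sqrt(vc["G"] / denom))
  g <- drop(Xc %*% beta)
  gev <- matrix(g, n, n_envs, dimnames = list(geno$accession_ids, envs))
  if (n_envs == 2 && vc["GxE"] > 0) {
    for (e in seq_len(n_envs)) {
      delta <- stats::rnorm(ncol(X), 0, sqrt(vc["GxE"] / denom))
      gev[, e] <- gev[, e] + drop(Xc %*% delta)
    }
  }
  A <- stats::rnorm(n, 0, sqrt(vc["A"]))
  E <- if (n_envs == 2) stats::rnorm(n_envs, 0, sqrt(vc["E"])) else 0
  rec <- expand.grid(accession = geno$accession_ids, environment = envs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i_env <- match(rec$environment, envs)
  i_acc <- match(rec$accession, geno$accession_ids)
  EA <- if (n_envs == 2 && vc["AxE"] > 0)
    stats::rnorm(nrow(rec), 0, sqrt(vc["AxE"])) else 0
  eps <- stats::rnorm(nrow(rec), 0, sqrt(vc["resid"]))
  if (n_envs == 1) {
    rec$value <- mu + A[i_acc] + g[i_acc] + eps
  } else {
    rec$value <- mu + E[i_env] + A[i_acc] + gev[cbind(i_acc, i_env)] + EA + eps
  }
  truth <- list(marker_effects = beta,
                variance_components = vc,
                true_genetic_values = gev,
                accession_effects = A,
                seed = as.integer(seed))
  list(trait = rec, truth = truth)
}

# Draw an AR1(rho_row) x AR1(rho_col) Gaussian surface on a rows x cols grid
# (unit marginal variance) via the matrix-normal Cholesky construction.
ar1xar1_surface <- function(rows, cols, rho_row, rho_col) {
  Lr <- chol(ar1_corr(rows, rho_row))
  Lc <- chol(ar1_corr(cols, rho_col))
  Z <- matrix(stats::rnorm(rows * cols), rows, cols)
  t(Lr) %*% Z %*% Lc  # rows x cols, entry (r, c)
}

# AR1 correlation matrix of dimension m.
ar1_corr <- function(m, rho) {
  if (abs(rho) >= 1) stop_genpred("|rho| must be < 1")
  rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Simulate an augmented field trial with spatially correlated plot error
#'
#' Lays accessions and repeated checks on a `rows x cols` grid (checks at
#' regularly spaced plots in serpentine order, cycling over `n_checks` check
#' entries) and adds a separable AR1(rho_row) x AR1(rho_col) Gaussian field
#' plus an independent nugget to the trait values.
#'
#' @param trait data.frame with `accession`, `environment`, `value`; must
#'   contain a single environment.
#' @param rows,cols grid dimensions; `rows * cols` must be at least the number
#'   of accessions plus enough plots for the checks.
#' @param rho_row,rho_col AR1 correlations, `|rho| < 1`.
#' @param sigma_spatial standard deviation of the spatial field.
#' @param sigma_nugget standard deviation of the independent plot error.
#' @param n_checks number of distinct repeated check entries.
#' @param seed integer seed.
#' @return A data.frame of class `field_trial` with columns `row`, `col`,
#'   `entry`, `is_check`, `value`, and attributes `spatial_params` and
#'   `truth` (the generated surface and pre-field values, for validation).
#' @export
simulate_field_trial <- function(trait, rows, cols, rho_row = 0.5, rho_col = 0.5,
                                 sigma_spatial = 1, sigma_nugget = 0,
                                 n_checks = 3, seed = 1) {
  stopifnot(is.data.frame(trait), all(c("accession", "environment", "value") %in% names(trait)))
  if (length(unique(trait$environment)) != 1L)
    stop_genpred("simulate_field_trial expects a single-environment trait table")
  check_scalar(rho_row, "rho_row", -1, 1, TRUE, TRUE)
  check_scalar(rho_col, "rho_col", -1, 1, TRUE, TRUE)
  check_scalar(sigma_spatial, "sigma_spatial", lower = 0)
  check_scalar(sigma_nugget, "sigma_nugget", lower = 0)
  n_acc <- nrow(trait)
  n_plots <- rows * cols
  n_check_plots <- n_plots - n_acc
  if (n_check_plots < max(2L, n_checks))
    stop_genpred("grid too small: %d plots for %d accessions leaves %d check plots",
                 n_plots, n_acc, n_check_plots)
  set.seed(as.integer(seed))
  # serpentine plot order
  ord <- unlist(lapply(seq_len(rows), function(r) {
    cc <- seq_len(cols); if (r %% 2 == 0) cc <- rev(cc)
    (r - 1) * cols + cc
  }))
  check_pos_serp <- unique(round(seq(1, n_plots, length.out = n_check_plots)))
  while (length(check_pos_serp) < n_check_plots)  # guard against rounding collisions
    check_pos_serp <- union(check_pos_serp, sample(setdiff(seq_len(n_plots), check_pos_serp), 1))
  check_pos <- ord[sort(check_pos_serp)]
  entry <- character(n_plots); is_check <- logical(n_plots)
  check_ids <- sprintf("check%d", seq_len(n_checks))
  entry[check_pos] <- rep_len(check_ids, n_check_plots)
  is_check[check_pos] <- TRUE
  entry[!is_check] <- sample(as.character(trait$accession))
  # fixed per-check means drawn once from the trait distribution
  check_mean <- stats::rnorm(n_checks, mean(trait$value), stats::sd(trait$value))
  names(check_mean) <- check_ids
  base <- numeric(n_plots)
  base[!is_check] <- trait$value[match(entry[!is_check], trait$accession)]
  base[is_check] <- check_mean[entry[is_check]]
  S <- sigma_spatial * ar1xar1_surface(rows, cols, rho_row, rho_col)
  grid_row <- rep(seq_len(rows), each = cols)
  grid_col <- rep(seq_len(cols), times = rows)
  surf <- S[cbind(grid_row, grid_col)]
  nug <- if (sigma_nugget > 0) stats::rnorm(n_plots, 0, sigma_nugget) else 0
  out <- data.frame(row = grid_row, col = grid_col, entry = entry,
                    is_check = is_check, value = base + surf + nug,
                    stringsAsFactors = FALSE)
  attr(out, "spatial_params") <- c(rho_row = rho_row, rho_col = rho_col,
                                   sigma_spatial2 = sigma_spatial^2,
                                   sigma_nugget2 = sigma_nugget^2)
  attr(out, "truth") <- list(surface = surf, base = base,
                             environment = trait$environment[1])
  attr(out, "environment") <- trait$environment[1]
  class(out) <- c("field_trial", "data.frame")
  out
}
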