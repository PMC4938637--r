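# Marker QC, allele frequencies, the centered/standardized genomic
# relationship matrix, and genomic heritability.

#' Per-marker allele frequencies
#'
#' Frequency of the counted allele at each marker, `p_k = mean(dosage)/2`
#' over non-missing entries.
#'
#' @param geno a [new_genotypes()] object.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  n_obs <- colSums(!is.na(geno$dosage))
  if (any(n_obs == 0))
    stop_genpred("%d marker(s) have no non-missing entries", sum(n_obs == 0))
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Filter and impute markers
#'
#' Removes markers failing minor-allele-frequency or call-rate thresholds and
#' mean-imputes remaining missing entries to the marker mean dosage `2 p_k`.
#' The removal log is attached as attribute `"filter_log"`.
#'
#' @param geno a [new_genotypes()] object.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param callrate_min minimum proportion of non-missing calls, in `[0, 1]`.
#' @return A [new_genotypes()] object with no missing values.
#' @export
prepare_markers <- function(geno, maf_min = 0.05, callrate_min = 0.80) {
  stopifnot(inherits(geno, "genotypes"))
  check_scalar(maf_min, "maf_min", 0, 0.5)
  check_scalar(callrate_min, "callrate_min", 0, 1)
  X <- geno$dosage
  callrate <- colMeans(!is.na(X))
  no_calls <- callrate == 0
  p <- rep(NA_real_, ncol(X))
  p[!no_calls] <- colMeans(X[, !no_calls, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_call <- callrate < callrate_min | no_calls
  fail_maf <- !fail_call & (is.na(maf) | maf < maf_min | maf == 0)
  keep <- !fail_call & !fail_maf
  if (!any(keep))
    stop_genpred("all %d markers removed (call-rate: %d, MAF: %d)",
                 ncol(X), sum(fail_call), sum(fail_maf))
  X <- X[, keep, drop = FALSE]
  pk <- p[keep]
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * pk[j]
  out <- geno
  out$dosage <- X
  out$marker_ids <- geno$marker_ids[keep]
  attr(out, "filter_log") <- list(
    n_input = length(keep), n_kept = sum(keep),
    n_fail_callrate = sum(fail_call), n_fail_maf = sum(fail_maf),
    maf_min = maf_min, callrate_min = callrate_min,
    removed = geno$marker_ids[!keep])
  out
}

#' Genomic relationship matrix
#'
#' VanRaden-style centered and standardized relationship matrix with entries
#' `G_ij = sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / sum_k 2 p_k (1 - p_k)`.
#'
#' @param geno a prepared [new_genotypes()] object (no missing values).
#' @param freqs optional externally supplied frequencies; defaults to
#'   frequencies estimated from `geno` itself.
#' @return An object of class `grm`: list with `matrix`, `accession_ids`,
#'   `freqs`, `n_markers_used`.
#' @export
compute_grm <- function(geno, freqs = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  if (anyNA(geno$dosage))
    stop_genpred("genotypes contain missing values; run prepare_markers() first")
  p <- freqs %||% allele_frequencies(geno)
  if (length(p) != ncol(geno$dosage))
    stop_genpred("freqs length does not match the number of markers")
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop_genpred("all markers monomorphic: GRM denominator is 0")
  Xc <- sweep(geno$dosage, 2, 2 * p)
  G <- tcrossprod(Xc) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(geno$accession_ids, geno$accession_ids)
  structure(list(matrix = G, accession_ids = geno$accession_ids,
                 freqs = p, n_markers_used = ncol(geno$dosage)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d accessions, %d markers, mean diagonal %.3f\n",
              nrow(x$matrix), x$n_markers_used, mean(diag(x$matrix))))
  invisible(x)
}

#' Genomic heritability
#'
#' Share of phenotypic variance captured by markers,
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param sigma_g2 genomic variance (>= 0).
#' @param sigma_e2 error variance (>= 0).
#' @return h2 in `[0, 1]`.
#' @export
genomic_heritability <- function(sigma_g2, sigma_e2) {
  check_scalar(sigma_g2, "sigma_g2", lower = 0)
  check_scalar(sigma_e2, "sigma_e2", lower = 0)
  if (sigma_g2 + sigma_e2 == 0)
    stop_genpred("sigma_g2 and sigma_e2 cannot both be zero")
  sigma_g2 / (sigma_g2 + sigma_e2)
}

# Add a small ridge to the GRM diagonal when a downstream solver requires
# strict positive definiteness (mean imputation can leave tiny negative
# eigenvalues).
bend_grm <- function(grm, epsilon = 1e-8) {
  grm$matrix <- grm$matrix + diag(epsilon, nrow(grm$matrix))
  grm
}
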