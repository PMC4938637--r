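# Population structure: eigendecomposition of the GRM and pre-adjustment of
# phenotypes on the leading eigenvectors.

#' Eigendecomposition of the genomic relationship matrix
#'
#' Top-k eigenpairs of G with the cumulative proportion of total variance
#' explained (negative eigenvalues are clipped to zero in the denominator).
#'
#' @param grm a [compute_grm()] object.
#' @param k number of leading eigenpairs to retain (default: all).
#' @return An object of class `grm_eigen`: `values` (descending), `vectors`
#'   (n x k, orthonormal, rows named by accession), `cumvar`.
#' @export
eigen_grm <- function(grm, k = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$matrix)
  k <- as.integer(k %||% n)
  if (k < 1 || k > n) stop_genpred("k must be in [1, %d]", n)
  ed <- eigen(grm$matrix, symmetric = TRUE)
  total <- sum(pmax(ed$values, 0))
  cumvar <- cumsum(pmax(ed$values[seq_len(k)], 0)) / total
  vectors <- ed$vectors[, seq_len(k), drop = FALSE]
  rownames(vectors) <- grm$accession_ids
  structure(list(values = ed$values[seq_len(k)], vectors = vectors,
                 cumvar = cumvar, accession_ids = grm$accession_ids),
            class = "grm_eigen")
}

#' Adjust phenotypes for population structure
#'
#' Per trait-by-environment, replaces values by least-squares residuals of a
#' regression on an intercept plus the first `n_axes` GRM eigenvectors. With
#' `n_axes = 0` this is a per-environment centering.
#'
#' @param trait data.frame with `accession`, `environment`, `value`.
#' @param decomp a [eigen_grm()] object covering every phenotyped accession.
#' @param n_axes number of leading eigenvectors to regress out (default 5).
#' @param pool_environments if `TRUE`, fit one projection across all
#'   environments instead of one per environment.
#' @return The trait data.frame with adjusted `value`.
#' @export
adjust_for_structure <- function(trait, decomp, n_axes = 5,
                                 pool_environments = FALSE) {
  stopifnot(is.data.frame(trait), inherits(decomp, "grm_eigen"))
  if (n_axes > ncol(decomp$vectors))
    stop_genpred("n_axes = %d exceeds the %d available eigenvectors",
                 n_axes, ncol(decomp$vectors))
  idx <- match(trait$accession, decomp$accession_ids)
  if (anyNA(idx))
    stop_genpred("accessions absent from the decomposition: %s",
                 paste(utils::head(unique(trait$accession[is.na(idx)]), 5), collapse = ", "))
  resid_fit <- function(rows) {
    y <- trait$value[rows]
    obs <- !is.na(y)
    X <- cbind(1, decomp$vectors[idx[rows], seq_len(n_axes), drop = FALSE])
    r <- y
    r[obs] <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])$residuals
    r
  }
  out <- trait
  if (pool_environments) {
    out$value <- resid_fit(seq_len(nrow(trait)))
  } else {
    for (e in unique(trait$environment)) {
      rows <- which(trait$environment == e)
      out$value[rows] <- resid_fit(rows)
    }
  }
  out
}
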