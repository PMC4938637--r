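# Shared fixtures, all generated in code.

# tiny deterministic genotype object from an explicit dosage matrix
toy_geno <- function(dosage, groups = NULL) {
  new_genotypes(dosage,
                accession_ids = paste0("a", seq_len(nrow(dosage))),
                marker_ids = paste0("m", seq_len(ncol(dosage))),
                group_labels = groups)
}

# prepared random genotypes + GRM in one call
quick_grm <- function(n, p, seed = 1, n_groups = 1, divergence = 0) {
  g <- simulate_genotypes(n, p, n_groups = n_groups, divergence = divergence,
                          seed = seed)
  gp <- prepare_markers(g, maf_min = 0.02)
  list(geno = gp, grm = compute_grm(gp))
}

# random PSD matrix of dimension n with unit-scale diagonal
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n, 2 * n)
  K <- tcrossprod(A) / (2 * n)
  (K + t(K)) / 2
}
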