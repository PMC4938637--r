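# Cross-validation designs and accuracy summaries: random TRN20-TST80 splits,
# CV1 accession-level holdout across environments, core-as-training
# evaluation, Pearson accuracies, and percent-change tables.

#' Build cross-validation partitions
#'
#' Random accession-level train/test splits. Under every scheme the split is
#' at the accession level, so a test accession has no training record in any
#' environment (the CV1 guarantee). `"core-as-training"` produces a single
#' replicate with the supplied core as the training set.
#'
#' @param accession_ids the full accession set.
#' @param scheme `"random-single-env"`, `"CV1-two-env"` or
#'   `"core-as-training"`.
#' @param train_fraction fraction of accessions in training, in `(0, 1)`.
#' @param n_replicates number of random replicates (ignored for cores).
#' @param seed integer seed; replicate streams are derived from
#'   `(seed, replicate)` so each replicate is individually reproducible.
#' @param core_ids training accessions for `"core-as-training"`.
#' @return An object of class `partition_set`: list of replicates, each with
#'   `train_ids` and `test_ids`.
#' @export
make_partitions <- function(accession_ids,
                            scheme = c("random-single-env", "CV1-two-env",
                                       "core-as-training"),
                            train_fraction = 0.2, n_replicates = 30,
                            seed = 1, core_ids = NULL) {
  scheme <- match.arg(scheme)
  accession_ids <- as.character(accession_ids)
  n <- length(accession_ids)
  if (scheme == "core-as-training") {
    if (is.null(core_ids)) stop_genpred("core-as-training requires core_ids")
    core_ids <- as.character(core_ids)
    if (!all(core_ids %in% accession_ids))
      stop_genpred("core_ids contain unknown accessions")
    reps <- list(list(train_ids = core_ids,
                      test_ids = setdiff(accession_ids, core_ids)))
  } else {
    check_scalar(train_fraction, "train_fraction", 0, 1, TRUE, TRUE)
    check_scalar(n_replicates, "n_replicates", lower = 1)
    n_train <- round(train_fraction * n)
    if (n_train < 2) stop_genpred("training set of size %d (< 2)", n_train)
    if (n_train >= n) stop_genpred("empty test set")
    reps <- lapply(seq_len(n_replicates), function(r) {
      set.seed(derive_seed(seed, r))
      tr <- sample(accession_ids, n_train)
      list(train_ids = tr, test_ids = setdiff(accession_ids, tr))
    })
  }
  structure(list(scheme = scheme, replicates = reps,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "partition_set")
}

# Correlation summaries for one replicate: per environment, pooled after
# within-environment centering (primary), and raw pooled.
replicate_accuracy <- function(obs_df, pred) {
  envs <- unique(obs_df$environment)
  per_env <- vapply(envs, function(e) {
    rows <- obs_df$environment == e
    safe_cor(obs_df$value[rows], pred[rows])
  }, numeric(1))
  names(per_env) <- envs
  o_c <- obs_df$value; p_c <- pred
  for (e in envs) {
    rows <- obs_df$environment == e
    o_c[rows] <- o_c[rows] - mean(o_c[rows])
    p_c[rows] <- p_c[rows] - mean(p_c[rows])
  }
  list(per_env = per_env,
       pooled_centered = safe_cor(o_c, p_c),
       pooled_raw = safe_cor(obs_df$value, pred))
}

#' Evaluate prediction accuracy under a partition design
#'
#' For every replicate, fits the model on the training accessions' records
#' only (the full GRM couples unobserved accessions), predicts the test
#' records, and reports Pearson correlations per environment plus the pooled
#' correlation across environments after within-environment centering of
#' observed and predicted values.
#'
#' @param trait data.frame with `accession`, `environment`, `value`.
#' @param grm a [compute_grm()] object covering all accessions.
#' @param spec a [model_spec()]. For repeated cross-validation a
#'   `method = "fixed"` spec (components from a pilot fit) keeps each
#'   replicate a single linear solve.
#' @param partitions a [make_partitions()] object.
#' @return An object of class `accuracy_report`: per-replicate correlations,
#'   their mean and SD (SD is `NA` for a single core replicate), the model
#'   name and scheme.
#' @export
evaluate <- function(trait, grm, spec, partitions) {
  stopifnot(is.data.frame(trait), inherits(partitions, "partition_set"))
  all_ids <- unique(as.character(trait$accession))
  if (!all(all_ids %in% grm$accession_ids))
    stop_genpred("trait contains accessions absent from the GRM")
  reps <- partitions$replicates
  rows <- lapply(seq_along(reps), function(r) {
    part <- reps[[r]]
    train <- trait[trait$accession %in% part$train_ids, , drop = FALSE]
    test <- trait[trait$accession %in% part$test_ids & !is.na(trait$value), ,
                  drop = FALSE]
    if (nrow(test) < 3) stop_genpred("fewer than 3 observed test records")
    rspec <- spec
    if (spec$method == "gibbs") rspec$seed <- derive_seed(spec$seed, r)
    fit <- fit_model(train, grm, rspec)
    pred <- predict(fit, test[, c("accession", "environment")])
    acc <- replicate_accuracy(test, pred$predicted)
    c(replicate = r, acc$per_env, pooled = acc$pooled_centered,
      pooled_raw = acc$pooled_raw)
  })
  per_replicate <- as.data.frame(do.call(rbind, rows))
  pooled <- per_replicate$pooled
  structure(list(scheme = partitions$scheme, model = spec$name,
                 per_replicate = per_replicate,
                 mean = mean(pooled), sd = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
                 mean_by_env = colMeans(per_replicate[, setdiff(names(per_replicate),
                   c("replicate", "pooled", "pooled_raw")), drop = FALSE]),
                 n_replicates = length(reps)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%s / %s: mean accuracy %.3f (SD %s) over %d replicate(s)\n",
              x$model, x$scheme, x$mean,
              if (is.na(x$sd)) "-" else sprintf("%.3f", x$sd), x$n_replicates))
  invisible(x)
}

#' Percent change in prediction accuracy vs a reference design
#'
#' `100 * (mean_ref - mean_candidate) / mean_ref` per candidate report;
#' positive values mean the candidate predicts worse than the reference.
#'
#' @param reference an [evaluate()] report (e.g. TRN20-TST80).
#' @param candidate a single report or a list of reports (averaged row-wise
#'   when a list of (reference, candidate) pairings over traits is intended,
#'   supply matched lists to both arguments).
#' @return data.frame with `candidate`, `reference_mean`, `candidate_mean`,
#'   `percent_change`.
#' @export
percent_change <- function(reference, candidate) {
  refs <- if (inherits(reference, "accuracy_report")) list(reference) else reference
  cands <- if (inherits(candidate, "accuracy_report")) list(candidate) else candidate
  if (length(refs) == 1 && length(cands) > 1) refs <- rep(refs, length(cands))
  if (length(refs) != length(cands))
    stop_genpred("reference and candidate lists must have equal length")
  rows <- mapply(function(r, c) {
    if (r$mean == 0) stop_genpred("zero reference mean accuracy")
    data.frame(candidate = paste(c$model, c$scheme, sep = "/"),
               reference_mean = r$mean, candidate_mean = c$mean,
               percent_change = 100 * (r$mean - c$mean) / r$mean,
               stringsAsFactors = FALSE)
  }, refs, cands, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Pilot variance components for repeated cross-validation
#'
#' Runs one Gibbs fit on the supplied records and returns its posterior-mean
#' variance components, for reuse in a `method = "fixed"` [model_spec()]
#' across CV replicates (two-stage estimation).
#'
#' @param trait,grm as in [fit_model()].
#' @param name model name.
#' @param iterations,burnin,thin,seed chain settings for the pilot.
#' @return Named variance-component vector.
#' @export
pilot_components <- function(trait, grm, name, iterations = 1500,
                             burnin = 500, thin = 5, seed = 1) {
  spec <- model_spec(name, method = "gibbs", iterations = iterations,
                     burnin = burnin, thin = thin, seed = seed)
  fit <- fit_model(trait, grm, spec)
  fit$variance_components
}
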