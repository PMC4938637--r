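# Config-driven pipeline runner tying the stages together:
# simulate -> spatial_adjust -> grm -> structure -> core -> fit -> evaluate.
# Every stage's parameters are validated against a schema before any
# computation starts; outputs are delimited text / JSON plus a manifest with
# per-output checksums.

# schema: per stage, allowed parameters with a validator each.
num_in <- function(lo, hi, strict_lo = FALSE, strict_hi = FALSE) {
  function(x, name) check_scalar(x, name, lo, hi, strict_lo, strict_hi)
}
is_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L)
    stop_genpred("'%s' must be a single string", name)
}
is_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_genpred("'%s' must be TRUE or FALSE", name)
}
is_numvec <- function(x, name) {
  if (!is.numeric(x)) stop_genpred("'%s' must be numeric", name)
}

pipeline_schema <- function() list(
  simulate = list(
    n_accessions = num_in(2, Inf), n_markers = num_in(1, Inf),
    n_groups = num_in(1, Inf), divergence = num_in(0, 1, FALSE, TRUE),
    maf_range = is_numvec, missing_rate = num_in(0, 1, FALSE, TRUE),
    n_envs = num_in(1, 2), mu = num_in(-Inf, Inf),
    variance_components = is_numvec),
  spatial_adjust = list(trial = is_string, environment = is_string),
  grm = list(geno = is_string, maf_min = num_in(0, 0.5),
             callrate_min = num_in(0, 1)),
  structure = list(n_axes = num_in(0, Inf), pool_environments = is_flag),
  core = list(method = is_string, fraction = num_in(0, 1, TRUE, TRUE),
              n_clusters = num_in(1, Inf), n_candidates = num_in(1, Inf),
              h2 = num_in(0, 1, TRUE, FALSE), n_pcs = num_in(1, Inf)),
  fit = list(model = is_string, method = is_string,
             iterations = num_in(10, Inf), burnin = num_in(0, Inf),
             thin = num_in(1, Inf), components = is_numvec),
  evaluate = list(model = is_string, scheme = is_string,
                  train_fraction = num_in(0, 1, TRUE, TRUE),
                  n_replicates = num_in(1, Inf),
                  iterations = num_in(10, Inf), burnin = num_in(0, Inf),
                  thin = num_in(1, Inf), use_core = is_flag)
)

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stages))
    stop_genpred("config must be a list (or YAML file) with a 'stages' element")
  schema <- pipeline_schema()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(schema))
      stop_genpred("stage %d: unknown stage '%s' (known: %s)", i,
                   st$stage %||% "<missing>", paste(names(schema), collapse = ", "))
    params <- st[setdiff(names(st), "stage")]
    allowed <- schema[[st$stage]]
    for (pn in names(params)) {
      if (!pn %in% names(allowed))
        stop_genpred("stage '%s': unknown parameter '%s'", st$stage, pn)
      allowed[[pn]](params[[pn]], pn)
    }
  }
  config
}

#' Run the genomic-prediction pipeline from a configuration
#'
#' Executes the configured stages in order, passing objects between stages
#' (a `grm` stage consumes the genotypes of an earlier `simulate` stage, an
#' `evaluate` stage the most recent fit/core, and so on), writing per-stage
#' delimited-text/JSON outputs under `out_dir`, and returning a manifest with
#' parameter echoes and MD5 checksums of every output. All stage parameters
#' are validated before any computation starts; rerunning an identical config
#' reproduces identical outputs.
#'
#' @param config list or YAML file path with elements `seed` (global seed;
#'   stage seeds are derived from it) and `stages` (ordered list; each entry
#'   has a `stage` name plus that stage's parameters).
#' @param out_dir output directory (created if needed).
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  seed <- as.integer(config$seed %||% 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list(package = "genpred",
                   version = as.character(utils::packageVersion("genpred")),
                   seed = seed, stages = list())
  need <- function(what, stage) {
    if (!exists(what, envir = state))
      stop_genpred("stage '%s' needs a '%s' from an earlier stage or file parameter",
                   stage, what)
    get(what, envir = state)
  }
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    p <- st[setdiff(names(st), "stage")]
    sseed <- derive_seed(seed, i)
    outputs <- character(0)
    switch(st$stage,
      simulate = {
        geno <- simulate_genotypes(
          p$n_accessions %||% 200, p$n_markers %||% 500,
          n_groups = p$n_groups %||% 1, divergence = p$divergence %||% 0,
          maf_range = p$maf_range %||% c(0.05, 0.5),
          missing_rate = p$missing_rate %||% 0, seed = sseed)
        vc <- p$variance_components %||% default_variance_components()
        sim <- simulate_phenotypes(geno, vc, n_envs = p$n_envs %||% 2,
                                   mu = p$mu %||% 0, seed = derive_seed(sseed, 1))
        assign("geno", geno, state); assign("trait", sim$trait, state)
        assign("truth", sim$truth, state)
        outputs <- c(write_genotypes(geno, file.path(out_dir, "geno.tsv")),
                     write_trait(sim$trait, file.path(out_dir, "pheno.tsv")))
      },
      spatial_adjust = {
        trial <- if (!is.null(p$trial)) read_trial(p$trial, p$environment %||% "OPT")
                 else need("trial", "spatial_adjust")
        sfit <- fit_ar1xar1(trial)
        adj <- adjust_phenotypes(trial, sfit)
        assign("trait", adj, state)
        rep_path <- file.path(out_dir, "spatial.json")
        jsonlite::write_json(list(rho_row = sfit$rho_row, rho_col = sfit$rho_col,
                                  sigma_spatial2 = sfit$sigma_spatial2,
                                  sigma_nugget2 = sfit$sigma_nugget2,
                                  loglik = sfit$loglik),
                             rep_path, auto_unbox = TRUE, digits = NA)
        outputs <- c(write_trait(adj, file.path(out_dir, "adjusted_pheno.tsv")),
                     rep_path)
      },
      grm = {
        geno <- if (!is.null(p$geno)) read_genotypes(p$geno)
                else need("geno", "grm")
        geno <- prepare_markers(geno, p$maf_min %||% 0.05,
                                p$callrate_min %||% 0.80)
        grm <- compute_grm(geno)
        assign("geno", geno, state); assign("grm", grm, state)
        outputs <- write_grm(grm, file.path(out_dir, "grm.tsv"))
      },
      structure = {
        grm <- need("grm", "structure")
        trait <- need("trait", "structure")
        dec <- eigen_grm(grm)
        adj <- adjust_for_structure(trait, dec, n_axes = p$n_axes %||% 5,
                                    pool_environments = p$pool_environments %||% FALSE)
        assign("trait", adj, state); assign("decomp", dec, state)
        scree <- data.frame(component = seq_along(dec$values),
                            eigenvalue = dec$values, cumvar = dec$cumvar)
        scree_path <- file.path(out_dir, "scree.tsv")
        utils::write.table(scree, scree_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs <- c(write_trait(adj, file.path(out_dir, "structure_adjusted_pheno.tsv")),
                     scree_path)
      },
      core = {
        method <- p$method %||% "diversity"
        plan <- if (method == "diversity") {
          diversity_core(need("geno", "core"), p$fraction %||% 0.2,
                         n_clusters = p$n_clusters,
                         n_candidates = p$n_candidates %||% 1000, seed = sseed)
        } else if (method == "prediction") {
          prediction_core(need("grm", "core"), p$fraction %||% 0.2,
                          h2 = p$h2 %||% 0.5, n_pcs = p$n_pcs, seed = sseed)
        } else stop_genpred("core method must be 'diversity' or 'prediction'")
        assign("core", plan, state)
        core_path <- file.path(out_dir, sprintf("core_%s.json", method))
        jsonlite::write_json(list(method = plan$method, fraction = plan$fraction,
                                  selected_ids = plan$selected_ids,
                                  seed = plan$seed),
                             core_path, auto_unbox = TRUE, digits = NA)
        outputs <- core_path
      },
      fit = {
        grm <- need("grm", "fit"); trait <- need("trait", "fit")
        spec <- model_spec(p$model %||% "M3", method = p$method %||% "gibbs",
                           components = p$components,
                           iterations = p$iterations %||% 6000,
                           burnin = p$burnin %||% 1000, thin = p$thin %||% 5,
                           seed = sseed)
        fit <- fit_model(trait, grm, spec)
        assign("fit", fit, state)
        fit_path <- file.path(out_dir, "fit.json")
        jsonlite::write_json(list(model = fit$model, mu = fit$mu,
                                  variance_components = as.list(fit$variance_components),
                                  within_env_percentages = as.list(fit$within_env_percentages),
                                  seed = spec$seed),
                             fit_path, auto_unbox = TRUE, digits = NA)
        pred_path <- file.path(out_dir, "pred.tsv")
        utils::write.table(fit$predictions, pred_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs <- c(fit_path, pred_path)
      },
      evaluate = {
        grm <- need("grm", "evaluate"); trait <- need("trait", "evaluate")
        scheme <- p$scheme %||% "random-single-env"
        parts <- if (isTRUE(p$use_core)) {
          make_partitions(unique(trait$accession), "core-as-training",
                          core_ids = need("core", "evaluate")$selected_ids,
                          seed = sseed)
        } else {
          make_partitions(unique(trait$accession), scheme,
                          train_fraction = p$train_fraction %||% 0.2,
                          n_replicates = p$n_replicates %||% 30, seed = sseed)
        }
        comps <- pilot_components(trait, grm, p$model %||% "M3",
                                  iterations = p$iterations %||% 1500,
                                  burnin = p$burnin %||% 500,
                                  thin = p$thin %||% 5, seed = sseed)
        spec <- model_spec(p$model %||% "M3", method = "fixed",
                           components = comps, seed = sseed)
        rep <- evaluate(trait, grm, spec, parts)
        assign("report", rep, state)
        rep_path <- file.path(out_dir, sprintf("report_%d.json", i))
        jsonlite::write_json(list(scheme = rep$scheme, model = rep$model,
                                  mean = rep$mean, sd = rep$sd,
                                  per_replicate = rep$per_replicate,
                                  components = as.list(comps)),
                             rep_path, auto_unbox = TRUE, digits = NA)
        outputs <- rep_path
      }
    )
    manifest$stages[[i]] <- list(stage = st$stage, params = p, seed = sseed,
                                 outputs = basename(outputs),
                                 checksums = unname(tools::md5sum(outputs)))
  }
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
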