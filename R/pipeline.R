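#' Declarative configuration for the end-to-end pipeline
#'
#' One document holding the sizes, seeds and options of every stage:
#' synthetic cohort (or user data), simulation library, posterior training,
#' evaluation and gene linkage. Unknown keys raise a validation error before
#' any computation.
#'
#' @param ... Overrides of the default fields, either as nested lists
#'   (`cohort`, `library`, `training`, `evaluate`, `link`) or the top-level
#'   fields `seed` and `out_dir`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    out_dir = "ephyslink_run",
    cohort = list(n_cells = 30, n_genes = 100, n_active_genes = 15,
                  phi = 2, misspecify = FALSE, offset = 0.5,
                  offset_feature = "ap_width"),
    library = list(n = 2000, batch = 200),
    training = list(scheme = "noise_ephys", sigma = 0.1, n_close = 1000,
                    n_hidden = 50, n_components = 4, max_epochs = 100),
    evaluate = list(n_post = 10, n_map_samples = 2000),
    link = list(rank = 2, alpha = 0.5, folds = 5, n_lambda = 30))
  validate_pipeline_config(merge_config(defaults, list(...)), defaults)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_pipeline_config <- function(cfg, defaults) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(cfg[[nm]]), names(defaults[[nm]]))
      if (length(bad))
        stop("unknown pipeline config key(s) in '", nm, "': ",
             paste(bad, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic pipeline: cohort, library, posterior, linkage
#'
#' Executes the stages in order — synthetic cohort generation, prior
#' simulation library, density-estimator training, posterior evaluation by
#' re-simulation, and sparse reduced-rank gene linkage — and writes all
#' artifacts (CSV tables, fitted models as RDS, provenance metadata) under
#' `config$out_dir`. Idempotent given identical config and seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `lib`, `model`, `fit`, `cv`, `srrr`, `group`).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  say("[1/5] synthetic cohort (%d cells)", config$cohort$n_cells)
  cohort <- make_cohort(n_cells = config$cohort$n_cells,
                        n_genes = config$cohort$n_genes,
                        n_active_genes = config$cohort$n_active_genes,
                        phi = config$cohort$phi, seed = seed)
  write_cohort(cohort, config$out_dir)

  say("[2/5] prior simulation library (n = %d)", config$library$n)
  lib <- build_library(n = config$library$n, batch = config$library$batch,
                       protocol = cohort$protocol, seed = seed + 1)
  write_library(lib, file.path(config$out_dir, "library"))

  obs <- apply_standardizer(cohort$features_trans, lib$std)
  if (isTRUE(config$cohort$misspecify))
    obs <- misspecify(obs, misspec_spec(config$cohort$offset,
                                        config$cohort$offset_feature))

  say("[3/5] posterior training (scheme %s)", config$training$scheme)
  tc <- npe_config(scheme = config$training$scheme,
                   sigma = config$training$sigma,
                   n_close = config$training$n_close,
                   n_hidden = config$training$n_hidden,
                   n_components = config$training$n_components,
                   max_epochs = config$training$max_epochs,
                   seed = seed + 2)
  pairs <- build_training_set(lib, obs, tc)
  model <- train_npe(pairs, tc, prior = lib$prior)
  saveRDS(model, file.path(config$out_dir, "posterior_model.rds"))

  say("[4/5] posterior evaluation (%d cells)", nrow(obs))
  fit <- evaluate_fit(model, obs, lib, n_post = config$evaluate$n_post,
                      n_map_samples = config$evaluate$n_map_samples,
                      seed = seed + 3)
  set.seed(seed + 5)
  fit$per_cell$entropy <- vapply(seq_len(nrow(obs)), function(i)
    posterior_entropy(model, obs[i, ], n_draws = 1000), numeric(1))
  data.table::fwrite(fit$per_cell, file.path(config$out_dir, "fit_per_cell.csv"))
  data.table::fwrite(fit$aggregate, file.path(config$out_dir, "fit_aggregate.csv"))

  say("[5/5] gene linkage (rank %d sRRR)", config$link$rank)
  X <- preprocess_expression(cohort$counts)
  Y <- scale(fit$map_theta)
  lam <- srrr_lambda_path(X, Y, config$link$alpha,
                          n_lambda = config$link$n_lambda)
  cv <- cv_srrr(X, Y, lam, alpha = config$link$alpha,
                rank = config$link$rank, folds = config$link$folds,
                seed = seed + 4)
  best <- cv$lambda[which.max(cv$r2_mean)]
  srrr <- fit_srrr(X, Y, rank = config$link$rank, lambda = best,
                   alpha = config$link$alpha)
  grp <- group_compare(fit$map_theta, predict_theta(srrr, X, fit$map_theta),
                       cohort$family)
  data.table::fwrite(cv, file.path(config$out_dir, "cv_curve.csv"))
  data.table::fwrite(data.table::data.table(
    parameter = param_names(),
    r2 = as.numeric(r2_per_parameter(srrr, X, Y))),
    file.path(config$out_dir, "r2_per_parameter.csv"))
  data.table::fwrite(data.table::as.data.table(latent_coords(srrr, X)),
                     file.path(config$out_dir, "latent.csv"))
  saveRDS(srrr, file.path(config$out_dir, "srrr_model.rds"))
  data.table::fwrite(data.table::data.table(
    group = rownames(grp$map_means),
    distance_contribution = sqrt(rowSums((grp$map_means - grp$pred_means)^2)),
    total_distance = grp$distance),
    file.path(config$out_dir, "group_distances.csv"))

  provenance <- list(
    package_version = as.character(utils::packageVersion("ephyslink")),
    seed = seed, config = unclass(config),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(provenance, file.path(config$out_dir, "run_info.yaml"))

  invisible(list(cohort = cohort, lib = lib, model = model, fit = fit,
                 cv = cv, srrr = srrr, group = grp))
}

# sRRR predictions mapped back to original parameter units (training Y was
# column-standardized against the MAP cohort)
predict_theta <- function(srrr, X, theta_ref) {
  P <- predict(srrr, X)
  sweep(sweep(P, 2, apply(theta_ref, 2, sd), "*"), 2, colMeans(theta_ref), "+")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}
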