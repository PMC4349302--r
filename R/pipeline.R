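#  Pipeline orchestration: staged runs with JSON manifests.
#
#  Each stage reads only its declared inputs and writes versioned outputs
#  plus a manifest (input hashes, seed, settings) so every downstream
#  number is traceable to a seed and configuration.  Re-running a stage
#  with an identical configuration reproduces identical artifacts.

.manifest <- function(stage, config, inputs, outputs) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_, "")
  settings <- config[setdiff(names(config), "out_dir")]
  if (!is.null(settings$noise)) settings$noise <- unclass(settings$noise)
  list(stage = stage,
       seed = config$seed,
       settings = settings,
       inputs = as.list(setNames(hashes, inputs)),
       outputs = outputs)
}

.write_manifest <- function(m, dir) {
  jsonlite::write_json(m, file.path(dir, paste0("manifest_", m$stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param variant model variant for single-model stages.
#' @param seed RNG seed (all randomness in the pipeline derives from it;
#'   no wall-clock seeding).
#' @param levels,iterations,runs,burn_in sampler settings (desk-scale
#'   defaults: 4 levels, 20000 iterations, 3 runs; the study-scale setting
#'   of 10 levels and 5e5 iterations is available by configuration).
#' @param ladder_power exponent of the power-law temperature ladder
#'   (default 10, the desk-scale choice -- see the methods vignette).
#' @param n_posterior posterior subsample size for predictions.
#' @param noise a [noise_spec()].
#' @return A configuration list.
#' @export
pipeline_config <- function(out_dir, variant = "A", seed = 1L,
                            levels = 4L, iterations = 20000L, runs = 3L,
                            burn_in = 0.5, n_posterior = 200L,
                            noise = noise_spec(), map_starts = 5L,
                            map_maxit = 100L, ladder_power = 10) {
  list(out_dir = out_dir, variant = variant, seed = as.integer(seed),
       levels = as.integer(levels), iterations = as.integer(iterations),
       runs = as.integer(runs), burn_in = burn_in,
       n_posterior = as.integer(n_posterior), noise = noise,
       ladder_power = ladder_power,
       map_starts = as.integer(map_starts),
       map_maxit = as.integer(map_maxit))
}

.pipe_paths <- function(config) {
  d <- config$out_dir
  list(dir = d,
       dataset = file.path(d, "dataset.csv"),
       truth = file.path(d, "ground_truth.json"),
       protocols = file.path(d, "protocols.json"),
       map = file.path(d, "map_estimates.csv"),
       prior = function(v) file.path(d, paste0("prior_", v, ".json")),
       chains = function(v) file.path(d, paste0("chains_", v, ".rds.csv")),
       evidence = file.path(d, "evidence.json"),
       predictions = file.path(d, "endogenous_predictions.csv"),
       perturbations = file.path(d, "perturbation_responses.json"))
}

# chains are persisted as a flat CSV (level, run, iteration, logl, params)
.write_chains <- function(chains, path) {
  L <- length(chains$ladder)
  rows <- list()
  for (r in seq_along(chains$runs)) {
    run <- chains$runs[[r]]
    for (l in seq_len(L)) {
      df <- as.data.frame(run$samples[, , l, drop = TRUE])
      names(df) <- chains$parameter_names
      df$level <- l; df$beta <- chains$ladder[l]
      df$run <- r; df$iteration <- seq_len(nrow(df))
      df$logl <- run$logl[, l]
      rows[[length(rows) + 1L]] <- df
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "_meta.json", path)
  jsonlite::write_json(
    list(ladder = chains$ladder, n_iter = chains$n_iter,
         n_burn = chains$n_burn, seed = chains$seed,
         parameter_names = chains$parameter_names,
         accept = lapply(chains$runs, `[[`, "accept_rate"),
         swap = lapply(chains$runs, `[[`, "swap_rate")),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run pipeline stages
#'
#' Stages: `synth` (generate data), `fit` (multistart MAP), `sample`
#' (parallel-tempering MCMC for the configured variant), `evidence`
#' (requires chains for both variants), `predict`, `perturb`, `quantify`
#' (standard-curve demonstration on synthetic blot intensities), or
#' `all`.
#'
#' @param config a [pipeline_config()] list.
#' @param stage stage name.
#' @return Invisibly, the manifest of the last stage run.
#' @export
run_pipeline <- function(config,
                         stage = c("all", "synth", "fit", "sample",
                                   "evidence", "predict", "perturb",
                                   "quantify")) {
  stage <- match.arg(stage)
  if (stage == "all") {
    for (s in c("synth", "fit", "sample", "evidence", "predict",
                "perturb", "quantify"))
      m <- run_pipeline(config, s)
    return(invisible(m))
  }
  paths <- .pipe_paths(config)
  if (!dir.exists(paths$dir)) dir.create(paths$dir, recursive = TRUE)
  v <- config$variant

  need <- function(f, producer) {
    if (!file.exists(f))
      abort(paste0("stage `", stage, "` needs ", basename(f),
                   "; run stage `", producer, "` first"))
  }

  if (stage == "synth") {
    syn <- generate_dataset(v, protocols = default_protocols(),
                            noise = config$noise, seed = config$seed)
    write.csv(syn$dataset, paths$dataset, row.names = FALSE)
    jsonlite::write_json(
      list(variant = v, parameters = as.list(syn$truth$parameters),
           seed = config$seed),
      paths$truth, auto_unbox = TRUE, digits = NA)
    write_protocol_json(default_protocols(), paths$protocols)
    out <- c(paths$dataset, paths$truth, paths$protocols)
    m <- .manifest(stage, config, character(), out)
  } else if (stage == "fit") {
    need(paths$dataset, "synth"); need(paths$protocols, "synth")
    model <- build_model(v)
    dataset <- read_dataset(paths$dataset)
    protocols <- read_protocol_json(paths$protocols)
    center <- ground_truth(v)
    prior <- default_prior(model, center)
    fit <- multistart_map(model, dataset, protocols, prior,
                          n_starts = config$map_starts, seed = config$seed,
                          init = log10(center), maxit = config$map_maxit)
    best <- fit$par[[1]]
    write.csv(tibble(parameter = names(best), map_log10 = as.numeric(best),
                     log_posterior = fit$value[1]),
              paths$map, row.names = FALSE)
    prior2 <- default_prior(model, setNames(10^best, names(best)))
    jsonlite::write_json(
      setNames(lapply(prior2$names, function(p)
        c(prior2$lower[[p]], prior2$upper[[p]])), prior2$names),
      paths$prior(v), digits = NA)
    m <- .manifest(stage, config, c(paths$dataset, paths$protocols),
                   c(paths$map, paths$prior(v)))
  } else if (stage == "sample") {
    need(paths$dataset, "synth"); need(paths$prior(v), "fit")
    model <- build_model(v)
    dataset <- read_dataset(paths$dataset)
    protocols <- read_protocol_json(paths$protocols)
    pb <- jsonlite::read_json(paths$prior(v))
    prior <- prior_spec(vapply(pb, function(x) x[[1]], 0),
                        vapply(pb, function(x) x[[2]], 0))
    map <- read.csv(paths$map)
    target <- tempered_target(model, dataset, protocols, prior)
    chains <- pt_sample(target,
                        ladder_beta(config$levels, config$ladder_power),
                        n_iter = config$iterations, n_runs = config$runs,
                        seed = config$seed,
                        init = setNames(map$map_log10, map$parameter),
                        burn_in = config$burn_in)
    .write_chains(chains, paths$chains(v))
    saveRDS(chains, file.path(paths$dir, paste0("chains_", v, ".rds")))
    m <- .manifest(stage, config,
                   c(paths$dataset, paths$protocols, paths$prior(v)),
                   paths$chains(v))
  } else if (stage == "evidence") {
    fa <- file.path(paths$dir, "chains_A.rds")
    fb <- file.path(paths$dir, "chains_B.rds")
    need(fa, "sample (variant A)"); need(fb, "sample (variant B)")
    evA <- model_evidence(readRDS(fa), "A", config$burn_in)
    evB <- model_evidence(readRDS(fb), "B", config$burn_in)
    bf <- bayes_factor(evA, evB)
    jsonlite::write_json(
      list(logZ_A = evA$logZ, se_A = evA$se,
           logZ_B = evB$logZ, se_B = evB$se,
           two_log_k = bf$two_log_k, se = bf$se, category = bf$category),
      paths$evidence, auto_unbox = TRUE, digits = NA)
    m <- .manifest(stage, config, c(fa, fb), paths$evidence)
  } else if (stage %in% c("predict", "perturb")) {
    f <- file.path(paths$dir, paste0("chains_", v, ".rds"))
    need(f, "sample")
    chains <- readRDS(f)
    model <- build_model(v)
    draws <- subsample_posterior(chains, config$n_posterior,
                                 seed = config$seed,
                                 burn_in = config$burn_in)
    colnames(draws) <- chains$parameter_names
    if (stage == "predict") {
      pred <- endogenous_distributions(model, draws)
      write.csv(pred$summary, paths$predictions, row.names = FALSE)
      m <- .manifest(stage, config, f, paths$predictions)
    } else {
      res <- lapply(c("feedback_knockout", "transfer_up_10", "pkd_up_10"),
                    function(s) {
                      r <- perturbation_response(model, draws, s)
                      list(scenario = s, expected_pct = r$expectation,
                           n_dropped = r$n_dropped)
                    })
      jsonlite::write_json(res, paths$perturbations,
                           auto_unbox = TRUE, digits = NA)
      m <- .manifest(stage, config, f, paths$perturbations)
    }
  } else {  # quantify
    std <- with_seed(config$seed, {
      mol <- c(2, 5, 10, 20, 50, 100) * 1e6
      tibble(molecules = mol,
             intensity = 2e-6 * mol + 3 + rnorm(6, 0, 1.5))
    })
    curve <- fit_standard_curve(std)
    inv <- inverse_predict(curve, intensity = 60)
    ab <- endogenous_abundance(ratio = 0.5,
                               ectopic_molecules = inv$molecules,
                               n_cells = 1e4,
                               cvs = c(0.3, inv$se / inv$molecules))
    out <- file.path(paths$dir, "quantification.json")
    jsonlite::write_json(
      list(standard_curve = as.list(glance(curve)),
           inverse_prediction = as.list(inv),
           endogenous = as.list(ab)),
      out, auto_unbox = TRUE, digits = NA)
    m <- .manifest(stage, config, character(), out)
  }
  .write_manifest(m, paths$dir)
  invisible(m)
}
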