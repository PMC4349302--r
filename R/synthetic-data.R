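#  Synthetic-data generation.
#
#  Stands in for the study's western-blot measurements: noise-free
#  trajectories from a documented ground-truth parameterization, absolute
#  steady-state quantification with a 25-40% coefficient of variation, and
#  relative phospho time courses with additive Gaussian noise scaled to
#  each course's maximum.

#' Noise specification
#'
#' @param cv_abs coefficient of variation of absolute quantification
#'   replicates (default 0.30; validated to the plausible blot range
#'   0.25--0.40 unless `validate = FALSE`).
#' @param rel_sd_frac SD of relative phospho measurements as a fraction of
#'   each time course's noise-free maximum (default 0.10).
#' @param n_replicates replicates per absolute record (default 3).
#' @param validate enforce the admissible CV range.
#' @return A list of class `ck_noise`.
#' @export
noise_spec <- function(cv_abs = 0.30, rel_sd_frac = 0.10,
                       n_replicates = 3L, validate = TRUE) {
  if (validate && (cv_abs < 0.25 || cv_abs > 0.40) && cv_abs != 0)
    abort("cv_abs outside the plausible 0.25-0.40 range; use validate = FALSE to override")
  stopifnot(rel_sd_frac >= 0, n_replicates >= 1)
  structure(list(cv_abs = cv_abs, rel_sd_frac = rel_sd_frac,
                 n_replicates = as.integer(n_replicates)),
            class = "ck_noise")
}

#' Shipped ground-truth parameterization
#'
#' Reads the documented synthetic ground-truth parameter file for a model
#' variant.  These values are a fixture: chosen so endogenous totals sit
#' near the measured orders of magnitude (PI4KIIIbeta ~2e6, PKD and CERT
#' ~5e5 molecules/cell), most PKD and PI4KIIIbeta mass is unphosphorylated
#' at rest, the basal PKD activation flux is about two orders of magnitude
#' above the transfer-dependent channel, and the variant-specific feedback
#' signs hold.
#'
#' @param variant `"A"` or `"B"`.
#' @return Named parameter vector (linear scale).
#' @export
ground_truth <- function(variant = c("A", "B")) {
  variant <- match.arg(variant)
  path <- system.file("extdata",
                      paste0("ground_truth_", variant, ".json"),
                      package = "certkinetics", mustWork = TRUE)
  p <- jsonlite::read_json(path)
  p <- unlist(p[!startsWith(names(p), "_")])
  model <- build_model(variant)
  .check_params(model, p)
}

#' Default calibration protocols
#'
#' The five experiment families used for calibration, refinement and
#' validation:
#' \describe{
#'   \item{E1}{endogenous absolute quantification: all inputs off, total
#'     PKD, PI4KIIIbeta and CERT at steady state.}
#'   \item{E2}{ectopic PI4KIIIbeta from 0 h (u3); total PI4KIIIbeta at
#'     24 h; PDBu (u1) at 24 h with relative pPKD and pPI4K at
#'     24 + \{0, 1/6, 1/3, 1/2, 1\} h.}
#'   \item{E3}{ectopic CERT from 0 h (u4); total CERT at 8/16/24 h;
#'     kb-NB142-70 (u2) at 24 h with relative pPKD and pCERT at
#'     24 + \{0, 1, 2, 3\} h.}
#'   \item{E4a/E4b}{refinement: early pPKD at 1/2/4 h during ectopic
#'     PI4KIIIbeta expression, and long-time pPKD at 24 + \{2, 4, 6\} h
#'     after PDBu.}
#'   \item{E5}{validation: ectopic PI4KIIIbeta, PKD inhibition at 24 h,
#'     pPI4K at 25.25 h.}
#' }
#'
#' @param refinement_horizon_h horizon of the long-time refinement course
#'   after PDBu addition (default 6 h).
#' @return Named list of [protocol()] objects.
#' @export
default_protocols <- function(refinement_horizon_h = 6) {
  obs <- function(...) {
    rows <- list(...)
    tibble(observable = vapply(rows, `[[`, "", 1),
           mode = vapply(rows, `[[`, "", 2),
           times_h = lapply(rows, `[[`, 3))
  }
  out <- list(
    protocol("E1", input_signal(),
             obs(list("PKD_total", "absolute", 0),
                 list("PI4K_total", "absolute", 0),
                 list("CERT_total", "absolute", 0)),
             horizon_h = 0),
    protocol("E2",
             input_signal(c("u3", "u1"), c(0, 24), c(1, 1)),
             obs(list("PI4K_total", "absolute", 24),
                 list("pPKD", "relative", 24 + c(0, 1/6, 1/3, 1/2, 1)),
                 list("pPI4K", "relative", 24 + c(0, 1/6, 1/3, 1/2, 1))),
             horizon_h = 25),
    protocol("E3",
             input_signal(c("u4", "u2"), c(0, 24), c(1, 1)),
             obs(list("CERT_total", "absolute", c(8, 16, 24)),
                 list("pPKD", "relative", 24 + c(0, 1, 2, 3)),
                 list("pCERT", "relative", 24 + c(0, 1, 2, 3))),
             horizon_h = 27),
    protocol("E4a",
             input_signal("u3", 0, 1),
             obs(list("pPKD", "relative", c(1, 2, 4))),
             horizon_h = 24),
    protocol("E4b",
             input_signal(c("u3", "u1"), c(0, 24), c(1, 1)),
             obs(list("pPKD", "relative",
                      24 + c(2, 4, refinement_horizon_h))),
             horizon_h = 24 + refinement_horizon_h),
    protocol("E5",
             input_signal(c("u3", "u2"), c(0, 24), c(1, 1)),
             obs(list("pPI4K", "relative", 25.25)),
             horizon_h = 25.25)
  )
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Generate a synthetic calibration dataset
#'
#' Simulates every protocol noise-free at the given parameters, then
#' draws noisy records: absolute records are `n_replicates` draws from a
#' normal with mean `m` and SD `cv_abs * m`, truncated at zero (the
#' recorded SD stays at the pre-truncation `cv_abs * m` for likelihood
#' consistency); relative records get additive normal noise with SD
#' `rel_sd_frac` times the course's noise-free maximum.  Deterministic
#' given `seed`.
#'
#' @param variant `"A"` or `"B"`.
#' @param params named parameter vector (default: the shipped
#'   [ground_truth()]).
#' @param protocols named list of [protocol()] objects.
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @return An object of class `synthetic_dataset`: `dataset` (tibble in
#'   the likelihood's column layout), `truth` (list with variant,
#'   parameters, noise, seed and the noise-free observables).
#' @export
generate_dataset <- function(variant = c("A", "B"),
                             params = NULL,
                             protocols = default_protocols(),
                             noise = noise_spec(), seed = 1L) {
  variant <- match.arg(variant)
  model <- build_model(variant)
  if (is.null(params)) params <- ground_truth(variant)
  params <- .check_params(model, params)
  stopifnot(inherits(noise, "ck_noise"))

  ss <- tryCatch(steady_state(model, params),
                 error = function(e)
                   abort(paste0("steady state failed for the ground truth: ",
                                conditionMessage(e))))
  clean <- list()
  for (p in protocols) {
    traj <- tryCatch(
      simulate_protocol(model, params, p, x0 = ss),
      error = function(e)
        abort(paste0("simulation failed for protocol ", p$id, ": ",
                     conditionMessage(e))))
    for (i in seq_len(nrow(p$observations))) {
      o <- p$observations[i, ]
      pred <- observe(traj, o$observable, "absolute",
                      times = o$times_h[[1]])
      clean[[length(clean) + 1L]] <- tibble(
        protocol_id = p$id, observable = o$observable, mode = o$mode,
        time_h = pred$time_h, value = pred$prediction)
    }
  }
  clean <- bind_rows(clean)

  recs <- with_seed(seed, {
    out <- list()
    for (k in seq_len(nrow(clean))) {
      row <- clean[k, ]
      if (row$mode == "absolute") {
        sdev <- noise$cv_abs * row$value
        vals <- if (sdev > 0) pmax(rnorm(noise$n_replicates, row$value, sdev), 0)
                else rep(row$value, noise$n_replicates)
        out[[k]] <- tibble(
          experiment_id = paste0(row$protocol_id, "_rep", seq_along(vals)),
          protocol_id = row$protocol_id, observable = row$observable,
          mode = "absolute", time_h = row$time_h, value = vals,
          sd = if (sdev > 0) sdev else max(row$value * 1e-6, 1e-6))
      } else {
        course_max <- max(clean$value[clean$protocol_id == row$protocol_id &
                                        clean$observable == row$observable])
        sdev <- noise$rel_sd_frac * course_max
        val <- if (sdev > 0) rnorm(1, row$value, sdev) else row$value
        out[[k]] <- tibble(
          experiment_id = row$protocol_id,
          protocol_id = row$protocol_id, observable = row$observable,
          mode = "relative", time_h = row$time_h, value = val,
          sd = if (sdev > 0) sdev else max(course_max * 1e-6, 1e-6))
      }
    }
    bind_rows(out)
  })

  structure(list(
    dataset = recs,
    truth = list(variant = variant, parameters = params,
                 noise = unclass(noise), seed = seed,
                 noise_free = clean)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset (CSV + ground-truth JSON)
#'
#' @param x a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "dataset.csv")
  write.csv(x$dataset, csv, row.names = FALSE)
  truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(variant = x$truth$variant,
         parameters = as.list(x$truth$parameters),
         noise = x$truth$noise, seed = x$truth$seed,
         noise_free = x$truth$noise_free),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(dataset = csv, ground_truth = truth))
}

#' Read a dataset CSV
#'
#' @param path a CSV with the likelihood's column layout.
#' @return A tibble.
#' @export
read_dataset <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
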