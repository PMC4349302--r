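#  Posterior predictions of the endogenous (unperturbed) network and the
#  three perturbation-response scenarios.

# operating point of one regulated reaction at a state: flux / vmax
.operating_points <- function(model, state, params, fluxes) {
  reg <- model$reactions[model$reactions$law == "regulated_mm", ]
  vmax <- vapply(reg$parameters, `[[`, "", 1)
  fl <- fluxes$flux[match(reg$id, fluxes$reaction)]
  setNames(fl / params[vmax], reg$id)
}

#' Endogenous steady-state distributions
#'
#' For every posterior draw: the steady state with all inputs off, all
#' reaction fluxes there (molecules/hour), and the operating point of
#' every regulated reaction (its flux as a fraction of `vmax`, a
#' dimensionless measure of saturation -- values far below 1 mean the
#' regulation is responsive).  Summaries are the expectation and the
#' `[0.5, 99.5]` percentile band per quantity.
#'
#' @param model a [build_model()] object.
#' @param draws matrix of posterior draws (rows = draws, columns = log10
#'   parameters named as in the model), e.g. [subsample_posterior()].
#' @param probs percentile band (default `c(0.005, 0.995)`).
#' @param max_drop_frac maximum tolerated fraction of draws whose steady
#'   state fails to converge before an error is raised.
#' @return An object of class `endogenous_prediction` with tibbles
#'   `draws` (`draw`, `type`, `quantity`, `value`) and `summary`
#'   (`type`, `quantity`, `mean`, `lo`, `hi`), plus `n_dropped`.
#' @export
endogenous_distributions <- function(model, draws, probs = c(0.005, 0.995),
                                     max_drop_frac = 0.1) {
  stopifnot(inherits(model, "kinetic_model"))
  draws <- .as_draw_matrix(model, draws)
  if (nrow(draws) == 0L) abort("posterior sample is empty")

  per <- vector("list", nrow(draws))
  dropped <- 0L
  warm <- NULL
  for (i in seq_len(nrow(draws))) {
    params <- setNames(10^draws[i, ], model$parameter_names)
    res <- tryCatch({
      ss <- steady_state(model, params, x0 = warm)
      warm <- as.numeric(ss)
      fl <- reaction_fluxes(model, ss, params)
      op <- .operating_points(model, ss, params, fl)
      bind_rows(
        tibble(type = "amount", quantity = names(ss), value = as.numeric(ss)),
        tibble(type = "amount", quantity = "transfer_J",
               value = transfer_flux(model, ss, params)),
        tibble(type = "flux", quantity = fl$reaction, value = fl$flux),
        tibble(type = "operating_point", quantity = names(op),
               value = as.numeric(op))
      )
    }, error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    res$draw <- i
    per[[i]] <- res
  }
  if (dropped > max_drop_frac * nrow(draws))
    abort(paste0(dropped, " of ", nrow(draws),
                 " draws failed steady-state convergence"))
  all_draws <- bind_rows(per)
  summ <- all_draws |>
    group_by(.data$type, .data$quantity) |>
    summarise(mean = mean(.data$value),
              lo = quantile(.data$value, probs[1], names = FALSE),
              hi = quantile(.data$value, probs[2], names = FALSE),
              .groups = "drop")
  structure(list(draws = all_draws, summary = summ,
                 n_dropped = dropped, variant = model$variant,
                 probs = probs),
            class = "endogenous_prediction")
}

#' @export
print.endogenous_prediction <- function(x, ...) {
  cat("<endogenous_prediction> variant", x$variant, "--",
      length(unique(x$draws$draw)), "draws,", x$n_dropped, "dropped\n")
  print(x$summary, n = 20)
  invisible(x)
}

.as_draw_matrix <- function(model, draws) {
  if (is.data.frame(draws)) draws <- as.matrix(draws)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  if (!is.null(colnames(draws))) {
    if (!setequal(colnames(draws), model$parameter_names))
      abort("draw columns do not match the model parameters")
    draws <- draws[, model$parameter_names, drop = FALSE]
  } else if (ncol(draws) != length(model$parameter_names)) {
    abort("draws have the wrong number of columns")
  } else {
    colnames(draws) <- model$parameter_names
  }
  draws
}

# steady-state summaries used by the perturbation machinery
.ss_readout <- function(model, params, x0 = NULL) {
  ss <- steady_state(model, params, x0 = x0)
  list(ss = ss,
       pkd_active = unname(ss["PKDpDAG"]),
       J = transfer_flux(model, ss, params))
}

# scale parameter `par` by lambda so that `readout` increases by `magnitude`
# relative to baseline; monotone bracketing + uniroot, 1e-6 relative tol
.solve_multiplier <- function(model, params, par, readout, base_value,
                              magnitude, x0) {
  target <- base_value * (1 + magnitude)
  g <- function(lam) {
    p2 <- params
    p2[par] <- params[par] * lam
    r <- .ss_readout(model, p2, x0 = x0)
    r[[readout]] - target
  }
  lo <- 1; hi <- 1 + max(2 * abs(magnitude), 0.2)
  sign_dir <- sign(magnitude)
  if (sign_dir < 0) { hi <- 1; lo <- 1 / (1 + 2 * abs(magnitude)) }
  glo <- g(lo); ghi <- g(hi)
  tries <- 0
  while (glo * ghi > 0 && tries < 12) {
    if (sign_dir >= 0) { hi <- hi * 2; ghi <- g(hi) }
    else { lo <- lo / 2; glo <- g(lo) }
    tries <- tries + 1
  }
  if (glo * ghi > 0) abort("could not bracket the perturbation multiplier")
  uniroot(g, c(lo, hi), tol = 1e-6 * max(1, abs(target)) /
            max(1, abs(base_value)))$root
}

#' Perturbation-response distributions
#'
#' Three in-silico scenarios applied per posterior draw, each reported as a
#' relative change (%) of the complementary readout:
#' \describe{
#'   \item{`feedback_knockout`}{the ceramide-transfer-dependent PKD
#'     activation channel is removed (`vmax_cer = 0`); reported is the
#'     relative change of active PKD (`PKDpDAG`) at steady state.}
#'   \item{`transfer_up_10`}{`k10` is scaled (by 1-D root finding) so the
#'     steady-state transfer flux `J` rises by exactly `magnitude`;
#'     reported is the relative change of active PKD.}
#'   \item{`pkd_up_10`}{the basal activation rate `k_act` is scaled so
#'     steady-state active PKD rises by exactly `magnitude`; reported is
#'     the relative change of `J`.}
#' }
#'
#' @inheritParams endogenous_distributions
#' @param scenario scenario kind.
#' @param magnitude relative increase targeted by the root-finding
#'   scenarios (default 0.10; must be > -1).
#' @return An object of class `perturbation_response` with tibble `draws`
#'   (`draw`, `response_pct`, `multiplier`), `expectation` (mean %),
#'   `scenario` and the count of dropped draws.
#' @export
perturbation_response <- function(model, draws,
                                  scenario = c("feedback_knockout",
                                               "transfer_up_10",
                                               "pkd_up_10"),
                                  magnitude = 0.10) {
  scenario <- match.arg(scenario)
  if (magnitude <= -1) abort("magnitude must be > -1")
  stopifnot(inherits(model, "kinetic_model"))
  draws <- .as_draw_matrix(model, draws)

  res <- vector("list", nrow(draws))
  dropped <- 0L
  warm <- NULL
  for (i in seq_len(nrow(draws))) {
    params <- setNames(10^draws[i, ], model$parameter_names)
    row <- tryCatch({
      base <- .ss_readout(model, params, x0 = warm)
      warm <- as.numeric(base$ss)
      if (scenario == "feedback_knockout") {
        p2 <- params
        p2["vmax_cer"] <- params["vmax_cer"] * 1e-300  # effectively zero, stays positive
        pert <- .ss_readout(model, p2, x0 = warm)
        tibble(draw = i, multiplier = 0,
               response_pct = 100 * (pert$pkd_active - base$pkd_active) /
                 base$pkd_active)
      } else if (scenario == "transfer_up_10") {
        if (magnitude == 0) {
          tibble(draw = i, multiplier = 1, response_pct = 0)
        } else {
          lam <- .solve_multiplier(model, params, "k10", "J", base$J,
                                   magnitude, warm)
          p2 <- params; p2["k10"] <- params["k10"] * lam
          pert <- .ss_readout(model, p2, x0 = warm)
          tibble(draw = i, multiplier = lam,
                 response_pct = 100 * (pert$pkd_active - base$pkd_active) /
                   base$pkd_active)
        }
      } else {
        if (magnitude == 0) {
          tibble(draw = i, multiplier = 1, response_pct = 0)
        } else {
          lam <- .solve_multiplier(model, params, "k_act", "pkd_active",
                                   base$pkd_active, magnitude, warm)
          p2 <- params; p2["k_act"] <- params["k_act"] * lam
          pert <- .ss_readout(model, p2, x0 = warm)
          tibble(draw = i, multiplier = lam,
                 response_pct = 100 * (pert$J - base$J) / base$J)
        }
      }
    }, error = function(e) NULL)
    if (is.null(row)) { dropped <- dropped + 1L; next }
    res[[i]] <- row
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) abort("all draws failed in the perturbation scenario")
  structure(list(draws = out,
                 expectation = mean(out$response_pct),
                 scenario = scenario, magnitude = magnitude,
                 variant = model$variant, n_dropped = dropped),
            class = "perturbation_response")
}

#' @export
print.perturbation_response <- function(x, ...) {
  cat("<perturbation_response>", x$scenario, "(magnitude",
      x$magnitude, ") on variant", x$variant, "\n")
  cat("  expected response:", signif(x$expectation, 4), "%  (",
      nrow(x$draws), "draws,", x$n_dropped, "dropped )\n")
  invisible(x)
}
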