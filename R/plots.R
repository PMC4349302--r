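#  Plotting and broom-style summaries.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_errorbar geom_abline facet_wrap labs scale_y_log10 theme_minimal
#'   geom_histogram geom_vline
NULL

#' Plot a simulated trajectory
#'
#' @param trajectory a [simulate_protocol()] result.
#' @param species optional subset of species names.
#' @param log_y log-scale the y axis.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, species = NULL, log_y = TRUE) {
  long <- tidyr::pivot_longer(trajectory, -"time_h",
                              names_to = "species", values_to = "amount")
  if (!is.null(species)) long <- long[long$species %in% species, ]
  p <- ggplot(long, aes(x = .data$time_h, y = .data$amount,
                        colour = .data$species)) +
    geom_line() +
    labs(x = "time (h)", y = "molecules per cell",
         title = attr(trajectory, "protocol_id")) +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  ggplot(d, aes(x = .data$molecules, y = .data$intensity)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = "molecules", y = "band intensity",
         title = "standard curve") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pt_chains <- function(object, parameter = NULL, ...) {
  L <- length(object$ladder)
  pnames <- object$parameter_names
  if (is.null(parameter)) parameter <- pnames[1]
  d <- bind_rows(lapply(seq_along(object$runs), function(r)
    tibble(run = factor(r),
           iteration = seq_len(object$n_iter),
           value = object$runs[[r]]$samples[, parameter, L])))
  ggplot(d, aes(x = .data$iteration, y = .data$value,
                colour = .data$run)) +
    geom_line(alpha = 0.7) +
    labs(y = paste0("log10(", parameter, ")"),
         title = "posterior chain (beta = 1)") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.endogenous_prediction <- function(object, type = "amount", ...) {
  d <- object$summary[object$summary$type == type, ]
  ggplot(d, aes(x = .data$quantity, y = .data$mean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    scale_y_log10() +
    labs(x = NULL,
         y = if (type == "flux") "molecules per hour"
             else if (type == "amount") "molecules per cell"
             else "fraction of vmax",
         title = paste("endogenous", type, "distribution")) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.perturbation_response <- function(object, ...) {
  ggplot(object$draws, aes(x = .data$response_pct)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$expectation, colour = "firebrick") +
    labs(x = "relative change (%)", y = "posterior draws",
         title = object$scenario) +
    theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.pt_chains <- function(x, burn_in = 0.5, ...) {
  L <- length(x$ladder)
  keep <- seq.int(floor(burn_in * x$n_iter) + 1L, x$n_iter)
  pool <- do.call(rbind, lapply(x$runs, function(r)
    r$samples[keep, , L, drop = TRUE]))
  tibble(parameter = x$parameter_names,
         mean = colMeans(pool),
         sd = apply(pool, 2, sd),
         q2.5 = apply(pool, 2, quantile, 0.025),
         q97.5 = apply(pool, 2, quantile, 0.975))
}

#' @exportS3Method generics::glance
glance.pt_chains <- function(x, ...) {
  tibble(n_runs = length(x$runs), n_iter = x$n_iter,
         n_levels = length(x$ladder),
         accept_posterior = mean(vapply(x$runs, function(r)
           r$accept_rate[length(x$ladder)], 0)),
         swap_rate = mean(vapply(x$runs, function(r) r$swap_rate, 0)),
         n_failed = sum(vapply(x$runs, function(r) r$n_failed, 0L)))
}

#' @exportS3Method generics::tidy
tidy.evidence_estimate <- function(x, ...) {
  tibble(variant = x$variant, run = seq_along(x$per_run),
         logZ = x$per_run)
}

#' @exportS3Method generics::glance
glance.evidence_estimate <- function(x, ...) {
  tibble(variant = x$variant, logZ = x$logZ, se = x$se,
         n_runs = length(x$per_run))
}

#' @exportS3Method generics::tidy
tidy.endogenous_prediction <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.perturbation_response <- function(x, ...) x$draws

#' @exportS3Method generics::glance
glance.perturbation_response <- function(x, ...) {
  tibble(scenario = x$scenario, magnitude = x$magnitude,
         expected_pct = x$expectation,
         lo = quantile(x$draws$response_pct, 0.005, names = FALSE),
         hi = quantile(x$draws$response_pct, 0.995, names = FALSE),
         n_dropped = x$n_dropped)
}
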