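#  Marginal likelihood by thermodynamic integration and Bayes factors.
#
#  log Z = integral over beta in [0, 1] of E_beta[log L], estimated by
#  trapezoidal quadrature over the tempering ladder, with the expectation
#  at each level taken from that level's post-burn-in chain.  Run-to-run
#  spread over repeated independent sampling runs provides the
#  uncertainty.

#' Per-level mean log-likelihoods
#'
#' @param chains a [pt_sample()] result.
#' @param burn_in discard fraction.
#' @return A tibble with columns `run`, `beta`, `mean_logl`, `n_noninfinite`.
#'   `-Inf` draws (failed simulations) are excluded from the mean and
#'   counted.
#' @export
mean_loglik_by_beta <- function(chains, burn_in = 0.5) {
  stopifnot(inherits(chains, "pt_chains"))
  keep <- seq.int(floor(burn_in * chains$n_iter) + 1L, chains$n_iter)
  out <- lapply(seq_along(chains$runs), function(r) {
    m <- chains$runs[[r]]$logl[keep, , drop = FALSE]
    tibble(run = r, beta = chains$ladder,
           mean_logl = apply(m, 2, function(x) mean(x[is.finite(x)])),
           n_noninfinite = apply(m, 2, function(x) sum(is.finite(x))))
  })
  bind_rows(out)
}

#' Thermodynamic integration
#'
#' Trapezoidal quadrature of the expected log-likelihood over the inverse
#' temperature; exact for integrands that are piecewise linear on the
#' ladder.
#'
#' @param mean_logl per-level mean log-likelihoods (one per ladder level).
#' @param ladder the inverse-temperature ladder.
#' @return The log marginal likelihood estimate.
#' @export
thermodynamic_integration <- function(mean_logl, ladder) {
  if (length(mean_logl) != length(ladder))
    abort("mean_logl and ladder must have the same length")
  if (any(!is.finite(mean_logl)))
    abort("per-level mean log-likelihoods must be finite")
  ladder <- .check_ladder(ladder)
  sum(diff(ladder) * (head(mean_logl, -1) + mean_logl[-1]) / 2)
}

#' Model evidence from tempered chains
#'
#' @param chains a [pt_sample()] result for one model.
#' @param variant label for the model (e.g. `"A"`).
#' @param burn_in discard fraction.
#' @return An object of class `evidence_estimate` with the per-run log
#'   marginal likelihoods, their mean `logZ` and run-to-run standard
#'   deviation `se`.
#' @export
model_evidence <- function(chains, variant = NA_character_, burn_in = 0.5) {
  ml <- mean_loglik_by_beta(chains, burn_in)
  per_run <- vapply(split(ml, ml$run), function(d)
    thermodynamic_integration(d$mean_logl, d$beta), 0)
  structure(list(variant = variant,
                 logZ = mean(per_run),
                 se = if (length(per_run) > 1) sd(per_run) else 0,
                 per_run = unname(per_run),
                 mean_logl = ml),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat("<evidence_estimate>", if (!is.na(x$variant)) paste("model", x$variant),
      "logZ =", signif(x$logZ, 6), "+/-", signif(x$se, 3),
      paste0("(", length(x$per_run), " runs)\n"))
  invisible(x)
}

.kass_raftery <- function(two_log_k) {
  a <- abs(two_log_k)
  if (a <= 2) "barely worth mentioning"
  else if (a <= 6) "positive"
  else if (a <= 10) "strong"
  else "very strong"
}

#' Bayes factor between two models
#'
#' `2 log K = 2 (logZ_A - logZ_B)`, with the run-to-run uncertainties
#' combined in quadrature and the strength of evidence categorized on the
#' Kass--Raftery scale: (0,2] barely worth mentioning, (2,6] positive,
#' (6,10] strong, >10 very strong (symmetric for negative values).
#'
#' @param evidence_a,evidence_b [model_evidence()] results.
#' @return An object of class `evidence_comparison` with elements
#'   `two_log_k`, `se`, `category`, `favored`.
#' @export
bayes_factor <- function(evidence_a, evidence_b) {
  stopifnot(inherits(evidence_a, "evidence_estimate"),
            inherits(evidence_b, "evidence_estimate"))
  v <- 2 * (evidence_a$logZ - evidence_b$logZ)
  se <- 2 * sqrt(evidence_a$se^2 + evidence_b$se^2)
  structure(list(two_log_k = v, se = se,
                 category = .kass_raftery(v),
                 favored = if (v >= 0) evidence_a$variant else evidence_b$variant,
                 models = c(evidence_a$variant, evidence_b$variant)),
            class = "evidence_comparison")
}

#' @export
print.evidence_comparison <- function(x, ...) {
  cat("<evidence_comparison> 2logK(", x$models[1], ",", x$models[2], ") = ",
      signif(x$two_log_k, 4), " +/- ", signif(x$se, 3),
      " [", x$category, "]\n", sep = "")
  invisible(x)
}
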