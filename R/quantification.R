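#  Absolute protein quantification from western-blot intensities.
#
#  A dilution series of a recombinant standard links band intensity to
#  molecule number by ordinary least squares; unknowns are read off the
#  curve by inverse regression with first-order (delta-method) error
#  propagation.  Endogenous copy numbers per cell follow from the signal
#  ratio between endogenous and ectopically expressed protein.

#' Fit a standard curve
#'
#' Ordinary least squares of intensity on molecule number, with intercept
#' (blot backgrounds shift intensities additively).  Needs at least three
#' points with distinct molecule values; the residual SD uses n - 2
#' degrees of freedom.
#'
#' @param data a data frame with columns `molecules` and `intensity`.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `residual_sd`, `n`, coefficient covariance `vcov`, and the underlying
#'   `lm` fit.
#' @export
fit_standard_curve <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("molecules", "intensity") %in% names(data)))
  if (nrow(data) < 3L) abort("a standard curve needs at least 3 points")
  if (length(unique(data$molecules)) < 2L)
    abort("molecule amounts are collinear (all identical)")
  fit <- lm(intensity ~ molecules, data = data)
  s <- unname(coef(fit)["molecules"])
  # suppressWarnings: summary.lm complains about exact (noise-free) fits
  structure(list(slope = s,
                 intercept = unname(coef(fit)["(Intercept)"]),
                 residual_sd = sqrt(sum(fit$residuals^2) / (nrow(data) - 2L)),
                 n = nrow(data), vcov = suppressWarnings(vcov(fit)),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> intensity =", signif(x$intercept, 6), "+",
      signif(x$slope, 6), "* molecules  (n =", x$n,
      ", residual SD =", signif(x$residual_sd, 4), ")\n")
  invisible(x)
}

#' Inverse regression: molecules from intensity
#'
#' Point estimate `(intensity - intercept) / slope` with a delta-method
#' standard error propagating the residual noise of a new measurement and
#' the coefficient covariance of the fitted curve.  Estimates at or below
#' zero molecules (intensity not above the intercept) are flagged invalid.
#'
#' @param curve a [fit_standard_curve()] object with positive slope.
#' @param intensity measured intensities (vectorized).
#' @return A tibble with columns `intensity`, `molecules`, `se`, `valid`.
#' @export
inverse_predict <- function(curve, intensity) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) abort("inverse regression requires a positive slope")
  b0 <- curve$intercept; b1 <- curve$slope
  x <- (intensity - b0) / b1
  V <- curve$vcov
  # d x / d y = 1/b1, d x / d b0 = -1/b1, d x / d b1 = -x/b1
  var_x <- (curve$residual_sd^2 + V[1, 1] + 2 * x * V[1, 2] +
              x^2 * V[2, 2]) / b1^2
  # numerical zero relative to the calibration range counts as "not above
  # the intercept"
  tol <- 1e-9 * max(abs(curve$fit$model$molecules))
  tibble(intensity = intensity, molecules = x, se = sqrt(pmax(var_x, 0)),
         valid = x > tol)
}

#' Endogenous abundance from an endogenous/ectopic signal ratio
#'
#' `molecules/cell = ratio * ectopic_molecules / n_cells`, with the
#' coefficient of variation of the inputs combined in quadrature.
#'
#' @param ratio endogenous-to-ectopic signal ratio (> 0).
#' @param ectopic_molecules absolute number of ectopic molecules in the
#'   measured lysate (> 0), e.g. from [inverse_predict()].
#' @param n_cells number of cells in the lysate (> 0).
#' @param cvs numeric vector of coefficients of variation of the inputs
#'   (combined in quadrature).
#' @return A tibble with columns `molecules_per_cell` and `cv`.
#' @export
endogenous_abundance <- function(ratio, ectopic_molecules, n_cells,
                                 cvs = c(0, 0, 0)) {
  if (any(c(ratio, ectopic_molecules, n_cells) <= 0))
    abort("ratio, ectopic_molecules and n_cells must all be positive")
  tibble(molecules_per_cell = ratio * ectopic_molecules / n_cells,
         cv = sqrt(sum(cvs^2)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = co[, 1], std_error = co[, 2])
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept,
         residual_sd = x$residual_sd,
         r_squared = suppressWarnings(summary(x$fit))$r.squared)
}
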