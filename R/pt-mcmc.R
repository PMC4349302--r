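#  Parallel-tempering Metropolis sampler.
#
#  A ladder of inverse temperatures beta_0 = 0 < ... < beta_{L-1} = 1
#  tempers the likelihood; every chain performs a Gaussian random-walk
#  Metropolis update in log10 parameter space per iteration, followed by
#  one adjacent-pair swap attempt.  Proposal step sizes are adapted toward
#  a 20-30% acceptance rate during burn-in and frozen afterwards, so the
#  post-burn-in kernel leaves the tempered targets invariant.

#' Inverse-temperature ladder
#'
#' Power-law schedule `beta_i = (i/(L-1))^power`, which concentrates
#' levels near `beta = 0` where the thermodynamic-integration integrand
#' varies fastest.
#'
#' @param n_levels number of levels `L` (>= 1); endpoints are exactly 0
#'   and 1 for `L >= 2`.
#' @param power schedule exponent (default 5).
#' @return Increasing numeric vector of length `n_levels`.
#' @export
ladder_beta <- function(n_levels = 10L, power = 5) {
  stopifnot(n_levels >= 1)
  if (n_levels == 1L) return(1)
  (seq(0, 1, length.out = n_levels))^power
}

.check_ladder <- function(ladder) {
  if (length(ladder) > 1) {
    if (ladder[1] != 0 || ladder[length(ladder)] != 1 ||
        any(diff(ladder) <= 0))
      abort("ladder must be strictly increasing from 0 to 1")
  } else if (!identical(as.numeric(ladder), 1)) {
    abort("a single-level ladder must be beta = 1")
  }
  as.numeric(ladder)
}

#' Parallel-tempering MCMC sampling
#'
#' @param target a [tempered_target()] object, or any list with functions
#'   `log_prior(theta)` and `log_lik(theta)` plus numeric `lower`/`upper`
#'   box bounds (used to draw initial states).
#' @param ladder inverse-temperature ladder, e.g. [ladder_beta()].
#' @param n_iter iterations per run.
#' @param n_runs number of independent repeated runs.
#' @param seed RNG seed; run `r` uses `seed + r - 1`.  Chains are
#'   bit-reproducible given the seed.
#' @param init optional initial log10 parameter vector (all levels start
#'   there); default: uniform draw inside the box per level.
#' @param step initial proposal standard deviation (log10 units), scalar
#'   or per-level vector.
#' @param burn_in fraction of iterations treated as burn-in (adaptation
#'   window; also the default discard fraction downstream).
#' @param adapt adapt step sizes toward 20--30% acceptance during burn-in.
#' @param swap attempt one adjacent-pair swap per iteration.
#' @return An object of class `pt_chains`: a list of runs, each with
#'   `samples` (iterations x parameters x levels array, log10 scale),
#'   `logl` (iterations x levels log-likelihood trace), acceptance rates,
#'   final step sizes, `ladder`, `seed` and failure counts.
#' @export
pt_sample <- function(target, ladder = ladder_beta(4), n_iter = 1000L,
                      n_runs = 1L, seed = 1L, init = NULL, step = 0.2,
                      burn_in = 0.5, adapt = TRUE, swap = TRUE) {
  ladder <- .check_ladder(ladder)
  stopifnot(n_iter >= 1, n_runs >= 1)
  L <- length(ladder)
  npar <- length(target$lower)
  pnames <- target$parameter_names
  if (is.null(pnames)) pnames <- paste0("p", seq_len(npar))
  steps0 <- rep_len(as.numeric(step), L)
  n_burn <- floor(burn_in * n_iter)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- with_seed(seed + r - 1L, {
      theta <- matrix(0, nrow = L, ncol = npar)
      for (l in seq_len(L)) {
        theta[l, ] <- if (!is.null(init)) as.numeric(init)
                      else runif(npar, target$lower, target$upper)
      }
      lp <- numeric(L); ll <- numeric(L)
      for (l in seq_len(L)) {
        lp[l] <- target$log_prior(theta[l, ])
        v <- target$log_lik(theta[l, ])
        ll[l] <- if (is.nan(v)) -Inf else v
      }
      steps <- steps0
      samples <- array(NA_real_, dim = c(n_iter, npar, L))
      logl <- matrix(NA_real_, n_iter, L)
      acc <- integer(L); acc_win <- integer(L); win <- 0L
      swap_try <- 0L; swap_acc <- 0L; n_failed <- 0L

      for (it in seq_len(n_iter)) {
        for (l in seq_len(L)) {
          prop <- theta[l, ] + steps[l] * rnorm(npar)
          lp_p <- target$log_prior(prop)
          if (is.finite(lp_p)) {
            v <- target$log_lik(prop)
            if (is.nan(v) || is.na(v)) { v <- -Inf; n_failed <- n_failed + 1L }
            ll_p <- v
            # beta = 0 samples the prior alone (0 * -Inf is undefined)
            num <- if (ladder[l] == 0) lp_p else lp_p + ladder[l] * ll_p
            den <- if (ladder[l] == 0) lp[l] else lp[l] + ladder[l] * ll[l]
            accept <- if (!is.finite(den)) is.finite(num)
                      else is.finite(num) && log(runif(1)) < (num - den)
            if (accept) {
              theta[l, ] <- prop; lp[l] <- lp_p; ll[l] <- ll_p
              acc[l] <- acc[l] + 1L; acc_win[l] <- acc_win[l] + 1L
            }
          }
        }
        if (swap && L > 1L) {
          j <- sample.int(L - 1L, 1L)
          swap_try <- swap_try + 1L
          dl <- (ladder[j] - ladder[j + 1L]) * (ll[j + 1L] - ll[j])
          if (is.finite(dl) && log(runif(1)) < dl) {
            tmp <- theta[j, ]; theta[j, ] <- theta[j + 1L, ]; theta[j + 1L, ] <- tmp
            tmp <- lp[j]; lp[j] <- lp[j + 1L]; lp[j + 1L] <- tmp
            tmp <- ll[j]; ll[j] <- ll[j + 1L]; ll[j + 1L] <- tmp
            swap_acc <- swap_acc + 1L
          }
        }
        samples[it, , ] <- t(theta)
        logl[it, ] <- ll
        win <- win + 1L
        if (adapt && it <= n_burn && win >= 50L) {
          rate <- acc_win / win
          steps[rate < 0.20] <- steps[rate < 0.20] * 0.8
          steps[rate > 0.30] <- steps[rate > 0.30] * 1.25
          acc_win[] <- 0L; win <- 0L
        }
      }
      dimnames(samples) <- list(NULL, pnames, NULL)
      list(samples = samples, logl = logl,
           accept_rate = acc / n_iter,
           swap_rate = if (swap_try) swap_acc / swap_try else NA_real_,
           steps = steps, ladder = ladder, seed = seed + r - 1L,
           n_burn = n_burn, n_failed = n_failed)
    })
  }
  structure(list(runs = runs, ladder = ladder, n_iter = n_iter,
                 n_burn = n_burn, parameter_names = pnames, seed = seed),
            class = "pt_chains")
}

#' @export
print.pt_chains <- function(x, ...) {
  cat("<pt_chains>", length(x$runs), "run(s),", x$n_iter, "iterations,",
      length(x$ladder), "temperature level(s)\n")
  cat("  acceptance (beta = 1):",
      paste(signif(vapply(x$runs, function(r)
        r$accept_rate[length(x$ladder)], 0), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction
#'
#' Computed across independent runs at one temperature level after
#' discarding burn-in:
#' `Rhat = sqrt(((N-1)/N * W + B/N) / W)` where `W` is the mean within-run
#' variance and `B/N` the variance of the run means.  The diagnostic
#' passes when every parameter has `Rhat < 1.1`.
#'
#' @param chains a [pt_sample()] result with at least two runs.
#' @param beta_index ladder index (default: the posterior, `beta = 1`).
#' @param burn_in discard fraction.
#' @return A tibble with columns `parameter`, `rhat`, `degenerate`;
#'   attribute `pass`.
#' @export
gelman_rubin <- function(chains, beta_index = NULL, burn_in = 0.5) {
  stopifnot(inherits(chains, "pt_chains"))
  if (length(chains$runs) < 2L) abort("need at least two runs")
  L <- length(chains$ladder)
  if (is.null(beta_index)) beta_index <- L
  keep <- seq.int(floor(burn_in * chains$n_iter) + 1L, chains$n_iter)
  draws <- lapply(chains$runs, function(r)
    r$samples[keep, , beta_index, drop = FALSE])
  npar <- dim(draws[[1]])[2]
  N <- length(keep)
  rhat <- numeric(npar); degen <- logical(npar)
  for (p in seq_len(npar)) {
    xs <- lapply(draws, function(d) d[, p, 1])
    W <- mean(vapply(xs, var, 0))
    Bn <- var(vapply(xs, mean, 0))   # B/N in the classical notation
    if (W <= 0 || !is.finite(W)) {
      rhat[p] <- Inf; degen[p] <- TRUE
    } else {
      rhat[p] <- sqrt(((N - 1) / N * W + Bn) / W)
    }
  }
  out <- tibble(parameter = chains$parameter_names, rhat = rhat,
                degenerate = degen)
  attr(out, "pass") <- all(is.finite(rhat)) && all(rhat < 1.1)
  out
}

#' Representative posterior subsample
#'
#' Pools the `beta = 1` chains of all runs after discarding burn-in, thins
#' uniformly, then draws a random subsample without replacement.
#' Deterministic given `seed`.
#'
#' @param chains a [pt_sample()] result.
#' @param n_out number of draws required.
#' @param seed RNG seed.
#' @param burn_in discard fraction.
#' @return A matrix (`n_out` x parameters, log10 scale).
#' @export
subsample_posterior <- function(chains, n_out, seed = 1L, burn_in = 0.5) {
  stopifnot(inherits(chains, "pt_chains"))
  L <- length(chains$ladder)
  keep <- seq.int(floor(burn_in * chains$n_iter) + 1L, chains$n_iter)
  pool <- do.call(rbind, lapply(chains$runs, function(r)
    r$samples[keep, , L, drop = TRUE]))
  if (is.null(dim(pool))) pool <- matrix(pool, ncol = 1)
  n_avail <- nrow(pool)
  if (n_out > n_avail)
    abort(paste0("requested ", n_out, " draws but only ", n_avail,
                 " post-burn-in draws are available"))
  if (n_out == n_avail) return(pool)
  thin_idx <- unique(round(seq(1, n_avail, length.out = min(n_avail, 4L * n_out))))
  pool <- pool[thin_idx, , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(pool), n_out))
  pool[sort(idx), , drop = FALSE]
}
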