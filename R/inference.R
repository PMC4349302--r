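#  Priors, likelihood and MAP estimation.
#
#  Parameters are inferred on the log10 scale with independent uniform
#  (log-uniform in linear space) priors.  The likelihood assumes the
#  deterministic ODE solution perturbed by additive, independent Gaussian
#  noise with the measured standard deviations; relative phospho-blot
#  courses carry an unknown multiplicative gain that is profiled out in
#  closed form before residuals are formed.

#' Define a log-uniform prior box
#'
#' @param lower,upper named numeric vectors of per-parameter log10 bounds.
#' @return An object of class `ck_prior`.
#' @export
prior_spec <- function(lower, upper) {
  stopifnot(!is.null(names(lower)), setequal(names(lower), names(upper)))
  upper <- upper[names(lower)]
  if (any(!(lower < upper))) abort("prior requires lower < upper everywhere")
  structure(list(lower = lower, upper = upper,
                 names = names(lower)), class = "ck_prior")
}

#' Default prior box around a parameter center
#'
#' A box of `half_width` log10 units (default 3, i.e. several orders of
#' magnitude) around a central parameterization, with two literature-style
#' restrictions: degradation rates are kept within protein half-lives of
#' 1--100 h, and endogenous synthesis rates are kept in the range that puts
#' steady-state totals between 1e3 and 1e9 molecules/cell given those
#' degradation bounds.
#'
#' @param model a [build_model()] object.
#' @param center named parameter vector on the linear scale (e.g. a MAP
#'   estimate or ground truth).
#' @param half_width box half-width in log10 units.
#' @return A [prior_spec()] object.
#' @export
default_prior <- function(model, center, half_width = 3) {
  center <- .check_params(model, center)
  lc <- log10(center)
  lo <- lc - half_width
  hi <- lc + half_width
  d_lo <- log10(log(2) / 100)   # half-life 100 h
  d_hi <- log10(log(2) / 1)     # half-life 1 h
  for (p in c("d_PKD", "d_PI4K", "d_CERT")) {
    lo[p] <- max(lo[p], d_lo); hi[p] <- min(hi[p], d_hi)
  }
  s_lo <- 3 + d_lo              # 1e3 molecules/cell at slowest turnover
  s_hi <- 9 + d_hi              # 1e9 molecules/cell at fastest turnover
  for (p in c("s_PKD", "s_PI4K", "s_CERT")) {
    lo[p] <- max(lo[p], s_lo); hi[p] <- min(hi[p], s_hi)
  }
  bad <- !(lo < hi)
  if (any(bad)) {  # center outside a capped range: recentre on the cap
    lo[bad] <- pmin(lo[bad], hi[bad]) - 0.5
  }
  prior_spec(lo, hi)
}

#' Log prior density
#'
#' Normalized uniform density over the log10 box: inside the box
#' `-sum(log(upper - lower))`, outside `-Inf`.
#'
#' @param theta named (or prior-ordered) vector of log10 parameters.
#' @param prior a [prior_spec()] object.
#' @return A single number (possibly `-Inf`).
#' @export
log_prior <- function(theta, prior) {
  stopifnot(inherits(prior, "ck_prior"))
  if (!is.null(names(theta))) theta <- theta[prior$names]
  if (length(theta) != length(prior$lower))
    abort("theta length does not match the prior")
  if (any(theta < prior$lower) || any(theta > prior$upper)) return(-Inf)
  -sum(log(prior$upper - prior$lower))
}

# observable -> state-matrix column indices (species columns, no time col)
.obs_cols <- function(observable) {
  switch(observable,
    "y4" = , "pPKD" = 2L,
    "y5" = , "pPI4K" = 4L,
    "y6" = , "pCERT" = 5L,
    "PKD_total" = 1:2, "PI4K_total" = 3:4, "CERT_total" = 5:7,
    abort(paste0("unknown observable: ", observable)))
}

# deduplicated simulation plan: protocols sharing an input schedule are
# integrated once per likelihood evaluation; a protocol whose schedule is a
# prefix of another's (identical inputs up to its horizon, extra switches
# only at or after it) shares that trajectory too
.sim_plan <- function(protocols, dataset) {
  ids <- unique(dataset$protocol_id)
  missing <- setdiff(ids, names(protocols))
  if (length(missing))
    abort(paste0("dataset references unknown protocols: ",
                 paste(missing, collapse = ", ")))
  sig <- vapply(ids, function(id) {
    p <- protocols[[id]]
    paste(paste(p$inputs$u, p$inputs$t_on_h, p$inputs$level,
                collapse = ";"), collapse = ";")
  }, "")
  groups <- lapply(split(ids, sig), function(g) {
    list(protocol_ids = g,
         inputs = protocols[[g[1]]]$inputs,
         horizon = max(vapply(g, function(id) protocols[[id]]$horizon_h, 0)))
  })
  is_prefix_of <- function(sub, sup) {
    a <- sub$inputs; b <- sup$inputs
    key <- function(d) paste(d$u, d$t_on_h, d$level)
    extra <- !(key(b) %in% key(a))
    all(key(a) %in% key(b)) &&
      all(b$t_on_h[extra] >= sub$horizon) &&
      sup$horizon >= sub$horizon
  }
  merged <- TRUE
  while (merged && length(groups) > 1) {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i == j) next
        if (is_prefix_of(groups[[i]], groups[[j]])) {
          groups[[j]]$protocol_ids <- c(groups[[j]]$protocol_ids,
                                        groups[[i]]$protocol_ids)
          groups[[i]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  lapply(groups, function(g) {
    g$times <- sort(unique(dataset$time_h[dataset$protocol_id %in%
                                            g$protocol_ids]))
    g
  })
}

#' Build a fast log-likelihood closure
#'
#' Precomputes the simulation plan (one ODE integration per unique input
#' schedule per evaluation) and caches the last endogenous steady state as
#' a warm start for the next evaluation.  Simulation failures return
#' `-Inf` rather than raising, so optimizers and samplers can reject the
#' proposal gracefully.
#'
#' @param model a [build_model()] object.
#' @param dataset measurement tibble with columns `experiment_id`,
#'   `protocol_id`, `observable`, `mode`, `time_h`, `value`, `sd`
#'   (absolute values in molecules/cell, `sd > 0`).
#' @param protocols named list of [protocol()] objects.
#' @param rtol,atol integrator tolerances.
#' @return A function `f(theta_log10) -> log-likelihood`.
#' @export
make_likelihood <- function(model, dataset, protocols, rtol = 1e-8,
                            atol = 1e-4) {
  stopifnot(inherits(model, "kinetic_model"))
  dataset <- as_tibble(dataset)
  req <- c("experiment_id", "protocol_id", "observable", "mode",
           "time_h", "value", "sd")
  if (!all(req %in% names(dataset)))
    abort(paste0("dataset must have columns: ", paste(req, collapse = ", ")))
  if (any(dataset$sd <= 0)) abort("all record SDs must be positive")
  plan <- .sim_plan(protocols, dataset)
  npar <- length(model$parameter_names)
  cache <- new.env(parent = emptyenv())
  variant_i <- if (model$variant == "B") 1L else 0L
  func <- paste0("ck_derivs_", model$variant)
  initf <- paste0("ck_init_", model$variant)

  # precompiled evaluation plan: segment boundaries, constant input levels,
  # output-row bookkeeping and per-record-group indices, so the hot path is
  # pure lsoda calls plus vector arithmetic
  eplan <- lapply(plan, function(pl) {
    H <- pl$horizon
    sw <- pl$inputs$t_on_h
    sw <- sort(unique(sw[sw > 0 & sw < H]))
    bounds <- c(0, sw, H)
    times_all <- sort(unique(c(bounds, pl$times)))
    segs <- lapply(seq_len(length(bounds) - 1L), function(s) {
      a <- bounds[s]; b <- bounds[s + 1L]
      tseg <- sort(unique(c(a, times_all[times_all > a & times_all < b], b)))
      list(tseg = tseg,
           u = as.numeric(.inputs_at(pl$inputs, a)),
           rows = match(tseg, times_all),
           keep = if (s == 1L) seq_along(tseg) else seq_along(tseg)[-1])
    })
    recs <- dataset[dataset$protocol_id %in% pl$protocol_ids, ]
    keys <- paste(recs$experiment_id, recs$protocol_id,
                  recs$observable, recs$mode)
    groups <- lapply(unique(keys), function(key) {
      g <- recs[keys == key, ]
      list(cols = .obs_cols(g$observable[1]),
           rows = match(g$time_h, times_all),
           relative = g$mode[1] == "relative",
           value = g$value, w = 1 / g$sd^2,
           const = sum(-0.5 * log(2 * pi * g$sd^2)))
    })
    list(n_times = length(times_all), segs = segs, groups = groups,
         static = H == 0)
  })

  function(theta) {
    if (length(theta) != npar) abort("theta has the wrong length")
    params <- 10^as.numeric(theta)
    ll <- tryCatch({
      ss <- .steady_state_fast(variant_i, params, cache$ss)
      cache$ss <- ss
      total <- 0
      for (pl in eplan) {
        if (pl$static) {
          traj <- matrix(ss, nrow = 1)
        } else {
          traj <- matrix(0, pl$n_times, 7)
          y <- ss
          for (sg in pl$segs) {
            out <- suppressWarnings(
              deSolve::lsoda(y, sg$tseg, func = func,
                             dllname = "certkinetics", initfunc = initf,
                             parms = c(params, sg$u),
                             rtol = rtol, atol = atol, maxsteps = 5000))
            if (attr(out, "istate")[1] < 0) abort("integrator failure")
            y <- out[nrow(out), -1]
            traj[sg$rows[sg$keep], ] <- out[sg$keep, -1, drop = FALSE]
          }
        }
        for (g in pl$groups) {
          x <- if (length(g$cols) == 1L) traj[g$rows, g$cols]
               else rowSums(traj[g$rows, g$cols, drop = FALSE])
          if (g$relative) {
            denom <- sum(x^2 * g$w)
            s <- if (denom > 0) max(sum(x * g$value * g$w) / denom, 0) else 0
            x <- s * x
          }
          total <- total + g$const - sum((g$value - x)^2 * g$w) / 2
        }
      }
      total
    }, error = function(e) -Inf)
    if (is.nan(ll)) ll <- -Inf
    ll
  }
}

# lean steady-state solver on raw numerics (warm-started Newton with
# integration fallback); mirrors steady_state() for u = 0
.steady_state_fast <- function(variant_i, params, guess = NULL,
                               tol = 1e-6) {
  u <- c(0, 0, 0, 0)
  f <- function(x) .Call("C_ck_rates", variant_i, x, params, u,
                         PACKAGE = "certkinetics")$dy
  if (!is.null(guess)) {
    pol <- .newton_polish(f, guess, tol, 25L)
    if (pol$ok && all(pol$x >= 0)) return(pol$x)
  }
  d <- params[23:25]
  start <- numeric(7)
  start[1] <- params[18] / params[23]
  start[3] <- params[19] / params[24]
  start[6] <- params[20] / params[25]
  t_end <- 10 / min(d)
  func <- if (variant_i == 1L) "ck_derivs_B" else "ck_derivs_A"
  initf <- if (variant_i == 1L) "ck_init_B" else "ck_init_A"
  out <- suppressWarnings(
    deSolve::lsoda(start, c(0, t_end), func = func,
                   dllname = "certkinetics", initfunc = initf,
                   parms = c(params, u), rtol = 1e-8, atol = 1e-4,
                   maxsteps = 10000))
  if (attr(out, "istate")[1] < 0) abort("integrator failure in steady state")
  x <- pmax(out[nrow(out), -1], 0)
  pol <- .newton_polish(f, x, tol, 50L)
  if (!pol$ok) abort(paste0("steady state did not converge; residual ",
                            format(pol$resid, digits = 4)))
  pol$x
}

#' Log likelihood of a parameter vector
#'
#' One-shot wrapper around [make_likelihood()].
#'
#' @inheritParams make_likelihood
#' @param theta log10 parameter vector.
#' @return A single number (`-Inf` on simulation failure).
#' @export
log_likelihood <- function(theta, model, dataset, protocols, ...) {
  make_likelihood(model, dataset, protocols, ...)(theta)
}

#' Tempered target
#'
#' Bundles model, data, protocols and prior into the object the sampler
#' and evidence machinery consume.  The tempered log density at inverse
#' temperature `beta` is `log_prior + beta * log_lik`; `beta = 1` is the
#' posterior and `beta = 0` the prior.
#'
#' @inheritParams make_likelihood
#' @param prior a [prior_spec()] object over the model's parameters.
#' @return An object of class `ck_target` with elements `log_prior`,
#'   `log_lik`, `lower`, `upper`, `parameter_names`.
#' @export
tempered_target <- function(model, dataset, protocols, prior, ...) {
  stopifnot(inherits(prior, "ck_prior"),
            setequal(prior$names, model$parameter_names))
  lo <- prior$lower[model$parameter_names]
  hi <- prior$upper[model$parameter_names]
  pr2 <- prior_spec(lo, hi)
  structure(list(
    log_prior = function(theta) log_prior(theta, pr2),
    log_lik = make_likelihood(model, dataset, protocols, ...),
    lower = lo, upper = hi,
    parameter_names = model$parameter_names
  ), class = "ck_target")
}

#' Tempered log density
#'
#' @param theta log10 parameter vector.
#' @param target a list with functions `log_prior` and `log_lik` (e.g.
#'   [tempered_target()]).
#' @param beta inverse temperature in `[0, 1]`.
#' @return `log_prior(theta) + beta * log_lik(theta)`.
#' @export
log_tempered <- function(theta, target, beta) {
  stopifnot(beta >= 0, beta <= 1)
  lp <- target$log_prior(theta)
  if (!is.finite(lp)) return(-Inf)
  if (beta == 0) return(lp)
  ll <- target$log_lik(theta)
  if (is.nan(ll)) ll <- -Inf
  lp + beta * ll
}

#' Multistart bounded maximization
#'
#' Core engine behind [multistart_map()]: `n_starts` L-BFGS-B runs from
#' uniform draws inside the box, ranked by objective value.  Deterministic
#' given `seed`.
#'
#' @param fn objective to maximize (takes a numeric vector).
#' @param lower,upper box bounds.
#' @param n_starts number of starts (>= 1).
#' @param seed RNG seed.
#' @param init optional matrix/vector of explicit starting points used
#'   before random ones.
#' @param maxit per-start iteration cap for `optim`.
#' @return A tibble with columns `rank`, `value`, `par` (list column),
#'   `convergence`.
#' @export
multistart_optimize <- function(fn, lower, upper, n_starts = 10L, seed = 1L,
                                init = NULL, maxit = 300L) {
  stopifnot(n_starts >= 1, all(lower < upper))
  npar <- length(lower)
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * npar, lower, upper),
                nrow = n_starts, byrow = TRUE)
    m
  })
  if (!is.null(init)) {
    init <- matrix(init, ncol = npar)
    starts <- rbind(init, starts)[seq_len(max(n_starts, nrow(init))), ,
                                  drop = FALSE]
  }
  res <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch({
      o <- optim(starts[i, ], fn, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(fnscale = -1, maxit = maxit))
      list(value = o$value, par = o$par, convergence = o$convergence)
    }, error = function(e) list(value = -Inf, par = starts[i, ],
                                convergence = 99L,
                                message = conditionMessage(e)))
  })
  vals <- vapply(res, `[[`, 0, "value")
  if (all(!is.finite(vals))) {
    msgs <- unique(unlist(lapply(res, function(r) r$message)))
    abort(paste0("all optimization starts failed",
                 if (length(msgs)) paste0(": ", paste(msgs, collapse = "; "))))
  }
  ord <- order(vals, decreasing = TRUE)
  tibble(rank = seq_along(ord),
         value = vals[ord],
         par = lapply(ord, function(i) res[[i]]$par),
         convergence = vapply(res, `[[`, 0L, "convergence")[ord])
}

#' Multistart MAP estimation
#'
#' Repeated bounded local maximizations of the log posterior from
#' log-uniformly sampled initial conditions, ranked by posterior value.
#'
#' @inheritParams tempered_target
#' @param n_starts number of random starts.
#' @param seed RNG seed (results are deterministic given the seed).
#' @param init optional explicit starting point(s) (log10 scale) tried
#'   before the random ones.
#' @param maxit per-start iteration cap.
#' @return A tibble as in [multistart_optimize()], with parameter names on
#'   each `par` element.
#' @export
multistart_map <- function(model, dataset, protocols, prior,
                           n_starts = 10L, seed = 1L, init = NULL,
                           maxit = 300L) {
  tgt <- tempered_target(model, dataset, protocols, prior)
  post <- function(theta) {
    lp <- tgt$log_prior(theta)
    if (!is.finite(lp)) return(-1e300)
    ll <- tgt$log_lik(theta)
    if (!is.finite(ll)) return(-1e300)
    lp + ll
  }
  out <- multistart_optimize(post, tgt$lower, tgt$upper,
                             n_starts = n_starts, seed = seed,
                             init = init, maxit = maxit)
  out$par <- lapply(out$par, setNames, tgt$parameter_names)
  out
}
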