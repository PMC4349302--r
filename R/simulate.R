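#  Perturbation-protocol simulation and observation mapping.
#
#  A protocol is a set of step inputs (transfection-driven ectopic
#  synthesis, PDBu activation, kb-NB142-70 inhibition) plus observation
#  requests.  Integration restarts at every input switch so the solver
#  never steps across a discontinuity; within a segment the inputs are
#  constant and the compiled right-hand side is used directly.

#' Define a perturbation protocol
#'
#' @param id protocol identifier.
#' @param inputs an [input_signal()] tibble (possibly empty).
#' @param observations a tibble with columns `observable`
#'   (`"pPKD"`/`"pPI4K"`/`"pCERT"` or their aliases `"y4"`/`"y5"`/`"y6"`,
#'   or `"PKD_total"`, `"PI4K_total"`, `"CERT_total"`), `mode`
#'   (`"absolute"` or `"relative"`) and `times_h` (list column of numeric
#'   observation times, hours).
#' @param horizon_h simulation horizon in hours.
#' @return An object of class `ck_protocol`.
#' @export
protocol <- function(id, inputs = input_signal(), observations = NULL,
                     horizon_h) {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(horizon_h), horizon_h >= 0)
  if (is.null(observations)) {
    observations <- tibble(observable = character(), mode = character(),
                           times_h = list())
  }
  stopifnot(all(c("observable", "mode", "times_h") %in% names(observations)))
  tt <- unlist(observations$times_h)
  if (length(tt) && (any(tt < 0) || any(tt > horizon_h)))
    abort("observation times must lie within [0, horizon]")
  if (!all(observations$mode %in% c("absolute", "relative")))
    abort("observation mode must be \"absolute\" or \"relative\"")
  inputs <- inputs[order(inputs$t_on_h), , drop = FALSE]
  structure(list(id = id, inputs = inputs,
                 observations = as_tibble(observations),
                 horizon_h = as.numeric(horizon_h)),
            class = "ck_protocol")
}

#' @export
print.ck_protocol <- function(x, ...) {
  cat("<ck_protocol>", x$id, "horizon", x$horizon_h, "h\n")
  if (nrow(x$inputs))
    cat("  inputs:", paste0(x$inputs$u, "@", x$inputs$t_on_h, "h(",
                            x$inputs$level, ")", collapse = ", "), "\n")
  cat("  observations:", nrow(x$observations), "series\n")
  invisible(x)
}

# one constant-input integration segment (deSolve, compiled RHS)
.integrate_segment <- function(model, y0, params, u, times,
                               rtol = 1e-8, atol = 1e-4) {
  v <- model$variant
  out <- deSolve::lsoda(
    y = as.numeric(y0), times = times,
    func = paste0("ck_derivs_", v), dllname = "certkinetics",
    initfunc = paste0("ck_init_", v),
    parms = c(as.numeric(params), as.numeric(u)),
    rtol = rtol, atol = atol, maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0) {
    abort(paste0("integrator failed near t = ",
                 format(out[nrow(out), 1], digits = 6),
                 " h (variant ", v, ")"))
  }
  out
}

#' Simulate a model through a perturbation protocol
#'
#' Integrates the ODE system piecewise between input switch times with
#' relative tolerance `rtol` (default 1e-8).  Unless `x0` is given, the
#' initial state is the endogenous steady state with all inputs off --
#' cells are assumed unperturbed before the experiment starts.
#'
#' @inheritParams rhs
#' @param protocol a [protocol()] object.
#' @param extra_times additional time points to include in the output grid.
#' @param n_grid number of additional equally spaced grid points for dense
#'   output (0 = only switch/observation times).
#' @param rtol,atol integrator tolerances.
#' @param x0 optional initial state (molecules/cell).
#' @return A tibble with column `time_h` and one column per species;
#'   attributes `variant` and `protocol_id`.
#' @export
simulate_protocol <- function(model, params, protocol, extra_times = NULL,
                              n_grid = 0L, rtol = 1e-8, atol = 1e-4,
                              x0 = NULL) {
  stopifnot(inherits(model, "kinetic_model"), inherits(protocol, "ck_protocol"))
  params <- .check_params(model, params)
  if (is.null(x0)) x0 <- steady_state(model, params)
  x0 <- .check_state(model, x0)

  H <- protocol$horizon_h
  obs_t <- unlist(protocol$observations$times_h)
  sw <- protocol$inputs$t_on_h
  sw <- sort(unique(sw[sw > 0 & sw < H]))
  grid <- sort(unique(c(0, H, sw, obs_t, extra_times,
                        if (n_grid > 0) seq(0, H, length.out = n_grid))))
  grid <- grid[grid >= 0 & grid <= H]

  if (H == 0 || length(grid) == 1L) {
    out <- as_tibble(as.list(c(time_h = 0, x0)))
  } else {
    bounds <- c(0, sw, H)
    rows <- vector("list", length(bounds) - 1L)
    y <- as.numeric(x0)
    for (s in seq_len(length(bounds) - 1L)) {
      a <- bounds[s]; b <- bounds[s + 1L]
      tseg <- sort(unique(c(a, grid[grid > a & grid < b], b)))
      u <- .inputs_at(protocol$inputs, a)
      seg <- .integrate_segment(model, y, params, u, tseg, rtol, atol)
      y <- as.numeric(seg[nrow(seg), -1])
      keep <- if (s == 1L) seq_len(nrow(seg)) else -1L
      rows[[s]] <- seg[keep, , drop = FALSE]
    }
    m <- do.call(rbind, rows)
    colnames(m) <- c("time_h", model$species_names)
    out <- as_tibble(as.data.frame(m))
  }
  attr(out, "variant") <- model$variant
  attr(out, "protocol_id") <- protocol$id
  out
}

# map an observable id to a species combination of a trajectory
.observable_values <- function(trajectory, observable) {
  nm <- names(trajectory)
  cert_forms <- setdiff(nm, c("time_h", "PKD", "PKDpDAG", "PI4K", "PI4Kp"))
  phospho_cert <- intersect(c("CERTpER", "CERTp"), nm)
  switch(observable,
    "y4" = , "pPKD" = trajectory$PKDpDAG,
    "y5" = , "pPI4K" = trajectory$PI4Kp,
    "y6" = , "pCERT" = trajectory[[phospho_cert]],
    "PKD_total" = trajectory$PKD + trajectory$PKDpDAG,
    "PI4K_total" = trajectory$PI4K + trajectory$PI4Kp,
    "CERT_total" = Reduce(`+`, trajectory[cert_forms]),
    abort(paste0("unknown observable: ", observable))
  )
}

#' Map a trajectory to a predicted observable series
#'
#' Absolute observables are species sums in molecules/cell.  Relative
#' observables (phospho-blot signals) carry an unknown per-time-course
#' gain; it is profiled in closed form against the paired data by weighted
#' least squares, `s = sum(x d / sd^2) / sum(x^2 / sd^2)`, clipped at zero.
#'
#' @param trajectory a [simulate_protocol()] result.
#' @param observable observable id (see [protocol()]).
#' @param mode `"absolute"` or `"relative"`.
#' @param data for relative mode, a data frame with columns `time_h`,
#'   `value`, `sd` paired with the requested times.
#' @param times observation times; defaults to `data$time_h` (relative) or
#'   all trajectory times.  Must be on the trajectory grid.
#' @return A tibble with columns `time_h`, `prediction` and (relative mode)
#'   `scale`.
#' @export
observe <- function(trajectory, observable,
                    mode = c("absolute", "relative"),
                    data = NULL, times = NULL) {
  mode <- match.arg(mode)
  if (is.null(times)) {
    times <- if (!is.null(data)) data$time_h else trajectory$time_h
  }
  idx <- match(round(times, 9), round(trajectory$time_h, 9))
  if (anyNA(idx))
    abort("requested observation times are not on the trajectory grid")
  x <- .observable_values(trajectory, observable)[idx]

  if (mode == "absolute") {
    return(tibble(time_h = times, prediction = x))
  }
  if (is.null(data))
    abort("relative mode needs paired data to profile the scale factor")
  stopifnot(all(c("value", "sd") %in% names(data)), nrow(data) == length(x))
  w <- 1 / data$sd^2
  denom <- sum(x^2 * w)
  s <- if (denom > 0) sum(x * data$value * w) / denom else 0
  s <- max(s, 0)
  tibble(time_h = times, prediction = s * x, scale = s)
}

#' Write protocols to JSON
#'
#' @param protocols a list of [protocol()] objects (or a single one).
#' @param path output file.
#' @export
write_protocol_json <- function(protocols, path) {
  if (inherits(protocols, "ck_protocol")) protocols <- list(protocols)
  payload <- lapply(protocols, function(p) {
    list(id = p$id,
         inputs = lapply(seq_len(nrow(p$inputs)), function(i)
           list(u = p$inputs$u[i], t_on_h = p$inputs$t_on_h[i],
                level = p$inputs$level[i])),
         observations = lapply(seq_len(nrow(p$observations)), function(i)
           list(observable = p$observations$observable[i],
                mode = p$observations$mode[i],
                times_h = p$observations$times_h[[i]])),
         horizon_h = p$horizon_h)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read protocols from JSON
#'
#' @param path a file written by [write_protocol_json()].
#' @return A named list of [protocol()] objects.
#' @export
read_protocol_json <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- lapply(raw, function(p) {
    inp <- if (length(p$inputs)) {
      input_signal(u = vapply(p$inputs, `[[`, "", "u"),
                   t_on_h = vapply(p$inputs, `[[`, 0, "t_on_h"),
                   level = vapply(p$inputs, `[[`, 0, "level"))
    } else input_signal()
    obs <- tibble(
      observable = vapply(p$observations, `[[`, "", "observable"),
      mode = vapply(p$observations, `[[`, "", "mode"),
      times_h = lapply(p$observations, function(o) as.numeric(unlist(o$times_h)))
    )
    protocol(p$id, inp, obs, p$horizon_h)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
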