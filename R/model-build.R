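#  Model definitions: species, parameters, reactions, stoichiometry.
#
#  Both variants describe the phosphorylation cycle of PKD, PI4KIIIbeta and
#  CERT at the trans-Golgi network.  Variant A ("shuttle") keeps CERT
#  ER-anchored so that PKD phosphorylation only detaches it from the TGN;
#  the lumped feedback of ceramide transfer on PKD activation makes the
#  loop positive overall.  Variant B ("neck-swinging") detaches
#  phosphorylated CERT from both membranes, so PKD activity suppresses the
#  transfer-active pool: a negative loop.

.ck_species <- list(
  A = c("PKD", "PKDpDAG", "PI4K", "PI4Kp", "CERTpER", "CERTaER", "CERTaTGN"),
  B = c("PKD", "PKDpDAG", "PI4K", "PI4Kp", "CERTp", "CERTa", "CERTaERTGN")
)

.ck_params_base <- c(
  "vmax1", "K1E", "K1S", "kdp_PI4K",
  "vmax3", "K3E", "K3S", "k9",
  "vmax5", "K5E", "K5S", "k10",
  "k_act", "vmax_cer", "K_cer", "k_pdbu", "k_deact",
  "s_PKD", "s_PI4K", "s_CERT", "s_ect_PI4K", "s_ect_CERT",
  "d_PKD", "d_PI4K", "d_CERT", "k_inh"
)

.ck_param_names <- function(variant) {
  if (variant == "B") c(.ck_params_base, "k_phos_free") else .ck_params_base
}

#' Build a kinetic model variant
#'
#' Constructs one of the two competing ODE models of the PKD--PI4KIIIbeta--
#' CERT network: variant `"A"` (shuttle mechanism, overall positive feedback
#' of ceramide transfer on PKD activation) or variant `"B"` (neck-swinging
#' mechanism, negative feedback through phosphorylation of the transfer-
#' active CERT pool).  Both variants have seven state variables
#' (molecules/cell); A has 26 kinetic parameters and B has 27 (the extra
#' one, `k_phos_free`, is a PKD-dependent phosphorylation of free CERT).
#'
#' Regulated reactions use a double-saturating rate law
#' `v = vmax * E/(K_E + E) * S/(K_S + S)` (regulator E, substrate S), which
#' is bounded by `vmax` and gives every regulation a well-defined operating
#' point `v / vmax`.  The ceramide-transfer flux `J = k10 * CERT_TGN`
#' (molecules/h) leaves the modelled state space (ceramide itself is not a
#' state) and feeds back on PKD activation through a saturating channel
#' `vmax_cer * J/(K_cer + J)`.
#'
#' Experimental inputs: `u1` PDBu activation of PKD (extra mass-action
#' activation channel `u1 * k_pdbu`), `u2` kb-NB142-70 inhibition of PKD
#' (all PKD-catalysed vmax terms and the basal/PDBu activation channels are
#' divided by `1 + k_inh * u2`), `u3`/`u4` ectopic synthesis of PI4KIIIbeta
#' and CERT.
#'
#' @param variant `"A"` or `"B"`.
#' @return An object of class `kinetic_model` with elements
#'   `variant`, `species_names`, `parameter_names`, `reactions` (a tibble of
#'   reaction specifications) and `stoichiometry` (species x flux matrix).
#' @examples
#' m <- build_model("A")
#' m$species_names
#' nrow(m$reactions)
#' @export
build_model <- function(variant = c("A", "B")) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% c("A", "B")) {
    abort("`variant` must be \"A\" or \"B\"")
  }
  sp <- .ck_species[[variant]]
  pars <- .ck_param_names(variant)
  cp <- sp[5]   # phospho-CERT form
  ca <- sp[6]   # transfer-competent, ER-side form (receives synthesis)
  ct <- sp[7]   # TGN-delivering form (carries the transfer flux)

  rx <- tibble(
    id = c("R1", "dephos_PI4K", "R3", "R9", "R5", "R10",
           "act_basal", "act_pdbu", "R6", "deact_PKD",
           "syn_PKD", "syn_PI4K", "syn_ect_PI4K", "syn_CERT", "syn_ect_CERT",
           paste0("deg_", sp)),
    law = c("regulated_mm", "mass_action", "regulated_mm", "mass_action",
            "regulated_mm", "output_flux",
            "mass_action", "mass_action", "regulated_mm", "mass_action",
            rep("synthesis", 5), rep("mass_action", 7)),
    regulator = c("PKDpDAG", NA, "PKDpDAG", NA, "PI4Kp", NA,
                  NA, NA, "J", NA, rep(NA, 5), rep(NA, 7)),
    substrate = c("PI4K", "PI4Kp", ct, cp, ca, ct,
                  "PKD", "PKD", "PKD", "PKDpDAG",
                  rep(NA, 5), sp),
    product = c("PI4Kp", "PI4K", cp, ca, ct, NA,
                "PKDpDAG", "PKDpDAG", "PKDpDAG", "PKD",
                "PKD", "PI4K", "PI4K", ca, ca, rep(NA, 7)),
    parameters = list(
      c("vmax1", "K1E", "K1S"), "kdp_PI4K",
      c("vmax3", "K3E", "K3S"), "k9",
      c("vmax5", "K5E", "K5S"), "k10",
      "k_act", "k_pdbu", c("vmax_cer", "K_cer"), "k_deact",
      "s_PKD", "s_PI4K", "s_ect_PI4K", "s_CERT", "s_ect_CERT",
      "d_PKD", "d_PKD", "d_PI4K", "d_PI4K", "d_CERT", "d_CERT", "d_CERT"
    ),
    input = c(NA, NA, NA, NA, NA, NA, NA, "u1", NA, NA,
              NA, NA, "u3", NA, "u4", rep(NA, 7))
  )
  if (variant == "B") {
    rx <- bind_rows(rx, tibble(
      id = "phos_free", law = "mass_action_bilinear",
      regulator = "PKDpDAG", substrate = ca, product = cp,
      parameters = list("k_phos_free"), input = NA_character_
    ))
  }

  # stoichiometry from the reaction table: substrate -1, product +1;
  # R10 is a pure output flux (ceramide leaves the modelled state space).
  S <- matrix(0, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$id))
  for (j in seq_len(nrow(rx))) {
    if (rx$law[j] == "output_flux") next
    if (!is.na(rx$substrate[j])) S[rx$substrate[j], j] <- S[rx$substrate[j], j] - 1
    if (!is.na(rx$product[j]))   S[rx$product[j], j]   <- S[rx$product[j], j] + 1
  }

  structure(
    list(variant = variant, species_names = sp, parameter_names = pars,
         reactions = rx, stoichiometry = S),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> variant", x$variant, "\n")
  cat("  species   (", length(x$species_names), "): ",
      paste(x$species_names, collapse = ", "), "\n", sep = "")
  cat("  parameters (", length(x$parameter_names), ")\n", sep = "")
  cat("  reactions  (", nrow(x$reactions), " flux terms)\n", sep = "")
  invisible(x)
}

.check_params <- function(model, params) {
  if (is.null(names(params))) {
    if (length(params) != length(model$parameter_names))
      abort("parameter vector has the wrong length")
    names(params) <- model$parameter_names
  }
  if (!setequal(names(params), model$parameter_names))
    abort("parameter names do not match the model")
  params <- params[model$parameter_names]
  if (any(!is.finite(params)) || any(params <= 0))
    abort("all parameters must be positive and finite")
  params
}

.check_state <- function(model, state) {
  if (is.null(names(state))) {
    if (length(state) != 7L) abort("state vector must have length 7")
    names(state) <- model$species_names
  }
  state <- state[model$species_names]
  if (any(!is.finite(state))) abort("state vector must be finite")
  if (any(state < 0)) abort("state amounts must be nonnegative")
  state
}

# resolve the four input levels at time t from an input-signal tibble,
# a plain numeric u-vector, or NULL (all inputs off)
.inputs_at <- function(inputs, t) {
  if (is.null(inputs)) return(c(u1 = 0, u2 = 0, u3 = 0, u4 = 0))
  if (is.numeric(inputs)) {
    stopifnot(length(inputs) == 4L)
    return(setNames(as.numeric(inputs), c("u1", "u2", "u3", "u4")))
  }
  u <- c(u1 = 0, u2 = 0, u3 = 0, u4 = 0)
  if (nrow(inputs)) {
    for (i in seq_len(nrow(inputs))) {
      if (t >= inputs$t_on_h[i]) u[inputs$u[i]] <- inputs$level[i]
    }
  }
  u
}

#' Define a piecewise-constant experimental input signal
#'
#' Each row switches one input on at `t_on_h` hours (levels in `[0, 1]`
#' unless deliberately overdriven).  `u1` = PDBu activation of PKD,
#' `u2` = kb-NB142-70 inhibition of PKD, `u3`/`u4` = ectopic synthesis of
#' PI4KIIIbeta / CERT.
#'
#' @param u character vector of input names (`"u1"`..`"u4"`).
#' @param t_on_h switch-on times in hours.
#' @param level input levels after switch-on.
#' @return A tibble with columns `u`, `t_on_h`, `level`.
#' @export
input_signal <- function(u = character(), t_on_h = numeric(),
                         level = numeric()) {
  if (length(u) && (!all(u %in% c("u1", "u2", "u3", "u4"))))
    abort("input names must be among u1..u4")
  if (any(!is.finite(t_on_h)) || any(t_on_h < 0))
    abort("switch times must be nonnegative and finite")
  tibble(u = as.character(u), t_on_h = as.numeric(t_on_h),
         level = as.numeric(level))
}

.rates_call <- function(model, state, params, u) {
  .Call("C_ck_rates", if (model$variant == "B") 1L else 0L,
        as.numeric(state), as.numeric(params), as.numeric(u),
        PACKAGE = "certkinetics")
}

#' Evaluate the ODE right-hand side
#'
#' Returns the time derivative of every species (molecules/(cell h)) at a
#' given state, as the stoichiometry-weighted sum of all reaction and
#' turnover fluxes.
#'
#' @param model a [build_model()] object.
#' @param state named or ordered state vector (molecules/cell, nonnegative).
#' @param params named parameter vector on the linear scale.
#' @param inputs an [input_signal()] tibble, a numeric `c(u1,u2,u3,u4)`
#'   vector, or `NULL` for all inputs off.
#' @param t time in hours (used only to resolve step inputs).
#' @return Named numeric vector of derivatives.
#' @export
rhs <- function(model, state, params, inputs = NULL, t = 0) {
  stopifnot(inherits(model, "kinetic_model"))
  state <- .check_state(model, state)
  params <- .check_params(model, params)
  u <- .inputs_at(inputs, t)
  out <- .rates_call(model, state, params, u)
  dy <- setNames(out$dy, model$species_names)
  if (any(!is.finite(dy))) {
    fl <- out$flux
    bad <- model$reactions$id[which(!is.finite(fl))[1]]
    abort(paste0("non-finite flux in reaction ", bad))
  }
  dy
}

#' Evaluate all reaction and turnover fluxes
#'
#' @inheritParams rhs
#' @return A tibble with columns `reaction`, `law` and `flux`
#'   (molecules/h); the stoichiometry-weighted sum of these fluxes equals
#'   [rhs()].
#' @export
reaction_fluxes <- function(model, state, params, inputs = NULL, t = 0) {
  stopifnot(inherits(model, "kinetic_model"))
  state <- .check_state(model, state)
  params <- .check_params(model, params)
  u <- .inputs_at(inputs, t)
  out <- .rates_call(model, state, params, u)
  if (any(!is.finite(out$flux))) {
    bad <- model$reactions$id[which(!is.finite(out$flux))[1]]
    abort(paste0("non-finite flux in reaction ", bad))
  }
  tibble(reaction = model$reactions$id,
         law = model$reactions$law,
         flux = out$flux)
}

#' Ceramide transfer flux
#'
#' `J = k10 *` (TGN-delivering CERT form): `CERTaTGN` in variant A,
#' `CERTaERTGN` in variant B.  Units molecules/h.
#'
#' @inheritParams rhs
#' @return A single nonnegative number.
#' @export
transfer_flux <- function(model, state, params) {
  stopifnot(inherits(model, "kinetic_model"))
  state <- .check_state(model, state)
  params <- .check_params(model, params)
  unname(params["k10"] * state[model$species_names[7]])
}

#' Solve for a steady state
#'
#' Integrates the system from a turnover-balanced initial guess over ten
#' times the slowest turnover timescale, then polishes the result with
#' damped Newton iterations on the right-hand side until the max-norm
#' residual is below `tol`.
#'
#' @inheritParams rhs
#' @param inputs constant input levels (numeric `c(u1,u2,u3,u4)`, an
#'   [input_signal()] evaluated at `t = Inf`, or `NULL`).
#' @param tol residual tolerance in molecules/(cell h).
#' @param x0 optional warm-start state; when supplied, Newton polishing is
#'   attempted directly from it before falling back to integration.
#' @param max_newton maximum Newton iterations.
#' @return Named steady-state vector with attribute `residual`.
#' @export
steady_state <- function(model, params, inputs = NULL, tol = 1e-6,
                         x0 = NULL, max_newton = 50L) {
  stopifnot(inherits(model, "kinetic_model"))
  params <- .check_params(model, params)
  u <- .inputs_at(inputs, t = Inf)

  f <- function(x) .rates_call(model, x, params, u)$dy

  if (!is.null(x0)) {
    pol <- .newton_polish(f, as.numeric(x0), tol, max_newton)
    if (pol$ok) {
      return(structure(setNames(pol$x, model$species_names),
                       residual = pol$resid))
    }
  }

  d <- params[c("d_PKD", "d_PI4K", "d_CERT")]
  start <- numeric(7)
  start[1] <- (params["s_PKD"]) / d["d_PKD"]
  start[3] <- (params["s_PI4K"] + u["u3"] * params["s_ect_PI4K"]) / d["d_PI4K"]
  start[6] <- (params["s_CERT"] + u["u4"] * params["s_ect_CERT"]) / d["d_CERT"]

  t_end <- 10 / min(d)
  sol <- .integrate_segment(model, start, params, u, c(0, t_end))
  x <- pmax(sol[nrow(sol), -1], 0)

  pol <- .newton_polish(f, as.numeric(x), tol, max_newton)
  if (!pol$ok) {
    # one longer integration before giving up
    sol <- .integrate_segment(model, as.numeric(x), params, u,
                              c(0, 10 * t_end))
    x <- pmax(sol[nrow(sol), -1], 0)
    pol <- .newton_polish(f, as.numeric(x), tol, max_newton)
  }
  if (!pol$ok) {
    abort(paste0("steady state did not converge; last residual ",
                 format(pol$resid, digits = 4)))
  }
  structure(setNames(pol$x, model$species_names), residual = pol$resid)
}

# damped Newton on f(x) = 0 with forward-difference Jacobian;
# rejects steps that leave the nonnegative orthant or raise the residual
.newton_polish <- function(f, x, tol, max_iter) {
  resid <- max(abs(f(x)))
  if (!is.finite(resid)) return(list(ok = FALSE, x = x, resid = Inf))
  for (it in seq_len(max_iter)) {
    if (resid <= tol) return(list(ok = TRUE, x = x, resid = resid))
    fx <- f(x)
    J <- matrix(0, 7, 7)
    for (j in 1:7) {
      h <- max(1e-6 * abs(x[j]), 1e-6)
      xh <- x; xh[j] <- xh[j] + h
      J[, j] <- (f(xh) - fx) / h
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(list(ok = FALSE, x = x, resid = resid))
    lambda <- 1
    improved <- FALSE
    for (k in 1:8) {
      xn <- x + lambda * step
      if (all(xn >= 0)) {
        rn <- max(abs(f(xn)))
        if (is.finite(rn) && rn < resid) {
          x <- xn; resid <- rn; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) return(list(ok = resid <= tol, x = x, resid = resid))
  }
  list(ok = resid <= tol, x = x, resid = resid)
}

#' Export a model definition to JSON
#'
#' Species, parameter names and reaction specifications, for provenance
#' alongside generated datasets and chain files.
#'
#' @param model a [build_model()] object.
#' @param path output file.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  rx <- model$reactions
  jsonlite::write_json(
    list(variant = model$variant,
         species = model$species_names,
         parameters = model$parameter_names,
         reactions = lapply(seq_len(nrow(rx)), function(i)
           list(id = rx$id[i], law = rx$law[i],
                regulator = rx$regulator[i], substrate = rx$substrate[i],
                product = rx$product[i],
                parameters = rx$parameters[[i]], input = rx$input[i]))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Import a model definition from JSON
#'
#' Rebuilds the model from its variant tag and verifies that the stored
#' species and parameter lists match the package's definition.
#'
#' @param path a file written by [model_to_json()].
#' @return A `kinetic_model`.
#' @export
model_from_json <- function(path) {
  raw <- jsonlite::read_json(path)
  m <- build_model(raw$variant)
  if (!identical(unlist(raw$species), m$species_names) ||
      !identical(unlist(raw$parameters), m$parameter_names))
    abort("stored model definition does not match this package version")
  m
}
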