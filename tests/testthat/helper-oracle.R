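# Independent hand-summed flux oracle: every rate law and mass balance is
# written out symbol by symbol in plain R, without touching the package's
# compiled evaluator or stoichiometry machinery.

oracle_rates <- function(variant, y, p, u) {
  names(u) <- c("u1", "u2", "u3", "u4")
  inh <- 1 / (1 + p[["k_inh"]] * u[["u2"]])
  PKD <- y[1]; PKDpDAG <- y[2]; PI4K <- y[3]; PI4Kp <- y[4]
  Cp <- y[5]; Ca <- y[6]; Ct <- y[7]
  E <- PKDpDAG

  vR1 <- inh * p[["vmax1"]] * E / (p[["K1E"]] + E) * PI4K / (p[["K1S"]] + PI4K)
  vdp <- p[["kdp_PI4K"]] * PI4Kp
  vR3 <- inh * p[["vmax3"]] * E / (p[["K3E"]] + E) * Ct / (p[["K3S"]] + Ct)
  vR9 <- p[["k9"]] * Cp
  vR5 <- p[["vmax5"]] * PI4Kp / (p[["K5E"]] + PI4Kp) * Ca / (p[["K5S"]] + Ca)
  J   <- p[["k10"]] * Ct
  vab <- inh * p[["k_act"]] * PKD
  vap <- inh * u[["u1"]] * p[["k_pdbu"]] * PKD
  vR6 <- if (PKD > 0) p[["vmax_cer"]] * J / (p[["K_cer"]] + J) else 0
  vde <- p[["k_deact"]] * PKDpDAG
  vpf <- if (variant == "B") inh * p[["k_phos_free"]] * E * Ca else 0

  sI <- p[["s_PI4K"]] + u[["u3"]] * p[["s_ect_PI4K"]]
  sC <- p[["s_CERT"]] + u[["u4"]] * p[["s_ect_CERT"]]
  dP <- p[["d_PKD"]]; dI <- p[["d_PI4K"]]; dC <- p[["d_CERT"]]

  dy <- c(
    p[["s_PKD"]] + vde - vab - vap - vR6 - dP * PKD,
    vab + vap + vR6 - vde - dP * PKDpDAG,
    sI + vdp - vR1 - dI * PI4K,
    vR1 - vdp - dI * PI4Kp,
    vR3 + vpf - vR9 - dC * Cp,
    p[["s_CERT"]] + u[["u4"]] * p[["s_ect_CERT"]] + vR9 - vR5 - vpf - dC * Ca,
    vR5 - vR3 - dC * Ct
  )
  flux <- c(R1 = vR1, dephos_PI4K = vdp, R3 = vR3, R9 = vR9, R5 = vR5,
            R10 = J, act_basal = vab, act_pdbu = vap, R6 = vR6,
            deact_PKD = vde,
            syn_PKD = p[["s_PKD"]], syn_PI4K = p[["s_PI4K"]],
            syn_ect_PI4K = u[["u3"]] * p[["s_ect_PI4K"]],
            syn_CERT = p[["s_CERT"]],
            syn_ect_CERT = u[["u4"]] * p[["s_ect_CERT"]],
            deg_1 = dP * PKD, deg_2 = dP * PKDpDAG, deg_3 = dI * PI4K,
            deg_4 = dI * PI4Kp, deg_5 = dC * Cp, deg_6 = dC * Ca,
            deg_7 = dC * Ct)
  if (variant == "B") flux <- c(flux, phos_free = vpf)
  list(dy = dy, flux = unname(flux))
}

# random positive parameter vector for a variant (log-uniform over a broad
# but finite range per parameter class)
random_params <- function(variant, scale = 1) {
  base <- ground_truth(variant)
  base * 10^runif(length(base), -scale, scale)
}

random_state <- function() {
  10^runif(7, 2, 6)
}

# parameters that switch the coupled reactions effectively off, leaving a
# pure synthesis/degradation (turnover) system
turnover_only_params <- function(variant) {
  p <- ground_truth(variant)
  off <- c("vmax1", "vmax3", "vmax5", "vmax_cer", "k_act", "k_pdbu",
           "kdp_PI4K", "k9", if (variant == "B") "k_phos_free")
  p[off] <- 1e-30
  p
}
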