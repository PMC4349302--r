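test_that("model structure: species and parameter counts per variant", {
  mA <- build_model("A")
  mB <- build_model("B")
  expect_length(mA$species_names, 7L)
  expect_length(mB$species_names, 7L)
  expect_length(mA$parameter_names, 26L)
  expect_length(mB$parameter_names, 27L)
  # the variants differ exactly in the three CERT states
  expect_identical(mA$species_names[1:4], mB$species_names[1:4])
  expect_length(setdiff(mA$species_names, mB$species_names), 3L)
  expect_length(setdiff(mB$species_names, mA$species_names), 3L)
  expect_error(build_model("C"), "variant")

  for (m in list(mA, mB)) {
    used <- unique(unlist(m$reactions$parameters))
    # k_inh enters through the inhibition factor on PKD-dependent terms
    expect_setequal(c(used, "k_inh"), m$parameter_names)
    # non-turnover parameters are owned by exactly one reaction
    counts <- table(unlist(m$reactions$parameters))
    shared <- c("d_PKD", "d_PI4K", "d_CERT")
    expect_true(all(counts[setdiff(names(counts), shared)] == 1L))
  }
})

test_that("rhs matches an independently hand-summed flux balance", {
  set.seed(42)
  for (variant in c("A", "B")) {
    m <- build_model(variant)
    for (rep in 1:10) {
      y <- random_state()
      p <- random_params(variant)
      u <- c(runif(1), runif(1), rbinom(1, 1, 0.5), rbinom(1, 1, 0.5))
      orc <- oracle_rates(variant, y, p, u)
      dy <- rhs(m, y, p, inputs = u)
      expect_equal(unname(dy), orc$dy, tolerance = 1e-10)
      fl <- reaction_fluxes(m, y, p, inputs = u)
      expect_equal(fl$flux, orc$flux, tolerance = 1e-10)
      # internal consistency: stoichiometric reassembly reproduces rhs
      expect_equal(as.numeric(m$stoichiometry %*% fl$flux), unname(dy),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs degenerate cases: empty system and pure decay", {
  m <- build_model("A")
  p <- ground_truth("A")
  p[c("s_PKD", "s_PI4K", "s_CERT")] <- 1e-300
  dy <- rhs(m, rep(0, 7), p)
  expect_equal(unname(dy), rep(0, 7), tolerance = 1e-200)

  p2 <- turnover_only_params("A")
  p2[c("s_PKD", "s_PI4K", "s_CERT")] <- 1e-300
  x0 <- 1234.5
  dy2 <- rhs(m, c(x0, 0, 0, 0, 0, 0, 0), p2)
  expect_equal(unname(dy2[1]), -p2[["d_PKD"]] * x0, tolerance = 1e-10)
  expect_true(all(abs(dy2[-1]) < 1e-12))

  expect_error(rhs(m, c(-1, rep(1, 6)), ground_truth("A")), "nonnegative")
})

test_that("regulated fluxes are bounded by vmax and vanish with the regulator", {
  for (variant in c("A", "B")) {
    m <- build_model(variant)
    p <- ground_truth(variant)
    set.seed(7)
    reg <- which(m$reactions$law == "regulated_mm")
    for (rep in 1:5) {
      pr <- random_params(variant)
      fl <- reaction_fluxes(m, random_state(), pr)
      expect_true(all(fl$flux >= 0))
      vmaxes <- pr[vapply(m$reactions$parameters[reg], `[[`, "", 1)]
      expect_true(all(fl$flux[reg] <= vmaxes))
    }

    # regulator at zero kills the regulated flux (PKDpDAG = 0 -> R1 = 0)
    y <- c(1e5, 0, 1e6, 1e5, 1e4, 1e5, 1e4)
    fl0 <- reaction_fluxes(m, y, p)
    expect_equal(fl0$flux[fl0$reaction == "R1"], 0)
    expect_equal(fl0$flux[fl0$reaction == "R3"], 0)

    # saturation: huge regulator and substrate drive the flux to vmax
    y2 <- c(1e3, 1e12, 1e12, 1e12, 1e4, 1e12, 1e12)
    fl2 <- reaction_fluxes(m, y2, p)
    expect_equal(fl2$flux[fl2$reaction == "R1"], p[["vmax1"]],
                 tolerance = 1e-5)
    expect_equal(fl2$flux[fl2$reaction == "R5"], p[["vmax5"]],
                 tolerance = 1e-5)
  }
})

test_that("transfer flux is the linear law on the TGN-bound CERT form", {
  mA <- build_model("A")
  p <- ground_truth("A")
  p["k10"] <- 2
  y <- c(1e5, 1e4, 1e6, 1e5, 1e4, 1e5, 100)
  expect_equal(transfer_flux(mA, y, p), 200)
  y[7] <- 0
  expect_equal(transfer_flux(mA, y, p), 0)
  mB <- build_model("B")
  pB <- ground_truth("B")
  pB["k10"] <- 0.5
  yB <- c(1e5, 1e4, 1e6, 1e5, 1e4, 1e5, 50)
  expect_equal(transfer_flux(mB, yB, pB), 25)
})

test_that("steady state: turnover balance, residual, and linear scaling", {
  for (variant in c("A", "B")) {
    m <- build_model(variant)
    p <- turnover_only_params(variant)
    ss <- steady_state(m, p)
    expect_equal(ss[["PKD"]], p[["s_PKD"]] / p[["d_PKD"]], tolerance = 1e-6)
    expect_equal(ss[[m$species_names[6]]], p[["s_CERT"]] / p[["d_CERT"]],
                 tolerance = 1e-6)
    expect_equal(ss[["PI4K"]], p[["s_PI4K"]] / p[["d_PI4K"]],
                 tolerance = 1e-6)
    # doubling synthesis doubles the turnover-only steady state
    p2 <- p
    p2[c("s_PKD", "s_PI4K", "s_CERT")] <- 2 * p[c("s_PKD", "s_PI4K", "s_CERT")]
    ss2 <- steady_state(m, p2)
    expect_equal(ss2[["PKD"]], 2 * ss[["PKD"]], tolerance = 1e-6)

    # full model: the residual criterion is the oracle
    pg <- ground_truth(variant)
    ssg <- steady_state(m, pg)
    expect_lt(max(abs(rhs(m, ssg, pg))), 1e-6)
    expect_true(all(ssg >= 0))
  }
})

test_that("protein totals are conserved when turnover is off", {
  for (variant in c("A", "B")) {
    m <- build_model(variant)
    p <- ground_truth(variant)
    p[c("s_PKD", "s_PI4K", "s_CERT", "s_ect_PI4K", "s_ect_CERT")] <- 1e-300
    p[c("d_PKD", "d_PI4K", "d_CERT")] <- 1e-300
    x0 <- c(4e5, 1e5, 1.5e6, 5e5, 1e5, 3e5, 1e5)
    pr <- protocol("cons", input_signal(),
                   tibble::tibble(observable = "PKD_total",
                                  mode = "absolute", times_h = list(0)),
                   horizon_h = 48)
    traj <- simulate_protocol(m, p, pr, n_grid = 25, x0 = x0)
    tot_pkd <- traj$PKD + traj$PKDpDAG
    tot_pi4k <- traj$PI4K + traj$PI4Kp
    tot_cert <- rowSums(traj[, m$species_names[5:7]])
    expect_equal(tot_pkd, rep(tot_pkd[1], length(tot_pkd)), tolerance = 1e-6)
    expect_equal(tot_pi4k, rep(tot_pi4k[1], length(tot_pi4k)), tolerance = 1e-6)
    expect_equal(tot_cert, rep(tot_cert[1], length(tot_cert)), tolerance = 1e-6)
    # nonnegativity along the trajectory
    expect_true(all(as.matrix(traj[, -1]) >= -1e-9))
  }
})

test_that("feedback signs: positive loop in A, negative loop in B", {
  mA <- build_model("A")
  pA <- ground_truth("A")
  ssA <- steady_state(mA, pA)
  p2 <- pA; p2["k10"] <- pA["k10"] * 1.05
  ss2 <- steady_state(mA, p2, x0 = ssA)
  expect_gt(ss2[["PKDpDAG"]], ssA[["PKDpDAG"]])

  mB <- build_model("B")
  pB <- ground_truth("B")
  ssB <- steady_state(mB, pB)
  p3 <- pB; p3["k_act"] <- pB["k_act"] * 1.05
  ss3 <- steady_state(mB, p3, x0 = ssB)
  expect_lt(transfer_flux(mB, ss3, p3), transfer_flux(mB, ssB, pB))
})

test_that("model JSON round trip preserves the definition", {
  m <- build_model("B")
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, f)
  m2 <- model_from_json(f)
  expect_identical(m2$species_names, m$species_names)
  expect_identical(m2$parameter_names, m$parameter_names)
})
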