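truth_draws <- function(variant, n = 1) {
  th <- log10(ground_truth(variant))
  matrix(rep(th, each = n), nrow = n, dimnames = list(NULL, names(th)))
}

test_that("a single-draw sample gives degenerate summaries equal to that draw", {
  m <- build_model("A")
  pred <- endogenous_distributions(m, truth_draws("A"))
  expect_equal(pred$summary$lo, pred$summary$hi)
  expect_equal(pred$summary$mean, pred$summary$lo)
  p <- ground_truth("A")
  ss <- steady_state(m, p)
  amt <- pred$summary[pred$summary$type == "amount", ]
  expect_equal(amt$mean[match(names(ss), amt$quantity)], as.numeric(ss),
               tolerance = 1e-9)
  expect_equal(amt$mean[amt$quantity == "transfer_J"],
               transfer_flux(m, ss, p), tolerance = 1e-9)
})

test_that("steady-state fluxes balance synthesis against degradation", {
  m <- build_model("A")
  p <- ground_truth("A")
  fl <- reaction_fluxes(m, steady_state(m, p), p)
  g <- function(id) fl$flux[fl$reaction == id]
  expect_equal(g("syn_PKD"), g("deg_PKD") + g("deg_PKDpDAG"),
               tolerance = 1e-8)
  expect_equal(g("syn_PI4K"), g("deg_PI4K") + g("deg_PI4Kp"),
               tolerance = 1e-8)
  expect_equal(g("syn_CERT"),
               g("deg_CERTpER") + g("deg_CERTaER") + g("deg_CERTaTGN"),
               tolerance = 1e-8)
})

test_that("operating points: half-saturated regulator with saturated substrate gives 0.5", {
  m <- build_model("A")
  p <- ground_truth("A")
  # state engineered so E = K1E and PI4K >> K1S
  y <- c(1e5, p[["K1E"]], 1e12, 0, 1, 1, 1)
  fl <- reaction_fluxes(m, y, p)
  op <- fl$flux[fl$reaction == "R1"] / p[["vmax1"]]
  expect_equal(op, 0.5, tolerance = 1e-5)
  # operating points of all regulated reactions live in [0, 1)
  pred <- endogenous_distributions(m, truth_draws("A"))
  ops <- pred$draws$value[pred$draws$type == "operating_point"]
  expect_true(all(ops >= 0 & ops < 1))
})

test_that("summaries are invariant to the order of posterior draws", {
  m <- build_model("A")
  th <- log10(ground_truth("A"))
  set.seed(15)
  draws <- matrix(rep(th, each = 6), nrow = 6,
                  dimnames = list(NULL, names(th)))
  draws <- draws + matrix(rnorm(length(draws), 0, 0.03), nrow = 6)
  p1 <- endogenous_distributions(m, draws)
  p2 <- endogenous_distributions(m, draws[6:1, ])
  expect_equal(p1$summary, p2$summary, tolerance = 1e-9)
})

test_that("zero-magnitude perturbations are exact no-ops", {
  m <- build_model("A")
  d <- truth_draws("A")
  for (sc in c("transfer_up_10", "pkd_up_10")) {
    r <- perturbation_response(m, d, sc, magnitude = 0)
    expect_equal(r$draws$response_pct, 0)
  }
  # feedback knockout is a no-op when the channel is already negligible
  p <- ground_truth("A")
  p["vmax_cer"] <- 1e-12
  d0 <- matrix(log10(p), nrow = 1, dimnames = list(NULL, names(p)))
  r0 <- perturbation_response(m, d0, "feedback_knockout")
  expect_equal(r0$expectation, 0, tolerance = 1e-6)

  # knockout cannot touch PI4K totals in the turnover-only limit
  pt <- turnover_only_params("A")
  base <- steady_state(m, pt)
  pko <- pt; pko["vmax_cer"] <- 1e-300
  ko_ss <- steady_state(m, pko, x0 = base)
  expect_equal(ko_ss[["PI4K"]] + ko_ss[["PI4Kp"]],
               base[["PI4K"]] + base[["PI4Kp"]], tolerance = 1e-9)
})

test_that("root-finding multiplier matches the closed form on a linear PKD cycle", {
  # all couplings off: PKD activation/deactivation plus turnover is linear,
  # so the steady state of active PKD has an explicit formula
  m <- build_model("A")
  p <- turnover_only_params("A")
  p["k_act"] <- 0.2; p["k_deact"] <- 2; p["kdp_PI4K"] <- 1; p["k9"] <- 1
  pkd_ss <- function(ka) {
    s <- p[["s_PKD"]]; d <- p[["d_PKD"]]; kd <- p[["k_deact"]]
    # solve the 2x2 linear balance for (PKD, PKDpDAG)
    A <- matrix(c(-(ka + d), kd, ka, -(kd + d)), 2, 2, byrow = TRUE)
    -solve(A, c(s, 0))
  }
  base <- pkd_ss(p[["k_act"]])
  target <- 1.1 * base[2]
  lam_star <- uniroot(function(l) pkd_ss(l * p[["k_act"]])[2] - target,
                      c(1, 2), tol = 1e-12)$root

  d0 <- matrix(log10(p), nrow = 1, dimnames = list(NULL, names(p)))
  r <- perturbation_response(m, d0, "pkd_up_10", magnitude = 0.10)
  expect_equal(r$draws$multiplier, lam_star, tolerance = 1e-4)
})

test_that("perturbation directions at the ground truth match the expected couplings", {
  mA <- build_model("A")
  dA <- truth_draws("A")
  up_pkd <- perturbation_response(mA, dA, "pkd_up_10")
  expect_gt(up_pkd$expectation, 0)          # more active PKD -> more transfer
  up_tr <- perturbation_response(mA, dA, "transfer_up_10")
  expect_gt(up_tr$expectation, 0)           # more transfer -> more active PKD
  ko <- perturbation_response(mA, dA, "feedback_knockout")
  expect_lt(ko$expectation, 0)              # removing the feedback lowers PKD
  expect_gt(ko$expectation, -5)             # ... by only a few percent

  mB <- build_model("B")
  dB <- truth_draws("B")
  up_pkdB <- perturbation_response(mB, dB, "pkd_up_10")
  expect_lt(up_pkdB$expectation, 0)         # negative PKD -> transfer coupling
})

test_that("broom-style summaries expose the response distribution", {
  m <- build_model("A")
  r <- perturbation_response(m, truth_draws("A"), "pkd_up_10")
  expect_s3_class(tidy(r), "tbl_df")
  gl <- glance(r)
  expect_identical(gl$scenario, "pkd_up_10")
  expect_equal(gl$expected_pct, r$expectation)
})
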