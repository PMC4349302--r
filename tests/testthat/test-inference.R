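test_that("log-uniform prior density and box behaviour", {
  pr <- prior_spec(c(a = -3), c(a = 3))
  expect_equal(log_prior(0, pr), -log(6))
  expect_equal(log_prior(3.1, pr), -Inf)
  expect_equal(log_prior(-4, pr), -Inf)
  pr2 <- prior_spec(c(a = 0, b = 0), c(a = 1, b = 2))
  expect_equal(log_prior(c(a = 0.5, b = 1), pr2), -log(2))
  expect_error(prior_spec(c(a = 1), c(a = 1)), "lower < upper")
})

test_that("default prior caps degradation and synthesis ranges", {
  m <- build_model("A")
  pr <- default_prior(m, ground_truth("A"))
  for (p in c("d_PKD", "d_PI4K", "d_CERT")) {
    expect_gte(pr$lower[[p]], log10(log(2) / 100))
    expect_lte(pr$upper[[p]], log10(log(2)))
  }
  expect_true(all(pr$upper - pr$lower <= 6 + 1e-12))
  expect_true(all(pr$upper - pr$lower > 0))
})

ll_fixture <- function(variant = "A", cv = 0, rel = 0, seed = 1) {
  syn <- generate_dataset(variant,
                          noise = noise_spec(cv, rel, 3, validate = FALSE),
                          seed = seed)
  list(model = build_model(variant), data = syn$dataset,
       protocols = default_protocols(), truth = syn$truth)
}

test_that("likelihood at zero residuals reduces to the normalization term", {
  fx <- ll_fixture(cv = 0, rel = 0)
  th <- log10(fx$truth$parameters)
  ll <- log_likelihood(th, fx$model, fx$data, fx$protocols)
  expect_equal(ll, sum(-0.5 * log(2 * pi * fx$data$sd^2)), tolerance = 1e-6)
})

test_that("a single unit residual with unit SD costs half a nat", {
  fx <- ll_fixture(cv = 0, rel = 0)
  base <- fx$data[fx$data$protocol_id == "E1" &
                    fx$data$observable == "PKD_total", ][1, ]
  d1 <- base; d1$value <- base$value; d1$sd <- 1
  d2 <- base; d2$value <- base$value + 1; d2$sd <- 1
  l1 <- log_likelihood(log10(fx$truth$parameters), fx$model, d1, fx$protocols)
  l2 <- log_likelihood(log10(fx$truth$parameters), fx$model, d2, fx$protocols)
  expect_equal(l1, -0.5 * log(2 * pi), tolerance = 1e-4)
  expect_equal(l2 - l1, -0.5, tolerance = 1e-4)
})

test_that("profiled relative scale matches a brute-force grid oracle", {
  fx <- ll_fixture(cv = 0.3, rel = 0.1, seed = 4)
  th <- log10(fx$truth$parameters)
  # isolate one relative time course
  rel <- fx$data[fx$data$protocol_id == "E3" & fx$data$observable == "pCERT", ]
  ll_prof <- log_likelihood(th, fx$model, rel, fx$protocols)

  # oracle: simulate, then optimize the scale numerically
  ss <- steady_state(fx$model, fx$truth$parameters)
  traj <- simulate_protocol(fx$model, fx$truth$parameters, fx$protocols$E3,
                            extra_times = rel$time_h, x0 = ss)
  x <- observe(traj, "pCERT", "absolute", times = rel$time_h)$prediction
  obj <- function(s) sum(-0.5 * log(2 * pi * rel$sd^2) -
                           (rel$value - s * x)^2 / (2 * rel$sd^2))
  s_hat <- optimize(obj, c(0, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(ll_prof, s_hat$objective, tolerance = 1e-6)
})

test_that("likelihood is invariant to rescaling a relative course and its SDs", {
  fx <- ll_fixture(cv = 0.3, rel = 0.1, seed = 5)
  th <- log10(fx$truth$parameters)
  d <- fx$data
  sel <- d$mode == "relative" & d$protocol_id == "E2" & d$observable == "pPKD"
  d2 <- d
  d2$value[sel] <- d$value[sel] * 37.5
  d2$sd[sel] <- d$sd[sel] * 37.5
  l1 <- log_likelihood(th, fx$model, d, fx$protocols)
  l2 <- log_likelihood(th, fx$model, d2, fx$protocols)
  # only the Gaussian normalization of the rescaled records differs
  shift <- -sum(sel) * log(37.5)
  expect_equal(l2 - l1, shift, tolerance = 1e-6)
})

test_that("duplicating an absolute record doubles its contribution", {
  fx <- ll_fixture(cv = 0.3, rel = 0.1, seed = 6)
  th <- log10(fx$truth$parameters)
  one <- fx$data[fx$data$mode == "absolute", ][1, ]
  l1 <- log_likelihood(th, fx$model, one, fx$protocols)
  l2 <- log_likelihood(th, fx$model, rbind(one, one), fx$protocols)
  expect_equal(l2, 2 * l1, tolerance = 1e-8)
})

test_that("fast likelihood path agrees with the public simulate/observe route", {
  fx <- ll_fixture(cv = 0.3, rel = 0.1, seed = 2)
  th <- log10(fx$truth$parameters) + 0.05  # move off the truth
  params <- setNames(10^th, names(fx$truth$parameters))
  ll_fast <- log_likelihood(th, fx$model, fx$data, fx$protocols)

  ss <- steady_state(fx$model, params)
  total <- 0
  for (pid in unique(fx$data$protocol_id)) {
    pr <- fx$protocols[[pid]]
    recs <- fx$data[fx$data$protocol_id == pid, ]
    traj <- simulate_protocol(fx$model, params, pr,
                              extra_times = recs$time_h, x0 = ss)
    for (key in unique(paste(recs$experiment_id, recs$observable, recs$mode))) {
      g <- recs[paste(recs$experiment_id, recs$observable, recs$mode) == key, ]
      pred <- if (g$mode[1] == "absolute")
        observe(traj, g$observable[1], "absolute", times = g$time_h)$prediction
      else observe(traj, g$observable[1], "relative", data = g)$prediction
      total <- total + sum(-0.5 * log(2 * pi * g$sd^2) -
                             (g$value - pred)^2 / (2 * g$sd^2))
    }
  }
  expect_equal(ll_fast, total, tolerance = 1e-8)
})

test_that("failed simulations yield -Inf, not an exception", {
  fx <- ll_fixture(cv = 0.3, rel = 0.1)
  th <- log10(fx$truth$parameters)
  th[] <- 12  # absurd corner: astronomically fast rates
  expect_no_error(v <- log_likelihood(th, fx$model, fx$data, fx$protocols))
  expect_true(v == -Inf || is.finite(v))
})

test_that("tempered density interpolates prior and posterior linearly in beta", {
  pr <- prior_spec(c(a = -1, b = -1), c(a = 1, b = 1))
  target <- list(log_prior = function(th) log_prior(th, pr),
                 log_lik = function(th) -sum((th - 0.3)^2))
  th <- c(a = 0.1, b = -0.2)
  lp <- target$log_prior(th); llv <- target$log_lik(th)
  expect_equal(log_tempered(th, target, 0), lp)
  expect_equal(log_tempered(th, target, 1), lp + llv)
  b <- c(0.25, 0.5, 0.75)
  vals <- vapply(b, function(bb) log_tempered(th, target, bb), 0)
  expect_equal(vals, lp + b * llv)
  # arithmetic check from the definition
  t2 <- list(log_prior = function(th) -1, log_lik = function(th) -2)
  expect_equal(log_tempered(0, t2, 0.5), -2)
})

test_that("multistart optimization finds an analytic optimum and is deterministic", {
  opt <- c(0.7, -1.3)
  fn <- function(x) -sum((x - opt)^2)
  res <- multistart_optimize(fn, lower = c(-5, -5), upper = c(5, 5),
                             n_starts = 8, seed = 11)
  expect_equal(res$par[[1]], opt, tolerance = 1e-4)
  expect_true(all(diff(res$value) <= 1e-12))
  res2 <- multistart_optimize(fn, lower = c(-5, -5), upper = c(5, 5),
                              n_starts = 8, seed = 11)
  expect_identical(res$value, res2$value)
  # a start placed at the optimum is returned unchanged
  res3 <- multistart_optimize(fn, lower = c(-5, -5), upper = c(5, 5),
                              n_starts = 1, seed = 1, init = opt)
  expect_equal(res3$par[[1]], opt, tolerance = 1e-10)
  expect_error(
    multistart_optimize(function(x) stop("boom"), -1, 1, n_starts = 2),
    "failed")
})
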