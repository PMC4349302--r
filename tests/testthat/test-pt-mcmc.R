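# small analytic targets for sampler validation
box_target <- function(log_lik, lower, upper, names = NULL) {
  lower <- setNames(lower, names)
  pr <- list(lower = lower, upper = setNames(upper, names))
  list(
    log_prior = function(th) {
      if (any(th < lower) || any(th > upper)) -Inf
      else -sum(log(upper - lower))
    },
    log_lik = log_lik, lower = lower, upper = upper,
    parameter_names = names
  )
}

batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(n_batch)
}

test_that("posterior moments on a standard normal target", {
  tgt <- box_target(function(th) -0.5 * th^2, -8, 8, "x")
  ch <- pt_sample(tgt, ladder = 1, n_iter = 50000, seed = 3, step = 1.5)
  x <- ch$runs[[1]]$samples[-(1:25000), 1, 1]
  expect_lt(abs(mean(x)), 3 * batch_se(x))
  expect_lt(abs(var(x) - 1), 0.1)
  # adapted acceptance in a sane random-walk range
  expect_gt(ch$runs[[1]]$accept_rate[1], 0.10)
  expect_lt(ch$runs[[1]]$accept_rate[1], 0.60)
})

test_that("tempering lets the sampler traverse well-separated modes", {
  lmix <- function(th) {
    log(0.5 * dnorm(th, -5, 1) + 0.5 * dnorm(th, 5, 1))
  }
  tgt <- box_target(lmix, -20, 20, "x")
  ch <- pt_sample(tgt, ladder = c(0, 1), n_iter = 50000, seed = 8, step = 1.5)
  x <- ch$runs[[1]]$samples[-(1:25000), 1, 2]
  frac_pos <- mean(x > 0)
  expect_gte(frac_pos, 0.4)
  expect_lte(frac_pos, 0.6)
  # both modes actually visited
  expect_gt(sum(x > 3), 100)
  expect_gt(sum(x < -3), 100)
})

test_that("chains are bit-reproducible given the seed", {
  tgt <- box_target(function(th) -0.5 * sum(th^2), c(-5, -5), c(5, 5))
  c1 <- pt_sample(tgt, ladder_beta(3), n_iter = 500, n_runs = 2, seed = 42)
  c2 <- pt_sample(tgt, ladder_beta(3), n_iter = 500, n_runs = 2, seed = 42)
  expect_identical(c1$runs[[1]]$samples, c2$runs[[1]]$samples)
  expect_identical(c1$runs[[2]]$logl, c2$runs[[2]]$logl)
  c3 <- pt_sample(tgt, ladder_beta(3), n_iter = 500, n_runs = 2, seed = 43)
  expect_false(identical(c1$runs[[1]]$samples, c3$runs[[1]]$samples))
})

test_that("swaps leave a unimodal posterior's moments unchanged", {
  tgt <- box_target(function(th) -0.5 * (th - 1)^2, -8, 8, "x")
  cs <- pt_sample(tgt, ladder_beta(3), n_iter = 30000, seed = 5, step = 1.5)
  cn <- pt_sample(tgt, ladder_beta(3), n_iter = 30000, seed = 5, step = 1.5,
                  swap = FALSE)
  xs <- cs$runs[[1]]$samples[-(1:15000), 1, 3]
  xn <- cn$runs[[1]]$samples[-(1:15000), 1, 3]
  tol <- 3 * sqrt(batch_se(xs)^2 + batch_se(xn)^2)
  expect_lt(abs(mean(xs) - mean(xn)), max(tol, 0.1))
  expect_lt(abs(var(xs) - var(xn)), 0.15)
})

test_that("the beta = 0 chain reproduces the prior box moments", {
  tgt <- box_target(function(th) -0.5 * sum((th - 0.5)^2),
                    c(-2, 0), c(4, 1), c("a", "b"))
  ch <- pt_sample(tgt, ladder_beta(3), n_iter = 40000, seed = 9, step = 2)
  draws <- ch$runs[[1]]$samples[-(1:20000), , 1]
  expect_equal(mean(draws[, 1]), 1, tolerance = 0.08)
  expect_equal(mean(draws[, 2]), 0.5, tolerance = 0.03)
  expect_equal(var(draws[, 1]), 36 / 12, tolerance = 0.25)
  expect_equal(var(draws[, 2]), 1 / 12, tolerance = 0.03)
})

test_that("long-run frequencies match a discrete three-state target", {
  # piecewise-constant density on [0, 3): exact state probabilities
  p <- c(0.2, 0.3, 0.5)
  lden <- function(th) {
    s <- floor(th) + 1L
    log(p[s])
  }
  tgt <- box_target(lden, 0, 3 - 1e-12, "x")
  ch <- pt_sample(tgt, ladder = 1, n_iter = 60000, seed = 12, step = 1.0)
  x <- ch$runs[[1]]$samples[-(1:30000), 1, 1]
  freq <- tabulate(floor(x) + 1L, 3) / length(x)
  # 3 x binomial SE with a conservative effective sample size
  n_eff <- length(x) / 20
  for (s in 1:3) {
    se <- sqrt(p[s] * (1 - p[s]) / n_eff)
    expect_lt(abs(freq[s] - p[s]), 3 * se)
  }
})

test_that("Gelman-Rubin passes for same-target runs and fails for separated ones", {
  tgt <- box_target(function(th) -0.5 * th^2, -8, 8, "x")
  ch <- pt_sample(tgt, ladder = 1, n_iter = 20000, n_runs = 3, seed = 21,
                  step = 1.5)
  gr <- gelman_rubin(ch)
  expect_true(all(gr$rhat >= 1 - 1e-8))
  expect_true(all(gr$rhat < 1.05))
  expect_true(attr(gr, "pass"))

  # synthetic separated runs: Rhat must blow up
  fake <- ch
  fake$runs[[1]]$samples[, 1, 1] <- rnorm(20000, -10)
  fake$runs[[2]]$samples[, 1, 1] <- rnorm(20000, 10)
  fake$runs[[3]]$samples[, 1, 1] <- rnorm(20000, 0)
  gr2 <- gelman_rubin(fake)
  expect_gt(gr2$rhat[1], 5)
  expect_false(attr(gr2, "pass"))

  # identical constant runs: degenerate flag
  fake2 <- ch
  for (r in 1:3) fake2$runs[[r]]$samples[, 1, 1] <- 1
  gr3 <- gelman_rubin(fake2)
  expect_true(gr3$degenerate[1])
  expect_identical(gr3$rhat[1], Inf)

  expect_error(gelman_rubin(pt_sample(tgt, ladder = 1, n_iter = 100)),
               "two runs")
})

test_that("posterior subsampling is order-stable, bounded and deterministic", {
  tgt <- box_target(function(th) -0.5 * sum(th^2), c(-5, -5), c(5, 5),
                    c("a", "b"))
  ch <- pt_sample(tgt, ladder_beta(2), n_iter = 1000, n_runs = 2, seed = 2)
  all_draws <- subsample_posterior(ch, 1000, seed = 1)  # everything retained
  expect_identical(dim(all_draws), c(1000L, 2L))
  pool <- do.call(rbind, lapply(ch$runs, function(r) r$samples[501:1000, , 2]))
  expect_equal(unname(all_draws), unname(pool))

  one <- subsample_posterior(ch, 1, seed = 7)
  expect_identical(dim(one), c(1L, 2L))
  s1 <- subsample_posterior(ch, 100, seed = 31)
  s2 <- subsample_posterior(ch, 100, seed = 31)
  expect_identical(s1, s2)
  expect_error(subsample_posterior(ch, 1001), "available")
})
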