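# Shared end-to-end inference products for the acceptance checks.
# Computed once per test run, on first use (the coverage chains are the
# expensive part: 4 tempering levels x 20000 iterations x 3 runs).

.e2e_env <- new.env(parent = emptyenv())

e2e_coverage_fit <- function() {
  if (!is.null(.e2e_env$cov)) return(.e2e_env$cov)
  syn <- generate_dataset("A", seed = 1)
  model <- build_model("A")
  center <- ground_truth("A")
  prior <- default_prior(model, center)
  target <- tempered_target(model, syn$dataset, default_protocols(), prior)
  chains <- pt_sample(target, ladder_beta(4, power = 10), n_iter = 20000,
                      n_runs = 3, seed = 1, init = log10(center), step = 0.1)
  .e2e_env$cov <- list(syn = syn, model = model, prior = prior,
                       chains = chains)
  .e2e_env$cov
}

e2e_sign_recovery <- function() {
  if (!is.null(.e2e_env$sign)) return(.e2e_env$sign)
  fit_evidence <- function(data_variant, model_variant, seed) {
    syn <- generate_dataset(data_variant, seed = seed)
    model <- build_model(model_variant)
    center <- ground_truth(model_variant)
    prior <- default_prior(model, center)
    target <- tempered_target(model, syn$dataset, default_protocols(), prior)
    ch <- pt_sample(target, ladder_beta(4, power = 10), n_iter = 4000,
                    n_runs = 1, seed = seed * 1000, init = log10(center),
                    step = 0.1)
    model_evidence(ch, model_variant)
  }
  res <- list()
  for (seed in 1:3) {
    for (dv in c("A", "B")) {
      bf <- bayes_factor(fit_evidence(dv, "A", seed),
                         fit_evidence(dv, "B", seed))
      res[[paste0(dv, seed)]] <- bf$two_log_k
    }
  }
  .e2e_env$sign <- res
  res
}
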