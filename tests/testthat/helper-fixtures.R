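# Shared fixtures: small cohorts and cheap MCMC settings so the default
# suite stays fast; the acceptance tests use the full study conditions.

tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_asian = 20, n_african = 24, seed = seed, ...)
}

tiny_panels <- function(seed = 1, ...) {
  suppressWarnings(average_panels(generate_scans(tiny_config(seed, ...))))
}

default_panels <- function(seed = 1, ...) {
  suppressWarnings(average_panels(generate_scans(synthetic_config(seed = seed, ...))))
}

quick_mcmc <- list(chains = 2, burnin = 500, iter = 1500)

quick_fit <- function(dv, labels, link = "logit", seed = 1) {
  fit_binary_regression(dv, labels, link,
                        chains = quick_mcmc$chains, burnin = quick_mcmc$burnin,
                        iter = quick_mcmc$iter, seed = seed)
}

# deterministic two-class Gaussian feature fixture
gaussian_fixture <- function(n1 = 10, n2 = 10, p = 4, delta = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = delta / sqrt(p)), n2, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("Asian", "African"), c(n1, n2)))
}
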