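test_that("null-slope data concentrate beta1 near zero and recover prevalence", {
  set.seed(21)
  dv <- rnorm(300)
  y <- rbinom(300, 1, 0.6)          # labels independent of DV
  fit <- quick_fit(dv, y, seed = 2)
  ci <- quantile(fit$draws[, "beta1"], c(0.025, 0.975))
  expect_gt(ci[2], -0.5); expect_lt(ci[1], 0.5)
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_equal(plogis(fit$posterior_mean[["beta0"]]), mean(y), tolerance = 0.1)
})

test_that("posterior mean approaches the Newton-Raphson MLE at moderate n", {
  set.seed(31)
  dv <- rnorm(1500)
  y <- rbinom(1500, 1, plogis(-1 + 2 * dv))
  fit <- fit_binary_regression(dv, y, "logit", chains = 3,
                               burnin = 1000, iter = 4000, seed = 5)
  mle <- coef(glm(y ~ dv, family = binomial()))
  ess <- coda::effectiveSize(coda::mcmc(fit$draws))
  mcse <- apply(fit$draws, 2, sd) / sqrt(ess)
  expect_lt(abs(fit$posterior_mean[["beta0"]] - mle[[1]]),
            4 * mcse[["beta0"]] + 0.02)
  expect_lt(abs(fit$posterior_mean[["beta1"]] - mle[[2]]),
            4 * mcse[["beta1"]] + 0.02)
})

test_that("all three links run, satisfy DIC identities, and stay reproducible", {
  set.seed(41)
  dv <- rnorm(250)
  y <- rbinom(250, 1, plogis(0.5 + 1.5 * dv))
  for (link in c("logit", "probit", "cloglog")) {
    fit <- quick_fit(dv, y, link, seed = 7)
    expect_equal(fit$dic, fit$dbar + fit$pd, tolerance = 1e-9)
    expect_gt(fit$pd, 0)
    expect_true(all(fit$rhat >= 0.98, na.rm = TRUE))
    expect_equal(nrow(fit$draws), quick_mcmc$chains * quick_mcmc$iter)
    again <- quick_fit(dv, y, link, seed = 7)
    expect_identical(fit$draws, again$draws)
  }
})

test_that("DIC drops when the true predictor is added over an intercept-only fit", {
  set.seed(51)
  dv <- rnorm(300)
  y <- rbinom(300, 1, plogis(-0.5 + 2 * dv))
  with_dv <- quick_fit(dv, y, seed = 3)
  without <- quick_fit(rep(0, 300), y, seed = 3)   # no usable predictor
  expect_lt(with_dv$dic, without$dic)
})

test_that("diagnostics detect convergence and divergence", {
  set.seed(61)
  good <- lapply(1:3, function(i)
    cbind(beta0 = rnorm(2000), beta1 = rnorm(2000)))
  d <- mcmc_diagnostics(good)
  expect_true(all(d$rhat < 1.05))
  expect_equal(dim(d$geweke_z), c(3, 2))

  bad <- good
  bad[[2]] <- bad[[2]] + 50
  d2 <- mcmc_diagnostics(bad)
  expect_gt(max(d2$rhat), 1.1)

  d3 <- mcmc_diagnostics(good[[1]])
  expect_true(all(is.na(d3$rhat)))   # single chain: rhat unavailable
})

test_that("white-noise chains rarely trip the Geweke diagnostic", {
  zs <- vapply(1:20, function(s) {
    set.seed(s + 100)
    mcmc_diagnostics(cbind(beta0 = rnorm(1500),
                           beta1 = rnorm(1500)))$geweke_z[1, ]
  }, numeric(2))
  expect_gte(mean(abs(zs) < 1.96), 0.9)
})

test_that("posterior probabilities are proper, monotone, and anchored at 0.5", {
  set.seed(71)
  dv <- rnorm(300)
  y <- rbinom(300, 1, plogis(-1 + 2 * dv))
  fit <- quick_fit(dv, y, seed = 9)
  grid <- seq(-4, 4, length.out = 41)
  p <- posterior_probability(fit, grid)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= -1e-9))  # beta1 mass positive -> non-decreasing
  b <- fit$posterior_mean
  p_mid <- posterior_probability(fit, -b[["beta0"]] / b[["beta1"]])
  expect_equal(p_mid, 0.5, tolerance = 0.03)
  expect_gt(posterior_probability(fit, 50), 0.999)
})

test_that("link selection returns the smallest converged DIC", {
  set.seed(81)
  dv <- rnorm(400)
  y <- rbinom(400, 1, plogis(-0.5 + 1.5 * dv))
  sel <- select_link(dv, y, chains = quick_mcmc$chains,
                     burnin = quick_mcmc$burnin, iter = quick_mcmc$iter,
                     seed = 11)
  cand <- sel$candidates
  expect_equal(sel$dic, min(cand$dic[cand$converged]))
  # ties at the minimum resolve toward the logit (listed first)
  winners <- cand$link[cand$converged &
                         cand$dic <= min(cand$dic[cand$converged]) + 1e-9]
  expect_equal(cand$link[cand$selected], winners[1])
})

test_that("complete separation is regularised by the prior rather than fatal", {
  dv <- c(rnorm(30, -3, 0.3), rnorm(30, 3, 0.3))
  y <- rep(0:1, each = 30)
  fit <- quick_fit(dv, y, seed = 13)
  expect_true(is.finite(fit$dic))
  expect_true(all(is.finite(fit$posterior_mean)))
})

test_that("label encoding accepts words and 0/1 but rejects junk", {
  set.seed(91)
  dv <- rnorm(60)
  labs <- rep(c("Asian", "African"), 30)
  f1 <- quick_fit(dv, labs, seed = 1)
  f2 <- quick_fit(dv, as.integer(labs == "African"), seed = 1)
  expect_identical(f1$draws, f2$draws)
  expect_error(quick_fit(dv, rep(c("x", "y"), 30)), "labels")
  expect_error(quick_fit(c(dv[-1], NA), labs), "finite")
})
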