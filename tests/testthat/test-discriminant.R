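test_that("perfectly separated one-dimensional classes are trivially solved", {
  set.seed(1)
  X <- cbind(f1 = c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)))
  y <- rep(c("Asian", "African"), each = 10)
  m <- fit_stepwise_lda(X, y)
  expect_equal(length(m$selected_features), 1)
  expect_equal(m$loo_accuracy, 1)
  expect_true(all(diag(m$loo_confusion) == c(10, 10)))
  # sign convention: African centroid positive
  expect_gt(m$group_means_dv[["African"]], m$group_means_dv[["Asian"]])
})

test_that("full LDA direction matches the closed-form Sw^-1 (mu2-mu1) oracle", {
  for (s in 1:6) {
    fx <- gaussian_fixture(n1 = 12, n2 = 12, p = 4, delta = 2.5, seed = s)
    m <- fit_stepwise_lda(fx$X, fx$y, stepwise = FALSE, loo = "none")
    mu1 <- colMeans(fx$X[fx$y == "Asian", ])
    mu2 <- colMeans(fx$X[fx$y == "African", ])
    Sw <- (cov(fx$X[fx$y == "Asian", ]) * 11 +
           cov(fx$X[fx$y == "African", ]) * 11) / 22
    w_oracle <- solve(Sw, mu2 - mu1)
    cosine <- sum(m$coefficients * w_oracle) /
      sqrt(sum(m$coefficients^2) * sum(w_oracle^2))
    expect_gte(cosine, 0.999)
  }
})

test_that("direction agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  fx <- gaussian_fixture(n1 = 15, n2 = 15, p = 5, delta = 2, seed = 3)
  m <- fit_stepwise_lda(fx$X, fx$y, stepwise = FALSE, loo = "none")
  ref <- MASS::lda(fx$X, grouping = factor(fx$y, c("Asian", "African")))
  cosine <- abs(sum(m$coefficients * ref$scaling) /
                  sqrt(sum(m$coefficients^2) * sum(ref$scaling^2)))
  expect_gte(cosine, 0.999)
})

test_that("eigenvalue equals the directly computed between/within SS ratio", {
  fx <- gaussian_fixture(seed = 4)
  m <- fit_stepwise_lda(fx$X, fx$y, stepwise = FALSE, loo = "none")
  dv <- predict(m, fx$X)$dv
  y <- factor(fx$y, c("Asian", "African"))
  mu <- tapply(dv, y, mean)
  ssb <- sum(table(y) * (mu - mean(dv))^2)
  ssw <- sum((dv - mu[y])^2)
  expect_equal(m$eigenvalue, ssb / ssw, tolerance = 1e-10)
  expect_gte(m$eigenvalue, 0)
})

test_that("DV is invariant to affine rescaling of a feature", {
  fx <- gaussian_fixture(seed = 5)
  m1 <- fit_stepwise_lda(fx$X, fx$y, stepwise = FALSE, loo = "none")
  X2 <- fx$X
  X2[, 2] <- X2[, 2] * 100 + 7
  m2 <- fit_stepwise_lda(X2, fx$y, stepwise = FALSE, loo = "none")
  expect_equal(predict(m1, fx$X)$dv, predict(m2, X2)$dv, tolerance = 1e-8)
})

test_that("stepwise threshold limits: 0 admits everything, Inf falls back", {
  fx <- gaussian_fixture(n1 = 20, n2 = 20, p = 3, delta = 3, seed = 6)
  m_all <- fit_stepwise_lda(fx$X, fx$y, f_enter = 0, f_remove = -1, loo = "none")
  expect_equal(length(m_all$selected_features), 3)
  expect_warning(
    m_none <- fit_stepwise_lda(fx$X, fx$y, f_enter = Inf, loo = "none"),
    "no feature")
  expect_equal(length(m_none$selected_features), 1)  # best single fallback
})

test_that("permuted labels drop leave-one-out accuracy to the prior baseline", {
  pan <- default_panels(seed = 2)
  rf <- build_ratios(pan, "Zr")
  set.seed(99)
  shuffled <- sample(rf$species)
  cv <- suppressWarnings(loo_classify(rf$features, shuffled, stepwise = FALSE))
  baseline <- max(table(shuffled)) / length(shuffled)
  expect_lt(cv$accuracy, baseline + 0.12)   # within binomial slack of chance
})

test_that("degenerate folds are skipped with a warning", {
  X <- cbind(f1 = c(0, 0.1, 10, 10.1, 9.9))
  y <- c("Asian", "Asian", "African", "African", "African")
  expect_warning(cv <- loo_classify(X, y), "skipped")
  # the two Asian-removal folds are unevaluable; the three African folds are
  expect_true(is.finite(cv$accuracy))
  expect_equal(sum(cv$confusion), 3)
})

test_that("denominator comparison reproduces the expected trade-off table", {
  pan <- default_panels(seed = 1)
  cmp <- compare_denominators(pan, c("none", "Zr", "P"), loo = "fixed")
  expect_equal(cmp$denominator, c("none", "Zr", "P"))
  expect_equal(cmp$valid_pct[cmp$denominator == "none"], 100)
  expect_equal(cmp$valid_pct[cmp$denominator == "P"], 100)
  zr <- cmp[cmp$denominator == "Zr", ]
  expect_gte(zr$valid_pct, 92)
  expect_lte(zr$valid_pct, 100)
  expect_gte(zr$loo_pct, 85)
  # a failed denominator is isolated, not fatal
  pan$Ag <- 0
  cmp2 <- compare_denominators(pan, c("Ag", "Zr"), loo = "fixed")
  expect_true(nzchar(cmp2$note[cmp2$denominator == "Ag"]))
  expect_true(is.finite(cmp2$loo_pct[cmp2$denominator == "Zr"]))
})
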