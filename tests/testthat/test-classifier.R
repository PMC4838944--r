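test_that("kappa: perfect, chance-level, and degenerate tables", {
  expect_equal(kappa_statistic(c(50, 0, 0, 50)), 1)
  # counts proportional to marginal products give exactly zero
  expect_equal(kappa_statistic(c(40, 60, 40, 60)), 0, tolerance = 1e-12)
  expect_equal(kappa_statistic(c(100, 0, 0, 0)), 1)  # p_e = 1, p_o = 1
  expect_error(kappa_statistic(c(0, 0, 0, 0)), "empty")
  expect_error(kappa_statistic(c(-1, 2, 3, 4)), "non-negative")
  # bounded in [-1, 1] over random tables
  set.seed(5)
  for (i in 1:50) {
    k <- kappa_statistic(rmultinom(1, 200, runif(4))[, 1])
    expect_gte(k, -1); expect_lte(k, 1)
  }
})

test_that("metrics: perfect table and undefined PPV handling", {
  m <- classification_metrics(c(50, 0, 0, 50))
  expect_equal(m$accuracy, 100)
  expect_equal(m$precision, 100)
  expect_warning(m2 <- classification_metrics(c(0, 10, 0, 30)),
                 "no predicted members")
  expect_equal(m2$precision, unname(m2$ppv["African"]))
})

test_that("metrics and kappa depend only on the confusion table", {
  set.seed(6)
  truth <- sample(c("Asian", "African"), 80, replace = TRUE)
  pred <- sample(c("Asian", "African"), 80, replace = TRUE)
  o <- sample(80)
  expect_equal(confusion_table(truth, pred), confusion_table(truth[o], pred[o]))
})

test_that("cut-off selection: separation plateau takes the smallest cut-off", {
  prob <- c(runif(30, 0.01, 0.2), runif(40, 0.8, 0.99))
  labels <- rep(c("Asian", "African"), c(30, 40))
  res <- select_cutoff(prob, labels)
  expect_equal(res$kappa, 1)
  # any cut-off in (max Asian, min African] is perfect; smallest grid point wins
  expect_equal(res$cutoff, min(res$curve$cutoff[res$curve$kappa == 1]))
  expect_lte(res$cutoff, max(prob[labels == "Asian"]) + 0.011)
})

test_that("cut-off selection under shuffled labels warns and stays near zero kappa", {
  set.seed(7)
  prob <- runif(150)
  labels <- sample(rep(c("Asian", "African"), c(70, 80)))
  expect_warning(res <- select_cutoff(prob, labels), "kappa")
  expect_lt(max(res$curve$kappa), 0.3)
  expect_false(res$qualified)
})

test_that("cut-off selection rejects degenerate probability vectors", {
  expect_error(select_cutoff(rep(0.5, 20), rep(c("Asian", "African"), 10)),
               "degenerate")
})

test_that("raising the cut-off never increases the count called African", {
  set.seed(8)
  prob <- runif(100)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(c) sum(prob >= c), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("boundary convention: probability exactly at the cut-off is African", {
  disc <- structure(list(selected_features = "Si/Zr",
                         coefficients = c(`Si/Zr` = 1), constant = 0,
                         eigenvalue = 1, group_means_dv = c(Asian = -1, African = 1),
                         threshold_dv = 0, n_valid = 10),
                    class = "discriminant_model")
  set.seed(9)
  dv <- c(rnorm(30, -1), rnorm(30, 1))
  fit <- quick_fit(dv, rep(c(0, 1), each = 30), seed = 2)
  cutres <- list(cutoff = 0.55, kappa = 0.9, accuracy = 95, precision = 95,
                 qualified = TRUE, curve = NULL)
  bundle <- build_classifier(disc, fit, cutres, "Zr")
  b <- fit$posterior_mean
  # invert the posterior-mean probability to land exactly on the cut-off
  dv_star <- (qlogis(0.55) - b[["beta0"]]) / b[["beta1"]]
  p_star <- posterior_probability(fit, dv_star)
  lab <- if (p_star >= bundle$cutoff) "African" else "Asian"
  expect_identical(ifelse(p_star >= 0.55, "African", "Asian"), lab)
})

test_that("end-to-end pipeline is reproducible and validates well", {
  tr <- generate_scans(synthetic_config(seed = 1))
  te <- generate_scans(synthetic_config(n_asian = 15, n_african = 20, seed = 77))
  run1 <- suppressWarnings(run_pipeline(tr, te, link = "logit",
                                        chains = 2, burnin = 400, iter = 1200,
                                        seed = 3))
  run2 <- suppressWarnings(run_pipeline(tr, te, link = "logit",
                                        chains = 2, burnin = 400, iter = 1200,
                                        seed = 3))
  expect_identical(run1$dependent$metrics, run2$dependent$metrics)
  expect_identical(run1$bundle$cutoff, run2$bundle$cutoff)
  expect_gte(run1$bundle$discriminant$loo_accuracy, 0.85)
  expect_gte(run1$independent$metrics$accuracy, 80)
  expect_s3_class(run1$dependent$probabilities, "data.frame")
  expect_equal(sum(run1$dependent$confusion), run1$bundle$discriminant$n_valid)
})

test_that("unlabeled test cohorts yield predictions but no metrics", {
  tr <- generate_scans(tiny_config(seed = 4))
  te <- generate_scans(synthetic_config(n_asian = 5, n_african = 5, seed = 88))
  te$species <- "unknown"
  run <- suppressWarnings(run_pipeline(tr, te, link = "logit",
                                       chains = 2, burnin = 300, iter = 900,
                                       seed = 2))
  expect_true(is.character(run$independent$metrics))
  expect_true(all(run$independent$predictions$label %in%
                    c("Asian", "African", "unclassifiable")))
})

test_that("specimens without a detected denominator are unclassifiable", {
  tr <- generate_scans(tiny_config(seed = 5))
  run <- suppressWarnings(run_pipeline(tr, link = "logit",
                                       chains = 2, burnin = 300, iter = 900,
                                       seed = 2))
  te_pan <- tiny_panels(seed = 91)
  te_pan$Zr[1] <- 0
  pred <- predict_tusks(run$bundle, te_pan)
  expect_equal(pred$label[1], "unclassifiable")
  expect_match(pred$reason[1], "Zr")
  expect_true(all(pred$label[te_pan$Zr > 0] != "unclassifiable"))
  # missing element columns are a named error
  te_bad <- te_pan[, setdiff(names(te_pan), "Si")]
  expect_error(predict_tusks(run$bundle, te_bad), "Si")
})

test_that("pipeline failures carry the stage name", {
  bad <- data.frame(specimen_id = "a", species = "Asian", Ca = 1)
  expect_error(suppressWarnings(run_pipeline(bad)), "stage")
})
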