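test_that("two-group ANOVA F equals squared t (oracle cross-check)", {
  set.seed(42)
  tab <- data.frame(specimen_id = sprintf("t%02d", 1:20),
                    species = "Asian", sex = "unknown",
                    site_long = rep(c("E0", "E1"), each = 10),
                    site_trans = "dorsal", layer = "enamel",
                    X = rnorm(20, 100, 5), stringsAsFactors = FALSE)
  res <- site_homogeneity(tab, "longitudinal")
  tt <- t.test(X ~ site_long, data = tab, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical values at all sites give F = 0, p = 1", {
  tab <- data.frame(specimen_id = sprintf("t%02d", 1:16),
                    species = "Asian", sex = "unknown",
                    site_long = rep(c("E0", "E1", "E2", "E3"), 4),
                    site_trans = "dorsal", layer = "enamel",
                    X = 5, stringsAsFactors = FALSE)
  res <- site_homogeneity(tab, "longitudinal")
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("an injected tip-only sulfur shift is detected longitudinally", {
  cfg <- synthetic_config(n_asian = 30, n_african = 15, site_effect_sd = 0,
                          seed = 13)
  sc <- generate_scans(cfg)
  sc$S[sc$site_long == "E0"] <- sc$S[sc$site_long == "E0"] * exp(1)
  res <- site_homogeneity(sc, "longitudinal")
  expect_lt(res$p_value[res$element == "S"], 0.05)
})

test_that("species contrast recovers the designed null and signal structure", {
  hits <- 0; nulls_ok <- 0
  for (s in 2:4) {
    pan <- default_panels(seed = s)
    sp <- group_contrast(pan, "species")
    sig <- sp$element[!is.na(sp$p_value) & sp$p_value < 0.05]
    if (length(setdiff(sig, c("Cl", "Cu", "Pb"))) >= 18) hits <- hits + 1
    nulls_ok <- nulls_ok + sum(!c("Cl", "Cu", "Pb") %in% sig)
  }
  expect_gte(hits, 2)            # >= 18 informative elements in most cohorts
  expect_gte(nulls_ok, 7)        # the three null elements rarely fire
})

test_that("identical groups produce only type-I-level significance", {
  pan <- tiny_panels(seed = 3, effect_scale = 0)
  sp <- group_contrast(pan, "species")
  expect_lt(mean(sp$p_value < 0.05, na.rm = TRUE), 0.25)
})

test_that("Ca/P ratio is higher in African panels", {
  for (s in 1:3) {
    cp <- ca_p_ratio(default_panels(seed = s))
    expect_gt(cp$by_species[["African"]], cp$by_species[["Asian"]])
  }
})

test_that("correlation matrix is symmetric, unit-diagonal, PSD", {
  pan <- default_panels(seed = 5)
  R <- correlation_matrix(pan)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, ncol(R)))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # uncorrelated trace pair stays near zero at n ~ 160
  expect_lt(abs(R["Ti", "Cd"]), 0.25)
  # zero-variance element flagged as NA
  pan$Ca <- 1
  expect_warning(R2 <- correlation_matrix(pan), "zero-variance")
  expect_true(all(is.na(R2["Ca", setdiff(colnames(R2), "Ca")])))
})

test_that("screening does not mutate its input panels", {
  sc <- generate_scans(tiny_config(seed = 6))
  before <- sc
  invisible(screen_elements(sc))
  expect_identical(sc, before)
})

test_that("hierarchical clustering recovers well-separated species", {
  prof <- default_species_profile()
  half <- (prof$african_log_mean - prof$asian_log_mean) * 1.5
  prof$african_log_mean <- prof$asian_log_mean + half
  cfg <- synthetic_config(n_asian = 25, n_african = 25, profile = prof,
                          axis_sd_asian = 0.05, axis_sd_african = 0.05,
                          seed = 8)
  pan <- suppressWarnings(average_panels(generate_scans(cfg)))
  cl <- hierarchical_clusters(pan, k = 2)
  truth <- pan$species
  # Rand index against the true species partition
  n <- length(truth)
  pairs <- combn(n, 2)
  same_cl <- cl$cluster[pairs[1, ]] == cl$cluster[pairs[2, ]]
  same_sp <- truth[pairs[1, ]] == truth[pairs[2, ]]
  rand <- mean(same_cl == same_sp)
  expect_gte(rand, 0.9)
})

test_that("clustering limit cases: singletons and duplicated specimens", {
  pan <- tiny_panels(seed = 9)
  cl <- hierarchical_clusters(pan, k = nrow(pan))
  expect_equal(length(unique(cl$cluster)), nrow(pan))
  dup <- rbind(pan, pan[1, ])
  dup$specimen_id[nrow(dup)] <- "copy"
  cl2 <- hierarchical_clusters(dup, k = 4)
  expect_equal(cl2$cluster[1], cl2$cluster[nrow(dup)])
  expect_error(hierarchical_clusters(pan, k = 0), "at least 1")
})

test_that("screen report is complete and internally consistent", {
  sc <- generate_scans(tiny_config(seed = 10))
  scr <- screen_elements(sc)
  expect_s3_class(scr, "element_screen")
  expect_equal(nrow(scr), 24)
  expect_true(all(scr$cv_asian > 0 & scr$cv_african > 0, na.rm = TRUE))
  ok <- !is.na(scr$ttest_p_species)
  expect_true(all(scr$ttest_p_species[ok] >= 0 & scr$ttest_p_species[ok] <= 1))
  # enamel-only synthetic scans cannot support a layer contrast
  expect_true(all(is.na(scr$ttest_p_layer)))
})
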