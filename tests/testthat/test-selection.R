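test_that("posterior model weights are visit frequencies of indicator subsets", {
  # fabricate a 10-iteration indicator history: subset {a} six times,
  # subset {a, b} four times
  X <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"),
                                              c("a", "b")))
  design <- toy_design(X)
  counts <- data.frame(tow_id = sprintf("t%d", 1:3),
                       island_id = c("A", "B", "C"), area_ha = 2,
                       y = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  dat <- build_model_data(counts, design)
  dr <- data.frame(alpha = rep(1, 10),
                   beta.a = 0.5, beta.b = 0.2,
                   w.a = rep(1, 10), w.b = c(rep(0, 6), rep(1, 4)),
                   mu.A = 1, mu.B = 1, mu.C = 1,
                   sigma2 = 1, k = 1)
  fit <- fake_fit(dr, c("a", "b"), design, dat)

  pw <- posterior_model_weights(fit)
  expect_equal(sum(pw$weights$weight), 1, tolerance = 1e-9)
  wa <- pw$weights$weight[pw$weights$model == "a"]
  wab <- pw$weights$weight[pw$weights$model == "a + b"]
  expect_equal(wa, 0.6)
  expect_equal(wab, 0.4)
  expect_true(pw$weights$best[pw$weights$model == "a"])
  expect_equal(best_subset(pw), "a")

  # partition identity: inclusion probability of a covariate equals the
  # summed weight of subsets containing it
  in_b <- vapply(pw$weights$model, function(l)
    "b" %in% strsplit(l, " \\+ ")[[1]], logical(1))
  expect_equal(unname(pw$inclusion["b"]),
               sum(pw$weights$weight[in_b]), tolerance = 1e-12)

  # identical indicators in every draw -> single subset, weight 1
  dr1 <- dr; dr1$w.b <- 1
  pw1 <- posterior_model_weights(fake_fit(dr1, c("a", "b"), design, dat))
  expect_equal(pw1$weights$weight, 1)

  # tie-break: equal-weight subsets resolved to fewer covariates
  dr2 <- dr; dr2$w.b <- c(rep(0, 5), rep(1, 5))
  pw2 <- posterior_model_weights(fake_fit(dr2, c("a", "b"), design, dat))
  expect_equal(pw2$weights$model[pw2$weights$best], "a")

  # weights require a selection fit
  fitns <- fake_fit(dr, c("a", "b"), design, dat, selection = FALSE)
  expect_error(posterior_model_weights(fitns), "selection")
})

test_that("the Bayesian p-value is seed-deterministic, order-invariant and detects gross misfit", {
  d <- demo_fit()
  fit <- d$fit
  fc1 <- bayesian_p_value(fit, seed = 42)
  fc2 <- bayesian_p_value(fit, seed = 42)
  expect_identical(fc1$bayesian_p, fc2$bayesian_p)
  expect_equal(fc1$bayesian_p,
               mean(fc1$discrepancy_simulated > fc1$discrepancy_observed))

  # reordering tows leaves the p-value unchanged
  dat <- fit$data
  perm <- rev(seq_along(dat$y))
  dat_perm <- dat
  dat_perm$y <- dat$y[perm]; dat_perm$area <- dat$area[perm]
  dat_perm$island <- dat$island[perm]
  fc3 <- bayesian_p_value(fit, data = dat_perm, seed = 42)
  expect_equal(fc3$bayesian_p, fc1$bayesian_p, tolerance = 0.02)

  # inflating the observed counts tenfold forces the p-value to 0
  dat10 <- dat
  dat10$y <- as.integer(dat$y * 10L)
  fc10 <- bayesian_p_value(fit, data = dat10, seed = 42)
  expect_lt(fc10$bayesian_p, 0.01)
})

test_that("human-metric comparison reports one ranked row per metric", {
  d <- demo_fit()
  # small fits: 2 metrics suffice to exercise the ranking contract
  cmp <- cached("human-metric-cmp", {
    compare_human_metrics(d$counts, d$sim$design,
                          metrics = c("humans_200km",
                                      "humans_per_km2_reef"),
                          n_iter = 2500, n_burn = 800, seed = 21)
  })
  expect_equal(nrow(cmp), 2)
  expect_setequal(cmp$rank, 1:2)
  expect_true(all(cmp$inclusion_probability >= 0 &
                    cmp$inclusion_probability <= 1))
  expect_true(all(cmp$bayesian_p >= 0 & cmp$bayesian_p <= 1))
  # data were generated with a true humans_200km effect
  expect_gt(cmp$inclusion_probability[cmp$metric == "humans_200km"], 0.8)
})

test_that("refitting the selected subset yields a coefficient table with intercept plus members", {
  d <- demo_fit()
  ref <- cached("refit-best", {
    refit_best(d$fit$data, c("humans_200km", "productivity"),
               n_iter = 2500, n_burn = 800, seed = 13)
  })
  expect_equal(ref$coefficients$parameter,
               c("alpha", "beta.humans_200km", "beta.productivity"))
  expect_true(all(ref$coefficients$lo <= ref$coefficients$hi))
  expect_false(isTRUE(ref$spec$selection))

  # empty subset: legal intercept-only fit whose alpha CI brackets the
  # island mean density scale
  ref0 <- cached("refit-null", {
    refit_best(d$fit$data, character(0), n_iter = 2500, n_burn = 800,
               seed = 14)
  })
  expect_equal(ref0$coefficients$parameter, "alpha")
  mu_cols <- paste0("mu.", ref0$data$islands)
  mean_mu <- mean(posterior_draws(ref0, mu_cols))
  expect_gt(ref0$coefficients$hi, ref0$coefficients$lo)
  expect_true(ref0$coefficients$lo < mean_mu &
                mean_mu < ref0$coefficients$hi * 2)
})
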