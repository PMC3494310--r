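# A small fabricated posterior with known draws makes the baseline and
# effect-curve arithmetic checkable in closed form.
fixed_draw_fit <- function(link = "identity") {
  X <- matrix(c(1.0, -0.5, 0.4, -1.2), 2, 2,
              dimnames = list(c("A", "B"),
                              c("humans_200km", "productivity")))
  # meta mirrors the real pipeline: humans log(x+1)-transformed
  design <- structure(list(
    island_ids = c("A", "B"), columns = colnames(X), X = X,
    transform_meta = list(
      humans_200km = list(log = TRUE, offset = 1, mean = 4, sd = 2),
      productivity = list(log = FALSE, offset = 0, mean = 250, sd = 50))),
    class = "design_matrix")
  counts <- data.frame(tow_id = c("t1", "t2", "t3", "t4"),
                       island_id = c("A", "A", "B", "B"),
                       area_ha = c(2, 2, 2, 2),
                       y = c(3L, 1L, 4L, 2L), stringsAsFactors = FALSE)
  dat <- build_model_data(counts, design)
  dr <- data.frame(alpha = c(2.0, 2.2),
                   beta.humans_200km = c(-0.8, -0.6),
                   beta.productivity = c(0.5, 0.4),
                   w.humans_200km = 1, w.productivity = 1,
                   mu.A = c(1.0, 1.1), mu.B = c(2.0, 2.1),
                   sigma2 = c(0.5, 0.6), k = c(1.5, 1.6))
  fake_fit(dr, colnames(X), design, dat, link = link)
}

test_that("single-draw baseline matches the truncated-normal mean in closed form", {
  fit <- fixed_draw_fit()
  dr1 <- posterior_draws(fit)[1, ]
  z0 <- (log(0 + 1) - 4) / 2                   # raw humans 0, standardized
  E0 <- dr1["alpha"] + dr1["beta.humans_200km"] * z0 +
    dr1["beta.productivity"] * 0.4
  v <- dr1["sigma2"] / 2                        # island A has 2 tows
  s <- sqrt(v)
  closed <- E0 + s * dnorm(E0 / s) / pnorm(E0 / s)
  d <- predicted_density_draws(fit, "A",
                               override = c(humans_200km = z0))
  expect_equal(unname(d[1]), unname(closed), tolerance = 1e-10)

  b <- baseline_density(fit, "A")
  expect_true(b$baseline_lo <= b$baseline_median &
                b$baseline_median <= b$baseline_hi)
  expect_error(baseline_density(fit, "ATLANTIS"), "island")
})

test_that("a zero human effect makes the baseline equal the fitted density", {
  fit <- fixed_draw_fit()
  for (ch in seq_along(fit$draws)) fit$draws[[ch]][, "beta.humans_200km"] <- 0
  for (isl in c("A", "B")) {
    fitted <- predicted_density_draws(fit, isl)
    basel <- predicted_density_draws(
      fit, isl, override = zero_human_override(fit, "humans_200km"))
    expect_equal(basel, fitted, tolerance = 1e-12)
  }
})

test_that("for an island with zero raw humans the counterfactual is the factual", {
  fit <- fixed_draw_fit()
  # give island B a raw human population of exactly 0
  z0 <- standardize_raw(fit$data$design, "humans_200km", 0)
  fit$data$X["B", "humans_200km"] <- z0
  fit$data$design$X["B", "humans_200km"] <- z0
  fitted <- predicted_density_draws(fit, "B")
  basel <- predicted_density_draws(
    fit, "B", override = zero_human_override(fit, "humans_200km"))
  expect_equal(basel, fitted, tolerance = 1e-12)
})

test_that("observed density is the ratio of totals with among-tow SE", {
  counts <- data.frame(tow_id = c("t1", "t2"), island_id = "A",
                       area_ha = c(2, 2), y = c(3L, 1L),
                       stringsAsFactors = FALSE)
  o <- observed_density(counts)
  expect_equal(o$density, 1.0)
  expect_equal(o$se, sd(c(1.5, 0.5)) / sqrt(2))

  # all-zero counts: 0/ha with zero SE
  z <- counts; z$y <- 0L
  oz <- observed_density(z)
  expect_equal(oz$density, 0)
  expect_equal(oz$se, 0)

  # pooling invariance: splitting a tow into two half-area tows with
  # split counts leaves the ratio-of-totals unchanged
  split <- data.frame(tow_id = c("t1a", "t1b", "t2"), island_id = "A",
                      area_ha = c(1, 1, 2), y = c(2L, 1L, 1L),
                      stringsAsFactors = FALSE)
  expect_equal(observed_density(split)$density, o$density)

  expect_error(observed_density(counts[0, ]), "no tows")
})

test_that("depletion ratios reproduce the observed/baseline interval arithmetic", {
  b <- list(baseline_lo = 1.2, baseline_median = 1.8, baseline_hi = 2.4)
  dep <- depletion_ratio(0.1, b)
  expect_equal(unname(dep["lo_pct"]), 100 * 0.1 / 2.4, tolerance = 1e-12)
  expect_equal(unname(dep["hi_pct"]), 100 * 0.1 / 1.2, tolerance = 1e-12)
  expect_equal(round(unname(dep["lo_pct"]), 1), 4.2)
  expect_equal(round(unname(dep["hi_pct"]), 1), 8.3)
  # output is sorted ascending regardless of input bound order
  expect_true(all(diff(dep) >= 0))
  expect_equal(unname(depletion_ratio(1.8, b)["median_pct"]), 100)
})

test_that("effect curves are flat without an effect and power-law under the log link", {
  fit <- fixed_draw_fit()
  for (ch in seq_along(fit$draws)) fit$draws[[ch]][, "beta.humans_200km"] <- 0
  ec <- effect_curve(fit, "humans_200km", grid = c(0, 10, 100, 1000))
  expect_true(all(abs(diff(ec$density_median)) < 1e-10))
  expect_true(all(ec$density_lo <= ec$density_median &
                    ec$density_median <= ec$density_hi))
  expect_true(all(diff(ec$x_raw) > 0))

  # log link + log-transformed covariate: exp(alpha + beta log x) = C x^beta
  fitl <- fixed_draw_fit(link = "log")
  # single draw, no hyperdispersion so the curve is the pure power law
  fitl$draws[[1]] <- fitl$draws[[1]][1, , drop = FALSE]
  fitl$draws[[1]][, "sigma2"] <- 1e-12
  fitl$draws[[1]][, "beta.productivity"] <- 0
  beta <- fitl$draws[[1]][, "beta.humans_200km"]
  grid <- c(10, 100, 1000)
  ecl <- effect_curve(fitl, "humans_200km", grid = grid,
                      conditioning = c(productivity = 0))
  # on the raw scale shifted by the +1 offset, density ~ C * (x+1)^(beta/sd)
  ratio <- ecl$density_median[2] / ecl$density_median[1]
  expect_equal(ratio, unname(((grid[2] + 1) / (grid[1] + 1))^(beta / 2)),
               tolerance = 1e-6)
})

test_that("doubling increments follow ln2 * sd / beta under the log link", {
  fitl <- fixed_draw_fit(link = "log")
  for (ch in seq_along(fitl$draws))
    fitl$draws[[ch]][, "beta.productivity"] <- log(2)
  # sd of raw productivity is 50 -> doubling every 50 raw units
  inc <- doubling_increment(fitl, "productivity")
  expect_equal(inc, 50, tolerance = 1e-12)

  # numeric check: expected density doubles between x and x + inc
  fitl$draws[[1]] <- fitl$draws[[1]][1, , drop = FALSE]
  fitl$draws[[1]][, "sigma2"] <- 1e-12
  fitl$draws[[1]][, "beta.humans_200km"] <- 0
  ec <- effect_curve(fitl, "productivity", grid = c(250, 250 + inc),
                     conditioning = c(humans_200km = 0))
  expect_equal(ec$density_median[2] / ec$density_median[1], 2,
               tolerance = 1e-9)

  # scaling: doubling the covariate spread doubles the increment
  fit2 <- fitl
  fit2$data$design$transform_meta$productivity$sd <- 100
  expect_equal(doubling_increment(fit2, "productivity"), 100,
               tolerance = 1e-12)

  # non-positive effect: no doubling, reported as NA sentinel
  fitn <- fixed_draw_fit(link = "log")
  for (ch in seq_along(fitn$draws))
    fitn$draws[[ch]][, "beta.productivity"] <- -0.3
  expect_true(is.na(doubling_increment(fitn, "productivity")))
})
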