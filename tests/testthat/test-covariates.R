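make_islands <- function(n = 8, seed = 42) {
  set.seed(seed)
  validate_island_table(data.frame(
    island_id = sprintf("I%02d", 1:n),
    region = "PRIA",
    humans_200km = c(0, round(exp(runif(n - 1, 0, 12)))),
    humans_per_km2_reef = c(0, runif(n - 1, 0.1, 500)),
    dist_pop_center_km = runif(n, 5, 1500),
    productivity = runif(n, 120, 450),
    min_sst = runif(n, 19, 28),
    reef_area_km2 = exp(runif(n, 1, 7)),
    stringsAsFactors = FALSE))
}

test_that("design matrix is standardized and the transform inverts exactly", {
  isl <- make_islands()
  d <- transform_covariates(isl)
  expect_true(all(abs(colMeans(d$X)) < 1e-8))
  expect_true(all(abs(apply(d$X, 2, sd) - 1) < 1e-8))

  # zero humans map through log(0 + 1) = 0 before standardization
  m <- d$transform_meta$humans_200km
  expect_equal(d$X[1, "humans_200km"] * m$sd + m$mean, 0)
  expect_equal(standardize_raw(d, "humans_200km", 0),
               d$X[1, "humans_200km"])

  # round trip raw -> standardized -> raw at 1e-10 relative
  for (cc in d$columns) {
    raw <- isl[[cc]]
    back <- unstandardize(d, cc, d$X[, cc])
    expect_equal(unname(back), raw, tolerance = 1e-10)
  }
})

test_that("degenerate covariates are rejected with informative errors", {
  isl <- make_islands()
  isl$productivity <- 200   # constant -> zero sd
  expect_error(transform_covariates(isl), "constant")

  isl2 <- make_islands()
  spec <- default_transform_spec()
  spec$humans_200km$offset <- 0   # log(0) with a zero-human island
  expect_error(transform_covariates(isl2, spec), "humans_200km")
})

test_that("correlation screen matches the direct Pearson formula and flags |r| above threshold", {
  # 5-island toy with hand-computable correlation
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -1, 0, -1, 1)     # exactly orthogonal to x
  z <- 2 * x                  # perfectly correlated with x
  X <- cbind(a = x / sd(x), b = (y - mean(y)) / sd(y), c = z / sd(z))
  rownames(X) <- paste0("I", 1:5)
  rep <- correlation_screen(toy_design(X), threshold = 0.7)

  direct_r <- function(u, v)
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(rep$pairwise_r["a", "b"], direct_r(x, y), tolerance = 1e-12)
  expect_equal(rep$pairwise_r["a", "c"], 1, tolerance = 1e-12)
  expect_equal(diag(rep$pairwise_r), c(a = 1, b = 1, c = 1))
  expect_equal(nrow(rep$flagged_pairs), 1)
  expect_setequal(unlist(rep$flagged_pairs[1, c("var1", "var2")]),
                  c("a", "c"))
})

test_that("VIF matches 1/(1-r^2) on two columns and the inverse-correlation diagonal in general", {
  set.seed(7)
  n <- 40
  z1 <- rnorm(n); z2 <- rnorm(n)
  r <- 0.5
  a <- scale(z1)[, 1]
  b <- scale(r * scale(z1)[, 1] + sqrt(1 - r^2) * scale(z2)[, 1])[, 1]
  X <- cbind(a = a, b = b)
  rownames(X) <- paste0("I", 1:n)
  d <- toy_design(X)
  v <- vif(d)
  r_ab <- cor(a, b)
  expect_equal(unname(v["a"]), 1 / (1 - r_ab^2), tolerance = 1e-8)
  expect_equal(unname(v["b"]), 1 / (1 - r_ab^2), tolerance = 1e-8)

  # general identity: VIF_j = diag of inverse correlation matrix
  z3 <- scale(rnorm(n) + 0.4 * z1)[, 1]
  X3 <- cbind(X, c = z3)
  rownames(X3) <- paste0("I", 1:n)
  v3 <- vif(toy_design(X3))
  expect_equal(unname(v3), unname(diag(solve(cor(X3)))), tolerance = 1e-8)

  # orthogonalized columns -> all VIF 1
  Xo <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))[, 2:3]
  Xo <- scale(Xo); colnames(Xo) <- c("u", "v")
  rownames(Xo) <- paste0("I", 1:n)
  expect_equal(unname(vif(toy_design(Xo))), c(1, 1), tolerance = 1e-8)

  # duplicated column -> infinite VIF, not an error
  Xd <- cbind(a = a, b = a)
  rownames(Xd) <- paste0("I", 1:n)
  expect_true(all(is.infinite(vif(toy_design(Xd)))))
})

test_that("model sets A and B never mix minimum SST with reef area", {
  sets <- build_model_sets()
  labs <- function(ss) vapply(ss, function(s)
    if (length(s) == 0) "null" else paste(sort(s), collapse = "+"),
    character(1))
  expect_true("humans_200km+min_sst+productivity" %in% labs(sets$A))
  expect_true("humans_200km+productivity+reef_area_km2" %in% labs(sets$B))
  # exhaustive: no emitted subset contains both confounded variables
  all_subsets <- c(sets$A, sets$B)
  expect_false(any(vapply(all_subsets, function(s)
    all(c("min_sst", "reef_area_km2") %in% s), logical(1))))
  # each set enumerates all 2^4 subsets of its pool
  expect_length(sets$A, 16)
  expect_length(sets$B, 16)

  # nothing available -> only the null model
  empty <- build_model_sets(available = character(0))
  expect_equal(empty$A, list(character(0)))
  expect_equal(empty$B, list(character(0)))
})
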