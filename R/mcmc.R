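#' Fit the hierarchical shark-density model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler over the blocks
#' (intercept), (each coefficient), (each latent indicator, when
#' selection is on), (each island density), (hypervariance) and
#' (overdispersion). Proposal step sizes adapt toward a 0.44 acceptance
#' rate during burn-in and are frozen afterwards, so retained draws
#' come from a fixed kernel targeting [log_posterior()]. Chains run
#' sequentially from a single seeded RNG stream; the same seed gives
#' bit-identical draws.
#'
#' @param data A `model_data` from [build_model_data()].
#' @param spec A `model_spec`.
#' @param n_iter Total iterations per chain (default 20000; the
#'   production-scale 500000 is a config choice, not a code change).
#' @param n_burn Burn-in iterations discarded per chain (default 4000).
#' @param chains Number of chains, at least 2 (default 2).
#' @param seed Integer RNG seed.
#' @param fix_sigma2,fix_k Optional fixed values for the hypervariance
#'   or overdispersion (used by oracle tests; `NULL` = sampled).
#' @param fix_w Optional fixed 0/1 indicator vector (requires
#'   `spec$selection`); `NULL` = sampled when selection is on.
#' @param init Optional named list overriding initial values
#'   (`alpha`, `beta`, `mu`, `sigma2`, `k`).
#' @return An object of class `shark_fit`: list with `draws` (one
#'   matrix per chain, retained iterations x parameters with columns
#'   `alpha`, `beta.<cov>`, `w.<cov>`, `mu.<island>`, `sigma2`, `k`),
#'   `acceptance`, `spec`, `data`, `n_iter`, `n_burn`, `seed`.
#' @export
run_mcmc <- function(data, spec, n_iter = 20000, n_burn = 4000,
                     chains = 2, seed = 1,
                     fix_sigma2 = NULL, fix_k = NULL, fix_w = NULL,
                     init = NULL) {
  stopifnot(inherits(data, "model_data"), inherits(spec, "model_spec"))
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (chains < 2) stop("at least 2 chains are required")
  covs <- spec$covariates
  p <- length(covs)
  bad <- setdiff(covs, colnames(data$X))
  if (length(bad) > 0) stop("covariate not in model data: ", bad[1])
  X <- data$X[, covs, drop = FALSE]
  nI <- length(data$islands)

  ## tows sorted by island for contiguous per-island access
  ord <- order(data$island)
  y <- data$y[ord]; area <- data$area[ord]; island <- data$island[ord]
  isl_len <- data$n_i
  isl_start <- c(0L, cumsum(isl_len)[-nI])

  ## initial values: observed per-island density, guarded away from 0
  obs_mu <- as.numeric(
    tapply(data$y, data$island, sum) /
      tapply(data$area, data$island, sum))
  obs_mu <- pmax(obs_mu, 0.05)
  init_mu <- if (!is.null(init$mu)) init$mu else obs_mu
  init_alpha <- if (!is.null(init$alpha)) init$alpha else {
    if (spec$link == "log") log(mean(init_mu)) else mean(init_mu)
  }
  init_beta <- if (!is.null(init$beta)) init$beta else rep(0, p)
  init_sigma2 <- if (!is.null(fix_sigma2)) fix_sigma2
                 else if (!is.null(init$sigma2)) init$sigma2 else 1
  init_k <- if (!is.null(fix_k)) fix_k
            else if (!is.null(init$k)) init$k else 1
  if (!is.null(fix_w)) {
    if (!spec$selection) stop("fix_w requires a selection model_spec")
    stopifnot(length(fix_w) == p)
    init_w <- as.integer(fix_w)
  } else {
    init_w <- rep(1L, p)
  }

  set.seed(as.integer(seed))
  par_names <- c("alpha",
                 if (p > 0) paste0("beta.", covs),
                 if (p > 0) paste0("w.", covs),
                 paste0("mu.", data$islands), "sigma2", "k")
  draws <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    ## overdisperse chain starts deterministically from the seeded stream
    jitter <- if (ch == 1) 0 else rnorm(1, 0, 0.5)
    res <- .mcmc_chain_cpp(
      y = y, area = area, island = island, X = X, n_i = isl_len,
      isl_start = isl_start, isl_len = isl_len,
      n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
      priors = unclass(spec$priors), log_link = (spec$link == "log"),
      selection = isTRUE(spec$selection),
      weight_by_n = isTRUE(spec$weight_variance_by_n),
      alpha0 = init_alpha + jitter, beta0 = init_beta, w0 = init_w,
      mu0 = init_mu, sigma20 = init_sigma2, k0 = init_k,
      fix_sigma2 = !is.null(fix_sigma2), fix_k = !is.null(fix_k),
      fix_w = !is.null(fix_w))
    m <- res$draws
    colnames(m) <- par_names
    draws[[ch]] <- m
    accept[[ch]] <- res$acceptance
  }
  structure(list(draws = draws, acceptance = accept, spec = spec,
                 data = data, n_iter = n_iter, n_burn = n_burn,
                 chains = chains, seed = seed,
                 fixed = list(sigma2 = fix_sigma2, k = fix_k, w = fix_w)),
            class = "shark_fit")
}

#' Pooled retained draws of one or more parameters
#'
#' @param fit A `shark_fit`.
#' @param parameters Column names; default all.
#' @return Matrix of pooled draws (all chains stacked) x parameters.
#' @export
posterior_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "shark_fit"))
  m <- do.call(rbind, fit$draws)
  if (is.null(parameters)) m
  else {
    bad <- setdiff(parameters, colnames(m))
    if (length(bad) > 0) stop("unknown parameter: ", bad[1])
    m[, parameters, drop = FALSE]
  }
}

#' Posterior summary table
#'
#' Median and central 95% credible interval (2.5th and 97.5th
#' percentiles of pooled retained draws) per parameter, plus the
#' Gelman-Rubin potential scale reduction factor.
#'
#' @param fit A `shark_fit`.
#' @param parameters Parameters to summarize (default: intercept,
#'   coefficients, hypervariance and overdispersion).
#' @return A `data.frame`: parameter, median, lo, hi, rhat.
#' @export
posterior_summary <- function(fit, parameters = NULL) {
  if (is.null(parameters)) {
    all <- colnames(fit$draws[[1]])
    parameters <- all[!startsWith(all, "mu.") & !startsWith(all, "w.")]
  }
  m <- posterior_draws(fit, parameters)
  data.frame(
    parameter = parameters,
    median = apply(m, 2, median),
    lo = apply(m, 2, quantile, 0.025),
    hi = apply(m, 2, quantile, 0.975),
    rhat = vapply(parameters, function(p) gelman_rubin(fit, p),
                  numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor from the classic between/within
#' chain variance decomposition: with m chains of length n,
#' `W` the mean within-chain variance and `B/n` the between-chain
#' variance of chain means, the pooled variance estimate is
#' `(n-1)/n W + B/n` and `Rhat = sqrt(pooled / W)`. Values near 1
#' indicate convergence. Chains with zero within-chain variance
#' (e.g. an indicator stuck at one value in every chain) are reported
#' as `NA` with a "degenerate" attribute rather than an error.
#'
#' @param fit A `shark_fit` (or a plain list of per-chain numeric
#'   vectors, for direct use of the formula).
#' @param parameter Parameter name (ignored for a plain list).
#' @return `Rhat` (scalar), possibly `NA` for degenerate chains.
#' @export
gelman_rubin <- function(fit, parameter = NULL) {
  chains <- if (inherits(fit, "shark_fit")) {
    lapply(fit$draws, function(m) m[, parameter])
  } else fit
  m <- length(chains)
  n <- length(chains[[1]])
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 retained iterations")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0)
    return(structure(NA_real_, degenerate = TRUE))
  V <- (n - 1) / n * W + B / n
  sqrt(V / W)
}
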