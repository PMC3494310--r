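#' Negative-binomial log pmf (mean/overdispersion parameterization)
#'
#' Counts per tow are overdispersed relative to the Poisson; the model
#' uses the negative binomial with mean `lam` and variance
#' `lam + lam^2 / k`, where `k` is the overdispersion (size) parameter.
#' At `k = 1` this is geometric in form; as `k -> Inf` it approaches
#' the Poisson. `lam = 0` is the degenerate point mass at zero.
#'
#' @param y Non-negative integer count(s).
#' @param lam Mean(s), `>= 0`.
#' @param k Overdispersion, `> 0`.
#' @return Log probability, vectorized over the inputs.
#' @export
nb_log_pmf <- function(y, lam, k) {
  if (any(lam < 0)) stop("lam must be >= 0")
  if (any(k <= 0)) stop("k must be > 0")
  n <- max(length(y), length(lam), length(k))
  y <- rep_len(y, n); lam <- rep_len(lam, n); k <- rep_len(k, n)
  out <- numeric(n)
  z <- lam == 0
  out[z] <- ifelse(y[z] == 0, 0, -Inf)
  if (any(!z))
    out[!z] <- dnbinom(y[!z], size = k[!z], mu = lam[!z], log = TRUE)
  out
}

#' Expected sharks per tow
#'
#' The per-tow mean count is the island's mean density (sharks/ha)
#' times the area swept by the tow (ha).
#'
#' @param mu_i Island mean density, sharks/ha.
#' @param area_ha Tow area, hectares.
#' @return Expected count `mu_i * area_ha`.
#' @export
tow_mean <- function(mu_i, area_ha) {
  if (any(mu_i < 0)) stop("mu_i must be >= 0")
  if (any(area_ha <= 0)) stop("area_ha must be > 0")
  mu_i * area_ha
}

#' Log density of the positive-truncated normal hyperdistribution
#'
#' Island mean densities are drawn from a normal distribution truncated
#' to positive support (a density cannot be negative, and the negative
#' binomial requires a non-negative mean). The density is renormalized
#' by `Phi(E / sd)`, the untruncated mass above zero.
#'
#' @param mu Evaluation point(s); values `<= 0` have log density `-Inf`.
#' @param E Location (mean of the untruncated normal).
#' @param var Variance of the untruncated normal, `> 0`.
#' @return Log density, vectorized.
#' @export
truncnorm_log_pdf <- function(mu, E, var) {
  if (any(var <= 0)) stop("var must be > 0")
  s <- sqrt(var)
  out <- dnorm(mu, mean = E, sd = s, log = TRUE) -
    pnorm(E / s, log.p = TRUE)
  out[mu <= 0] <- -Inf
  out
}

#' Mean of the positive-truncated normal
#'
#' Closed form `E + s * phi(E/s) / Phi(E/s)`; used as the predicted
#' density under the identity link so predictions stay positive.
#'
#' @inheritParams truncnorm_log_pdf
#' @return The truncated-normal mean, always positive.
#' @export
truncnorm_mean <- function(E, var) {
  s <- sqrt(var)
  a <- E / s
  E + s * exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
}

## Inverse-CDF draw from the positive-truncated normal (vectorized).
rtruncnorm_pos <- function(n, E, var) {
  s <- sqrt(var)
  lo <- pnorm(0, mean = E, sd = s)
  u <- runif(n, lo, 1)
  qnorm(pmin(u, 1 - 1e-16), mean = E, sd = s)
}

#' Prior specification
#'
#' Uninformative defaults: regression coefficients and intercept are
#' normal with mean 0 and variance 100; the hyperdistribution precision
#' `1/sigma^2` is Gamma(0.01, 0.01) (equivalently inverse-gamma on the
#' hypervariance); the overdispersion `k` is Gamma(0.01, 0.01); each
#' latent inclusion indicator is Bernoulli(0.5).
#'
#' @param coef_mean,coef_var Normal prior on `alpha` and each `beta_j`.
#' @param hypervar_gamma_shape,hypervar_gamma_rate Gamma prior on the
#'   precision `1/sigma^2`.
#' @param k_gamma_shape,k_gamma_rate Gamma prior on `k`.
#' @param indicator_prob Prior inclusion probability of each covariate.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_var = 100,
                       hypervar_gamma_shape = 0.01,
                       hypervar_gamma_rate = 0.01,
                       k_gamma_shape = 0.01, k_gamma_rate = 0.01,
                       indicator_prob = 0.5) {
  stopifnot(coef_var > 0, hypervar_gamma_shape > 0,
            hypervar_gamma_rate > 0, k_gamma_shape > 0,
            k_gamma_rate > 0, indicator_prob > 0, indicator_prob < 1)
  structure(list(coef_mean = coef_mean, coef_var = coef_var,
                 hypervar_gamma_shape = hypervar_gamma_shape,
                 hypervar_gamma_rate = hypervar_gamma_rate,
                 k_gamma_shape = k_gamma_shape,
                 k_gamma_rate = k_gamma_rate,
                 indicator_prob = indicator_prob),
            class = "prior_spec")
}

#' Model specification
#'
#' @param covariates Ordered names of design-matrix columns entering the
#'   regression for the hyperdistribution location.
#' @param link `"identity"` (default; the truncation to positive
#'   densities acts on the natural scale) or `"log"` (location is
#'   `exp(E_i)`, giving multiplicative covariate effects).
#' @param priors A [prior_spec()].
#' @param selection If `TRUE`, each covariate carries a latent 0/1
#'   inclusion indicator sampled in the chain (Kuo-Mallick selection).
#' @param weight_variance_by_n If `TRUE` (default) the hyperdistribution
#'   variance for island i is `sigma^2 / n_i`, `n_i` the number of tows.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(covariates, link = c("identity", "log"),
                       priors = prior_spec(), selection = FALSE,
                       weight_variance_by_n = TRUE) {
  link <- match.arg(link)
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(covariates = covariates, link = link, priors = priors,
                 selection = selection,
                 weight_variance_by_n = weight_variance_by_n),
            class = "model_spec")
}

#' Assemble model-ready data
#'
#' Joins pooled tow counts with the standardized design matrix and
#' precomputes the per-island tow index and tow counts `n_i` used to
#' weight the hyperdistribution variance.
#'
#' @param counts Output of [group_counts()].
#' @param design A `design_matrix` covering every island in `counts`.
#' @param covariates Design columns the model may use.
#' @return A list of class `model_data` with `y`, `area`, `island`
#'   (1-based index per tow), `islands` (ids in index order), `X`
#'   (islands x covariates), `n_i`, and the `design` itself.
#' @export
build_model_data <- function(counts, design,
                             covariates = design$columns) {
  miss <- setdiff(unique(counts$island_id), design$island_ids)
  if (length(miss) > 0)
    stop("island(s) missing from design matrix: ", miss[1])
  bad <- setdiff(covariates, design$columns)
  if (length(bad) > 0) stop("unknown design column: ", bad[1])
  islands <- intersect(design$island_ids, unique(counts$island_id))
  idx <- match(counts$island_id, islands)
  n_i <- as.integer(table(factor(counts$island_id, levels = islands)))
  structure(list(y = as.integer(counts$y), area = counts$area_ha,
                 island = idx, islands = islands,
                 X = design$X[islands, covariates, drop = FALSE],
                 n_i = n_i, design = design),
            class = "model_data")
}

#' Linear predictor of the hyperdistribution location
#'
#' `E_i = alpha + sum_j w_j beta_j x_ij`; the latent indicators `w_j`
#' gate each covariate's effect in and out of the model. Under the log
#' link the location used by the hyperdistribution is `exp(E_i)`.
#'
#' @param alpha Intercept.
#' @param beta Coefficient vector.
#' @param w 0/1 inclusion indicators, same length as `beta`.
#' @param x Standardized covariate row (vector) or matrix (islands x
#'   covariates).
#' @return `E_i` (scalar or vector over islands).
#' @export
linear_predictor <- function(alpha, beta, w, x) {
  if (is.matrix(x)) {
    drop(alpha + x %*% (w * beta))
  } else {
    alpha + sum(w * beta * x)
  }
}

#' Joint log posterior of the hierarchical model
#'
#' Sum of (i) the negative-binomial log likelihood of every tow count
#' given `lambda_t = mu_i * area_t` and `k`; (ii) the positive-truncated
#' normal log density of each island mean density `mu_i` with location
#' `E_i` (or `exp(E_i)` under the log link) and variance `sigma^2/n_i`;
#' (iii) normal priors on `alpha` and each `beta_j`; (iv) the gamma
#' prior on the precision `1/sigma^2` (including the Jacobian to the
#' `sigma^2` scale); (v) the gamma prior on `k`; and (vi) Bernoulli
#' priors on the indicators when selection is on. `-Inf` if any
#' `mu_i <= 0`.
#'
#' @param state Named list with `alpha`, `beta`, `sigma2`, `k`, `mu`,
#'   and (if selection) `w`.
#' @param data A `model_data`.
#' @param spec A `model_spec`.
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(state, data, spec) {
  p <- length(spec$covariates)
  if (length(state$beta) != p) stop("beta length != number of covariates")
  if (length(state$mu) != length(data$islands))
    stop("mu length != number of islands")
  if (any(state$mu <= 0) || state$sigma2 <= 0 || state$k <= 0)
    return(-Inf)
  w <- if (is.null(state$w)) rep(1, p) else state$w
  pr <- spec$priors

  lam <- state$mu[data$island] * data$area
  ll <- sum(nb_log_pmf(data$y, lam, state$k))

  E <- linear_predictor(state$alpha, state$beta, w,
                        data$X[, spec$covariates, drop = FALSE])
  loc <- if (spec$link == "log") exp(E) else E
  v_i <- if (spec$weight_variance_by_n) state$sigma2 / data$n_i
         else rep(state$sigma2, length(data$n_i))
  lp_mu <- sum(truncnorm_log_pdf(state$mu, loc, v_i))

  lp_coef <- sum(dnorm(c(state$alpha, state$beta), pr$coef_mean,
                       sqrt(pr$coef_var), log = TRUE))
  ## Gamma(a,b) on tau = 1/sigma2, with Jacobian |dtau/dsigma2| = sigma2^-2
  a <- pr$hypervar_gamma_shape; b <- pr$hypervar_gamma_rate
  lp_s2 <- a * log(b) - lgamma(a) - (a + 1) * log(state$sigma2) -
    b / state$sigma2
  ak <- pr$k_gamma_shape; bk <- pr$k_gamma_rate
  lp_k <- ak * log(bk) - lgamma(ak) + (ak - 1) * log(state$k) -
    bk * state$k
  lp_w <- if (spec$selection) {
    sum(ifelse(w == 1, log(pr$indicator_prob),
               log1p(-pr$indicator_prob)))
  } else 0

  ll + lp_mu + lp_coef + lp_s2 + lp_k + lp_w
}
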