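#' Posterior model weights from latent-indicator histories
#'
#' Each retained MCMC iteration visits one covariate subset, namely
#' `{j : w_j = 1}`; the posterior weight of a subset is the relative
#' frequency with which the chain visited it. Per-covariate inclusion
#' probabilities (the mean of each `w_j`) are reported alongside. The
#' highest-weight model is flagged; ties are broken in favor of fewer
#' covariates, then lexicographically by label.
#'
#' @param fit A `shark_fit` run with `selection = TRUE`.
#' @return A `model_weight_table`: list with `weights` (data frame:
#'   `model` label, `covariates` list-column, `weight`, `best` flag)
#'   and `inclusion` (named per-covariate inclusion probabilities).
#' @export
posterior_model_weights <- function(fit) {
  stopifnot(inherits(fit, "shark_fit"))
  if (!isTRUE(fit$spec$selection))
    stop("posterior model weights require a fit with selection = TRUE")
  covs <- fit$spec$covariates
  W <- posterior_draws(fit, paste0("w.", covs))
  colnames(W) <- covs
  labels <- apply(W, 1, function(r) {
    inc <- covs[r == 1]
    if (length(inc) == 0) "null" else paste(inc, collapse = " + ")
  })
  tab <- table(labels)
  wt <- as.numeric(tab) / length(labels)
  lab <- names(tab)
  sizes <- vapply(lab, function(l) {
    if (l == "null") 0L else length(strsplit(l, " \\+ ")[[1]])
  }, integer(1))
  ord <- order(-wt, sizes, lab)
  df <- data.frame(model = lab[ord], weight = wt[ord],
                   n_covariates = sizes[ord], best = FALSE,
                   stringsAsFactors = FALSE)
  df$best[1] <- TRUE
  structure(list(weights = df,
                 inclusion = colMeans(W),
                 n_draws = nrow(W)),
            class = "model_weight_table")
}

#' @export
print.model_weight_table <- function(x, ...) {
  cat("Posterior model weights (", x$n_draws, " retained draws)\n\n",
      sep = "")
  df <- x$weights
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-45s %6.3f%s\n", df$model[i], df$weight[i],
                if (df$best[i]) " *" else ""))
  }
  cat("\nPer-covariate inclusion probabilities:\n")
  for (nm in names(x$inclusion))
    cat(sprintf("  %-25s %6.3f\n", nm, x$inclusion[nm]))
  invisible(x)
}

#' Best covariate subset from a weight table
#'
#' @param weights A `model_weight_table`.
#' @return Character vector of covariate names (empty for the null
#'   model).
#' @export
best_subset <- function(weights) {
  stopifnot(inherits(weights, "model_weight_table"))
  lab <- weights$weights$model[weights$weights$best]
  if (lab == "null") character(0) else strsplit(lab, " \\+ ")[[1]]
}

#' Posterior-predictive goodness of fit (Bayesian p-value)
#'
#' At every retained draw a replicate data set of shark counts is
#' simulated from the fitted generative process (negative binomial at
#' the draw's island densities and overdispersion, on the observed tow
#' areas). Lack of fit is the sum of squared residuals
#' `sum_t (y_t - lambda_t)^2`; the Bayesian p-value is the proportion
#' of draws in which the replicate's discrepancy exceeds the observed
#' data's. Values near 0.5 indicate a well-fitting model; values near
#' 0 or 1 indicate systematic misfit.
#'
#' @param fit A `shark_fit`.
#' @param data A `model_data`; defaults to the data the model was
#'   fitted to.
#' @param seed Integer seed for the replicate simulations.
#' @return A `fit_check`: list with `bayesian_p`,
#'   `discrepancy_observed`, `discrepancy_simulated`.
#' @export
bayesian_p_value <- function(fit, data = fit$data, seed = 1) {
  stopifnot(inherits(fit, "shark_fit"))
  mu <- posterior_draws(fit, paste0("mu.", data$islands))
  k <- posterior_draws(fit, "k")[, 1]
  set.seed(as.integer(seed))
  d <- .pp_discrepancy_cpp(mu, k, as.integer(data$island),
                           data$area, as.integer(data$y))
  structure(list(bayesian_p = mean(d$simulated > d$observed),
                 discrepancy_observed = d$observed,
                 discrepancy_simulated = d$simulated),
            class = "fit_check")
}

#' Compare candidate human-effect metrics
#'
#' Fits a single-covariate selection model for each candidate metric of
#' human pressure (humans within 200 km, humans per square kilometer of
#' reef, distance to the nearest population center) and reports each
#' metric's posterior inclusion probability and Bayesian p-value.
#' Metrics are ranked by goodness of fit, `|bayesian_p - 0.5|`
#' (smaller is better); ties fall back to higher inclusion
#' probability, then to input order.
#'
#' @param counts Output of [group_counts()].
#' @param design A `design_matrix` containing every metric.
#' @param metrics Candidate covariate names.
#' @param link,priors Passed to [model_spec()].
#' @param n_iter,n_burn,chains,seed Passed to [run_mcmc()].
#' @return A `data.frame`, one row per metric: inclusion probability,
#'   Bayesian p-value, `abs_p_dist` and `rank`.
#' @export
compare_human_metrics <- function(counts, design,
                                  metrics = c("humans_200km",
                                              "humans_per_km2_reef",
                                              "dist_pop_center_km"),
                                  link = "identity",
                                  priors = prior_spec(),
                                  n_iter = 6000, n_burn = 1500,
                                  chains = 2, seed = 1) {
  bad <- setdiff(metrics, design$columns)
  if (length(bad) > 0) stop("metric not in design matrix: ", bad[1])
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[i]
    sp <- model_spec(m, link = link, priors = priors, selection = TRUE)
    dat <- build_model_data(counts, design, covariates = m)
    fit <- run_mcmc(dat, sp, n_iter = n_iter, n_burn = n_burn,
                    chains = chains, seed = seed + i - 1)
    pw <- posterior_model_weights(fit)
    fc <- bayesian_p_value(fit, seed = seed + i - 1)
    data.frame(metric = m,
               inclusion_probability = unname(pw$inclusion[m]),
               bayesian_p = fc$bayesian_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$abs_p_dist <- abs(out$bayesian_p - 0.5)
  ord <- order(out$abs_p_dist, -out$inclusion_probability,
               seq_len(nrow(out)))
  out$rank <- match(seq_len(nrow(out)), ord)
  out
}

#' Refit the selected model without indicators
#'
#' Once a best subset is identified, the latent indicators are removed
#' and the model refitted with those covariates always included, to
#' estimate each regression coefficient's posterior median and 95%
#' credible interval on the standardized scale.
#'
#' @param data A `model_data`.
#' @param subset Covariate names of the selected model (empty =
#'   intercept-only).
#' @param link,priors Passed to [model_spec()].
#' @param ... Passed to [run_mcmc()].
#' @return A `shark_fit` with a `coefficients` element: data frame of
#'   posterior median and 95% CI for the intercept and each subset
#'   member.
#' @export
refit_best <- function(data, subset, link = "identity",
                       priors = prior_spec(), ...) {
  sp <- model_spec(subset, link = link, priors = priors,
                   selection = FALSE)
  counts <- data.frame(tow_id = seq_along(data$y),
                       island_id = data$islands[data$island],
                       area_ha = data$area, y = data$y,
                       stringsAsFactors = FALSE)
  dat <- build_model_data(counts, data$design, covariates = subset)
  fit <- run_mcmc(dat, sp, ...)
  pars <- c("alpha", if (length(subset) > 0) paste0("beta.", subset))
  fit$coefficients <- posterior_summary(fit, pars)
  fit
}
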