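#' Counterfactual human-free baseline density for one island
#'
#' At each retained draw the linear predictor is recomputed with every
#' human-effect covariate set to the standardized image of a raw value
#' of zero humans (i.e. raw 0 pushed through the stored log(x+offset)
#' transform and standardization — not a literal 0 in standardized
#' space, which would mean the sample-mean human population). All
#' other covariates keep the island's observed values. The predicted
#' density for the draw is the mean of the positive-truncated normal
#' at that location with variance `sigma2 / n_i` (location `exp(E)`
#' under the log link), and the baseline estimate is the median and
#' central 95% interval over draws.
#'
#' @param fit A `shark_fit`.
#' @param island Island identifier present in the fitted data.
#' @param human_covariates Covariates zeroed out in the counterfactual
#'   (default: any of the three human metrics present in the model).
#' @return A `data.frame` row: `island_id`, `baseline_lo`,
#'   `baseline_median`, `baseline_hi`.
#' @export
baseline_density <- function(fit, island,
                             human_covariates = c("humans_200km",
                                                  "humans_per_km2_reef",
                                                  "dist_pop_center_km")) {
  d <- predicted_density_draws(fit, island,
                               override = zero_human_override(
                                 fit, human_covariates))
  q <- quantile(d, c(0.025, 0.5, 0.975))
  data.frame(island_id = island, baseline_lo = q[[1]],
             baseline_median = q[[2]], baseline_hi = q[[3]],
             row.names = NULL, stringsAsFactors = FALSE)
}

## Standardized values representing "raw humans = 0" for each human
## metric in the fitted model (other metrics are left untouched).
zero_human_override <- function(fit, human_covariates) {
  covs <- intersect(human_covariates, fit$spec$covariates)
  vapply(covs, function(cc)
    standardize_raw(fit$data$design, cc, 0), numeric(1))
}

#' Per-draw predicted density for one island
#'
#' The fitted expected density of an island at its observed covariates
#' (or with selected covariates overridden at given standardized
#' values): the positive-truncated normal mean at the draw's location
#' and island-specific variance.
#'
#' @param fit A `shark_fit`.
#' @param island Island identifier.
#' @param override Named numeric vector of standardized covariate
#'   values replacing the island's observed values (may be empty).
#' @return Numeric vector, one predicted density per retained draw.
#' @export
predicted_density_draws <- function(fit, island, override = numeric(0)) {
  data <- fit$data
  i <- match(island, data$islands)
  if (is.na(i)) stop("island not in fitted data: ", island)
  covs <- fit$spec$covariates
  x <- if (length(covs) > 0) data$X[i, covs] else numeric(0)
  for (nm in names(override)) {
    if (nm %in% covs) x[nm] <- override[[nm]]
  }
  dr <- posterior_draws(fit)
  alpha <- dr[, "alpha"]
  E <- alpha
  if (length(covs) > 0) {
    B <- dr[, paste0("beta.", covs), drop = FALSE]
    Wcols <- paste0("w.", covs)
    W <- if (all(Wcols %in% colnames(dr)))
      dr[, Wcols, drop = FALSE] else matrix(1, nrow(dr), length(covs))
    E <- alpha + drop((B * W) %*% x)
  }
  loc <- if (fit$spec$link == "log") exp(E) else E
  v_i <- if (isTRUE(fit$spec$weight_variance_by_n))
    dr[, "sigma2"] / data$n_i[i] else dr[, "sigma2"]
  truncnorm_mean(loc, v_i)
}

#' Observed island density from tow records
#'
#' Ratio of totals — total sharks over total hectares across the
#' island's kept tows — which is robust to unequal tow lengths. The
#' standard error reflects among-tow variation of per-tow densities.
#'
#' @param counts Rows of a [group_counts()] table for one island (or a
#'   full table plus `island`).
#' @param island Optional island identifier to subset on.
#' @return A list: `density` (sharks/ha), `se`, `n_tows`.
#' @export
observed_density <- function(counts, island = NULL) {
  if (!is.null(island)) counts <- counts[counts$island_id == island, ]
  n <- nrow(counts)
  if (n == 0) stop("no tows for the requested island")
  dens <- sum(counts$y) / sum(counts$area_ha)
  per_tow <- counts$y / counts$area_ha
  se <- if (n > 1) sd(per_tow) / sqrt(n) else 0
  list(density = dens, se = se, n_tows = n)
}

#' Depletion ratio: observed density as a percentage of baseline
#'
#' Applies `100 * observed / baseline` across the baseline credible
#' bounds and median; because a larger baseline means a smaller ratio,
#' the output is re-sorted to run low-to-high.
#'
#' @param observed Observed density, sharks/ha.
#' @param baseline A row from [baseline_density()] (or any list with
#'   `baseline_lo`, `baseline_median`, `baseline_hi`).
#' @return Named numeric vector `lo_pct`, `median_pct`, `hi_pct`
#'   (ascending).
#' @export
depletion_ratio <- function(observed, baseline) {
  b <- c(baseline$baseline_lo, baseline$baseline_median,
         baseline$baseline_hi)
  if (any(b <= 0)) stop("baseline must be positive")
  pct <- sort(100 * observed / b)
  c(lo_pct = pct[1], median_pct = pct[2], hi_pct = pct[3])
}

#' Full baseline table (observed vs human-free baseline, per island)
#'
#' @param fit A `shark_fit`.
#' @param counts The [group_counts()] table the model was fitted to.
#' @param islands Island table (for region labels); optional.
#' @param human_covariates Passed to [baseline_density()].
#' @return A `data.frame`: island, region, observed density and SE,
#'   baseline lo/median/hi, depletion lo/median/hi percentages.
#' @export
baseline_table <- function(fit, counts, islands = NULL,
                           human_covariates = c("humans_200km",
                                                "humans_per_km2_reef",
                                                "dist_pop_center_km")) {
  rows <- lapply(fit$data$islands, function(isl) {
    b <- baseline_density(fit, isl, human_covariates)
    o <- observed_density(counts, isl)
    dep <- depletion_ratio(o$density, b)
    data.frame(island_id = isl,
               region = if (!is.null(islands))
                 islands$region[match(isl, islands$island_id)]
               else NA_character_,
               observed_density = o$density, observed_se = o$se,
               baseline_lo = b$baseline_lo,
               baseline_median = b$baseline_median,
               baseline_hi = b$baseline_hi,
               depletion_lo_pct = dep[["lo_pct"]],
               depletion_median_pct = dep[["median_pct"]],
               depletion_hi_pct = dep[["hi_pct"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expected-density curve over one covariate
#'
#' Sweeps one covariate over a grid spanning its observed raw range
#' while holding the others at a constant representative value
#' (default: their median standardized value over the islands in the
#' fit), and returns the posterior median and 95% interval of expected
#' density at each grid point. Under the log link with a
#' log-transformed covariate the curve is a power function of the raw
#' value.
#'
#' @param fit A `shark_fit`.
#' @param covariate Covariate to sweep (must be in the fitted model).
#' @param grid Raw covariate values; default 50 points over the
#'   observed range.
#' @param conditioning Named standardized values for the remaining
#'   covariates; default column medians.
#' @param n_ref Reference number of tows for the predictive variance
#'   (default: median island tow count).
#' @return A `data.frame`: `covariate`, `x_raw`, `density_lo`,
#'   `density_median`, `density_hi`.
#' @export
effect_curve <- function(fit, covariate, grid = NULL,
                         conditioning = NULL, n_ref = NULL) {
  covs <- fit$spec$covariates
  if (!covariate %in% covs) stop("covariate not in fitted model")
  design <- fit$data$design
  X <- fit$data$X[, covs, drop = FALSE]
  if (is.null(grid)) {
    raw <- unstandardize(design, covariate, X[, covariate])
    grid <- seq(min(raw), max(raw), length.out = 50)
  }
  if (is.null(conditioning)) {
    others <- setdiff(covs, covariate)
    conditioning <- vapply(others, function(cc) median(X[, cc]),
                           numeric(1))
  }
  if (is.null(n_ref)) n_ref <- median(fit$data$n_i)
  dr <- posterior_draws(fit)
  alpha <- dr[, "alpha"]
  B <- dr[, paste0("beta.", covs), drop = FALSE]
  Wcols <- paste0("w.", covs)
  W <- if (all(Wcols %in% colnames(dr)))
    dr[, Wcols, drop = FALSE] else matrix(1, nrow(dr), length(covs))
  v <- if (isTRUE(fit$spec$weight_variance_by_n))
    dr[, "sigma2"] / n_ref else dr[, "sigma2"]
  rows <- lapply(grid, function(xr) {
    x <- setNames(numeric(length(covs)), covs)
    x[names(conditioning)] <- conditioning
    x[covariate] <- standardize_raw(design, covariate, xr)
    E <- alpha + drop((B * W) %*% x)
    loc <- if (fit$spec$link == "log") exp(E) else E
    d <- truncnorm_mean(loc, v)
    q <- quantile(d, c(0.025, 0.5, 0.975))
    data.frame(covariate = covariate, x_raw = xr,
               density_lo = q[[1]], density_median = q[[2]],
               density_hi = q[[3]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Covariate increment that doubles expected density
#'
#' Under the log link the expected density is proportional to
#' `exp(beta_j z_j)` in the standardized covariate, so density doubles
#' for every raw-unit increase of `ln(2) * sd_x / beta_j` (the
#' standardized posterior-median coefficient back-scaled by the
#' covariate's pre-standardization spread). Under the identity link no
#' constant increment exists; a local increment at a reference
#' location `E_ref` is reported instead (`E_ref * sd_x / beta_j`, the
#' raw-unit change adding `E_ref` to the linear predictor). A
#' non-positive median coefficient means density never doubles with
#' increasing covariate; `NA` is returned.
#'
#' @param fit A `shark_fit`.
#' @param covariate Covariate name (log-transformed covariates return
#'   the increment on the log-raw scale).
#' @param E_ref Reference linear-predictor value for the identity
#'   link; default the posterior median of `alpha`.
#' @return Increment in raw covariate units (`NA` if the effect is not
#'   positive).
#' @export
doubling_increment <- function(fit, covariate, E_ref = NULL) {
  if (!covariate %in% fit$spec$covariates)
    stop("covariate not in fitted model")
  beta <- median(posterior_draws(fit, paste0("beta.", covariate)))
  if (beta <= 0) return(NA_real_)
  m <- fit$data$design$transform_meta[[covariate]]
  if (fit$spec$link == "log") {
    log(2) * m$sd / beta
  } else {
    if (is.null(E_ref)) E_ref <- median(posterior_draws(fit, "alpha"))
    E_ref * m$sd / beta
  }
}
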