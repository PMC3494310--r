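#' Regional survey profiles
#'
#' The default profiles emulate the structure of the towed-diver
#' monitoring program: 46 islands in 5 regions, roughly 35 surveys per
#' island, raw covariates within each region's observed range (human
#' population within 200 km in persons, productivity in
#' mg C m^-2 day^-1, minimum monthly SST in degrees C, reef area in
#' km^2), human populations heavy-right-skewed with a point mass at
#' exactly zero for regions where most islands are uninhabited.
#'
#' @return A list of region profiles, each a list with `name`,
#'   `n_islands`, `tows_min`, `tows_max`, per-covariate `c(min, max)`
#'   ranges, and `p_zero_humans`.
#' @export
default_region_profiles <- function() {
  prof <- function(name, n, humans, prod, sst, area, p_zero) {
    list(name = name, n_islands = n, tows_min = 30L, tows_max = 40L,
         humans_200km = humans, productivity = prod, min_sst = sst,
         reef_area_km2 = area, complexity = c(1.5, 5.5),
         p_zero_humans = p_zero)
  }
  list(
    prof("MHI",     9L, c(51000, 970000), c(234, 270), c(23.8, 24.4),
         c(71, 1662), 0.0),
    prof("NWHI",    9L, c(40, 200),       c(244, 290), c(19.2, 23.1),
         c(317, 2447), 0.8),
    prof("Mariana", 16L, c(50, 101000),   c(121, 165), c(25.8, 27.3),
         c(4, 203), 0.55),
    prof("AmSamoa", 5L, c(10, 105000),    c(130, 151), c(27.3, 28.3),
         c(18, 353), 0.0),
    prof("PRIA",    7L, c(5, 10),         c(147, 445), c(25.3, 27.3),
         c(20, 240), 0.85)
  )
}

## log-uniform quantile on [lo, hi] (lo > 0)
qloguni <- function(u, lo, hi) exp(log(lo) + u * (log(hi) - log(lo)))

#' Generate an island network from regional profiles
#'
#' Covariates are drawn within each profile's raw range: uniform for
#' productivity, SST and complexity; log-uniform for reef area and for
#' human population (with the profile's point mass at exactly 0).
#' Humans per km^2 of reef is derived as humans within 200 km divided
#' by reef area; distance to the nearest population center declines
#' with human population with multiplicative noise, so the three human
#' metrics are correlated as in the real survey. Optionally a Gaussian
#' copula couples reef area and minimum SST to reproduce the strong
#' negative correlation between log reef area and temperature seen in
#' the survey (large high-latitude Hawaiian reefs in cold water).
#'
#' @param profiles List of region profiles.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param area_sst_correlation If non-`NULL`, the target correlation
#'   between log reef area and minimum SST (e.g. -0.66), induced via a
#'   global Gaussian copula over the per-region ranges.
#' @return A validated island table (one row per island) with an
#'   appended `mean_complexity` column.
#' @export
generate_islands <- function(profiles = default_region_profiles(),
                             seed = 1, area_sst_correlation = NULL) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  set.seed(as.integer(seed))
  rows <- list()
  for (pf in profiles) {
    n <- pf$n_islands
    u_area <- runif(n)
    u_sst <- runif(n)
    if (!is.null(area_sst_correlation)) {
      rho <- area_sst_correlation
      z1 <- qnorm(u_area)
      z2 <- rho * z1 + sqrt(1 - rho^2) * qnorm(u_sst)
      u_sst <- pnorm(z2)
    }
    zero <- runif(n) < pf$p_zero_humans
    humans <- ifelse(zero, 0,
                     qloguni(runif(n), max(pf$humans_200km[1], 1),
                             pf$humans_200km[2]))
    area <- qloguni(u_area, pf$reef_area_km2[1], pf$reef_area_km2[2])
    dist <- 1500 / (1 + humans)^0.25 * exp(rnorm(n, 0, 0.4))
    rows[[pf$name]] <- data.frame(
      island_id = sprintf("%s_%02d", pf$name, seq_len(n)),
      region = pf$name,
      humans_200km = humans,
      humans_per_km2_reef = humans / area,
      dist_pop_center_km = pmax(dist, 1),
      productivity = runif(n, pf$productivity[1], pf$productivity[2]),
      min_sst = pf$min_sst[1] + u_sst * diff(pf$min_sst),
      reef_area_km2 = area,
      mean_complexity = runif(n, pf$complexity[1], pf$complexity[2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_island_table(out)
}

#' Default generative truth for simulation studies
#'
#' Identity-link truth on the standardized covariate scale chosen so
#' island densities span roughly 0.1-7 sharks/ha — the observed range
#' from heavily populated reefs to the most productive remote reefs —
#' with a strong negative human effect and positive productivity and
#' temperature effects.
#'
#' @param covariates Names of covariates carrying effects.
#' @param beta Standardized effect sizes (density units per SD).
#' @param alpha Intercept (mean density scale).
#' @param sigma2 Hypervariance before the 1/n_i weighting.
#' @param k Negative-binomial overdispersion.
#' @param link `"identity"` or `"log"`.
#' @return A list of class `truth_record`.
#' @export
default_truth <- function(covariates = c("humans_200km", "productivity",
                                         "min_sst"),
                          beta = c(-1.2, 0.8, 0.5),
                          alpha = 2.5, sigma2 = 1, k = 1.5,
                          link = "identity") {
  stopifnot(length(beta) == length(covariates))
  structure(list(alpha = alpha, beta = setNames(beta, covariates),
                 covariates = covariates, sigma2 = sigma2, k = k,
                 link = link),
            class = "truth_record")
}

#' Simulate towed-diver surveys from a known truth
#'
#' Draws each island's mean density from the positive-truncated normal
#' at the truth's linear predictor (variance `sigma2 / n_i`), then
#' per-tow counts from the negative binomial at `mu_i * area_t`. Tow
#' lengths are normal around the observed 2.2-km average (truncated at
#' the 1-km validity threshold), belt width is 10 m, and the pooled
#' group count is split among the five reef species with the observed
#' basin-wide composition. Per-tow complexity scores scatter around
#' the island's mean. Output passes the full validation path with zero
#' exclusions.
#'
#' @param islands Island table from [generate_islands()].
#' @param truth A `truth_record`.
#' @param seed Integer seed.
#' @param tows_min,tows_max Range of surveys per island.
#' @param years Calendar years to cycle through.
#' @return A list: `tows` (validated tow table), `islands`, `design`
#'   (the standardized design matrix used), and `truth` extended with
#'   per-island `n_i`, `E_i`, `mu_i` (realized densities) and
#'   `baseline_i` (true expected density with humans set to zero).
#' @export
generate_tows <- function(islands, truth = default_truth(), seed = 1,
                          tows_min = 30, tows_max = 40,
                          years = 2004:2010) {
  stopifnot(inherits(truth, "truth_record"))
  design <- transform_covariates(islands)
  bad <- setdiff(truth$covariates, design$columns)
  if (length(bad) > 0) stop("truth covariate not in design: ", bad[1])
  set.seed(as.integer(seed))
  nI <- nrow(islands)
  n_i <- sample(tows_min:tows_max, nI, replace = TRUE)
  X <- design$X[, truth$covariates, drop = FALSE]
  E <- drop(truth$alpha + X %*% truth$beta)
  loc <- if (truth$link == "log") exp(E) else E
  mu <- rtruncnorm_pos(nI, loc, truth$sigma2 / n_i)

  ## true counterfactual baseline: humans at raw 0, same realized n_i
  human_covs <- intersect(c("humans_200km", "humans_per_km2_reef",
                            "dist_pop_center_km"), truth$covariates)
  X0 <- X
  for (cc in human_covs) X0[, cc] <- standardize_raw(design, cc, 0)
  E0 <- drop(truth$alpha + X0 %*% truth$beta)
  loc0 <- if (truth$link == "log") exp(E0) else E0
  baseline <- truncnorm_mean(loc0, truth$sigma2 / n_i)

  species_mix <- c(gray = 0.71, whitetip = 0.19, blacktip = 0.06,
                   galapagos = 0.03, nurse = 0.01)
  rows <- list()
  tow_no <- 0L
  for (i in seq_len(nI)) {
    n <- n_i[i]
    len <- pmin(pmax(rnorm(n, 2.2, 0.35), 1), 4.5)
    area <- len * 10 / 10
    ytot <- rnbinom(n, size = truth$k, mu = mu[i] * area)
    sp <- t(vapply(ytot, function(yy)
      as.integer(stats::rmultinom(1, yy, species_mix)),
      integer(length(species_mix))))
    colnames(sp) <- names(species_mix)
    cx <- pmin(pmax(round(islands$mean_complexity[i] +
                            rnorm(n, 0, 0.7)), 1), 6)
    df <- data.frame(
      tow_id = sprintf("T%05d", tow_no + seq_len(n)),
      island_id = islands$island_id[i],
      year = rep_len(years, n),
      habitat = "forereef",
      length_km = len, width_m = 10, complexity = as.integer(cx),
      stringsAsFactors = FALSE)
    rows[[i]] <- cbind(df, as.data.frame(sp))
    tow_no <- tow_no + n
  }
  tows <- validate_tow_table(do.call(rbind, rows))
  truth$n_i <- setNames(n_i, islands$island_id)
  truth$E_i <- setNames(E, islands$island_id)
  truth$mu_i <- setNames(mu, islands$island_id)
  truth$baseline_i <- setNames(baseline, islands$island_id)
  truth$seed <- seed
  list(tows = tows, islands = islands, design = design, truth = truth)
}

#' One-call synthetic survey at the study scale
#'
#' Convenience wrapper: [generate_islands()] then [generate_tows()]
#' under a single seed, at the default study conditions (46 islands in
#' 5 regions, 30-40 tows per island).
#'
#' @inheritParams generate_tows
#' @param profiles Region profiles.
#' @param area_sst_correlation Passed to [generate_islands()].
#' @return As [generate_tows()].
#' @export
simulate_survey <- function(profiles = default_region_profiles(),
                            truth = default_truth(), seed = 1,
                            area_sst_correlation = NULL) {
  islands <- generate_islands(profiles, seed = seed,
                              area_sst_correlation = area_sst_correlation)
  generate_tows(islands, truth, seed = seed + 1)
}

## Printed survey-summary structure: surveys and per-species totals per region.
SURVEY_SUMMARY_STRUCTURE <- list(
  MHI     = list(n_islands = 9L, surveys = 336L,
                 totals = c(gray = 16L, whitetip = 27L, blacktip = 0L,
                            galapagos = 12L, nurse = 0L)),
  NWHI    = list(n_islands = 9L, surveys = 219L,
                 totals = c(gray = 62L, whitetip = 102L, blacktip = 0L,
                            galapagos = 104L, nurse = 0L)),
  Mariana = list(n_islands = 16L, surveys = 371L,
                 totals = c(gray = 304L, whitetip = 227L,
                            blacktip = 17L, galapagos = 0L,
                            nurse = 52L)),
  AmSamoa = list(n_islands = 5L, surveys = 364L,
                 totals = c(gray = 30L, whitetip = 82L, blacktip = 23L,
                            galapagos = 0L, nurse = 6L)),
  PRIA    = list(n_islands = 7L, surveys = 317L,
                 totals = c(gray = 2891L, whitetip = 433L,
                            blacktip = 226L, galapagos = 6L,
                            nurse = 0L))
)

#' Deterministic fixture reproducing the survey summary table
#'
#' Builds, without any random draws, a tow table and island table whose
#' regional structure matches the published survey summary exactly: 46
#' reefs in 5 regions, 1607 forereef surveys, per-region and total
#' per-species shark counts (4620 sharks in all), and per-region
#' covariate ranges hitting the printed minima and maxima. Species
#' counts are spread over a region's tows as evenly as integers allow.
#' Regenerating the fixture gives byte-identical files.
#'
#' @param dir Optional directory; if given, `tows.csv` and
#'   `islands.csv` are written there.
#' @return A list with `tows` and `islands` tables (and `paths` if
#'   written).
#' @export
make_survey_summary_fixture <- function(dir = NULL) {
  ranges <- list(  # raw covariate ranges per region (persons, not 1000s)
    MHI     = list(humans = c(51000, 970000), prod = c(234, 270),
                   sst = c(23.8, 24.4), area = c(71, 1662)),
    NWHI    = list(humans = c(0, 200), prod = c(244, 290),
                   sst = c(19.2, 23.1), area = c(317, 2447)),
    Mariana = list(humans = c(0, 101000), prod = c(121, 165),
                   sst = c(25.8, 27.3), area = c(4, 203)),
    AmSamoa = list(humans = c(10, 105000), prod = c(130, 151),
                   sst = c(27.3, 28.3), area = c(18, 353)),
    PRIA    = list(humans = c(0, 10), prod = c(147, 445),
                   sst = c(25.3, 27.3), area = c(20, 240))
  )
  spread <- function(lo, hi, n) lo + (seq_len(n) - 1) / (n - 1) * (hi - lo)
  isl_rows <- list()
  tow_rows <- list()
  for (rg in names(SURVEY_SUMMARY_STRUCTURE)) {
    st <- SURVEY_SUMMARY_STRUCTURE[[rg]]
    rr <- ranges[[rg]]
    n <- st$n_islands
    ids <- sprintf("%s_%02d", rg, seq_len(n))
    isl_rows[[rg]] <- data.frame(
      island_id = ids, region = rg,
      humans_200km = spread(rr$humans[1], rr$humans[2], n),
      humans_per_km2_reef = spread(rr$humans[1], rr$humans[2], n) /
        spread(rr$area[1], rr$area[2], n),
      dist_pop_center_km = spread(5, 500, n),
      productivity = spread(rr$prod[1], rr$prod[2], n),
      min_sst = spread(rr$sst[1], rr$sst[2], n),
      reef_area_km2 = spread(rr$area[1], rr$area[2], n),
      stringsAsFactors = FALSE)
    ## surveys spread across islands, extra tows to the first islands
    base <- st$surveys %/% n
    extra <- st$surveys %% n
    per_isl <- rep(base, n) + (seq_len(n) <= extra)
    m <- st$surveys
    ## species counts spread across the region's tows
    alloc <- function(total) {
      rep(total %/% m, m) + (seq_len(m) <= total %% m)
    }
    sp <- vapply(REEF_SPECIES, function(s) alloc(st$totals[[s]]),
                 integer(m))
    tow_rows[[rg]] <- data.frame(
      tow_id = sprintf("%s_T%04d", rg, seq_len(m)),
      island_id = rep(ids, per_isl),
      year = rep_len(2004:2010, m),
      habitat = "forereef",
      length_km = 2.2, width_m = 10, complexity = 3L,
      stringsAsFactors = FALSE)
    tow_rows[[rg]] <- cbind(tow_rows[[rg]], as.data.frame(sp))
  }
  islands <- do.call(rbind, isl_rows)
  tows <- validate_tow_table(do.call(rbind, tow_rows))
  rownames(islands) <- rownames(tows) <- NULL
  out <- list(tows = tows, islands = validate_island_table(islands))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tp <- file.path(dir, "tows.csv")
    ip <- file.path(dir, "islands.csv")
    write_tow_table(out$tows, tp)
    write_island_table(out$islands, ip)
    out$paths <- c(tows = tp, islands = ip)
  }
  out
}
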