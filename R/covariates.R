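#' Default covariate transform specification
#'
#' Human-population metrics are right-skewed over several orders of
#' magnitude and include exact zeros (uninhabited islands), so they get
#' `log(x + 1)`; distance to the nearest population center and reef
#' area are strictly positive and get a plain log. Productivity,
#' minimum SST and mean complexity enter untransformed. All columns are
#' standardized (centered, unit variance) after transformation.
#'
#' @return A named list, per covariate: `list(log = flag, offset = real)`.
#' @export
default_transform_spec <- function() {
  list(
    humans_200km        = list(log = TRUE,  offset = 1),
    humans_per_km2_reef = list(log = TRUE,  offset = 1),
    dist_pop_center_km  = list(log = TRUE,  offset = 0),
    productivity        = list(log = FALSE, offset = 0),
    min_sst             = list(log = FALSE, offset = 0),
    reef_area_km2       = list(log = TRUE,  offset = 0),
    mean_complexity     = list(log = FALSE, offset = 0)
  )
}

#' Read a covariate transform spec from a YAML file
#'
#' The file maps covariate names to `{log: bool, offset: real}`
#' entries, e.g.
#'
#' ```yaml
#' humans_200km: {log: true, offset: 1}
#' productivity: {log: false}
#' ```
#'
#' Missing fields default to `log: false`, `offset: 0`.
#'
#' @param path YAML file path.
#' @return A transform spec usable by [transform_covariates()].
#' @export
read_transform_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e)
    list(log = isTRUE(e$log),
         offset = if (is.null(e$offset)) 0 else as.numeric(e$offset)))
}

#' Build the standardized design matrix
#'
#' Applies per-covariate log transforms (with offsets for columns that
#' may contain zeros), then centers and scales each column to mean 0,
#' sd 1 across islands. The transform metadata stored with the matrix
#' is sufficient to map any raw covariate value into standardized space
#' (used by the counterfactual baseline, which needs the standardized
#' image of "zero humans") and to invert the transform exactly.
#'
#' @param islands Validated island table; a `mean_complexity` column may
#'   be appended beforehand (see [island_mean_complexity()]).
#' @param spec Transform spec as from [default_transform_spec()];
#'   only covariates named in `spec` and present in `islands` are used.
#' @return An object of class `design_matrix`: list with `island_ids`,
#'   `columns`, `X` (islands x covariates, standardized) and
#'   `transform_meta` (per column: log flag, offset, pre-standardization
#'   mean and sd).
#' @export
transform_covariates <- function(islands, spec = default_transform_spec()) {
  cols <- intersect(names(spec), names(islands))
  if (length(cols) == 0) stop("no covariates in common between spec and table")
  n <- nrow(islands)
  X <- matrix(NA_real_, n, length(cols),
              dimnames = list(islands$island_id, cols))
  meta <- list()
  for (cc in cols) {
    raw <- islands[[cc]]
    sp <- spec[[cc]]
    if (isTRUE(sp$log)) {
      shifted <- raw + sp$offset
      if (any(shifted <= 0)) {
        bad <- islands$island_id[which(shifted <= 0)[1]]
        stop("log transform of non-positive value in '", cc,
             "' (island ", bad, "); supply a positive offset")
      }
      v <- log(shifted)
    } else {
      v <- raw
    }
    m <- mean(v)
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop("covariate '", cc, "' is constant across islands; ",
           "cannot standardize")
    X[, cc] <- (v - m) / s
    meta[[cc]] <- list(log = isTRUE(sp$log), offset = sp$offset,
                       mean = m, sd = s)
  }
  structure(list(island_ids = islands$island_id, columns = cols,
                 X = X, transform_meta = meta),
            class = "design_matrix")
}

#' Map raw covariate values to standardized space, and back
#'
#' @param design A `design_matrix`.
#' @param column Covariate name.
#' @param raw Raw covariate values (for `standardize_raw`).
#' @return Standardized values (or raw values for `unstandardize`).
#' @export
standardize_raw <- function(design, column, raw) {
  m <- design$transform_meta[[column]]
  if (is.null(m)) stop("unknown design column: ", column)
  v <- if (m$log) log(raw + m$offset) else raw
  (v - m$mean) / m$sd
}

#' @rdname standardize_raw
#' @param z Standardized values.
#' @export
unstandardize <- function(design, column, z) {
  m <- design$transform_meta[[column]]
  if (is.null(m)) stop("unknown design column: ", column)
  v <- z * m$sd + m$mean
  if (m$log) exp(v) - m$offset else v
}

#' Pairwise-correlation screen for collinear covariates
#'
#' Computes the Pearson correlation for every pair of design columns
#' and flags pairs whose absolute correlation exceeds the threshold
#' (default 0.7). Strongly collinear covariates should not enter a
#' model together; they are split into separate candidate model sets
#' instead (see [build_model_sets()]).
#'
#' @param design A `design_matrix`.
#' @param threshold Absolute-correlation flag threshold.
#' @return A `collinearity_report`: list with `pairwise_r` (symmetric
#'   matrix), `flagged_pairs` (data frame var1/var2/r), `threshold`.
#' @export
correlation_screen <- function(design, threshold = 0.7) {
  if (nrow(design$X) < 3) stop("need at least 3 islands")
  r <- cor(design$X)
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[idx[, 1]],
                        var2 = colnames(r)[idx[, 2]],
                        r = r[idx], stringsAsFactors = FALSE)
  structure(list(pairwise_r = r, flagged_pairs = flagged,
                 threshold = threshold),
            class = "collinearity_report")
}

#' Variance inflation factors
#'
#' VIF of column j is `1 / (1 - R2_j)` with `R2_j` from the ordinary
#' least-squares regression of column j on the remaining columns. A
#' perfectly collinear column is reported as `Inf` rather than raising
#' an error. Final models are expected to have VIFs near or below 2.
#'
#' @param design A `design_matrix`.
#' @param columns Subset of columns to assess (default: all).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design, columns = design$columns) {
  X <- design$X[, columns, drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("need more islands than columns for VIF")
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Enumerate the candidate covariate subsets (model sets A and B)
#'
#' Reef area and minimum SST are strongly negatively correlated across
#' the surveyed islands (large Hawaiian islands sit in cold water), so
#' they are never allowed in the same model: set A contains every
#' subset of {human metric, productivity, minimum SST, complexity} and
#' set B every subset of {human metric, productivity, reef area,
#' complexity}, each including the null (intercept-only) model.
#'
#' @param human Name of the human-effect covariate (default
#'   `"humans_200km"`).
#' @param available Covariate names actually available; candidates are
#'   intersected with this set.
#' @return A list with elements `A` and `B`, each a list of character
#'   vectors (the null model is `character(0)`).
#' @export
build_model_sets <- function(human = "humans_200km",
                             available = c(human, "productivity",
                                           "min_sst", "reef_area_km2",
                                           "mean_complexity")) {
  pool_A <- intersect(c(human, "productivity", "min_sst",
                        "mean_complexity"), available)
  pool_B <- intersect(c(human, "productivity", "reef_area_km2",
                        "mean_complexity"), available)
  subsets <- function(pool) {
    n <- length(pool)
    out <- list(character(0))
    if (n == 0) return(out)
    for (k in seq_len(n)) {
      cmb <- utils::combn(pool, k, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  list(A = subsets(pool_A), B = subsets(pool_B))
}
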