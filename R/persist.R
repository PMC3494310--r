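#' Persist a fitted model's draws to disk
#'
#' Writes one CSV per chain (`chain1.csv`, `chain2.csv`, ... with an
#' `iteration` column plus one column per parameter, full double
#' precision) and a JSON manifest (`manifest.json`) recording the
#' model specification, seed, iteration counts and parameter names, so
#' a fit can be reloaded losslessly and its provenance audited.
#'
#' @param fit A `shark_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_fit()]
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "shark_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in seq_along(fit$draws)) {
    m <- fit$draws[[ch]]
    df <- data.frame(iteration = seq_len(nrow(m)) + fit$n_burn, m,
                     check.names = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    parameters = colnames(fit$draws[[1]]),
    chains = fit$chains, n_iter = fit$n_iter, n_burn = fit$n_burn,
    seed = fit$seed,
    spec = list(covariates = fit$spec$covariates,
                link = fit$spec$link,
                selection = fit$spec$selection,
                weight_variance_by_n = fit$spec$weight_variance_by_n,
                priors = unclass(fit$spec$priors)),
    islands = fit$data$islands, n_i = fit$data$n_i,
    acceptance = fit$acceptance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a persisted fit
#'
#' Rebuilds the draw matrices and model specification from the files
#' written by [write_fit()]. The attached data are limited to what the
#' manifest records (island ids and tow counts); refitting or
#' posterior prediction against new data requires the original tables.
#'
#' @param dir Directory written by [write_fit()].
#' @return A `shark_fit` whose draws equal the persisted ones.
#' @export
read_fit <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  draws <- lapply(seq_len(mf$chains), function(ch) {
    df <- utils::read.csv(file.path(dir, sprintf("chain%d.csv", ch)),
                          check.names = FALSE)
    as.matrix(df[, setdiff(names(df), "iteration"), drop = FALSE])
  })
  pr <- do.call(prior_spec, as.list(mf$spec$priors))
  covs <- if (is.null(mf$spec$covariates)) character(0)
          else mf$spec$covariates
  sp <- model_spec(covs, link = mf$spec$link,
                   priors = pr, selection = mf$spec$selection,
                   weight_variance_by_n = mf$spec$weight_variance_by_n)
  structure(list(draws = draws, acceptance = mf$acceptance, spec = sp,
                 data = list(islands = mf$islands, n_i = mf$n_i),
                 n_iter = mf$n_iter, n_burn = mf$n_burn,
                 chains = mf$chains, seed = mf$seed),
            class = "shark_fit")
}
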