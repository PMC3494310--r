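# Shared fixture builders for the test suite. Everything is generated in
# code; MCMC fits reused across files are cached as RDS in tempdir() so a
# full test run pays for each fit once.

tiny_tow_table <- function() {
  validate_tow_table(data.frame(
    tow_id = c("t1", "t2", "t3"),
    island_id = c("A", "A", "B"),
    year = c(2005L, 2007L, 2010L),
    habitat = "forereef",
    length_km = c(2.0, 2.5, 1.8),
    width_m = 10,
    complexity = c(3L, 4L, 2L),
    gray = c(2L, 0L, 5L), whitetip = c(1L, 0L, 0L),
    blacktip = c(0L, 0L, 1L), galapagos = c(0L, 0L, 0L),
    nurse = c(0L, 1L, 0L),
    stringsAsFactors = FALSE))
}

toy_design <- function(X) {
  # wrap an already-standardized matrix as a design_matrix
  cols <- colnames(X)
  meta <- lapply(cols, function(cc)
    list(log = FALSE, offset = 0, mean = 0, sd = 1))
  names(meta) <- cols
  structure(list(island_ids = rownames(X), columns = cols, X = X,
                 transform_meta = meta),
            class = "design_matrix")
}

cached <- function(name, expr) {
  path <- file.path(tempdir(), paste0("sharkbaseline-test-", name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

# A mid-sized fitted model shared by selection / baseline tests.
demo_fit <- function() {
  cached("demo-fit", {
    sim <- simulate_survey(seed = 101)
    cnt <- group_counts(sim$tows, species_group("all_reef_sharks"))
    covs <- c("humans_200km", "productivity", "min_sst")
    dat <- build_model_data(cnt, sim$design, covariates = covs)
    fit <- run_mcmc(dat, model_spec(covs), n_iter = 6000, n_burn = 1500,
                    chains = 2, seed = 11)
    list(sim = sim, counts = cnt, fit = fit)
  })
}

# Fabricated posterior with hand-chosen draws, for exact-arithmetic tests
# of weight counting, baselines and doubling increments.
fake_fit <- function(draw_df, covs, design, data, link = "identity",
                     selection = TRUE) {
  sp <- model_spec(covs, link = link, selection = selection)
  m <- as.matrix(draw_df)
  structure(list(draws = list(m), acceptance = list(), spec = sp,
                 data = data, n_iter = nrow(m), n_burn = 0, chains = 1,
                 seed = 0),
            class = "shark_fit")
}
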