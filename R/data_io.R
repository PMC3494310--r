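#' @useDynLib sharkbaseline, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median qnorm pnorm dnorm rnorm runif sd quantile
#'   cor lm.fit rnbinom rmultinom var dnbinom setNames
#' @importFrom utils read.csv write.csv head
NULL

## Species codes used throughout. The five reef-associated species form the
## pooled "all reef sharks" group; tiger and hammerhead sharks range beyond
## reefs and are never modeled.
REEF_SPECIES <- c("gray", "whitetip", "blacktip", "galapagos", "nurse")
EXCLUDED_SPECIES <- c("tiger", "hammerhead")

REGIONS <- c("MHI", "NWHI", "Mariana", "AmSamoa", "PRIA")
HABITATS <- c("forereef", "backreef", "lagoon")

COVARIATE_COLS <- c("humans_200km", "humans_per_km2_reef",
                    "dist_pop_center_km", "productivity", "min_sst",
                    "reef_area_km2")

#' Define a shark species group
#'
#' Returns the species codes belonging to one of the modeled groups:
#' the pooled all-reef-sharks group (gray reef, whitetip reef, blacktip
#' reef, Galapagos and tawny nurse sharks) or a single focal species.
#' Tiger and hammerhead sharks are never members of any group.
#'
#' @param name One of `"all_reef_sharks"`, `"gray_reef"`, `"whitetip_reef"`.
#' @return An object of class `species_group`: a list with `name` and
#'   `member_codes`.
#' @examples
#' species_group("all_reef_sharks")$member_codes
#' @export
species_group <- function(name = c("all_reef_sharks", "gray_reef",
                                   "whitetip_reef")) {
  name <- match.arg(name)
  codes <- switch(name,
    all_reef_sharks = REEF_SPECIES,
    gray_reef = "gray",
    whitetip_reef = "whitetip")
  structure(list(name = name, member_codes = codes),
            class = "species_group")
}

#' Read a tow-survey table
#'
#' Reads a comma-delimited table with one row per towed-diver survey and
#' validates it: required columns present, counts non-negative integers,
#' complexity on the 1-6 visual scale, habitat one of
#' forereef/backreef/lagoon. The surveyed area in hectares is always
#' recomputed as `length_km * width_m / 10`; if the file carries an
#' `area_ha` column it is cross-checked against the recomputed value at
#' 1% relative tolerance and the recomputed value wins.
#'
#' @param path Path to a CSV file with columns `tow_id`, `island_id`,
#'   `year`, `habitat`, `length_km`, `width_m`, `complexity`, and one
#'   column per species code.
#' @param species Character vector of species-count columns expected in
#'   the file. Columns in this list that are absent are filled with 0
#'   (tow surveys record every individual over 50 cm, so absence of a
#'   code means none were seen).
#' @return A `data.frame` with one row per tow, the species-count
#'   columns coerced to integer, and a recomputed `area_ha` column.
#' @export
read_tow_table <- function(path, species = REEF_SPECIES) {
  if (!file.exists(path)) stop("tow table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tow_id", "island_id", "year", "habitat", "length_km",
                "width_m", "complexity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("tow table is missing required column(s): ",
         paste(missing, collapse = ", "))
  validate_tow_table(df, species = species)
}

#' @rdname read_tow_table
#' @param df A data frame already in memory with the tow-table schema.
#' @export
validate_tow_table <- function(df, species = REEF_SPECIES) {
  for (sp in species) {
    if (!sp %in% names(df)) {
      df[[sp]] <- 0L
      next
    }
    v <- df[[sp]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0)
      stop("invalid count in column '", sp, "' at row ", bad[1],
           ": counts must be non-negative integers")
    df[[sp]] <- as.integer(v)
  }
  if (any(!df$habitat %in% HABITATS))
    stop("unknown habitat value(s): ",
         paste(unique(setdiff(df$habitat, HABITATS)), collapse = ", "))
  if (any(df$length_km <= 0)) stop("length_km must be positive")
  if (any(df$width_m <= 0)) stop("width_m must be positive")
  bad_cx <- which(!(df$complexity %in% 1:6))
  if (length(bad_cx) > 0)
    stop("complexity must be an integer in 1..6 (row ", bad_cx[1], ")")
  area <- df$length_km * df$width_m / 10
  if ("area_ha" %in% names(df)) {
    rel <- abs(df$area_ha - area) / pmax(area, .Machine$double.eps)
    if (any(rel > 0.01))
      warning("stored area_ha deviates >1% from length*width at row ",
              which(rel > 0.01)[1], "; recomputed value used")
  }
  df$area_ha <- area
  df$year <- as.integer(df$year)
  df
}

#' Write a tow-survey table
#'
#' Inverse of [read_tow_table()]; the written file round-trips losslessly
#' at printed precision (15 significant digits).
#'
#' @param df Validated tow table.
#' @param path Output CSV path.
#' @export
write_tow_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an island-covariate table
#'
#' One row per island: region label plus the six island-level
#' covariates (humans within 200 km, humans per km^2 of reef, distance
#' to nearest population center, oceanic primary productivity, minimum
#' monthly sea-surface temperature, reef area).
#'
#' @param path Path to a CSV with columns `island_id`, `region`, and the
#'   covariates above.
#' @return A validated `data.frame`, one row per island.
#' @export
read_island_table <- function(path) {
  if (!file.exists(path)) stop("island table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("island_id", "region", COVARIATE_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("island table is missing required column(s): ",
         paste(missing, collapse = ", "))
  validate_island_table(df)
}

#' @rdname read_island_table
#' @param df An island table already in memory.
#' @export
validate_island_table <- function(df) {
  if (anyDuplicated(df$island_id))
    stop("duplicated island_id: ",
         df$island_id[duplicated(df$island_id)][1])
  if (any(!df$region %in% REGIONS))
    stop("unknown region label(s): ",
         paste(unique(setdiff(df$region, REGIONS)), collapse = ", "))
  num <- COVARIATE_COLS
  for (cc in num) {
    if (any(!is.finite(df[[cc]])))
      stop("non-finite value in covariate '", cc, "'")
  }
  if (any(df$humans_200km < 0)) stop("humans_200km must be >= 0")
  if (any(df$dist_pop_center_km <= 0)) stop("dist_pop_center_km must be > 0")
  if (any(df$productivity <= 0)) stop("productivity must be > 0")
  if (any(df$reef_area_km2 <= 0)) stop("reef_area_km2 must be > 0")
  df
}

#' @rdname read_island_table
#' @export
write_island_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the survey exclusion rules
#'
#' Keeps only tows that pass, in order: the year window (the early
#' 2000-2003 surveys used a different observer pool), the minimum tow
#' length (tows under 1 km indicate an anomalous dive), and the habitat
#' stratum (back reefs and lagoons are absent from most islands, so only
#' forereef surveys are analyzed). A tow is counted against the first
#' rule it violates.
#'
#' @param df Validated tow table.
#' @param min_year,max_year Calendar-year window (defaults 2004-2010).
#' @param min_length_km Minimum tow length in km (default 1).
#' @param habitat Habitat stratum retained (default `"forereef"`).
#' @return A list with `kept` (the filtered table) and `excluded`, a
#'   named list of counts per rule (`year`, `short_tow`, `habitat`).
#' @export
filter_tows <- function(df, min_year = 2004, max_year = 2010,
                        min_length_km = 1, habitat = "forereef") {
  fail_year <- df$year < min_year | df$year > max_year
  fail_len <- !fail_year & df$length_km < min_length_km
  fail_hab <- !fail_year & !fail_len & df$habitat != habitat
  keep <- !(fail_year | fail_len | fail_hab)
  list(kept = df[keep, , drop = FALSE],
       excluded = list(year = sum(fail_year),
                       short_tow = sum(fail_len),
                       habitat = sum(fail_hab)))
}

#' Pool counts over a species group
#'
#' @param df Validated tow table.
#' @param group A [species_group()].
#' @return A `data.frame` with `tow_id`, `island_id`, `area_ha` and the
#'   pooled count `y`, one row per input tow.
#' @export
group_counts <- function(df, group) {
  stopifnot(inherits(group, "species_group"))
  unknown <- setdiff(group$member_codes, names(df))
  if (length(unknown) > 0)
    stop("species code(s) not in tow table: ",
         paste(unknown, collapse = ", "))
  y <- as.integer(rowSums(df[, group$member_codes, drop = FALSE]))
  data.frame(tow_id = df$tow_id, island_id = df$island_id,
             area_ha = df$area_ha, y = y, stringsAsFactors = FALSE)
}

#' Regional summary of surveys, covariates and shark totals
#'
#' Per region: number of reefs surveyed, number of surveys, min-max
#' range of each covariate, and the total count of each shark species;
#' a final `Total` row carries grand totals.
#'
#' @param tows Validated tow table.
#' @param islands Validated island table covering every `island_id` in
#'   `tows`.
#' @param species Species-count columns to total.
#' @return A `data.frame` with one row per region plus a `Total` row.
#' @export
summarize_by_region <- function(tows, islands, species = REEF_SPECIES) {
  orphan <- setdiff(tows$island_id, islands$island_id)
  if (length(orphan) > 0)
    stop("tow island_id absent from island table: ", orphan[1])
  tows$region <- islands$region[match(tows$island_id, islands$island_id)]
  regions <- intersect(REGIONS, unique(tows$region))
  rows <- lapply(regions, function(rg) {
    tw <- tows[tows$region == rg, , drop = FALSE]
    isl <- islands[islands$region == rg &
                     islands$island_id %in% tw$island_id, , drop = FALSE]
    rng <- function(v) paste0(format(min(v), trim = TRUE), "-",
                              format(max(v), trim = TRUE))
    out <- data.frame(region = rg,
                      n_reefs = length(unique(tw$island_id)),
                      n_surveys = nrow(tw),
                      humans_200km = rng(isl$humans_200km),
                      productivity = rng(isl$productivity),
                      min_sst = rng(isl$min_sst),
                      reef_area_km2 = rng(isl$reef_area_km2),
                      stringsAsFactors = FALSE)
    for (sp in species) out[[sp]] <- sum(tw[[sp]])
    out
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(region = "Total",
                    n_reefs = sum(out$n_reefs),
                    n_surveys = sum(out$n_surveys),
                    humans_200km = "", productivity = "", min_sst = "",
                    reef_area_km2 = "", stringsAsFactors = FALSE)
  for (sp in species) tot[[sp]] <- sum(out[[sp]])
  out <- rbind(out, tot)
  out$total_sharks <- as.integer(rowSums(out[, species, drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Island means of the tow complexity score
#'
#' Divers score reef physical complexity per tow on a 1-6 visual scale;
#' the island-level covariate is the arithmetic mean of the scores over
#' the retained tows (an ordinal score used as a continuous covariate).
#'
#' @param tows Validated (and typically filtered) tow table.
#' @return Named numeric vector of mean complexity per island.
#' @export
island_mean_complexity <- function(tows) {
  tapply(tows$complexity, tows$island_id, mean)
}
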