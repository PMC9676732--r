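# Reading, validation and normalization of the five input tables and the
# cancer-site grouping. All readers take delimited UTF-8 CSV with a header
# row and return validated tibbles on a shared country_id vocabulary.

#' Read the cancer-site vocabulary and reporting-group map
#'
#' The vocabulary comprises 35 exhaustive, mutually exclusive topographical
#' site labels; each maps to exactly one of 14 reporting groups (Breast,
#' Cervical, Upper gastrointestinal, ...). The default map ships with the
#' package and is an editable YAML file.
#'
#' @param path path to a YAML file with a top-level `groups:` mapping of group
#'   label to a list of site labels. `NULL` uses the packaged default.
#' @return a list with elements `sites` (character vector of site labels),
#'   `map` (named character vector, site -> group) and `group_names`.
#' @export
read_site_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "site_groups.yaml", package = "canorphans")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("site-group file lacks a 'groups' mapping", call. = FALSE)
  map <- unlist(lapply(names(cfg$groups), function(g) {
    setNames(rep(g, length(cfg$groups[[g]])), unlist(cfg$groups[[g]]))
  }))
  dup <- names(map)[duplicated(names(map))]
  if (length(dup)) {
    stop("site(s) mapped to more than one group: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  list(sites = names(map), map = map, group_names = names(cfg$groups))
}

# check that every site in `sites` is covered by the map (totality)
check_site_group_totality <- function(site_groups, sites) {
  missing <- setdiff(sites, names(site_groups$map))
  if (length(missing)) {
    stop("site-group map missing site(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

read_csv_checked <- function(path, required) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error: ", basename(path), " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a female cancer-death table
#'
#' Expects columns `country_id`, `site`, `age_group`, `deaths`: female cancer
#' deaths in a single reference year by country, topographical site and
#' 5-year age group (0-4, 5-9, ..., 85+).
#'
#' @param path CSV path.
#' @param year the calendar year the deaths refer to.
#' @param site_groups site vocabulary (from [read_site_groups()]) used to
#'   validate the `site` labels; `NULL` skips the vocabulary check.
#' @return tibble with columns `country_id`, `site`, `age_group` (canonical),
#'   `deaths`, `year`.
#' @export
read_death_table <- function(path, year, site_groups = read_site_groups()) {
  df <- read_csv_checked(path, c("country_id", "site", "age_group", "deaths"))
  df$age_group <- canonicalize_band(df$age_group)
  if (any(is.na(df$deaths)) || any(df$deaths < 0)) {
    stop("validation error: negative or missing deaths", call. = FALSE)
  }
  if (!is.null(site_groups)) {
    unknown <- setdiff(unique(df$site), site_groups$sites)
    if (length(unknown)) {
      stop("validation error: unknown site label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  # bands must not overlap within a (country, site); absent bands mean zero
  ov <- df |>
    dplyr::mutate(lo = band_lo(.data$age_group), hi = band_hi(.data$age_group)) |>
    dplyr::arrange(.data$lo) |>
    dplyr::summarise(overlap = dplyr::n() > 1L &&
                       any(.data$lo[-1] <= .data$hi[-dplyr::n()]),
                     .by = c("country_id", "site")) |>
    dplyr::filter(.data$overlap)
  if (nrow(ov)) {
    stop("validation error: overlapping or duplicated age bands for ",
         ov$country_id[1], "/", ov$site[1], call. = FALSE)
  }
  tibble::tibble(
    country_id = as.character(df$country_id),
    site = as.character(df$site),
    age_group = df$age_group,
    deaths = as.numeric(df$deaths),
    year = as.integer(year)
  )
}

#' Write a death table back to CSV
#'
#' Inverse of [read_death_table()]; deaths round-trip bit-exactly.
#' @param dt a death table tibble.
#' @param path output CSV path.
#' @export
write_death_table <- function(dt, path) {
  readr::write_csv(dt[, c("country_id", "site", "age_group", "deaths")], path)
  invisible(path)
}

# parse "2010-2014" period labels into start/end integers
parse_period <- function(period) {
  period <- canonicalize_band(period)
  tibble::tibble(period = period,
                 period_start = band_lo(period),
                 period_end = band_hi(period))
}

#' Read a cohort fertility schedule
#'
#' Expects columns `country_id`, `age_group` (5-year bands within 15-49),
#' `period` (5-year calendar windows, e.g. `"2010-2014"`, running mid-year to
#' mid-year) and `rate_per_1000` (births per 1,000 women per year). Rates are
#' converted to per-woman on read. Periods must tile at least 2000-2019
#' without gaps; fertility is implicitly zero outside ages 15-49.
#'
#' @param path CSV path.
#' @return tibble with `country_id`, `age_group`, `period`, `period_start`,
#'   `period_end`, `rate` (per woman per year).
#' @export
read_fertility_table <- function(path) {
  df <- read_csv_checked(path, c("country_id", "age_group", "period", "rate_per_1000"))
  df$age_group <- canonicalize_band(df$age_group)
  if (any(is.na(df$rate_per_1000)) || any(df$rate_per_1000 < 0)) {
    stop("validation error: negative or missing fertility rate", call. = FALSE)
  }
  lo <- band_lo(df$age_group); hi <- band_hi(df$age_group)
  if (any(lo < 15L | hi > 49L)) {
    stop("validation error: fertility age band outside 15-49: ",
         paste(unique(df$age_group[lo < 15L | hi > 49L]), collapse = ", "),
         call. = FALSE)
  }
  pp <- parse_period(df$period)
  out <- tibble::tibble(
    country_id = as.character(df$country_id),
    age_group = df$age_group,
    period = pp$period,
    period_start = pp$period_start,
    period_end = pp$period_end,
    rate = df$rate_per_1000 / 1000
  )
  # periods must be 5-year, contiguous and cover 2000-2019 in every country
  per <- dplyr::distinct(out, .data$country_id, .data$period_start, .data$period_end)
  if (any(per$period_end - per$period_start != 4L)) {
    stop("validation error: fertility periods must span 5 calendar years",
         call. = FALSE)
  }
  cover <- per |>
    dplyr::summarise(
      ok = all(seq(2000L, 2019L) %in%
                 unlist(Map(seq, .data$period_start, .data$period_end))) &&
        !anyDuplicated(unlist(Map(seq, .data$period_start, .data$period_end))),
      .by = "country_id")
  if (any(!cover$ok)) {
    stop("validation error: fertility periods do not tile 2000-2019 for ",
         paste(cover$country_id[!cover$ok], collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a child mortality table
#'
#' Expects columns `country_id`, `age`, `year`, `hazard` with single ages
#' 0-17 (deaths per person-year). Ages supplied as 5-year band labels are
#' expanded by constant repetition across the single ages they cover.
#' The grid must be complete over ages 0-17 for every year present.
#'
#' @param path CSV path.
#' @param years years required to be present (default 2002-2020).
#' @return tibble with `country_id`, `age` (integer), `year`, `hazard`.
#' @export
read_child_mortality <- function(path, years = 2002:2020) {
  df <- read_csv_checked(path, c("country_id", "age", "year", "hazard"))
  if (any(is.na(df$hazard)) || any(df$hazard < 0)) {
    stop("validation error: negative or missing hazard", call. = FALSE)
  }
  if (!is.numeric(df$age)) {
    # band labels: expand by repetition within the band, clipped to 0-17
    band <- canonicalize_band(df$age)
    lo <- band_lo(band); hi <- pmin(band_hi(band), 17L)
    keep <- lo <= 17L
    df <- df[keep, ]; lo <- lo[keep]; hi <- hi[keep]
    reps <- hi - lo + 1L
    df <- df[rep(seq_len(nrow(df)), reps), ]
    df$age <- unlist(Map(seq, lo, hi))
  }
  out <- tibble::tibble(
    country_id = as.character(df$country_id),
    age = as.integer(df$age),
    year = as.integer(df$year),
    hazard = as.numeric(df$hazard)
  )
  grid <- tidyr::expand_grid(age = 0:17, year = as.integer(years))
  miss <- out |>
    dplyr::distinct(.data$country_id) |>
    tidyr::expand_grid(grid) |>
    dplyr::anti_join(out, by = c("country_id", "age", "year"))
  if (nrow(miss)) {
    stop("validation error: child-mortality grid missing cells, e.g. (age ",
         miss$age[1], ", year ", miss$year[1], ") for ", miss$country_id[1],
         "; ", nrow(miss), " cell(s) missing in total", call. = FALSE)
  }
  out
}

#' Read a population table
#'
#' Expects columns `country_id`, `sex` (`female` or `both`), `age_group`,
#' `year`, `count`. Female counts feed the historic-death reconstruction;
#' both-sex child counts (band `"0-17"` at the reference year) feed the
#' per-100,000-children rates.
#'
#' @param path CSV path.
#' @return tibble with those columns, bands canonicalized.
#' @export
read_population <- function(path) {
  df <- read_csv_checked(path, c("country_id", "sex", "age_group", "year", "count"))
  if (any(is.na(df$count)) || any(df$count < 0)) {
    stop("validation error: negative or missing population count", call. = FALSE)
  }
  if (!all(df$sex %in% c("female", "both"))) {
    stop("validation error: sex must be 'female' or 'both'", call. = FALSE)
  }
  tibble::tibble(
    country_id = as.character(df$country_id),
    sex = as.character(df$sex),
    age_group = canonicalize_band(df$age_group),
    year = as.integer(df$year),
    count = as.numeric(df$count)
  )
}

#' Human Development Index category from its value
#'
#' Fixed cut points: low (<0.55), medium (0.55-0.69), high (0.70-0.79) and
#' very high (0.8-1.0); missing values map to `"missing"`.
#'
#' @param hdi numeric vector in \[0, 1\] (NA allowed).
#' @return character vector of categories.
#' @export
hdi_category <- function(hdi) {
  out <- rep("missing", length(hdi))
  ok <- !is.na(hdi)
  out[ok & hdi < 0.55] <- "low"
  out[ok & hdi >= 0.55 & hdi < 0.70] <- "medium"
  out[ok & hdi >= 0.70 & hdi < 0.80] <- "high"
  out[ok & hdi >= 0.80] <- "very_high"
  out
}

#' Read country metadata
#'
#' Expects columns `country_id`, `name`, `region`, `subregion`, `hdi` (the
#' HDI value, may be empty). The HDI category is recomputed from the value.
#'
#' @param path CSV path.
#' @return tibble with `country_id`, `name`, `region`, `subregion`, `hdi`,
#'   `hdi_category`.
#' @export
read_country_meta <- function(path) {
  df <- read_csv_checked(path, c("country_id", "name", "region", "subregion", "hdi"))
  if (any(!nzchar(df$region)) || any(!nzchar(df$subregion))) {
    stop("validation error: empty region/subregion", call. = FALSE)
  }
  hdi <- suppressWarnings(as.numeric(df$hdi))
  if (any(!is.na(hdi) & (hdi < 0 | hdi > 1))) {
    stop("validation error: HDI outside [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    country_id = as.character(df$country_id),
    name = as.character(df$name),
    region = as.character(df$region),
    subregion = as.character(df$subregion),
    hdi = hdi,
    hdi_category = hdi_category(hdi)
  )
}

#' Assemble the validated table bundle
#'
#' Restricts all member tables to the intersection of their country sets,
#' attaches the site-group map and a validation report listing any dropped
#' countries. The site-group map must cover every site present in the death
#' table.
#'
#' @param deaths,fertility,child_mortality,population,country_meta tables as
#'   returned by the corresponding readers.
#' @param site_groups site vocabulary/grouping from [read_site_groups()].
#' @return an object of class `world_bundle`: a list with the six members and
#'   a `report` element.
#' @export
assemble_bundle <- function(deaths, fertility, child_mortality, population,
                            country_meta, site_groups = read_site_groups()) {
  check_site_group_totality(site_groups, unique(deaths$site))
  sets <- list(deaths = unique(deaths$country_id),
               fertility = unique(fertility$country_id),
               child_mortality = unique(child_mortality$country_id),
               population = unique(population$country_id),
               country_meta = unique(country_meta$country_id))
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("empty country intersection across tables", call. = FALSE)
  dropped <- lapply(sets, setdiff, y = common)
  keep <- function(df) df[df$country_id %in% common, , drop = FALSE]
  structure(
    list(deaths = keep(deaths),
         fertility = keep(fertility),
         child_mortality = keep(child_mortality),
         population = keep(population),
         country_meta = keep(country_meta),
         site_groups = site_groups,
         report = list(countries = sort(common),
                       n_countries = length(common),
                       dropped = dropped[vapply(dropped, length, 1L) > 0])),
    class = "world_bundle"
  )
}

#' @export
print.world_bundle <- function(x, ...) {
  cat("<world_bundle> ", x$report$n_countries, " countries, ",
      dplyr::n_distinct(x$deaths$site), " cancer sites, reference year ",
      x$deaths$year[1], "\n", sep = "")
  if (length(x$report$dropped)) {
    for (nm in names(x$report$dropped)) {
      cat("  dropped (", nm, "): ",
          paste(x$report$dropped[[nm]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write the bundle validation report as JSON
#'
#' @param bundle a `world_bundle`.
#' @param path output JSON path.
#' @export
write_validation_report <- function(bundle, path) {
  jsonlite::write_json(bundle$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
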