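# Aggregation of orphan arrays to summary statistics: orphans per 100 female
# cancer deaths, per 100,000 children, child-age distributions at the
# mid-period ages, mean ages, and country/region/HDI/site-group summary
# tables. Ratios for aggregates are always ratio-of-sums (aggregated
# numerator over aggregated denominator), never means of member ratios.
# Stored values are full precision; display rounding is a formatting step.

#' Orphans per 100 female cancer deaths
#'
#' @param orphans orphan count(s).
#' @param deaths female cancer death count(s) (all ages).
#' @return `100 * orphans / deaths`; `NA` where `deaths` is zero.
#' @export
per_100_deaths <- function(orphans, deaths) {
  ifelse(deaths > 0, 100 * orphans / deaths, NA_real_)
}

#' Orphans per 100,000 children
#'
#' @param orphans orphan count(s).
#' @param children both-sex population aged 0-17 at mid-reference-year.
#' @return `1e5 * orphans / children`; `NA` where `children` is zero.
#' @export
per_100k_children <- function(orphans, children) {
  ifelse(children > 0, 1e5 * orphans / children, NA_real_)
}

#' Round for table display
#'
#' Display-only rounding used by the published-table dialect (ratios to the
#' nearest integer, percentages to one decimal). Stored values remain full
#' precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @param nearest round to a multiple (e.g. 1000 for text-style rounding);
#'   overrides `digits`.
#' @return rounded numeric vector.
#' @export
display_round <- function(x, digits = 0, nearest = NULL) {
  if (!is.null(nearest)) return(round(x / nearest) * nearest)
  round(x, digits)
}

# value column of an orphan array or prevalence result
value_col <- function(arr) {
  if ("expected_orphans" %in% names(arr)) "expected_orphans" else "prevalent_orphans"
}

# child age bin from birth year under the mid-period convention
# (age at ref = ref - y - 0.5): <5, 5-9, 10-17
age_bin <- function(birth_year, ref_year) {
  dplyr::case_when(
    birth_year >= ref_year - 5L ~ "u5",
    birth_year >= ref_year - 10L ~ "a5_9",
    birth_year >= ref_year - 18L ~ "a10_17",
    TRUE ~ NA_character_
  )
}

#' Child-age distribution of an orphan array
#'
#' Percentage shares of orphans whose age at the reference year (mid-period
#' convention, `ref - birth_year - 0.5`) falls under 5, in 5-9, and in 10-17.
#' Shares sum to 100 before any rounding; a zero total yields `NA` shares.
#'
#' @param arr an `orphan_array` or `prevalence_result`.
#' @param by optional character vector of grouping columns (e.g.
#'   `"country_id"`); `NULL` for the whole array.
#' @param ref_year reference year; defaults to the array's attribute.
#' @return tibble with the grouping columns and `share_u5`, `share_5_9`,
#'   `share_10_17`.
#' @export
age_distribution <- function(arr, by = NULL, ref_year = attr(arr, "ref_year")) {
  v <- value_col(arr)
  df <- tibble::as_tibble(arr)
  df$bin <- age_bin(df$birth_year, ref_year)
  out <- df |>
    dplyr::summarise(
      total = sum(.data[[v]]),
      u5 = sum(.data[[v]][.data$bin == "u5"]),
      a5_9 = sum(.data[[v]][.data$bin == "a5_9"]),
      a10_17 = sum(.data[[v]][.data$bin == "a10_17"]),
      .by = dplyr::all_of(by)
    )
  out |>
    dplyr::mutate(
      share_u5 = ifelse(.data$total > 0, 100 * .data$u5 / .data$total, NA_real_),
      share_5_9 = ifelse(.data$total > 0, 100 * .data$a5_9 / .data$total, NA_real_),
      share_10_17 = ifelse(.data$total > 0, 100 * .data$a10_17 / .data$total, NA_real_)
    ) |>
    dplyr::select(dplyr::all_of(by), "share_u5", "share_5_9", "share_10_17")
}

#' Mean age at orphaning
#'
#' Orphan-weighted mean of the mid-period child ages
#' (`ref - birth_year - 0.5`, i.e. 0.5, 1.5, ..., 17.5).
#'
#' @param arr an `orphan_array` or `prevalence_result`.
#' @param ref_year reference year; defaults to the array's attribute.
#' @return mean age in years (`NA` for an empty array).
#' @export
mean_age_at_orphaning <- function(arr, ref_year = attr(arr, "ref_year")) {
  v <- value_col(arr)
  w <- arr[[v]]
  if (!length(w) || sum(w) == 0) return(NA_real_)
  ages <- ref_year - arr$birth_year - 0.5
  sum(w * ages) / sum(w)
}

#' Deaths-weighted average age at cancer death
#'
#' Weighted mean of single ges at death restricted to an age range
#' (default 15-69, the ages whose children can still be minors).
#'
#' @param single_age_deaths tibble from [split_deaths_single_age()].
#' @param age_range inclusive age range.
#' @return mean age in years (`NA` when no deaths fall in the range).
#' @export
avg_age_at_death <- function(single_age_deaths, age_range = c(15, 69)) {
  d <- single_age_deaths[single_age_deaths$md >= age_range[1] &
                           single_age_deaths$md <= age_range[2], ]
  if (!nrow(d) || sum(d$deaths) == 0) return(NA_real_)
  sum(d$deaths * d$md) / sum(d$deaths)
}

# map countries to aggregation units for a given level
unit_key <- function(bundle, level) {
  meta <- bundle$country_meta
  switch(level,
    country = tibble::tibble(country_id = meta$country_id, unit = meta$country_id),
    subregion = tibble::tibble(country_id = meta$country_id, unit = meta$subregion),
    region = tibble::tibble(country_id = meta$country_id, unit = meta$region),
    world = tibble::tibble(country_id = meta$country_id, unit = "World"),
    hdi = tibble::tibble(country_id = meta$country_id, unit = meta$hdi_category)
  )
}

#' Summary table of new (and optionally prevalent) orphans
#'
#' Aggregates an orphan array to the published-table shape: female cancer
#' deaths, average age at cancer death (15-69), new orphans, percent of the
#' world total, orphans per 100 deaths and per 100,000 children, child-age
#' shares, mean age at orphaning, and (when supplied) the prevalent
#' counterparts. Ratios are recomputed from aggregated numerators and
#' denominators. At the `hdi` level, countries without an HDI value are
#' excluded and their count recorded in the `n_excluded` attribute.
#'
#' @param bundle a `world_bundle`.
#' @param new_arr an `orphan_array` from [estimate_new_orphans()].
#' @param prev_arr optional `prevalence_result`.
#' @param level one of `"country"`, `"subregion"`, `"region"`, `"world"`,
#'   `"hdi"`, `"site_group"`.
#' @param ref_year reference year; defaults to the array's attribute.
#' @return a tibble of summary rows.
#' @export
orphan_summary <- function(bundle, new_arr, prev_arr = NULL,
                           level = c("country", "subregion", "region",
                                     "world", "hdi", "site_group"),
                           ref_year = attr(new_arr, "ref_year")) {
  level <- match.arg(level)
  sad <- split_deaths_single_age(bundle$deaths)
  child_pop <- bundle$population |>
    dplyr::filter(.data$sex == "both", .data$age_group == "0-17",
                  .data$year == ref_year) |>
    dplyr::select("country_id", children = "count")
  world_new <- sum(new_arr$expected_orphans)

  if (level == "site_group") {
    map <- bundle$site_groups$map
    key <- tibble::tibble(site = names(map), unit = unname(map))
    world_children <- sum(child_pop$children)
    deaths_u <- bundle$deaths |>
      dplyr::left_join(key, by = "site") |>
      dplyr::summarise(deaths = sum(.data$deaths), .by = "unit")
    age_u <- sad |>
      dplyr::left_join(key, by = "site") |>
      dplyr::filter(.data$md >= 15, .data$md <= 69) |>
      dplyr::summarise(avg_age_at_death_15_69 = sum(.data$deaths * .data$md) /
                         sum(.data$deaths), .by = "unit")
    arr_u <- tibble::as_tibble(new_arr) |>
      dplyr::left_join(key, by = "site")
    new_u <- arr_u |>
      dplyr::summarise(new_orphans = sum(.data$expected_orphans), .by = "unit")
    shares <- age_distribution(structure(arr_u, ref_year = ref_year,
                                         class = class(new_arr)),
                               by = "unit", ref_year = ref_year)
    ages <- arr_u |>
      dplyr::summarise(mean_age_at_orphaning = sum(
        .data$expected_orphans * (ref_year - .data$birth_year - 0.5)) /
          sum(.data$expected_orphans), .by = "unit")
    out <- deaths_u |>
      dplyr::left_join(age_u, by = "unit") |>
      dplyr::left_join(new_u, by = "unit") |>
      dplyr::left_join(shares, by = "unit") |>
      dplyr::left_join(ages, by = "unit") |>
      dplyr::mutate(
        pct_of_total = 100 * .data$new_orphans / world_new,
        per_100_deaths = per_100_deaths(.data$new_orphans, .data$deaths),
        per_100k_children = per_100k_children(.data$new_orphans, world_children)
      )
    if (!is.null(prev_arr)) {
      prev_u <- tibble::as_tibble(prev_arr) |>
        dplyr::left_join(key, by = "site") |>
        dplyr::summarise(prevalent_orphans = sum(.data$prevalent_orphans),
                         .by = "unit")
      pshares <- age_distribution(prev_arr |>
                                    dplyr::left_join(key, by = "site"),
                                  by = "unit", ref_year = ref_year) |>
        dplyr::rename(prev_share_u5 = "share_u5", prev_share_5_9 = "share_5_9",
                      prev_share_10_17 = "share_10_17")
      out <- out |>
        dplyr::left_join(prev_u, by = "unit") |>
        dplyr::left_join(pshares, by = "unit") |>
        dplyr::mutate(prevalent_per_100k =
                        per_100k_children(.data$prevalent_orphans, world_children))
    }
    return(dplyr::arrange(out, dplyr::desc(.data$new_orphans)))
  }

  key <- unit_key(bundle, level)
  n_excluded <- 0L
  if (level == "hdi") {
    n_excluded <- sum(key$unit == "missing")
    key <- key[key$unit != "missing", , drop = FALSE]
  }
  deaths_u <- bundle$deaths |>
    dplyr::inner_join(key, by = "country_id") |>
    dplyr::summarise(deaths = sum(.data$deaths), .by = "unit")
  age_u <- sad |>
    dplyr::inner_join(key, by = "country_id") |>
    dplyr::filter(.data$md >= 15, .data$md <= 69) |>
    dplyr::summarise(avg_age_at_death_15_69 = sum(.data$deaths * .data$md) /
                       sum(.data$deaths), .by = "unit")
  child_u <- child_pop |>
    dplyr::inner_join(key, by = "country_id") |>
    dplyr::summarise(children = sum(.data$children), .by = "unit")
  arr_u <- tibble::as_tibble(new_arr) |>
    dplyr::inner_join(key, by = "country_id")
  new_u <- arr_u |>
    dplyr::summarise(new_orphans = sum(.data$expected_orphans), .by = "unit")
  shares <- age_distribution(structure(arr_u, ref_year = ref_year,
                                       class = class(new_arr)),
                             by = "unit", ref_year = ref_year)
  ages <- arr_u |>
    dplyr::summarise(mean_age_at_orphaning = sum(
      .data$expected_orphans * (ref_year - .data$birth_year - 0.5)) /
        sum(.data$expected_orphans), .by = "unit")
  out <- deaths_u |>
    dplyr::left_join(age_u, by = "unit") |>
    dplyr::left_join(new_u, by = "unit") |>
    dplyr::left_join(child_u, by = "unit") |>
    dplyr::left_join(shares, by = "unit") |>
    dplyr::left_join(ages, by = "unit") |>
    dplyr::mutate(
      pct_of_total = 100 * .data$new_orphans / world_new,
      per_100_deaths = per_100_deaths(.data$new_orphans, .data$deaths),
      per_100k_children = per_100k_children(.data$new_orphans, .data$children)
    )
  if (!is.null(prev_arr)) {
    prev_u <- tibble::as_tibble(prev_arr) |>
      dplyr::inner_join(key, by = "country_id") |>
      dplyr::summarise(prevalent_orphans = sum(.data$prevalent_orphans),
                       .by = "unit")
    pshares <- age_distribution(prev_arr |>
                                  dplyr::inner_join(key, by = "country_id"),
                                by = "unit", ref_year = ref_year) |>
      dplyr::rename(prev_share_u5 = "share_u5", prev_share_5_9 = "share_5_9",
                    prev_share_10_17 = "share_10_17")
    out <- out |>
      dplyr::left_join(prev_u, by = "unit") |>
      dplyr::left_join(pshares, by = "unit") |>
      dplyr::mutate(prevalent_per_100k =
                      per_100k_children(.data$prevalent_orphans, .data$children))
  }
  attr(out, "n_excluded") <- n_excluded
  dplyr::arrange(out, .data$unit)
}
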