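# Prevalent maternal orphans at mid-reference-year: historic female cancer
# deaths are reconstructed for yd = ref-17 .. ref-1 by applying trend
# multipliers to the reference-year age-specific mortality rates and the
# year-specific female population, then each death-year cohort's surviving,
# still-minor children are accumulated with excess child mortality (mrr)
# after the maternal death.

#' Mortality-rate-ratio scenario labels
#'
#' The fixed label -> value pairs for the excess mortality of bereaved
#' children: a = 1.25, b = 1.5, c = 2.0, d = 2.6, e = 1.0 (comparator).
#'
#' @return named numeric vector.
#' @export
mrr_values <- function() {
  c(a = 1.25, b = 1.5, c = 2.0, d = 2.6, e = 1.0)
}

#' Scenario configuration for the prevalence estimator
#'
#' @param trend one of `"S1"` (stable reference-year rates), `"S2"` (rates
#'   rising 1\%/year towards the reference year), `"S3"` (falling 1\%/year),
#'   `"S4"` (S2 for low/medium-HDI countries, S3 for high/very-high).
#' @param mrr one of the labels `"a"`-`"e"` (see [mrr_values()]).
#' @param include_ref_year_half if `TRUE`, adds half of the reference-year
#'   new-orphan array (children orphaned in the first half of the reference
#'   year and still under 18 at mid-year) to the prevalence.
#' @return a list of class `scenario_config` with `trend`, `mrr_label`,
#'   `mrr_value`, `include_ref_year_half`.
#' @export
scenario_config <- function(trend = "S1", mrr = "a",
                            include_ref_year_half = FALSE) {
  trend <- match.arg(trend, c("S1", "S2", "S3", "S4"))
  mrr <- match.arg(mrr, names(mrr_values()))
  structure(list(trend = trend, mrr_label = mrr,
                 mrr_value = unname(mrr_values()[mrr]),
                 include_ref_year_half = isTRUE(include_ref_year_half)),
            class = "scenario_config")
}

#' Trend multiplier on reference-year mortality rates
#'
#' S1 -> 1; S2 -> `0.99^(ref - yd)`; S3 -> `1.01^(ref - yd)`; S4 applies the
#' S2 rule to low/medium-HDI countries and the S3 rule to high/very-high-HDI
#' countries and errors when the HDI category is missing.
#'
#' @param trend scenario label `"S1"`-`"S4"`.
#' @param yd calendar year(s) the multiplier is for.
#' @param hdi_category country HDI category (required for S4).
#' @param ref_year reference year (default 2020).
#' @return numeric multiplier(s).
#' @export
trend_multiplier <- function(trend, yd, hdi_category = NULL, ref_year = 2020) {
  trend <- match.arg(trend, c("S1", "S2", "S3", "S4"))
  k <- ref_year - yd
  switch(trend,
    S1 = rep(1, length(yd)),
    S2 = 0.99^k,
    S3 = 1.01^k,
    S4 = {
      if (is.null(hdi_category) || any(is.na(hdi_category)) ||
          any(hdi_category == "missing")) {
        stop("S4 requires an HDI category", call. = FALSE)
      }
      ifelse(hdi_category %in% c("low", "medium"), 0.99^k, 1.01^k)
    })
}

# female population count per (country, band, year), as a lookup tibble
female_pop <- function(population, years) {
  population |>
    dplyr::filter(.data$sex == "female", .data$year %in% years) |>
    dplyr::select("country_id", "age_group", "year", "count")
}

#' Reconstruct the female cancer-death table for a historic year
#'
#' Applies the trend multiplier to the reference-year age-specific mortality
#' rates (reference deaths over reference female population) and the female
#' population of year `yd`:
#' `deaths_yd = multiplier * deaths_ref / pop_ref * pop_yd` per band.
#'
#' @param bundle a `world_bundle`.
#' @param trend scenario label `"S1"`-`"S4"`.
#' @param yd the historic calendar year.
#' @param ref_year reference year (default 2020).
#' @return a death table tibble for year `yd`.
#' @export
historic_deaths <- function(bundle, trend, yd, ref_year = 2020) {
  pops <- female_pop(bundle$population, c(yd, ref_year)) |>
    tidyr::pivot_wider(names_from = "year", values_from = "count",
                       names_prefix = "pop_")
  meta <- bundle$country_meta[, c("country_id", "hdi_category")]
  out <- bundle$deaths |>
    dplyr::left_join(pops, by = c("country_id", "age_group")) |>
    dplyr::left_join(meta, by = "country_id")
  pop_ref <- out[[paste0("pop_", ref_year)]]
  pop_yd <- out[[paste0("pop_", yd)]]
  if (any(is.na(pop_ref) | is.na(pop_yd))) {
    stop("female population missing for some country/band in ", yd,
         " or ", ref_year, call. = FALSE)
  }
  if (any(pop_ref == 0 & out$deaths > 0)) {
    stop("zero reference-year population in a band with nonzero deaths",
         call. = FALSE)
  }
  mult <- trend_multiplier(trend, yd,
                           hdi_category = if (trend == "S4") out$hdi_category,
                           ref_year = ref_year)
  tibble::tibble(
    country_id = out$country_id,
    site = out$site,
    age_group = out$age_group,
    deaths = ifelse(out$deaths == 0, 0,
                    mult * out$deaths / pop_ref * pop_yd),
    year = as.integer(yd)
  )
}

#' Estimate prevalent maternal orphans at mid-reference-year
#'
#' For each death year `yd` in `ref_year - 17 .. ref_year - 1` and maternal
#' age at death 15-67, reconstructed single-age deaths are multiplied by the
#' expected number of children (born `y <= yd`, at maternal ages 15-49) who
#' are alive and still under 18 at the reference year, with the child's
#' hazards multiplied by the scenario's mortality rate ratio after the
#' maternal death. Countries without an HDI value are excluded (with a
#' warning) under trend S4.
#'
#' @param bundle a `world_bundle`.
#' @param scenario a [scenario_config()].
#' @param ref_year reference year (default 2020).
#' @param rr_table parity corrections from [parity_rr_table()].
#' @return tibble of class `prevalence_result` with `country_id`, `site`,
#'   `death_year`, `birth_year`, `prevalent_orphans` (summed over maternal
#'   ages); attributes `ref_year` and `scenario`.
#' @export
estimate_prevalent_orphans <- function(bundle, scenario = scenario_config(),
                                       ref_year = 2020,
                                       rr_table = parity_rr_table()) {
  stopifnot(inherits(scenario, "scenario_config"))
  countries <- sort(unique(bundle$deaths$country_id))
  if (scenario$trend == "S4") {
    cat_by_country <- setNames(bundle$country_meta$hdi_category,
                               bundle$country_meta$country_id)
    drop <- countries[cat_by_country[countries] == "missing" |
                        is.na(cat_by_country[countries])]
    if (length(drop)) {
      warning("excluding countries without HDI under S4: ",
              paste(drop, collapse = ", "), call. = FALSE)
      countries <- setdiff(countries, drop)
      for (nm in c("deaths", "fertility", "child_mortality", "population",
                   "country_meta")) {
        bundle[[nm]] <- bundle[[nm]][bundle[[nm]]$country_id %in% countries, ,
                                     drop = FALSE]
      }
    }
  }
  yds <- (ref_year - 17L):(ref_year - 1L)
  mds <- 15:67
  pieces <- list()
  for (country in countries) {
    Fm <- fert_lookup(bundle$fertility, country)
    H <- hazard_lookup(bundle$child_mortality, country)
    # under-18-and-alive probabilities: rows birth years ref-17..ref-1,
    # columns death years; zero for children born <= ref-18 (aged out)
    ys_all <- (ref_year - 17L):(ref_year - 1L)
    PU18 <- matrix(0, length(ys_all), length(yds),
                   dimnames = list(ys_all, yds))
    for (iy in seq_along(ys_all)) {
      y <- ys_all[iy]
      xs <- 0:(ref_year - 1L - y)
      ch <- cumsum(vapply(xs, function(x) {
        v <- H[x + 1L, as.character(y + x)]
        if (is.na(v)) stop("missing hazard cell for birth year ", y, call. = FALSE)
        v
      }, numeric(1)))
      total <- ch[length(ch)]
      for (jd in seq_along(yds)) {
        yd <- yds[jd]
        if (y > yd) next
        pre <- ch[yd - y + 1L]
        PU18[iy, jd] <- exp(-(pre + scenario$mrr_value * (total - pre)))
      }
    }
    for (jd in seq_along(yds)) {
      yd <- yds[jd]
      hd <- historic_deaths(bundle, scenario$trend, yd, ref_year)
      sad <- split_deaths_single_age(hd[hd$country_id == country, , drop = FALSE])
      sad <- sad[sad$contributes, , drop = FALSE]
      ys <- ys_all[ys_all <= yd]
      # fertility components at the mother's age in year y: ma = md - (yd - y)
      comp <- minor_children_matrix(Fm, ys, yd, mds)
      pu <- PU18[as.character(ys), jd]
      comp <- comp * rep(pu, each = length(mds))
      for (site in unique(sad$site)) {
        d <- numeric(length(mds))
        rows <- sad[sad$site == site, , drop = FALSE]
        d[match(rows$md, mds)] <- rows$deaths
        rr <- parity_rr(site, mds, rr_table)
        by_y <- colSums((d * rr) * comp)
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          country_id = country, site = site,
          death_year = yd, birth_year = as.integer(ys),
          prevalent_orphans = as.numeric(by_y)
        )
      }
    }
  }
  out <- dplyr::bind_rows(pieces)
  if (scenario$include_ref_year_half) {
    new_arr <- estimate_new_orphans(bundle, ref_year, rr_table)
    half <- new_arr |>
      dplyr::filter(.data$birth_year >= ref_year - 17L,
                    .data$country_id %in% countries) |>
      dplyr::summarise(prevalent_orphans = 0.5 * sum(.data$expected_orphans),
                       .by = c("country_id", "site", "birth_year")) |>
      dplyr::mutate(death_year = as.integer(ref_year))
    out <- dplyr::bind_rows(out, half)
  }
  attr(out, "ref_year") <- as.integer(ref_year)
  attr(out, "scenario") <- scenario
  class(out) <- c("prevalence_result", class(out))
  out
}

#' Sensitivity grid of global prevalence over trend and mrr scenarios
#'
#' Runs the prevalence estimator for every (trend, mrr) combination and
#' reports the global total, its percentage deviation from the S1a baseline,
#' and the grid's minimum and maximum (as attributes `min` and `max`).
#'
#' @param bundle a `world_bundle`.
#' @param trends trend labels to include.
#' @param mrr_labels mrr labels to include.
#' @param ref_year reference year (default 2020).
#' @param rr_table parity corrections.
#' @return tibble with `trend`, `mrr_label`, `mrr_value`, `total`,
#'   `pct_dev_from_s1a`.
#' @export
sensitivity_grid <- function(bundle, trends = c("S1", "S2", "S3", "S4"),
                             mrr_labels = names(mrr_values()),
                             ref_year = 2020, rr_table = parity_rr_table()) {
  run_total <- function(trend, mrr) {
    sum(estimate_prevalent_orphans(
      bundle, scenario_config(trend, mrr), ref_year, rr_table
    )$prevalent_orphans)
  }
  grid <- tidyr::expand_grid(trend = trends, mrr_label = mrr_labels)
  grid$mrr_value <- unname(mrr_values()[grid$mrr_label])
  grid$total <- unname(mapply(run_total, grid$trend, grid$mrr_label))
  base <- if (any(grid$trend == "S1" & grid$mrr_label == "a")) {
    grid$total[grid$trend == "S1" & grid$mrr_label == "a"]
  } else {
    run_total("S1", "a")
  }
  grid$pct_dev_from_s1a <- 100 * (grid$total - base) / base
  attr(grid, "min") <- min(grid$total)
  attr(grid, "max") <- max(grid$total)
  grid
}
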