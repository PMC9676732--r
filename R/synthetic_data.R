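# Synthetic world-table generator. Produces internally consistent
# cancer-death, fertility, child-mortality, population and country-metadata
# tables on the exact CSV dialects the readers consume, from a compact
# configuration of per-country fertility levels (TFR, peak age, spread),
# per-site log-normal cancer-mortality age curves, child-mortality levels
# and population structure. Magnitudes are stylized; only the structure of
# real world tables is emulated. A seed fixes all outputs bit-exactly.

#' Synthetic world configuration
#'
#' The default emulates three countries spanning the development gradient
#' (high-fertility/high-child-mortality, intermediate, low-fertility/
#' low-child-mortality) and four cancer sites with distinct age profiles and
#' parity relevance (breast, cervix, ovary, lung).
#'
#' @param countries tibble with one row per country: `country_id`, `name`,
#'   `region`, `subregion`, `hdi`, `tfr` (total fertility rate, births per
#'   woman), `fert_peak`/`fert_sd` (age curve of fertility, years),
#'   `child_m0` (infant hazard per person-year), `pop_female` (total female
#'   population), `growth` (annual population growth rate), `rate_scale`
#'   (country multiplier on cancer death rates).
#' @param sites tibble with one row per cancer site: `site` (a label from the
#'   35-site vocabulary), `level` (peak death rate per woman-year), `mu`
#'   (modal age at death, years), `sigma` (log-scale spread).
#' @param parity named numeric vector of target fertility relative risks for
#'   sites whose cancer risk depends on parity (the per-birth death-hazard
#'   mechanism is calibrated to induce them), or `NULL` for independence.
#' @param fert_jitter,rate_jitter,haz_jitter log-normal jitter SDs applied to
#'   the fertility age shape (renormalized to the TFR), death rates and child
#'   hazards, so different seeds give different worlds.
#' @param period_start first fertility period start year (default 2000;
#'   earlier starts emit additional identical-rate periods, useful when
#'   estimating for historic reference years).
#' @param years calendar years covered by the child-mortality and population
#'   tables.
#' @param ref_year reference year of the death table.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    countries = NULL, sites = NULL, parity = NULL,
    fert_jitter = 0.05, rate_jitter = 0.10, haz_jitter = 0.10,
    period_start = 2000L, years = 2002:2020, ref_year = 2020L) {
  if (is.null(countries)) {
    countries <- tibble::tibble(
      country_id = c("SYN1", "SYN2", "SYN3"),
      name = c("Synthetia", "Medistan", "Borealia"),
      region = c("Africa", "Asia", "Europe"),
      subregion = c("Eastern Africa", "South-Central Asia", "Western Europe"),
      hdi = c(0.48, 0.65, 0.88),
      tfr = c(4.5, 2.4, 1.6),
      fert_peak = c(23, 27, 31),
      fert_sd = c(6.5, 6.0, 5.5),
      child_m0 = c(0.035, 0.012, 0.003),
      pop_female = c(3e6, 8e6, 2e6),
      growth = c(0.025, 0.012, 0.001),
      rate_scale = c(1.4, 1.0, 0.8)
    )
  }
  if (is.null(sites)) {
    sites <- tibble::tibble(
      site = c("Breast", "Cervix uteri", "Ovary", "Trachea, bronchus and lung"),
      level = c(8e-4, 6e-4, 2e-4, 4e-4),
      mu = c(55, 50, 62, 67),
      sigma = c(0.35, 0.35, 0.30, 0.25)
    )
  }
  cfg <- structure(list(countries = countries, sites = sites, parity = parity,
                        fert_jitter = fert_jitter, rate_jitter = rate_jitter,
                        haz_jitter = haz_jitter,
                        period_start = as.integer(period_start),
                        years = as.integer(years),
                        ref_year = as.integer(ref_year)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  co <- cfg$countries
  need <- c("country_id", "name", "region", "subregion", "hdi", "tfr",
            "fert_peak", "fert_sd", "child_m0", "pop_female", "growth",
            "rate_scale")
  if (!all(need %in% names(co))) {
    stop("invalid config: countries table lacks ",
         paste(setdiff(need, names(co)), collapse = ", "), call. = FALSE)
  }
  if (any(co$tfr < 0) || any(co$child_m0 < 0) || any(co$pop_female <= 0) ||
      any(co$fert_sd <= 0)) {
    stop("invalid config: rates and population sizes must be non-negative",
         call. = FALSE)
  }
  if (any(cfg$sites$level < 0) || any(cfg$sites$sigma <= 0)) {
    stop("invalid config: site levels must be non-negative", call. = FALSE)
  }
  if (!is.null(cfg$parity)) {
    if (is.null(names(cfg$parity)) ||
        !all(names(cfg$parity) %in% cfg$sites$site)) {
      stop("invalid config: parity targets must be named by configured sites",
           call. = FALSE)
    }
    if (any(cfg$parity <= 0)) stop("invalid config: parity RR must be > 0",
                                   call. = FALSE)
  }
  if (cfg$period_start > 2000L || (2000L - cfg$period_start) %% 5L != 0L) {
    stop("invalid config: period_start must be 2000 or an earlier multiple of 5 below it",
         call. = FALSE)
  }
  invisible(cfg)
}

# relative child-mortality hazard by single age 0-17 (infant high, dip in
# middle childhood, slight adolescent rise)
child_hazard_shape <- function() {
  c(1, rep(0.25, 4), rep(0.12, 5), rep(0.08, 5), rep(0.10, 3))
}

# Realize the synthetic rate surfaces for every country. Deterministic given
# (config, seed); the same surfaces drive both the written tables and the
# microsimulation oracle.
synth_rates <- function(config, seed) {
  validate_synthetic_config(config)
  set.seed(as.integer(seed))
  bands <- mortality_bands()
  band_mid <- (band_lo(bands) + band_hi(bands)) / 2
  fbands <- fertility_bands()
  fmid <- (band_lo(fbands) + band_hi(fbands)) / 2
  periods <- seq(config$period_start, 2015L, by = 5L)
  out <- list()
  for (i in seq_len(nrow(config$countries))) {
    co <- config$countries[i, ]
    # fertility: jittered gaussian age shape renormalized so the single-age
    # rates sum exactly to the TFR; constant across periods; capped at 0.5
    w <- exp(-(fmid - co$fert_peak)^2 / (2 * co$fert_sd^2)) *
      exp(stats::rnorm(length(fmid), 0, config$fert_jitter))
    fert_band <- pmin(co$tfr * w / (5 * sum(w)), 0.5)
    # cancer death rates per woman-year by band x site (log-normal age curve)
    dr <- sapply(seq_len(nrow(config$sites)), function(j) {
      s <- config$sites[j, ]
      s$level * co$rate_scale *
        exp(-(log(band_mid / s$mu))^2 / (2 * s$sigma^2)) *
        exp(stats::rnorm(length(band_mid), 0, config$rate_jitter))
    })
    dimnames(dr) <- list(bands, config$sites$site)
    # child hazards by single age, constant across calendar years
    haz <- co$child_m0 * child_hazard_shape() *
      exp(stats::rnorm(18L, 0, config$haz_jitter))
    # stable-ish female age structure: younger where growth is higher
    struct <- exp(-(co$growth + 0.01) * band_mid)
    pop2020 <- co$pop_female * struct / sum(struct)
    names(pop2020) <- bands
    out[[co$country_id]] <- list(
      country = co,
      fert_band = setNames(fert_band, fbands),
      periods = periods,
      death_rates = dr,
      hazard = setNames(haz, 0:17),
      pop2020 = pop2020
    )
  }
  out
}

# female population in a band for a given year
synth_pop_year <- function(rates_c, year, ref_year = 2020L) {
  rates_c$pop2020 * (1 + rates_c$country$growth)^(year - ref_year)
}

#' Generate a synthetic world bundle and its on-disk fixtures
#'
#' Writes the five CSV tables into `dir`, reads them back with the package
#' readers and assembles a validated bundle, so the generated fixtures
#' exercise the same IO path as real data. Deaths are configured rates times
#' the reference-year female population; both-sex child counts use a fixed
#' 2.04 child sex ratio on the female child population.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; fixes all outputs bit-exactly.
#' @param dir output directory for the fixture CSVs (created if needed;
#'   default a fresh temporary directory).
#' @return a `world_bundle`; the fixture paths are in `attr(, "paths")`.
#' @export
make_world <- function(config = synthetic_config(), seed = 1L,
                       dir = tempfile("synthworld")) {
  rates <- synth_rates(config, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bands <- mortality_bands()
  ref <- config$ref_year

  deaths <- dplyr::bind_rows(lapply(rates, function(rc) {
    tidyr::expand_grid(site = colnames(rc$death_rates), age_group = bands) |>
      dplyr::mutate(country_id = rc$country$country_id,
                    deaths = rc$death_rates[cbind(.data$age_group, .data$site)] *
                      rc$pop2020[.data$age_group])
  }))[, c("country_id", "site", "age_group", "deaths")]

  fert <- dplyr::bind_rows(lapply(rates, function(rc) {
    tidyr::expand_grid(age_group = names(rc$fert_band),
                       period_start = rc$periods) |>
      dplyr::mutate(country_id = rc$country$country_id,
                    period = paste0(.data$period_start, "-", .data$period_start + 4L),
                    rate_per_1000 = 1000 * rc$fert_band[.data$age_group])
  }))[, c("country_id", "age_group", "period", "rate_per_1000")]

  cm <- dplyr::bind_rows(lapply(rates, function(rc) {
    tidyr::expand_grid(age = 0:17, year = config$years) |>
      dplyr::mutate(country_id = rc$country$country_id,
                    hazard = rc$hazard[as.character(.data$age)])
  }))[, c("country_id", "age", "year", "hazard")]

  pop <- dplyr::bind_rows(lapply(rates, function(rc) {
    fem <- tidyr::expand_grid(age_group = bands, year = config$years) |>
      dplyr::mutate(country_id = rc$country$country_id, sex = "female",
                    count = rc$pop2020[.data$age_group] *
                      (1 + rc$country$growth)^(.data$year - ref))
    kids_f <- sum(rc$pop2020[c("0-4", "5-9", "10-14")]) +
      0.6 * rc$pop2020["15-19"]
    both <- tibble::tibble(country_id = rc$country$country_id, sex = "both",
                           age_group = "0-17", year = ref,
                           count = unname(2.04 * kids_f))
    dplyr::bind_rows(fem, both)
  }))[, c("country_id", "sex", "age_group", "year", "count")]

  meta <- config$countries[, c("country_id", "name", "region", "subregion", "hdi")]

  paths <- list(deaths = file.path(dir, "deaths.csv"),
                fertility = file.path(dir, "fertility.csv"),
                child_mortality = file.path(dir, "child_mortality.csv"),
                population = file.path(dir, "population.csv"),
                country_meta = file.path(dir, "country_meta.csv"))
  readr::write_csv(deaths, paths$deaths)
  readr::write_csv(fert, paths$fertility)
  readr::write_csv(cm, paths$child_mortality)
  readr::write_csv(pop, paths$population)
  readr::write_csv(meta, paths$country_meta)

  bundle <- assemble_bundle(
    deaths = read_death_table(paths$deaths, year = ref),
    fertility = read_fertility_table(paths$fertility),
    child_mortality = read_child_mortality(paths$child_mortality,
                                           years = config$years),
    population = read_population(paths$population),
    country_meta = read_country_meta(paths$country_meta)
  )
  attr(bundle, "paths") <- paths
  bundle
}
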