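# Shared fixtures built in code. Small hand-made tables mirror the reader
# outputs exactly; synthetic bundles are cached per (label, seed) because
# several test files reuse the same worlds.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(label, config, seed) {
  key <- paste(label, seed, sep = "#")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- make_world(config, seed = seed)
  }
  .world_cache[[key]]
}

default_world <- function(seed = 1L) {
  cached_world("default", synthetic_config(), seed)
}

# a world with zero child mortality, no growth and periods back to 1985:
# the setting where the incidence/prevalence cross-identity holds exactly
stable_world <- function(seed = 1L) {
  cfg <- synthetic_config(period_start = 1985L, years = 1985:2020)
  cfg$countries$child_m0 <- 0
  cfg$countries$growth <- 0
  cached_world("stable", cfg, seed)
}

rr_none <- function() parity_rr_table()[0, ]

# constant-rate fertility schedule shaped like read_fertility_table() output
const_fertility <- function(rate = 0.1, country = "X",
                            period_starts = seq(2000L, 2015L, 5L)) {
  grid <- expand.grid(age_group = fertility_bands_(),
                      period_start = period_starts,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    country_id = country,
    age_group = grid$age_group,
    period = paste0(grid$period_start, "-", grid$period_start + 4L),
    period_start = grid$period_start,
    period_end = grid$period_start + 4L,
    rate = rate
  )
}

fertility_bands_ <- function() paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-")

# constant-hazard child mortality table
const_hazard <- function(h = 0, country = "X", years = 2002:2020) {
  grid <- expand.grid(age = 0:17, year = years)
  tibble::tibble(country_id = country, age = grid$age,
                 year = grid$year, hazard = h)
}

# hazard table with a single nonzero cell
hazard_one_cell <- function(h, age, country = "X", years = 2002:2020) {
  cm <- const_hazard(0, country, years)
  cm$hazard[cm$age == age] <- h
  cm
}

# write a death-table CSV and read it back
roundtrip_deaths <- function(df, year = 2020, site_groups = read_site_groups()) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  read_death_table(path, year = year, site_groups = site_groups)
}
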