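# Reading, validation and normalization of the input tables.

test_that("death table parses, canonicalizes bands and round-trips exactly", {
  df <- tibble::tibble(country_id = "A", site = "Breast",
                       age_group = c("40-44", "45 - 49"),
                       deaths = c(500, 300))
  dt <- roundtrip_deaths(df)
  expect_equal(nrow(dt), 2L)
  expect_equal(sum(dt$deaths), 800)
  expect_equal(dt$age_group, c("40-44", "45-49"))
  expect_equal(dt$year, c(2020L, 2020L))

  # write -> read reproduces deaths bit-exactly
  out <- tempfile(fileext = ".csv")
  write_death_table(dt, out)
  dt2 <- read_death_table(out, year = 2020)
  expect_identical(dt2$deaths, dt$deaths)
})

test_that("death table rejects malformed and invalid input", {
  bad <- tibble::tibble(country_id = "A", site = "Breast", age_group = "40-44")
  path <- tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(read_death_table(path, 2020), "lacks column.*deaths")

  expect_error(
    roundtrip_deaths(tibble::tibble(country_id = "A", site = "Breast",
                                    age_group = "40-44", deaths = -1)),
    "negative")
  expect_error(
    roundtrip_deaths(tibble::tibble(country_id = "A", site = "Kidney cancer",
                                    age_group = "40-44", deaths = 1)),
    "unknown site.*Kidney cancer")
  expect_error(
    roundtrip_deaths(tibble::tibble(country_id = "A", site = "Breast",
                                    age_group = c("40-44", "42-46"),
                                    deaths = c(1, 1))),
    "overlapping")
})

test_that("a full 35-site x 18-band x 3-country grid yields 1,890 records", {
  vocab <- read_site_groups()
  expect_length(vocab$sites, 35L)
  expect_length(vocab$group_names, 14L)
  cfg <- synthetic_config(
    sites = tibble::tibble(site = vocab$sites, level = 1e-4, mu = 58, sigma = 0.4))
  b <- make_world(cfg, seed = 11)
  expect_equal(nrow(b$deaths), 35L * 18L * 3L)
})

test_that("fertility rates convert from per-1,000 and validate bands/periods", {
  grid <- expand.grid(age_group = paste(seq(15, 45, 5), seq(19, 49, 5), sep = "-"),
                      period = c("2000-2004", "2005-2009", "2010-2014", "2015-2019"),
                      country_id = c("A", "B"), stringsAsFactors = FALSE)
  grid$rate_per_1000 <- 120
  path <- tempfile(fileext = ".csv")
  readr::write_csv(grid, path)
  ft <- read_fertility_table(path)
  expect_equal(nrow(ft), 7L * 4L * 2L)
  expect_true(all(ft$rate == 0.12))
  # re-expressing per 1,000 recovers the input exactly
  expect_identical(ft$rate * 1000, grid$rate_per_1000[1] + numeric(nrow(ft)))

  grid2 <- grid; grid2$rate_per_1000[1] <- -5
  readr::write_csv(grid2, path)
  expect_error(read_fertility_table(path), "negative")

  grid3 <- grid; grid3$age_group[1] <- "50-54"
  readr::write_csv(grid3, path)
  expect_error(read_fertility_table(path), "outside 15-49")

  grid4 <- grid[grid$period != "2005-2009", ]
  readr::write_csv(grid4, path)
  expect_error(read_fertility_table(path), "tile 2000-2019")
})

test_that("child mortality grid completeness is enforced and bands expand", {
  cm <- const_hazard(0.01)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(cm[, c("country_id", "age", "year", "hazard")], path)
  got <- read_child_mortality(path)
  expect_equal(nrow(got), 18L * 19L)

  readr::write_csv(cm[cm$year != 2007, c("country_id", "age", "year", "hazard")], path)
  expect_error(read_child_mortality(path), "2007")

  # 5-year bands are expanded by repetition across single ages
  banded <- expand.grid(age = c("0-4", "5-9", "10-14", "15-19"),
                        year = 2002:2020, stringsAsFactors = FALSE)
  banded$country_id <- "X"; banded$hazard <- 0.02
  readr::write_csv(banded[, c("country_id", "age", "year", "hazard")], path)
  got <- read_child_mortality(path)
  expect_equal(sort(unique(got$age)), 0:17)
  expect_true(all(got$hazard == 0.02))
})

test_that("HDI categories follow the fixed cut points", {
  expect_equal(hdi_category(c(0.39, 0.55, 0.69, 0.70, 0.79, 0.80, 0.96, NA)),
               c("low", "medium", "medium", "high", "high", "very_high",
                 "very_high", "missing"))
})

test_that("bundle assembly intersects country sets and reports drops", {
  b <- default_world()
  paths <- attr(b, "paths")
  deaths <- b$deaths
  fert <- b$fertility[b$fertility$country_id != "SYN3", ]
  b2 <- assemble_bundle(deaths, fert, b$child_mortality, b$population,
                        b$country_meta, b$site_groups)
  expect_setequal(b2$report$countries, c("SYN1", "SYN2"))
  expect_equal(b2$report$dropped$deaths, "SYN3")

  # identical sets: no drops
  expect_length(default_world()$report$dropped, 0L)

  # map missing a site present in the deaths is a totality violation
  sg <- b$site_groups
  thy <- deaths[1, ]; thy$site <- "Thyroid"
  deaths_t <- rbind(deaths, thy)
  sg$map <- sg$map[names(sg$map) != "Thyroid"]
  expect_error(assemble_bundle(deaths_t, b$fertility, b$child_mortality,
                               b$population, b$country_meta, sg),
               "missing site.*Thyroid")

  expect_error(assemble_bundle(deaths[deaths$country_id == "none", ],
                               b$fertility, b$child_mortality, b$population,
                               b$country_meta, b$site_groups),
               "empty country intersection")
})

test_that("group totals equal site totals (group totality)", {
  b <- default_world()
  map <- b$site_groups$map
  by_site <- sum(b$deaths$deaths)
  by_group <- b$deaths |>
    dplyr::mutate(group = map[site]) |>
    dplyr::summarise(d = sum(deaths), .by = group)
  expect_lt(abs(sum(by_group$d) - by_site) / by_site, 1e-12)
})
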