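# New-orphan estimator: single-age splitting, per-woman expected children,
# and the deaths x expected-children product with its invariants.

make_tiny_bundle <- function(deaths_df, fert = const_fertility(0.1, "X"),
                             cm = const_hazard(0, "X")) {
  pop <- tibble::tibble(country_id = "X", sex = "female",
                        age_group = rep(mort_bands <- c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+"),
                                        times = 19),
                        year = rep(2002:2020, each = 18), count = 1e5)
  both <- tibble::tibble(country_id = "X", sex = "both", age_group = "0-17",
                         year = 2020L, count = 3e5)
  meta <- tibble::tibble(country_id = "X", name = "X", region = "R",
                         subregion = "S", hdi = 0.7,
                         hdi_category = "high")
  assemble_bundle(deaths_df, fert, cm, rbind(pop, both), meta)
}

test_that("banded deaths split uniformly into single ages, totals conserved", {
  dt <- tibble::tibble(country_id = "X", site = "Breast",
                       age_group = c("40-44", "50-54", "85+"),
                       deaths = c(500, 0, 1000), year = 2020L)
  sad <- split_deaths_single_age(dt)
  expect_equal(sad$deaths[sad$md %in% 40:44], rep(100, 5))
  expect_equal(sad$deaths[sad$md %in% 50:54], rep(0, 5))
  expect_equal(sum(sad$deaths), sum(dt$deaths))
  expect_true(all(!sad$contributes[sad$md >= 68]))
  expect_true(all(sad$contributes[sad$md %in% 40:44]))
})

test_that("expected minor children enumerate the 18 birth cohorts", {
  dt <- tibble::tibble(country_id = "X", site = "Breast", age_group = "40-44",
                       deaths = 500, year = 2020L)
  b <- make_tiny_bundle(dt)
  # constant fertility 0.10, zero child mortality, md 40: mother aged 22-39
  # over 2002-2019, all inside 15-49 -> every component 0.10
  emc <- expected_minor_children(b, "X", 40, "Breast")
  expect_equal(emc$birth_year, 2002:2019)
  expect_equal(emc$expected, rep(0.1, 18))
  expect_equal(sum(emc$expected), 1.8)
  # md 70: no birth can have happened at ages 15-49 within the window
  expect_equal(expected_minor_children(b, "X", 70, "Breast")$expected,
               rep(0, 18))
  # zero fertility
  b0 <- make_tiny_bundle(dt, fert = const_fertility(0, "X"))
  expect_equal(expected_minor_children(b0, "X", 40, "Breast")$expected,
               rep(0, 18))
})

test_that("orphans are deaths times expected children, with RR applied", {
  dt <- tibble::tibble(country_id = "X", site = "Breast", age_group = "40-44",
                       deaths = 500, year = 2020L)
  b <- make_tiny_bundle(dt)
  arr <- estimate_new_orphans(b, rr_table = rr_none())
  # 100 deaths at each of md 40..44, each with per-woman total 1.8
  expect_equal(sum(arr$expected_orphans), 500 * 1.8)
  expect_equal(sum(arr$expected_orphans[arr$md == 40]), 100 * 1.8)

  # zero deaths -> zero array
  dt0 <- dt; dt0$deaths <- 0
  expect_equal(sum(estimate_new_orphans(make_tiny_bundle(dt0))$expected_orphans), 0)

  # switching a site's RR from 1 to 1.1 scales that site's orphans by 1.1
  rr <- tibble::tibble(site = "Breast", rr = 1.1, min_age_at_death = NA_real_)
  arr_rr <- estimate_new_orphans(b, rr_table = rr)
  expect_equal(sum(arr_rr$expected_orphans), 1.1 * sum(arr$expected_orphans))
})

test_that("orphan support excludes md >= 68 and out-of-window birth years", {
  b <- default_world()
  arr <- estimate_new_orphans(b)
  expect_true(all(arr$md >= 15 & arr$md <= 67))
  expect_true(all(arr$birth_year >= 2002 & arr$birth_year <= 2019))
  expect_true(all(arr$expected_orphans >= 0))
})

test_that("estimator is linear in deaths and additive over sites and groups", {
  b <- default_world()
  arr <- estimate_new_orphans(b, rr_table = rr_none())
  b2 <- b
  b2$deaths$deaths <- 2 * b$deaths$deaths
  arr2 <- estimate_new_orphans(b2, rr_table = rr_none())
  expect_equal(arr2$expected_orphans, 2 * arr$expected_orphans)

  by_country <- arr |>
    dplyr::summarise(total = sum(expected_orphans), .by = country_id)
  by_site <- arr |>
    dplyr::summarise(total = sum(expected_orphans), .by = c(country_id, site)) |>
    dplyr::summarise(total = sum(total), .by = country_id)
  map <- b$site_groups$map
  by_group <- arr |>
    dplyr::mutate(group = map[site]) |>
    dplyr::summarise(total = sum(expected_orphans), .by = c(country_id, group)) |>
    dplyr::summarise(total = sum(total), .by = country_id)
  expect_equal(by_site$total, by_country$total, tolerance = 1e-9)
  expect_equal(by_group$total[order(by_group$country_id)],
               by_country$total[order(by_country$country_id)],
               tolerance = 1e-9)
})

test_that("totals are monotone in fertility and child mortality", {
  b <- default_world()
  base <- sum(estimate_new_orphans(b, rr_table = rr_none())$expected_orphans)

  b_f <- b
  i <- which(b_f$fertility$country_id == "SYN1")[1]
  b_f$fertility$rate[i] <- b_f$fertility$rate[i] * 1.5
  expect_gte(sum(estimate_new_orphans(b_f, rr_table = rr_none())$expected_orphans),
             base)

  b_m <- b
  j <- which(b_m$child_mortality$country_id == "SYN1")[1]
  b_m$child_mortality$hazard[j] <- b_m$child_mortality$hazard[j] + 0.1
  expect_lte(sum(estimate_new_orphans(b_m, rr_table = rr_none())$expected_orphans),
             base)
})
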