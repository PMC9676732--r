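# Historic-death reconstruction, trend scenarios, excess-mortality variants
# and the prevalence accumulation.

test_that("trend multipliers follow the scenario rules", {
  expect_equal(trend_multiplier("S1", 2005), 1.0)
  expect_equal(trend_multiplier("S2", 2018), 0.99^2)
  expect_equal(trend_multiplier("S3", 2010), 1.01^10)
  expect_equal(trend_multiplier("S4", 2010, "very_high"), 1.01^10)
  expect_equal(trend_multiplier("S4", 2010, "low"), 0.99^10)
  expect_equal(trend_multiplier("S4", 2010, "medium"), 0.99^10)
  expect_error(trend_multiplier("S4", 2010), "HDI")
  expect_error(trend_multiplier("S4", 2010, "missing"), "HDI")
})

test_that("historic deaths scale with population and the trend multiplier", {
  b <- stable_world()  # constant population over time
  hd <- historic_deaths(b, "S1", 2010)
  expect_equal(hd$deaths, b$deaths$deaths, tolerance = 1e-12)
  expect_equal(unique(hd$year), 2010L)

  hd2 <- historic_deaths(b, "S2", 2019)
  expect_equal(hd2$deaths, 0.99 * b$deaths$deaths, tolerance = 1e-12)

  # halving the female population in yd halves the deaths
  b_half <- b
  sel <- b_half$population$sex == "female" & b_half$population$year == 2010
  b_half$population$count[sel] <- b_half$population$count[sel] / 2
  hd3 <- historic_deaths(b_half, "S1", 2010)
  expect_equal(hd3$deaths, b$deaths$deaths / 2, tolerance = 1e-12)
})

test_that("prevalence is zero without deaths and ordered across trends", {
  b <- default_world()
  b0 <- b; b0$deaths$deaths <- 0
  expect_equal(sum(estimate_prevalent_orphans(b0)$prevalent_orphans), 0)

  totals <- sapply(c("S1", "S2", "S3"), function(tr) {
    p <- estimate_prevalent_orphans(b, scenario_config(tr, "a"))
    tapply(p$prevalent_orphans, p$country_id, sum)
  })
  # country by country: S3 >= S1 >= S2 (multipliers >= / <= 1)
  expect_true(all(totals[, "S3"] >= totals[, "S1"]))
  expect_true(all(totals[, "S1"] >= totals[, "S2"]))
})

test_that("prevalence is monotone non-increasing in the excess mortality ratio", {
  b <- default_world()
  tot <- sapply(c("e", "a", "b", "c", "d"), function(m)  # mrr 1, 1.25, 1.5, 2, 2.6
    sum(estimate_prevalent_orphans(b, scenario_config("S1", m))$prevalent_orphans))
  expect_true(all(diff(tot) <= 0))
})

test_that("with zero child mortality the mrr has no effect", {
  b <- stable_world()
  t_e <- sum(estimate_prevalent_orphans(b, scenario_config("S1", "e"))$prevalent_orphans)
  t_d <- sum(estimate_prevalent_orphans(b, scenario_config("S1", "d"))$prevalent_orphans)
  expect_equal(t_e, t_d, tolerance = 1e-12)
})

test_that("prevalence decomposes into per-death-year new-orphan runs", {
  # stable world (constant population, zero child mortality), S1, mrr = 1:
  # the yd-slice of the prevalence restricted to births before yd equals the
  # new-orphan total computed for reference year yd, keeping only children
  # still under 18 at 2020; the remainder of the slice is exactly the
  # same-year-birth term the prevalence sum includes
  b <- stable_world()
  prev <- estimate_prevalent_orphans(b, scenario_config("S1", "e"),
                                     rr_table = rr_none())
  for (yd in c(2003, 2010, 2019)) {
    slice <- prev[prev$death_year == yd, ]
    lhs <- sum(slice$prevalent_orphans[slice$birth_year < yd])
    nmc <- estimate_new_orphans(b, ref_year = yd, rr_table = rr_none())
    rhs <- sum(nmc$expected_orphans[nmc$birth_year >= 2003])
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_true(all(slice$birth_year <= yd))
  }
  # children born <= 2002 never contribute (aged out by mid-2020)
  expect_true(all(prev$birth_year >= 2003))
})

test_that("countries without HDI are excluded from S4 with a warning", {
  b <- default_world()
  b$country_meta$hdi[b$country_meta$country_id == "SYN2"] <- NA
  b$country_meta$hdi_category <- hdi_category(b$country_meta$hdi)
  expect_warning(p <- estimate_prevalent_orphans(b, scenario_config("S4", "a")),
                 "SYN2")
  expect_false("SYN2" %in% p$country_id)
})

test_that("the sensitivity grid brackets the scenario space", {
  b <- default_world()
  one <- sensitivity_grid(b, trends = "S1", mrr_labels = "a")
  expect_equal(nrow(one), 1L)
  expect_equal(one$pct_dev_from_s1a, 0)

  grid <- sensitivity_grid(b, trends = c("S1", "S2", "S3"),
                           mrr_labels = c("a", "d", "e"))
  best <- grid[which.max(grid$total), ]
  worst <- grid[which.min(grid$total), ]
  expect_equal(c(best$trend, best$mrr_label), c("S3", "e"))
  expect_equal(c(worst$trend, worst$mrr_label), c("S2", "d"))
  expect_equal(attr(grid, "max"), max(grid$total))
})

test_that("the half-year option adds half the reference-year minor orphans", {
  b <- default_world()
  base <- estimate_prevalent_orphans(b, scenario_config("S1", "a"))
  with_half <- estimate_prevalent_orphans(
    b, scenario_config("S1", "a", include_ref_year_half = TRUE))
  new_arr <- estimate_new_orphans(b)
  minors <- sum(new_arr$expected_orphans[new_arr$birth_year >= 2003])
  expect_equal(sum(with_half$prevalent_orphans),
               sum(base$prevalent_orphans) + 0.5 * minors,
               tolerance = 1e-9)
})
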