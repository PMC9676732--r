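# Primitive rate lookups and survival probabilities underlying both
# estimators: step-function fertility on the 5-year x 5-year grid, parity
# corrections to cohort fertility, and child survival as exponentiated
# cumulative hazards (no actuarial a(x) correction; the hazards are treated
# as annual cumulative-hazard increments).

#' Default parity-risk fertility corrections
#'
#' Multiplicative corrections to a decedent's cohort fertility for cancers
#' whose risk is associated with parity: cervix 1.1, ovary 0.8, and breast
#' 0.93 for deaths over age 50. All other sites are 1.
#'
#' @param path optional YAML file with a `parity_rr` list (`site`, `rr`,
#'   optional `min_age_at_death`); `NULL` uses the packaged default.
#' @return tibble with columns `site`, `rr`, `min_age_at_death`.
#' @export
parity_rr_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenarios.yaml", package = "canorphans")
  }
  cfg <- yaml::read_yaml(path)
  rows <- lapply(cfg$parity_rr, function(x) {
    tibble::tibble(site = x$site, rr = as.numeric(x$rr),
                   min_age_at_death = as.numeric(x$min_age_at_death %||% NA))
  })
  dplyr::bind_rows(rows)
}

#' Parity correction factor for a site and maternal age at death
#'
#' @param site cancer-site label (vector ok).
#' @param md maternal age at death in years (vector ok, recycled).
#' @param table correction table from [parity_rr_table()].
#' @return numeric factor(s); 1 for unlisted sites or when the death is not
#'   above the site's age threshold.
#' @export
parity_rr <- function(site, md, table = parity_rr_table()) {
  n <- max(length(site), length(md))
  site <- rep_len(site, n); md <- rep_len(md, n)
  out <- rep(1, n)
  for (i in seq_len(nrow(table))) {
    hit <- site == table$site[i]
    if (!is.na(table$min_age_at_death[i])) {
      hit <- hit & md > table$min_age_at_death[i]
    }
    out[hit] <- table$rr[i]
  }
  out
}

# per-country fertility lookup matrix: rows single ages 15..49, columns the
# calendar years covered by the periods; step function on the 5x5 grid
fert_lookup <- function(fertility, country) {
  ft <- fertility[fertility$country_id == country, , drop = FALSE]
  if (!nrow(ft)) stop("no fertility schedule for country ", country, call. = FALSE)
  years <- seq(min(ft$period_start), max(ft$period_end))
  ages <- 15:49
  M <- matrix(0, length(ages), length(years),
              dimnames = list(ages, years))
  for (i in seq_len(nrow(ft))) {
    a <- band_lo(ft$age_group[i]):band_hi(ft$age_group[i])
    y <- ft$period_start[i]:ft$period_end[i]
    M[as.character(a), as.character(y)] <- ft$rate[i]
  }
  M
}

#' Age- and period-specific fertility rate
#'
#' Step-function lookup on the 5-year age x 5-year period grid: returns the
#' rate of the grid cell containing (`year`, `age`), per woman per year.
#' Fertility is zero outside ages 15-49 regardless of year; for ages within
#' 15-49, years outside the period grid raise an error (no extrapolation).
#'
#' @param fertility schedule from [read_fertility_table()].
#' @param country country identifier.
#' @param year calendar year(s).
#' @param age age(s) in completed years; recycled against `year`.
#' @return numeric rate(s) per woman per year.
#' @export
fertility_rate <- function(fertility, country, year, age) {
  n <- max(length(year), length(age))
  year <- rep_len(as.integer(year), n); age <- rep_len(as.integer(age), n)
  M <- fert_lookup(fertility, country)
  yrs <- as.integer(colnames(M))
  out <- numeric(n)
  inside <- age >= 15L & age <= 49L
  if (any(inside & (year < min(yrs) | year > max(yrs)))) {
    stop("year outside the fertility period grid: ",
         paste(unique(year[inside & (year < min(yrs) | year > max(yrs))]),
               collapse = ", "), call. = FALSE)
  }
  idx <- inside
  out[idx] <- M[cbind(age[idx] - 14L, year[idx] - min(yrs) + 1L)]
  out
}

# per-country child hazard matrix: rows ages 0..17, columns calendar years
hazard_lookup <- function(child_mortality, country) {
  cm <- child_mortality[child_mortality$country_id == country, , drop = FALSE]
  if (!nrow(cm)) stop("no child-mortality table for country ", country, call. = FALSE)
  years <- seq(min(cm$year), max(cm$year))
  H <- matrix(NA_real_, 18L, length(years), dimnames = list(0:17, years))
  H[cbind(cm$age + 1L, cm$year - min(cm$year) + 1L)] <- cm$hazard
  H
}

# cumulative hazard along the cohort diagonal: ages x0..x1 of a child born in
# year y, hazard at age x read in calendar year y + x
cohort_cumhaz <- function(H, y, x0, x1) {
  if (x1 < x0) return(0)
  years <- as.integer(colnames(H))
  x <- x0:x1
  cols <- y + x - min(years) + 1L
  if (any(cols < 1L) || any(cols > ncol(H)) || any(x > 17L) || any(x < 0L)) {
    stop("missing hazard cell for birth year ", y, " (ages ", x0, "-", x1, ")",
         call. = FALSE)
  }
  vals <- H[cbind(x + 1L, cols)]
  if (anyNA(vals)) {
    stop("missing hazard cell for birth year ", y, call. = FALSE)
  }
  sum(vals)
}

#' Probability a child survives from birth to the reference year
#'
#' `exp(-sum of annual hazards)` along the cohort diagonal: the hazard at age
#' x is read in calendar year `birth_year + x`, for x = 0 up to
#' `ref_year - 1 - birth_year`.
#'
#' @param child_mortality table from [read_child_mortality()].
#' @param country country identifier.
#' @param birth_year the child's year of birth (at most `ref_year - 1`).
#' @param ref_year the reference year.
#' @return survival probability in \[0, 1\].
#' @export
survival_to_reference <- function(child_mortality, country, birth_year, ref_year) {
  stopifnot(birth_year <= ref_year - 1)
  H <- hazard_lookup(child_mortality, country)
  exp(-cohort_cumhaz(H, birth_year, 0L, ref_year - 1L - birth_year))
}

#' Probability a child is alive and under 18 at the reference year
#'
#' Zero when `ref_year - birth_year >= 18`. Otherwise the survival
#' probability with different hazards before and after the maternal death:
#' baseline hazards for ages 0..(yd - y), and `mrr` times the baseline for
#' ages (yd - y + 1)..(ref_year - 1 - y). With `mrr = 1` this collapses to
#' [survival_to_reference()].
#'
#' @param child_mortality table from [read_child_mortality()].
#' @param country country identifier.
#' @param birth_year child's year of birth `y` (`y <= death_year`).
#' @param death_year the mother's year of death `yd`.
#' @param mrr mortality rate ratio applied to the child's hazards after the
#'   maternal death (>= 1, or 1 for no excess).
#' @param ref_year the reference year (default 2020).
#' @return probability in \[0, 1\].
#' @export
prob_under18_at_ref <- function(child_mortality, country, birth_year,
                                death_year, mrr = 1, ref_year = 2020) {
  stopifnot(birth_year <= death_year, mrr > 0)
  if (ref_year - birth_year >= 18) return(0)
  H <- hazard_lookup(child_mortality, country)
  split_x <- death_year - birth_year
  pre <- cohort_cumhaz(H, birth_year, 0L, split_x)
  post <- if (split_x + 1L <= ref_year - 1L - birth_year) {
    cohort_cumhaz(H, birth_year, split_x + 1L, ref_year - 1L - birth_year)
  } else 0
  exp(-(pre + mrr * post))
}

# vectorized survival over birth years for one country (estimator hot path);
# returns named vector over ys
survival_vector <- function(H, ys, ref_year) {
  vapply(ys, function(y) exp(-cohort_cumhaz(H, y, 0L, ref_year - 1L - y)),
         numeric(1)) |> setNames(ys)
}
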