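# Expected new maternal orphans for a reference year, decomposed by country,
# cancer site, single-year maternal age at death and child birth year:
#   orphans(c, t, md, y) = D(c, t, md) * RR_t(md) * FR(c, y, ma) * P(alive | y)
# with ma = md - (ref - y), summed over child birth years y = ref-18..ref-1.
# Deaths at maternal ages 68+ cannot give rise to orphans (fertility is zero
# beyond age 49, so the youngest child of such a woman is already 18).

#' Spread banded deaths uniformly over single ages
#'
#' Each 5-year band's deaths are divided by five across its single ages
#' (including the open-ended 85+ band, whose width is taken as five; those
#' deaths never contribute orphans). Band totals are conserved exactly.
#'
#' @param deaths a death table from [read_death_table()].
#' @return tibble with `country_id`, `site`, `md` (single age), `deaths`,
#'   `year` and `contributes` (TRUE for maternal ages 15-67, the ages at
#'   death that can give rise to maternal orphans).
#' @export
split_deaths_single_age <- function(deaths) {
  lo <- band_lo(deaths$age_group)
  hi <- band_hi(deaths$age_group)
  w <- hi - lo + 1L
  idx <- rep(seq_len(nrow(deaths)), w)
  tibble::tibble(
    country_id = deaths$country_id[idx],
    site = deaths$site[idx],
    md = unlist(Map(seq, lo, hi)),
    year = deaths$year[idx],
    deaths = deaths$deaths[idx] / w[idx]
  ) |>
    dplyr::mutate(contributes = .data$md >= 15L & .data$md <= 67L)
}

# component matrix over (md, y): FR(c, y, md - (ref - y)), zero where the
# mother's age at the birth falls outside 15-49
minor_children_matrix <- function(Fm, ys, ref_year, mds = 15:67) {
  yrs <- as.integer(colnames(Fm))
  comp <- matrix(0, length(mds), length(ys),
                 dimnames = list(mds, ys))
  for (j in seq_along(ys)) {
    y <- ys[j]
    ma <- mds - (ref_year - y)
    ok <- ma >= 15L & ma <= 49L
    if (any(ok)) {
      if (y < min(yrs) || y > max(yrs)) {
        stop("year outside the fertility period grid: ", y, call. = FALSE)
      }
      comp[ok, j] <- Fm[cbind(ma[ok] - 14L, y - min(yrs) + 1L)]
    }
  }
  comp
}

#' Per-woman expected surviving minor children, by child birth year
#'
#' For a woman dying at age `md` in `ref_year`, the expected number of her
#' children born in year `y` who are alive at the reference year:
#' `RR_t(md) * FR(country, y, md - (ref_year - y)) * P(alive at ref | y)`,
#' for `y` in `ref_year - 18 .. ref_year - 1`. Components are zero where her
#' age at the birth falls outside 15-49; for `md >= 68` every component is
#' zero.
#'
#' @param bundle a `world_bundle`.
#' @param country country identifier.
#' @param md maternal age at death (single year).
#' @param site cancer-site label (determines the parity correction).
#' @param ref_year reference year (default 2020).
#' @param rr_table parity corrections from [parity_rr_table()].
#' @return tibble with `birth_year` and `expected` (per woman).
#' @export
expected_minor_children <- function(bundle, country, md, site,
                                    ref_year = 2020,
                                    rr_table = parity_rr_table()) {
  ys <- (ref_year - 18L):(ref_year - 1L)
  Fm <- fert_lookup(bundle$fertility, country)
  H <- hazard_lookup(bundle$child_mortality, country)
  comp <- minor_children_matrix(Fm, ys, ref_year, mds = md)
  surv <- survival_vector(H, ys, ref_year)
  rr <- parity_rr(site, md, rr_table)
  tibble::tibble(birth_year = as.integer(ys),
                 expected = as.numeric(comp[1, ] * surv) * rr)
}

#' Estimate new maternal orphans due to cancer
#'
#' Multiplies single-age female cancer deaths by the expected number of
#' surviving minor children per woman, giving expected orphans by country,
#' site, maternal age at death and child birth year. Summing over `md` and
#' `birth_year` gives the country x site totals; only maternal ages 15-67
#' contribute.
#'
#' @param bundle a `world_bundle`.
#' @param ref_year reference year (default 2020).
#' @param rr_table parity corrections from [parity_rr_table()]; pass a
#'   zero-row tibble for an uncorrected (RR = 1) run.
#' @param deaths optional death table overriding `bundle$deaths` (used by the
#'   prevalence estimator to inject reconstructed historic deaths).
#' @return tibble of class `orphan_array` with `country_id`, `site`, `md`,
#'   `birth_year`, `expected_orphans`; attribute `ref_year`.
#' @export
estimate_new_orphans <- function(bundle, ref_year = 2020,
                                 rr_table = parity_rr_table(),
                                 deaths = NULL) {
  deaths <- deaths %||% bundle$deaths
  sad <- split_deaths_single_age(deaths)
  sad <- sad[sad$contributes, , drop = FALSE]
  ys <- (ref_year - 18L):(ref_year - 1L)
  mds <- 15:67
  pieces <- list()
  for (country in unique(sad$country_id)) {
    Fm <- fert_lookup(bundle$fertility, country)
    H <- hazard_lookup(bundle$child_mortality, country)
    surv <- survival_vector(H, ys, ref_year)
    comp <- minor_children_matrix(Fm, ys, ref_year, mds) *
      rep(surv, each = length(mds))
    cs <- sad[sad$country_id == country, , drop = FALSE]
    for (site in unique(cs$site)) {
      d <- numeric(length(mds))
      rows <- cs[cs$site == site, , drop = FALSE]
      d[match(rows$md, mds)] <- rows$deaths
      rr <- parity_rr(site, mds, rr_table)
      E <- (d * rr) * comp  # recycles by row (md)
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        country_id = country,
        site = site,
        md = rep(mds, times = length(ys)),
        birth_year = rep(as.integer(ys), each = length(mds)),
        expected_orphans = as.vector(E)
      )
    }
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "ref_year") <- as.integer(ref_year)
  class(out) <- c("orphan_array", class(out))
  out
}
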