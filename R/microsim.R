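# Individual-level microsimulation oracle for the analytic estimators.
# Women are simulated from the same rate surfaces that generate the world
# tables: annual births are Bernoulli events with probability equal to the
# (capped) fertility rate, child survival is a chain of annual Bernoulli
# draws under the lifetable hazards, and cancer death is a Bernoulli draw
# under the configured death rates. Orphans are counted child by child among
# decedent women and scaled to the population. Monte-Carlo standard errors
# come from independent replicate blocks of women.
#
# When the parity-dependence switch is off, cancer death is independent of
# fertility, so death indicators are drawn before the birth histories and
# children are simulated only for decedent women -- the same joint
# distribution at a fraction of the cost. With the switch on, a per-birth
# multiplicative factor g on the woman's death hazard induces the
# parity-cancer association; g is calibrated per site and cohort so the
# decedents' expected parity is the configured relative risk times the
# cohort mean, and the factor is normalized so marginal death rates stay at
# their configured values.

# fertility band rate for single ages (0 outside 15-49)
fert_at_age <- function(fert_band, age) {
  out <- numeric(length(age))
  ok <- age >= 15L & age <= 49L
  out[ok] <- fert_band[(age[ok] - 15L) %/% 5L + 1L]
  out
}

# mortality band label containing a single age
band_of_age <- function(age) {
  i <- pmin(age %/% 5L, 17L)
  mortality_bands()[i + 1L]
}

# solve for the per-birth hazard factor g so that the decedents' expected
# parity equals target_rr times the cohort's expected parity
calibrate_parity_g <- function(p_y, target_rr) {
  p <- p_y[p_y > 0]
  if (!length(p) || target_rr == 1) return(1)
  f <- function(g) sum(p * g / (1 - p + p * g)) - target_rr * sum(p)
  if (f(1e6) < 0 || f(1e-9) > 0) {
    stop("parity target ", target_rr, " not attainable for this cohort",
         call. = FALSE)
  }
  uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
}

# expected g^K over the cohort's birth probabilities (normalizing constant)
parity_norm <- function(p_y, g) prod(1 - p_y + p_y * g)

# simulate annual survival of children to the end of year end_year;
# birth_year: vector per child; hazard: named vector by age 0-17;
# after the maternal death year yd (ages > yd - birth_year) hazards are
# multiplied by mrr. Returns logical vector (alive at ref).
sim_child_survival <- function(birth_year, hazard, end_year, yd = NULL, mrr = 1) {
  alive <- rep(TRUE, length(birth_year))
  for (y in unique(birth_year)) {
    k <- which(birth_year == y)
    a <- rep(TRUE, length(k))
    for (x in 0:(end_year - y)) {
      m <- if (!is.null(yd) && x > yd - y) mrr else 1
      p <- exp(-hazard[x + 1L] * m)
      a <- a & (runif(length(k)) < p)
    }
    alive[k] <- a
  }
  alive
}

# per-woman death probabilities (n x 1) and per-site rates (n x S); applies
# the parity mechanism when K (parity per woman) is supplied
death_probs <- function(rates_c, md, config, K = NULL, mult = 1) {
  dr <- rates_c$death_rates[band_of_age(md), , drop = FALSE] * mult
  cal <- list()
  if (!is.null(config$parity) && !is.null(K)) {
    for (site in names(config$parity)) {
      target <- config$parity[[site]]
      g_by_md <- vapply(15:67, function(m) {
        p_y <- fert_at_age(rates_c$fert_band,
                           m - (config$ref_year - ((config$ref_year - 18L):(config$ref_year - 1L))))
        calibrate_parity_g(p_y, target)
      }, numeric(1))
      norm_by_md <- vapply(15:67, function(m) {
        p_y <- fert_at_age(rates_c$fert_band,
                           m - (config$ref_year - ((config$ref_year - 18L):(config$ref_year - 1L))))
        parity_norm(p_y, g_by_md[m - 14L])
      }, numeric(1))
      g <- g_by_md[md - 14L]
      dr[, site] <- dr[, site] * g^K / norm_by_md[md - 14L]
      cal[[site]] <- setNames(g_by_md, 15:67)
    }
  }
  list(p = rowSums(dr), by_site = dr, calibration = cal)
}

microsim_result <- function(total, block_tot, n_blocks, n_women, n_dec,
                            bins, by_site, calibration) {
  structure(list(
    count = total,
    se = stats::sd(block_tot) * sqrt(n_blocks),
    n_women = n_women,
    n_decedents = n_dec,
    by_age_bin = bins,
    by_site = by_site,
    calibration = calibration
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> count ", format(x$count, digits = 6), " (se ",
      format(x$se, digits = 4), "), ", x$n_decedents, " decedents of ",
      x$n_women, " women per country-cohort\n", sep = "")
  invisible(x)
}

#' Microsimulation oracle for new orphans
#'
#' Simulates `n_women` women per country (cohorts sampled in proportion to
#' the single-age female population), their 18-year birth histories, their
#' children's survival and their cancer death in the reference year, and
#' counts the surviving minor children of decedents, scaled to the
#' population. Validates [estimate_new_orphans()] on worlds generated by
#' [make_world()] with the same `config` and `seed`.
#'
#' @param config a [synthetic_config()].
#' @param n_women women simulated per country.
#' @param seed integer seed; the world rates are realized with this seed (so
#'   they match `make_world(config, seed)`) and the simulation draws with a
#'   stream derived from it.
#' @param n_blocks replicate blocks for the Monte-Carlo standard error.
#' @return a `microsim_result`: `count`, `se`, `n_women`, `n_decedents`,
#'   `by_age_bin`, `by_site`, `calibration` (parity factors, when on).
#' @export
microsim_new_orphans <- function(config = synthetic_config(), n_women = 2e5,
                                 seed = 1L, n_blocks = 10L) {
  rates <- synth_rates(config, seed)
  set.seed(as.integer(seed) + 1000003L)
  ref <- config$ref_year
  ys <- (ref - 18L):(ref - 1L)
  parity_on <- !is.null(config$parity)
  block_tot <- numeric(n_blocks)
  total <- 0; n_dec <- 0L
  bins <- c(u5 = 0, a5_9 = 0, a10_17 = 0)
  by_site <- setNames(numeric(nrow(config$sites)), config$sites$site)
  calibration <- list()
  for (rc in rates) {
    pop_md <- rc$pop2020[band_of_age(15:67)] / 5
    md <- sample(15:67, n_women, replace = TRUE, prob = pop_md)
    W <- sum(pop_md) / n_women
    blk <- (seq_len(n_women) - 1L) %% n_blocks + 1L
    # birth probabilities by (woman, birth year): mother's age md - (ref - y)
    P <- sapply(ys, function(y) fert_at_age(rc$fert_band, md - (ref - y)))
    if (parity_on) {
      B <- matrix(runif(n_women * length(ys)) < P, n_women)
      dp <- death_probs(rc, md, config, K = rowSums(B))
      calibration[[rc$country$country_id]] <- dp$calibration
    } else {
      dp <- death_probs(rc, md, config)
    }
    die <- runif(n_women) < dp$p
    idx <- which(die)
    n_dec <- n_dec + length(idx)
    if (!length(idx)) next
    if (!parity_on) {
      B <- matrix(FALSE, n_women, length(ys))
      B[idx, ] <- runif(length(idx) * length(ys)) < P[idx, , drop = FALSE]
    }
    site_of <- vapply(idx, function(i) {
      sample(colnames(dp$by_site), 1L, prob = dp$by_site[i, ])
    }, character(1))
    kid <- which(B[idx, , drop = FALSE], arr.ind = TRUE)
    if (nrow(kid)) {
      by <- ys[kid[, 2]]
      alive <- sim_child_survival(by, rc$hazard, ref - 1L)
      contrib <- W * alive
      women <- idx[kid[, 1]]
      total <- total + sum(contrib)
      block_tot <- block_tot + as.numeric(
        tapply(contrib, factor(blk[women], levels = seq_len(n_blocks)), sum,
               default = 0))
      b <- age_bin(by, ref)
      for (bb in names(bins)) bins[bb] <- bins[bb] + sum(contrib[b == bb])
      for (s in unique(site_of)) {
        by_site[s] <- by_site[s] + sum(contrib[site_of[kid[, 1]] == s])
      }
    }
  }
  microsim_result(total, block_tot, n_blocks, n_women, n_dec, bins, by_site,
                  calibration)
}

#' Microsimulation oracle for prevalent orphans
#'
#' For each historic death year, simulates `n_women` women alive that year
#' (cohorts in proportion to that year's female population), their birth
#' histories up to and including the death year, cancer death under the
#' trend-scaled rates, and their children's survival to mid-reference-year
#' with hazards multiplied by `mrr` after the maternal death. Children who
#' have reached 18 by the reference year are not counted. Validates
#' [estimate_prevalent_orphans()].
#'
#' @inheritParams microsim_new_orphans
#' @param mrr mortality rate ratio applied to a child's hazards after the
#'   maternal death.
#' @param trend trend scenario label `"S1"`-`"S4"`.
#' @return a `microsim_result` (`n_women` is per country-death-year).
#' @export
microsim_prevalent <- function(config = synthetic_config(), n_women = 2e5,
                               seed = 1L, mrr = 1, trend = "S1",
                               n_blocks = 10L) {
  rates <- synth_rates(config, seed)
  set.seed(as.integer(seed) + 2000003L)
  ref <- config$ref_year
  yds <- (ref - 17L):(ref - 1L)
  parity_on <- !is.null(config$parity)
  block_tot <- numeric(n_blocks)
  total <- 0; n_dec <- 0L
  bins <- c(u5 = 0, a5_9 = 0, a10_17 = 0)
  by_site <- setNames(numeric(nrow(config$sites)), config$sites$site)
  for (rc in rates) {
    hcat <- hdi_category(rc$country$hdi)
    for (yd in yds) {
      mult <- trend_multiplier(trend, yd, hcat, ref)
      pop_md <- rc$pop2020[band_of_age(15:67)] / 5 *
        (1 + rc$country$growth)^(yd - ref)
      md <- sample(15:67, n_women, replace = TRUE, prob = pop_md)
      W <- sum(pop_md) / n_women
      blk <- (seq_len(n_women) - 1L) %% n_blocks + 1L
      ys <- (ref - 18L):yd
      P <- sapply(ys, function(y) fert_at_age(rc$fert_band, md - (yd - y)))
      if (parity_on) {
        B <- matrix(runif(n_women * length(ys)) < P, n_women)
        dp <- death_probs(rc, md, config, K = rowSums(B), mult = mult)
      } else {
        dp <- death_probs(rc, md, config, mult = mult)
      }
      die <- runif(n_women) < dp$p
      idx <- which(die)
      n_dec <- n_dec + length(idx)
      if (!length(idx)) next
      if (!parity_on) {
        B <- matrix(FALSE, n_women, length(ys))
        B[idx, ] <- runif(length(idx) * length(ys)) < P[idx, , drop = FALSE]
      }
      site_of <- vapply(idx, function(i) {
        sample(colnames(dp$by_site), 1L, prob = dp$by_site[i, ])
      }, character(1))
      kid <- which(B[idx, , drop = FALSE], arr.ind = TRUE)
      if (!nrow(kid)) next
      by <- ys[kid[, 2]]
      minor <- by >= ref - 17L  # children born earlier are 18+ at ref
      kid <- kid[minor, , drop = FALSE]; by <- by[minor]
      if (!nrow(kid)) next
      alive <- sim_child_survival(by, rc$hazard, ref - 1L, yd = yd, mrr = mrr)
      contrib <- W * alive
      women <- idx[kid[, 1]]
      total <- total + sum(contrib)
      block_tot <- block_tot + as.numeric(
        tapply(contrib, factor(blk[women], levels = seq_len(n_blocks)), sum,
               default = 0))
      b <- age_bin(by, ref)
      for (bb in names(bins)) bins[bb] <- bins[bb] + sum(contrib[b == bb])
      for (s in unique(site_of)) {
        by_site[s] <- by_site[s] + sum(contrib[site_of[kid[, 1]] == s])
      }
    }
  }
  microsim_result(total, block_tot, n_blocks, n_women, n_dec, bins, by_site,
                  list())
}
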