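#' Configuration for the synthetic AMI registry generator
#'
#' Builds and validates the parameter set controlling the synthetic city:
#' geography, demography, true incidence surfaces, and record-level noise.
#' The defaults describe a city of the scale studied in township-level AMI
#' surveillance work: ~300 townships grouped into 16 districts, twelve years
#' of data aggregated into four 3-year periods, four age groups from 35 up,
#' and stratum baseline incidence rates of realistic magnitude (tens per
#' 100,000 person-years for young women up to >1000 per 100,000 for the
#' oldest groups).
#'
#' @param n_districts number of districts.
#' @param townships_per_district townships in each district (>= 2).
#' @param years inclusive run of calendar years; its length must be a
#'   multiple of `period_length`.
#' @param period_length years per analysis period (default 3).
#' @param age_groups ordered labels of the age bands.
#' @param age_breaks lower bounds of the age bands plus an upper cap used
#'   when simulating individual ages.
#' @param sexes sex labels.
#' @param baseline_rates numeric array `age x sex x period` of stratum
#'   baseline incidence per 100,000 person-years, or `NULL` for the built-in
#'   defaults.
#' @param sd_spatial marginal standard deviation of the spatially structured
#'   log-rate field (ICAR-type, simulated on the township adjacency graph).
#' @param sd_unstructured standard deviation of the iid log-rate noise.
#' @param dup_probs named numeric vector of record-noise probabilities:
#'   `transfer` (split a stay into a same-day discharge/readmission pair),
#'   `short_stay` (spurious stay of <= 1 day for a new person),
#'   `readmission` (extra admission within 28 days of a true event's onset),
#'   `dual_death` (an in-hospital death is also present in the death stream).
#' @param fatal_frac fraction of true events that are fatal.
#' @param out_of_hospital_fatal_frac among fatal events, fraction dying out
#'   of hospital (recorded in the death stream only).
#' @param pop_median median township population aged 35+ (both sexes).
#' @param pop_log_sd log-scale dispersion of township populations.
#' @param pop_growth annual multiplicative population growth.
#' @param census_noise_sd log-scale sd of the multiplicative perturbation
#'   applied to the census copy of district populations.
#' @param discordant_district index (1-based) of the district whose yearbook
#'   population is deliberately inflated relative to the census, or `NULL`
#'   for none.
#' @param discordant_factor inflation factor for the discordant district.
#' @param seed integer root seed; every generator output is a pure function
#'   of the configuration including this seed.
#'
#' @return an object of class `registry_config` (a validated list).
#' @export
registry_config <- function(n_districts = 16L,
                            townships_per_district = 19L,
                            years = 2007:2018,
                            period_length = 3L,
                            age_groups = c("35-49", "50-64", "65-79", "80+"),
                            age_breaks = c(35, 50, 65, 80, 96),
                            sexes = c("male", "female"),
                            baseline_rates = NULL,
                            sd_spatial = 0.3,
                            sd_unstructured = 0.1,
                            dup_probs = c(transfer = 0.05, short_stay = 0.03,
                                          readmission = 0.05, dual_death = 1),
                            fatal_frac = 0.3,
                            out_of_hospital_fatal_frac = 0.3,
                            pop_median = 33903,
                            pop_log_sd = 0.82,
                            pop_growth = 0.005,
                            census_noise_sd = 0.01,
                            discordant_district = 2L,
                            discordant_factor = 1.3,
                            seed = 1L) {
  stopifnot(n_districts >= 1, townships_per_district >= 2,
            length(years) >= period_length,
            length(years) %% period_length == 0,
            all(diff(years) == 1),
            length(age_breaks) == length(age_groups) + 1,
            length(sexes) >= 1)
  need <- c("transfer", "short_stay", "readmission", "dual_death")
  if (!all(need %in% names(dup_probs)))
    stop("dup_probs must name: ", paste(need, collapse = ", "))
  dup_probs <- dup_probs[need]
  if (any(dup_probs < 0 | dup_probs > 1)) stop("dup_probs must lie in [0, 1]")
  if (sd_spatial < 0 || sd_unstructured < 0) stop("effect sds must be >= 0")
  if (fatal_frac < 0 || fatal_frac > 1 ||
      out_of_hospital_fatal_frac < 0 || out_of_hospital_fatal_frac > 1)
    stop("fractions must lie in [0, 1]")

  n_periods <- length(years) %/% period_length
  periods <- split(years, rep(seq_len(n_periods), each = period_length))
  names(periods) <- vapply(periods, function(y)
    paste0(min(y), "-", max(y)), character(1))

  if (is.null(baseline_rates)) {
    baseline_rates <- default_baseline_rates(age_groups, sexes, n_periods)
  }
  stopifnot(length(dim(baseline_rates)) == 3,
            dim(baseline_rates)[1] == length(age_groups),
            dim(baseline_rates)[2] == length(sexes),
            dim(baseline_rates)[3] == n_periods,
            all(baseline_rates > 0))
  dimnames(baseline_rates) <- list(age_groups, sexes, names(periods))

  structure(list(
    n_districts = as.integer(n_districts),
    townships_per_district = as.integer(townships_per_district),
    years = as.integer(years),
    period_length = as.integer(period_length),
    periods = periods,
    age_groups = age_groups,
    age_breaks = age_breaks,
    sexes = sexes,
    baseline_rates = baseline_rates,
    sd_spatial = sd_spatial,
    sd_unstructured = sd_unstructured,
    dup_probs = dup_probs,
    fatal_frac = fatal_frac,
    out_of_hospital_fatal_frac = out_of_hospital_fatal_frac,
    pop_median = pop_median,
    pop_log_sd = pop_log_sd,
    pop_growth = pop_growth,
    census_noise_sd = census_noise_sd,
    discordant_district = discordant_district,
    discordant_factor = discordant_factor,
    seed = as.integer(seed)
  ), class = "registry_config")
}

# Stratum baselines (per 100,000 person-years) of the magnitude reported for
# a large East-Asian megacity: strong age gradient, male excess, rising
# trends in younger males and declining trends in older groups. Reference
# values are defined on four periods and interpolated to other period counts.
default_baseline_rates <- function(age_groups, sexes, n_periods) {
  ref <- array(NA_real_, dim = c(4, 2, 4))
  ref[, 1, ] <- rbind(c(96.5, 118.8, 137.0, 148.8),
                      c(279.8, 317.5, 336.1, 372.6),
                      c(686.2, 729.6, 669.3, 645.2),
                      c(1282.0, 1378.0, 1262.0, 1301.0))
  ref[, 2, ] <- rbind(c(12.2, 12.3, 12.6, 12.3),
                      c(85.3, 100.3, 87.2, 83.1),
                      c(525.5, 562.9, 500.6, 445.9),
                      c(1220.0, 1372.0, 1317.0, 1192.0))
  if (length(age_groups) != 4 || length(sexes) != 2)
    stop("default baseline rates require 4 age groups and 2 sexes; ",
         "supply baseline_rates explicitly otherwise")
  out <- array(NA_real_, dim = c(4, 2, n_periods))
  for (a in 1:4) for (s in 1:2) {
    if (n_periods == 1) out[a, s, 1] <- ref[a, s, 1]
    else out[a, s, ] <- stats::approx(seq(0, 1, length.out = 4), ref[a, s, ],
                                      xout = seq(0, 1, length.out = n_periods))$y
  }
  out
}

#' Lay out townships and districts on a planar lattice
#'
#' Townships are placed on a near-square lattice in serpentine (boustrophedon)
#' order so that any contiguous run of townships is connected; districts are
#' contiguous runs of `townships_per_district` cells. Adjacency is
#' rook-neighbourhood (shared lattice edge), which yields a symmetric,
#' connected graph without self-loops — all that an intrinsic CAR prior needs
#' from real administrative geography.
#'
#' @param config a [registry_config()].
#' @return an object of class `township_map`: a list with `townships`
#'   (data.frame: township_id, district_id, row, col), `edges` (data.frame of
#'   undirected edges, `from < to`), and `n`.
#' @export
sim_township_map <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  n <- config$n_districts * config$townships_per_district
  if (n < 2) stop("need at least 2 townships")
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  # serpentine ordering of lattice cells, row-major with even rows reversed
  ord <- integer(0)
  for (r in seq_len(nr)) {
    cols <- if (r %% 2 == 1) seq_len(nc) else rev(seq_len(nc))
    ord <- c(ord, (r - 1) * nc + cols)
  }
  cells <- ord[seq_len(n)]
  row <- (cells - 1) %/% nc + 1
  col <- (cells - 1) %% nc + 1
  township_id <- sprintf("T%03d", seq_len(n))
  district_id <- sprintf("D%02d", rep(seq_len(config$n_districts),
                                      each = config$townships_per_district))
  townships <- data.frame(township_id, district_id, row, col,
                          stringsAsFactors = FALSE)
  # rook adjacency among occupied cells
  occ <- matrix(NA_integer_, nr, nc)
  occ[cbind(row, col)] <- seq_len(n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    r <- row[i]; cc <- col[i]
    if (cc < nc && !is.na(occ[r, cc + 1])) { from <- c(from, i); to <- c(to, occ[r, cc + 1]) }
    if (r < nr && !is.na(occ[r + 1, cc])) { from <- c(from, i); to <- c(to, occ[r + 1, cc]) }
  }
  edges <- data.frame(from = township_id[pmin(from, to)],
                      to = township_id[pmax(from, to)],
                      stringsAsFactors = FALSE)
  structure(list(townships = townships, edges = edges, n = n),
            class = "township_map")
}

#' @export
print.township_map <- function(x, ...) {
  cat("Township map:", x$n, "townships,",
      length(unique(x$townships$district_id)), "districts,",
      nrow(x$edges), "adjacency edges\n")
  invisible(x)
}

#' Simulate true incidence surfaces
#'
#' Log true rates are `log(baseline) + u_i + v_i`, with `u` a zero-mean
#' spatially structured field simulated from the intrinsic CAR family via the
#' eigendecomposition of the graph Laplacian (null space removed, rescaled so
#' the marginal standard deviation equals `sd_spatial`) and `v` iid normal
#' noise with sd `sd_unstructured`. Both effects are centred to sum to zero
#' across townships, matching the identifiability constraint the fitting
#' model imposes. The same `u` and `v` apply to every stratum, so the
#' geographic pattern is shared across ages, sexes and periods.
#'
#' @param config a [registry_config()].
#' @param map a [sim_township_map()] result.
#' @return object of class `ground_truth_rates`: list with `rate` (array
#'   township x age x sex x period, events per 100,000 person-years), `u`,
#'   `v`.
#' @export
sim_true_rates <- function(config, map) {
  stopifnot(inherits(config, "registry_config"), inherits(map, "township_map"))
  n <- map$n
  adj <- build_adjacency(map)
  if (adj$n_components > 1 && length(adj$islands) == 0)
    stop("adjacency graph is disconnected; no island policy applies")
  set.seed(config$seed + 1L)
  u <- numeric(n)
  if (config$sd_spatial > 0) {
    idx <- match(map$edges$from, map$townships$township_id)
    jdx <- match(map$edges$to, map$townships$township_id)
    L <- matrix(0, n, n)
    for (k in seq_along(idx)) {
      L[idx[k], jdx[k]] <- L[idx[k], jdx[k]] - 1
      L[jdx[k], idx[k]] <- L[jdx[k], idx[k]] - 1
    }
    diag(L) <- -rowSums(L)
    eg <- eigen(L, symmetric = TRUE)
    keep <- eg$values > 1e-8 * max(eg$values)
    z <- rnorm(sum(keep))
    u <- drop(eg$vectors[, keep, drop = FALSE] %*% (z / sqrt(eg$values[keep])))
    u <- u - mean(u)
    u <- u * config$sd_spatial / stats::sd(u)
  }
  v <- numeric(n)
  if (config$sd_unstructured > 0) {
    v <- rnorm(n, 0, config$sd_unstructured)
    v <- v - mean(v)
  }
  na <- length(config$age_groups); ns <- length(config$sexes)
  np <- length(config$periods)
  rate <- array(NA_real_, dim = c(n, na, ns, np),
                dimnames = list(map$townships$township_id, config$age_groups,
                                config$sexes, names(config$periods)))
  re <- exp(u + v)
  for (a in seq_len(na)) for (s in seq_len(ns)) for (p in seq_len(np))
    rate[, a, s, p] <- config$baseline_rates[a, s, p] * re
  structure(list(rate = rate, u = u, v = v), class = "ground_truth_rates")
}

#' Simulate township populations and district age structures
#'
#' Township populations (aged 35+, both sexes combined) are log-normally
#' dispersed around the configured median; annual totals by sex follow a
#' deterministic growth factor and a near-even sex split. Age structure is
#' only generated at district level (four-group proportions per sex), so a
#' township's true age-specific person-years equal its sex total times its
#' district's proportions — exactly the assumption the disaggregation step
#' makes, which lets tests verify exact recovery. A second, census-like copy
#' of district totals is produced with small multiplicative noise plus one
#' deliberately discordant district for Bland-Altman checking.
#'
#' @param config a [registry_config()].
#' @param map a [sim_township_map()] result.
#' @return object of class `registry_population`: list with
#'   `township_totals` (township_id, year, sex, total),
#'   `district_dist` (district_id, sex, age_group, proportion),
#'   `census` (district_id, yearbook, census, year).
#' @export
sim_population <- function(config, map) {
  stopifnot(inherits(config, "registry_config"), inherits(map, "township_map"))
  set.seed(config$seed + 2L)
  n <- map$n
  base <- rlnorm(n, meanlog = log(config$pop_median), sdlog = config$pop_log_sd)
  frac_male <- pmin(0.6, pmax(0.4, rnorm(n, 0.5, 0.01)))
  years <- config$years
  growth <- (1 + config$pop_growth)^(years - years[1])
  tt <- expand.grid(township_id = map$townships$township_id,
                    year = years, sex = config$sexes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ti <- match(tt$township_id, map$townships$township_id)
  yi <- match(tt$year, years)
  sexfrac <- ifelse(tt$sex == config$sexes[1], frac_male[ti], 1 - frac_male[ti])
  tt$total <- round(base[ti] * growth[yi] * sexfrac)

  # district age-sex structure: jittered around a plausible 35+ profile
  base_prop <- c(0.40, 0.32, 0.21, 0.07)
  if (length(config$age_groups) != 4)
    base_prop <- rep(1 / length(config$age_groups), length(config$age_groups))
  districts <- unique(map$townships$district_id)
  dd <- expand.grid(district_id = districts, sex = config$sexes,
                    age_group = config$age_groups,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dd <- dd[order(dd$district_id, dd$sex), ]
  prop <- numeric(nrow(dd))
  for (d in districts) for (s in config$sexes) {
    sel <- dd$district_id == d & dd$sex == s
    p <- base_prop * exp(rnorm(length(base_prop), 0, 0.08))
    prop[sel] <- p / sum(p)
  }
  dd$proportion <- prop
  rownames(dd) <- NULL

  ref_year <- if (2010 %in% years) 2010L else years[ceiling(length(years) / 2)]
  dmap <- map$townships$district_id[match(tt$township_id, map$townships$township_id)]
  sel <- tt$year == ref_year
  yearbook <- tapply(tt$total[sel], dmap[sel], sum)
  census <- as.numeric(yearbook) * exp(rnorm(length(yearbook), 0, config$census_noise_sd))
  if (!is.null(config$discordant_district)) {
    di <- config$discordant_district
    if (di >= 1 && di <= length(yearbook))
      census[di] <- census[di] / config$discordant_factor
  }
  census_df <- data.frame(district_id = names(yearbook),
                          yearbook = as.numeric(yearbook),
                          census = round(census), year = ref_year,
                          stringsAsFactors = FALSE)
  structure(list(township_totals = tt, district_dist = dd, census = census_df),
            class = "registry_population")
}

#' Simulate individual hospitalization and death records
#'
#' For each township x sex x age-group x year stratum the number of true
#' disease events is Poisson with mean `rate x person-years`. Every true
#' event belongs to a distinct person. Non-fatal events produce one
#' hospitalization (stay of 2-14 days); fatal in-hospital events produce a
#' hospitalization with discharge status `died` and (with probability
#' `dup_probs["dual_death"]`) a matching death record; fatal out-of-hospital
#' events produce a death record only. Record-level noise is then injected:
#' same-day transfer splits, spurious stays of <= 1 day for new persons, and
#' readmissions within 28 days of a true event's onset. Ground-truth unique
#' event counts are retained per township stratum.
#'
#' @param config a [registry_config()].
#' @param rates a [sim_true_rates()] result.
#' @param population a [sim_population()] result.
#' @param map a [sim_township_map()] result.
#' @return object of class `registry_records`: list with `hospital` and
#'   `deaths` data frames (the raw record streams), and `truth` (data.frame
#'   township_id, sex, age_group, period, events — unique true events).
#' @export
sim_events <- function(config, rates, population, map) {
  stopifnot(inherits(config, "registry_config"),
            inherits(rates, "ground_truth_rates"),
            inherits(population, "registry_population"),
            inherits(map, "township_map"))
  set.seed(config$seed + 3L)
  tt <- population$township_totals
  dd <- population$district_dist
  if (any(tt$total < 0)) stop("negative person-years")
  dmap <- map$townships$district_id[match(tt$township_id, map$townships$township_id)]
  # expand totals over age groups: person-years per township-sex-age-year
  strata <- merge(cbind(tt, district_id = dmap), dd,
                  by = c("district_id", "sex"), sort = FALSE)
  strata$person_years <- strata$total * strata$proportion
  if (any(strata$person_years < 0)) stop("person-years must be positive")
  year_period <- vapply(strata$year, function(y) {
    names(config$periods)[vapply(config$periods, function(p) y %in% p, logical(1))]
  }, character(1))
  ti <- match(strata$township_id, map$townships$township_id)
  ai <- match(strata$age_group, config$age_groups)
  si <- match(strata$sex, config$sexes)
  pi <- match(year_period, names(config$periods))
  lambda <- rates$rate[cbind(ti, ai, si, pi)] / 1e5 * strata$person_years
  strata$n_events <- rpois(nrow(strata), lambda)

  idx <- rep(seq_len(nrow(strata)), strata$n_events)
  n_ev <- length(idx)
  lo <- config$age_breaks[match(strata$age_group[idx], config$age_groups)]
  hi <- config$age_breaks[match(strata$age_group[idx], config$age_groups) + 1] - 1
  ev <- data.frame(
    person_id = sprintf("P%07d", seq_len(n_ev)),
    township_id = strata$township_id[idx],
    sex = strata$sex[idx],
    age_group = strata$age_group[idx],
    age = lo + floor(runif(n_ev) * (hi - lo + 1)),
    year = strata$year[idx],
    period = year_period[idx],
    stringsAsFactors = FALSE
  )
  ystart <- as.Date(sprintf("%d-01-01", ev$year))
  ylen <- as.integer(as.Date(sprintf("%d-01-01", ev$year + 1)) - ystart)
  ev$onset <- ystart + floor(runif(n_ev) * ylen)
  ev$fatal <- runif(n_ev) < config$fatal_frac
  ev$ooh <- ev$fatal & (runif(n_ev) < config$out_of_hospital_fatal_frac)

  dx_pool <- c("I21.0", "I21.1", "I21.4", "I21.9", "I22.0", "I22.1", "I22.9")
  dp <- config$dup_probs

  hosp_ev <- ev[!ev$ooh, , drop = FALSE]
  n_h <- nrow(hosp_ev)
  los <- ifelse(hosp_ev$fatal, floor(runif(n_h) * 11),      # 0-10 days
                2 + floor(runif(n_h) * 13))                 # 2-14 days
  hosp <- data.frame(
    person_id = hosp_ev$person_id,
    admission_date = hosp_ev$onset,
    discharge_date = hosp_ev$onset + los,
    discharge_status = ifelse(hosp_ev$fatal, "died", "alive"),
    dx_code = sample(dx_pool, n_h, replace = TRUE),
    age = hosp_ev$age, sex = hosp_ev$sex,
    township_id = hosp_ev$township_id,
    stringsAsFactors = FALSE
  )

  # in-hospital deaths dual-recorded in the death stream
  inh <- hosp_ev$fatal & (runif(n_h) < dp["dual_death"])
  deaths_inh <- data.frame(
    person_id = hosp_ev$person_id[inh],
    death_date = hosp$discharge_date[inh],
    place = "in_hospital",
    cause_code = sample(dx_pool, sum(inh), replace = TRUE),
    age = hosp_ev$age[inh], sex = hosp_ev$sex[inh],
    township_id = hosp_ev$township_id[inh],
    stringsAsFactors = FALSE
  )
  ooh_ev <- ev[ev$ooh, , drop = FALSE]
  deaths_ooh <- data.frame(
    person_id = ooh_ev$person_id,
    death_date = ooh_ev$onset,
    place = "out_of_hospital",
    cause_code = sample(dx_pool, nrow(ooh_ev), replace = TRUE),
    age = ooh_ev$age, sex = ooh_ev$sex,
    township_id = ooh_ev$township_id,
    stringsAsFactors = FALSE
  )
  deaths <- rbind(deaths_inh, deaths_ooh)

  # noise 1: same-day transfer splits (stay -> two same-day-chained stays)
  split_sel <- runif(n_h) < dp["transfer"]
  if (any(split_sel)) {
    k <- which(split_sel)
    off <- floor(runif(length(k)) * (los[k] + 1))
    part1 <- hosp[k, , drop = FALSE]
    part1$discharge_date <- part1$admission_date + off
    part1$discharge_status <- "alive"
    part2 <- hosp[k, , drop = FALSE]
    part2$admission_date <- part1$discharge_date
    hosp <- rbind(hosp[-k, , drop = FALSE], part1, part2)
  }

  # noise 2: spurious <= 1-day stays for otherwise-unseen persons
  n_spur <- rbinom(1, n_h, dp["short_stay"])
  if (n_spur > 0) {
    sp_town <- sample(map$townships$township_id, n_spur, replace = TRUE)
    sp_start <- as.Date(sprintf("%d-01-01", config$years[1]))
    sp_span <- as.integer(as.Date(sprintf("%d-12-31", config$years[length(config$years)])) - sp_start)
    sp_adm <- sp_start + floor(runif(n_spur) * sp_span)
    spur <- data.frame(
      person_id = sprintf("S%06d", seq_len(n_spur)),
      admission_date = sp_adm,
      discharge_date = sp_adm + floor(runif(n_spur) * 2),  # 0 or 1 day
      discharge_status = "alive",
      dx_code = sample(dx_pool, n_spur, replace = TRUE),
      age = 35 + floor(runif(n_spur) * 55),
      sex = sample(config$sexes, n_spur, replace = TRUE),
      township_id = sp_town,
      stringsAsFactors = FALSE
    )
    hosp <- rbind(hosp, spur)
  }

  # noise 3: readmissions within 28 days of a non-fatal index event's onset
  readm_ok <- !hosp_ev$fatal & (los + 2 <= 28) & (runif(n_h) < dp["readmission"])
  if (any(readm_ok)) {
    k <- which(readm_ok)
    gap <- los[k] + 2 + floor(runif(length(k)) * (28 - los[k] - 1))  # in [los+2, 28]
    adm <- hosp_ev$onset[k] + pmin(gap, 28)
    los2 <- 2 + floor(runif(length(k)) * 4)
    readm <- data.frame(
      person_id = hosp_ev$person_id[k],
      admission_date = adm,
      discharge_date = adm + los2,
      discharge_status = "alive",
      dx_code = sample(dx_pool, length(k), replace = TRUE),
      age = hosp_ev$age[k], sex = hosp_ev$sex[k],
      township_id = hosp_ev$township_id[k],
      stringsAsFactors = FALSE
    )
    hosp <- rbind(hosp, readm)
  }
  rownames(hosp) <- NULL; rownames(deaths) <- NULL

  truth <- aggregate(list(events = rep(1L, n_ev)),
                     by = ev[c("township_id", "sex", "age_group", "period")],
                     FUN = sum)
  structure(list(hospital = hosp, deaths = deaths, truth = truth,
                 n_true_events = n_ev),
            class = "registry_records")
}

#' Generate a complete synthetic registry
#'
#' Convenience wrapper running [sim_township_map()], [sim_true_rates()],
#' [sim_population()] and [sim_events()] with a shared configuration.
#'
#' @param config a [registry_config()].
#' @return object of class `synthetic_registry`: list with `config`, `map`,
#'   `rates`, `population`, `records`.
#' @export
sim_registry <- function(config = registry_config()) {
  map <- sim_township_map(config)
  rates <- sim_true_rates(config, map)
  population <- sim_population(config, map)
  records <- sim_events(config, rates, population, map)
  structure(list(config = config, map = map, rates = rates,
                 population = population, records = records),
            class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("Synthetic AMI registry\n")
  cat("  townships:", x$map$n, " districts:", x$config$n_districts, "\n")
  cat("  years:", min(x$config$years), "-", max(x$config$years),
      " periods:", length(x$config$periods), "\n")
  cat("  true events:", x$records$n_true_events,
      " hospital records:", nrow(x$records$hospital),
      " death records:", nrow(x$records$deaths), "\n")
  invisible(x)
}

#' Write a synthetic registry to plain-text files
#'
#' Writes hospital.csv, deaths.csv, population.csv, district_dist.csv,
#' adjacency.csv (edge list), townships.csv and ground_truth.json into `dir`.
#'
#' @param registry a [sim_registry()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "synthetic_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("hospital.csv", "deaths.csv", "population.csv",
                            "district_dist.csv", "adjacency.csv",
                            "townships.csv", "ground_truth.json"))
  write.csv(registry$records$hospital, paths[1], row.names = FALSE)
  write.csv(registry$records$deaths, paths[2], row.names = FALSE)
  write.csv(registry$population$township_totals, paths[3], row.names = FALSE)
  write.csv(registry$population$district_dist, paths[4], row.names = FALSE)
  write.csv(registry$map$edges, paths[5], row.names = FALSE)
  write.csv(registry$map$townships, paths[6], row.names = FALSE)
  jsonlite::write_json(
    list(n_true_events = registry$records$n_true_events,
         truth = registry$records$truth),
    paths[7], dataframe = "columns", digits = NA)
  invisible(paths)
}

#' Assign analysis periods to calendar years
#'
#' @param year integer vector of calendar years.
#' @param periods named list of year vectors as in `registry_config()$periods`.
#' @return character vector of period labels (NA when outside all periods).
#' @export
assign_period <- function(year, periods) {
  lab <- rep(NA_character_, length(year))
  for (p in names(periods)) lab[year %in% periods[[p]]] <- p
  lab
}

#' Assign age-group labels from ages
#'
#' @param age numeric vector of ages in years.
#' @param breaks lower bounds of age bands plus an upper cap
#'   (default `c(35, 50, 65, 80, Inf)`).
#' @param labels band labels.
#' @return character vector of labels (NA below the first break).
#' @export
assign_age_group <- function(age, breaks = c(35, 50, 65, 80, Inf),
                             labels = c("35-49", "50-64", "65-79", "80+")) {
  stopifnot(length(breaks) == length(labels) + 1)
  as.character(cut(age, breaks = breaks, labels = labels, right = FALSE))
}
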