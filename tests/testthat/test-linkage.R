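test_that("eligibility filter keeps I21-I22 at ages 35+ and counts drops", {
  h <- rbind(hosp_rec("p1", "2008-01-01", "2008-01-05", dx = "I21.4", age = 60),
             hosp_rec("p2", "2008-01-01", "2008-01-05", dx = "I25.1", age = 60),
             hosp_rec("p3", "2008-01-01", "2008-01-05", dx = "I21.0", age = 34),
             hosp_rec("p4", "2008-01-01", "2008-01-05", dx = "I22.9", age = 35))
  d <- rbind(death_rec("p5", "2008-02-01", code = "I21.9", age = 80),
             death_rec("p6", "2008-02-01", code = "C34.1", age = 80))
  out <- filter_eligible(h, d)
  expect_setequal(out$hospital$person_id, c("p1", "p4"))
  expect_identical(out$deaths$person_id, "p5")
  expect_equal(unname(out$dropped["hospital_code"]), 1)
  expect_equal(unname(out$dropped["hospital_age"]), 1)
  expect_equal(unname(out$dropped["death_code"]), 1)

  d_bad <- death_rec("p7", "2008-02-01", code = "garbage", age = 80)
  expect_warning(out2 <- filter_eligible(h, d_bad), "malformed")
  expect_equal(unname(out2$dropped["death_malformed_code"]), 1)
})

test_that("same-day chains collapse into single episodes with summed stay length", {
  h <- rbind(hosp_rec("p1", "2008-01-01", "2008-01-05"),
             hosp_rec("p1", "2008-01-05", "2008-01-09"))
  ep <- merge_same_day_episodes(h)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_date, as.Date("2008-01-01"))
  expect_equal(ep$end_date, as.Date("2008-01-09"))
  expect_equal(ep$total_los, 8)
  expect_equal(ep$n_stays, 2L)

  # a gap of more than a day leaves two episodes
  h2 <- rbind(hosp_rec("p1", "2008-01-01", "2008-01-05"),
              hosp_rec("p1", "2008-01-07", "2008-01-09"))
  expect_equal(nrow(merge_same_day_episodes(h2)), 2)

  # single stay passes through unchanged
  ep3 <- merge_same_day_episodes(hosp_rec("p1", "2008-01-01", "2008-01-05"))
  expect_equal(ep3$total_los, 4)
  expect_false(ep3$fatal)

  # overlapping stays merge and are flagged
  h4 <- rbind(hosp_rec("p1", "2008-01-01", "2008-01-10"),
              hosp_rec("p1", "2008-01-03", "2008-01-06", status = "died"))
  ep4 <- merge_same_day_episodes(h4)
  expect_equal(nrow(ep4), 1)
  expect_true(ep4$overlap)
  expect_true(ep4$fatal)
})

test_that("short-stay exclusion respects its death and readmission exceptions", {
  ep1 <- merge_same_day_episodes(hosp_rec("p1", "2008-01-01", "2008-01-02"))
  out <- exclude_short_stays(ep1, empty_deaths())
  expect_equal(nrow(out$episodes), 0)
  expect_equal(out$n_excluded, 1L)

  # same-day death record keeps the stay
  out2 <- exclude_short_stays(ep1, death_rec("p1", "2008-01-02"))
  expect_equal(nrow(out2$episodes), 1)

  # a 1-day stay that chained into a same-day readmission is kept
  h3 <- rbind(hosp_rec("p1", "2008-01-01", "2008-01-01"),
              hosp_rec("p1", "2008-01-01", "2008-01-02"))
  ep3 <- merge_same_day_episodes(h3)
  out3 <- exclude_short_stays(ep3, empty_deaths())
  expect_equal(nrow(out3$episodes), 1)

  # fatal 1-day stay is kept
  ep4 <- merge_same_day_episodes(
    hosp_rec("p1", "2008-01-01", "2008-01-01", status = "died"))
  expect_equal(nrow(exclude_short_stays(ep4, empty_deaths())$episodes), 1)
})

test_that("in-hospital deaths are absorbed; others become death-only episodes", {
  ep <- merge_same_day_episodes(
    hosp_rec("p1", "2008-01-01", "2008-01-09", status = "died"))
  lk <- link_in_hospital_deaths(ep, death_rec("p1", "2008-01-09"))
  expect_equal(nrow(lk$episodes), 1)
  expect_true(lk$episodes$fatal)
  expect_equal(lk$n_dual, 1L)

  lk2 <- link_in_hospital_deaths(ep[0, ],
                                 death_rec("p2", "2008-03-01",
                                           place = "out_of_hospital"))
  expect_equal(nrow(lk2$episodes), 1)
  expect_identical(lk2$episodes$source, "death_only")
  expect_true(lk2$episodes$fatal)

  # death 11 days after discharge is separate here, merged by the 28-day rule
  ep3 <- merge_same_day_episodes(hosp_rec("p1", "2008-01-01", "2008-01-09"))
  lk3 <- link_in_hospital_deaths(ep3, death_rec("p1", "2008-01-20"))
  expect_equal(nrow(lk3$episodes), 2)
  cl3 <- apply_28day_rule(lk3$episodes)
  expect_equal(nrow(cl3$events), 1)
  expect_true(cl3$events$fatal)
})

test_that("28-day collapse is anchored at the index onset", {
  mk <- function(days) {
    do.call(rbind, lapply(days, function(d)
      hosp_rec("p1", as.Date("2008-01-01") + d, as.Date("2008-01-03") + d)))
  }
  ep <- merge_same_day_episodes(mk(c(0, 20, 40)))
  cl <- apply_28day_rule(ep)
  expect_equal(nrow(cl$events), 2)  # day 20 merges; day 40 anchors anew
  expect_equal(cl$n_collapsed, 1L)
  expect_equal(as.numeric(cl$events$onset_date - as.Date("2008-01-01")),
               c(0, 40))

  ep2 <- merge_same_day_episodes(mk(c(0, 29)))
  expect_equal(nrow(apply_28day_rule(ep2)$events), 2)  # 29 > 28
  ep2b <- merge_same_day_episodes(mk(c(0, 28)))
  expect_equal(nrow(apply_28day_rule(ep2b)$events), 1)  # boundary included

  ep3 <- merge_same_day_episodes(mk(0))
  expect_equal(nrow(apply_28day_rule(ep3)$events), 1)
})

test_that("pipeline agrees with the brute-force oracle on random record sets", {
  set.seed(42)
  n_cases <- 10000
  cases <- lapply(seq_len(n_cases), function(i) random_person_case())
  # oracle
  oracle <- lapply(cases, function(cs) oracle_link_person(cs$hosp, cs$dths))
  # pipeline, all persons at once
  recs <- lapply(seq_len(n_cases), function(i)
    case_to_records(cases[[i]], sprintf("c%05d", i)))
  hosp <- do.call(rbind, c(list(empty_hospital()),
                           Filter(Negate(is.null),
                                  lapply(recs, `[[`, "hospital"))))
  dths <- do.call(rbind, c(list(empty_deaths()),
                           Filter(Negate(is.null),
                                  lapply(recs, `[[`, "deaths"))))
  linked <- link_events(hosp, dths)
  got_n <- table(factor(linked$events$person_id,
                        levels = sprintf("c%05d", seq_len(n_cases))))
  fatal_tab <- tapply(linked$events$fatal,
                      factor(linked$events$person_id,
                             levels = sprintf("c%05d", seq_len(n_cases))),
                      sum)
  fatal_tab[is.na(fatal_tab)] <- 0
  exp_n <- vapply(oracle, `[[`, integer(1), "n_events")
  exp_f <- vapply(oracle, `[[`, integer(1), "n_fatal")
  expect_equal(as.integer(got_n), exp_n)
  expect_equal(as.integer(fatal_tab), exp_f)
})

test_that("linkage is idempotent on its own events", {
  set.seed(7)
  cfg <- registry_config(n_districts = 3, townships_per_district = 4,
                         years = 2007:2009, pop_median = 5000, seed = 7)
  reg <- sim_registry(cfg)
  linked <- link_events(reg$records$hospital, reg$records$deaths)
  ev <- linked$events
  # re-express events as records: fatal ones via the death stream
  h <- data.frame(person_id = ev$person_id[!ev$fatal],
                  admission_date = ev$onset_date[!ev$fatal],
                  discharge_date = ev$onset_date[!ev$fatal] + 2,
                  discharge_status = "alive", dx_code = "I21.0",
                  age = ev$age[!ev$fatal], sex = ev$sex[!ev$fatal],
                  township_id = ev$township_id[!ev$fatal],
                  stringsAsFactors = FALSE)
  d <- data.frame(person_id = ev$person_id[ev$fatal],
                  death_date = ev$onset_date[ev$fatal],
                  place = "out_of_hospital", cause_code = "I21.0",
                  age = ev$age[ev$fatal], sex = ev$sex[ev$fatal],
                  township_id = ev$township_id[ev$fatal],
                  stringsAsFactors = FALSE)
  relinked <- link_events(h, d)
  expect_equal(relinked$audit$n_final_events, nrow(ev))
  key <- function(e) sort(paste(e$person_id, e$onset_date, e$fatal))
  expect_equal(key(relinked$events), key(ev))
})

test_that("widening the deduplication window never increases the event count", {
  set.seed(11)
  for (rep in 1:50) {
    cs <- random_person_case()
    rec <- case_to_records(cs, "p1")
    hosp <- if (is.null(rec$hospital)) empty_hospital() else rec$hospital
    dths <- if (is.null(rec$deaths)) empty_deaths() else rec$deaths
    counts <- vapply(c(7, 28, 56, 90), function(w)
      link_events(hosp, dths, window = w)$audit$n_final_events, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("aggregation builds a complete stratified table", {
  cfg <- registry_config(n_districts = 1, townships_per_district = 4,
                         years = 2007:2012)
  map <- sim_township_map(cfg)
  ev0 <- data.frame(person_id = character(), onset_date = as.Date(character()),
                    fatal = logical(), township_id = character(),
                    age = numeric(), sex = character(),
                    stringsAsFactors = FALSE)
  tab0 <- aggregate_events(ev0, map, cfg$periods)
  expect_equal(sum(tab0$events), 0)
  expect_equal(nrow(tab0), 4 * 2 * 4 * 2)  # townships x sexes x ages x periods

  ev <- data.frame(person_id = "p1", onset_date = as.Date("2009-06-15"),
                   fatal = FALSE, township_id = "T001", age = 40,
                   sex = "male", stringsAsFactors = FALSE)
  tab <- aggregate_events(ev, map, cfg$periods)
  hit <- tab[tab$events > 0, ]
  expect_equal(hit$period, "2007-2009")  # boundary year by onset membership
  expect_equal(hit$age_group, "35-49")

  ev_bad <- ev; ev_bad$township_id <- "T999"
  expect_error(aggregate_events(ev_bad, map, cfg$periods), "T999")
})
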