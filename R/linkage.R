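#' Filter records for AMI eligibility
#'
#' Keeps hospital records whose principal diagnosis, and death records whose
#' underlying cause, is an ICD-10 I21 or I22 code, restricted to ages at or
#' above `min_age` (35 by default). Each stream is filtered on its own code,
#' with no cross-stream veto. Malformed codes (not letter-digit shaped) are
#' rejected with a warning and counted.
#'
#' @param hospital data.frame with columns person_id, admission_date,
#'   discharge_date, discharge_status, dx_code, age, sex, township_id.
#' @param deaths data.frame with columns person_id, death_date, place,
#'   cause_code, age, sex, township_id.
#' @param min_age minimum eligible age in years.
#' @param code_prefixes ICD-10 prefixes defining the condition.
#' @return list with filtered `hospital`, `deaths`, and `dropped`
#'   (named counts by reason).
#' @export
filter_eligible <- function(hospital, deaths, min_age = 35,
                            code_prefixes = c("I21", "I22")) {
  req_h <- c("person_id", "admission_date", "discharge_date",
             "discharge_status", "dx_code", "age", "sex", "township_id")
  req_d <- c("person_id", "death_date", "place", "cause_code", "age", "sex",
             "township_id")
  if (!all(req_h %in% names(hospital)))
    stop("hospital records missing columns: ",
         paste(setdiff(req_h, names(hospital)), collapse = ", "))
  if (!all(req_d %in% names(deaths)))
    stop("death records missing columns: ",
         paste(setdiff(req_d, names(deaths)), collapse = ", "))

  code_ok <- function(x) grepl("^[A-Z][0-9]{2}", as.character(x))
  pat <- paste0("^(", paste(code_prefixes, collapse = "|"), ")")

  h_malformed <- !code_ok(hospital$dx_code)
  d_malformed <- !code_ok(deaths$cause_code)
  if (any(h_malformed) || any(d_malformed))
    warning(sum(h_malformed) + sum(d_malformed),
            " record(s) rejected for malformed ICD codes")
  h_code <- !h_malformed & grepl(pat, hospital$dx_code)
  d_code <- !d_malformed & grepl(pat, deaths$cause_code)
  h_age <- hospital$age >= min_age
  d_age <- deaths$age >= min_age

  dropped <- c(
    hospital_malformed_code = sum(h_malformed),
    hospital_code = sum(!h_code & !h_malformed),
    hospital_age = sum(h_code & !h_age),
    death_malformed_code = sum(d_malformed),
    death_code = sum(!d_code & !d_malformed),
    death_age = sum(d_code & !d_age)
  )
  list(hospital = hospital[h_code & h_age, , drop = FALSE],
       deaths = deaths[d_code & d_age, , drop = FALSE],
       dropped = dropped)
}

#' Merge same-day discharge/readmission chains into care episodes
#'
#' Within each person, hospital stays sorted by admission date are chained
#' whenever a stay begins on (or before) the running discharge date of the
#' episode so far: same-day discharge/readmission pairs — transfers included
#' — become one continuous care episode. Overlapping stays (admission before
#' the previous discharge) are also folded into one episode and flagged.
#' Episode onset is the first admission, end the last discharge, total length
#' of stay the sum of the constituent stay lengths, and the episode is fatal
#' if any constituent stay ended in death.
#'
#' @param hospital filtered hospital records.
#' @return data.frame of episodes: person_id, onset_date, end_date,
#'   total_los, fatal, n_stays, overlap, source, township_id, age, sex.
#' @export
merge_same_day_episodes <- function(hospital) {
  cols <- c("person_id", "admission_date", "discharge_date",
            "discharge_status", "township_id", "age", "sex")
  dt <- data.table::as.data.table(hospital[, cols])
  dt[, admission_date := as.Date(admission_date)]
  dt[, discharge_date := as.Date(discharge_date)]
  if (any(dt$discharge_date < dt$admission_date))
    stop("discharge before admission in hospital records")
  if (nrow(dt) == 0) {
    return(data.frame(person_id = character(), onset_date = as.Date(character()),
                      end_date = as.Date(character()), total_los = numeric(),
                      fatal = logical(), n_stays = integer(),
                      overlap = logical(), source = character(),
                      township_id = character(), age = numeric(),
                      sex = character(), stringsAsFactors = FALSE))
  }
  data.table::setorder(dt, person_id, admission_date, discharge_date)
  dt[, chain_end := data.table::shift(cummax(as.integer(discharge_date)), fill = NA),
     by = person_id]
  dt[, new_episode := is.na(chain_end) | as.integer(admission_date) > chain_end]
  dt[, overlap := !is.na(chain_end) & as.integer(admission_date) < chain_end]
  dt[, episode_id := cumsum(new_episode), by = person_id]
  # plain-column aggregations keep data.table's grouped fast path
  dt[, died := discharge_status == "died"]
  dt[, los := as.numeric(discharge_date - admission_date)]
  ep <- dt[, .(
    onset_date = min(admission_date),
    end_date = max(discharge_date),
    total_los = sum(los),
    n_died = sum(died),
    n_stays = .N,
    n_overlap = sum(overlap),
    township_id = township_id[1],
    age = age[1],
    sex = sex[1]
  ), by = .(person_id, episode_id)]
  ep[, fatal := n_died > 0L]
  ep[, overlap := n_overlap > 0L]
  ep[, c("episode_id", "n_died", "n_overlap") := NULL]
  ep[, source := "hospital"]
  data.table::setcolorder(ep, c("person_id", "onset_date", "end_date",
                                "total_los", "fatal", "n_stays", "overlap",
                                "source", "township_id", "age", "sex"))
  as.data.frame(ep)
}

#' Exclude implausibly short hospital episodes
#'
#' Episodes with a total length of stay of one day or less that did not end
#' in death, have no death record for the person during the episode, and are
#' not same-day chains (single stay) are removed: such stays are unlikely to
#' be true AMI admissions.
#'
#' @param episodes output of [merge_same_day_episodes()].
#' @param deaths filtered death records.
#' @return list with `episodes` (retained) and `n_excluded`.
#' @export
exclude_short_stays <- function(episodes, deaths) {
  short <- episodes$total_los <= 1 & !episodes$fatal & episodes$n_stays == 1
  if (any(short) && nrow(deaths) > 0) {
    eps <- data.table::data.table(
      row = which(short),
      person_id = episodes$person_id[short],
      onset = as.Date(episodes$onset_date[short]),
      end = as.Date(episodes$end_date[short]))
    dd <- data.table::data.table(person_id = deaths$person_id,
                                 death_date = as.Date(deaths$death_date))
    hit <- eps[dd, on = .(person_id, onset <= death_date, end >= death_date),
               .(row = x.row), nomatch = NULL]
    short[unique(hit$row)] <- FALSE
  }
  list(episodes = episodes[!short, , drop = FALSE], n_excluded = sum(short))
}

#' Link death records to hospital episodes
#'
#' A death record whose person has a hospital episode containing the death
#' date is absorbed into that episode (the episode becomes fatal) — a case
#' identified in both streams counts once. Remaining death records become
#' death-only episodes with onset at the death date. When a death date falls
#' on the shared boundary of two episodes it is absorbed into the earlier one.
#'
#' @param episodes retained hospital episodes.
#' @param deaths filtered death records.
#' @return list with `episodes` (hospital episodes, fatality updated, plus
#'   death-only episodes) and `n_dual` (death records absorbed).
#' @export
link_in_hospital_deaths <- function(episodes, deaths) {
  deaths <- as.data.frame(deaths)
  if (nrow(deaths) > 0) deaths$death_date <- as.Date(deaths$death_date)
  absorbed <- rep(FALSE, nrow(deaths))
  if (nrow(deaths) > 0 && nrow(episodes) > 0) {
    epi <- data.table::as.data.table(episodes)
    epi[, episode_row := .I]
    dd <- data.table::as.data.table(deaths)
    dd[, death_row := .I]
    hit <- epi[dd, on = .(person_id, onset_date <= death_date,
                          end_date >= death_date),
               .(death_row = i.death_row, episode_row = x.episode_row,
                 onset = x.onset_date), nomatch = NULL]
    if (nrow(hit) > 0) {
      data.table::setorder(hit, death_row, onset)
      hit <- hit[!duplicated(death_row)]
      absorbed[hit$death_row] <- TRUE
      episodes$fatal[hit$episode_row] <- TRUE
    }
  }
  rest <- deaths[!absorbed, , drop = FALSE]
  if (nrow(rest) > 0) {
    death_ep <- data.frame(
      person_id = rest$person_id,
      onset_date = rest$death_date,
      end_date = rest$death_date,
      total_los = 0, fatal = TRUE, n_stays = 0L, overlap = FALSE,
      source = "death_only",
      township_id = rest$township_id, age = rest$age, sex = rest$sex,
      stringsAsFactors = FALSE
    )
    episodes <- rbind(episodes, death_ep)
  }
  list(episodes = episodes, n_dual = sum(absorbed))
}

#' Collapse episodes within a 28-day window into single events
#'
#' Implements the WHO-MONICA convention: per person, the earliest episode
#' anchors an event; any later episode whose onset falls within `window`
#' days of the anchor's onset merges into it (the event is fatal if any
#' member is); an episode starting more than `window` days after the anchor
#' opens a new event. The window is anchored at the index onset, not rolled
#' forward.
#'
#' @param episodes unified episodes from [link_in_hospital_deaths()].
#' @param window window length in days (default 28).
#' @return list with `events` (data.frame person_id, onset_date, fatal,
#'   township_id, age, sex) and `n_collapsed` (episodes merged away).
#' @export
apply_28day_rule <- function(episodes, window = 28) {
  if (nrow(episodes) == 0) {
    return(list(events = data.frame(
      person_id = character(), onset_date = as.Date(character()),
      fatal = logical(), township_id = character(), age = numeric(),
      sex = character(), stringsAsFactors = FALSE), n_collapsed = 0L))
  }
  dt <- data.table::as.data.table(episodes)
  data.table::setorder(dt, person_id, onset_date, end_date)
  collapse_one <- function(onset) {
    onset_i <- as.integer(onset)
    grp <- integer(length(onset))
    anchor <- onset_i[1]; g <- 1L
    for (k in seq_along(onset_i)) {
      if (onset_i[k] - anchor > window) { g <- g + 1L; anchor <- onset_i[k] }
      grp[k] <- g
    }
    grp
  }
  # fast path: persons with a single episode need no scan
  dt[, grp := 1L]
  multi <- dt[, .N, by = person_id][N > 1, person_id]
  if (length(multi) > 0)
    dt[person_id %in% multi, grp := collapse_one(onset_date), by = person_id]
  ev <- dt[, .(
    onset_date = onset_date[1],
    fatal = any(fatal),
    township_id = township_id[1],
    age = age[1],
    sex = sex[1],
    n_members = .N
  ), by = .(person_id, grp)]
  n_collapsed <- sum(ev$n_members - 1L)
  ev[, c("grp", "n_members") := NULL]
  list(events = as.data.frame(ev), n_collapsed = n_collapsed)
}

#' Run the full record-linkage pipeline
#'
#' Applies, in order: eligibility filtering (I21-I22, age >= `min_age`),
#' same-day episode merging, short-stay exclusion, in-hospital death linkage,
#' and the 28-day single-event rule. Returns the unique AMI events together
#' with an audit of how many records each rule removed or merged.
#'
#' @param hospital raw hospital-discharge records.
#' @param deaths raw death-registration records.
#' @param min_age minimum eligible age (default 35).
#' @param window deduplication window in days (default 28).
#' @return object of class `ami_events`: list with `events` (data.frame
#'   person_id, onset_date, fatal, township_id, age, sex) and `audit`
#'   (named counts).
#' @export
link_events <- function(hospital, deaths, min_age = 35, window = 28) {
  flt <- filter_eligible(hospital, deaths, min_age = min_age)
  ep <- merge_same_day_episodes(flt$hospital)
  n_merged <- if (nrow(ep) > 0) sum(ep$n_stays - 1L) else 0L
  ex <- exclude_short_stays(ep, flt$deaths)
  lk <- link_in_hospital_deaths(ex$episodes, flt$deaths)
  cl <- apply_28day_rule(lk$episodes, window = window)
  audit <- list(
    n_input_hospital = nrow(hospital),
    n_input_death = nrow(deaths),
    n_dropped = as.list(flt$dropped),
    n_merged_same_day = n_merged,
    n_excluded_short_stay = ex$n_excluded,
    n_dual_recorded_deaths = lk$n_dual,
    n_collapsed_28day = cl$n_collapsed,
    n_final_events = nrow(cl$events)
  )
  structure(list(events = cl$events, audit = audit), class = "ami_events")
}

#' @export
print.ami_events <- function(x, ...) {
  a <- x$audit
  cat("AMI event linkage\n")
  cat("  input records:     ", a$n_input_hospital, "hospital /",
      a$n_input_death, "death\n")
  cat("  same-day merges:   ", a$n_merged_same_day, "\n")
  cat("  short-stay excl.:  ", a$n_excluded_short_stay, "\n")
  cat("  dual-recorded:     ", a$n_dual_recorded_deaths, "\n")
  cat("  28-day collapsed:  ", a$n_collapsed_28day, "\n")
  cat("  unique events:     ", a$n_final_events, "\n")
  invisible(x)
}

#' Aggregate events into township strata
#'
#' Counts events per township x sex x age-group x period, producing a
#' complete table (zeros included). Events are assigned to periods by their
#' onset year.
#'
#' @param events the `events` data.frame of an [link_events()] result, or an
#'   `ami_events` object.
#' @param map a [sim_township_map()] result (or any object with
#'   `$townships$township_id`).
#' @param periods named list of year vectors.
#' @param age_breaks,age_groups age band definition, as in
#'   [assign_age_group()].
#' @param sexes sex labels expected in the data.
#' @return data.frame township_id, sex, age_group, period, events (class
#'   `stratified_counts`).
#' @export
aggregate_events <- function(events, map, periods,
                             age_breaks = c(35, 50, 65, 80, Inf),
                             age_groups = c("35-49", "50-64", "65-79", "80+"),
                             sexes = c("male", "female")) {
  if (inherits(events, "ami_events")) events <- events$events
  townships <- map$townships$township_id
  bad <- setdiff(unique(events$township_id), townships)
  if (length(bad) > 0)
    stop("events reference townships not in map: ",
         paste(head(bad, 10), collapse = ", "))
  yr <- as.integer(format(as.Date(events$onset_date), "%Y"))
  period <- assign_period(yr, periods)
  if (anyNA(period)) {
    warning(sum(is.na(period)), " event(s) outside all analysis periods dropped")
    keep <- !is.na(period)
    events <- events[keep, , drop = FALSE]; period <- period[keep]
  }
  age_group <- assign_age_group(events$age, age_breaks, age_groups)
  full <- expand.grid(township_id = townships, sex = sexes,
                      age_group = age_groups, period = names(periods),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    counts <- aggregate(
      list(events = rep(1L, nrow(events))),
      by = list(township_id = events$township_id, sex = events$sex,
                age_group = age_group, period = period),
      FUN = sum)
    full <- merge(full, counts,
                  by = c("township_id", "sex", "age_group", "period"),
                  all.x = TRUE, sort = FALSE)
    full$events[is.na(full$events)] <- 0L
  } else {
    full$events <- 0L
  }
  full <- full[order(full$township_id, full$sex, full$age_group, full$period), ]
  rownames(full) <- NULL
  class(full) <- c("stratified_counts", "data.frame")
  full
}
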