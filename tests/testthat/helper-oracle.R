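# Independent brute-force implementation of the four deduplication rules,
# applied per person with explicit loops. Deliberately written in the most
# literal way possible so it can serve as an oracle for the vectorized
# pipeline.

oracle_link_person <- function(hosp, dths, window = 28) {
  # hosp: data.frame(admission, discharge, died); dths: data.frame(day)
  # days are integers; returns list(n_events, n_fatal)
  episodes <- list()
  if (nrow(hosp) > 0) {
    hosp <- hosp[order(hosp$admission, hosp$discharge), , drop = FALSE]
    cur <- list(onset = hosp$admission[1], end = hosp$discharge[1],
                los = hosp$discharge[1] - hosp$admission[1],
                fatal = hosp$died[1], n = 1L)
    if (nrow(hosp) > 1) {
      for (k in 2:nrow(hosp)) {
        if (hosp$admission[k] <= cur$end) {
          cur$end <- max(cur$end, hosp$discharge[k])
          cur$los <- cur$los + (hosp$discharge[k] - hosp$admission[k])
          cur$fatal <- cur$fatal || hosp$died[k]
          cur$n <- cur$n + 1L
        } else {
          episodes[[length(episodes) + 1]] <- cur
          cur <- list(onset = hosp$admission[k], end = hosp$discharge[k],
                      los = hosp$discharge[k] - hosp$admission[k],
                      fatal = hosp$died[k], n = 1L)
        }
      }
    }
    episodes[[length(episodes) + 1]] <- cur
  }
  # short-stay exclusion
  keep <- list()
  for (ep in episodes) {
    has_death <- nrow(dths) > 0 && any(dths$day >= ep$onset & dths$day <= ep$end)
    if (ep$los <= 1 && !ep$fatal && ep$n == 1L && !has_death) next
    keep[[length(keep) + 1]] <- ep
  }
  episodes <- keep
  # death linkage
  death_only <- integer(0)
  if (nrow(dths) > 0) {
    for (day in dths$day) {
      hit <- FALSE
      for (j in seq_along(episodes)) {
        if (day >= episodes[[j]]$onset && day <= episodes[[j]]$end) {
          episodes[[j]]$fatal <- TRUE
          hit <- TRUE
          break
        }
      }
      if (!hit) death_only <- c(death_only, day)
    }
  }
  for (day in death_only)
    episodes[[length(episodes) + 1]] <- list(onset = day, end = day, los = 0,
                                             fatal = TRUE, n = 0L)
  if (length(episodes) == 0) return(list(n_events = 0L, n_fatal = 0L))
  # 28-day anchored collapse
  onsets <- vapply(episodes, `[[`, numeric(1), "onset")
  fatals <- vapply(episodes, `[[`, logical(1), "fatal")
  ord <- order(onsets)
  onsets <- onsets[ord]; fatals <- fatals[ord]
  n_events <- 0L; n_fatal <- 0L
  anchor <- -Inf; cur_fatal <- FALSE
  for (k in seq_along(onsets)) {
    if (onsets[k] - anchor > window) {
      if (n_events > 0L && cur_fatal) n_fatal <- n_fatal + 1L
      n_events <- n_events + 1L
      anchor <- onsets[k]
      cur_fatal <- fatals[k]
    } else {
      cur_fatal <- cur_fatal || fatals[k]
    }
  }
  if (cur_fatal) n_fatal <- n_fatal + 1L
  list(n_events = n_events, n_fatal = n_fatal)
}

# random per-person record sets: up to `max_records` records within `span`
# days, a mix of hospital stays and death records
random_person_case <- function(max_records = 6, span = 90) {
  n_h <- sample(0:4, 1)
  n_d <- sample(0:min(2, max_records - n_h), 1)
  if (n_h + n_d == 0) n_h <- 1
  hosp <- data.frame(admission = integer(0), discharge = integer(0),
                     died = logical(0))
  if (n_h > 0) {
    adm <- sample(0:(span - 11), n_h, replace = TRUE)
    los <- sample(0:10, n_h, replace = TRUE)
    hosp <- data.frame(admission = adm, discharge = adm + los,
                       died = runif(n_h) < 0.15)
  }
  dths <- data.frame(day = integer(0))
  if (n_d > 0)
    dths <- data.frame(day = sample(0:(span - 1), n_d, replace = TRUE))
  list(hosp = hosp, dths = dths)
}

# express a per-person case in the record schemas the pipeline reads
case_to_records <- function(case, person_id, township_id = "T001") {
  base_date <- as.Date("2008-01-01")
  h <- d <- NULL
  if (nrow(case$hosp) > 0)
    h <- data.frame(person_id = person_id,
                    admission_date = base_date + case$hosp$admission,
                    discharge_date = base_date + case$hosp$discharge,
                    discharge_status = ifelse(case$hosp$died, "died", "alive"),
                    dx_code = "I21.0", age = 60, sex = "male",
                    township_id = township_id, stringsAsFactors = FALSE)
  if (nrow(case$dths) > 0)
    d <- data.frame(person_id = person_id,
                    death_date = base_date + case$dths$day,
                    place = "in_hospital", cause_code = "I21.0",
                    age = 60, sex = "male", township_id = township_id,
                    stringsAsFactors = FALSE)
  list(hospital = h, deaths = d)
}

empty_hospital <- function() {
  data.frame(person_id = character(), admission_date = as.Date(character()),
             discharge_date = as.Date(character()),
             discharge_status = character(), dx_code = character(),
             age = numeric(), sex = character(), township_id = character(),
             stringsAsFactors = FALSE)
}

empty_deaths <- function() {
  data.frame(person_id = character(), death_date = as.Date(character()),
             place = character(), cause_code = character(), age = numeric(),
             sex = character(), township_id = character(),
             stringsAsFactors = FALSE)
}

hosp_rec <- function(person_id, admission, discharge, status = "alive",
                     dx = "I21.0", age = 60, sex = "male", township = "T001") {
  data.frame(person_id = person_id, admission_date = as.Date(admission),
             discharge_date = as.Date(discharge), discharge_status = status,
             dx_code = dx, age = age, sex = sex, township_id = township,
             stringsAsFactors = FALSE)
}

death_rec <- function(person_id, date, place = "in_hospital", code = "I21.0",
                      age = 60, sex = "male", township = "T001") {
  data.frame(person_id = person_id, death_date = as.Date(date), place = place,
             cause_code = code, age = age, sex = sex, township_id = township,
             stringsAsFactors = FALSE)
}

# Moran's I with a permutation test, for spatial-signal checks
morans_i <- function(x, edges_from, edges_to, n_perm = 999) {
  n <- length(x)
  w_sum <- 2 * length(edges_from)
  stat <- function(z) {
    zc <- z - mean(z)
    num <- 2 * sum(zc[edges_from] * zc[edges_to])
    (n / w_sum) * num / sum(zc^2)
  }
  obs <- stat(x)
  perms <- replicate(n_perm, stat(sample(x)))
  list(I = obs, p = (1 + sum(perms >= obs)) / (n_perm + 1))
}
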