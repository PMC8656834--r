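#' Standard population weights
#'
#' Validates a weight table for direct standardization: one row per stratum
#' (e.g. sex x age-group), weights non-negative and summing to 1 within
#' 1e-9.
#'
#' @param weights data.frame with a `weight` column plus stratum columns
#'   (typically `sex` and `age_group`).
#' @return the validated data.frame, classed `standard_weights`.
#' @export
standard_weights <- function(weights) {
  if (!"weight" %in% names(weights)) stop("weights need a 'weight' column")
  if (any(weights$weight < 0)) stop("weights must be non-negative")
  if (abs(sum(weights$weight) - 1) > 1e-9) stop("weights must sum to 1")
  class(weights) <- c("standard_weights", "data.frame")
  weights
}

#' Standard weights from a population table
#'
#' Derives census-style standardization weights from person-years in a
#' reference period: the share of total person-years in each sex x age-group
#' stratum. For synthetic runs this plays the role of the reference census
#' age-sex distribution.
#'
#' @param population a [disaggregate_population()] table.
#' @param period reference period label; default the first.
#' @return a [standard_weights()] data.frame with columns sex, age_group,
#'   weight.
#' @export
weights_from_population <- function(population, period = NULL) {
  if (is.null(period)) period <- sort(unique(population$period))[1]
  sub <- population[population$period == period, , drop = FALSE]
  agg <- aggregate(person_years ~ sex + age_group, data = sub, FUN = sum)
  agg$weight <- agg$person_years / sum(agg$person_years)
  standard_weights(agg[c("sex", "age_group", "weight")])
}

#' Directly standardized rates
#'
#' Computes, per group (by default township and period), the weighted sum of
#' stratum-specific rates using fixed standard-population weights:
#' \eqn{\sum_s w_s r_s}. When the weight table carries only `age_group`, the
#' result is an age-standardized rate; with `sex` and `age_group` it is an
#' age-sex-standardized rate.
#'
#' @param rate_table long data.frame of rates with stratum columns matching
#'   the weight table (e.g. township_id, sex, age_group, period, rate).
#' @param weights a [standard_weights()] table.
#' @param by grouping columns of the output.
#' @param rate_col name of the rate column.
#' @return data.frame of `by` columns plus `std_rate`.
#' @export
direct_standardize <- function(rate_table, weights,
                               by = c("township_id", "period"),
                               rate_col = "rate") {
  weights <- standard_weights(as.data.frame(weights))
  strat_cols <- setdiff(names(weights), "weight")
  if (!all(strat_cols %in% names(rate_table)))
    stop("rate table lacks stratum columns: ",
         paste(setdiff(strat_cols, names(rate_table)), collapse = ", "))
  merged <- merge(rate_table, weights, by = strat_cols)
  # every weighted stratum must be present in every group
  n_strata <- nrow(weights)
  cnt <- aggregate(list(k = merged$weight), by = merged[by], FUN = length)
  if (any(cnt$k != n_strata))
    stop("some groups are missing weighted strata")
  merged$wr <- merged$weight * merged[[rate_col]]
  out <- aggregate(list(std_rate = merged$wr), by = merged[by], FUN = sum)
  out[do.call(order, out[by]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Percent change between two rates
#'
#' `100 * (rate_end - rate_start) / rate_start`, reported to one decimal as
#' surveillance tables print it.
#'
#' @param rate_start,rate_end positive start rate and end rate (vectorized).
#' @return percent change, rounded to 1 decimal.
#' @export
percent_change <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) stop("rate_start must be positive")
  round(100 * (rate_end - rate_start) / rate_start, 1)
}

#' Percentile-based geographic inequality of area rates
#'
#' The absolute inequality is the gap between the 90th and 10th percentiles
#' of area rates, the relative inequality their ratio. Percentiles use
#' linear interpolation between order statistics and are rounded to one
#' decimal before the gap and ratio are derived, matching how published
#' tables print and difference their percentiles.
#'
#' @param rates numeric vector of area rates (per 100,000), length >= 10.
#' @return object of class `inequality_summary`: list with `p10`, `p90`,
#'   `absolute_gap`, `relative_ratio`, `median`, `q1`, `q3`, `n`.
#' @export
inequality_metrics <- function(rates) {
  if (length(rates) < 10) stop("need at least 10 areas")
  q <- quantile(rates, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  out <- inequality_from_percentiles(round(q[1], 1), round(q[5], 1))
  out$median <- round(q[3], 1)
  out$q1 <- round(q[2], 1)
  out$q3 <- round(q[4], 1)
  out$n <- length(rates)
  out
}

#' Inequality gap and ratio from given percentiles
#'
#' Derives the absolute (p90 - p10) and relative (p90 / p10) geographic
#' inequality from 10th and 90th percentile rates, e.g. as printed in a
#' published table; the ratio is reported to one decimal.
#'
#' @param p10,p90 the 10th and 90th percentile rates.
#' @return object of class `inequality_summary` (ratio `NA` with a warning
#'   when `p10` is zero).
#' @export
inequality_from_percentiles <- function(p10, p90) {
  ratio <- if (p10 == 0) {
    warning("p10 is zero; relative ratio undefined")
    NA_real_
  } else round(p90 / p10, 1)
  structure(list(p10 = p10, p90 = p90,
                 absolute_gap = round(p90 - p10, 1),
                 relative_ratio = ratio),
            class = "inequality_summary")
}

#' @export
print.inequality_summary <- function(x, ...) {
  cat(sprintf("p10 %.1f, p90 %.1f -> gap %.1f, ratio %s",
              x$p10, x$p90, x$absolute_gap,
              ifelse(is.na(x$relative_ratio), "NA",
                     sprintf("%.1f", x$relative_ratio))))
  if (!is.null(x$median))
    cat(sprintf("  (median %.1f, IQR %.1f-%.1f, n=%d)",
                x$median, x$q1, x$q3, x$n))
  cat("\n")
  invisible(x)
}

#' Rank-based decile classification of area rates
#'
#' Areas are ranked by rate (ties broken by the stable order of `ids`) and
#' split into ten bins whose sizes differ by at most one; bin 10 holds the
#' highest rates and is the conventional "high-rate" flag.
#'
#' @param rates numeric vector of area rates, length >= 10.
#' @param ids area identifiers used for stable tie-breaking (default the
#'   element order).
#' @return data.frame id, rate, decile (1 low - 10 high), high_rate
#'   (decile == 10).
#' @export
decile_classify <- function(rates, ids = seq_along(rates)) {
  n <- length(rates)
  if (n < 10) stop("need at least 10 areas")
  ord <- order(rates, ids)
  sizes <- rep(n %/% 10, 10)
  extra <- n %% 10
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  dec <- integer(n)
  dec[ord] <- rep(1:10, times = sizes)
  data.frame(id = ids, rate = rates, decile = dec,
             high_rate = dec == 10L, stringsAsFactors = FALSE)
}

# standardized-rate table per township/period for the summary rows:
# total (age-sex standardized) and per-sex (age-standardized within sex)
township_summary_rates <- function(rate_table, weights) {
  weights <- standard_weights(as.data.frame(weights))
  total <- direct_standardize(rate_table, weights)
  per_sex <- lapply(split(weights, weights$sex), function(w) {
    w$weight <- w$weight / sum(w$weight)
    sx <- w$sex[1]
    res <- direct_standardize(rate_table[rate_table$sex == sx, ],
                              w[c("age_group", "weight")],
                              by = c("township_id", "period"))
    res$sex <- sx
    res
  })
  list(total = total, per_sex = do.call(rbind, per_sex))
}

summary_row_order <- function(rate_table) {
  sexes <- unique(rate_table$sex)
  ages <- unique(rate_table$age_group)
  rows <- c("total")
  for (s in sexes) rows <- c(rows, s, paste(s, ages, sep = ":"))
  rows
}

#' Median (IQR) incidence summary across townships
#'
#' Reproduces the standard surveillance table layout: one row for the
#' age-sex-standardized total, one age-standardized row per sex, and one row
#' per sex x age-group, with the median and quartiles of township rates in
#' each analysis period. Values are rounded to one decimal.
#'
#' @param rate_table a [posterior_rate_table()] data.frame.
#' @param weights a [standard_weights()] table with sex and age_group.
#' @return data.frame with columns `row` plus `median_<period>`,
#'   `q1_<period>`, `q3_<period>` for every period.
#' @export
summarize_table1 <- function(rate_table, weights) {
  periods <- sort(unique(rate_table$period))
  std <- township_summary_rates(rate_table, weights)
  get_rates <- function(row, p) {
    if (row == "total") {
      std$total$std_rate[std$total$period == p]
    } else if (!grepl(":", row)) {
      std$per_sex$std_rate[std$per_sex$sex == row & std$per_sex$period == p]
    } else {
      parts <- strsplit(row, ":", fixed = TRUE)[[1]]
      rate_table$rate[rate_table$sex == parts[1] &
                        rate_table$age_group == parts[2] &
                        rate_table$period == p]
    }
  }
  rows <- summary_row_order(rate_table)
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  for (p in periods) {
    med <- q1 <- q3 <- numeric(length(rows))
    for (k in seq_along(rows)) {
      r <- get_rates(rows[k], p)
      if (length(r) == 0) stop("empty stratum: ", rows[k], " / ", p)
      qq <- quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      q1[k] <- round(qq[1], 1); med[k] <- round(qq[2], 1)
      q3[k] <- round(qq[3], 1)
    }
    out[[paste0("median_", p)]] <- med
    out[[paste0("q1_", p)]] <- q1
    out[[paste0("q3_", p)]] <- q3
  }
  out
}

#' Geographic inequality summary across townships
#'
#' Companion to [summarize_table1()]: per row and period, the 10th and 90th
#' percentiles of township rates with the absolute gap and relative ratio.
#'
#' @inheritParams summarize_table1
#' @return data.frame with columns `row` plus `p10_<period>`,
#'   `p90_<period>`, `gap_<period>`, `ratio_<period>`.
#' @export
summarize_table2 <- function(rate_table, weights) {
  periods <- sort(unique(rate_table$period))
  std <- township_summary_rates(rate_table, weights)
  get_rates <- function(row, p) {
    if (row == "total") {
      std$total$std_rate[std$total$period == p]
    } else if (!grepl(":", row)) {
      std$per_sex$std_rate[std$per_sex$sex == row & std$per_sex$period == p]
    } else {
      parts <- strsplit(row, ":", fixed = TRUE)[[1]]
      rate_table$rate[rate_table$sex == parts[1] &
                        rate_table$age_group == parts[2] &
                        rate_table$period == p]
    }
  }
  rows <- summary_row_order(rate_table)
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  for (p in periods) {
    p10 <- p90 <- gap <- ratio <- numeric(length(rows))
    for (k in seq_along(rows)) {
      r <- get_rates(rows[k], p)
      if (length(r) == 0) stop("empty stratum: ", rows[k], " / ", p)
      iq <- inequality_metrics(r)
      p10[k] <- iq$p10; p90[k] <- iq$p90
      gap[k] <- iq$absolute_gap; ratio[k] <- iq$relative_ratio
    }
    out[[paste0("p10_", p)]] <- p10
    out[[paste0("p90_", p)]] <- p90
    out[[paste0("gap_", p)]] <- gap
    out[[paste0("ratio_", p)]] <- ratio
  }
  out
}
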