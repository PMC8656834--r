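#' Disaggregate township populations by age using district distributions
#'
#' Township population counts are available by sex and year only; age
#' structure is available at district level. Person-years per township x sex
#' x age-group are obtained by proportional allocation:
#' `total(township, sex, year) * proportion(district, sex, age)`, then summed
#' over the years of each analysis period. The allocation conserves sex
#' totals exactly. Age distributions are applied within sex, so township
#' sex information is retained.
#'
#' @param township_totals data.frame township_id, year, sex, total.
#' @param district_dist data.frame district_id, sex, age_group, proportion;
#'   proportions must sum to 1 (within 1e-9) per district-sex.
#' @param map a [sim_township_map()] result supplying the township-district
#'   lookup.
#' @param periods named list of year vectors.
#' @return data.frame township_id, sex, age_group, period, person_years
#'   (class `population_table`).
#' @export
disaggregate_population <- function(township_totals, district_dist, map,
                                    periods) {
  chk <- aggregate(proportion ~ district_id + sex, data = district_dist, FUN = sum)
  if (any(abs(chk$proportion - 1) > 1e-9))
    stop("district age distributions must sum to 1 within each district-sex")
  dmap <- map$townships$district_id[match(township_totals$township_id,
                                          map$townships$township_id)]
  if (anyNA(dmap))
    stop("township_totals reference townships not in map")
  missing_d <- setdiff(unique(dmap), unique(district_dist$district_id))
  if (length(missing_d) > 0)
    stop("no age distribution for district(s): ",
         paste(missing_d, collapse = ", "))
  tt <- cbind(township_totals, district_id = dmap)
  tt$period <- assign_period(tt$year, periods)
  tt <- tt[!is.na(tt$period), , drop = FALSE]
  long <- merge(tt, district_dist, by = c("district_id", "sex"), sort = FALSE)
  long$person_years <- long$total * long$proportion
  out <- aggregate(person_years ~ township_id + sex + age_group + period,
                   data = long, FUN = sum)
  out <- out[order(out$township_id, out$sex, out$age_group, out$period), ]
  rownames(out) <- NULL
  class(out) <- c("population_table", "data.frame")
  out
}

#' Bland-Altman agreement between two population sources
#'
#' Classical Bland-Altman comparison of paired district populations (e.g.
#' statistical-yearbook versus census counts): per-pair mean and difference,
#' overall mean difference (bias), limits of agreement at
#' `mean_diff +/- 1.96 sd(diff)`, and the districts whose difference falls
#' outside the limits.
#'
#' @param a,b data.frames with columns `district_id` and `total`, covering
#'   the same districts.
#' @param id_col,value_col column names for identifiers and values.
#' @return object of class `bland_altman`: list with `table` (district_id,
#'   mean, difference), `mean_diff`, `loa` (lower, upper), `flagged`
#'   (district ids outside the limits).
#' @export
bland_altman <- function(a, b, id_col = "district_id", value_col = "total") {
  ids <- a[[id_col]]
  if (!setequal(ids, b[[id_col]]))
    stop("the two sources must cover the same districts")
  if (length(ids) < 3)
    stop("Bland-Altman needs at least 3 districts")
  va <- a[[value_col]]
  vb <- b[[value_col]][match(ids, b[[id_col]])]
  m <- (va + vb) / 2
  d <- va - vb
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  flagged <- ids[abs(d - bias) > 1.96 * s]
  structure(list(
    table = data.frame(district_id = ids, mean = m, difference = d,
                       stringsAsFactors = FALSE),
    mean_diff = bias, loa = loa, flagged = flagged
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement over", nrow(x$table), "districts\n")
  cat(sprintf("  mean difference: %.1f\n", x$mean_diff))
  cat(sprintf("  limits of agreement: [%.1f, %.1f]\n",
              x$loa["lower"], x$loa["upper"]))
  if (length(x$flagged) > 0)
    cat("  outside limits:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no districts outside limits\n")
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$table$mean, x$table$difference,
                 xlab = "Mean of sources", ylab = "Difference (a - b)",
                 main = "Bland-Altman", pch = 19, ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  if (length(x$flagged) > 0) {
    sel <- x$table$district_id %in% x$flagged
    graphics::points(x$table$mean[sel], x$table$difference[sel],
                     col = "red", pch = 19)
    graphics::text(x$table$mean[sel], x$table$difference[sel],
                   labels = x$table$district_id[sel], pos = 3, col = "red")
  }
  invisible(x)
}

#' Exclude a district from map and analysis tables
#'
#' Removes a district's townships from the map (adjacency pruned to the
#' remaining townships) and from any supplied tables carrying a
#' `township_id` or `district_id` column, for sensitivity reruns.
#'
#' @param map a [sim_township_map()] result.
#' @param district_id district to remove.
#' @param tables optional named list of data.frames to filter.
#' @return list with `map` (pruned) and `tables` (filtered, same names).
#' @export
exclude_district <- function(map, district_id, tables = list()) {
  if (!district_id %in% map$townships$district_id)
    stop("unknown district: ", district_id)
  keep <- map$townships$district_id != district_id
  keep_ids <- map$townships$township_id[keep]
  new_map <- map
  new_map$townships <- map$townships[keep, , drop = FALSE]
  rownames(new_map$townships) <- NULL
  new_map$edges <- map$edges[map$edges$from %in% keep_ids &
                               map$edges$to %in% keep_ids, , drop = FALSE]
  rownames(new_map$edges) <- NULL
  new_map$n <- sum(keep)
  tables <- lapply(tables, function(df) {
    if ("township_id" %in% names(df))
      df <- df[df$township_id %in% keep_ids, , drop = FALSE]
    if ("district_id" %in% names(df))
      df <- df[df$district_id != district_id, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  list(map = new_map, tables = tables)
}
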