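mk_rates <- function(rates_by_stratum, township_id = "T001",
                     period = "2007-2009") {
  # rates_by_stratum: named by "sex:age"
  parts <- strsplit(names(rates_by_stratum), ":", fixed = TRUE)
  data.frame(township_id = township_id,
             sex = vapply(parts, `[[`, character(1), 1),
             age_group = vapply(parts, `[[`, character(1), 2),
             period = period,
             rate = unname(rates_by_stratum),
             stringsAsFactors = FALSE)
}

test_that("direct standardization reproduces hand-computed examples", {
  w <- standard_weights(data.frame(age_group = c("35-49", "50-64",
                                                 "65-79", "80+"),
                                   weight = c(0.4, 0.3, 0.2, 0.1)))
  rt <- data.frame(township_id = "T001", period = "p1",
                   age_group = c("35-49", "50-64", "65-79", "80+"),
                   rate = c(100, 300, 700, 1300), stringsAsFactors = FALSE)
  out <- direct_standardize(rt, w)
  # 0.4*100 + 0.3*300 + 0.2*700 + 0.1*1300 = 400
  expect_equal(out$std_rate, 400)

  # equal stratum rates standardize to that rate for any weights
  rt2 <- rt; rt2$rate <- 250
  expect_equal(direct_standardize(rt2, w)$std_rate, 250)

  # weights proportional to own person-years reproduce the crude rate
  py <- c(4000, 3000, 2000, 1000)
  events <- c(4, 9, 14, 13)
  rt3 <- rt; rt3$rate <- events / py * 1e5
  w_own <- standard_weights(data.frame(age_group = rt$age_group,
                                       weight = py / sum(py)))
  expect_equal(direct_standardize(rt3, w_own)$std_rate,
               sum(events) / sum(py) * 1e5)

  # linearity and scale invariance
  expect_equal(direct_standardize(transform(rt, rate = 2 * rate), w)$std_rate,
               2 * out$std_rate)
  rt4 <- rt; rt4$rate <- rt$rate + 50
  expect_equal(direct_standardize(rt4, w)$std_rate, out$std_rate + 50)

  # a group missing a weighted stratum is an error, not a silent NA
  expect_error(direct_standardize(rt[-2, ], w), "missing weighted strata")
  expect_error(standard_weights(data.frame(age_group = "a", weight = 0.7)),
               "sum to 1")
  expect_error(standard_weights(data.frame(age_group = c("a", "b"),
                                           weight = c(1.2, -0.2))),
               "non-negative")
})

test_that("weights_from_population reflect reference-period person-years", {
  pop <- expand.grid(township_id = c("T001", "T002"),
                     sex = c("male", "female"),
                     age_group = c("35-49", "50-64"),
                     period = c("p1", "p2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop$person_years <- 1000
  pop$person_years[pop$age_group == "50-64" & pop$period == "p1"] <- 3000
  w <- weights_from_population(pop, period = "p1")
  expect_equal(sum(w$weight), 1)
  expect_equal(w$weight[w$age_group == "50-64"],
               rep(3 / 8, 2))  # 3000/(1000+3000) split over sexes
})

test_that("percent change matches published-table arithmetic", {
  expect_equal(percent_change(216.3, 231.6), 7.1)
  expect_equal(percent_change(77.5, 88.9), 14.7)
  expect_equal(percent_change(138.1, 126.9), -8.1)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(0, 100), "positive")
})

test_that("inequality metrics match published percentile arithmetic", {
  # gap and ratio derived from printed percentiles
  iq <- inequality_from_percentiles(77.9, 426.3)
  expect_equal(iq$absolute_gap, 348.4)
  expect_equal(iq$relative_ratio, 5.5)
  iq2 <- inequality_from_percentiles(104.5, 472.3)
  expect_equal(iq2$absolute_gap, 367.8)
  expect_equal(iq2$relative_ratio, 4.5)

  # equal rates: gap 0, ratio 1
  iq3 <- inequality_metrics(rep(200, 20))
  expect_equal(iq3$absolute_gap, 0)
  expect_equal(iq3$relative_ratio, 1)

  # known quantiles of 1..101: p10 = 11, p90 = 91 (type 7)
  iq4 <- inequality_metrics(as.numeric(1:101))
  expect_equal(iq4$p10, 11)
  expect_equal(iq4$p90, 91)
  expect_equal(iq4$absolute_gap, 80)
  expect_equal(iq4$relative_ratio, round(91 / 11, 1))

  # permutation invariance
  set.seed(3)
  x <- rlnorm(307, log(200), 0.5)
  a <- inequality_metrics(x); b <- inequality_metrics(sample(x))
  expect_equal(a$p10, b$p10)
  expect_equal(a$relative_ratio, b$relative_ratio)

  expect_warning(iq0 <- inequality_from_percentiles(0, 50), "zero")
  expect_true(is.na(iq0$relative_ratio))
  expect_error(inequality_metrics(1:5), "at least 10")
  expect_output(print(iq), "gap 348.4")
})

test_that("decile classification is balanced, ordered and rank-invariant", {
  d <- decile_classify(as.numeric(10:1), ids = letters[1:10])
  expect_equal(d$decile, 10:1)  # highest rate in decile 10
  expect_identical(d$id[d$high_rate], "a")

  set.seed(5)
  x <- rlnorm(307, log(200), 0.4)
  d2 <- decile_classify(x, ids = sprintf("T%03d", 1:307))
  sizes <- as.integer(table(d2$decile))
  expect_equal(sum(sizes), 307)
  expect_lte(diff(range(sizes)), 1)
  # all rates in decile 10 exceed all rates in decile 1
  expect_gt(min(d2$rate[d2$decile == 10]), max(d2$rate[d2$decile == 1]))
  # invariant under monotone transformation
  d3 <- decile_classify(log(x), ids = sprintf("T%03d", 1:307))
  expect_equal(d3$decile, d2$decile)

  expect_error(decile_classify(1:9), "at least 10")
})

test_that("table summaries carry every row and period with consistent arithmetic", {
  set.seed(9)
  townships <- sprintf("T%03d", 1:20)
  grid <- expand.grid(township_id = townships,
                      sex = c("male", "female"),
                      age_group = c("35-49", "50-64", "65-79", "80+"),
                      period = c("2007-2009", "2010-2012"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- rlnorm(nrow(grid), log(200), 0.4)
  w <- standard_weights(expand.grid(sex = c("male", "female"),
                                    age_group = c("35-49", "50-64",
                                                  "65-79", "80+"),
                                    KEEP.OUT.ATTRS = FALSE,
                                    stringsAsFactors = FALSE) |>
                          transform(weight = 1 / 8))
  t1 <- summarize_table1(grid, w)
  t2 <- summarize_table2(grid, w)
  expect_equal(t1$row, c("total",
                         "male", paste("male", c("35-49", "50-64", "65-79",
                                                 "80+"), sep = ":"),
                         "female", paste("female", c("35-49", "50-64",
                                                     "65-79", "80+"),
                                         sep = ":")))
  expect_identical(t2$row, t1$row)
  expect_true(all(c("median_2007-2009", "q1_2010-2012") %in% names(t1)))
  expect_true(all(c("p10_2007-2009", "ratio_2010-2012") %in% names(t2)))

  # the total row equals the inequality of the standardized township rates
  std <- direct_standardize(grid, w)
  ref <- inequality_metrics(std$std_rate[std$period == "2007-2009"])
  expect_equal(t2$`gap_2007-2009`[t2$row == "total"], ref$absolute_gap)
  expect_equal(t1$`median_2007-2009`[t1$row == "total"], ref$median)
  # a sex:age row is the raw stratum quantile
  r <- grid$rate[grid$sex == "male" & grid$age_group == "80+" &
                   grid$period == "2010-2012"]
  expect_equal(t1$`median_2010-2012`[t1$row == "male:80+"],
               round(median(r), 1))
  expect_equal(t2$`p90_2010-2012`[t2$row == "male:80+"],
               round(quantile(r, 0.9, names = FALSE), 1))
})
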