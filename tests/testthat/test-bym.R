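test_that("adjacency construction handles lattices, paths, islands and bad input", {
  # 2x2 lattice via map
  map <- sim_township_map(registry_config(n_districts = 1,
                                          townships_per_district = 4,
                                          years = 2007:2009))
  adj <- build_adjacency(map)
  expect_equal(unname(adj$degree), rep(2L, 4))
  expect_equal(adj$icar_rank, 3L)  # n - 1 for one connected component

  # path graph from an edge list
  adj2 <- build_adjacency(data.frame(from = c("a", "b"), to = c("b", "c")),
                          ids = c("a", "b", "c"))
  expect_equal(unname(adj2$degree), c(1L, 2L, 1L))
  expect_equal(adj2$nbr[[2]], c(1L, 3L))

  # matrix input with an isolated island
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- m["b", "c"] <- m["c", "b"] <- 1
  adj3 <- build_adjacency(m)
  expect_identical(adj3$islands, "d")
  expect_equal(adj3$n_components, 2L)
  expect_equal(adj3$icar_rank, 2L)  # 3 non-islands, 1 component among them

  # duplicate/reversed edges deduplicate
  adj4 <- build_adjacency(data.frame(from = c("a", "b", "a"),
                                     to = c("b", "a", "b")),
                          ids = c("a", "b"))
  expect_equal(nrow(adj4$edges), 1)

  m_bad <- m; m_bad["a", "c"] <- 1
  expect_error(build_adjacency(m_bad), "symmetric")
  expect_error(build_adjacency(data.frame(from = "a", to = "z"),
                               ids = c("a", "b")), "unknown ids")
  expect_error(build_adjacency(data.frame(from = "a", to = "a"),
                               ids = c("a", "b")), "self-loops")
})

test_that("bym validates inputs and warns on all-zero counts", {
  map <- sim_township_map(registry_config(n_districts = 1,
                                          townships_per_district = 4,
                                          years = 2007:2009))
  expect_error(bym(c(1, 2), rep(1e4, 4), map), "one entry per area")
  expect_error(bym(c(-1, 0, 0, 0), rep(1e4, 4), map), "non-negative")
  expect_error(bym(rep(1, 4), c(0, 1, 1, 1) * 1e4, map), "positive")
  expect_error(bym(rep(1, 4), rep(1e4, 4), map, n_iter = 100,
                   n_burnin = 100), "n_iter > n_burnin")
  expect_warning(bym(rep(0L, 4), rep(1e4, 4), map, n_iter = 200,
                     n_burnin = 100, seed = 1), "all counts are zero")
})

test_that("posterior tracks the data in the likelihood-dominated limit", {
  # enormous exposures: y = E * r exactly, posterior rates must sit at r
  map <- sim_township_map(registry_config(n_districts = 2,
                                          townships_per_district = 8,
                                          years = 2007:2009))
  r <- seq(150, 450, length.out = map$n) / 1e5
  E <- rep(5e6, map$n)
  y <- round(E * r)
  fit <- bym(y, E, map, n_chains = 2, n_iter = 1500, n_burnin = 750, seed = 3)
  expect_true(all(abs(fit$rates$rate - y / E * 1e5) / (y / E * 1e5) < 0.02))
  # credible intervals bracket the point estimate
  expect_true(all(fit$rates$lower < fit$rates$rate &
                    fit$rates$rate < fit$rates$upper))
})

test_that("small-count areas are shrunk towards their neighbourhood", {
  set.seed(8)
  map <- sim_township_map(registry_config(n_districts = 2,
                                          townships_per_district = 18,
                                          years = 2007:2009))
  true_rate <- 200 / 1e5
  E <- rep(5000, map$n)           # ~10 expected events per area
  y <- rpois(map$n, E * true_rate)
  fit <- bym(y, E, map, n_chains = 2, n_iter = 1500, n_burnin = 750, seed = 5)
  raw <- y / E * 1e5
  small <- y < 20
  expect_gt(sum(small), 5)
  # posterior means lie between raw rates and the global mean
  shrunk <- abs(fit$rates$rate[small] - mean(raw)) <=
    abs(raw[small] - mean(raw)) + 1e-6
  expect_gt(mean(shrunk), 0.8)
  # overall spread is reduced
  expect_lt(sd(fit$rates$rate), sd(raw))
})

test_that("chains are exactly reproducible from the seed", {
  map <- sim_township_map(registry_config(n_districts = 1,
                                          townships_per_district = 6,
                                          years = 2007:2009))
  y <- c(5L, 12L, 9L, 7L, 15L, 4L)
  E <- rep(4000, 6)
  f1 <- bym(y, E, map, n_chains = 2, n_iter = 400, n_burnin = 200, seed = 17)
  f2 <- bym(y, E, map, n_chains = 2, n_iter = 400, n_burnin = 200, seed = 17)
  expect_identical(f1$chains, f2$chains)
  f3 <- bym(y, E, map, n_chains = 2, n_iter = 400, n_burnin = 200, seed = 18)
  expect_false(identical(f1$chains[[1]]$alpha, f3$chains[[1]]$alpha))
})

test_that("convergence diagnostics flag pathologies", {
  map <- sim_township_map(registry_config(n_districts = 1,
                                          townships_per_district = 6,
                                          years = 2007:2009))
  y <- c(5L, 12L, 9L, 7L, 15L, 4L)
  E <- rep(4000, 6)
  fit <- bym(y, E, map, n_chains = 2, n_iter = 800, n_burnin = 400, seed = 2)
  cc <- check_convergence(fit)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(cc$table)))
  expect_true(all(cc$table$ess > 0, na.rm = TRUE))

  one <- bym(y, E, map, n_chains = 1, n_iter = 400, n_burnin = 200, seed = 2)
  expect_error(check_convergence(one), "at least 2 chains")

  # two copies of the same chain: degenerate, must warn
  fake <- fit
  fake$chains[[2]] <- fake$chains[[1]]
  expect_warning(check_convergence(fake), "identical")

  # rhat/ess on synthetic chains: far-apart chains give large rhat
  ch_far <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(ch_far), 2)
  ch_ok <- list(rnorm(500), rnorm(500))
  expect_lt(rhat(ch_ok), 1.05)
  # iid chains: ESS near the raw draw count
  expect_gt(ess(ch_ok), 500)
  # perfectly autocorrelated chain: tiny ESS
  ar <- as.numeric(stats::filter(rnorm(500), 0.99, method = "recursive"))
  expect_lt(ess(list(ar, ar + rnorm(500, sd = 1e-3))), 100)
})

test_that("S3 methods return coherent quantities", {
  map <- sim_township_map(registry_config(n_districts = 1,
                                          townships_per_district = 6,
                                          years = 2007:2009))
  y <- c(5L, 12L, 9L, 7L, 15L, 4L)
  E <- rep(4000, 6)
  fit <- bym(y, E, map, n_chains = 2, n_iter = 600, n_burnin = 300, seed = 4)
  expect_named(coef(fit), c("alpha", "tau_u", "tau_v"))
  expect_equal(fitted(fit), fit$E * fit$rates$rate / 1e5)
  expect_equal(residuals(fit, type = "response"), y - fitted(fit))
  expect_equal(residuals(fit), (y - fitted(fit)) / sqrt(fitted(fit)))
  sim <- simulate(fit, nsim = 5, seed = 1)
  expect_equal(dim(sim), c(5, 6))
  expect_true(all(sim >= 0))
  expect_output(print(fit), "BYM convolution")
  expect_output(print(summary(fit)), "Parameters")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("stratified fitting produces a complete rate table", {
  cfg <- registry_config(n_districts = 2, townships_per_district = 6,
                         years = 2007:2012, pop_median = 8000, seed = 12)
  reg <- sim_registry(cfg)
  linked <- link_events(reg$records$hospital, reg$records$deaths)
  counts <- aggregate_events(linked, reg$map, cfg$periods)
  pop <- disaggregate_population(reg$population$township_totals,
                                 reg$population$district_dist,
                                 reg$map, cfg$periods)
  fits <- fit_bym_strata(counts, pop, reg$map, n_iter = 400, n_burnin = 200,
                         seed = 1)
  expect_s3_class(fits, "bym_strata")
  expect_length(fits$fits, 2 * 4 * 2)  # sex x age x period strata
  tab <- posterior_rate_table(fits)
  expect_equal(nrow(tab), 12 * 2 * 4 * 2)
  expect_true(all(tab$rate > 0))
  expect_true(all(tab$lower <= tab$rate & tab$rate <= tab$upper))
  # same seed, same table
  fits2 <- fit_bym_strata(counts, pop, reg$map, n_iter = 400, n_burnin = 200,
                          seed = 1)
  expect_equal(posterior_rate_table(fits2), tab)

  expect_error(fit_bym_strata(counts, pop[-1, ], reg$map), "missing strata")
})
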