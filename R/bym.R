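#' Build a neighbour structure for the ICAR prior
#'
#' Accepts a [sim_township_map()] object, an undirected edge list
#' (data.frame with columns `from`, `to`) plus the full id vector, or a
#' symmetric 0/1 adjacency matrix. Returns symmetric neighbour lists with
#' degree-0 townships (islands) reported; under the island policy these
#' areas get no structured effect and rely on the unstructured one.
#'
#' @param x map object, edge data.frame, or adjacency matrix.
#' @param ids area identifiers; required when `x` is an edge data.frame,
#'   ignored otherwise.
#' @return object of class `adjacency`: list with `n`, `ids`, `nbr`
#'   (1-based integer neighbour lists), `degree`, `edges` (2-column integer
#'   matrix), `islands` (ids with no neighbours), `comp_id`,
#'   `n_components` (components of the whole graph), and `icar_rank`
#'   (rank of the ICAR precision on non-island areas).
#' @export
build_adjacency <- function(x, ids = NULL) {
  if (inherits(x, "adjacency")) return(x)
  if (inherits(x, "township_map")) {
    ids <- x$townships$township_id
    ef <- match(x$edges$from, ids)
    et <- match(x$edges$to, ids)
  } else if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || !isTRUE(all.equal(x, t(x))))
      stop("adjacency matrix must be square and symmetric")
    if (any(diag(x) != 0)) stop("adjacency matrix must have zero diagonal")
    ids <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
    w <- which(x != 0 & upper.tri(x), arr.ind = TRUE)
    ef <- w[, 1]; et <- w[, 2]
  } else if (is.data.frame(x)) {
    if (is.null(ids)) stop("supply the full id vector with an edge list")
    ef <- match(x$from, ids); et <- match(x$to, ids)
    if (anyNA(ef) || anyNA(et)) stop("edge list references unknown ids")
  } else stop("cannot interpret adjacency input")
  n <- length(ids)
  if (any(ef == et)) stop("self-loops are not allowed")
  # deduplicate undirected edges
  key <- paste(pmin(ef, et), pmax(ef, et))
  keep <- !duplicated(key)
  ef2 <- pmin(ef, et)[keep]; et2 <- pmax(ef, et)[keep]
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  for (k in seq_along(ef2)) {
    nbr[[ef2[k]]] <- c(nbr[[ef2[k]]], et2[k])
    nbr[[et2[k]]] <- c(nbr[[et2[k]]], ef2[k])
  }
  nbr <- lapply(nbr, sort)
  degree <- lengths(nbr)
  # connected components by BFS
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      for (nb in nbr[[node]]) if (comp[nb] == 0L) {
        comp[nb] <- cur; queue <- c(queue, nb)
      }
    }
  }
  islands <- ids[degree == 0]
  n_free <- sum(degree > 0)
  c_free <- length(unique(comp[degree > 0]))
  structure(list(
    n = n, ids = ids, nbr = nbr, degree = degree,
    edges = cbind(from = ef2, to = et2),
    islands = islands, comp_id = comp, n_components = cur,
    icar_rank = if (n_free > 0) n_free - c_free else 0L
  ), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat("Adjacency:", x$n, "areas,", nrow(x$edges), "edges,",
      x$n_components, "component(s)")
  if (length(x$islands) > 0) cat(",", length(x$islands), "island(s)")
  cat("\n")
  invisible(x)
}

#' Fit the BYM convolution model to one stratum of area counts
#'
#' Fits the Besag-York-Mollie disease-mapping model
#' \deqn{y_i \sim \mathrm{Poisson}(E_i e^{\alpha + u_i + v_i})}
#' with an intrinsic CAR (ICAR) prior on the spatially structured effects
#' \eqn{u} over the supplied adjacency, iid normal unstructured effects
#' \eqn{v}, a flat prior on the intercept \eqn{\alpha}, and Gamma(a, b)
#' hyperpriors on both precisions. Sampling is Metropolis-within-Gibbs:
#' adaptive random-walk Metropolis for \eqn{\alpha}, each \eqn{u_i} and
#' \eqn{v_i} (proposals tuned towards 0.44 acceptance during burn-in only),
#' and a sum-to-zero recentring of \eqn{u} after every sweep. Islands
#' (areas without neighbours) have \eqn{u_i \equiv 0} and rely on
#' \eqn{v_i}.
#'
#' Because the likelihood identifies only the sum \eqn{w = u + v}, the
#' split and the precisions are additionally updated in the eigenbasis of
#' the graph Laplacian, where both priors are diagonal: the precisions move
#' by Metropolis steps on the log scale against the marginal density
#' \eqn{p(w \mid \tau_u, \tau_v)} with the split integrated out
#' (interleaved with a joint rescaling move on \eqn{w} that traverses the
#' scale/precision funnel), random eigencomponents of \eqn{w} are refreshed
#' by independence proposals from their prior, and the \eqn{u}/\eqn{v}
#' split is then redrawn exactly from its Gaussian full conditional. A
#' conjugate Gibbs refresh of both precisions ends each sweep.
#'
#' @param y non-negative integer event counts per area.
#' @param E person-years (exposure offset) per area, all positive.
#' @param adjacency anything [build_adjacency()] accepts.
#' @param n_chains number of MCMC chains (>= 2 recommended for diagnostics).
#' @param n_iter iterations per chain, including burn-in.
#' @param n_burnin burn-in iterations discarded (and used for adaptation).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param a,b shape and rate of the Gamma hyperprior on both precisions
#'   (default Gamma(0.5, 0.0005), a common disease-mapping choice).
#' @param seed integer seed; chain `k` runs under `seed + k - 1`. `NULL`
#'   leaves the RNG state alone.
#' @return an object of class `bym`: list with `chains` (per-chain draws of
#'   alpha, tau_u, tau_v and matrices u, v), `rates` (data.frame area,
#'   posterior-mean rate per 100,000 person-years, 95% credible bounds),
#'   the data, the adjacency, and the sampler settings.
#' @seealso [check_convergence()], [fit_bym_strata()]
#' @examples
#' map <- sim_township_map(registry_config(n_districts = 2,
#'                                         townships_per_district = 8))
#' E <- rep(5e4, map$n)
#' y <- rpois(map$n, E * 250 / 1e5)
#' fit <- bym(y, E, map, n_iter = 600, n_burnin = 300, seed = 1)
#' fit
#' @export
bym <- function(y, E, adjacency, n_chains = 2, n_iter = 4000,
                n_burnin = n_iter %/% 2, thin = 1,
                a = 0.5, b = 0.0005, seed = NULL) {
  adj <- build_adjacency(adjacency)
  n <- adj$n
  if (length(y) != n || length(E) != n)
    stop("y and E must have one entry per area (", n, ")")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must be non-negative integers")
  if (any(E <= 0)) stop("person-years E must be positive")
  if (n_iter <= n_burnin || n_burnin < 0) stop("need n_iter > n_burnin >= 0")
  if (n_chains < 1) stop("need at least one chain")
  y <- as.integer(round(y))
  if (all(y == 0))
    warning("all counts are zero; posterior will be close to the prior")

  island <- adj$degree == 0
  crude <- log((sum(y) + 0.5) / sum(E))
  nbr0 <- lapply(adj$nbr, function(v) as.integer(v - 1L))
  # eigenbasis of the graph Laplacian on non-island areas, used for the
  # marginal precision updates and the exact u/v split redraw
  free <- which(!island)
  if (length(free) > 0) {
    pos <- match(seq_len(n), free)
    L <- matrix(0, length(free), length(free))
    diag(L) <- adj$degree[free]
    for (k in seq_len(nrow(adj$edges))) {
      i <- pos[adj$edges[k, 1]]; j <- pos[adj$edges[k, 2]]
      L[i, j] <- L[i, j] - 1
      L[j, i] <- L[j, i] - 1
    }
    eig <- eigen(L, symmetric = TRUE)
    Vt <- t(eig$vectors)
    lambda <- pmax(eig$values, 0)
  } else {
    Vt <- matrix(0, 0, 0)
    lambda <- numeric(0)
  }
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    init_jitter <- if (n_chains > 1) 0.1 * (ch - 1) else 0
    chains[[ch]] <- .bym_mcmc(
      y = y, E = as.numeric(E), nbr = nbr0,
      edge_i = as.integer(adj$edges[, 1] - 1L),
      edge_j = as.integer(adj$edges[, 2] - 1L),
      island = island, icar_rank = as.integer(adj$icar_rank),
      Vt = Vt, lambda = lambda,
      n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
      thin = as.integer(thin), a = a, b = b,
      alpha_init = crude + init_jitter,
      u_init = numeric(n), v_init = numeric(n),
      tau_u_init = 10, tau_v_init = 10)
  }

  log_rate <- do.call(rbind, lapply(chains, function(cc)
    cc$alpha + cc$u + cc$v))  # draws x n, alpha recycled down columns
  rate_draws <- exp(log_rate) * 1e5
  rates <- data.frame(
    area = adj$ids,
    rate = colMeans(rate_draws),
    lower = apply(rate_draws, 2, quantile, 0.025, names = FALSE),
    upper = apply(rate_draws, 2, quantile, 0.975, names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(
    chains = chains, rates = rates, y = y, E = as.numeric(E),
    adjacency = adj,
    settings = list(n_chains = n_chains, n_iter = n_iter,
                    n_burnin = n_burnin, thin = thin, a = a, b = b,
                    seed = seed),
    call = match.call()
  ), class = "bym")
}

#' @export
print.bym <- function(x, ...) {
  s <- x$settings
  cat("BYM convolution Poisson model\n")
  cat("  areas:", x$adjacency$n, " events:", sum(x$y), "\n")
  cat("  chains:", s$n_chains, " kept draws/chain:",
      length(x$chains[[1]]$alpha), "\n")
  cat(sprintf("  posterior mean rate: %.1f per 100,000 (range %.1f-%.1f)\n",
              mean(x$rates$rate), min(x$rates$rate), max(x$rates$rate)))
  invisible(x)
}

#' @export
coef.bym <- function(object, ...) {
  c(alpha = mean(unlist(lapply(object$chains, `[[`, "alpha"))),
    tau_u = mean(unlist(lapply(object$chains, `[[`, "tau_u"))),
    tau_v = mean(unlist(lapply(object$chains, `[[`, "tau_v"))))
}

#' @export
fitted.bym <- function(object, ...) {
  object$E * object$rates$rate / 1e5
}

#' Residuals for a fitted BYM model
#' @param object a [bym()] fit.
#' @param type `"pearson"` (default) or `"response"`.
#' @param ... unused.
#' @export
residuals.bym <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$y - mu
  if (type == "pearson") r <- r / sqrt(mu)
  r
}

#' Simulate replicate count vectors from the posterior predictive
#' @param object a [bym()] fit.
#' @param nsim number of replicate data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix `nsim x n` of simulated counts.
#' @export
simulate.bym <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- do.call(rbind, lapply(object$chains, function(cc)
    exp(cc$alpha + cc$u + cc$v)))
  idx <- sample.int(nrow(draws), nsim, replace = nsim > nrow(draws))
  out <- matrix(NA_integer_, nsim, length(object$y))
  for (k in seq_len(nsim))
    out[k, ] <- rpois(length(object$y), object$E * draws[idx[k], ])
  out
}

#' @export
summary.bym <- function(object, ...) {
  co <- coef(object)
  diag <- tryCatch(check_convergence(object, n_u = 5),
                   error = function(e) NULL)
  out <- list(coefficients = co, rates = object$rates,
              diagnostics = diag, settings = object$settings)
  class(out) <- "summary.bym"
  out
}

#' @export
print.summary.bym <- function(x, ...) {
  cat("BYM convolution Poisson model\n\nParameters (posterior means):\n")
  print(round(x$coefficients, 4))
  cat("\nArea rates per 100,000 person-years:\n")
  print(summary(x$rates$rate))
  if (!is.null(x$diagnostics)) {
    cat("\nConvergence:\n")
    print(x$diagnostics$table, digits = 3)
    if (x$diagnostics$flag)
      cat("WARNING: R-hat above 1.05 for some parameter(s)\n")
  }
  invisible(x)
}

#' @export
plot.bym <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("alpha", "tau_u", "tau_v")) {
    d <- lapply(x$chains, `[[`, p)
    graphics::plot(d[[1]], type = "l", xlab = "kept draw", ylab = p,
                   main = paste("trace:", p),
                   ylim = range(unlist(d)))
    if (length(d) > 1)
      for (k in 2:length(d)) graphics::lines(d[[k]], col = k)
  }
  raw <- x$y / x$E * 1e5
  graphics::plot(raw, x$rates$rate, xlab = "raw rate / 100,000",
                 ylab = "posterior mean rate", main = "shrinkage", pch = 19,
                 cex = 0.6)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# ---- convergence diagnostics ------------------------------------------------

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2
    out <- c(out, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  out
}

#' Split-R-hat of a set of chains
#' @param chains list of numeric vectors (one per chain), each of equal length.
#' @return the split-\eqn{\widehat{R}} statistic.
#' @export
rhat <- function(chains) {
  sc <- split_chains(chains)
  m <- length(sc); n <- length(sc[[1]])
  means <- vapply(sc, mean, numeric(1))
  vars <- vapply(sc, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a set of chains
#'
#' Multi-chain effective sample size using the rank-free combined
#' autocorrelation estimator with Geyer initial-positive-sequence
#' truncation.
#'
#' @param chains list of numeric vectors (one per chain).
#' @return estimated effective sample size.
#' @export
ess <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  if (n < 4) return(NA_real_)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + (if (m > 1) var(means) else 0)
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1, 400)
  acov <- sapply(chains, function(ch)
    stats::acf(ch, lag.max = max_lag, plot = FALSE,
               type = "covariance")$acf[, 1, 1])
  acov <- if (is.matrix(acov)) rowMeans(acov) else acov
  rho <- 1 - (W - acov) / var_plus   # rho[1] corresponds to lag 0
  # Geyer: sum pairs while they stay positive
  tau <- 1
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  m * n / tau
}

#' Convergence diagnostics for a BYM fit
#'
#' Split-R-hat and effective sample size for the intercept, both precisions,
#' and a random sample of structured effects. The fit is flagged when any
#' R-hat exceeds 1.05.
#'
#' @param fit a [bym()] object with at least 2 chains.
#' @param n_u number of structured effects to check (default 10).
#' @param rhat_limit flag threshold (default 1.05).
#' @param seed seed for the choice of structured effects.
#' @return list with `table` (parameter, rhat, ess) and `flag`.
#' @export
check_convergence <- function(fit, n_u = 10, rhat_limit = 1.05, seed = 1) {
  stopifnot(inherits(fit, "bym"))
  if (length(fit$chains) < 2)
    stop("convergence diagnostics need at least 2 chains")
  get <- function(p) lapply(fit$chains, `[[`, p)
  if (isTRUE(all.equal(fit$chains[[1]]$alpha, fit$chains[[2]]$alpha)))
    warning("chains are identical (same seed?); R-hat is degenerate")
  params <- list(alpha = get("alpha"), tau_u = get("tau_u"),
                 tau_v = get("tau_v"))
  free <- which(fit$adjacency$degree > 0)
  if (length(free) > 0 && n_u > 0) {
    set.seed(seed)
    pick <- sort(sample(free, min(n_u, length(free))))
    for (i in pick)
      params[[paste0("u[", fit$adjacency$ids[i], "]")]] <-
        lapply(fit$chains, function(cc) cc$u[, i])
  }
  tab <- data.frame(
    parameter = names(params),
    rhat = vapply(params, rhat, numeric(1)),
    ess = vapply(params, ess, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab, flag = any(tab$rhat > rhat_limit, na.rm = TRUE))
}

# ---- stratified fitting -----------------------------------------------------

#' Fit the BYM model separately for every sex-age-period stratum
#'
#' Mirrors the surveillance design: each sex x age-group x period stratum is
#' fitted independently on the same township adjacency, with no sharing
#' across strata.
#'
#' @param counts a [aggregate_events()] table (township_id, sex, age_group,
#'   period, events).
#' @param population a [disaggregate_population()] table (township_id, sex,
#'   age_group, period, person_years).
#' @param adjacency anything [build_adjacency()] accepts; area ids must
#'   match `township_id`.
#' @param n_chains,n_iter,n_burnin,thin,a,b sampler settings passed to
#'   [bym()].
#' @param seed root seed; stratum `k` uses `seed + 131 * k`.
#' @param verbose print progress.
#' @return object of class `bym_strata`: list of `bym` fits (named
#'   `sex.age_group.period`) plus the stratum index.
#' @export
fit_bym_strata <- function(counts, population, adjacency,
                           n_chains = 2, n_iter = 2000,
                           n_burnin = n_iter %/% 2, thin = 1,
                           a = 0.5, b = 0.0005, seed = 1, verbose = FALSE) {
  adj <- build_adjacency(adjacency)
  dat <- merge(counts, population,
               by = c("township_id", "sex", "age_group", "period"))
  if (nrow(dat) < nrow(counts))
    stop("population table is missing strata present in the counts")
  strata <- unique(dat[c("sex", "age_group", "period")])
  strata <- strata[order(strata$sex, strata$age_group, strata$period), ]
  fits <- vector("list", nrow(strata))
  names(fits) <- paste(strata$sex, strata$age_group, strata$period, sep = ".")
  for (k in seq_len(nrow(strata))) {
    sel <- dat$sex == strata$sex[k] & dat$age_group == strata$age_group[k] &
      dat$period == strata$period[k]
    sub <- dat[sel, ]
    sub <- sub[match(adj$ids, sub$township_id), ]
    if (anyNA(sub$events))
      stop("stratum ", names(fits)[k], " missing townships")
    if (verbose) message("fitting stratum ", names(fits)[k])
    fits[[k]] <- bym(sub$events, sub$person_years, adj,
                     n_chains = n_chains, n_iter = n_iter,
                     n_burnin = n_burnin, thin = thin, a = a, b = b,
                     seed = if (is.null(seed)) NULL else seed + 131L * k)
  }
  structure(list(fits = fits, strata = strata), class = "bym_strata")
}

#' @export
print.bym_strata <- function(x, ...) {
  cat("BYM fits for", length(x$fits), "strata (",
    paste(dim(table(x$strata$sex, x$strata$age_group)), collapse = " x "),
    "sex x age, x", length(unique(x$strata$period)), "periods )\n")
  invisible(x)
}

#' Posterior-mean incidence table across strata
#'
#' @param x a [fit_bym_strata()] result.
#' @return data.frame township_id, sex, age_group, period, rate (posterior
#'   mean per 100,000 person-years), lower, upper (95% credible bounds).
#' @export
posterior_rate_table <- function(x) {
  stopifnot(inherits(x, "bym_strata"))
  if (any(vapply(x$fits, is.null, logical(1))))
    stop("missing fits for strata: ",
         paste(names(x$fits)[vapply(x$fits, is.null, logical(1))],
               collapse = ", "))
  out <- do.call(rbind, lapply(seq_along(x$fits), function(k) {
    r <- x$fits[[k]]$rates
    data.frame(township_id = r$area,
               sex = x$strata$sex[k],
               age_group = x$strata$age_group[k],
               period = x$strata$period[k],
               rate = r$rate, lower = r$lower, upper = r$upper,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
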