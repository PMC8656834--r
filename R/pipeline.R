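#' Write a township map as GeoJSON
#'
#' Each township becomes a unit-square polygon at its lattice position, with
#' township id, district id and any extra per-township properties attached —
#' enough for choropleth (e.g. decile) rendering in standard GIS tools.
#'
#' @param map a [sim_township_map()] result.
#' @param file output path.
#' @param properties optional data.frame with a `township_id` column; its
#'   remaining columns become feature properties.
#' @return invisibly, `file`.
#' @export
write_map_geojson <- function(map, file, properties = NULL) {
  tw <- map$townships
  extra <- NULL
  if (!is.null(properties)) {
    stopifnot("township_id" %in% names(properties))
    extra <- properties[match(tw$township_id, properties$township_id), ,
                        drop = FALSE]
  }
  features <- lapply(seq_len(nrow(tw)), function(i) {
    x <- tw$col[i]; y <- tw$row[i]
    ring <- list(c(x - 1, y - 1), c(x, y - 1), c(x, y), c(x - 1, y),
                 c(x - 1, y - 1))
    props <- list(township_id = tw$township_id[i],
                  district_id = tw$district_id[i])
    if (!is.null(extra)) {
      for (cn in setdiff(names(extra), "township_id"))
        props[[cn]] <- extra[[cn]][i]
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Run the full synthetic surveillance pipeline
#'
#' Orchestrates generate -> link -> disaggregate -> fit -> summarize as one
#' reproducible run: synthesizes a registry from `config`, links records
#' into unique AMI events, disaggregates populations into person-years,
#' fits the BYM model per sex x age-group x period stratum, and writes the
#' summary products (median/IQR table, inequality table, deciles, percent
#' changes, Bland-Altman check, audit and manifest) into `out_dir`. All
#' randomness flows from `config$seed`.
#'
#' @param config a [registry_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @param mcmc list of sampler settings: n_chains, n_iter, n_burnin, thin.
#' @param exclude optional district id to drop before analysis (sensitivity
#'   mode).
#' @param verbose print stage progress.
#' @return object of class `ami_pipeline`: list with `config`, `out_dir`,
#'   `audit`, `rate_table`, `table1`, `table2`, `deciles`,
#'   `percent_change`, `bland_altman`, `manifest`.
#' @export
run_pipeline <- function(config = registry_config(), out_dir,
                         mcmc = list(n_chains = 2, n_iter = 2000,
                                     n_burnin = 1000, thin = 1),
                         exclude = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "registry_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  t0 <- Sys.time()

  say("synthesize registry")
  reg <- sim_registry(config)
  write_registry(reg, file.path(out_dir, "registry"))

  say("link records")
  linked <- link_events(reg$records$hospital, reg$records$deaths)
  agg_breaks <- c(config$age_breaks[-length(config$age_breaks)], Inf)
  counts <- aggregate_events(linked, reg$map, config$periods,
                             age_breaks = agg_breaks,
                             age_groups = config$age_groups,
                             sexes = config$sexes)

  say("disaggregate population")
  pop <- disaggregate_population(reg$population$township_totals,
                                 reg$population$district_dist,
                                 reg$map, config$periods)
  ba <- bland_altman(
    data.frame(district_id = reg$population$census$district_id,
               total = reg$population$census$yearbook),
    data.frame(district_id = reg$population$census$district_id,
               total = reg$population$census$census))

  map <- reg$map
  if (!is.null(exclude)) {
    say("excluding district ", exclude)
    ex <- exclude_district(map, exclude,
                           tables = list(counts = counts, pop = pop))
    map <- ex$map
    counts <- ex$tables$counts
    pop <- ex$tables$pop
  }

  ref_period <- {
    has2010 <- vapply(config$periods, function(y) 2010 %in% y, logical(1))
    if (any(has2010)) names(config$periods)[has2010][1]
    else names(config$periods)[1]
  }
  weights <- weights_from_population(pop, period = ref_period)

  say("fit BYM per stratum (", length(config$sexes) *
        length(config$age_groups) * length(config$periods), " fits )")
  fits <- fit_bym_strata(counts, pop, map,
                         n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                         n_burnin = mcmc$n_burnin,
                         thin = if (is.null(mcmc$thin)) 1 else mcmc$thin,
                         seed = config$seed)
  rate_tab <- posterior_rate_table(fits)

  say("summarize")
  table1 <- summarize_table1(rate_tab, weights)
  table2 <- summarize_table2(rate_tab, weights)
  std <- direct_standardize(rate_tab, weights)
  periods <- names(config$periods)
  first <- periods[1]; last <- periods[length(periods)]
  dec_list <- lapply(c(first, last), function(p) {
    s <- std[std$period == p, ]
    d <- decile_classify(round(s$std_rate, 1), s$township_id)
    data.frame(township_id = d$id, period = p, std_rate = d$rate,
               decile = d$decile, high_rate = d$high_rate,
               stringsAsFactors = FALSE)
  })
  deciles <- do.call(rbind, dec_list)
  s1 <- std[std$period == first, ]
  s2 <- std[std$period == last, ]
  pc <- data.frame(
    township_id = s1$township_id,
    rate_start = round(s1$std_rate, 1),
    rate_end = round(s2$std_rate[match(s1$township_id, s2$township_id)], 1),
    stringsAsFactors = FALSE)
  pc$percent_change <- percent_change(pc$rate_start, pc$rate_end)

  say("write outputs")
  files <- c(
    table1 = file.path(out_dir, "table1.csv"),
    table2 = file.path(out_dir, "table2.csv"),
    rates = file.path(out_dir, "posterior_rates.csv"),
    deciles = file.path(out_dir, "deciles.csv"),
    percent_change = file.path(out_dir, "percent_change.csv"),
    counts = file.path(out_dir, "counts.csv"),
    population = file.path(out_dir, "person_years.csv"),
    bland_altman = file.path(out_dir, "bland_altman.csv"),
    audit = file.path(out_dir, "audit.json"),
    geojson = file.path(out_dir, "deciles.geojson")
  )
  write.csv(table1, files["table1"], row.names = FALSE)
  write.csv(table2, files["table2"], row.names = FALSE)
  write.csv(rate_tab, files["rates"], row.names = FALSE)
  write.csv(deciles, files["deciles"], row.names = FALSE)
  write.csv(pc, files["percent_change"], row.names = FALSE)
  write.csv(counts, files["counts"], row.names = FALSE)
  write.csv(pop, files["population"], row.names = FALSE)
  write.csv(ba$table, files["bland_altman"], row.names = FALSE)
  jsonlite::write_json(
    c(linked$audit, list(bland_altman_flagged = ba$flagged)),
    files["audit"], auto_unbox = TRUE, digits = NA)
  geo_props <- deciles[deciles$period == last,
                       c("township_id", "decile", "high_rate")]
  write_map_geojson(map, files["geojson"], properties = geo_props)

  reg_files <- list.files(file.path(out_dir, "registry"), full.names = TRUE)
  all_files <- c(unname(files), reg_files)
  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    excluded_district = if (is.null(exclude)) NA else exclude,
    n_townships = map$n,
    mcmc = mcmc,
    audit = linked$audit,
    files = data.frame(
      path = basename(all_files),
      md5 = unname(tools::md5sum(all_files)),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  structure(list(config = config, out_dir = out_dir, audit = linked$audit,
                 rate_table = rate_tab, table1 = table1, table2 = table2,
                 deciles = deciles, percent_change = pc, bland_altman = ba,
                 weights = weights, map = map,
                 manifest = manifest), class = "ami_pipeline")
}

#' @export
print.ami_pipeline <- function(x, ...) {
  cat("AMI surveillance pipeline run\n")
  cat("  output:", x$out_dir, "\n")
  cat("  townships:", x$map$n, " unique events:", x$audit$n_final_events, "\n")
  tot <- x$table2[x$table2$row == "total", ]
  cat("  total-row inequality (first period): gap",
      tot[[grep("^gap_", names(tot))[1]]], "ratio",
      tot[[grep("^ratio_", names(tot))[1]]], "\n")
  invisible(x)
}

#' Sensitivity rerun excluding one district
#'
#' Reruns the downstream stages of [run_pipeline()] without the given
#' district (same configuration and seed) and tabulates the inequality
#' metrics of the main and reduced runs side by side, one row per
#' summary-row x period.
#'
#' @param main a completed [run_pipeline()] result.
#' @param district_id district to exclude.
#' @param out_dir output directory for the rerun (default
#'   `<main out_dir>/sensitivity_<district>`).
#' @param mcmc sampler settings (default: those of the main run).
#' @return list with `main`, `sensitivity` (both `ami_pipeline`) and
#'   `comparison` (data.frame row, period, gap_main, gap_excl, ratio_main,
#'   ratio_excl).
#' @export
sensitivity_rerun <- function(main, district_id,
                              out_dir = file.path(main$out_dir,
                                                  paste0("sensitivity_",
                                                         district_id)),
                              mcmc = main$manifest$mcmc) {
  stopifnot(inherits(main, "ami_pipeline"))
  sens <- run_pipeline(main$config, out_dir, mcmc = mcmc,
                       exclude = district_id)
  long <- function(tab, tag) {
    periods <- sub("^gap_", "", grep("^gap_", names(tab), value = TRUE))
    do.call(rbind, lapply(periods, function(p) {
      data.frame(row = tab$row, period = p,
                 gap = tab[[paste0("gap_", p)]],
                 ratio = tab[[paste0("ratio_", p)]],
                 run = tag, stringsAsFactors = FALSE)
    }))
  }
  a <- long(main$table2, "main")
  b <- long(sens$table2, "excluded")
  comparison <- merge(a[c("row", "period", "gap", "ratio")],
                      b[c("row", "period", "gap", "ratio")],
                      by = c("row", "period"),
                      suffixes = c("_main", "_excl"))
  comparison <- comparison[order(comparison$row, comparison$period), ]
  rownames(comparison) <- NULL
  list(main = main, sensitivity = sens, comparison = comparison)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file's `registry:` section onto [registry_config()] arguments
#' and returns its `mcmc:` section (if any) alongside.
#'
#' @param file path to a YAML file.
#' @return list with `config` (a `registry_config`) and `mcmc` (list).
#' @export
read_run_config <- function(file) {
  spec <- yaml::read_yaml(file)
  reg <- spec$registry
  if (is.null(reg)) reg <- list()
  if (!is.null(reg$years) && length(reg$years) == 2)
    reg$years <- seq(reg$years[1], reg$years[2])
  if (!is.null(reg$dup_probs)) reg$dup_probs <- unlist(reg$dup_probs)
  config <- do.call(registry_config, reg)
  mcmc <- spec$mcmc
  if (is.null(mcmc)) mcmc <- list(n_chains = 2, n_iter = 2000,
                                  n_burnin = 1000, thin = 1)
  list(config = config, mcmc = mcmc)
}
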