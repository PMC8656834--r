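# amimap

Small-area Bayesian disease mapping of acute myocardial infarction (AMI)
incidence from linked administrative records.

Routine surveillance of AMI at sub-city scale has to solve four problems at
once: hospital discharge and death registration streams record the same
clinical event several times (transfers, readmissions, dual death records);
township population denominators are only published as totals and must be
disaggregated into sex–age strata; township-level counts are too sparse for
raw rates, so they need spatial smoothing; and the headline outputs are
standardized rates and geographic inequality summaries, not model
parameters. `amimap` implements that pipeline end to end, together with a
fully synthetic registry generator with known ground truth so every stage
is testable without confidential data.

## What it does

* **Event linkage** (`link_events()`): WHO-MONICA style deduplication —
  same-day transfer chains are merged into care episodes, implausible
  short stays (≤ 1 day, non-fatal, single stay) are excluded, in-hospital
  death records are absorbed into their episode, and episodes with onset
  within 28 days of an index onset collapse into one event.
* **Population denominators** (`disaggregate_population()`,
  `bland_altman()`): proportional sex–age disaggregation of township
  totals using district compositions, plus a Bland–Altman consistency
  check between population sources with a sensitivity rerun
  (`exclude_district()`, `sensitivity_rerun()`).
* **Spatial smoothing** (`bym()`, `fit_bym_strata()`): the
  Besag–York–Mollié convolution model, fitted per sex × age-group ×
  period stratum by a compiled Metropolis-within-Gibbs sampler, with
  split-R̂ and effective-sample-size diagnostics in-package (`rhat()`,
  `ess()`, `check_convergence()`).
* **Summaries** (`direct_standardize()`, `summarize_table1()`,
  `summarize_table2()`, `inequality_metrics()`, `decile_classify()`):
  direct age-sex standardization, median (Q1–Q3) tables, 10th/90th
  percentile inequality gap and ratio, and decile maps, orchestrated by
  `run_pipeline()`.

## The model

For one stratum with counts $y_i$ and person-years $E_i$ over townships
$i = 1, \dots, n$:

$$y_i \sim \mathrm{Poisson}(E_i\, e^{\alpha + u_i + v_i})$$

with a flat prior on $\alpha$, an intrinsic CAR prior
$u \sim \mathrm{ICAR}(\tau_u)$ on the township adjacency graph
(sum-to-zero, islands fixed at 0), iid $v_i \sim N(0, 1/\tau_v)$, and
$\tau_u, \tau_v \sim \mathrm{Gamma}(0.5,\ 0.0005)$. Because the likelihood
identifies only $w = u + v$, the sampler updates the precisions against the
marginal density of $w$ (split integrated out) in the eigenbasis of the
graph Laplacian and redraws the $u/v$ split exactly from its Gaussian full
conditional; see the methods vignette
(`vignettes/ami-surveillance-methods.Rmd`) for details.

## Worked example

Simulate a 52-township city over 2007–2018, link its records, and fit one
stratum:

```r
library(amimap)

cfg <- registry_config(n_districts = 4, townships_per_district = 13,
                       years = 2007:2018, pop_median = 6000, seed = 42)
reg <- sim_registry(cfg)
linked <- link_events(reg$records$hospital, reg$records$deaths)
linked$audit$n_final_events
#> [1] 19364
reg$records$n_true_events   # linkage recovers the ground truth exactly
#> [1] 19364
```

The generator injected 879 transfer fragments, 516 spurious short stays,
4,096 dual death records and 684 within-28-day readmissions into those
19,364 true events; the four linkage rules remove all of them.

```r
counts <- aggregate_events(linked, reg$map, cfg$periods,
                           age_breaks = c(cfg$age_breaks[-length(cfg$age_breaks)], Inf),
                           age_groups = cfg$age_groups, sexes = cfg$sexes)
pop <- disaggregate_population(reg$population$township_totals,
                               reg$population$district_dist,
                               reg$map, cfg$periods)

sel_c <- counts[counts$sex == "male" & counts$age_group == "65-79" &
                counts$period == "2016-2018", ]
sel_p <- pop[pop$sex == "male" & pop$age_group == "65-79" &
             pop$period == "2016-2018", ]
ids <- reg$map$townships$township_id
y <- sel_c$events[match(ids, sel_c$township_id)]
E <- sel_p$person_years[match(ids, sel_p$township_id)]

fit <- bym(y, E, reg$map, n_chains = 2, n_iter = 2000, n_burnin = 1000,
           seed = 7)
fit
#> BYM convolution Poisson model
#>   areas: 52  events: 1137
#>   chains: 2  kept draws/chain: 1000
#>   posterior mean rate: 704.3 per 100,000 (range 487.7-1303.4)

summary(fit)
#> BYM convolution Poisson model
#>
#> Parameters (posterior means):
#>    alpha    tau_u    tau_v
#>  -4.9972 395.1246 604.3749
#>
#> Area rates per 100,000 person-years:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   487.7   582.1   669.4   704.3   786.5  1303.4
#>
#> Convergence:
#>   parameter rhat ess
#> 1     alpha 1.02 155
#> 2     tau_u 1.00 304
#> 3     tau_v 1.00 327
#> 4   u[T001] 1.01 262
#> 5   u[T004] 1.00 457
#> 6   u[T023] 1.01 346
#> 7   u[T034] 1.00 344
#> 8   u[T039] 1.00 150
```

The usual modelling verbs work: `coef()`, `fitted()`, `residuals()`
(Pearson or response), `simulate()` (posterior predictive counts) and
`plot()` (traces plus smoothed-vs-raw rates).

The full pipeline — linkage, denominators, a BYM fit for each of the 32
sex × age × period strata, standardization, inequality tables and decile
maps — is one call:

```r
run <- run_pipeline(cfg, out_dir = "ami_run",
                    mcmc = list(n_chains = 2, n_iter = 2000,
                                n_burnin = 1000, thin = 1))
run$table2[run$table2$row == "total",
           c("p10_2016-2018", "p90_2016-2018",
             "gap_2016-2018", "ratio_2016-2018")]
#>   p10_2016-2018 p90_2016-2018 gap_2016-2018 ratio_2016-2018
#> 1           269         363.6          94.6             1.4

list.files("ami_run")
#>  [1] "audit.json"          "bland_altman.csv"    "counts.csv"
#>  [4] "deciles.csv"         "deciles.geojson"     "manifest.json"
#>  [7] "percent_change.csv"  "person_years.csv"    "posterior_rates.csv"
#> [10] "registry"            "table1.csv"          "table2.csv"
```

Outputs are deterministic given the config seed: rerunning the pipeline
reproduces every file byte for byte (the manifest records their MD5s).

## Documentation

Every exported function is documented (`?bym`, `?link_events`, …), and the
methods vignette (`vignettes/ami-surveillance-methods.Rmd`) records the
methodological conventions: rule ordering in the linkage, rounding before
deriving gaps and ratios, ICAR rank and identifiability handling, and the
design of the synthetic registry.
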