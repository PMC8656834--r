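---
title: "Methods: small-area AMI incidence surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area AMI incidence surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amimap)
```

# Overview

`amimap` implements a township-level surveillance analysis of acute
myocardial infarction (AMI) incidence from two administrative record
streams — hospital discharges and death registrations — in five stages:

1. **Synthesis**: generate a synthetic city with known ground truth
   (`sim_registry()`), so every later stage can be validated exactly.
2. **Linkage**: deduplicate records into unique AMI events
   (`link_events()`).
3. **Population**: disaggregate township population totals into
   sex-age-period person-years (`disaggregate_population()`), with a
   Bland-Altman consistency check between population sources
   (`bland_altman()`).
4. **Modelling**: fit a Besag-York-Mollié (BYM) convolution Poisson model
   per sex × age-group × period stratum (`bym()`, `fit_bym_strata()`).
5. **Summaries**: direct standardization, median/IQR and inequality tables,
   decile maps (`direct_standardize()`, `summarize_table1()`,
   `summarize_table2()`, `decile_classify()`), orchestrated by
   `run_pipeline()`.

This vignette records the methodological choices and their rationale.

# Event definition and linkage

An AMI record is eligible when its principal diagnosis (hospital stream) or
underlying cause (death stream) starts with ICD-10 `I21` or `I22` and the
person is aged 35 or older. The four deduplication rules are applied in a
fixed order:

1. **Same-day chain merging.** Within a person, stays sorted by admission
   are chained whenever a stay begins on or before the running discharge
   date of the chain; transfers split across facilities become one care
   episode. The episode's total length of stay is the *sum* of constituent
   stay lengths, so a genuine multi-day admission split into transfer
   fragments is never mistaken for a short stay.
2. **Short-stay exclusion.** Single-stay episodes with total length of stay
   of at most one day that did not end in death and have no death record
   during the episode are removed as implausible AMI admissions.
3. **In-hospital death linkage.** A death record dated inside one of the
   person's episodes marks that episode fatal and is counted once
   (dual-recorded case); on a boundary shared by two episodes the earlier
   one absorbs it. Unmatched death records become death-only events at the
   death date.
4. **28-day rule (WHO-MONICA).** Per person, the earliest episode anchors
   an event; later episodes with onset within 28 days of the *anchor's*
   onset merge into it. The window is anchored at the index onset, not
   rolled forward, so onsets at days 0, 20 and 40 yield two events (20
   merges into 0; 40 starts a new event). Day 28 itself still merges.

Event onset is the admission date (or death date for death-only events):
symptom-onset time is not observed in administrative data, and admission is
the standard registry proxy. These orderings and conventions are exercised
against a brute-force per-person oracle on ~10,000 random record sets in
the test suite.

# Population denominators

Township-year population totals by sex are disaggregated into age groups
with the *district-level* age-sex composition: each township inherits its
district's proportions, which is exactly how registry denominators are
built when township-level age structure is unavailable. Person-years for a
period are the sum of the yearly totals in it (one person counted once per
calendar year). A Bland-Altman comparison between the two available
district population sources flags districts whose difference lies outside
mean ± 1.96 SD; `exclude_district()` supports a sensitivity analysis
without the flagged district.

# The BYM convolution model

For one sex × age-group × period stratum with counts $y_i$ and person-years
$E_i$ over townships $i = 1, \dots, n$:

$$y_i \sim \text{Poisson}(E_i \, e^{\alpha + u_i + v_i})$$

with a flat prior on the intercept $\alpha$, an intrinsic conditional
autoregressive (ICAR) prior on the structured effects $u$ over the township
adjacency graph, iid $N(0, 1/\tau_v)$ unstructured effects $v$, and
Gamma(0.5, 0.0005) hyperpriors on both precisions — a conventional weakly
informative disease-mapping choice. Strata are fitted independently (no
sharing across sex, age or period), mirroring the surveillance design.

Choices worth recording:

* **Identifiability.** The ICAR prior is improper; $u$ is recentred to sum
  to zero after every sweep with the mean moved into $\alpha$, so the
  likelihood is untouched. Islands (areas with no neighbours) have
  $u_i \equiv 0$ and rely on $v_i$.
* **ICAR rank.** The Gibbs update for $\tau_u$ uses shape
  $a + \text{rank}/2$ where rank = (number of non-island areas) − (number
  of connected components among them), the rank of the ICAR precision.
* **Sampler.** Metropolis-within-Gibbs in compiled code: adaptive
  random-walk proposals for $\alpha$ and each $u_i$, $v_i$ (tuned towards
  0.44 acceptance during burn-in only, so the post-burn-in chain is a
  fixed Markov kernel). Because the likelihood identifies only the sum
  $w = u + v$, the split and the precisions are updated in the eigenbasis
  of the graph Laplacian, where both priors are diagonal: the precisions
  move by log-scale Metropolis steps against the *marginal* density
  $p(w \mid \tau_u, \tau_v)$ with the split integrated out — so they never
  random-walk along the ridge of any particular split — interleaved with a
  joint rescaling move $w \to cw$ that traverses the scale/precision
  funnel; random eigencomponents of $w$ are refreshed by independence
  proposals from their prior (accepted by the bare likelihood ratio, which
  is near one exactly in sparse strata where coordinate-wise updates are
  slowest); and the $u$/$v$ split is then redrawn exactly from its
  Gaussian full conditional given $w$, followed by a conjugate Gibbs
  refresh of both precisions.
* **Diagnostics.** Split-$\widehat{R}$ and a Geyer
  initial-positive-sequence effective sample size are implemented in the
  package (`rhat()`, `ess()`, `check_convergence()`); runs are flagged when
  any monitored $\widehat{R}$ exceeds 1.05.
* **Validation.** With one area and a flat prior on $\alpha$ the posterior
  of the rate is the closed-form Gamma$(y, E)$; the sampler is checked
  against it. On synthetic cities the posterior log-rates beat raw $y/E$
  rates (RMSE against ground truth) on sparse townships with ~94% coverage
  of 95% intervals.

# Standardization and inequality

Directly standardized rates are $\sum_s w_s r_s$ with fixed weights $w_s$
from a reference population (`weights_from_population()`, by default the
period containing 2010). The summary tables report, per analysis period:

* **Table 1 layout**: median (Q1–Q3) of township rates — the total row uses
  age-sex-standardized rates, per-sex rows use age-standardized (weights
  renormalized within sex), and sex × age rows use raw stratum rates.
* **Table 2 layout**: 10th and 90th percentiles of the same township-rate
  distributions with the absolute gap (p90 − p10) and relative ratio
  (p90 / p10).

Percentiles use R's default type-7 interpolation and are rounded to one
decimal *before* the gap and ratio are derived; that matches how published
surveillance tables print percentiles and difference them, and makes the
derived arithmetic exactly reproducible from a printed table. Townships are
also ranked into deciles of equal size (±1) for mapping; decile 10 is the
conventional high-rate flag.

# The synthetic registry

The generator is the package's own design, built so that each linkage rule
has a dedicated, identifiable noise source:

* **Geography**: a serpentine (boustrophedon) lattice of districts, each a
  contiguous block of townships; rook adjacency. Real township polygons are
  deliberately not emulated — contiguity and a connected graph are what the
  model consumes.
* **True rates**: per-stratum baselines (a plausible age-sex gradient with
  period trends) modulated by a shared township field: a proper sample of
  the ICAR distribution on the lattice (graph-Laplacian eigenbasis, null
  space removed) rescaled to `sd_spatial`, plus iid noise `sd_unstructured`.
* **Populations**: lognormal township totals (default median 33,903,
  log-sd 0.82 — metropolitan-township scale), district age-sex
  compositions, small census noise, and one deliberately discordant
  district (yearbook inflated ×1.3) for the Bland-Altman check to find.
* **Records**: each true event belongs to a unique person, then noise is
  injected: transfer splits (length-of-stay-preserving same-day chains),
  spurious ≤1-day stays under new person ids, readmissions within the
  28-day window, and dual death records for in-hospital deaths. Genuine
  non-fatal stays last ≥2 days, so the short-stay rule removes injected
  noise and nothing else — which is what makes *exact* noise cancellation a
  testable property rather than a statistical one.

What the generator does not emulate: migration, age drift within periods,
out-of-area hospitalization, coding drift across ICD revisions, and
township boundary changes. Problem sizes in tests (e.g. 100-township
cities, 4 analysis periods) are the package's own validation choices.

# Worked example

```{r example, eval = FALSE}
cfg <- registry_config(n_districts = 4, townships_per_district = 13,
                       years = 2007:2018, pop_median = 6000, seed = 42)
run <- run_pipeline(cfg, out_dir = tempfile("ami_run_"),
                    mcmc = list(n_chains = 2, n_iter = 2000,
                                n_burnin = 1000, thin = 1))
run$table2[run$table2$row == "total", ]
```

See the README for a full worked example with printed output, and
`scripts/acceptance.R` in the source tree for the end-to-end validation
run.
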