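# helmamp

Single-cell and population-level analysis of antimicrobial peptide (AMP)
activity against bacteria, built around mother-machine microfluidics
data. Helminth (parasitic nematode) secretions contain candidate AMPs;
testing whether such a peptide merely slows bacterial growth or actively
lyses cells — and whether the single-cell effects are large enough to
explain the colony-count reductions seen in bulk assays — requires an
analysis chain spanning very different scales. `helmamp` implements that
chain as tested, reusable components:

* **`trench_sim`** — a continuous-time stochastic simulator of dead-end
  mother-machine trenches (75 µm × 1 µm, single-file cells): exponential
  elongation with a treatment window that reduces the rate by a set
  fraction, sizer division with asymmetry noise, Poisson lysis, open-end
  eviction, 1-min frame sampling and multiplicative length noise. It
  emits both observations and full ground truth, serving as the oracle
  for everything downstream.
* **`lineage_tracking`** — dynamic-programming reconstruction of cell
  lineages, divisions, lyses and evictions from per-frame cell tables,
  with likelihood-based scoring and an explicit model of divisions whose
  second daughter vanishes between frames.
* **`single_cell_stats`** — per-cell elongation rates (OLS slope of
  log-length vs time), sliding-window growth-rate timeseries, lysis
  frequencies and exposure-corrected lysis rates with exact Poisson
  intervals, and Welch t-tests on replicate-level summaries.
* **`population_model`** — the deterministic birth–death link between
  single-cell rates and bulk culture size:
  `ratio = exp(((α_t − λ_t) − (α_c − λ_c)) · T)`, with analytic
  inversions for the growth inhibition or lysis rate a target kill would
  require.
* **`bulk_assay`** — Miles–Misra colony counting:
  `CFU/mL = colonies × 20 × dilution × 5`, inoculum bookkeeping,
  countable-plate selection, percent reduction, one-way ANOVA with Tukey
  HSD, and a Poisson-plating simulator for end-to-end consistency
  checks.
* **`peptide_lab`** — peptide physicochemistry (Henderson–Hasselbalch
  net charge, isoelectric point by bisection, composition, ε₂₈₀ and
  Beer–Lambert concentration, disulfide detection from cysteine SG
  geometry in PDB files) and consensus screening of AMP-candidate
  predictor score tables.

## Worked example

Simulate four trenches under a 15% growth-inhibiting, mildly lytic
treatment applied during minutes 90–270, re-derive the single-cell
effects by tracking the (noisy) observations, and push them through the
population model:

```r
library(helmamp)

p <- sim_params(n_trenches = 4, t_total = 300, inhibition = 0.15,
                lambda_treat = 0.05, obs_noise_sd = 0.02, seed = 42)
sim <- simulate_trenches(p)
trk <- track_trenches(sim$observations)
est <- elongation_rates(sim$observations, trk, breaks = c(90, 270))

window_mean_rate(est, c(0, 90))    # 0.0281  (1/min, pre-treatment)
window_mean_rate(est, c(90, 270))  # 0.0238  (1/min, under treatment)
lys <- lysis_rate(trk$records, window = c(90, 270))
lys$rate                           # 0.066   (events/cell/h, 14 events)

pop <- population_params(alpha_control = 0.028,
                         alpha_treated = window_mean_rate(est, c(90, 270)),
                         lambda_treated = lys$rate / 60,
                         duration_min = 210)
reduction_percent(predict_ratio(pop))            # 67.0  (% CFU reduction)
100 * required_inhibition(90, 0.028, duration_min = 210)  # 39.2 (%)
required_lysis_rate(90, 210) * 60                # 0.66  (/h)
```

Reading the numbers: the tracker recovers a ~15% growth-rate dip
(0.0281 → 0.0238 1/min) and a lysis rate of ~0.07 events per cell per
hour. Sustained over a 210-min bulk incubation, that growth inhibition
alone predicts a CFU reduction in the tens of percent — while a 90% kill
would require either ~39% growth inhibition or a lysis rate of
0.66 events/cell/h, roughly ten times what the single-cell data show.
Growth inhibition, not lysis, is what can account for large bulk
colony-count reductions at these single-cell effect sizes.

Candidate screening works on plain CSV score tables:

```r
scores <- read.csv(system.file("extdata", "candidate_scores.csv",
                               package = "helmamp"))
subset(screen_candidates(scores), retained)$id
#> "Hmet" "Tchis" "Tdes" "Tsap" "Tscp"
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "helmamp-cli.R", package = "helmamp")` with
`simulate`, `track`, `stats`, `popmodel`, `bulk` and `screen`
subcommands.

## Vignette

`vignettes/helmamp-methods.Rmd` documents the models and their
assumptions, the default parameters and why they were chosen, what the
synthetic-data generator does and does not emulate, the tracking
likelihood and fate taxonomy (including its observability limits), and
the package's numerical conventions.
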