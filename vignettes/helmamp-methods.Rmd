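---
title: "Methods: from single-cell antimicrobial effects to bulk colony counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell antimicrobial effects to bulk colony counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helmamp)
```

# Overview

`helmamp` implements the computational chain of a single-cell
antimicrobial-activity study on trench-confined bacteria: a stochastic
simulator of mother-machine trenches that doubles as the pipeline's ground
truth, lineage tracking from per-frame segmentation tables, single-cell
growth-rate and lysis-rate estimation, a deterministic birth–death model
linking those single-cell effects to bulk colony-count reductions, the
Miles–Misra CFU assay statistics, and the physicochemical
characterisation and consensus triage of candidate antimicrobial
peptides (AMPs). This vignette records the models, the parameters that
matter, and the design decisions taken where the problem was genuinely
open.

# The trench simulator

## Model

A mother-machine trench is a dead-end channel (default 75 µm × 1 µm)
holding a single file of rod-shaped cells; the cell at the dead end (the
"mother") stays put while offspring are pushed toward, and eventually out
of, the open end. The simulator evolves each trench in exact continuous
time:

* **Elongation.** Each cell grows exponentially,
  `L(t) = L_birth · exp(α_eff t)`, with
  `α_eff = alpha0 · (1 − inhibition)` inside the treatment window
  `[treat_start, treat_end)` and `alpha0` outside it.
* **Division (sizer).** Each cell draws a division threshold at birth
  from a lognormal with mean `div_len_mean` and CV `div_len_cv`, and
  splits when it reaches it; the daughter fraction is
  `N(0.5, div_asym_sd)`, truncated to `[0.25, 0.75]`. Thresholds are
  re-drawn (up to 100 times) until they exceed 1.2× the birth length, so
  a newborn can never divide again within a fraction of a frame — without
  this guard, sub-frame division chains would create cells no observer
  could ever see.
* **Lysis.** Each cell carries an exponential clock with the
  window-appropriate rate (`lambda0` or `lambda_treat`, events per cell
  per hour); on lysis the cell is removed and all distal cells translate
  instantly toward the dead end.
* **Eviction.** Cells are stacked from the dead end; when a cell's distal
  edge is pushed past `trench_len` it is evicted. (The alternative
  convention — evicting only once the *proximal* edge crosses the open
  end — would let a cell span the trench mouth and break the invariant
  that all cell segments fit inside `[0, trench_len]`; the distal-edge
  rule keeps the geometry consistent and matches the physical picture of
  offspring being swept away as soon as they protrude into the flow
  lane.)

Events (divisions, lyses, evictions, treatment-phase switches) are
scheduled by exact next-event sampling; the only discretisation is the
observation process, which samples every `frame_interval` minutes and
multiplies each true length by lognormal noise
`exp(N(0, obs_noise_sd²))`. Observed centroids are obtained by stacking
the *observed* lengths, as a segmentation pipeline would.

Founder cells fill `init_fill` of the trench with sizes drawn from the
stationary size distribution of an exponentially growing sizer population
(density ∝ 1/L² between birth and division size). This matters: seeding
with, say, uniform cell-cycle phases over-represents old cells and causes
an initial division burst that biases population growth upward by several
percent — enough to fail the agreement check between the stochastic
simulator and the closed-form model.

## Default parameters

The study organism is a fast-growing Gram-positive rod in rich medium at
37 °C. The device geometry and schedule are fixed by the experimental
design: 75 µm trenches, 1-min frames, 90 min pre-treatment, a 180-min
treatment window `[90, 270)`, and recovery afterwards. Biological rates
are *plausible defaults, not fitted values* (no device-specific growth
parameters are published for this setup):

| parameter | default | unit | rationale |
|---|---|---|---|
| `alpha0` | 0.028 | 1/min | ≈25 min doubling time in rich medium |
| `inhibition` | 0 (0.15 treated) | — | upper end of the observed 10–15% growth-rate decrease |
| `lambda0` | 0.01 | /cell/h | spontaneous lysis is rare |
| `lambda_treat` | 0.05 | /cell/h | elevated but far below the rate a bulk kill would need |
| `div_len_mean` | 6 | µm | typical division length for a long rod |
| `div_len_cv` | 0.1 | — | threshold variability |
| `div_asym_sd` | 0.04 | — | near-symmetric septation |
| `obs_noise_sd` | 0.02 | — | 2% length measurement error |
| `init_fill` | 0.6 | — | trenches loaded partly full |

## What the generator does and does not emulate

It reproduces: exponential single-cell growth with a treatment dip,
stochastic sizer division with asymmetry noise, Poisson lysis,
single-file geometry with open-end eviction, 1-min sampling, and
multiplicative length noise. It deliberately does **not** model:
segmentation false positives/negatives or merged cells, image
registration errors, diffusive depletion of the peptide along the trench
(real treatment effects weaken toward the dead end), growth-rate
heterogeneity between cells, or filamentation. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model,
not robustness to every real-world segmentation artefact.

# Lineage tracking

Tracking reconstructs the lineage forest from the per-frame observation
table alone. For each consecutive frame pair the tracker chooses, by
dynamic programming over the rank-ordered cells, the order-preserving
assignment in which each current cell maps to one next-frame cell
(growth), two adjacent next-frame cells (division), or none
(lysis/eviction), with unexplained next-frame cells entering as heavily
penalised parentless tracks (nothing can enter a dead-end trench).

The assignment score is a negative log-likelihood:

* Length residuals are Gaussian on the log scale:
  `log(L_next / L_pred)² / (4σ²)` for growth and an analogous term for
  the summed daughter lengths of a division, with
  `L_pred = L · exp(α̂ Δt)` from a running (median-smoothed) growth-rate
  estimate. The noise scale σ is estimated on the fly from the match
  residuals (MAD-based, exponentially smoothed, floored at 10⁻³) unless
  supplied; with noise-free input it collapses to the floor and the
  discrimination becomes essentially exact.
* Each structural move carries a prior penalty on the −log scale:
  division 3, eviction 4, lysis 6, hidden division 6, appearance 12.
  The asymmetry between eviction and lysis encodes that in a packed
  trench evictions are roughly as frequent as divisions while lyses are
  rare; when noise makes two near-identical distal cells swappable, the
  cheaper reading is the eviction. An earlier formulation with
  absolute-log residuals and near-zero move penalties mis-ranked exactly
  these hypotheses and systematically overcounted lysis.
* **Hidden divisions.** A cell whose apparent length drops by more than
  the division tolerance cannot have shrunk; it must have divided while
  its second daughter vanished within the same frame interval (evicted
  at the open end, or lysed right after birth). The tracker prices this
  as a continuation through the surviving daughter, with a residual
  measuring how far the implied daughter fraction is from an even split.
* Division acceptance requires the daughter-length sum within 15%
  (configurable) of the predicted parent length. Ties break toward
  growth, then division, then termination.

The DP runs over the sequences reversed (distal end first) so that a
termination before any next-frame cell has been consumed — i.e. with no
surviving distal neighbour — can be priced as an eviction while interior
terminations are priced as lyses, without enlarging the state space.

## Fate taxonomy and its limits

A terminated track is classified by `classify_fate()`: disappearance with
a surviving distal neighbour is lysis (cells leave only via the open
end); disappearance with no distal survivor is eviction if the cell's
distal edge was within `eviction_margin` (default one mean cell length,
6 µm) of the open end, and lysis otherwise. Tracks reaching the last
frame are censored, as are tracks interrupted by missing frames.

Two observability limits are intrinsic, not tracker defects. First, a
daughter born and evicted between two frames is never observed; no
algorithm can recover it. Second, a distal-most cell that lyses while the
column reaches close to the open end leaves exactly the same observable
trace as an eviction. `observable_forest()` therefore collapses the
simulator's exact ground truth to what an ideal observer could know —
unobserved cells dropped, one-observed-daughter divisions merged into the
parent track, and (when given the margin) ambiguous distal lyses resolved
to evictions under the same declared convention the tracker uses.
Tracking is evaluated against this observable forest; on noise-free data
the reconstruction is expected to be *identical* to it, and the test
suite checks exactly that.

# Single-cell statistics

* **Elongation rate** is the OLS slope of `ln(length)` vs time; at least
  3 frames are required and shorter segments are flagged invalid. Tracks
  are split at the treatment boundaries (a cell spanning the boundary
  mixes two growth regimes) and additionally wherever the length drops by
  more than the division tolerance — the signature of a hidden-division
  continuation. Without the second split the embedded halving drags the
  mean recovered rate measurably below the truth.
* **Growth timeseries** are sliding-window means and standard deviations
  of the per-cell rates against their segment mid-times; empty windows
  yield `NA`, never zero. `window_mean_rate()` gives the replicate-level
  summary over a fixed window (e.g. 250–300 min).
* **Lysis frequency** follows the plotting convention
  `n_events / (n_lineages × window_hours)`, counting every lineage alive
  at any point in the window. This is *not* an exposure-corrected rate:
  lineages live about one division time, far less than a 3-h window, so
  the statistic understates the per-cell hazard. `lysis_rate()` divides
  by true cell-hours of exposure instead and carries the exact
  (Garwood/`poisson.test`) 95% interval; it is the estimator used for
  rate-recovery checks against the simulator's λ.
* **Replicate comparison** is a Welch two-sample t-test on
  replicate-level summaries. The replicate, not the cell, is the unit of
  inference: thousands of cells within a lane share the device, medium
  and focus drift, and treating them as independent would be
  pseudoreplication.

# The population model

Bulk culture size under condition *c* is modelled as deterministic
exponential birth–death growth, `N_c(T) = N_c(0) · exp((α_c − λ_c) T)`,
so the treated/control ratio after exposure T is

```
ratio = exp(((α_treated − λ_treated) − (α_control − λ_control)) · T)
```

and the reported statistic is `100 · (1 − ratio)` percent reduction.
Mapping the single-cell elongation rate onto the per-capita population
rate assumes balanced growth (stationary size distribution), which holds
in the simulator and is cross-checked by `simulate_population()`, a
well-mixed agent simulation under the same division/lysis laws: the test
suite requires the closed form to match the mean of 100 stochastic runs
within three standard errors.

The model inverts analytically. `required_inhibition()` gives the
fraction of the control growth rate that must be removed to reach a
target reduction in a given time; `required_lysis_rate()` gives the lysis
rate that would achieve it with no growth inhibition
(`−log(1 − R/100)/T`, e.g. `log(10)/210 min ≈ 0.66/h` for a 90% kill in
210 min). Comparing the latter with the lysis rate recovered from
single-cell data quantifies the argument that observed lysis frequencies
are far too low to explain a 90% bulk reduction, while a 15% growth-rate
inhibition sustained over the treatment window readily produces
reductions in the tens of percent. Any richer structure the original
model may have had (lag phases, density dependence) is out of scope; this
is the minimal deterministic interpretation consistent with that
conclusion.

# The bulk assay

The Miles–Misra bookkeeping follows the wet-lab protocol constants: a
culture at OD600 0.165 (≈1.5×10⁸ CFU/mL) is pre-diluted 1:5000
(→3×10⁴ CFU/mL), 10 µL seeds a 200 µL well (300 CFU, 1.5×10³ CFU/mL),
and after 210 min a 10 µL aliquot is serially diluted (10/100/1000) and
drop-plated. The back-calculation is
`CFU/mL = colonies × 20 × dilution_factor × 5` (a 10 µL drop is 1/100 mL).
"The least diluted plate yielding distinct colonies" is operationalised
as the smallest dilution whose count falls in a countable band (default
3–300); if every plate overshoots the band the most diluted one is used
with a warning. Condition comparison is one-way ANOVA with Tukey HSD at
α = 0.05, on raw CFU/mL by default (log10 optional — the original
analysis does not state which scale was used). When the assay is
simulated end-to-end, plating is Poisson: colony counts are
`Poisson(CFU/mL × drop_mL / dilution)`, which is what makes the
round-trip check (model reduction → plating → CFU statistics → recovered
reduction) a meaningful consistency test rather than an identity.

# Peptide characterisation and screening

* **Charge and pI.** Net charge is the Henderson–Hasselbalch sum over
  ionizable groups (N-terminus, His, Lys, Arg positive; C-terminus, Asp,
  Glu, Cys, Tyr negative). The pKa table is a named preset — Bjellqvist
  by default, EMBOSS as an alternative, individual values overridable —
  because published charge calculators do not document identical tables;
  printed literature charges should be treated as reproducible to a few
  tenths of a unit, not exactly, and both full-precursor and mature
  (signal-removed) forms are worth reporting since sources rarely state
  which was used. The pI is the unique root of the strictly decreasing
  charge curve, found by bisection to 0.01 pH units.
* **Extinction and concentration.** ε₂₈₀ = 5500·nTrp + 1490·nTyr +
  125·n_cystine (the cystine term only for oxidised cysteines), and
  Beer–Lambert `c = A280/(ε·path)`; a peptide with no chromophore is an
  explicit error, not a zero.
* **Disulfides.** Cysteine SG–SG distances within 2.0–3.0 Å mark likely
  disulfide bonds; conflicts are resolved greedily by ascending distance
  so each cysteine joins at most one bond (the test suite confirms the
  greedy choice against a brute-force minimum-weight matching on small
  instances). Parsing takes standard PDB ATOM records, first model,
  first alternate location.
* **Screening.** A candidate table row is retained if any evidence
  stream fires: ampir (precursor or mature) score > 0.7, MultiPep
  antimicrobial or antibacterial score > 0.7 (only defined for sequences
  under 200 residues), or a top CAMP BLAST hit with E ≤ 10⁻⁵. All
  thresholds are configurable; raising any of them can only shrink the
  retained set. The shipped `candidate_scores.csv` fixture transcribes
  the study's published score table and reproduces its five-peptide
  shortlist.

# Numerical choices and degenerate inputs

Event scheduling uses closed-form next-event times under piecewise
constant rates, so there is no frame-interval bias in rate recovery.
Division thresholds with CV 0 collapse to deterministic sizers;
`alpha0 = 0` with a division threshold below the initial length is an
explicit error (the cell could never reach its threshold). Identical
parameters and seed give bit-identical output; all randomness flows
through explicitly seeded generators (`withr::with_seed`), never the
global RNG state. Zero lineages in a lysis window, a zero-variance ANOVA,
a division of the full sequence as a "signal peptide", and a zero control
CFU are all explicit errors rather than NaNs.

Problem sizes in the shipped tests and acceptance script were chosen so
the whole chain demonstrates its properties at desk scale: 2–20 trenches
of 150–300 one-minute frames for tracking and recovery checks, 100
stochastic seeds for the population-model comparison, and three
replicates per condition for the assay statistics — the same order as one
imaging session of the real device.

# Known limitations

* The fate taxonomy interprets disappearances; in data with heavy
  segmentation dropout, dropout would masquerade as lysis (dropout is not
  modelled here, and real pipelines should gap-fill upstream).
* The lysis/eviction ambiguity band near the open end is resolved by
  convention; per-cell lysis rates inherit a small downward bias from
  genuinely ambiguous events, well inside the exact Poisson interval at
  realistic event counts.
* The population model assumes balanced exponential growth for the full
  exposure; saturation effects near stationary phase are not modelled.
* Charge/pI values depend on the pKa preset; cross-tool comparisons
  should state the table used.
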