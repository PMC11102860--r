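---
title: "Modelling the spread of confirmed insecticide resistance with ResistCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the spread of confirmed insecticide resistance with ResistCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ResistCA)
```

## The model and its assumptions

ResistCA models confirmed phenotypic insecticide resistance (IR) in
malaria vectors as a binary cellular automaton. The study area is a
planar lattice of square cells (5 km by default), and the clock ticks
monthly. A cell's state is 1 when the vector population it contains is
in the WHO *confirmed resistance* class — bioassay mortality below 90%
within 60 minutes of exposure — and 0 otherwise. The dynamics only
track this binary state: "possible" (90 ≤ mortality < 98) and
"susceptible" (98–100) populations are classified but not propagated,
and no genetics (allele frequencies, resistance mechanisms) are
represented.

The update has two channels. The **diffusion** channel captures spread:
a cell becomes (or stays) confirmed when confirmed resistance is already
present in its *closed* Moore neighbourhood — the 8 surrounding cells
plus the cell itself — *and* the local driver conditions satisfy at
least one diffusion rule. Counting the cell as its own neighbour is what
makes persistence work: a confirmed cell whose conditions stay
favourable keeps its state without needing a resistant neighbour. The
**emergence** channel captures long-range onset: a cell becomes
confirmed, regardless of neighbourhood, when an emergence rule holds
locally. A cell where both channels fail is 0 at the next step *even if
it was confirmed* — deteriorating conditions (say, temperature rising
past what the resistant population tolerates) erase the state. This
"conditions-first" reading is the strictest one consistent with a
disappearance clause; the alternative (a confirmed cell persisting on
neighbourhood presence alone while its own conditions fail) would make
confirmed resistance effectively irreversible, which contradicts the
intended dynamics.

Updates are synchronous and double-buffered: every decision at step *t*
reads the complete state at *t*, so the cell visit order can never
matter. Neighbourhoods truncate at the lattice edge (a corner cell has
3 neighbours); geographic domains are not toroidal. The engine is fully
deterministic — all randomness in the package lives in the synthetic
generator.

Coordinates are planar kilometres on a single projected plane. No CRS
handling is attempted: 5 × 5 km cells are only exact after projection,
so real lon/lat data must be pre-projected upstream. Cells are half-open
squares (closed on the lower/left edges), which makes point-to-cell
assignment a true partition: every in-bounds point belongs to exactly
one cell, and boundary points deterministically go right/up.

## Transition rules

Rules are declarative threshold predicates over named driver layers.
A *condition* constrains one driver; a *rule* is a conjunction of
conditions; a rule list is a disjunction (each rule describes one
sufficient driver combination). Conventions that needed fixing:

* interval conditions are **closed** on both ends — a band "15 to
  38 °C" includes 15 and 38;
* `greater_than` / `less_than` are **strict** — coverage "surpassing
  0.76" excludes 0.76;
* categorical conditions test exact code equality;
* a condition on a missing driver or `NA` cell evaluates **false** and
  is counted (one warning per run): absent data never asserts
  resistance;
* which rules gate diffusion versus emergence is configurable; by
  default the same rules serve both channels, since a combination that
  sustains resistance where it already is should equally permit onset
  where conditions allow.

The three built-in rules (`builtinRuleSet()`) encode driver
combinations consistently associated with confirmed IR in field data:
irrigated rice farming on its own; irrigated rice plus vegetable
farming within 15–38 °C; and ITN/IRS coverage above 0.76 plus vegetable
farming within the same band. Full operational rule sets for each
species × insecticide class are expected to come from calibration
against surveillance records, not from the package.

## Temporal conventions

Many driver databases are annual while the model is monthly. Yearly
continuous values are anchored at **January** of their year and
linearly interpolated between anchors, holding constant before the
first and after the last; anchored months reproduce their value
exactly. Whether a published annual value represents a January
snapshot, a mid-year value or an annual mean is generally not stated by
providers; January anchoring is a reproducibility convention, not a
claim about the data. Categorical layers (land use / land cover codes)
are never interpolated — each month takes the nearest anchor's codes,
ties to the earlier year.

In the other direction, the model's monthly states are bridged to
annually reported surveillance with an **any-month** rule: a cell is
predicted confirmed for a year iff its state is 1 in at least one month
of that year. This matches the conservative "any record confirmed"
aggregation used when rasterizing records (below).

## From bioassay records to observed grids

`classifyMortality()` implements the WHO bands. The published band
wording ("90 to 97", "98 to 100") leaves (97, 98) unassigned; the
package uses possible = [90, 98) so the three states partition [0, 100]
— verified exhaustively in the tests. `rasterizeRecords()` marks a
covered cell confirmed-present when **any** of its records for the
species/class/year classifies confirmed; cells without records carry no
status at all, and validation only ever scores covered cells. This
record-located evaluation is what makes small-denominator yearly
accuracies (including exact 1.0 years and undefined years) meaningful.
`initialSeed()` starts the automaton from every confirmed cell of the
earliest observed year — a whole-cohort seeding convention, chosen
because surveillance rarely identifies a single origin cell.

## Driver selection statistics

The screening pipeline mirrors standard exploratory practice:

* **Pearson r** against the confirmed-IR indicator, with drivers
  flagged important at |r| > 0.2;
* **chi-square** association for categorical drivers, without
  continuity correction, significant at p < 0.05;
* **PCA on the correlation matrix** (drivers are standardized — their
  units are incommensurate: °C, mm, fractions, persons/km²).
  Components are retained up to the smallest count whose cumulative
  explained variance strictly exceeds 0.80 (with a 1e-9 guard so a
  cumulative landing exactly on 0.80 is not counted as "over");
  drivers are retained at |loading| > 0.25 on any retained component.
  Kaiser flags (eigenvalue > 1) are reported but deliberately not
  enforced as a filter;
* **clustering** of drivers under distance 1 − |r| with average
  linkage: duplicated or strongly collinear drivers merge near height
  0, independent ones near 1. `selectDrivers()` keeps one
  representative per cluster — the member with maximal |r| against the
  indicator, ties broken lexicographically by name — among drivers
  passing both the PCA and correlation screens.

One numerical caveat the tests encode: with exactly duplicated driver
pairs the leading eigenvalues are degenerate, so individual loadings
within the tied eigenspace are rotation-arbitrary; only
rotation-invariant quantities (retained counts, per-driver loading
norms) are asserted.

## Validation and calibration

`validateStates()` computes per-year confusion counts (Tp, Tn, Fp, Fn)
at covered cells and the accuracy `(Tp + Tn) / (Tp + Tn + Fp + Fn)`;
years with no covered cells are reported `NA` and excluded from the
mean. `calibrateRules()` implements threshold fine-tuning as an
exhaustive search over a declared candidate grid: each combination
edits the named rule thresholds (in both channels), re-runs the
automaton from the seed, and is scored by mean annual training
accuracy. The maximizer is deterministic — the first-encountered
maximum in declared iteration order (first target varying fastest) — so
tied candidates resolve reproducibly; the returned score always equals
an independent re-validation of the returned rule set.

## The synthetic-data generator

The generator exists so every stage is testable end to end with no
external data. Its defaults define the reference study conditions used
throughout the tests: a 30 × 30 lattice of 5-km cells, 60 monthly steps
from January 2000, the three built-in rules planted as ground truth, a
single central seed cell, and 50 records per year.

Continuous driver surfaces are sums of a few seeded low-frequency
plane-wave cosines, min–max normalized into the declared range, plus an
optional 12-month sinusoid and i.i.d. noise, clipped back to the range.
Ranges are realistic for sub-Saharan study areas: temperature 12–42 °C
(seasonal amplitude 4 °C) — deliberately wider than the 15–38 °C rule
band so the band binds; precipitation 0–300 mm; relative humidity
20–95%; NDVI 0–0.9; coverage and crop fractions in [0, 1]; population
density 0–1000 /km²; elevation static. Crop fractions are
zero-inflated (70% of area has exactly zero irrigated rice, 50% zero
vegetables): presence thresholds like "irrigated rice > 0" are only
spatially selective if part of the map is genuinely crop-free.
The categorical land-cover layer is a smooth surface quantile-binned
into 5 contiguous patches. Everything derives from one integer seed.

Ground truth is generated by the automaton itself under the planted
rules, so truth is by construction a trajectory of the model class.
Records are then sampled per year: cells uniformly without replacement,
mortality uniform in [40, 89.9] for cells whose *annual* truth is
confirmed and [90, 100] otherwise — bands chosen so the WHO classifier
recovers the label unambiguously — with coordinates jittered inside the
cell. Sampling against annual (any-month) truth rather than a single
month keeps the generator consistent with the annual validation bridge;
with label noise 0 this makes end-to-end recovery exact (mean accuracy
1.0), a designed identity that the tests verify. With label noise *p* a
record's band is swapped with probability *p*, and mean accuracy
degrades to roughly 1 − *p*.

What the generator does **not** emulate: the spatial covariance of real
African driver surfaces, spatially clustered and biased surveillance
sampling, inter-annual driver trends, reporting heterogeneity across
countries and years, or rule misspecification (truth outside the model
class). Passing recovery tests therefore demonstrates internal
consistency of engine, sampling, rasterization and validation — not
predictive skill on real surveillance data, which the original study
assessed against held-out countries.

## Problem sizes and runtime choices

The test suite runs the engine-versus-oracle comparison on 100 random
10 × 10 lattices, the reversibility check exhaustively over all 2⁹
neighbourhood configurations, the chi-square oracle on 1000 random
tables, and the end-to-end recovery at the reference 30 × 30 × 60
scenario across 20 seeds — sizes chosen to exercise every code path
while keeping a full run around half a minute on one core. The
acceptance script repeats these computations from scratch under a
caller-supplied seed.

## Known limitations

* Binary state only; no intensity, no partial resistance, no
  within-cell population structure.
* Deterministic rules: no probabilistic transitions or fuzzy
  thresholds.
* Single projected plane; no reprojection, geodesic areas or country
  clipping.
* Calibration is exhaustive over user-declared candidates; no gradient
  or stochastic search (the intended use is small threshold grids).
* State rasters are plain multi-frame TIFF plus a JSON run
  configuration; georeferencing tags are not written.
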