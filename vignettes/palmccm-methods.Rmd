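---
title: "Detecting causal drivers of stem carbohydrates and reproductive growth with palmccm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting causal drivers of stem carbohydrates and reproductive growth with palmccm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmccm)
```

## The problem

Oil palms store non-structural carbohydrates (NSC) — starch and soluble
sugars — in the stem, where they buffer imbalances between photosynthetic
supply and the demand of developing fruit bunches. Monthly monitoring of a
few replicate trees yields four short biological time series per tree:
total female reproductive organ (FRO) volume $V_t$, its growth rate $G_t$,
and whole-stem starch and soluble-sugar contents. Daily meteorology at the
site provides candidate climate drivers, condensed into cumulative
temperature ($CT_n$) and cumulative rainfall ($CR_n$) over the $n$ days
ending on each sampling date ($n = 1, \dots, 60$).

The inferential question is directional: does reproductive growth drive
sugar mobilisation, or the reverse? Do cumulative climate windows force
NSC storage, and over which horizon and with what delay? Correlation
cannot answer this for short, seasonal, nonlinearly coupled series.
`palmccm` implements the empirical-dynamic-modelling (EDM) answer:
convergent cross mapping (CCM) with twin-surrogate significance testing,
for exactly this replicated monthly design.

## Preprocessing model

Each organ is measured as a width/depth/height triplet $(a, b, c)$ and
treated as an ellipsoid; the tree total is

$$V_t = \sum_i \tfrac{4}{3} \pi \, a_i b_i c_i, \qquad
  G_t = \frac{V_t - V_{t-1}}{d_t - d_{t-1}},$$

with $d_t - d_{t-1}$ the actual day gap between sampling dates. The three
measurements enter the formula as printed, with no halving; a date with no
living organs records $V_t = 0$ by default (an observed absence — set
`empty_fro = NA` to treat it as missing instead). Stem NSC at a date is
the arithmetic mean of the top, middle and bottom core assays; if one or
two heights are missing the mean of the present ones is used with a
warning, so isolated assay failures do not punch holes in the composite
series. Daily temperature gaps (single days or runs) are bridged by the
mean of the nearest present values on both sides; cumulative series then
sum the $n$ days ending on, and including, each sampling date. Day length
is computed from solar geometry (via `geosphere`) as an input variable
only.

## Composite series from replicate trees

Four trees over 42 months give 168 observations, but no single series long
enough for state-space reconstruction. Following the composite
("dewdrop") approach for replicated short series, each tree's series is
standardised to mean 0 and unit variance and the replicates are
concatenated with recorded boundaries; delay vectors are never allowed to
span a tree boundary. The replicates are treated as exchangeable
trajectories of the same underlying dynamical system — the assumption
under which pooling library points across trees is valid.

## Cross mapping

A delay embedding of the *library* series $y$ reconstructs the system
state as $(y_t, y_{t-\tau}, \dots, y_{t-(E-1)\tau})$ with $\tau$ fixed at
one sampling interval. Simplex projection predicts the *target* series $x$
at offset $tp$ from the $E+1$ nearest library states, weighted by
$w_i = \exp(-d_i / d_1)$. Skill $\rho$ is the Pearson correlation between
predictions and observations. If $x$ forces $y$, the attractor of $y$
encodes the history of $x$, so $y$ cross-maps $x$ with skill that grows
("converges") as more library is used — the CCM causality criterion. The
lag $tp$ at maximal skill estimates the transmission delay, with negative
$tp$ meaning the cause leads the effect.

Numerical choices, all of which matter on short series:

* **Leave-one-out exclusion.** A query's own state (any library vector
  sharing its time index) is excluded, so full-library skill is honest
  out-of-sample skill. A consequence worth knowing: self-cross-mapping a
  continuous-valued series gives $\rho$ slightly below 1.
* **Zero-distance ties.** If the nearest distance is zero, the smallest
  positive neighbour distance scales the exponent so exact matches share
  the top weight; remaining distance ties break toward the lower vector
  index, making results order-independent and reproducible.
* **Embedding dimension.** $E$ is selected per ordered pair from 2–8 by
  maximising full-library cross-map skill at $tp = -1$, and reused across
  that pair's lag grid.
* **Library-size scan.** 15 log-spaced sizes from $E+2$ to the full
  vector count, 100 seeded random draws per sub-maximal size, the full
  set (deterministic) at the top. Convergence requires the median skill
  at the largest library to exceed that at the smallest *and* a positive
  Kendall rank correlation between size and median skill.
* **Missing values.** Delay vectors containing a missing coordinate are
  dropped, as are queries without a defined target value at the offset.

S-map scans (`smap_scan`) screen every series for state dependence before
cross mapping: locally weighted linear forecasts with weights
$\exp(-\theta d / \bar d)$ across
$\theta \in \{0, 0.1, \dots, 8\}$; skill improving at $\theta > 0$ over
the global linear map at $\theta = 0$ indicates nonlinear dynamics. Local
regressions are solved by SVD pseudo-inverse, so rank-deficient
neighbourhoods degrade gracefully. The screen is advisory: failing series
are flagged and analysed anyway, and its practical role is to justify
capping cumulative windows at 60 days — longer sums are increasingly
linear (smoothed) and EDM loses its footing.

## Twin-surrogate significance

Every causal claim is tested against twin surrogates: random trajectories
on the original attractor. States are *twins* when their recurrence-matrix
columns coincide (maximum-norm distances, threshold at the target
recurrence rate, default 0.125); a surrogate starts at a random state,
follows the original successor map, and jumps uniformly among the
successors of a twin class whenever it visits one. At a segment end the
trajectory continues from the successor of a recurrence-neighbour of the
terminal state, preserving dynamical continuity. The observed skill is
significant when it exceeds the ensemble's 95th percentile
(linear-interpolation quantile), with 1000 surrogates by default. The
surrogate replaces the *target* (putative cause): this destroys the
specific temporal pairing under test while preserving the cause's
dynamics. (Surrogating the library instead is available via
`surrogate_of = "library"`.)

Two departures from the bare textbook construction were forced by short,
noisy, seasonal data, and both are load-bearing:

* **Phase locking (`period = 12` in the pipeline).** Monthly series that
  share an annual driver are skilful at cross-mapping each other purely
  through calendar alignment. A surrogate that starts at a random phase
  destroys that alignment and therefore *understates* the null: in our
  seasonal-confounder experiments the plain twin-surrogate test rejected
  essentially always. With phase locking, twin exchanges are restricted
  to states at the same month-of-year and trajectories (re)start at the
  calendar phase being filled, so the null ensemble retains
  calendar-locked seasonality and the test discounts it. This is what
  "the twin surrogate considers seasonality" has to mean operationally.
* **Selection-consistent null.** When $E$ is chosen by maximising skill,
  the observed statistic is a maximum over candidate dimensions; testing
  it against a fixed-$E$ null roughly doubled the false-positive rate in
  our null calibration. When `cross_map` or `lag_scan` selects $E$
  itself, each surrogate's skill is therefore maximised over the same $E$
  range before the 95% bound is taken.

Exact twins can be absent in short noisy series embedded at high
dimension. The generator escalates the recurrence rate through
0.05–0.2 and then falls back to smaller embedding dimensions for the
surrogate walk (the cross map itself keeps its own $E$); twins are
reliably found by $E \le 3$. Only if every combination fails does it
error.

## The pipeline

`run_biological_ccm` evaluates all ordered (library, target) pairs among
$V$, $G$, starch and sugar over lags $-6$ to $+6$ months, with the
per-row maximum flagged and convergence checked at the best lag —
the layout of the study's pairwise trait table. `run_climate_ccm`
cross-maps each biological variable (library) onto $CT_n$ or $CR_n$
(target) for $n = 1,\dots,60$ and lags $\pm 8$ months, with a surrogate
bound per cell; for each variable and driver, $E$ is selected once at a
reference window (default 30 days). Because cumulative targets have no
missing values, the neighbour geometry depends only on the lag, and the
60-window surface reuses 17 lag geometries — this is what makes full
surfaces cheap. `summarize_terms` condenses each surface into short
(1–20), mid (21–40) and long (41–60 day) terms with the majority-
significance rule (significant at more than half the term's windows) and
the "dotted" flag (best skill coexisting with more than five
non-significant windows in the term), and ranks terms by best skill.

No multiple-testing correction is applied across lags or windows; the
majority rule over cumulative days is the analysis's own robustness
device, implemented as stated. Treatments (NAT/PFT) are analysed as
separate composites, never pooled.

## The synthetic-data generator

`simulate_study` generates the full input layout — organ tables, NSC
tables at three stem heights, daily climate — with known causal structure
(`simulation_truth`), so every stage of the pipeline can be validated
without any field data:

* **Latent dynamics.** Coupled logistic maps on $(0,1)$ at monthly
  resolution: variable $v$ obeys
  $v_{t+1} = v_t (r_v - r_v v_t - \sum_u \beta_{uv}\, u_{t+1-\ell_{uv}})$,
  so a coupling lag $\ell$ means the cause leads the effect by $\ell$
  months and cross mapping peaks at $tp = -\ell$. Each tree is an
  *independent realisation* of the same system (own initial condition):
  this is the regime the dewdrop composite assumes, and it matters — if
  all trees shared one latent trajectory, the composite library could
  time-stamp calendar dates across replicates and any two variables would
  cross-map each other regardless of coupling. Maps are clamped into
  $(0.001, 0.999)$, a near-extinction bounce that keeps strongly forced
  runs finite.
* **Confounding and noise.** A shared seasonal signal
  ($0.5\,\sin(2\pi t/12)$ by default, on the standardised scale) is added
  to every variable of every tree, calendar-locked; observation noise is
  i.i.d. Gaussian per tree (sd 0.25 by default, the regime where
  compositing replicates is worthwhile).
* **Climate.** Daily temperature is a weak annual sinusoid (mean
  27.4 °C, amplitude 1.5 °C, peaking in late May) plus AR(1) noise, with
  $t_{max}/t_{min}$ at a fixed diurnal half-range; rainfall is a
  zero-inflated gamma with Markov wet-day persistence scaled to an
  expected 2000 mm per year — a humid equatorial regime with weak
  thermal seasonality.
* **Planted climate forcing.** Optionally one variable is forced by the
  $n$-day cumulative driver at lag $\ell$; the driver enters through its
  empirical CDF (rank-uniform on $(0,1)$), so heavy-tailed rainfall sums
  keep their full forcing variance.
* **Round trip.** Organ dimensions are synthesised so that
  `fro_volume`/`fro_growth` recompute the generator's per-tree $V$ and
  $G$ exactly; NSC values are written identically at the three stem
  heights.

What the generator does *not* emulate: real NSC assay units and
magnitudes (everything lives on the standardised scale), spatial gradients
along the stem, organ-stage demography, observation-date irregularity
beyond calendar-month spacing, and climate–trait feedbacks (climate is
exogenous). Passing the validation suite therefore shows the *inference
machinery* is sound at study-like sizes, not that any particular field
conclusion is right.

## Validation experiments and their problem sizes

The test suite validates the machinery end to end on systems with known
truth; the problem sizes below were chosen to make each property
measurable while keeping the default run short:

* **Oracle equivalence.** Simplex projection agrees exactly (neighbours,
  weights, predictions) with a brute-force implementation on 100 random
  composite instances.
* **Direction recovery.** On the standard benchmark (logistic pair,
  $x \to y$ at strength 0.32, $n = 400$), the true direction's
  full-library $\rho$ exceeds 0.8 and beats the reverse direction in
  ≥ 95 of 100 seeded replicates, at $E = 2$ — the generator's known
  attractor dimension, which is also used in the other benchmark
  experiments; dimension selection is a device for real data, not for
  systems whose dimension we built.
* **Lag recovery.** A planted two-month transmission delay is located at
  $tp = -2$ in ≥ 90 of 100 replicates.
* **Seasonal null.** Two uncoupled variables sharing the seasonal
  confounder, at the study layout (4 × 42), are declared significant in
  ≤ 10% of 200 replicates (level 0.95, 1000 phase-locked surrogates,
  $E$ selected as in the full procedure).
* **Climate-window recovery.** A planted dependence of sugar on the
  30-day cumulative rainfall at lag 2 is located within ±5 days of
  $n = 30$ at exactly $tp = -2$ in ≥ 80% of 50 replicates, on composites
  of 4 trees × 300 months (length 1200). Window lengths are intrinsically
  hard to pin down — $CR_{25}$ and $CR_{30}$ correlate at about
  $\sqrt{25/30} \approx 0.91$ by construction — so this experiment needs
  the longer composite; at the study layout (4 × 42) the same experiment
  finds the exact lag in roughly 40% and the ±5-day window in roughly
  30% of replicates. That is the honest small-sample picture: at
  168 points the surface localises the *region* of forcing, and
  single-cell argmax claims should be read with the majority-rule term
  summary, not cell by cell.
* **Round trip and determinism.** Preprocessing reproduces the latent
  $V$, $G$ to within $10^{-9}$ relative error, and identical
  configuration and seed yield byte-identical output files.

## Known limitations

* Cross mapping cannot separate bidirectional coupling from very strong
  unidirectional forcing (synchrony), and the composite design assumes
  replicate trees share one attractor — systematic tree-to-tree
  differences in dynamics (not just level/scale, which standardisation
  absorbs) would violate it.
* With $E \ge 3$, a delay vector encodes the last several forcing values
  with similar fidelity, so neighbouring negative lags compete; lag
  estimates sharpen markedly at small $E$ and large libraries.
* Transmission-lag estimates degrade qualitatively with observation
  noise. Pinpointing the exact lag amounts to locally inverting the map
  for the forcing value, which needs neighbour distances finer than the
  noise floor; at noise sd 0.25 (a quarter of the signal) the coupling's
  *echo* through the effect's own dynamics outweighs the direct imprint
  and the best lag drifts to adjacent, more negative values. The
  direction-and-lag recovery property is therefore validated at noise
  sd 0.1; at the default 0.25 the tools still detect *that* coupling
  exists, but single-lag readings should not be over-interpreted.
* The twin-surrogate null is conditional on the observed trajectory; with
  very few twins the ensemble degenerates toward shifted copies of the
  original and the test loses power rather than size.
* No multiple-testing correction is applied across the 60 × 17 climate
  surface; per-cell significance there is a screening device, interpreted
  through the term-level majority rule.
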