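---
title: "Methods: hydrologic descriptors, clustering, and surrogate GHG accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrologic descriptors, clustering, and surrogate GHG accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and the numerical and design choices
behind `paddyghg`, in the spirit of a methods appendix: what is computed,
under which conventions, which parameters matter, and what the synthetic
data can and cannot tell you.

## 1. Water-level series and ingestion

A field's record is a daily water level in cm relative to the soil surface:
positive values are ponded floodwater height, negative values the depth of
the saturated front read in a perforated monitoring tube, censored at the
tube depth of −15 cm (deeper water tables are recorded as exactly −15 and
flagged). Ingestion (`read_water_series()`) enforces a complete daily grid
per field.

Missing-day policy (a design choice; field protocols rarely state one):
interior gaps of up to **3 consecutive days** are filled by linear
interpolation and flagged `observed = FALSE`; longer gaps invalidate the
field, because event-duration descriptors (A5–A8, B4–B6) are sensitive to
how a gap is bridged. Gap-filled days participate in descriptor computation.
Fields spanning fewer than 30 days are rejected. Percentage descriptors use
each field's own monitoring span as the base, since spans differ between
campaigns.

## 2. The 17 hydrologic descriptors

Days are classified by level `l`:

* flooded iff `l > 0` — "above soil level" is read strictly, so `l = 0`
  counts as drained (band [−5, 0]);
* flood bands half-open on the left: (0, 5], (5, 10], > 10 cm;
* drainage bands: [−5, 0], [−10, −5), < −10 cm (censored −15 readings fall
  in the last).

Maximal runs of flooded/drained days form flood/dry events. Flood duration
classes are 1 day, 2–7 ("within a week"), 8–30 ("within a month"), > 30
("more than a month"); the boundary readings are a convention the source
tables leave open. A dry event is banded by its **deepest** level (events
can span bands; the extreme governs the redox state reached). B4–B6 are 0
when a band has no event, avoiding undefined means.

The A-group percentages are taken over monitored days (A1), flooded days
(A2–A4) and flood events (A5–A8); B1–B3 over drained days. These bases make
the composition identities A2+A3+A4 = 100, A5+…+A8 = 100 and B1+B2+B3 = 100
hold exactly whenever the base is non-empty, which the test suite asserts on
random series against an independent brute-force day-by-day oracle.

Transition counters use consecutive-day pairs: C2 counts pairs with
`l_t ≥ +5` and `l_{t+1} ≤ −5` (thresholds inclusive); C3 counts pairs with a
drop `l_t − l_{t+1} > 10` (strict), regardless of the end level's sign. The
two definitions are independent; no ordering between C2 and C3 is implied.
Series shorter than two days have no transitions and are rejected.

## 3. Hydrologic clustering

Descriptors mix percentages, counts and durations, so columns are
standardized (mean 0, sd 1, denominator n−1) before K-means;
zero-variance columns are left at 0 with a warning. K-means uses Lloyd's
algorithm (Euclidean distance) with 50 random restarts (centers sampled from
the data rows), 300 iterations, keeping the lowest within-cluster sum of
squares; restarts that end with an empty cluster are discarded. Cluster
quality is summarized by pseudo-R² defined as 1 − WCSS/TSS (one of several
conventions; it is stated in the object so downstream users know which was
used).

The number of clusters is chosen by mean silhouette width over k = 2…8,
**subject to a minimum cluster size of 3**; ties go to the smallest k. The
size floor operationalizes "a reasonable number of members per cluster":
without it, silhouette often prefers shaving 1–2 outlying fields into their
own cluster. Labels are re-ordered so cluster 1 is the driest and cluster k
the wettest by the centroids' unstandardized A1, making cluster numbers
comparable across runs.

Descriptor importance for the clustering is measured by permutation: the
importance of descriptor j is the mean fraction of fields whose
nearest-centroid assignment changes when column j is permuted across fields
(200 permutations by default; Monte-Carlo error on this fraction is about
±0.02 at that setting).

Between-cluster emission differences use one-way ANOVA with Fisher's LSD at
α = 0.05 in the classical unprotected-after-significant-F convention:
pairwise comparisons (pooled error mean square, no multiplicity correction)
are made only when the overall F-test is significant. Letters are assigned
by descending mean with the standard insert-and-absorb algorithm; singleton
clusters are excluded with a warning.

## 4. Pedotransfer functions

* Bulk density from organic carbon (when not measured):
  `BD = 1.449·exp(−0.03·OC)` (Abdelbaki 2018), clamped to (0.8, 1.8) g/cm³
  with a warning. Measured BD is never overwritten; provenance is recorded
  per field.
* Porosity: `φ = 1 − BD/2.65`, particle density fixed at 2.65 g/cm³ — hence
  zero porosity occurs exactly at BD = 2.65.
* Retention and conductivity: Saxton & Rawls (2006) equations for
  volumetric water content at 1500 kPa (wilting point), 33 kPa (field
  capacity), saturation, and `K_sat = 1930·(θ_s − θ_33)^(3−λ)` mm/h, with
  organic matter = 1.724 × OC. The retention source for water-filled pore
  space is a documented fallback choice: WFPS% = 100·θ/φ with θ from the
  Saxton–Rawls retention curve. Each equation is verified in the tests
  against an independent second transcription.
* In dense clayey soils the Saxton–Rawls θ₃₃ can exceed the BD-derived
  porosity; WFPS is capped just below saturation rather than reported
  above 100 %.

## 5. GWP accounting

Seasonal totals are inclusive sums from sowing to harvest. CO₂-equivalents
use the AR6 GWP100 factors applied to the emitted gas mass: 27 kg CO₂-eq per
kg CH₄ and 273 per kg N₂O, reported in mt CO₂-eq ha⁻¹:
`GWP = (27·CH₄ + 273·N₂O/1000)/1000`. The factors are immutable defaults,
overridable only explicitly (e.g. for AR5 comparisons). Conversion is linear
and unit-audited in the tests.

## 6. Emission-level classification

Seasonal CH₄ is discretized into five ordered levels. The default is
equal-frequency (quantile) binning on the pooled training values — intervals
left-open right-closed except the lowest — because published cut points for
this kind of analysis are near-quantiles of the pooled data. Two published
fixed-boundary sets ship as presets (56.6/129/207/317 and 73.6/162/254/383
kg CH₄ ha⁻¹); the two disagree in print, so both are provided and neither is
treated as canonical.

Records are split 80:20 with per-level stratification (`floor(n·0.8 + 0.5)`
per level after a seeded shuffle). The forest uses 500 trees and √p
descriptors per split; its out-of-bag error is the headline error. The
single interpretable tree is grown with a minimum leaf of 5 and pruned by
the 1-SE cost-complexity rule under seeded 10-fold internal
cross-validation. Forest size, leaf size and pruning rule are this package's
choices (commonly left unstated in applied work) and are recorded in the
fitted object.

## 7. Sensitivity design

Each cluster is represented by its **medoid** — the member field closest to
the centroid in standardized descriptor space, ties broken to the smallest
field id. The default grid crosses N-rate multipliers {1, 1.25, 1.5, 1.75,
2} of the baseline schedule (all split doses scaled proportionally) with
residue fractions {0, 0.25, 0.5, 0.75, 1}. Two baseline N rates circulate
for this region — 125 kg N ha⁻¹ (basal 25 + two top dressings of 50) and
90 kg N ha⁻¹; both ship as presets (`n_schedule_preset()`), with 125 as the
default and the discrepancy left visible to the user. Deltas are taken
against the (×1, residue 0) cell. With noise on, cells are means ± sd of 30
replicate draws; with noise off the grid is deterministic.

## 8. The synthetic-data module

### What it emulates

`generate_landscape()` draws fields from five hydrologic archetypes per
scenario. The **wet** scenario (season 2021-07-07 to 2021-11-11) emulates a
rain-fed year: a briefly flooded dry type, shallow (≈3 cm) ponding with and
without drainage breaks, and deep (≈13 cm) ponding with and without one
sustained mid-season drainage event. The **dry** scenario (2022-07-06 to
2022-11-02) emulates an irrigation-driven year: a never-flooded type
(water table below −12 cm), two intermittent types (frequent one-day
irrigation floods vs. sparser 2–3-day floods), a persistently
shallow-flooded type and a long-deep-flood type. Mixture weights put ~45 %
of dry-scenario fields in the intermittent longer-flood type and under 10 %
in the never-flooded type.

A field's series is template + stationary AR(1) noise (marginal sd 0.8–1.2
cm, ρ = 0.5–0.6; the innovation sd is scaled so the stated sd is the
marginal one) + Poisson-counted irrigation pulses receding linearly, clamped
to [−15, +25] cm.

### Why the templates look the way they do

The archetypes are intended to be *recoverable*: K-means plus silhouette
selection should find exactly five tight clusters. Event-class descriptors
flip discretely when a trajectory grazes a banding edge — one noise
excursion across 0 cm splits a month-long flood into two week-class events
and swings A7/A8 by 100 points. The templates therefore follow a
"band-edge hygiene" rule, adopted at design time: levels sit roughly three
noise-sd away from the classification edges (0, ±5, ±10 cm); flood entries
and exits are 1–2-day jumps so the zero crossing is confined to a narrow
window; rain-fed ponded types receive no irrigation pulses (their water is
monsoon-driven in any case); and engineered quick-drop signatures clear the
C2/C3 thresholds by ≥ 2.5 sd. Wet-year flood durations are also kept below
~55 % of the monitoring span so that surrogate CH₄ stays inside a realistic
seasonal envelope (roughly 7–608 kg ha⁻¹) under the default lognormal noise.

### The surrogate emission model

The surrogate is a declared stand-in for a process-based biogeochemistry
simulator, **not** a reimplementation of one. With `a1` the flooded fraction
(A1/100), `a4` the deep-flood share of flooded days (A4/100) and `R` the
residue fraction:

* CH₄ (kg ha⁻¹) = `650 · a1^1.4 · (1 + 0.5·a4) · (1 + 0.4·R·a1) · exp(ε₁)`,
  ε₁ ~ N(0, 0.25²). CH₄ is zero for never-flooded fields, increasing in
  flooding, deep water and residue, and independent of the N rate.
* N₂O (g ha⁻¹) = `(10 + 1.2·N_eff) · (1 + 2·T) · (1 + 0.5·clay/100) ·
  exp(ε₂)`, ε₂ ~ N(0, 0.3²). `N_eff` sums only doses applied on days the
  field is not flooded — a dose broadcast onto standing water contributes
  nothing. `T` is the number of drained↔flooded day transitions within ±7
  days of any application, divided by the number of applications: wet–dry
  cycling around fertilization is the N₂O "hot-moment" driver.

The defaults were calibrated once so that a seeded wet-scenario landscape
spans roughly the realistic seasonal CH₄ range and CH₄ carries > 90 % of
CO₂-equivalents there, and were not revisited.

### What the synthetic data does **not** show

* The generator is phenomenological (template + AR(1) + pulses), not a
  water-balance model; it reproduces descriptor patterns, not hydraulics.
* Daily flux dynamics, crop growth and soil carbon pools are out of scope;
  only seasonal totals are produced.
* The surrogate's transition term makes seasonal N₂O for extremely flashy
  irrigation-driven fields (T ≈ 5–8) reach the low thousands of g ha⁻¹ —
  above the few-hundred maxima typical of published dry-year estimates.
  With the default parameters, the transition index and the printed N₂O
  ceilings cannot both be honored; the qualitative pattern (dry flashy
  years ≫ wet stable years; N₂O dominant in the driest clusters) is
  preserved and the magnitude caveat stated here.
* Passing recovery tests on this data shows the pipeline is correct and
  that well-separated hydrologic types are recoverable — not that real
  landscapes are this well separated. Real tube data have reading errors,
  missing spells, and fields between archetypes.

## 9. Problem sizes and tolerances used in the tests

Unit tests run the oracle comparison on 300 random series and the recovery
checks on 12–160-field landscapes; the acceptance suite uses 1,000 random
series for the descriptor oracle, a 160-field dry landscape for cluster
recovery (adjusted Rand > 0.9), and a 47 + 160 pooled landscape for the
importance ranking. Exact identities (descriptor oracle, GWP arithmetic,
split counts) are asserted to 1e−12; the surrogate exponent recovery to
1e−6; PTF dual transcriptions to 1e−6 relative. K-means runs Lloyd
iterations to assignment convergence (at most 300); medoid ties use a
1e−12 distance tolerance before the lexicographic rule.
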