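---
title: "Quantitative continuous IHC scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative continuous IHC scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcscore)
```

This vignette is the package's own account of the science it implements:
what is being modelled, which parameters matter, what the synthetic data do
and do not emulate, and where the design was genuinely open.

## The measurement model

Brightfield IHC images mix two chromogens: hematoxylin (blue, nuclei) and
DAB (brown, the membrane marker). Under the Beer–Lambert law the per-channel
absorbance `A_c = -log10(I_c / I0)` is linear in the stain amounts, so the
per-pixel DAB amount is obtained by projecting the absorbance vector onto a
stain basis (`stain_basis()`, Ruifrok–Johnston H-DAB by default, completed
with an orthogonal residual vector so the 3×3 system is invertible).

**The OD unit.** The package reports scaled OD units equal to 100 × base-10
absorbance (`od_scale = 100` in `deconvolve_dab()` and `render_roi()`). The
positivity thresholds 6–120 then span visually faint to very strong brown:
6 units = 0.06 absorbance ≈ a 13% dimming of the DAB channel, at the edge of
perception; 120 units = 1.2 absorbance ≈ 94% dimming. The scale factor is a
single configuration constant; nothing downstream depends on it beyond the
threshold list.

**Segmentation.** Cell instances grow from supplied cell centres by a seeded
watershed with the membrane posterior as energy, restricted to the
epithelium mask; the posterior maps come from an upstream detector that is
outside this package's scope, which is why they are inputs. The flooding
uses the morphological watershed semantics — the priority of a pixel is the
maximum energy along its growth path — so a region must cross its own
membrane crest before it can claim anything beyond it. Compartments inside
each instance: membrane = a band of `band_px` (default 3, allowed 2–4)
8-connected erosion steps from the instance boundary, including ridges
shared with touching neighbours; nucleus = nuclei posterior ≥ 0.5, minus the
band; cytoplasm = remainder. The three masks are disjoint and exhaustive by
construction, and the per-cell measurement is the arithmetic mean OD over
each non-empty compartment. The membrane OD is measured on the full band
rather than the one-pixel ridge; with a 3 px band at 0.5 µm/px this averages
over ≈ 1.5 µm of membrane signal, which is also how the band is rendered in
the synthetic ground truth.

## Per-patient readouts

For one patient with cells `i = 1..N`, membrane ODs `OD_i`, and centroid
distances `d_ij`:

* **OD quantiles / mean** of `{OD_i}` (quantiles 5–95 in steps of 5,
  linear interpolation between order statistics, R type 7).
* **% OD-positive**: `100 · #{OD_i ≥ t}/N`, inclusive comparison, over the
  threshold list `{6, 8, 10, 12, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90,
  100, 110, 120}`.
* **Positive density**: positives per mm² of analysed epithelium.
* **Binary spatial proximity score (bSPS)**: the fraction of cells that are
  positive themselves *or* have at least one positive neighbour within
  radius `r ∈ {10, 25, 50, 75} µm` (Euclidean, inclusive `d ≤ r`, self
  excluded from the neighbourhood). This models the ADC bystander effect: a
  cell close enough to an expressing cell is likely to be killed even if it
  expresses nothing. With `r → 0` the neighbourhood empties and bSPS reduces
  exactly to % OD-positive — a limit the tests assert with float equality.
* **Continuous SPS (cSPS)**: per cell, a distance-weighted neighbourhood OD
  with weights `w_ij = 1 − d_ij/r` and self-weight 1. The raw weighted sum
  does not reduce to the cell's own OD as `r → 0` whenever neighbourhoods
  are non-trivial, so the package normalises by the total weight (a convex
  combination of the neighbourhood's ODs); the exact `r → 0` limit then
  holds, and each cell's value is bounded by the neighbourhood's min and max
  OD. The literal raw weighted sum is available via `normalize = FALSE`.
* **sTIL density**: stromal TILs per mm² of tumour centre. The denominator
  is the full tumour-centre area, matching how such densities are reported;
  a stromal-area denominator would need a stromal segmentation that is not
  among the inputs.

The default grid enumerates 19 + 1 + 17 + 17 + 68 + 80 + 1 = 203 readouts in
a fixed, documented order. The full published grids in this area are larger
(they include additional feature variants whose exact composition is not
derivable from the printed parameter lists); the package treats its own
enumeration as the ground truth for all counts.

Spatial queries use a uniform grid index with bucket width `r`; neighbour
contributions are accumulated in ascending cell order so the results are
bit-identical to the all-pairs scan, which the test suite asserts.

## Consolidation

Readouts with a single unique value are dropped; so are near-zero-variance
readouts (unique values / patients < 0.1 **and** top-two frequency ratio
> 95:5). Then, while any pair has |Spearman ρ| ≥ 0.99 (average ranks for
ties, absolute value), the member with the larger mean absolute correlation
against the remaining set is discarded and the means are re-evaluated. The
published description fixes the discard criterion but not the processing
order, so the package processes the largest |ρ| pair first and breaks all
remaining ties by lexicographic readout name — this makes the surviving set
independent of input column order, which the tests check on random matrices.

## Cut-point optimisation and validation

Every observed readout value is a candidate cut; `value ≥ cut` defines the
biomarker-positive group; cuts leaving either group under 20% prevalence are
inadmissible (guards the log-rank test's power against extreme splits). Two
targets: maximise positive-group ORR (responders = CR/PR; SD, PD and NE are
non-responders, with NE kept in denominators), or maximise the log-rank χ²
(equivalent to minimising p while avoiding underflow ties at very small p).
Ties take the smallest cut, which favours the more inclusive positive group
and makes the scan deterministic. The optimum is stabilised as the modal cut
over B = 50 bootstrap resamples (modal ties again to the smallest cut).

The log-rank statistic is the standard two-group form with the
hypergeometric variance for ties; the implementation is a single C++ pass
over the time-sorted risk table (it sits inside the bootstrap × candidate ×
permutation loops), and the test suite requires agreement with both an
independently coded risk-table oracle and `survival::survdiff` to 1e-10 on
random datasets.

**Repeated cross-validation.** The cohort is split into k = 5 random folds;
a cut is trained on each set of k−1 folds and applied to the held-out fold,
so each patient is labelled once per split by a model that never saw it;
labels are pooled within a split for the cross-validated Kaplan–Meier
curves. Patients pooled across folds are not independent observations, so
the pooled curves cannot be tested with a standard log-rank test; instead
the clinical rows (time, event, response together) are permuted m times
against the fixed readout, the whole pipeline is re-run per permutation, and
the empirical p is the add-one estimator `(1 + #{null ≥ obs})/(m + 1)`,
which can never return 0. Full-fidelity defaults are n = 300 splits and
m = 1200 permutations; examples and tests use n = 10, m = 99, which changes
resolution, not validity.

Two choices here were genuinely open:

* *Across-split aggregation.* How n per-split pooled statistics combine into
  one number is not prescribed anywhere; the package uses their mean, and —
  the governing principle — applies the **identical** aggregation to every
  permutation, because the permutation test is exact exactly when observed
  and null statistics go through the same machinery.
* *Permutation cost control.* For the same reason, permutations evaluate the
  same number of splits as the observed run by default (`n_perm = n`).
  Evaluating fewer splits per permutation is cheaper but gives the null
  statistic a heavier tail than the observed one (a mean over fewer
  positively correlated split statistics), making the p conservative; the
  option exists (`n_perm < n`) but is not the default. Permuted runs reuse
  the observed run's fold partitions and bootstrap draws (same seed), a
  variance-reduction choice that preserves exchangeability.

## The synthetic cohort generator

The generator is the package's study population; its defaults are fixed and
everything in the test suite runs against them.

* **Spatial process**: Thomas cluster process (Poisson parents, Gaussian
  offspring, default cluster radius 30 µm, mean 25 cells/cluster) in a
  1 × 1 mm tissue window; uniform-Poisson available. Clustering matters
  because the SPS features only separate from plain %-positive when
  positive cells cluster spatially.
* **OD model**: per-patient lognormal "expressing" component (location
  `log 12`–`log 35`, scale 0.3–0.6, in scaled OD units) plus a near-zero
  negative component (|N(1, 0.5)|). The negative-cell *fraction* is drawn
  from one of two ranges — ≤ 8% for planted-positive patients, 30–55% for
  planted-negative — which creates a gap in the planted readout
  (% membrane-OD ≥ 6) between the groups; the planted cut (default 80%)
  sits inside that gap. With `positive_cell_clustering` the negative cells
  fill whole spatial clusters, so negative regions exist and bSPS does not
  saturate.
* **Outcomes**: exponential PFS with independent uniform censoring on
  (0, 36) months; the planted-positive hazard is `hazard_ratio` times the
  planted-negative hazard (default 0.58 with a planted-negative median of
  8.6 months, i.e. positives progress slower — medians ≈ 14.8 vs 8.6
  months); response is Bernoulli on a logit scale (≈ 30% in negatives,
  effect +1.0 giving ≈ 53% in positives), with a fixed 3% non-evaluable
  rate counted as non-responders; planted-positive prevalence defaults to
  76%. These defaults emulate the headline pattern of a trastuzumab
  deruxtecan phase-1 breast-cancer cohort: a large biomarker-high group
  with longer PFS and higher ORR.
* **Rendering**: cells are drawn as equal-radius disks (default 5 µm at
  0.5 µm/px), Voronoi-split where disks overlap; the membrane band is the
  same 3-erosion band the segmenter uses; DAB absorbance on each
  compartment equals the cell's true OD / 100 with N(0, 0.004) per-pixel
  absorbance noise (which dithers the 8-bit quantisation so compartment
  means stay unbiased); hematoxylin 0.65 on nuclei. Posteriors are smoothed
  indicators; the membrane posterior is saturated on the band support so
  the watershed sees a clean crest plateau rather than a spurious
  low-energy rim at the blur edge. Cells closer than `min_sep_um`
  (default 1.8 × radius) are dropped sequentially with a count — under a
  hard-core constraint this is equivalent to regenerating the layout — or
  raise an error, per configuration.

**What the generator does not emulate**: histological texture, nuclear
pleomorphism and cell-size variation, stromal architecture, staining
artefacts, scanner colour drift, section-thickness effects, and any
within-patient correlation between OD and cell geometry. Passing tests
therefore demonstrate that the *pipeline mechanics* are correct under the
stated statistical structure, not that the scores are clinically valid on
real tissue.

## Numerical choices

* Quantiles: linear interpolation between order statistics (type 7),
  everywhere.
* Positivity comparisons are inclusive (`≥`), both at cell level (OD
  threshold) and patient level (cut point).
* Watershed determinism: flood level = max energy along the path; plateau
  contests resolved by distance from the pixel to the claiming region's
  seed (splitting contested plateaus along the midline between seeds), then
  FIFO arrival order, then lexicographic pixel index. An earlier plain
  lexicographic plateau rule produced boundary drift of several pixels
  along shared membrane bands; the seed-distance rule removes it and is
  equally deterministic.
* Dice of two empty masks is 1.0; empty vs non-empty is 0.0. The surface
  distance metric is the *symmetric* average (ASSD): reported one-sided
  "asymmetric" variants differ between directions, and the symmetric mean
  is the standard choice.
* Saturated-black pixels clip at a configured maximum OD (default 300
  units); negative deconvolution coefficients (noise) clip at 0.
* Empirical p uses the add-one estimator; with m < 19 the resolution is
  coarser than 0.05 and the package warns.
* All randomness flows from explicit integer seeds; identical seed and
  configuration give byte-identical cohorts, bootstrap draws, splits and
  permutations.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale: cohorts of
48–151 patients with 50–1200 cells each, three rendered 256 µm ROIs
(≈ 290 cells) for the imaging round trip, cross-validation at n = 10–30
splits with m = 99 permutations, and 100–200 null cohorts for type-I
calibration. The full-fidelity n = 300 / m = 1200 schedule is available
through `cv_config()` unchanged.

## Known limitations

* **Exact cut recovery is limited by the flatness of the log-rank profile.**
  Moving a cut past one patient changes the log-rank χ² by O(1) while the
  statistic's sampling noise per candidate is also O(1), so even with a
  hazard ratio of 3 at 120 patients the optimal and modal cuts wander a
  patient or two around the planted boundary; the modal cut lands *exactly*
  on the boundary value (the only observed value inside the planted gap) in
  roughly a quarter to a third of simulated cohorts, and within one or two
  patients of it in most of the rest. This is a property of cut-point
  dichotomisation itself — the bootstrap mode stabilises but cannot
  sharpen a flat objective — and is the reason discovered cut points should
  be read as regions, not points.
* Membrane circumferentiality/completeness (used by manual guidelines) is
  not modelled in any score.
* The cSPS neighbourhood weighting is linear by definition; other kernels
  (e.g. exponential decay with the payload's diffusion length) would slot
  into the same normalised form but are not implemented.
* The consolidation result depends on the deterministic tie rules when
  correlations tie exactly; with continuous readouts this is rare but can
  occur with heavily tied rank data.
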