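---
title: "Prioritizing PFAS features in non-target HRMS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing PFAS features in non-target HRMS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorscreen)
```

## The screening problem

Per- and polyfluoroalkyl substances (PFAS) comprise thousands of industrial
chemicals built around CF~2~/CF~3~ moieties, most of which have no reference
standard. Non-target screening of high-resolution LC/GC-MS data therefore has
to prioritize: a complex environmental extract yields thousands of detected
features, of which only tens are plausibly fluorinated. `fluorscreen`
implements a filter-first workflow that stacks several independent lines of
evidence — carbon-normalized mass-defect filtering, Kendrick mass-defect
homologue detection, MS^2^ diagnostic-fragment and fragment-difference
matching, adduct-aware suspect screening, and elution-profile correlation —
so that the surviving shortlist is small enough for manual identification.

Every stage only *flags* features; nothing is deleted from the results
table. This keeps the funnel auditable and makes re-running the
prioritization with different cutoffs cheap (`reprioritize()` operates on
cached state and never re-reads the raw file).

## Feature detection and the carbon estimate

The feature finder is a deliberately transparent greedy EIC tracer, not a
port of a production peak picker: feature finding is treated as a swappable
front-end (external feature tables are accepted via `read_feature_csv()`),
so the goal is a correct, inspectable baseline rather than parity with any
particular algorithm. The most intense unclaimed centroid above the MS^1^
intensity threshold (default 2000 counts) seeds a trace extended across
adjacent scans within the mass tolerance (default 10 ppm, one missing scan
bridged). A trace is reported as a feature when

* its chromatographic FWHM (linear interpolation of the half-maximum
  crossings) lies between 1 s and 1 min,
* a coeluting M+1 isotopologue trace exists at +1.0033548 Da (the
  ^13^C–^12^C spacing), giving at least two isotope traces, and
* the M+1/M apex ratio lies within ±50% of the isotopologue expectation for
  the implied carbon count — a simple plausibility guard against accidental
  isobaric pairings.

Claimed centroids are never reused, so each chromatographic peak is reported
exactly once. The apex m/z is intensity-weighted over the trace; the area is
trapezoidal in counts × min.

The carbon number of a feature is estimated from the isotopologue ratio as

$$C \approx \frac{I_{M+1}/I_M}{0.011145},$$

using apex intensities. The divisor is the conventional per-carbon M+1
increment; the exact binomial envelope ratio is
$n_C\,a_{13}/a_{12} = n_C \times 0.010816$, about 3% lower, and heteroatoms
(S, N, O) add small positive contributions. The estimate is therefore a few
percent accurate at best, which is ample for carbon-normalized filtering; it
degrades with decreasing ion abundance. Features with $I_{M+1} = 0$ get
`NA` carbon estimates, are excluded from carbon-normalized filters, and are
listed with empty MD/C–m/C columns.

## Mass-defect filtering in the MD/C–m/C plane

The mass defect is computed with the nearest-integer convention,
$\mathrm{MD} = m - \mathrm{round}(m) \in (-0.5, +0.5]$. The wrap is the
point: saturated hydrocarbons accumulate +0.0078 Da per hydrogen, so above
roughly 60 carbons their true defect exceeds +0.5 Da and folds over to
negative MD — right into the region where fluorinated compounds (F
contributes −0.0016 Da) live. A plain MD window therefore misclassifies
heavy hydrocarbons.

Normalizing both axes by the estimated carbon number fixes this. In the
(m/C, MD/C) plane:

* pure CH~2~ compositions sit at m/C = 14 with positive MD/C; real
  hydrocarbon matrix spreads over m/C ≈ 10–25;
* fluorine-dominated compounds are pushed to high m/C (PFOA ≈ 51, 6:2 diPAP
  ≈ 49, even the H-rich 6:2 FTAB ≈ 38) with near-zero or negative MD/C;
* lightly fluorinated pharmaceuticals (fluoxetine, three F, m/C ≈ 18)
  correctly remain with the hydrocarbons — the separation sharpens with the
  fluorine fraction and cannot isolate single-CF~3~ compounds.

The default cutoffs keep features with **m/C > 30** and **MD/C < +0.003**;
each is individually optional. Both defaults are inherited from practice on
QTOF soil data, where they remove ~90% of matrix features; they should be
revisited per matrix by inspecting the plane first.

## Kendrick homologue detection

With a repeating unit R (default CF~2~; exact mass 49.996806, nominal 50),
the Kendrick mass is $KM = m \times 50 / 49.996806$ and the defect
$\mathrm{KMD} = \mathrm{round}(KM) - KM$. Members of a homologous series
share KMD up to measurement error. With this sign convention CH~2~-type
series carry small positive KMD; only within-series equality matters, not
the sign.

Two features are homologue candidates when their m/z difference is within
±2 mDa (default) of an *integer multiple* of the unit mass; series are
connected components of this relation with ≥ 3 members (default). Allowing
multiples > 1 means ladders with missing members are still linked, at the
cost that a bridging feature can merge two series. Retention time is
deliberately not used as a criterion; the systematic RT shift of a genuine
series is checked visually with `extract_series_eics()`. The series step
runs on the MD/C–m/C survivors, which empirically is what keeps the
false-series count manageable in complex matrices.

## MS^2^ evidence

Each feature receives at most one MS^2^ spectrum: among data-dependent scans
whose precursor is within 5 mDa and 0.2 min (defaults), the one with the
highest precursor intensity wins; a scan is given to its nearest-m/z feature
on conflict, ties broken by earlier scan.

Two matchers run on every assigned spectrum, considering only peaks at or
above the MS^2^ noise threshold (default 2000 counts; the single most
instrument-dependent parameter):

* **Diagnostic fragments.** Peaks are matched at ±2 mDa against a fragment
  list. The shipped starter list (~40 ions: the C~n~F~2n+1~^−^ series,
  sulfonate/phosphate head groups, ether fragments; positive-mode
  carbocation series) is generated from ion formulas at load time —
  electron-mass corrected, never hard-coded — and users can drop in larger
  literature collections via `read_fragment_csv()`.
* **Fragment mass differences.** All pairwise gaps between peaks are matched
  against characteristic differences (CF~2~, C~2~F~4~, HF, CF~2~O,
  C~2~F~4~O, HF+CO~2~, C~10~H~3~F~17~), detecting PFAS-typical ladders
  without knowing any fragment mass in advance.

Formula-bearing fragment matches then seed `propagate_formulas()`: an
unannotated peak at an annotated peak ± a listed difference inherits the
formula with the difference applied element-wise, iterated to a fixed point;
subtractions that would need negative element counts are rejected. No
multiple-testing control is applied beyond the filter-first design itself —
the point of filtering early is precisely that the later, looser matchers
see few candidates.

## Suspect screening

Suspect lists carry name, SMILES, formula, and neutral monoisotopic mass;
the mass is recomputed from the formula on load and >1 mDa mismatches are
warned about and corrected (corrupt public lists are common). Features are
matched at ±4 mDa (default) under the adducts [M−H]^−^ (negative mode) and
[M+H]^+^/[M]^+^ (positive mode; intact cations matter for betaines in AFFF
formulations). Adduct arithmetic is electron-correct: the proton mass
1.0072765 Da is used for (de)protonation and the electron mass 0.00054858 Da
for [M]^+^. All feature–suspect matches are reported; deduplication is left
to the analyst.

## EIC correlation of in-source families

In-source fragments and adducts share their parent's elution profile
exactly. `correlate_coeluting()` correlates the seed feature's EIC with
every feature apexing within ±25 s (default), over the shared MS^1^ grid
spanning the window, and keeps members with squared Pearson correlation
≥ 0.95 (default; r^2^ is scale-invariant, so relative ionization efficiency
does not matter). The extraction width of 5 mDa is a half-window (±5 mDa).
Candidate EICs with fewer than 5 nonzero points are treated as undefined and
excluded rather than reported as spurious zeros. Member mass offsets
matching a small built-in table (−HF, +HCl, +HBr, +CH~2~O~2~, +C~2~H~4~O~2~,
±CF~2~, ...) are labelled to speed up molecular-ion reasoning.

## The synthetic-data generator

`generate_run()` emulates, from exact formulas only, the data regimes every
stage must handle: Gaussian elution profiles on a uniform 0.5 s MS^1^ grid
over 0.5–8.5 min; M+1 (and M+2) traces at the true isotopologue envelope
ratio of each ion formula; two CF~2~-spaced perfluoroalkyl ladders (PFCA
C~4~–C~10~, PFSA C~4~–C~8~) with per-homologue RT increments; ~50
hydrocarbon-type matrix features; half of the matrix shared with a blank run
at comparable abundance; one four-member in-source family ([M−H]^−^,
[M−HF−H]^−^, [M+Cl]^−^, [M+Ac]^−^ on a shared profile); and ddMS^2^ scans
carrying C~n~F~2n+1~^−^ fragments plus an HF-spaced peak. Default noise (2
ppm m/z jitter, 5% multiplicative intensity noise) reflects a well-behaved
QTOF; the recovery contracts are asserted at zero noise, where every planted
quantity is exact.

Matrix compositions are drawn as C~c~H~h~O~o~ with ion m/C in [12.5, 25]:
pure C~c~H~h~ cannot exceed m/C ≈ 14, so oxygen is admitted to reproduce the
broader m/C 10–25 band real matrices show. Species are placed so that any
two are separated by ≥30 mDa or ≥0.3 min, and matrix features keep 45 s
clear of the in-source family — planted structures are meant to be
unambiguous, which is what makes exact-recovery assertions meaningful.

What the generator does **not** emulate — peak tailing, chemical noise,
ionization suppression, isotope-pattern distortion at low abundance,
co-isolated chimeric MS^2^ spectra — bounds what passing tests show about
real data: they certify the algorithms against their contracts, not
instrument robustness.

## Numerical choices and degenerate inputs

* Atomic monoisotopic masses (IUPAC, 6 decimals) live in one internal table;
  every mass in the package, including shipped fragment lists, derives from
  it.
* `round()` half-to-even can land a defect exactly on −0.5; it is folded to
  keep MD in (−0.5, +0.5].
* Isotope patterns are aggregated per nominal mass (no fine structure),
  with peaks spaced by the ^13^C gap — sufficient for carbon estimation and
  visual isotope checks.
* Blank correction compares integrated areas (not apex intensities) under
  the fivefold rule; it is idempotent and independent of blank-row order.
* MS^2^ assignment tie-breaks: highest precursor intensity, then nearest
  precursor m/z, then earlier scan.
* Empty inputs (no features, empty spectra, blank list empty) pass through
  with warnings rather than errors wherever the workflow can continue.
* Results CSVs render doubles with `formatC(..., format = "g", digits =
  10)`, making identical analyses byte-identical on disk.

## Problem sizes and runtime

The test suite and the acceptance script run the full synthetic scenario
(66 species, ~1000 MS^1^ scans, 13 ddMS^2^ scans, plus a blank) through the
entire pipeline in a few seconds on one core; the oracle-equivalence suite
uses 100 random spectra of up to ~200 peaks, and the carbon-recovery checks
use C ∈ {1..60} noise-free plus 1000 shot-noise replicates. These sizes were
chosen to exercise every code path with exact ground truth while keeping a
full check run fast enough to iterate on.

## Known limitations

* The MD/C–m/C filter cannot retain compounds whose fluorine fraction is
  small (one or two CF~3~ groups on a hydrocarbon skeleton).
* Carbon estimates — and everything normalized by them — inherit the ~3%
  bias of the 0.011145 convention plus heteroatom M+1 contributions.
* Homologue detection by connected components can merge distinct series
  through bridging features, and reports no RT-shift verification.
* One sample (plus optional blank) per run; cross-sample consensus and RT
  alignment are out of scope.
* Charge states other than ±1, isotope-labelled formulas, and fine isotope
  structure are unsupported.
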