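---
title: "Methods: qSIP enrichment estimation and DOM molecular analysis"
author: "qsipdom authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qSIP enrichment estimation and DOM molecular analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsipdom)
```

# Scope

`qsipdom` implements two quantitative chains used when coupling stable
isotope probing with dissolved organic matter (DOM) chemistry in marine
systems: (1) converting paired labeled/unlabeled CsCl density-gradient qPCR
profiles into an excess atom fraction (EAF) of ¹³C per marker gene, and
(2) turning negative-mode FT-ICR-MS peak lists into formula-assigned,
classified, comparable DOM samples. Both chains are backed by seeded
simulators with serialized ground truth, so the estimators can be validated
by round trips rather than by fixtures.

# The qSIP chain

## Model

DNA bands in a CsCl equilibrium gradient at a buoyant density set by its GC
content; incorporating ¹³C increases its mass and hence its density. A
gradient profile is summarized by the copy-weighted mean density
$W = \sum_i \rho_i y_i / \sum_i y_i$ over fractions with quantified copies.
From the unlabeled (control) profile the GC content is inferred by
inverting a linear GC–density calibration; GC then fixes the mean
per-nucleotide molecular weight of unlabeled DNA and the maximum weight
attainable at full ¹³C substitution (heavier at low GC, because AT pairs
carry more carbon-bound hydrogen per unit mass). The labeled profile's
density shift is attributed entirely to added mass,
$M_{lab} = M_{light} \cdot W_{lab}/W_{light}$, and

$$\mathrm{EAF} = \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}
  \,(1 - 0.01111233),$$

where 0.01111233 is the natural ¹³C abundance: a fully labeled molecule has
EAF $1 - 0.01111233 \approx 0.9889$, and EAF 0.3 means 30% of the carbon
atoms in the targeted gene are labeled (also reported as 30 atom %).

## Two calibrations, one switch

Two linear GC–density relations coexist in practice and are deliberately
*not* interchangeable:

* `"schildkraut"`: $\rho = 1.660 + 0.098\,GC$ — the classic relation, used
  for forward predictions of where a genome of known GC should band
  (`densityFromGC(0.315)` ≈ 1.69 g/mL).
* `"hungate"`: $W_{light} = 1.646057 + 0.083506\,G$ — the calibration
  embedded in the qSIP equation chain, inverted by `gcFromDensity()`.

`eafFromProfiles(calibration = )` defaults to `"hungate"` because the EAF
equations form a self-consistent system with that calibration; the
Schildkraut form remains available for sensitivity analysis. The forward
and inverse Hungate forms are mutual inverses to 1e-12; implied GC outside
[0, 1] by up to 0.05 is treated as measurement noise (clamped with a
warning), larger excursions are an error.

## Aggregation, guards, sign conventions

* Profiles need at least three quantified fractions (`minQuantified = 3`);
  one- or two-fraction "bands" give spuriously precise W values and are
  rejected. Fractions flagged below detection (control reactions with
  Cq > 35 define the floor) contribute zero copies.
* Pairing is one-to-one by replicate id, or `"mean-control"` (every labeled
  profile against the mean control density) for designs without replicate
  controls, as in water-column incubations.
* Per-pair EAFs are aggregated as mean ± SD. Negative EAFs are retained in
  the per-pair table — they diagnose noise levels — and clipped at zero
  only in the `mean_clipped` summary. An optional seeded bootstrap over
  replicate pairs (default 1000 resamples when enabled) gives a 95%
  interval on the mean.
* `quantifyFromCq()` converts Cq to copies through a standard curve that
  must have efficiency within 90–110% and $R^2 > 0.9$; W is invariant to
  any overall scaling of copies, so per-volume versus per-gram
  normalization does not affect EAF.

## The gradient simulator

`simulateGradientPair()` inverts the chain: GC fixes the unlabeled band
center, the true EAF fixes the labeled one, and copies per fraction are a
Gaussian band (the standard isoconcentration approximation for DNA in CsCl)
integrated over each fraction's density interval, scaled to the total
copies (conserved exactly before noising). Defaults are the study
conditions: 15 fractions spanning 1.66–1.78 g/mL around a 1.70 g/mL
starting density, and 20% CV multiplicative lognormal qPCR noise with unit
mean. The band width (0.006 g/mL) is not stated by gradient protocols and
is config-exposed; it was chosen so the band spans a handful of fractions,
as in published gradient qPCR profiles. What the simulator does *not*
emulate: gradient compression at the tube ends, diffusion between
fractionation and qPCR, multi-taxon mixtures within one marker, or
correlated pipetting error across fractions — so passing round trips
demonstrate estimator correctness under the banding model, not robustness
to every laboratory artifact.

With no noise and the default 15-fraction grid, recovery is within 0.005
of truth for EAF ∈ {0, 0.05, 0.3, 0.9} at GC ∈ {0.3, 0.5, 0.7} (the
residual is discretization bias of the binned band, largest when the band
sits near the span edge). With 20% CV noise, the mean over 100 seeded
simulations is within 0.02 of truth; a Monte-Carlo check put the bias at
≤ 0.0013 with a standard error of ≈ 0.0016, so that band is comfortable
rather than tuned.

# The DOM chain

## Formula assignment

Peaks are assumed singly charged deprotonated ions, $M = m/z + 1.00727646$;
multiply charged species and adducts are out of scope. `enumerateFormulas()`
searches C₁₋₁₀₀H₁₋₂₅₀O₁₋₁₀₀N₀₋₄S₀₋₂P₀₋₁ for masses within a ppm tolerance,
using exact isotope masses (¹²C = 12, ¹H = 1.00782503, ¹⁶O = 15.99491462,
¹⁴N = 14.00307401, ³²S = 31.97207069, ³¹P = 30.97376151). Chemical filters:
H ≤ 2C + 2 + N, and DBE $= 1 + C - H/2 + N/2 + P/2$ a non-negative integer,
which encodes the nitrogen rule for even-electron neutral molecules. The
search solves for the hydrogen count from the residual mass — valid because
any sensible ppm window is far narrower than one hydrogen mass — and the
test suite checks it against a brute-force enumerator that walks the whole
grid.

Defaults that are decisions, not reconstructions of any particular vendor
pipeline: tolerance 0.5 ppm (appropriate for a 15 T instrument after
internal calibration; config-exposed), oxygen-free formulas excluded
(`minOxygen = 1`, matching marine-DOM reporting; the enumerator reaches
them with `minOxygen = 0`), no isotopologue verification (no ¹³C satellite
peaks are modelled). The best candidate is the smallest absolute ppm error;
peaks with two or more candidates in tolerance are flagged ambiguous and
can be dropped. At zero mass error the true formula has error exactly zero
and is always the best candidate, which is why the 500-formula round trip
below 500 Da recovers 100% — uniqueness (one candidate in the window) is a
separate, measured property that degrades with mass.

## Calibration and detection limit

`internalCalibrate()` matches a list of known formulas (marine DOM
calibration lists typically carry > 100) within a coarse 3 ppm window, fits
a linear ppm-error-versus-m/z model, and removes it; least squares
guarantees the calibrants' RMS error never increases. Fewer than five
matches is a failed calibration: peaks pass through unchanged with a
warning and a `calibrated = FALSE` diagnostic. The detection limit is
relative — peaks below a stated fraction of the base-peak intensity are
removed — because a relative cut is comparable between samples of different
absolute signal; the threshold is config-exposed (default 0, i.e. off) as
published procedures differ in the exact value.

## Aromaticity and the nine classes

$\mathrm{AI_{mod}} = \dfrac{1 + C - 0.5\,O - S - 0.5\,(H + N + P)}
{C - 0.5\,O - S - N - P}$, clamped to 0 when the numerator is negative or
the denominator non-positive. Classification order: AI_mod > 0.5 is
aromatic (split by O/C at 0.5); else H/C < 1.5 is highly unsaturated
(split by O/C); else H/C ≤ 2 with N > 0 is "Unsaturated with N" (the
nitrogen condition takes precedence over the O/C split — these are the
degraded-peptide-like formulas); else H/C ≤ 2 is unsaturated (split by
O/C); else saturated (split by O/C). Boundary choices: AI_mod exactly 0.5
is non-aromatic (the aromatic rules are strict inequalities), O/C exactly
0.5 is O-poor (the O-poor rules use ≤). With these precedences the nine
rules partition the whole constraint space — a property-based sweep in the
tests confirms every formula receives exactly one class.

## Sample comparison

Relative intensities (per-sample normalization to a unit sum) are the
comparison currency. `domSet()` assembles samples into a
`SummarizedExperiment` subclass over the union of formulas, zeros for
absences (no imputation). Bray–Curtis
$\mathrm{BC}(j,k)=\sum|x_j-x_k| / \sum(x_j+x_k)$ is authored here and
verified against `vegan::vegdist` to 1e-12; a percent-scale view (×100) is
available since dissimilarities are often reported that way.
`principalCoordinates()` performs Gower double-centering
($B = -\tfrac12 J D^2 J$) and eigendecomposition; coordinates use positive
eigenvalues only, negatives are reported but uncorrected (no
Lingoes/Cailliez adjustment by default — for mildly non-Euclidean
Bray–Curtis matrices the leading axes are unaffected and the eigenvalue
table makes any negative mass visible). For Euclidean inputs the embedding
reconstructs pairwise distances to 1e-8 and recovers planar configurations
up to rotation/reflection.

Habitat grouping follows fixed depth/O₂/redox rules: surface ocean (5–10 m,
160–110 µM O₂), oxycline (50–95 m, 110–40 µM O₂), OMZ (95–125 m, < 60 µM
O₂), suboxic core top, sulfidic subseafloor (12–28 cm below seafloor).
Depth takes precedence where ranges meet — 95 m is assigned to the OMZ —
and metadata outside all ranges raise an error rather than being silently
binned.

## The spectrum and group simulators

`simulatePeakList()` samples distinct formulas from the constraint space
restricted to H/C 0.5–2.2 and O/C 0–1.2 (the occupied region of marine-DOM
van Krevelen space), applies Gaussian ppm error (default SD 0.2 ppm,
post-calibration scale) and lognormal intensities, and appends uniform
noise peaks carrying no truth formula. `simulateDomGroups()` models habitat
contrasts at the level the differences are reported: multiplicative
intensity shifts per compound class (default: "Unsaturated with N"
enriched threefold and "Highly unsaturated O-poor" halved in the sediment
group), shared formula pool, lognormal per-sample noise (sdlog 0.3),
renormalized rows. Neither simulator models mass-dependent sensitivity,
salt adducts, or peak-shape interference; round trips therefore validate
the assignment and ordination logic, not raw-spectrum processing (which is
out of scope — input begins at peak lists).

# Numerical and interface choices

* All simulators are pure functions of config + seed; identical seeds give
  identical outputs.
* Delimited text (CSV, header, "." decimal) is the universal exchange
  format; densities and EAFs are written to 4 decimals, ppm errors to 3.
* `runPipeline()` validates configurations strictly (unknown keys are
  rejected before any computation) and writes a provenance record (config
  echo, package version, seed) next to its outputs.
* Test problem sizes — 500-formula assignment round trips below 500 Da,
  100-seed noise recovery, 50k-formula classification sweeps, 10-point
  ordination recovery — were chosen as the smallest sizes at which the
  properties are meaningfully exercised; all are seeded and deterministic.

# Known limitations

Only ¹³C qSIP is implemented (no ¹⁸O/¹⁵N variants) and no per-OTU
partitioning of gradient profiles from amplicon relative abundances.
Formula assignment handles \[M−H\]⁻ monoisotopic peaks only — no charge
deconvolution, isotopic fine structure, or homologous-series filtering.
PCoA reports but does not correct negative eigenvalues. The habitat rules
encode one study system's ranges; other systems will need their own
boundaries.
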