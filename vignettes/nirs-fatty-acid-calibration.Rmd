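---
title: "Calibrating fatty-acid composition from NIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating fatty-acid composition from NIR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsfa)
```

This vignette is the package's account of its own science: the model and
its assumptions, the parameters that matter and why they default the way
they do, what the synthetic-data generator emulates and what it cannot, and
the design choices made where the underlying study left the design open.

## The measurement model

A freeze-dried, minced beef sample is scanned in reflectance; absorbance is
recorded as log(1/R) on a uniform wavelength grid, by default 1000–2500 nm
in 0.5 nm steps (3001 points; `wl_grid()`). Each sample is scanned twice
and the replicate scans are averaged arithmetically
(`average_replicates()`). The working assumption throughout is the linear
(Beer–Lambert-like) one: after suitable pre-treatment, absorbance at each
wavelength is approximately affine in the analyte concentrations, with
multiplicative and additive scatter effects from particle-size variation as
the dominant nuisance.

Two inconsistent grid conventions circulate for this instrument class — a
constant-wavenumber grid (10,000→4000 cm⁻¹ in 2 cm⁻¹ steps) and a
constant-wavelength grid (1000→2500 nm in 0.5 nm steps); they cannot both
be uniform. The package's canonical grid is constant-nm, because every
window and gap parameter of the pre-treatment catalog is expressed in grid
points on one uniform axis; wavenumber resampling is deliberately out of
scope.

## Pre-treatment operators

Operators compose in the stored chain order, which follows the conventional
column order of published model tables: baseline → normalization → scatter
correction → smoothing → derivative.

* **Offset** subtracts the per-spectrum minimum.
* **Area** divides by the per-spectrum L1 norm.
* **SNV** centres and scales each spectrum to unit standard deviation. The
  SD uses the sample (n−1) convention — the same convention the package's
  own unit-variance invariant is tested against.
* **Detrend** removes a least-squares quadratic in wavelength (the "D" of
  SNVD). Degree 2 is the standard SNV-detrend definition.
* **MSC / EMSC** regress each spectrum on a reference and invert the fitted
  affine (MSC) or affine-plus-quadratic-baseline (EMSC) distortion. The
  reference is the mean of the calibration spectra as pre-treated by the
  preceding chain steps; validation spectra never contribute to it. EMSC's
  polynomial terms use the wavelength mapped to [−1, 1] for conditioning.
* **Savitzky–Golay** derivatives (`SG-d-p-w`: derivative order, polynomial
  order, window in points) use local polynomial least squares via
  `signal::sgolayfilt`; edge points come from one-sided fits of the same
  local polynomial, so chains preserve grid length. Derivatives are scaled
  by the grid step, giving units of absorbance·nm⁻¹.
* **Norris gap** first derivatives (`NG-1-g`) are the symmetric difference
  across a gap of g points divided by 2·g·step; edge points replicate the
  nearest interior value. Window and gap parameters are interpreted as grid
  points, not nm — the published values are small odd integers typical of
  point counts.

Published model tables contain two irregular smoothing tokens (`SG1-1-1`,
`SG1-2-2`) in their *Smooth* column. The parser accepts the `SG1-p-w` form
as a zeroth-derivative smoothing pass with the stated polynomial order,
normalizing the window up to the smallest valid odd value, and flags the
step `low_confidence = TRUE`; with the normalized minimal windows these
steps are close to identity, which is consistent with their column being
"None" in almost every other row.

## NIPALS PLS and factor selection

`fit_pls()` implements NIPALS PLS1 on column-mean-centered spectra and
mean-centered response; no unit-variance scaling is applied to X, the
standard choice for absorbance spectra where the wavelength variance
structure is informative. With a single response the NIPALS weight
iteration converges on the first pass; the iteration cap (500) and
tolerance (1e-10 on the weight change) are retained as guards. Calibration
scores are mutually orthogonal, and the model is summarized by a
coefficient vector in the original wavelength space, so prediction is a
single inner product.

When the factor count is not imposed, `select_factors()` uses
venetian-blind k-fold cross-validation (default k = 10, blind assignment
seeded through a single shuffle): candidate counts 1…F_max are scored by
the squared correlation of pooled held-out predictions with y, and the
smallest count within one standard error (across folds) of the best is
chosen. Optimizing *calibration* R² alone is degenerate — it always prefers
more factors — which is why cross-validation stands in even though the
published models tuned on calibration fit; the published factor counts can
always be imposed verbatim via `model_configs()`. Inside cross-validation
loops the fit may truncate at the effective rank of a training fold
(`truncate_rank = TRUE`) so that probing F beyond the rank of a noiseless
system scores the rank-exhausted model instead of failing.

## Hotelling screening

`hotelling_h()` computes the score-space Hotelling statistic
H = Σₖ tₖ²/var(tₖ) with variances from the calibration scores, and
`remove_outliers_refit()` performs a single remove-and-refit pass at the
default cutoff H > 10 — one elimination event, not an iterated loop. Two
caveats are deliberate and documented rather than hidden. First, the exact
statistic behind the published workflow (score-space T² versus leverage) is
not stated anywhere; score-space T² is implemented and the threshold is
configurable. Second, the mean calibration H equals F·(n−1)/n, so a fixed
cutoff of 10 bites progressively harder as F grows: a 9-factor model flags
roughly a third of well-behaved Gaussian scores. Users running high-F
models should raise the threshold (or set it to `Inf`) consciously; the
packaged suite keeps the published value because it is part of the workflow
being emulated.

## Validation metrics

SEC uses n−F−1 degrees of freedom, charging the model for its factors. SEP
is the bias-corrected standard deviation of validation residuals, with
RMSEP available alongside (`rmsep()`); a pure bias therefore moves RMSEP
but not SEP. R² is the squared Pearson correlation of reference and
prediction — the scatter-plot definition. It is insensitive to scale and
sign of the predictions; a model with R²p = 1 and a constant offset is
"perfectly consistent but biased", which is exactly what the
SEP-versus-RMSEP split is there to reveal. RPD = SD/SEP uses the
*validation-set* SD: of the two candidate readings of "the standard
deviation of the laboratory", this is the one that reproduces the published
RPD values from the published SDs and SEPs. Consistency = 100·SEC/SEP;
values near 100% mean the model transfers, values far below 100% mean
over-fitting. The RPD class boundary is conventional: below 2, screening;
2 and above, analytical.

Two cells of the published performance tables are internally inconsistent:
the total-fraction 20:1 RPD (printed 1.8; SD/SEP of the printed values
gives 2.35) and the total-fraction 18:1c9 Consistency (printed 88.59;
100·SEC/SEP gives 89.02). Every other of the 96 RPD/Consistency cells
reproduces within 0.1/0.01, and all 96 CV cells reproduce within 0.05. The
reproduction tests assert exactly this, excluding the two discrepant cells
by name.

Fraction shares are computed on calibration-set means, which reproduces the
published share percentages (18.3% phospholipid for Total FA, 98.1% for
20:4n-6, and so on). A few published shares (74.1% PUFA, 9.9%/9.0% for the
18:1 isomers) do not match any ratio of the printed means; the package
reports table-mean ratios and does not guess at the original computation.

## The split and the pipeline

`random_split()` implements the literal published rule: one uniform draw
per sample, calibration iff u < 0.67. This is per-sample Bernoulli, not a
stratified allocation; a `strata` argument applies the same rule within
breeds for users who prefer the stratified reading. The expected
calibration fraction is 67% with binomial spread — the split sizes are not
fixed at 222/110. (The study's own abstract says 220 calibration samples
while its methods say 222; the methods count is treated as authoritative.)

`run_analyte()` wires the stages in a fixed order — split, fit chain on
calibration, transform both sets, fit PLS, Hotelling screen and single
refit, predict validation, report — and enforces the no-leakage discipline
throughout: nothing fitted ever sees a validation spectrum. The `n` column
of a report row is the number of calibration samples retained after
outlier removal, matching the varying per-analyte n of the published
report tables (up to the full calibration size). Whether outlier removal
preceded or followed factor selection in the original workflow is unknown;
here selection precedes removal, and both are configurable.

## Wavelength selection

`select_wavelengths()` retains wavelengths whose |coefficient| exceeds a
quantile, mirroring the published "selected according to the loadings and
regression coefficients, then tested" procedure. The "then tested" half is
where the design needed care. Judging the reduced set by pooled
cross-validated *correlation* is unsound: on a pure-noise response the
reduced model reliably looks better, partly because the selection leaks
information if the mask is derived from the full-data fit, and partly
because squared correlation rewards prediction variance rather than
accuracy. The implemented check therefore (a) re-derives the mask inside
every training fold, and (b) scores by predictive Q² = 1 − PRESS/SStot,
adopting the reduced set only when it beats the full set by a margin
(default 0.01) *and* is itself genuinely predictive (Q² > 0.2). Reducing
the wavelength set of a model with no predictive value is never reported
as an improvement. Selection is off by default — the published model table
does not record which models used it.

## What the synthetic generator emulates

`simulate_concentrations()` draws the 20 fatty acids for both lipid
fractions with lognormal marginals moment-matched to the published
calibration means and CVs. Lognormality is forced by the data: CVs up to
98% on a positive quantity rule out Gaussian marginals. A latent lognormal
"fatness" factor couples the neutral-lipid parts of all analytes through a
Gaussian copula (default correlation 0.93), while phospholipid parts
couple weakly (0.3): carcass fatness drives storage lipid, membrane lipid
stays comparatively constant. Totals are built constructively as
phospholipid + non-negative neutral draw, so phospholipid ≤ total holds
per analyte by construction, with the neutral marginal matched to the
difference of the fraction means and variances. Group sums are sums of
constituents — SFA includes the two aldehydes and PUFA includes CLA (the
published group rows are themselves inconsistent on CLA; chemically it is
a conjugated diene) — and TotalFA is the constituent sum divided by a
coverage of 0.93, because the 20 reported FAs carry ~93% of the total
fatty-acid mass in the published tables. With these defaults the emergent
TotalFA distribution lands within a few percent of the published mean and
CV at n = 2000, which the test suite asserts.

`simulate_spectra()` mixes concentrations into absorbance linearly: a
monotone baseline flat at 0.4 up to 1600 nm rising to 1.0 at 2500 nm (the
shape of freeze-dried beef spectra, water bands absent by construction),
stylized Gaussian band libraries per fatty acid — shared C–H bands near
1725/1765 and 2310/2348 nm plus class bands and one small analyte-specific
band, deliberately inducing the collinearity that makes minor FAs hard —
at 4·10⁻⁵ absorbance per mg/100 g, then per-scan multiplicative gain
(SD 0.1), additive offset (SD 0.02) and white noise (SD 0.005 absorbance).
Two scans per sample exercise replicate averaging.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: nonlinear detector and path-length effects,
wavelength-correlated instrument noise, temperature drift, band shapes
that shift with matrix composition, and any nonlinearity of the
concentration–absorbance relationship. The generator is nearly ideal for
the linear method that consumes it, so synthetic R²p values (≈0.99 for the
Total FA analog) sit far above anything achievable on real spectra
(published: 0.79). The synthetic benchmark demonstrates *recoverability* —
the pipeline finds structure the generator put in, with the qualitative
total-versus-phospholipid contrast reproduced (median synthetic R²p ≈ 0.7
for total-fraction models versus ≈ 0.05 for phospholipid models, mirroring
the published contrast) — not *attainable accuracy*.

## Numerical choices and degenerate inputs

* SNV and area normalization reject constant and all-zero spectra with
  explicit degenerate-input errors; MSC/EMSC reject |slope| < 1e-12.
* NIPALS stops with an error on a zero-variance response or an exhausted X
  residual (unless rank truncation was requested by a CV loop).
* CV percentages are undefined (NA) at zero mean; shares are NA at zero
  total; RPD and Consistency are errors at SEP ≤ 0. Negative
  neutral-by-difference values are clipped to zero with a warning.
* Spectra CSVs are written with `%.17g`, so a write/read round trip is
  bit-exact.
* Tie-breaks: factor selection resolves ties toward fewer factors (one-SE
  rule); the RPD class boundary at exactly 2 counts as analytical.

## Problem sizes used by the checks

The test suite and acceptance script use the study's own scale where the
check depends on it: the recovery benchmark runs n = 300 samples on the
full 3001-point grid with the stated noise levels, the full suite runs all
48 published configurations at n = 332, and distributional checks on the
generator use n = 2000 draws. Smaller grids (21–151 points) are used where
the property under test is grid-size-invariant (operator identities,
parser behavior, metric arithmetic).

## Known limitations

* The package reproduces the published *workflow*, not the published
  *numbers*: the original spectra and chromatography values are not
  public, so performance figures are only checkable on synthetic data.
* The Hotelling cutoff interacts with the factor count (see above).
* R² as squared correlation hides bias by construction; consult SEP vs
  RMSEP.
* The irregular smoothing tokens are interpreted, flagged, and close to
  identity; if the original software meant something else by them, those
  two models differ.
* Factor selection optimizes cross-validated fit; the published models
  optimized calibration fit with expert oversight. Imposing the published
  factor counts (as `run_suite()` does) sidesteps the difference.
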