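---
title: "Methods: cell-type-specific toxicity analysis for 3D midbrain organoid screens"
author: "organoidScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific toxicity analysis for 3D midbrain organoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidScreen)
```

# Scope and model of the assay

`organoidScreen` implements the analysis chain of a high-content toxicity
screen on 3D human midbrain organoids grown one per well of a 96-well plate.
Two readouts are modelled:

1. **ATP-luminescence viability.** Each well's luminescence (two 20-µl
   technical replicates in 3D mode, a single in-plate reading in 2D culture
   mode) is averaged and expressed as a percentage of the mean of the same
   plate's solvent-control (DMSO) wells. Normalizing per plate cancels any
   plate-level gain factor exactly, which the test suite asserts to machine
   precision.
2. **Cell-type-specific content from whole-mount immunofluorescence.**
   Cleared organoids are imaged in three channels — DAPI (nuclei), Map2-488
   (pan-neuronal), TH-647 (dopaminergic) — on several confocal planes spaced
   36.6 µm apart (three planes in the primary screen, five in dose-response
   panels). The image pipeline quantifies, per well, total organoid area and
   the integrated raw-channel brightness of gated TH+ and Map2+ ROIs.

Comparing the two normalized signals per compound separates *general*
neurotoxicity (both populations fall) from *dopaminergic-selective* toxicity
(TH falls more than Map2), the screen's scientific target.

# The image pipeline

Per plane and per well:

1. **Organoid region.** All channels are summed pixel-wise, a circular
   **median filter** (radius 10 px, mirror edges) removes dust-scale
   features, and a global Otsu threshold followed by hole filling and
   8-connected labelling yields candidate regions. Candidates carry area,
   chain-length perimeter, roundness `4*pi*A/P^2` (clamped to [0, 1], since
   digital perimeter estimates can push the ratio slightly above 1 for
   near-circular masks), and mean DAPI intensity measured on the **raw**
   nuclear channel (the vendor software does not document whether its DAPI
   statistic is computed pre- or post-filter; raw is the choice made here).
2. **Organoid gate.** A candidate is a bona fide organoid iff area
   > 9000 µm², roundness > 0.4 and mean DAPI > 190 abu — strict
   inequalities, exactly as printed, so boundary-equal values are rejected.
   The largest passing candidate is the organoid; dust specks and debris
   fail on area and DAPI.
3. **Background correction.** TH (647 nm): the image minus its Gaussian
   smooth (σ = 10 px), clipped at 0. Map2 (488 nm), primary mode: Gaussian
   subtraction with σ = 5 px followed by a **sliding-parabola top-hat**
   (curvature 10); dose-response mode: Gaussian subtraction with σ = 10 px
   and no parabola. Printed "px" filter sizes are interpreted as the median
   footprint *radius* and the Gaussian *standard deviation*; both are
   configurable because the vendor's unit conventions are unpublished.
4. **Cell ROIs.** Local maxima of the background-corrected (BC) image above
   a robust noise floor — `max(median + k*MAD, floor)` inside the organoid
   mask, k = 3, floor = 20 abu, minimum seed separation 4 px — seed an
   intensity-guided marker-based watershed (`EBImage::propagate`). Growth is
   restricted to mask pixels above a lower hysteresis floor
   (`max(median + 1*MAD, 8 abu)`) so a segment covers its cell's footprint
   without tiling the whole organoid. The vendor's "find cells, algorithm C"
   is proprietary; this re-specification is validated against generator
   ground truth (exact ROI counts on noise-free renders).
5. **Cell gates** (strict comparisons): primary TH+ — area > 25 µm² and mean
   BC brightness strictly between 200 and 2200 abu ("brightness" is read as
   the ROI's *mean* BC intensity; the dose-response variant explicitly names
   *maximum* brightness, implying the primary statistic is a different one,
   and mean is the conventional default). Primary Map2+ — area > 10 µm².
   Dose-response TH+ — area > 10 µm² and maximum brightness < 5000 abu.
6. **Integration.** The raw-channel (not BC) brightness of all selected ROIs
   is summed per plane and accumulated over planes and fields of view.

Per well, TH and Map2 sums are divided by the summed organoid area, then
expressed as a percentage of the mean of the plate's DMSO controls (area
normalization first, plate normalization second — the two steps are
described as sequential additions and are implemented in that order). QC
retains a well only if an organoid was found **and** both channels produced
at least one selected ROI ("signal present"); excluded wells are logged with
a reason and never silently dropped.

## The sliding parabola

Background is estimated as the grayscale opening of the image with a
paraboloid structuring element `z(r) = -r²/curvature`; subtracting it is a
top-hat that removes any structure smoother than the element while retaining
features whose curvature exceeds `2/curvature` (cell-scale blobs). The
mapping of the vendor's "curvature 10" to physical units is unknown; the
paraboloid parameterization above is declared, not derived, and the element
reproduces itself exactly (an image equal to a paraboloid cap comes back as
background to machine precision, a property the tests assert). The opening
is computed exactly in O(n) per row/column with the separable lower-envelope
algorithm for parabolic erosion/dilation.

# Dose-response model

Responses are fitted with the variable-slope four-parameter logistic on
log10 concentration,

    y = bottom + (top - bottom) / (1 + 10^((x - logIC50) * hill)),

so a **positive** Hill slope describes a response falling with dose from the
no-effect plateau `top`; `y(logIC50) = (top + bottom)/2` and
`IC50 = 10^logIC50` µM. Note the sign convention: the common plotting
software writes the exponent as `(logIC50 - x)*HillSlope` and fits falling
curves with negative slopes; the two forms describe identical curves with
`hill` negated, and this package standardizes on positive-slope = toxic so
that generator effects and fitted curves read the same way.

Solvent controls (0 µM) cannot be placed on a log axis; they are assigned
the log10 of the lowest tested concentration — x = −2 for the standard
series starting at 0.01 µM. All solvent replicates share that x. This
follows the published procedure exactly even though it slightly biases the
upper plateau; a regression test bounds the effect.

Fitting is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, no
parameter bounds by default, matching the plotting software's defaults) with
the initialization heuristic: top = max(y), bottom = min(y), logIC50 = the x
whose y is nearest the half-range, |hill| = 1 signed by the y-trend. If the
LM path cannot be initialized (rank-deficient Jacobian on degenerate
designs) a Nelder–Mead/BFGS fallback minimizes the same RSS. The convergence
flag is honest: constant responses and |hill| < 1e-6 are flagged
unidentifiable and `ic50()` refuses to report. Noise-free data generated
from the model are recovered to relative error below 1e-6, and at 5% CV
noise with 8 wells per dose the median |logIC50| error is well under 0.15
log units (both asserted in the acceptance tests).

# Screening statistics

One two-sided pooled-variance (Student) unpaired t-test per compound
(df = n₁ + n₂ − 2), assuming Gaussian distributions with equal SDs, in three
families: compound-vs-DMSO relative viability, per-compound TH-vs-Map2
relative signal, and per-concentration 2D-vs-3D viability (dose-response
panels test per concentration instead of per compound). The Bonferroni–Dunn
correction multiplies each raw p by the family size m and caps at 1 — which
is what the originating software's multiple-t-test tool computes under that
name — and significance means adjusted p < 0.05. m counts only the tests
actually performed: arms reduced below n = 2 by sample loss are marked
untestable and excluded from m, and lost wells reduce n rather than being
imputed. The suite verifies type-I calibration (0.05 ± 0.01 over 10,000
null pooled t-tests at n = 4/4), family-wise error control over 500
simulated 84-compound null screens sharing a 12-well control arm, and ≥ 90%
detection of a designed selective toxicant whose TH signal sits 5 noise SDs
below Map2 (8 wells per arm, the dose-response design; at the primary
screen's n = 3 a 5σ shift is not reliably detectable after an 84-fold
correction, which is precisely why the screen's dose-response follow-up
increases n).

# Sample-attrition survival emulation

Organoid loss during processing correlates with dose and is treated as an
indirect toxicity readout, emulated as a survival curve: remaining-sample
counts are averaged across compounds/cell lines/readouts on a common
concentration grid, rounded half-away-from-zero (the spreadsheet convention;
the tie rule is not documented in the original procedure and is declared
here), and mapped to integer x with the solvent control at x = 0 and each
concentration step incrementing x by 1. Every unit drop of the rounded count
is an event at that x (a drop of d is d events); a censoring entry one step
past the highest concentration carries the samples remaining. The step curve
starts at 1 and drops by multiplicity/initial count per event — verified
against `survival::survfit` as an independent Kaplan–Meier oracle. Counts
that *increase* along x are rejected rather than silently monotonized; the
end-to-end runner reports "no series" for single plates whose stochastic
loss produced non-monotone counts.

The canonical worked example — counts 8, 8, 8 then 7 from the third
concentration of the 9-step series onward — yields exactly one event at
x = 3 and censoring at x = 10.

# The synthetic generator

No imaging data are deposited for this assay, so the package ships a
generator that produces plates with the statistical structure the analysis
assumes, exporting per-well ground truth (true population counts, surviving
fractions, rendered foreground integrals, dust placements, plate gain, lost
flags) for oracle testing.

* **Geometry.** One spherical organoid per well, rendered per plane as a
  bright nuclear disc: radius ~ N(64, 2%) px at 1 µm/px (area ≈ 12,900 µm²,
  comfortably above the 9000 µm² gate; 2% radius CV gives the 4% size CV
  reported for control organoids), centre jittered ±6 px.
* **Cells.** "Cell" means a 2D Gaussian blob on one plane (σ = 2 px,
  lognormal per-cell brightness), since the assay quantifies per-plane ROIs,
  not 3D-reconstructed cells. Baselines: 45 TH+ (amplitude ~ LN(log 1600,
  0.12), minimum separation 10 px so noise-free renders are countable
  exactly) and 110 Map2+ (LN(log 1000, 0.12), separation 6 px) per well,
  assigned to planes uniformly. Amplitudes are set so primary TH+ ROIs fall
  inside the 200–2200 abu mean-BC window with margin.
* **Survival.** Per-compound 4PL effects (TH, Map2, viability) thin the
  baseline counts binomially: survivors ~ Binomial(n, f(dose)). Selective
  toxicants are encoded by logIC50(TH) < logIC50(Map2). The suite checks the
  thinning's mean and variance (χ² at α = 0.01, > 500 draws).
* **Backgrounds, dust, noise.** Per-channel base + smooth planar gradient
  (one random direction per well); dust specks 1–5 px at 2–3× background,
  placed only outside the organoid (margin 8 px) to exercise the gates'
  rejection branches — pipeline outputs are asserted invariant to them;
  pixel noise = signal-proportional Gaussian (2%) plus an additive floor
  (SD 3 abu), clipped at 0.
* **Luminescence.** reading = plate gain × per-cell signal × surviving
  cells × (1 + well effect, 2%) × (1 + replicate noise, 3%); the plate gain
  is lognormal (σ_log = 0.1) and cancels under plate normalization. The
  resulting control viability CV ≈ 3%, the published homogeneity of the
  assay.
* **Sample loss.** Bernoulli per well with a logistic-in-viability
  probability rescaled so p(1) = 0.05 exactly (> 90% retention under
  control conditions) and p(0) = 0.9. Only the qualitative dose–loss
  correlation is documented for the real system; the logistic form and its
  parameters are declared model choices.
* **Determinism.** Every well draws from an RNG substream seeded by a hash
  of (master seed, plate id, well), so outputs are pure functions of
  (config, effects, seed) and adding a well never perturbs its neighbours.

What the generator does **not** emulate: optical physics (PSF, clearing
artifacts, depth attenuation), 3D cell morphology, cross-plane identity of
cells, staining chemistry, or spatial biology within the organoid. Passing
tests therefore demonstrate that the *analysis* is correct and calibrated on
data satisfying its assumptions — not that those assumptions hold for any
particular real acquisition.

# Numerical and design choices

* Default pixel size is 1 µm/px so that printed µm² thresholds equal px²
  in synthetic data; it must be set explicitly for real acquisitions, whose
  pixel size the assay description does not state. Image files are 16-bit
  unsigned multi-page TIFFs, plane-major, with a JSON calibration sidecar.
* All background-subtraction results are clipped at 0 (intensities are
  non-negative by contract); exact channel-gain linearity of integrated sums
  is therefore bounded by the gain rather than exact, and the tests assert
  the bound.
* Integration accuracy: on noisy renders the integrated TH sum lands within
  5% of the generator's foreground-integral truth. The residual bias is
  dominated by the Gaussian BC's self-subtraction of the blob
  (σ_blob²/(σ_blob² + σ_smooth²) ≈ 4%) minus the background picked up under
  ROI pixels; the hysteresis region floor keeps lost tails small.
* Missing values are written as empty CSV fields, never 0; lost wells have
  no viability row at all (absence ≠ zero).
* Problem sizes in the test and acceptance suites are desk-scale — frames of
  192 px, 1 field of view per well, 3 planes (primary) or 5 (dose-response),
  a handful of compounds per simulated plate, with multi-plate statistics
  exercised at the table level — chosen so the whole suite runs in minutes
  while still covering every pipeline branch at the assay's native
  parameter values.

# Known limitations

* The re-specified "find image region"/"find cells" steps are validated
  against ground truth, not against the proprietary implementations; on real
  Operetta exports the gates' absolute abu thresholds would need
  recalibration to the instrument's intensity scale.
* The 4PL fit reports extrapolated IC50s when sample loss removes the lower
  plateau (as the real assay does at its highest doses); downstream users
  should check `isConverged()` and the fitted plateaus before citing an
  IC50, and QC exclusion of no-signal wells biases marker-channel logIC50
  estimates upward when an effect is near-complete.
* Replicate-correlation analysis (`replicateR2`) is provided as a summary
  statistic; no inter-plate bridging normalization is attempted.
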