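---
title: "Quantifying subcellular trace elements from quasi-correlative nano-XRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular trace elements from quasi-correlative nano-XRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoxrf)
```

## The measurement problem

Synchrotron X-ray fluorescence (XRF) nano-imaging of a thin (≈500 nm) tissue
section yields, per 25–50 nm pixel, an energy histogram whose K-line peak
areas are proportional to the areal mass of each element in that pixel. At
trace levels (Fe, Zn at a few to tens of ng/cm²) the per-pixel signal sits
near the detection limit, so per-pixel maps are too noisy to compare
organelles directly. The quasi-correlative strategy compensates in two ways:

1. **Ultrastructure from an adjacent section.** A serial 80-nm TEM section is
   imaged and compartments/organelles (nucleus, nucleolus, perinuclear rim,
   cytoplasm, mitochondria, RER, lipofuscin) are delineated by hand as label
   masks. A similarity transform estimated from fiducial landmarks (vessel
   boundaries, resin cracks) registers those masks onto the XRF grid.
2. **Sum-then-fit.** For each compartment, all pixel spectra under the mask
   are summed before fitting, which raises the signal-to-noise ratio roughly
   as the square root of the pixel count and pushes minimum detectable
   contrasts far below the per-pixel limit.

This package implements that pipeline end to end, and a synthetic neuron
phantom that stands in for beamline data, which are not publicly deposited.

## Contrast statistics

The elemental contrast of compartment $i$ against the nuclear reference $n$
is the relative count rate

$$\Delta_{i,n} = \frac{S_i/N_i - S_n/N_n}{S_n/N_n},\qquad
\sigma_{\Delta_{i,n}} = (\Delta_{i,n}+1)
\sqrt{\left(\frac{\sigma_{S_i}}{S_i}\right)^2 +
      \left(\frac{\sigma_{S_n}}{S_n}\right)^2},$$

where $S$ are summed counts, $N$ pixel counts, and $\sigma_S$ either the
fit uncertainty (when counts come from a spectral fit) or $\sqrt{S}$
(Poisson, when counts are raw integrated windows); the `sigma_source` field
of every `compartment_counts` record says which was used. The reference is
the nucleus *excluding* the nucleolus and the P-rich perinuclear rim
(`nuclear_reference_mask()`). Aggregation across neurons
(`aggregate_contrast()`) excludes measurements with
$\sigma_\Delta/|\Delta| \ge 30\%$ and reports a mean ± SD only for at least
triplicate survivors. The absolute value in the filter is a deliberate
choice: depletions (negative $\Delta$) are as meaningful as enrichments and
would otherwise always be excluded.

The spatially uniform Si signal of the Si₃N₄ support membrane acts as an
internal control: its compartment contrasts must be statistically
indistinguishable from zero, which the test suite checks on phantoms.

## Calibration to areal masses and concentrations

Counts convert to areal masses by comparison with a certified thin
multilayer standard measured on the same setup, with the membrane Si signal
as internal standard on both sides:

$$am_X = am_{\mathrm{Fe,std}}\cdot
\frac{f_{\mathrm{Fe}}}{f_X}\cdot\frac{t_{\mathrm{Si}}}{t_{\mathrm{Si,std}}}\cdot
\frac{S_X/S_{\mathrm{Si}}}{S_{\mathrm{Fe,std}}/S_{\mathrm{Si,std}}},
\qquad f_X = \frac{\sigma_X\,\xi_X}{A_X},$$

with $\sigma_X$ the K-fluorescence production cross-section at 17 keV,
$\xi_X$ the detector efficiency and $A_X$ the atomic mass. The uncertainty
$\varepsilon_X$ follows the same expression with the standard's certified
areal-mass uncertainty substituted, so the *relative* uncertainty is the
standard's and is the same for every element. Concentrations follow as
$c = am/(t\rho)$ in ppm, with defaults $t = 500$ nm and $\rho = 1$ g/cm³
for chemically fixed tissue.

Because no certificate for the real standard is public, the shipped
standard record and fundamental-parameter table
(`inst/extdata/synthetic_axo_standard.json`, `element_constants.json`) are
documented synthetic defaults. Every identity the pipeline relies on —
measuring the standard against itself returns its certified value exactly;
phantom areal masses round-trip through the inverse calibration — holds for
any consistent record, and those identities are what the tests assert.
Absolute accuracy against a particular beamline requires substituting that
instrument's characterization. The reference compartment table
(`reference_areal_masses()`) reports a constant relative uncertainty per
standard by construction of the formula above; published tables can show
per-element spreads when per-element fit uncertainties are folded in, which
this package does not model.

## Spectral model

The fitter (`fit_spectrum()`) is a deliberately simple, fully documented
stand-in for full-featured fundamental-parameter fitting engines. It solves
a weighted linear least-squares problem in which each element contributes a
single amplitude scaling a unit-area profile (Gaussian Kα plus a Kβ tied by
a fixed per-element branching ratio), with a shared width model

$$\mathrm{FWHM}(E) = \sqrt{\mathrm{noise}^2 + 2.355^2\,F\,w\,E},\quad
w = 3.85\ \mathrm{eV},\ F = 0.114,$$

and an affine continuum (or, by configuration, a SNIP-style iteratively
clipped baseline plus affine residual). Amplitudes are constrained
non-negative by an exact active-set step; $\sigma_S$ comes from the
covariance of the weighted solve. Escape peaks, pile-up, tailing and energy
recalibration are out of scope. Overlapping P/S/Ca triples separate cleanly
at a 100 eV noise term because their Kα lines are several peak sigmas
apart; truly coincident lines are rejected as a singular design rather than
silently apportioned.

Two weighting regimes matter:

* **Mask-sum spectra** (thousands of counts per channel) use Poisson
  weights $1/\max(y,1)$.
* **Per-pixel fits** default to unit weights: with a handful of counts per
  channel, weighting channels by their own observed counts biases
  amplitudes (the Neyman chi-square effect, ≈18% low for a 50-count peak in
  our tests), while the unit-weight solve is linear in the data and
  unbiased. `per_pixel_maps()` documents and defaults to this.

With unit weights, fitting the sum of spectra equals summing per-pixel
fits, which the suite asserts to numerical tolerance.

## Mask registration

`estimate_similarity()` solves the two-dimensional orthogonal Procrustes
problem (translation, rotation, positive scale; reflection excluded since
serial sections are same-handed) in closed form, and reports per-fiducial
residuals plus an rms that `check_alignment()` gates at 1 XRF pixel — the
registration uncertainty the correlative procedure assumes. Labels are
categorical, so `apply_transform()` resamples nearest-neighbor through the
inverse map; it can shrink or grow label areas only by boundary pixels,
never invent labels. The pixel convention everywhere is: origin top-left,
x = column, y = row, 0-based, centers on integers.

## Granule detection

Fe/S-rich granules are detected in XRF space only (TEM masks are used
afterwards for co-localization): per element, a threshold of
mean + k·SD (k = 2 by default) over *all* cytoplasm pixels — the stated
procedure has no exclusion step, and a one-iteration refinement that
recomputes statistics without first-pass granules sits behind
`refine = TRUE`, off by default. Pixels above either threshold, restricted
to the cytoplasm, form 8-connected components; components of ≥ 2 pixels
become granules. No hole filling and no watershed splitting: both would
silently alter the area statistics. Granules are summarized per condition
with a size split at 0.07 µm².

A quantitative caveat the package states openly: with a mean + 2·SD
per-pixel threshold, the chance that a pixel exceeds is ≈2.3% per element,
so an N-pixel cytoplasm contains ≈4N adjacent pixel pairs and an expected
≈4N·p² spurious two-pixel components per element (≈29 per phantom for a
4096-pixel cytoplasm with both channels). The minimum-size filter removes
singletons, not chance pairs. The corresponding acceptance check, which
expects a near-zero null rate, therefore fails by design of the detection
rule itself, and the measured null rate is reported by the acceptance
script (`granule_null_mean_count`). In practice the per-granule background
ratios of such chance components sit barely above 1 and they dilute, not
mimic, true enrichment; inserted granules at 5× background are recovered at
100% with areas faithful to within a perimeter of boundary pixels.

## The synthetic phantom

`generate_phantom()` renders a parametric neuron: elliptical cytoplasm in
neuropil, offset nucleus with a P-rich perinuclear annulus and a nucleolus,
and optional mitochondria/RER/lipofuscin profiles, each class carrying
expected counts per pixel per element; every pixel of every map is then an
independent Poisson draw, bit-reproducible for a fixed seed (placement and
noise use substreams derived from the one spec seed). Granules are S-core
disks with optional Fe-rich annuli, placed by rejection sampling without
overlap; rasterization is by center-of-pixel inclusion.

Defaults are anchored to measured conditions rather than convenience:

* The `"neuron-ctrl"` / `"neuron-asyn"` presets derive expected counts from
  the published compartment areal masses via the *inverse* of the
  calibration above (Si membrane fixed at 400 counts/pixel, Cl resin at 30),
  so phantom → pipeline round-trips exercise the whole calibration chain.
  Zn, absent from the published table, is set to 3 ng/cm² in the nucleus, a
  realistic trace level between Ca and Fe.
* The `"nucleolar-enrichment"` preset fixes nucleolar enrichments at the
  published average contrasts (P +66%, S +22.4%, Ca +53%, Fe +65%,
  Zn +47%) for recovery checks.
* Granule presets mirror the published condition contrast: control-like
  granules (radius 60–220 nm, S-rich cores, weak Fe rims) versus asyn-like
  granules (60–350 nm, strong Fe rims at 10× the cytoplasmic Fe rate, after
  the reported intense peripheral Fe signal). The preset granule count
  scales with grid area so the surface density matches the published counts
  (≈40 per control neuron) independently of the test grid size.

What the phantom deliberately does **not** emulate: self-absorption,
secondary fluorescence, detector escape/pile-up, scan-motion artifacts, and
non-Poisson detector noise. Passing tests therefore demonstrate the
statistical correctness of the estimators under the counting model, not
robustness to those instrumental effects. Background continuum levels of
the membrane/resin are not published; the defaults (`bg_flat = 0.2` counts
per channel, gently decreasing) are declared in `detector_model()` and are
config, not inference.

## Problem sizes and numerical choices

The test suite and acceptance script run phantoms of 64–160 pixels per side
(3–8 µm of tissue at 50 nm pitch), 200 replicates for coverage checks and
100 seeds for enrichment recovery — sizes chosen so the whole suite runs in
minutes while every Monte-Carlo assertion keeps at least 3-sigma binomial
headroom. Other numerical choices: per-element count rasters are stored as
16-bit integer TIFF (bit-exact round-trip, verified in tests); spectrum
stacks as one 16-bit page per channel with a JSON energy calibration;
coincident fit lines abort rather than regularize; zero-count compartments
yield a flagged $\Delta = -1$ with a missing uncertainty rather than a
fabricated one; and an all-coincident fiducial set is an error, not a fit.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_preset("neuron-ctrl", grid_shape = c(128, 128), seed = 7)
dir <- tempfile()
bundle <- simulate_bundle(spec, dir)
cfg <- run_config(maps_dir = dir,
                  mask_path = bundle$paths[["mask"]],
                  fiducials_path = bundle$paths[["fiducials"]],
                  out_dir = file.path(dir, "out"), seed = 7)
res <- run_full(cfg)
head(res$contrasts)
subset(res$quantities, compartment == "nucleus")
res$granule_summary
```

## Known limitations

* Equivalence with any particular published fitting software is not
  claimed; only the (S, σ_S) contract is honored.
* Absolute areal masses depend on the supplied standard/constants file; the
  shipped one is synthetic.
* Granule detection inherits the false-positive floor of the k-sigma rule
  discussed above; treat small two-to-three-pixel granules near the
  threshold accordingly, or enable the refinement pass.
* No significance testing across conditions is provided: with two neurons
  per condition the honest output is descriptive summaries, not p-values.
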