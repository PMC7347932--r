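# nanoxrf

Quantification of trace elements in subcellular compartments from
quasi-correlative nano-imaging: synchrotron X-ray fluorescence (XRF) maps of
a ~500 nm tissue section combined with compartment/organelle masks drawn on
TEM images of an adjacent serial section. The package is written for
analysts of scanning-XRF data of brain tissue (the motivating system is
dopaminergic neurons of the rat substantia nigra under α-synuclein
overexpression), but every stage is generic raster-and-spectrum machinery.

## What it computes

Given per-element count maps (or a full per-pixel spectrum stack), label
masks and fiducial landmarks, the pipeline:

1. **Fits K-lines.** Mask-summed spectra are deconvoluted by weighted linear
   least squares over Gaussian Kα lines with ratio-tied Kβ, a shared
   detector width model and an affine (or SNIP-clipped) background, giving
   summed counts `S` and uncertainty `σ_S` per element.
2. **Registers masks.** A closed-form similarity transform (translation,
   rotation, scale; no reflection) is estimated from fiducial pairs and
   gated at a 1-pixel rms residual; labels resample nearest-neighbor.
3. **Contrasts compartments** against the nuclear reference (nucleus minus
   nucleolus and perinuclear rim):

   `Δ_{i,n} = (S_i/N_i − S_n/N_n) / (S_n/N_n)`,
   `σ_Δ = (Δ+1)·sqrt((σ_Si/S_i)² + (σ_Sn/S_n)²)`,

   aggregating across neurons only for `σ_Δ/|Δ| < 30%` and at least
   triplicate survivors. The membrane Si signal serves as a null control.
4. **Calibrates to areal masses** (ng/cm²) against a thin multilayer
   standard with internal Si normalization,
   `am_X = am_Fe,std · (f_Fe/f_X) · (t_Si/t_Si,std) ·
   (S_X/S_Si)/(S_Fe,std/S_Si,std)` with `f = σ·ξ/A`, and to concentrations
   `c = am/(t·ρ)` in ppm (defaults: t = 500 nm, ρ = 1 g/cm³).
5. **Detects Fe/S-rich granules** in the cytoplasm by per-element
   mean + 2·SD thresholds, 8-connected components of ≥ 2 pixels, and
   summarizes per-granule composition (Fe/S mass ratio, background ratios,
   σ/mean) with a size split at 0.07 µm².

A synthetic neuron phantom (`generate_phantom()`, `phantom_preset()`)
reproduces the statistical structure of the real data — compartmented
geometry, published compartment areal masses inverted to expected counts,
Poisson shot noise, S-core/Fe-rim granules — so the full pipeline runs and
is tested without beamline data.

## Worked example

```r
library(nanoxrf)
spec <- phantom_preset("neuron-ctrl", grid_shape = c(128, 128), seed = 7)
dir <- tempfile()
bundle <- simulate_bundle(spec, dir)
cfg <- run_config(maps_dir = dir,
                  mask_path = bundle$paths[["mask"]],
                  fiducials_path = bundle$paths[["fiducials"]],
                  out_dir = file.path(dir, "out"), seed = 7)
res <- run_full(cfg)

head(subset(res$contrasts, element == "Fe"), 7)
#>    element     compartment reference    delta sigma_delta n_pixels included_flag
#> 29      Fe        neuropil   nucleus -0.30388      0.0129     8172          TRUE
#> 30      Fe       cytoplasm   nucleus -0.17718      0.0154     6379          TRUE
#> 31      Fe    mitochondria   nucleus -0.19719      0.0566       80          TRUE
#> 32      Fe             RER   nucleus -0.21086      0.0372      197          TRUE
#> 33      Fe      lipofuscin   nucleus  0.30192      0.0775       71          TRUE
#> 34      Fe perinuclear_rim   nucleus  0.00916      0.0348      331         FALSE
#> 35      Fe       nucleolus   nucleus  0.53522      0.0651      130          TRUE
```

Read: relative to the nuclear reference, this phantom neuron's nucleolus is
Fe-enriched (+54 ± 7%) and its cytoplasm Fe-depleted (−18 ± 2%); the
perinuclear-rim Fe contrast is excluded because its relative uncertainty
exceeds the 30% reporting rule (Δ is consistent with 0 there). The
lipofuscin enrichment (+30%) reflects the preset's 1.8× Fe rate.

```r
subset(res$quantities, compartment == "nucleus")
#>    compartment element n_px    s am_ng_cm2 eps_ng_cm2 eps_pct  c_ppm
#> 26     nucleus       P 1024 1672     76.96     10.236    13.3 1539.3
#> 27     nucleus       S 1024 2150     59.76      7.948    13.3 1195.2
#> 28     nucleus      Ca 1024  172      1.20      0.160    13.3   24.0
#> 29     nucleus      Fe 1024 3412      9.98      1.328    13.3  199.6
#> 30     nucleus      Zn 1024 1516      3.07      0.408    13.3   61.3
```

The recovered nuclear areal masses (P 77, S 59.8, Ca 1.20, Fe 9.98 ng/cm²)
round-trip the preset's target composition (79, 59.2, 1.2, 10) within
Poisson counting error, and the ppm column is `am × 20` at the 500-nm /
1 g/cm³ defaults. `res$granule_summary` and `out/granules.csv` carry the
per-granule records. A thin CLI over the same functions ships in
`inst/cli/nanoxrf.R` (subcommands `simulate`, `run-full`).

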