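#' Named phantom presets
#'
#' Ready-made [phantom_spec()]s whose expected counts per pixel are derived
#' from the reference compartment areal masses via the inverse of the
#' thin-film calibration, so a phantom -> pipeline round-trip exercises the
#' whole calibration chain. Presets:
#'
#' * `"neuron-ctrl"` — control-condition composition (reference neuron N1),
#'   control-like granules: mostly S-rich, radii 60-220 nm, ~40 per neuron.
#' * `"neuron-asyn"` — alpha-synuclein-overexpression composition, asyn-like
#'   granules: fewer but larger (60-350 nm) with strong Fe-rich rims.
#' * `"nucleolar-enrichment"` — nucleolar enrichments fixed at the published
#'   average contrasts (P +66%, S +22.4%, Ca +53%, Fe +65%, Zn +47%; cytoplasm
#'   P +41.5%, S +19.7%, Ca +97%), no granules; used for contrast-recovery
#'   checks.
#'
#' Zn is not part of the reference areal-mass table; its nuclear areal mass
#' is set to 3 ng/cm^2 (a realistic trace level between Ca and Fe). The Si
#' membrane contributes a spatially uniform `si_rate` everywhere and Cl (the
#' embedding resin) a uniform 30 counts/pixel.
#'
#' @param name preset name.
#' @param grid_shape,pixel_size_nm,seed passed to [phantom_spec()].
#' @param si_rate expected Si membrane counts per pixel.
#' @param std calibration standard used for the areal-mass -> rate inversion.
#' @param granules override the preset's granule population: a
#'   [granule_spec()], `NULL` to disable, or `"auto"` (default) for the
#'   preset population. The auto count scales with the grid area so the
#'   granule surface density is grid-independent.
#' @param organelles include organelle shapes in the geometry.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(name = c("neuron-ctrl", "neuron-asyn",
                                    "nucleolar-enrichment"),
                           grid_shape = c(256, 256), pixel_size_nm = 50,
                           seed = 1L, si_rate = 400,
                           std = calibration_standard(),
                           granules = "auto", organelles = TRUE) {
  name <- match.arg(name)
  ref <- reference_areal_masses()
  cond <- if (name == "neuron-asyn") "ASYN" else "CTRL"
  ref <- ref[ref$condition == cond & ref$neuron == "N1", ]
  am_of <- function(compartment) {
    rows <- ref[ref$compartment == compartment, ]
    am <- stats::setNames(rows$am_ng_cm2, rows$element)
    c(am, Zn = unname(3 * if (compartment == "nucleolus") 1.47 else 1))
  }
  rate_of <- function(am) {
    r <- rate_from_areal_mass(am, names(am), std, si_rate)
    stats::setNames(c(r, Si = si_rate, Cl = 30), c(names(am), "Si", "Cl"))
  }
  nuc <- am_of("nucleus")
  if (name == "nucleolar-enrichment") {
    nucleolus <- nuc * (1 + c(Fe = 0.65, Ca = 0.53, S = 0.224, P = 0.66,
                              Zn = 0.47)[names(nuc)])
    cytoplasm <- nuc * (1 + c(Fe = 0, Ca = 0.97, S = 0.197, P = 0.415,
                              Zn = 0)[names(nuc)])
  } else {
    nucleolus <- am_of("nucleolus")
    cytoplasm <- am_of("cytoplasm")
  }
  cyto_rate <- rate_of(cytoplasm)
  mult <- function(base, fac) {
    out <- base
    out[names(fac)] <- out[names(fac)] * fac
    out
  }
  composition <- list(
    neuropil = mult(cyto_rate, c(P = 0.6, S = 1.3, Fe = 0.9)),
    cytoplasm = cyto_rate,
    nucleus = rate_of(nuc),
    perinuclear_rim = mult(rate_of(nuc), c(P = 1.9)),
    nucleolus = rate_of(nucleolus),
    mitochondria = mult(cyto_rate, c(P = 1.1, S = 1.1, Ca = 1.3)),
    RER = mult(cyto_rate, c(P = 1.5, Ca = 1.6)),
    lipofuscin = mult(cyto_rate, c(Ca = 1.8, Fe = 1.8))
  )
  if (identical(granules, "auto")) {
    granules <- if (name == "nucleolar-enrichment") NULL else {
      fe_bg <- cyto_rate[["Fe"]]
      s_bg <- cyto_rate[["S"]]
      density_scale <- prod(grid_shape) / 256^2
      if (name == "neuron-ctrl") {
        granule_spec(n = max(1, round(40 * density_scale)),
                     radius_nm = c(60, 220),
                     core_rates = c(S = 1.5 * s_bg, Fe = 0.5 * fe_bg),
                     rim_rates = c(Fe = 1.5 * fe_bg),
                     rim_width_nm = 1.2 * pixel_size_nm)
      } else {
        granule_spec(n = max(1, round(30 * density_scale)),
                     radius_nm = c(60, 350),
                     core_rates = c(S = 1.0 * s_bg),
                     rim_rates = c(Fe = 10 * fe_bg),
                     rim_width_nm = 1.6 * pixel_size_nm)
      }
    }
  }
  phantom_spec(grid_shape = grid_shape, pixel_size_nm = pixel_size_nm,
               compartments = phantom_geometry(grid_shape, organelles),
               composition = composition, granules = granules, seed = seed)
}
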