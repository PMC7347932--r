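#' Element fundamental-parameter constants
#'
#' Loads the per-element constants used by the thin-film calibration: the
#' K-fluorescence production cross-section `sigma` (cm^2/g at 17 keV), the
#' detector efficiency `xi`, and the atomic mass `A` (g/mol), and derives the
#' total fundamental-parameter correction `f = sigma * xi / A`. The shipped
#' default table is a documented synthetic instrument characterization (see
#' the JSON file's comment); supply your own file for absolute work.
#'
#' @param path JSON file; defaults to the table shipped with the package.
#' @return data.frame with columns `element`, `sigma_cm2_g`, `xi`, `A_g_mol`,
#'   `f`.
#' @export
element_constants <- function(path = system.file("extdata",
                                                 "element_constants.json",
                                                 package = "nanoxrf")) {
  raw <- jsonlite::fromJSON(path)
  tab <- as.data.frame(raw$elements)
  stopifnot(all(tab$sigma_cm2_g > 0), all(tab$xi > 0 & tab$xi <= 1),
            all(tab$A_g_mol > 0))
  tab$f <- tab$sigma_cm2_g * tab$xi / tab$A_g_mol
  tab
}

#' Thin multilayer calibration standard record
#'
#' The calibration compares the sample's `S_X / S_Si` count-rate ratio with
#' the same ratio measured on a certified thin multilayer standard of known
#' Fe areal mass, the Si signal of the Si3N4 support window serving as
#' internal standard on both. The shipped record is synthetic (no certificate
#' is public); all identities used by the pipeline hold for any consistent
#' record.
#'
#' @param path JSON file; defaults to the synthetic record shipped with the
#'   package.
#' @param constants element constants table from [element_constants()].
#' @return An object of class `calibration_standard`: the certificate fields
#'   plus the `f` table.
#' @export
calibration_standard <- function(path = system.file("extdata",
                                                    "synthetic_axo_standard.json",
                                                    package = "nanoxrf"),
                                 constants = element_constants()) {
  raw <- jsonlite::fromJSON(path)
  std <- list(
    am_fe_axo = raw$am_fe_axo_ng_cm2,
    eps_fe_axo = raw$eps_fe_axo_ng_cm2,
    s_fe_axo = raw$s_fe_axo,
    s_si_axo = raw$s_si_axo,
    t_si = raw$t_si_cm,
    t_si_axo = raw$t_si_axo_cm,
    constants = constants
  )
  with(std, stopifnot(am_fe_axo > 0, eps_fe_axo > 0, s_fe_axo > 0,
                      s_si_axo > 0, t_si > 0, t_si_axo > 0))
  class(std) <- "calibration_standard"
  std
}

#' @export
print.calibration_standard <- function(x, ...) {
  cat("<calibration_standard> am_Fe = ", x$am_fe_axo, " ng/cm2 (eps ",
      x$eps_fe_axo, "), S_Fe/S_Si = ",
      signif(x$s_fe_axo / x$s_si_axo, 4), ", ",
      nrow(x$constants), " elements in f table\n", sep = "")
  invisible(x)
}

f_of <- function(std, element) {
  i <- match(element, std$constants$element)
  if (any(is.na(i))) {
    stop("element(s) not in fundamental-parameter table: ",
         paste(element[is.na(i)], collapse = ", "))
  }
  std$constants$f[i]
}

#' Areal mass from count rates (thin-film semi-quantitative calibration)
#'
#' Converts summed counts of element `X` to an areal mass in ng/cm^2 by
#' comparison with the standard:
#' `am_X = am_Fe,std * (f_Fe/f_X) * (t_Si/t_Si,std) *
#'  (S_X/S_Si) / (S_Fe,std/S_Si,std)`,
#' with `f = sigma * xi / A`. The uncertainty `eps_X` follows the same
#' formula with the standard's certified areal-mass uncertainty in place of
#' its areal mass, so the relative uncertainty is the standard's and is
#' identical for every element.
#'
#' @param s_x summed counts of element X in the region (vectorized).
#' @param s_si summed Si counts of the same region (internal standard;
#'   scalar or same length).
#' @param std a [calibration_standard()].
#' @param element element symbol(s), recycled against `s_x`.
#' @return data.frame with columns `element`, `am` (ng/cm^2), `eps`
#'   (ng/cm^2), `eps_rel` (eps/am, constant).
#' @export
areal_mass <- function(s_x, s_si, std, element) {
  stopifnot(inherits(std, "calibration_standard"))
  if (any(s_si <= 0)) stop("internal Si standard absent (S_Si must be > 0)")
  if (any(s_x < 0)) stop("counts must be >= 0")
  n <- max(length(s_x), length(element))
  s_x <- rep_len(s_x, n); element <- rep_len(element, n)
  s_si <- rep_len(s_si, n)
  f_x <- f_of(std, element)
  f_fe <- f_of(std, "Fe")
  scale <- (f_fe / f_x) * (std$t_si / std$t_si_axo) *
    (s_x / s_si) / (std$s_fe_axo / std$s_si_axo)
  data.frame(element = element,
             am = std$am_fe_axo * scale,
             eps = std$eps_fe_axo * scale,
             eps_rel = std$eps_fe_axo / std$am_fe_axo)
}

#' Areal mass to concentration in ppm
#'
#' `c = am / (t * rho)`, expressed as mass fraction x 1e6 (ppm). Defaults
#' correspond to a 500 nm section of chemically fixed tissue with density
#' taken as 1 g/cm^3.
#'
#' @param am areal mass in ng/cm^2 (vectorized).
#' @param t_cm section thickness in cm (default 5e-5, i.e. 500 nm).
#' @param rho_g_cm3 section density in g/cm^3 (default 1).
#' @return concentration(s) in ppm.
#' @export
to_ppm <- function(am, t_cm = 5e-5, rho_g_cm3 = 1) {
  if (t_cm <= 0) stop("section thickness must be > 0")
  if (rho_g_cm3 <= 0) stop("density must be > 0")
  if (any(am < 0)) stop("areal mass must be >= 0")
  # ng/cm^2 -> g/cm^2 (1e-9), / (g/cm^2) -> mass fraction, x 1e6 -> ppm
  am * 1e-9 / (t_cm * rho_g_cm3) * 1e6
}

#' Expected counts per pixel for a target areal mass (calibration inverse)
#'
#' Inverts the areal-mass calibration: given a target areal mass and a Si
#' membrane count rate per pixel, returns the expected element counts per
#' pixel that the calibration would map back to that areal mass. Used by the
#' phantom generator so phantom -> pipeline round-trips exercise the full
#' calibration chain.
#'
#' @param am target areal mass, ng/cm^2.
#' @param element element symbol(s).
#' @param std a [calibration_standard()].
#' @param si_rate expected Si counts per pixel of the membrane.
#' @return expected counts per pixel (same length as `am`).
#' @export
rate_from_areal_mass <- function(am, element, std, si_rate) {
  stopifnot(inherits(std, "calibration_standard"), si_rate > 0, all(am >= 0))
  f_x <- f_of(std, element)
  f_fe <- f_of(std, "Fe")
  (am / std$am_fe_axo) * (f_x / f_fe) * (std$t_si_axo / std$t_si) *
    (std$s_fe_axo / std$s_si_axo) * si_rate
}

#' Background areal masses in the cytoplasm outside detected granules
#'
#' Applies the thin-film calibration to the summed counts of the cytoplasm
#' with granule pixels removed — the background (BGD) reference against
#' which per-granule enrichments are expressed.
#'
#' @param maps named list of `element_map`s; must include `"Si"` for the
#'   internal standard.
#' @param cytoplasm logical matrix of cytoplasm pixels (or a `region_mask`
#'   with a `cytoplasm` class).
#' @param granule_labels optional integer matrix of granule labels (0 =
#'   background) to exclude; NULL excludes nothing.
#' @param std a [calibration_standard()].
#' @return data.frame (one row per non-Si element): `element`, `s`, `am`,
#'   `eps`, `mean_counts` (per pixel), `n_px`.
#' @export
granule_background_quant <- function(maps, cytoplasm, granule_labels = NULL,
                                     std = calibration_standard()) {
  if (inherits(cytoplasm, "region_mask")) {
    cytoplasm <- mask_binary(cytoplasm, "cytoplasm")
  }
  bg <- cytoplasm
  if (!is.null(granule_labels)) bg <- bg & (granule_labels == 0L)
  if (!any(bg)) stop("empty background region")
  if (!"Si" %in% names(maps)) stop("internal Si standard absent (no Si map)")
  s_si <- sum(maps[["Si"]]$counts[bg], na.rm = TRUE)
  els <- setdiff(names(maps), "Si")
  s <- vapply(els, function(e) sum(maps[[e]]$counts[bg], na.rm = TRUE),
              numeric(1))
  q <- areal_mass(s, s_si, std, els)
  data.frame(element = els, s = s, am = q$am, eps = q$eps,
             mean_counts = s / sum(bg), n_px = sum(bg),
             row.names = NULL)
}

#' Reference compartment areal masses
#'
#' Published compartment-level areal masses (ng/cm^2), concentrations (ppm)
#' and relative uncertainties (%) of Fe, Ca, S and P in the nucleus,
#' nucleolus, cytoplasm and pooled Fe/S granules of dopaminergic neuron
#' bodies in rat substantia nigra, for the control and the
#' alpha-synuclein-overexpressing condition (two neurons each). Used as the
#' realistic composition scale of the synthetic phantom and as the input of
#' the ppm-conversion consistency checks.
#'
#' @return data.frame with columns `condition`, `neuron`, `element`,
#'   `compartment`, `am_ng_cm2`, `c_ppm`, `eps_pct`.
#' @export
reference_areal_masses <- function() {
  utils::read.csv(system.file("extdata", "compartment_areal_masses.csv",
                              package = "nanoxrf"),
                  stringsAsFactors = FALSE)
}
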