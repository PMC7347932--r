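#' K-line emission energies and branching ratios
#'
#' Tabulated Ka/Kb energies (keV) and Kb/Ka intensity ratios for the elements
#' handled by the fitter. Values are standard X-ray data-booklet numbers for a
#' Si drift detector geometry; the Kb/Ka ratio ties the Kb amplitude to the Ka
#' amplitude so each element contributes a single free parameter to the fit.
#'
#' @return A data.frame with columns `element`, `ka_kev`, `kb_kev`,
#'   `kb_ka_ratio`.
#' @export
xrf_lines <- function() {
  data.frame(
    element     = c("Si",    "P",     "S",     "Cl",    "K",     "Ca",    "Fe",    "Zn"),
    ka_kev      = c(1.740,   2.014,   2.307,   2.622,   3.312,   3.691,   6.404,   8.639),
    kb_kev      = c(1.836,   2.139,   2.464,   2.816,   3.590,   4.013,   7.058,   9.572),
    kb_ka_ratio = c(0.020,   0.030,   0.050,   0.080,   0.110,   0.128,   0.134,   0.138),
    stringsAsFactors = FALSE
  )
}

#' Detector response model for K-line fitting
#'
#' Describes the energy axis, peak-width model and background model used both
#' to render synthetic spectra and to fit measured ones. The peak FWHM follows
#' the usual Si-detector form
#' `FWHM(E) = sqrt(noise^2 + 2.355^2 * fano * w * E)` with the electron-hole
#' pair energy `w = 3.85e-3` keV.
#'
#' @param elements character vector of element symbols the model must cover.
#' @param n_channels number of energy channels.
#' @param gain_kev energy gain in keV/channel (> 0).
#' @param offset_kev energy of channel 1 minus one gain step, in keV.
#' @param noise_fwhm_kev electronic noise FWHM at 0 keV, in keV.
#' @param fano Fano factor (dimensionless).
#' @param background background model: `"linear"` (default) fits an affine
#'   continuum over the spectrum; `"snip"` subtracts an iteratively clipped
#'   baseline before a linear residual term.
#' @param bg_flat,bg_slope continuum used when *rendering* synthetic spectra:
#'   expected background counts per channel are
#'   `bg_flat + bg_slope * (E - E_mid)`, clipped at zero.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(elements = c("Si", "P", "S", "Cl", "Ca", "Fe", "Zn"),
                           n_channels = 1024L,
                           gain_kev = 0.01,
                           offset_kev = 0,
                           noise_fwhm_kev = 0.10,
                           fano = 0.114,
                           background = c("linear", "snip"),
                           bg_flat = 0.2,
                           bg_slope = -0.01) {
  background <- match.arg(background)
  stopifnot(gain_kev > 0, n_channels >= 2, noise_fwhm_kev > 0, fano > 0)
  lines <- xrf_lines()
  missing <- setdiff(elements, lines$element)
  if (length(missing) > 0) {
    stop("no tabulated K-line energy for element(s): ",
         paste(missing, collapse = ", "))
  }
  lines <- lines[lines$element %in% elements, , drop = FALSE]
  e_max <- offset_kev + n_channels * gain_kev
  if (any(lines$kb_kev >= e_max)) {
    bad <- lines$element[lines$kb_kev >= e_max]
    stop("K lines of ", paste(bad, collapse = ", "),
         " fall outside the calibrated energy range (max ", e_max, " keV)")
  }
  structure(list(
    lines = lines,
    n_channels = as.integer(n_channels),
    gain_kev = gain_kev,
    offset_kev = offset_kev,
    noise_fwhm_kev = noise_fwhm_kev,
    fano = fano,
    background = background,
    bg_flat = bg_flat,
    bg_slope = bg_slope
  ), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model> ", nrow(x$lines), " elements, ",
      x$n_channels, " channels @ ", x$gain_kev * 1e3, " eV/ch, ",
      "background: ", x$background, "\n", sep = "")
  invisible(x)
}

# channel-center energies in keV
channel_energies <- function(detector) {
  detector$offset_kev + detector$gain_kev * (seq_len(detector$n_channels) - 0.5)
}

# Gaussian sigma (keV) at energy E
peak_sigma <- function(detector, e_kev) {
  fwhm <- sqrt(detector$noise_fwhm_kev^2 +
                 2.355^2 * detector$fano * 3.85e-3 * e_kev)
  fwhm / 2.355
}

# Unit-area (one count total) K-line profile of one element over all
# channels: Ka Gaussian plus ratio-tied Kb Gaussian, normalized so the
# channel sum is 1. Amplitudes in the fit are therefore total line counts.
element_profile <- function(detector, element) {
  ln <- detector$lines[detector$lines$element == element, , drop = FALSE]
  if (nrow(ln) == 0) stop("element not in detector model: ", element)
  e <- channel_energies(detector)
  g <- detector$gain_kev
  ka <- stats::dnorm(e, ln$ka_kev, peak_sigma(detector, ln$ka_kev)) * g
  kb <- stats::dnorm(e, ln$kb_kev, peak_sigma(detector, ln$kb_kev)) * g
  p <- (ka + ln$kb_ka_ratio * kb) / (1 + ln$kb_ka_ratio)
  p / sum(p)
}
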