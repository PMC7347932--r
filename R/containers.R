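#' Per-element fitted-count raster
#'
#' A single-element count map on a stated pixel grid. `counts` holds fitted or
#' raw K-line counts per pixel; `sigma`, when present, holds the per-pixel
#' count uncertainty (for raw integrated counts this is `sqrt(counts)`,
#' Poisson).
#'
#' @param counts numeric matrix (rows x cols) of non-negative counts; NA marks
#'   pixels whose per-pixel fit failed.
#' @param element element symbol (e.g. "Fe").
#' @param pixel_size_nm pixel pitch in nm (> 0).
#' @param sigma optional matrix of per-pixel uncertainties, same shape.
#' @return An object of class `element_map`.
#' @export
element_map <- function(counts, element, pixel_size_nm, sigma = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), pixel_size_nm > 0, is.character(element))
  if (any(counts < 0, na.rm = TRUE)) stop("element_map counts must be >= 0")
  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    stopifnot(identical(dim(sigma), dim(counts)))
  }
  structure(list(counts = counts, element = element,
                 pixel_size_nm = pixel_size_nm, sigma = sigma),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat("<element_map> ", x$element, ": ", nrow(x$counts), "x", ncol(x$counts),
      " px @ ", x$pixel_size_nm, " nm, total ",
      format(sum(x$counts, na.rm = TRUE), big.mark = ","), " counts\n",
      sep = "")
  invisible(x)
}

#' Labeled compartment/organelle mask
#'
#' A label raster in which each pixel carries one non-negative integer label;
#' 0 is background. `class_table` names each positive label with a compartment
#' or organelle class (nucleus, nucleolus, perinuclear_rim, cytoplasm,
#' neuropil, mitochondria, RER, lipofuscin, granule).
#'
#' Pixel convention used throughout the package: pixel centers at integer
#' coordinates, origin at top-left, x = column, y = row, 0-based.
#'
#' @param labels integer matrix of labels (>= 0).
#' @param class_table named integer vector or named list mapping class name ->
#'   label, or a character vector indexed by label. Internally stored as a
#'   named integer vector `class name -> label`.
#' @param pixel_size_nm pixel pitch in nm.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, class_table, pixel_size_nm) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(pixel_size_nm > 0)
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be >= 0")
  ct <- unlist(class_table)
  storage.mode(ct) <- "integer"
  if (is.null(names(ct)) || any(names(ct) == "")) {
    stop("class_table must map class names to labels")
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, ct)
  if (length(unknown) > 0) {
    stop("labels present in raster but absent from class_table: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(labels = labels, class_table = ct,
                 pixel_size_nm = pixel_size_nm),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  n <- vapply(x$class_table, function(l) sum(x$labels == l), integer(1))
  cat("<region_mask> ", nrow(x$labels), "x", ncol(x$labels), " px @ ",
      x$pixel_size_nm, " nm\n", sep = "")
  for (i in seq_along(n)) {
    cat(sprintf("  %-16s label %d: %d px\n",
                names(x$class_table)[i], x$class_table[i], n[i]))
  }
  invisible(x)
}

#' Logical pixel mask for one class of a region mask
#'
#' @param mask a `region_mask`.
#' @param class class name present in the mask's class table.
#' @return logical matrix, TRUE where the raster carries that class.
#' @export
mask_binary <- function(mask, class) {
  stopifnot(inherits(mask, "region_mask"))
  if (!class %in% names(mask$class_table)) {
    stop("class not in mask class table: ", class)
  }
  mask$labels == mask$class_table[[class]]
}

#' Nuclear reference mask
#'
#' The reference compartment for contrast calculations is the nucleus
#' excluding the nucleolus and the P-rich perinuclear rim; this helper
#' subtracts those classes (when present) from the nucleus pixels.
#'
#' @param mask a `region_mask` containing a `nucleus` class.
#' @return logical matrix of reference-nucleus pixels.
#' @export
nuclear_reference_mask <- function(mask) {
  ref <- mask_binary(mask, "nucleus")
  for (cl in c("nucleolus", "perinuclear_rim")) {
    if (cl %in% names(mask$class_table)) ref <- ref & !mask_binary(mask, cl)
  }
  ref
}

#' Per-pixel energy-histogram stack
#'
#' @param counts 3-D integer array `[rows, cols, channels]` of non-negative
#'   counts.
#' @param offset_kev,gain_kev linear energy calibration: channel `k` spans
#'   `offset + (k-1)*gain` to `offset + k*gain` keV.
#' @param live_time_s live time per pixel, seconds.
#' @param pixel_size_nm pixel pitch in nm.
#' @return An object of class `spectrum_stack`.
#' @export
spectrum_stack <- function(counts, offset_kev = 0, gain_kev = 0.01,
                           live_time_s = 0.05, pixel_size_nm = 50) {
  stopifnot(length(dim(counts)) == 3, gain_kev > 0, dim(counts)[3] >= 2)
  if (any(counts < 0)) stop("spectrum counts must be >= 0")
  structure(list(counts = counts, offset_kev = offset_kev,
                 gain_kev = gain_kev, live_time_s = live_time_s,
                 pixel_size_nm = pixel_size_nm),
            class = "spectrum_stack")
}

#' A (summed) XRF spectrum
#'
#' @param counts numeric vector of channel counts (>= 0).
#' @param n_pixels number of pixels summed (>= 1).
#' @param offset_kev,gain_kev energy calibration.
#' @return An object of class `xrf_spectrum`.
#' @export
xrf_spectrum <- function(counts, n_pixels = 1L, offset_kev = 0,
                         gain_kev = 0.01) {
  stopifnot(n_pixels >= 1, gain_kev > 0, all(counts >= 0))
  structure(list(counts = as.numeric(counts), n_pixels = as.integer(n_pixels),
                 offset_kev = offset_kev, gain_kev = gain_kev),
            class = "xrf_spectrum")
}

#' @export
print.xrf_spectrum <- function(x, ...) {
  cat("<xrf_spectrum> ", length(x$counts), " channels, ",
      x$n_pixels, " px summed, ", format(sum(x$counts), big.mark = ","),
      " counts\n", sep = "")
  invisible(x)
}
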