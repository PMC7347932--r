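# On-disk formats. Count rasters are 16-bit single-channel TIFF (bit-exact
# for integer counts up to 65535) with a JSON sidecar carrying pixel size,
# element and units; label masks are 8-bit TIFF + JSON class table; spectrum
# stacks are multi-page 16-bit TIFF (one page per energy channel) + JSON
# energy calibration. Pixel convention: origin top-left, x = column, y = row,
# 0-based, pixel centers at integer coordinates.

MAX16 <- 65535

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an element map as TIFF + JSON sidecar
#'
#' @param map an [element_map()]; counts must be integers in 0..65535
#'   (fitted maps are rounded).
#' @param path output TIFF path; the sidecar goes next to it.
#' @return `path`, invisibly.
#' @export
write_element_map <- function(map, path) {
  stopifnot(inherits(map, "element_map"))
  counts <- round(map$counts)
  counts[is.na(counts)] <- 0
  if (max(counts) > MAX16) stop("counts exceed 16-bit TIFF range")
  tiff::writeTIFF(counts / MAX16, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(element = map$element,
                            pixel_size_nm = map$pixel_size_nm,
                            units = "raw counts",
                            n_missing = sum(is.na(map$counts))),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read an element map written by [write_element_map()]
#'
#' Also accepts externally fitted single-channel TIFF maps, provided the
#' JSON sidecar declares `element` and `pixel_size_nm`.
#'
#' @param path TIFF path.
#' @return an [element_map()].
#' @export
read_element_map <- function(path) {
  meta <- jsonlite::fromJSON(sidecar_path(path))
  counts <- tiff::readTIFF(path, as.is = TRUE)
  element_map(counts, meta$element, meta$pixel_size_nm)
}

#' Write a label mask as 8-bit TIFF + JSON class table
#'
#' @param mask a [region_mask()] (labels must be < 256).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  if (max(mask$labels) > 255) stop("labels exceed 8-bit TIFF range")
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(class_table = as.list(mask$class_table),
                            pixel_size_nm = mask$pixel_size_nm),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label mask written by [write_region_mask()]
#'
#' @param path TIFF path.
#' @return a [region_mask()].
#' @export
read_region_mask <- function(path) {
  meta <- jsonlite::fromJSON(sidecar_path(path))
  labels <- tiff::readTIFF(path, as.is = TRUE)
  region_mask(labels, unlist(meta$class_table), meta$pixel_size_nm)
}

#' Write a spectrum stack as multi-page TIFF + JSON sidecar
#'
#' One 16-bit page per energy channel.
#'
#' @param stack a [spectrum_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_spectrum_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectrum_stack"))
  if (max(stack$counts) > MAX16) stop("counts exceed 16-bit TIFF range")
  nch <- dim(stack$counts)[3]
  pages <- lapply(seq_len(nch), function(k) stack$counts[, , k] / MAX16)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(offset_kev = stack$offset_kev,
                            gain_kev = stack$gain_kev,
                            live_time_s = stack$live_time_s,
                            pixel_size_nm = stack$pixel_size_nm,
                            n_channels = nch),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a spectrum stack written by [write_spectrum_stack()]
#'
#' @param path TIFF path.
#' @return a [spectrum_stack()].
#' @export
read_spectrum_stack <- function(path) {
  meta <- jsonlite::fromJSON(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  spectrum_stack(arr, offset_kev = meta$offset_kev, gain_kev = meta$gain_kev,
                 live_time_s = meta$live_time_s,
                 pixel_size_nm = meta$pixel_size_nm)
}

#' Write fiducial pairs to CSV
#'
#' Columns `src_x, src_y, dst_x, dst_y`, 0-based pixel units.
#'
#' @param fiducials a [fiducial_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  utils::write.csv(data.frame(src_x = fiducials$src[, 1],
                              src_y = fiducials$src[, 2],
                              dst_x = fiducials$dst[, 1],
                              dst_y = fiducials$dst[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
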