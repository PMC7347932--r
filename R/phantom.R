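#' Granule population specification for the phantom
#'
#' Granules are rendered as S-rich core disks with an optional Fe-rich
#' annulus, emulating the S-core / Fe-rim morphology of sub-micron
#' cytoplasmic granules. Pixel membership is by center-of-pixel inclusion.
#'
#' @param n number of granules to place.
#' @param radius_nm length-2 range of core radii in nm (sampled uniformly).
#' @param core_rates named numeric vector of expected counts/pixel *added* in
#'   the core disk (e.g. `c(S = 4, Fe = 1)`).
#' @param rim_rates named numeric vector added in the rim annulus
#'   (e.g. `c(Fe = 12)`); use `NULL` for core-only granules.
#' @param rim_width_nm rim annulus width in nm.
#' @param region compartment class granules are placed in.
#' @param max_attempts rejection-sampling budget per granule; exceeding it
#'   aborts with an error naming the placement failure.
#' @return object of class `granule_spec`.
#' @export
granule_spec <- function(n = 40, radius_nm = c(60, 220),
                         core_rates = c(S = 4, Fe = 1),
                         rim_rates = c(Fe = 6), rim_width_nm = 75,
                         region = "cytoplasm", max_attempts = 200L) {
  stopifnot(n >= 0, length(radius_nm) == 2, all(radius_nm > 0),
            radius_nm[1] <= radius_nm[2], rim_width_nm >= 0,
            all(core_rates >= 0), is.null(rim_rates) || all(rim_rates >= 0))
  structure(list(n = as.integer(n), radius_nm = radius_nm,
                 core_rates = core_rates, rim_rates = rim_rates,
                 rim_width_nm = rim_width_nm, region = region,
                 max_attempts = as.integer(max_attempts)),
            class = "granule_spec")
}

#' Neuron-phantom specification
#'
#' Declares a compartmented neuron geometry, a per-class elemental
#' composition (expected counts per pixel), an optional granule population
#' and a seed. Shapes are rasterized in declared order, later shapes
#' overwriting earlier ones (deterministic z-order); the first shape must be
#' of type `"background"` so the class masks partition the grid.
#'
#' @param grid_shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm pixel pitch in nm.
#' @param compartments list of shapes; each is a list with fields `class`,
#'   `type` (`"background"`, `"ellipse"` or `"annulus"`), `center`
#'   (`c(row, col)` in 0-based pixels), `radii` (`c(r_row, r_col)` in px),
#'   `theta` (rotation, radians, optional) and, for annuli, `width` (px,
#'   outward from the ellipse boundary).
#' @param composition named list: class -> named numeric vector of expected
#'   counts per pixel per element. All rates must be >= 0; classes used in
#'   `compartments` must be present.
#' @param granules a [granule_spec()] or `NULL`.
#' @param seed integer seed governing placement and noise (per-stage
#'   substreams are derived from it).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(256, 256), pixel_size_nm = 50,
                         compartments = phantom_geometry(grid_shape),
                         composition, granules = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 8), pixel_size_nm > 0)
  if (compartments[[1]]$type != "background") {
    stop("first compartment shape must be of type 'background'")
  }
  for (sh in compartments) {
    if (sh$type == "background") next
    lo <- sh$center - sh$radii - (sh$width %||% 0)
    hi <- sh$center + sh$radii + (sh$width %||% 0)
    if (any(lo < 0) || any(hi > grid_shape - 1)) {
      stop("compartment shape '", sh$class, "' extends outside the grid")
    }
  }
  classes <- unique(vapply(compartments, `[[`, "", "class"))
  missing <- setdiff(classes, names(composition))
  if (length(missing) > 0) {
    stop("composition missing for class(es): ", paste(missing, collapse = ", "))
  }
  for (cl in names(composition)) {
    r <- composition[[cl]]
    if (is.null(names(r)) || any(names(r) == "") || any(r < 0)) {
      stop("composition for '", cl, "' must be a named vector of rates >= 0")
    }
  }
  if (!is.null(granules)) {
    stopifnot(inherits(granules, "granule_spec"))
    if (granules$n > 0 && granules$radius_nm[1] < pixel_size_nm) {
      stop("granule radii must be >= 1 pixel (", pixel_size_nm, " nm)")
    }
  }
  structure(list(grid_shape = grid_shape, pixel_size_nm = pixel_size_nm,
                 compartments = compartments, composition = composition,
                 granules = granules, seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default procedural neuron geometry
#'
#' A neuron body in neuropil: elliptical cytoplasm, offset nucleus with a
#' P-rich perinuclear rim drawn as a thin annulus over the nuclear boundary,
#' a nucleolus, and a few mitochondria, RER and lipofuscin profiles in the
#' cytoplasm. Sizes scale with the grid.
#'
#' @param grid_shape `c(rows, cols)` in pixels.
#' @param organelles include mitochondria/RER/lipofuscin shapes (default
#'   TRUE).
#' @return list of shape descriptions for [phantom_spec()].
#' @export
phantom_geometry <- function(grid_shape = c(256, 256), organelles = TRUE) {
  n <- min(grid_shape)
  cen <- (grid_shape - 1) / 2
  ell <- function(class, center, radii, theta = 0, width = NULL) {
    c(list(class = class, type = if (is.null(width)) "ellipse" else "annulus",
           center = center, radii = radii, theta = theta),
      if (!is.null(width)) list(width = width))
  }
  nuc_c <- cen + c(-0.06, 0.08) * n
  shapes <- list(
    list(class = "neuropil", type = "background"),
    ell("cytoplasm", cen, c(0.42, 0.38) * n, theta = 0.3),
    ell("nucleus", nuc_c, c(0.16, 0.14) * n),
    ell("perinuclear_rim", nuc_c, c(0.16, 0.14) * n, width = max(2, 0.02 * n)),
    ell("nucleolus", nuc_c + c(0.04, -0.03) * n, c(0.05, 0.05) * n)
  )
  if (organelles) {
    org <- list(
      ell("mitochondria", cen + c(0.26, -0.10) * n, c(0.030, 0.018) * n, 0.8),
      ell("mitochondria", cen + c(0.16, -0.24) * n, c(0.032, 0.017) * n, -0.5),
      ell("mitochondria", cen + c(-0.22, -0.14) * n, c(0.028, 0.018) * n, 0.2),
      ell("RER", cen + c(-0.05, -0.28) * n, c(0.09, 0.025) * n, 1.2),
      ell("RER", cen + c(0.28, 0.12) * n, c(0.07, 0.022) * n, -0.9),
      ell("lipofuscin", cen + c(-0.26, 0.10) * n, c(0.030, 0.030) * n),
      ell("lipofuscin", cen + c(0.10, -0.31) * n, c(0.024, 0.024) * n)
    )
    # organelles drawn after cytoplasm but before nucleus/rim/nucleolus
    shapes <- c(shapes[1:2], org, shapes[3:5])
  }
  shapes
}

# raster of one shape: logical matrix by center-of-pixel inclusion
rasterize_shape <- function(shape, grid_shape) {
  rows <- matrix(0:(grid_shape[1] - 1), grid_shape[1], grid_shape[2])
  cols <- matrix(0:(grid_shape[2] - 1), grid_shape[1], grid_shape[2],
                 byrow = TRUE)
  if (shape$type == "background") {
    return(matrix(TRUE, grid_shape[1], grid_shape[2]))
  }
  th <- shape$theta %||% 0
  dr <- rows - shape$center[1]; dc <- cols - shape$center[2]
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  inner <- (u / shape$radii[1])^2 + (v / shape$radii[2])^2 <= 1
  if (shape$type == "ellipse") return(inner)
  if (shape$type == "annulus") {
    w <- shape$width
    outer_ <- (u / (shape$radii[1] + w))^2 + (v / (shape$radii[2] + w))^2 <= 1
    return(outer_ & !inner)
  }
  stop("unknown shape type: ", shape$type)
}

# deterministic substream seeds, kept below 2^31 - 1
substream <- function(seed, k) (as.integer(seed) + k) %% 2147483629L

#' Generate a neuron-phantom dataset
#'
#' Renders the compartment geometry, builds per-element expected-rate maps
#' from the composition, places granules by rejection sampling inside their
#' placement region, then draws every pixel of every element map as an
#' independent Poisson variate. Identical `(spec, seed)` reproduce identical
#' maps bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return list with:
#'   * `maps`: named list of [element_map()]s (Poisson counts);
#'   * `truth`: list with `masks` (a [region_mask()] of compartment classes,
#'     which partition the grid), `rates` (named list of expected-rate
#'     matrices, granule contribution included), `granule_table` (one row per
#'     rendered granule: center, radius, pixel counts, expected extra counts
#'     per element) and `granule_labels` (integer raster of granule ids).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  classes <- unique(vapply(spec$compartments, `[[`, "", "class"))
  class_table <- stats::setNames(seq_along(classes), classes)
  labels <- matrix(0L, gs[1], gs[2])
  for (sh in spec$compartments) {
    labels[rasterize_shape(sh, gs)] <- class_table[[sh$class]]
  }
  elements <- sort(unique(unlist(lapply(spec$composition, names))))
  rates <- stats::setNames(lapply(elements, function(el) {
    m <- matrix(0, gs[1], gs[2])
    for (cl in classes) {
      r <- spec$composition[[cl]][el]
      if (!is.na(r)) m[labels == class_table[[cl]]] <- r
    }
    m
  }), elements)

  granule_labels <- matrix(0L, gs[1], gs[2])
  granule_table <- NULL
  g <- spec$granules
  if (!is.null(g) && g$n > 0) {
    set.seed(substream(spec$seed, 0L))
    px <- spec$pixel_size_nm
    if (!g$region %in% classes) stop("granule region class not in geometry: ",
                                     g$region)
    region <- labels == class_table[[g$region]]
    region_idx <- which(region)
    rows <- (region_idx - 1) %% gs[1]
    cols <- (region_idx - 1) %/% gs[1]
    rowg <- matrix(0:(gs[1] - 1), gs[1], gs[2])
    colg <- matrix(0:(gs[2] - 1), gs[1], gs[2], byrow = TRUE)
    occupied <- matrix(FALSE, gs[1], gs[2])
    recs <- vector("list", g$n)
    for (i in seq_len(g$n)) {
      placed <- FALSE
      for (attempt in seq_len(g$max_attempts)) {
        j <- sample.int(length(region_idx), 1)
        r_nm <- stats::runif(1, g$radius_nm[1], g$radius_nm[2])
        r_px <- r_nm / px
        w_px <- g$rim_width_nm / px
        d2 <- (rowg - rows[j])^2 + (colg - cols[j])^2
        core <- d2 <= r_px^2
        foot <- d2 <= (r_px + w_px)^2
        if (!all(region[foot]) || any(occupied[foot])) next
        rim <- foot & !core
        for (el in names(g$core_rates)) {
          if (!el %in% elements) stop("granule core element '", el,
                                      "' absent from composition")
          rates[[el]][core] <- rates[[el]][core] + g$core_rates[[el]]
        }
        if (!is.null(g$rim_rates)) {
          for (el in names(g$rim_rates)) {
            if (!el %in% elements) stop("granule rim element '", el,
                                        "' absent from composition")
            rates[[el]][rim] <- rates[[el]][rim] + g$rim_rates[[el]]
          }
        }
        occupied[foot] <- TRUE
        granule_labels[foot] <- i
        extra <- stats::setNames(numeric(length(elements)), elements)
        for (el in names(g$core_rates)) {
          extra[el] <- extra[el] + g$core_rates[[el]] * sum(core)
        }
        for (el in names(g$rim_rates %||% numeric(0))) {
          extra[el] <- extra[el] + g$rim_rates[[el]] * sum(rim)
        }
        recs[[i]] <- data.frame(id = i, center_row = rows[j],
                                center_col = cols[j], radius_px = r_px,
                                n_core_px = sum(core), n_rim_px = sum(rim),
                                t(extra))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("granule placement failed for granule ", i, " after ",
             g$max_attempts, " attempts (region too crowded)")
      }
    }
    granule_table <- do.call(rbind, recs)
  }

  set.seed(substream(spec$seed, 1L))
  maps <- stats::setNames(lapply(elements, function(el) {
    counts <- matrix(stats::rpois(prod(gs), rates[[el]]), gs[1], gs[2])
    element_map(counts, el, spec$pixel_size_nm, sigma = sqrt(counts))
  }), elements)

  list(maps = maps,
       truth = list(
         masks = region_mask(labels, class_table, spec$pixel_size_nm),
         rates = rates,
         granule_table = granule_table,
         granule_labels = granule_labels))
}

#' Render a full spectrum stack from element maps
#'
#' For every pixel, the expected channel content is the sum of each element's
#' unit-area K-line profile scaled to that pixel's counts, plus a smooth
#' continuum (the detector model's `bg_flat`/`bg_slope`, clipped at zero);
#' each channel is then drawn as an independent Poisson variate.
#' Deterministic under a fixed seed.
#'
#' @param maps named list of [element_map()]s on a common grid.
#' @param detector a [detector_model()] covering the map elements.
#' @param seed integer seed.
#' @param live_time_s live time per pixel (metadata only).
#' @return a [spectrum_stack()].
#' @export
render_spectra <- function(maps, detector, seed = 1L, live_time_s = 0.05) {
  stopifnot(length(maps) >= 1, inherits(detector, "detector_model"))
  gs <- dim(maps[[1]]$counts)
  for (m in maps) stopifnot(identical(dim(m$counts), gs))
  missing <- setdiff(names(maps), detector$lines$element)
  if (length(missing) > 0) {
    stop("no tabulated K-line energy for element(s): ",
         paste(missing, collapse = ", "))
  }
  nch <- detector$n_channels
  e <- channel_energies(detector)
  bg <- pmax(0, detector$bg_flat + detector$bg_slope * (e - mean(e)))
  profiles <- vapply(names(maps), function(el) element_profile(detector, el),
                     numeric(nch))
  counts_mat <- vapply(maps, function(m) as.vector(m$counts),
                       numeric(prod(gs)))
  if (is.null(dim(counts_mat))) counts_mat <- matrix(counts_mat, nrow = 1)
  set.seed(substream(seed, 2L))
  out <- array(0L, dim = c(gs[1], gs[2], nch))
  chunk <- max(1L, floor(2e6 / nch))
  npx <- prod(gs)
  for (start in seq(1L, npx, by = chunk)) {
    idx <- start:min(npx, start + chunk - 1L)
    lambda <- counts_mat[idx, , drop = FALSE] %*% t(profiles)
    lambda <- sweep(lambda, 2, bg, `+`)
    draws <- stats::rpois(length(lambda), lambda)
    # fill [pixel, channel] draws into the [row, col, channel] array
    out[idx + rep((seq_len(nch) - 1L) * npx, each = length(idx))] <- draws
  }
  spectrum_stack(out, offset_kev = detector$offset_kev,
                 gain_kev = detector$gain_kev, live_time_s = live_time_s,
                 pixel_size_nm = maps[[1]]$pixel_size_nm)
}
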