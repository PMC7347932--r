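#' 8-connected component labelling of a binary image
#'
#' Flood-fill labelling with the particle-analysis convention of diagonal
#' (8-) connectivity. Written here because the installed image stacks only
#' provide 4-connected labelling.
#'
#' @param binary logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background), labelled in
#'   raster-scan order of their first pixel.
#' @export
label_components <- function(binary, connectivity = 8L) {
  stopifnot(is.logical(binary), connectivity %in% c(4L, 8L))
  nr <- nrow(binary); nc <- ncol(binary)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  fg <- which(binary)
  lab <- 0L
  stack <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    stack[1] <- start; top <- 1L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (binary[q] && labels[q] == 0L) {
          labels[q] <- lab
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  labels
}

#' Detect Fe/S-enriched granules in the cytoplasm
#'
#' Per element, the threshold is `mean + k * SD` of the counts over all
#' cytoplasm pixels (granules included — the stated procedure has no
#' exclusion step; set `refine = TRUE` for a one-iteration refinement that
#' recomputes the statistics excluding the first-pass granules and
#' re-thresholds). A pixel is enriched when its Fe *or* S counts exceed the
#' corresponding threshold; 8-connected components of at least `min_size`
#' enriched cytoplasm pixels become labelled granules.
#'
#' @param fe_map,s_map [element_map()]s on a common grid.
#' @param cytoplasm logical matrix of cytoplasm pixels, or a [region_mask()]
#'   with a `cytoplasm` class.
#' @param k threshold stringency in SD units (> 0; default 2).
#' @param min_size minimum granule size in pixels (default 2,
#'   "multi-pixel" granules).
#' @param refine recompute background statistics excluding first-pass
#'   granules and re-threshold once (default FALSE).
#' @return integer label matrix of granules; attributes `thresholds`
#'   (per-element), `enriched_element` (per-granule: "Fe", "S" or "both")
#'   and `cytoplasm_stats`.
#' @export
detect_granules <- function(fe_map, s_map, cytoplasm, k = 2, min_size = 2L,
                            refine = FALSE) {
  if (inherits(cytoplasm, "region_mask")) {
    cytoplasm <- mask_binary(cytoplasm, "cytoplasm")
  }
  stopifnot(identical(dim(fe_map$counts), dim(s_map$counts)),
            identical(dim(fe_map$counts), dim(cytoplasm)))
  if (!any(cytoplasm)) stop("empty cytoplasm mask")
  if (k <= 0) stop("k must be > 0")

  pass <- function(bg_mask) {
    stats_of <- function(map) {
      v <- map$counts[bg_mask]
      c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v))
    }
    fe_st <- stats_of(fe_map); s_st <- stats_of(s_map)
    thr <- c(Fe = unname(fe_st["mean"] + k * fe_st["sd"]),
             S = unname(s_st["mean"] + k * s_st["sd"]))
    fe_hot <- fe_map$counts > thr["Fe"]
    s_hot <- s_map$counts > thr["S"]
    enriched <- (fe_hot | s_hot) & cytoplasm
    enriched[is.na(enriched)] <- FALSE
    labels <- label_components(enriched, 8L)
    sizes <- tabulate(labels)
    keep <- which(sizes >= min_size)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    list(labels = labels, thr = thr, fe_hot = fe_hot, s_hot = s_hot,
         stats = rbind(Fe = fe_st, S = s_st))
  }

  p1 <- pass(cytoplasm)
  res <- if (refine && any(p1$labels > 0L)) {
    pass(cytoplasm & p1$labels == 0L)
  } else p1
  labels <- res$labels
  n <- max(labels)
  cls <- character(n)
  for (i in seq_len(n)) {
    px <- labels == i
    has_fe <- any(res$fe_hot[px], na.rm = TRUE)
    has_s <- any(res$s_hot[px], na.rm = TRUE)
    cls[i] <- if (has_fe && has_s) "both" else if (has_fe) "Fe" else "S"
  }
  attr(labels, "thresholds") <- res$thr
  attr(labels, "enriched_element") <- cls
  attr(labels, "cytoplasm_stats") <- res$stats
  attr(labels, "k") <- k
  attr(labels, "min_size") <- as.integer(min_size)
  labels
}

#' Measure detected granules
#'
#' Per granule: pixel count and area; summed Fe and S counts and (when a
#' calibration standard and Si map are supplied) areal masses by the
#' thin-film calibration applied to the granule-summed counts; Fe/S mass
#' ratio; mean-count ratios over the cytoplasm-minus-granules background
#' (Fe/BGD, S/BGD); within-granule relative SD (sigma/mean) per element;
#' centroid; and the size class split at 0.07 um^2.
#'
#' @param labels granule label matrix from [detect_granules()].
#' @param maps named list of [element_map()]s; needs `Fe` and `S`, and `Si`
#'   if `std` is given.
#' @param cytoplasm logical cytoplasm matrix or `region_mask` (background
#'   reference region).
#' @param std a [calibration_standard()] or `NULL` to skip areal masses.
#' @param pixel_size_nm pixel pitch; defaults to the Fe map's.
#' @param size_split_um2 area separating small from large granules
#'   (default 0.07).
#' @param condition free-text condition label carried into the records.
#' @return data.frame, one row per granule: `id`, `condition`, `n_px`,
#'   `area_um2`, `size_class`, `fe_counts`, `s_counts`, `fe_am`, `s_am`,
#'   `fe_s_ratio`, `fe_over_bgd`, `s_over_bgd`, `fe_rsd`, `s_rsd`,
#'   `centroid_row`, `centroid_col`, `enriched_element`.
#' @export
measure_granules <- function(labels, maps, cytoplasm, std = NULL,
                             pixel_size_nm = maps[["Fe"]]$pixel_size_nm,
                             size_split_um2 = 0.07, condition = NA_character_) {
  stopifnot(all(c("Fe", "S") %in% names(maps)))
  if (inherits(cytoplasm, "region_mask")) {
    cytoplasm <- mask_binary(cytoplasm, "cytoplasm")
  }
  n <- max(labels)
  px_area_um2 <- (pixel_size_nm * 1e-3)^2
  bg <- cytoplasm & labels == 0L
  fe_bgd <- mean(maps[["Fe"]]$counts[bg], na.rm = TRUE)
  s_bgd <- mean(maps[["S"]]$counts[bg], na.rm = TRUE)
  enriched <- attr(labels, "enriched_element")
  rows <- lapply(seq_len(n), function(i) {
    px <- which(labels == i)
    fe <- maps[["Fe"]]$counts[px]
    s <- maps[["S"]]$counts[px]
    n_px <- length(px)
    fe_sum <- sum(fe, na.rm = TRUE); s_sum <- sum(s, na.rm = TRUE)
    if (!is.null(std)) {
      if (!"Si" %in% names(maps)) stop("internal Si standard absent (no Si map)")
      si_sum <- sum(maps[["Si"]]$counts[px], na.rm = TRUE)
      q <- areal_mass(c(fe_sum, s_sum), si_sum, std, c("Fe", "S"))
      fe_am <- q$am[1]; s_am <- q$am[2]
    } else {
      fe_am <- NA_real_; s_am <- NA_real_
    }
    rr <- (px - 1) %% nrow(labels)
    cc <- (px - 1) %/% nrow(labels)
    data.frame(
      id = i, condition = condition, n_px = n_px,
      area_um2 = n_px * px_area_um2,
      size_class = if (n_px * px_area_um2 < size_split_um2) "small" else "large",
      fe_counts = fe_sum, s_counts = s_sum,
      fe_am = fe_am, s_am = s_am,
      fe_s_ratio = if (s_sum > 0) {
        if (!is.null(std)) fe_am / s_am else fe_sum / s_sum
      } else NA_real_,
      fe_over_bgd = mean(fe, na.rm = TRUE) / fe_bgd,
      s_over_bgd = mean(s, na.rm = TRUE) / s_bgd,
      fe_rsd = stats::sd(fe) / mean(fe, na.rm = TRUE),
      s_rsd = stats::sd(s) / mean(s, na.rm = TRUE),
      centroid_row = mean(rr), centroid_col = mean(cc),
      enriched_element = if (!is.null(enriched)) enriched[i] else NA_character_)
  })
  if (n == 0) {
    return(data.frame(id = integer(0), condition = character(0),
                      n_px = integer(0), area_um2 = numeric(0),
                      size_class = character(0), fe_counts = numeric(0),
                      s_counts = numeric(0), fe_am = numeric(0),
                      s_am = numeric(0), fe_s_ratio = numeric(0),
                      fe_over_bgd = numeric(0), s_over_bgd = numeric(0),
                      fe_rsd = numeric(0), s_rsd = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      enriched_element = character(0)))
  }
  do.call(rbind, rows)
}

#' Per-condition granule summaries with size-class split
#'
#' @param records granule table from [measure_granules()] (conditions may be
#'   mixed; the `condition` column partitions them).
#' @param size_split_um2 area separating small from large (default 0.07).
#' @return data.frame, one row per condition x size class (plus an `"all"`
#'   size class row): `condition`, `size_class`, `n`, `mean_area_um2`,
#'   `sd_area_um2`, `mean_fe_over_bgd`, `mean_s_over_bgd`, `mean_fe_s_ratio`,
#'   `rel_sd_fe`, `rel_sd_s` (SD/mean of the per-granule Fe and S means
#'   across granules).
#' @export
summarize_granules <- function(records, size_split_um2 = 0.07) {
  one <- function(rec, condition, size_class) {
    n <- nrow(rec)
    mean_or_na <- function(v) if (n > 0) mean(v, na.rm = TRUE) else NA_real_
    sd_or_na <- function(v) if (n > 1) stats::sd(v, na.rm = TRUE) else NA_real_
    fe_means <- rec$fe_over_bgd
    s_means <- rec$s_over_bgd
    data.frame(condition = condition, size_class = size_class, n = n,
               mean_area_um2 = mean_or_na(rec$area_um2),
               sd_area_um2 = sd_or_na(rec$area_um2),
               mean_fe_over_bgd = mean_or_na(fe_means),
               mean_s_over_bgd = mean_or_na(s_means),
               mean_fe_s_ratio = mean_or_na(rec$fe_s_ratio),
               rel_sd_fe = sd_or_na(fe_means) / mean_or_na(fe_means),
               rel_sd_s = sd_or_na(s_means) / mean_or_na(s_means))
  }
  conds <- unique(records$condition)
  if (length(conds) == 0) conds <- NA_character_
  out <- lapply(conds, function(cd) {
    rec <- records[is.na(cd) | records$condition %in% cd, , drop = FALSE]
    small <- rec[rec$area_um2 < size_split_um2, , drop = FALSE]
    large <- rec[rec$area_um2 >= size_split_um2, , drop = FALSE]
    rbind(one(rec, cd, "all"), one(small, cd, "small"),
          one(large, cd, "large"))
  })
  do.call(rbind, out)
}

#' Co-localize detected granules with a transformed TEM mask class
#'
#' Granules are detected in XRF space and only afterwards compared with the
#' ultrastructure; this reports, per granule, the fraction of its pixels
#' covered by a given TEM-derived class (e.g. lipofuscin) and flags granules
#' matching no recognizable structure.
#'
#' @param labels granule label matrix.
#' @param tem_mask a [region_mask()] already resampled onto the XRF grid
#'   (see [apply_transform()]).
#' @param class class name to test overlap against.
#' @param min_overlap fraction above which a granule counts as co-localized
#'   (default 0.5).
#' @return data.frame: `id`, `n_px`, `overlap_fraction`, `colocalized`.
#' @export
colocalize_granules <- function(labels, tem_mask, class = "lipofuscin",
                                min_overlap = 0.5) {
  target <- mask_binary(tem_mask, class)
  stopifnot(identical(dim(target), dim(labels)))
  n <- max(labels)
  out <- lapply(seq_len(n), function(i) {
    px <- labels == i
    frac <- sum(target & px) / sum(px)
    data.frame(id = i, n_px = sum(px), overlap_fraction = frac,
               colocalized = frac >= min_overlap)
  })
  if (n == 0) {
    return(data.frame(id = integer(0), n_px = integer(0),
                      overlap_fraction = numeric(0), colocalized = logical(0)))
  }
  do.call(rbind, out)
}
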