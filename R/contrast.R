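#' Summed counts of one element in one compartment
#'
#' The elementary record of the contrast calculation: total counts `S`, their
#' uncertainty `sigma_S`, and the pixel count `N` of one compartment of one
#' neuron. When built from raw integrated count maps the Poisson uncertainty
#' `sigma_S = sqrt(S)` applies; when built from a spectral fit, the fit's
#' `sigma_S` is used (the `sigma_source` field records which).
#'
#' @param element element symbol.
#' @param s summed counts (>= 0).
#' @param sigma_s uncertainty of `s` (> 0, or NA when `s` is 0).
#' @param n pixel count (>= 1).
#' @param compartment compartment/organelle class name.
#' @param neuron_id identifier for the neuron/section.
#' @param sigma_source `"poisson"` or `"fit"`.
#' @return object of class `compartment_counts`.
#' @export
compartment_counts <- function(element, s, sigma_s = sqrt(s), n,
                               compartment = NA_character_,
                               neuron_id = NA_character_,
                               sigma_source = "poisson") {
  stopifnot(s >= 0, n >= 1)
  if (!is.na(sigma_s) && sigma_s <= 0 && s > 0) stop("sigma_s must be > 0")
  structure(list(element = element, s = s, sigma_s = sigma_s,
                 n = as.integer(n), compartment = compartment,
                 neuron_id = neuron_id, sigma_source = sigma_source),
            class = "compartment_counts")
}

#' Compartment counts from an element map and a pixel mask
#'
#' Sums an element map over the mask-true pixels; `sigma_S = sqrt(S)`
#' (Poisson) unless the map carries per-pixel fit uncertainties, in which
#' case they are combined in quadrature.
#'
#' @param map an [element_map()].
#' @param mask logical matrix on the map grid, or a [region_mask()] together
#'   with `class`.
#' @param class compartment class when `mask` is a `region_mask`; also
#'   recorded in the result.
#' @param neuron_id identifier passed through.
#' @return a [compartment_counts()].
#' @export
compartment_counts_from_map <- function(map, mask, class = NA_character_,
                                        neuron_id = NA_character_) {
  stopifnot(inherits(map, "element_map"))
  if (inherits(mask, "region_mask")) {
    stopifnot(!is.na(class))
    mask <- mask_binary(mask, class)
  }
  stopifnot(identical(dim(mask), dim(map$counts)))
  if (!any(mask)) stop("compartment has zero pixels")
  s <- sum(map$counts[mask], na.rm = TRUE)
  if (!is.null(map$sigma)) {
    sigma <- sqrt(sum(map$sigma[mask]^2, na.rm = TRUE))
    src <- "fit"
  } else {
    sigma <- sqrt(s)
    src <- "poisson"
  }
  compartment_counts(map$element, s, if (s > 0) sigma else NA_real_,
                     sum(mask), compartment = class, neuron_id = neuron_id,
                     sigma_source = src)
}

#' Relative count-rate contrast of a compartment versus the nuclear reference
#'
#' Computes `Delta_{i,n} = (S_i/N_i - S_n/N_n) / (S_n/N_n)` and its
#' propagated uncertainty
#' `sigma_Delta = (Delta + 1) * sqrt((sigma_Si/S_i)^2 + (sigma_Sn/S_n)^2)`.
#' `S_n = 0` is an error (the reference rate is the denominator); `S_i = 0`
#' returns `Delta = -1` with a flag and a missing `sigma_Delta` (the
#' propagation formula divides by `S_i`).
#'
#' @param i [compartment_counts()] of the compartment of interest.
#' @param n [compartment_counts()] of the reference (nuclear) compartment.
#' @return object of class `contrast_result` with fields `delta`,
#'   `sigma_delta`, `element`, `compartment`, `reference`, `neuron_id`,
#'   `n_pixels_i`, `n_pixels_n`, `zero_counts_flag`.
#' @export
delta <- function(i, n) {
  stopifnot(inherits(i, "compartment_counts"),
            inherits(n, "compartment_counts"))
  if (!identical(i$element, n$element)) {
    stop("compartment and reference measure different elements: ",
         i$element, " vs ", n$element)
  }
  if (n$s <= 0) stop("reference compartment has zero counts")
  d <- (i$s / n$s) * (n$n / i$n) - 1
  if (i$s <= 0) {
    sd_d <- NA_real_
    flag <- TRUE
  } else {
    sd_d <- (d + 1) * sqrt((i$sigma_s / i$s)^2 + (n$sigma_s / n$s)^2)
    flag <- FALSE
  }
  structure(list(delta = d, sigma_delta = sd_d, element = i$element,
                 compartment = i$compartment, reference = n$compartment,
                 neuron_id = i$neuron_id, n_pixels_i = i$n,
                 n_pixels_n = n$n, zero_counts_flag = flag),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s %s vs %s: Delta = %+.3f +/- %.3f\n",
              x$element, x$compartment, x$reference, x$delta,
              x$sigma_delta))
  invisible(x)
}

#' Aggregate contrasts across neurons under the reporting rules
#'
#' Averages `Delta` over neurons, excluding entries whose relative
#' uncertainty `sigma_Delta / |Delta|` is 30% or more (or whose
#' `sigma_Delta` is missing), and reporting a mean +/- SD only when at least
#' three measurements survive. `|Delta|` is used in the filter denominator
#' because depletions (negative contrasts) are as informative as
#' enrichments.
#'
#' @param results list of [delta()] results sharing element and compartment
#'   pair.
#' @param max_rel_unc exclusion threshold on `sigma_Delta / |Delta|`
#'   (default 0.30).
#' @param min_n minimum surviving measurements (default 3, "triplicate").
#' @return object of class `aggregate_contrast`: `mean_delta`, `sd_delta`,
#'   `n_included`, `n_excluded`, `reportable`, `exclusion_reasons`,
#'   `element`, `compartment`, `reference`.
#' @export
aggregate_contrast <- function(results, max_rel_unc = 0.30, min_n = 3L) {
  if (length(results) > 0) {
    els <- unique(vapply(results, `[[`, "", "element"))
    cps <- unique(vapply(results, function(r) paste(r$compartment, r$reference),
                         ""))
    if (length(els) > 1 || length(cps) > 1) {
      stop("results mix elements or compartment pairs")
    }
  }
  reasons <- character(0)
  keep <- logical(length(results))
  for (k in seq_along(results)) {
    r <- results[[k]]
    if (is.na(r$sigma_delta)) {
      reasons <- c(reasons, "missing sigma_delta")
    } else if (r$delta == 0 || r$sigma_delta / abs(r$delta) >= max_rel_unc) {
      reasons <- c(reasons, sprintf("relative uncertainty %.2f >= %.2f",
                                    if (r$delta == 0) Inf else
                                      r$sigma_delta / abs(r$delta),
                                    max_rel_unc))
    } else {
      keep[k] <- TRUE
    }
  }
  deltas <- vapply(results[keep], `[[`, numeric(1), "delta")
  reportable <- sum(keep) >= min_n
  structure(list(
    mean_delta = if (reportable) mean(deltas) else NA_real_,
    sd_delta = if (reportable) stats::sd(deltas) else NA_real_,
    n_included = sum(keep), n_excluded = sum(!keep),
    reportable = reportable, exclusion_reasons = reasons,
    element = if (length(results)) results[[1]]$element else NA_character_,
    compartment = if (length(results)) results[[1]]$compartment else NA_character_,
    reference = if (length(results)) results[[1]]$reference else NA_character_),
    class = "aggregate_contrast")
}

#' @export
print.aggregate_contrast <- function(x, ...) {
  if (x$reportable) {
    cat(sprintf("<aggregate_contrast> %s %s vs %s: %+.3f +/- %.3f (n = %d, %d excluded)\n",
                x$element, x$compartment, x$reference, x$mean_delta,
                x$sd_delta, x$n_included, x$n_excluded))
  } else {
    cat(sprintf("<aggregate_contrast> %s %s vs %s: not reportable (%d included, %d excluded)\n",
                x$element, x$compartment, x$reference, x$n_included,
                x$n_excluded))
  }
  invisible(x)
}

#' Tidy per-measurement contrast table
#'
#' @param results list of [delta()] results (any mix of elements/pairs).
#' @param max_rel_unc inclusion threshold as in [aggregate_contrast()].
#' @return data.frame with columns `element`, `compartment`, `reference`,
#'   `delta`, `sigma_delta`, `n_pixels`, `neuron_id`, `included_flag`,
#'   `exclusion_reason`.
#' @export
contrast_table <- function(results, max_rel_unc = 0.30) {
  rows <- lapply(results, function(r) {
    reason <- ""
    included <- TRUE
    if (is.na(r$sigma_delta)) {
      included <- FALSE; reason <- "missing sigma_delta"
    } else if (r$delta == 0 || r$sigma_delta / abs(r$delta) >= max_rel_unc) {
      included <- FALSE; reason <- "relative uncertainty >= threshold"
    }
    data.frame(element = r$element, compartment = r$compartment,
               reference = r$reference, delta = r$delta,
               sigma_delta = r$sigma_delta, n_pixels = r$n_pixels_i,
               neuron_id = r$neuron_id, included_flag = included,
               exclusion_reason = reason)
  })
  do.call(rbind, rows)
}
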