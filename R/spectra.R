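#' Sum a spectrum stack over a pixel mask
#'
#' Channel-wise sum of the spectra of all mask-true pixels. Summing before
#' fitting trades spatial resolution for signal-to-noise: per-pixel trace
#' counts are near the detection limit, but the summed spectrum of a
#' compartment supports a stable fit.
#'
#' @param stack a [spectrum_stack()].
#' @param mask logical matrix on the stack grid, or a [region_mask()]
#'   together with `class`.
#' @param class compartment class when `mask` is a `region_mask`.
#' @return an [xrf_spectrum()] with `n_pixels` the mask size.
#' @export
sum_spectrum <- function(stack, mask, class = NULL) {
  stopifnot(inherits(stack, "spectrum_stack"))
  if (inherits(mask, "region_mask")) {
    stopifnot(!is.null(class))
    mask <- mask_binary(mask, class)
  }
  gs <- dim(stack$counts)[1:2]
  stopifnot(identical(dim(mask), gs))
  if (!any(mask)) stop("compartment has zero pixels")
  flat <- matrix(stack$counts, prod(gs), dim(stack$counts)[3])
  counts <- colSums(flat[as.vector(mask), , drop = FALSE])
  xrf_spectrum(counts, n_pixels = sum(mask), offset_kev = stack$offset_kev,
               gain_kev = stack$gain_kev)
}

# SNIP-style iterative clipping baseline estimate on a count vector
snip_baseline <- function(y, iterations = 24L) {
  v <- log1p(log1p(pmax(y, 0)))
  n <- length(v)
  for (m in rev(seq_len(min(iterations, (n - 1) %/% 2)))) {
    i <- (m + 1):(n - m)
    v[i] <- pmin(v[i], (v[i - m] + v[i + m]) / 2)
  }
  expm1(expm1(v))
}

#' Fit element K-line counts in a summed spectrum
#'
#' Weighted linear least-squares fit of Gaussian Ka peaks (with ratio-tied
#' Kb) at tabulated energies sharing the detector width model, plus a
#' background (affine continuum, or a SNIP-clipped baseline with an affine
#' residual). Channel weights are Poisson, `1/max(count, 1)`; element
#' amplitudes are constrained non-negative by an exact active-set step.
#' `sigma_S` comes from the covariance of the weighted linear solve.
#'
#' @param spec an [xrf_spectrum()].
#' @param elements character vector of element symbols to fit (>= 1).
#' @param detector a [detector_model()]; its energy calibration must match
#'   the spectrum's.
#' @param weights `"poisson"` (default) or `"none"` (unit weights; makes the
#'   amplitude solve exactly linear in the data).
#' @return object of class `fit_result`: data.frame `counts` with columns
#'   `element`, `s`, `sigma_s`, `clamped`; `background` coefficients;
#'   `chi2_red`; `n_pixels`.
#' @export
fit_spectrum <- function(spec, elements, detector,
                         weights = c("poisson", "none")) {
  stopifnot(inherits(spec, "xrf_spectrum"), length(elements) >= 1,
            inherits(detector, "detector_model"))
  weights <- match.arg(weights)
  if (length(spec$counts) != detector$n_channels ||
      abs(spec$gain_kev - detector$gain_kev) > 1e-12 ||
      abs(spec$offset_kev - detector$offset_kev) > 1e-9) {
    stop("spectrum energy calibration does not match the detector model")
  }
  if (sum(spec$counts) <= 0) stop("spectrum has no counts")
  elements <- unique(elements)
  # reject pairs whose Ka lines coincide at this resolution
  ka <- stats::setNames(
    detector$lines$ka_kev[match(elements, detector$lines$element)], elements)
  if (any(is.na(ka))) stop("no tabulated K-line energy for element(s): ",
                           paste(elements[is.na(ka)], collapse = ", "))
  for (i in seq_along(elements)) {
    for (j in seq_len(i - 1)) {
      sep <- abs(ka[i] - ka[j])
      lim <- 0.25 * peak_sigma(detector, (ka[i] + ka[j]) / 2)
      if (sep < lim) {
        stop("singular design: K lines of ", elements[j], " and ",
             elements[i], " coincide at the detector resolution")
      }
    }
  }
  y <- spec$counts
  e <- channel_energies(detector)
  prof <- vapply(elements, function(el) element_profile(detector, el),
                 numeric(length(y)))
  if (detector$background == "snip") {
    base <- snip_baseline(y)
    y_fit <- y - base
  } else {
    base <- NULL
    y_fit <- y
  }
  x <- cbind(prof, bg0 = 1, bg1 = e - mean(e))
  w <- if (weights == "poisson") 1 / pmax(y, 1) else rep(1, length(y))
  n_el <- length(elements)

  solve_wls <- function(cols) {
    xw <- x[, cols, drop = FALSE] * sqrt(w)
    fit <- qr.solve(crossprod(xw), crossprod(xw, y_fit * sqrt(w)))
    drop(fit)
  }
  active <- seq_len(ncol(x))     # columns currently free
  repeat {
    beta <- solve_wls(active)
    el_idx <- which(active <= n_el)
    neg <- el_idx[beta[el_idx] < 0]
    if (length(neg) == 0) break
    drop_col <- neg[which.min(beta[neg])]
    active <- active[-drop_col]
    if (!any(active <= n_el)) {
      beta <- solve_wls(active)
      break
    }
  }
  s <- stats::setNames(numeric(n_el), elements)
  s[active[active <= n_el]] <- beta[active <= n_el]
  clamped <- !(seq_len(n_el) %in% active)
  # sigma from the unconstrained weighted covariance (positive for all
  # requested elements, clamped ones included)
  xw_all <- x * sqrt(w)
  cov_all <- tryCatch(solve(crossprod(xw_all)),
                      error = function(e) stop("singular design matrix: ",
                                               conditionMessage(e)))
  sigma_s <- sqrt(pmax(diag(cov_all)[seq_len(n_el)], 0))
  fitted_cols <- active
  yhat <- drop(x[, fitted_cols, drop = FALSE] %*%
                 solve_wls(fitted_cols)) + (if (is.null(base)) 0 else base)
  dof <- max(length(y) - length(active), 1)
  chi2 <- sum(w * (y - yhat)^2) / dof
  bg <- beta[active > n_el]
  structure(list(
    counts = data.frame(element = elements, s = unname(s),
                        sigma_s = unname(sigma_s), clamped = clamped),
    background = bg, chi2_red = chi2, n_pixels = spec$n_pixels,
    weights = weights, background_model = detector$background),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$n_pixels, " px, chi2_red = ",
      signif(x$chi2_red, 4), "\n", sep = "")
  print(transform(x$counts, s = signif(s, 5), sigma_s = signif(sigma_s, 4)))
  invisible(x)
}

#' Fitted counts of one element from a fit result
#'
#' @param fit a [fit_result][fit_spectrum()].
#' @param element element symbol.
#' @return list with `s` and `sigma_s`.
#' @export
fit_counts <- function(fit, element) {
  i <- match(element, fit$counts$element)
  if (is.na(i)) stop("element not fitted: ", element)
  list(s = fit$counts$s[i], sigma_s = fit$counts$sigma_s[i])
}

#' Per-pixel element maps from a spectrum stack
#'
#' Fits every pixel's spectrum independently (no spatial regularization) and
#' returns one [element_map()] per requested element, with the fit
#' `sigma_s` as the per-pixel uncertainty. Pixels whose fit fails (zero
#' counts or a singular solve) are flagged missing (NA) and counted.
#'
#' Unlike the mask-sum path, per-pixel spectra live in the low-count regime
#' where weighting channels by their own observed counts biases the
#' amplitudes (the Neyman chi-square effect), so the default here is unit
#' weights, which keep the linear amplitude solve unbiased.
#'
#' @param stack a [spectrum_stack()].
#' @param elements elements to fit.
#' @param detector a [detector_model()].
#' @param weights as in [fit_spectrum()]; default `"none"` (see above).
#' @return named list of [element_map()]s; attribute `n_failed` gives the
#'   number of pixels flagged missing.
#' @export
per_pixel_maps <- function(stack, elements, detector,
                           weights = c("none", "poisson")) {
  stopifnot(inherits(stack, "spectrum_stack"))
  weights <- match.arg(weights)
  gs <- dim(stack$counts)[1:2]
  npx <- prod(gs)
  flat <- matrix(stack$counts, npx, dim(stack$counts)[3])
  s_mat <- matrix(NA_real_, npx, length(elements))
  sig_mat <- matrix(NA_real_, npx, length(elements))
  n_failed <- 0L
  for (p in seq_len(npx)) {
    yp <- flat[p, ]
    if (sum(yp) == 0) {
      s_mat[p, ] <- 0
      sig_mat[p, ] <- NA_real_
      next
    }
    sp <- xrf_spectrum(yp, 1L, stack$offset_kev, stack$gain_kev)
    fit <- tryCatch(fit_spectrum(sp, elements, detector, weights),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    s_mat[p, ] <- fit$counts$s
    sig_mat[p, ] <- fit$counts$sigma_s
  }
  if (n_failed > 0) {
    message("per_pixel_maps: ", n_failed, " pixel fit(s) failed and were flagged missing")
  }
  maps <- stats::setNames(lapply(seq_along(elements), function(k) {
    element_map(matrix(s_mat[, k], gs[1], gs[2]), elements[k],
                stack$pixel_size_nm,
                sigma = matrix(sig_mat[, k], gs[1], gs[2]))
  }), elements)
  attr(maps, "n_failed") <- n_failed
  maps
}
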