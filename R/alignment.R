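#' Fiducial point pairs
#'
#' Paired landmark coordinates picked in the TEM mosaic (source) and the XRF
#' map (destination): angular features of cell boundaries, blood vessels or
#' resin cracks, chosen as distant as possible from the region of interest.
#' Coordinates are 0-based pixels, x = column, y = row.
#'
#' @param src,dst two-column matrices (or data.frames) of (x, y) coordinates,
#'   equal row counts, >= 2 pairs.
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  storage.mode(src) <- "double"; storage.mode(dst) <- "double"
  stopifnot(ncol(src) == 2, ncol(dst) == 2)
  if (nrow(src) != nrow(dst)) stop("unequal numbers of source and destination points")
  if (nrow(src) < 2) stop("at least 2 fiducial pairs are required")
  if (anyDuplicated(src)) stop("duplicate source points")
  structure(list(src = unname(src), dst = unname(dst)), class = "fiducial_set")
}

#' Read fiducials from CSV
#'
#' Expects columns `src_x, src_y, dst_x, dst_y` in 0-based pixel units.
#'
#' @param path CSV file path.
#' @return a [fiducial_set()].
#' @export
read_fiducials <- function(path) {
  d <- utils::read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(d))) {
    stop("fiducial CSV must have columns ", paste(need, collapse = ", "))
  }
  fiducial_set(d[, c("src_x", "src_y")], d[, c("dst_x", "dst_y")])
}

#' Estimate a similarity transform from fiducials
#'
#' Least-squares estimate of the translation, rotation and (positive) scale
#' mapping source onto destination coordinates,
#' `dst = s * R(theta) * src + t`, minimizing the summed squared destination
#' residuals (the classical orthogonal-Procrustes solution, reflection
#' excluded: adjacent sections are same-handed). The root-mean-square
#' residual over the fiducials is reported alongside.
#'
#' @param fiducials a [fiducial_set()].
#' @return object of class `similarity_transform` with fields `scale`,
#'   `rotation` (radians), `translation` (length-2, x and y, pixels),
#'   `rms_residual` (pixels) and `residuals` (per-fiducial, pixels).
#' @export
estimate_similarity <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  src <- fiducials$src; dst <- fiducials$dst
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  xs <- sweep(src, 2, mu_s); xd <- sweep(dst, 2, mu_d)
  var_s <- sum(xs^2)
  if (var_s == 0) stop("degenerate fiducials: all source points coincident")
  # cross-covariance; rotation without reflection from its polar angle
  a <- sum(xs * xd)                        # sum x.x' + y.y'
  b <- sum(xs[, 1] * xd[, 2] - xs[, 2] * xd[, 1])  # sum x.y' - y.x'
  theta <- atan2(b, a)
  scale <- sqrt(a^2 + b^2) / var_s
  r <- rot2(theta)
  translation <- as.numeric(mu_d - scale * (r %*% mu_s))
  fitted <- t(scale * r %*% t(src) + translation)
  res <- sqrt(rowSums((dst - fitted)^2))
  structure(list(scale = scale, rotation = theta, translation = translation,
                 rms_residual = sqrt(mean(res^2)), residuals = res),
            class = "similarity_transform")
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Construct a similarity transform directly
#'
#' @param scale positive scale factor.
#' @param rotation rotation angle in radians (counter-clockwise in (x, y)).
#' @param translation length-2 translation (x, y) in pixels.
#' @param rms_residual residual to record (default 0 for exact transforms).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0), rms_residual = 0) {
  stopifnot(scale > 0, length(translation) == 2, rms_residual >= 0)
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation),
                 rms_residual = rms_residual, residuals = numeric(0)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.4f, rotation %.4f rad, t = (%.2f, %.2f), rms %.3f px\n",
              x$scale, x$rotation, x$translation[1], x$translation[2],
              x$rms_residual))
  invisible(x)
}

# forward map of (x, y) points; pts is an n x 2 matrix
transform_points <- function(tf, pts) {
  t(tf$scale * rot2(tf$rotation) %*% t(as.matrix(pts)) + tf$translation)
}

#' Invert a similarity transform
#'
#' @param tf a `similarity_transform`.
#' @return the inverse `similarity_transform`.
#' @export
invert_similarity <- function(tf) {
  r_inv <- rot2(-tf$rotation)
  similarity_transform(scale = 1 / tf$scale, rotation = -tf$rotation,
                       translation = as.numeric(-(r_inv %*% tf$translation) / tf$scale))
}

#' Resample a label mask through a similarity transform
#'
#' Maps a TEM-space label raster onto the XRF pixel grid. Labels are
#' categorical, so resampling is nearest-neighbor through the inverse
#' transform (each destination pixel looks up the source pixel its center
#' maps back to); destination pixels falling outside the source grid get
#' background (0).
#'
#' @param mask a [region_mask()] in source coordinates.
#' @param tf a `similarity_transform` mapping source -> destination pixels.
#' @param target_grid `c(rows, cols)` of the destination grid.
#' @param target_pixel_size_nm pixel pitch of the destination grid; defaults
#'   to the source pitch divided by the transform scale.
#' @return a [region_mask()] on the target grid (same class table).
#' @export
apply_transform <- function(mask, tf, target_grid,
                            target_pixel_size_nm = mask$pixel_size_nm / tf$scale) {
  stopifnot(inherits(mask, "region_mask"),
            inherits(tf, "similarity_transform"),
            all(is.finite(c(tf$scale, tf$rotation, tf$translation))))
  target_grid <- as.integer(target_grid)
  inv <- invert_similarity(tf)
  xy <- cbind(rep(0:(target_grid[2] - 1), each = target_grid[1]),
              rep(0:(target_grid[1] - 1), times = target_grid[2]))
  src_xy <- transform_points(inv, xy)
  sc <- as.integer(round(src_xy[, 1]))  # source column (x)
  sr <- as.integer(round(src_xy[, 2]))  # source row (y)
  inb <- sr >= 0 & sr < nrow(mask$labels) & sc >= 0 & sc < ncol(mask$labels)
  out <- integer(nrow(xy))
  out[inb] <- mask$labels[cbind(sr[inb] + 1L, sc[inb] + 1L)]
  region_mask(matrix(out, target_grid[1], target_grid[2]),
              mask$class_table, target_pixel_size_nm)
}

#' Check alignment quality against the 1-pixel criterion
#'
#' The correlative procedure assumes mask-to-map registration good to about
#' one XRF pixel; this gate fails a transform whose rms fiducial residual
#' exceeds that.
#'
#' @param tf a `similarity_transform` (as returned by
#'   [estimate_similarity()]).
#' @param max_rms acceptance threshold in pixels (default 1).
#' @return list with `pass` (logical), `rms_residual`, `max_rms` and the
#'   per-fiducial `residuals`.
#' @export
check_alignment <- function(tf, max_rms = 1) {
  stopifnot(inherits(tf, "similarity_transform"))
  list(pass = tf$rms_residual <= max_rms,
       rms_residual = tf$rms_residual,
       max_rms = max_rms,
       residuals = tf$residuals)
}
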