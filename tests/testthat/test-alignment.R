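test_that("identical point sets give the identity transform", {
  pts <- cbind(c(0, 5, 9, 2), c(1, 7, 3, 8))
  tf <- estimate_similarity(fiducial_set(pts, pts))
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$rotation, 0, tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0), tolerance = 1e-12)
  expect_equal(tf$rms_residual, 0, tolerance = 1e-12)
})

test_that("constructed rotation + shift is recovered exactly", {
  src <- cbind(c(0, 10, 0, 7, 3), c(0, 0, 8, 5, 9))
  dst <- t(apply(src, 1, function(p) c(-p[2], p[1]) + c(10, -5)))
  tf <- estimate_similarity(fiducial_set(src, dst))
  expect_equal(tf$rotation, pi / 2, tolerance = 1e-12)
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$translation, c(10, -5), tolerance = 1e-10)
  expect_equal(tf$rms_residual, 0, tolerance = 1e-10)
})

test_that("jittered fiducials are recovered within grid-search oracle tolerance", {
  set.seed(41)
  true <- similarity_transform(scale = 1.25, rotation = 0.3,
                               translation = c(12, -4))
  src <- cbind(runif(6, 0, 60), runif(6, 0, 60))
  dst <- nanoxrf:::transform_points(true, src) +
    matrix(rnorm(12, 0, 0.5), 6, 2)
  fid <- fiducial_set(src, dst)
  tf <- estimate_similarity(fid)

  # brute-force grid-search oracle over (scale, rotation); translation by
  # centroid matching at each grid point
  best <- list(rss = Inf)
  for (s in seq(1.1, 1.4, by = 0.005)) {
    for (th in seq(0.1, 0.5, by = 0.005)) {
      r <- nanoxrf:::rot2(th)
      tcand <- colMeans(dst) - s * as.numeric(r %*% colMeans(src))
      fitted <- t(s * r %*% t(src) + tcand)
      rss <- sum((dst - fitted)^2)
      if (rss < best$rss) best <- list(rss = rss, s = s, th = th)
    }
  }
  expect_lt(abs(tf$scale - best$s), 0.005)
  expect_lt(abs(tf$rotation - best$th), 0.005)
  expect_lte(sum(tf$residuals^2), best$rss + 1e-9)  # true LS optimum

  # independent cross-check: vegan's procrustes on the same pairs
  skip_if_not_installed("vegan")
  pr <- vegan::procrustes(dst, src, scale = TRUE, symmetric = FALSE)
  expect_equal(tf$scale, pr$scale, tolerance = 1e-6)
  ang <- atan2(pr$rotation[1, 2], pr$rotation[1, 1])
  expect_equal(abs(tf$rotation), abs(ang), tolerance = 1e-6)
})

test_that("estimation is invariant to fiducial ordering and fails on degenerate input", {
  src <- cbind(c(0, 10, 0, 7), c(0, 0, 8, 5))
  dst <- src * 2 + 3
  tf1 <- estimate_similarity(fiducial_set(src, dst))
  ord <- c(3, 1, 4, 2)
  tf2 <- estimate_similarity(fiducial_set(src[ord, ], dst[ord, ]))
  expect_equal(tf1$scale, tf2$scale)
  expect_equal(tf1$rotation, tf2$rotation)
  expect_equal(tf1$translation, tf2$translation)
  expect_error(fiducial_set(matrix(5, 3, 2), matrix(1, 3, 2)),
               "duplicate source points")
  coincident <- structure(list(src = matrix(5, 3, 2),
                               dst = cbind(c(0, 1, 2), c(0, 1, 2))),
                          class = "fiducial_set")
  expect_error(estimate_similarity(coincident), "degenerate")
})

test_that("composing a transform with its inverse is the identity on points", {
  tf <- similarity_transform(scale = 0.8, rotation = -0.7,
                             translation = c(3.2, -1.1))
  pts <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  back <- nanoxrf:::transform_points(invert_similarity(tf),
                                     nanoxrf:::transform_points(tf, pts))
  expect_equal(back, pts, tolerance = 1e-10)
})

test_that("label resampling conserves areas and never invents labels", {
  lab <- matrix(0L, 30, 30)
  lab[5:12, 6:14] <- 1L; lab[20:25, 18:26] <- 2L
  rm0 <- region_mask(lab, c(nucleus = 1L, cytoplasm = 2L), 50)
  # identity
  expect_identical(apply_transform(rm0, similarity_transform(),
                                   c(30, 30))$labels, lab)
  # pure integer translation shifts exactly, conserving in-bounds areas
  tr <- apply_transform(rm0, similarity_transform(translation = c(3, 2)),
                        c(30, 30))
  expect_equal(sum(tr$labels == 1L), sum(lab == 1L))
  expect_identical(tr$labels[7:14, 9:17], lab[5:12, 6:14])
  # no new labels under arbitrary transforms
  tfr <- similarity_transform(scale = 1.7, rotation = 0.4,
                              translation = c(-2, 5))
  out <- apply_transform(rm0, tfr, c(60, 60))
  expect_true(all(unique(as.vector(out$labels)) %in% c(0L, 1L, 2L)))
})

test_that("scaling a disk by 2 quadruples its area within boundary tolerance", {
  n <- 41
  d2 <- (row(diag(n)) - 21)^2 + (col(diag(n)) - 21)^2
  lab <- matrix(0L, n, n); lab[d2 <= 100] <- 1L
  rm0 <- region_mask(lab, c(granule = 1L), 50)
  out <- apply_transform(rm0, similarity_transform(scale = 2), c(82, 82))
  a0 <- sum(lab == 1L)
  expect_lt(abs(sum(out$labels == 1L) - 4 * a0), 2 * pi * 20 + 8)
})

test_that("the 1-pixel alignment gate passes and fails as specified", {
  expect_true(check_alignment(similarity_transform(rms_residual = 0))$pass)
  expect_false(check_alignment(similarity_transform(rms_residual = 2))$pass)
  # jitter fixture: 0.4 px residuals should pass at the default threshold
  set.seed(42)
  src <- cbind(runif(8, 0, 100), runif(8, 0, 100))
  dst <- src + matrix(rnorm(16, 0, 0.4), 8, 2)
  tf <- estimate_similarity(fiducial_set(src, dst))
  rep <- check_alignment(tf)
  expect_true(rep$pass)
  expect_length(rep$residuals, 8)
})
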