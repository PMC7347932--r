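det <- detector_model(c("Si", "P", "S", "Ca", "Fe", "Zn"))

test_that("sum_spectrum is the channel-wise sum over mask pixels", {
  set.seed(3)
  arr <- array(rpois(4 * 4 * 32, 5), dim = c(4, 4, 32))
  st <- spectrum_stack(arr, gain_kev = 0.3)  # 32 ch x 0.3 keV
  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  sp <- sum_spectrum(st, one)
  expect_equal(sp$counts, as.numeric(arr[2, 3, ]))
  expect_equal(sp$n_pixels, 1L)
  # additivity over disjoint masks
  a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE
  b <- !a
  expect_equal(sum_spectrum(st, a | b)$counts,
               sum_spectrum(st, a)$counts + sum_spectrum(st, b)$counts)
  expect_error(sum_spectrum(st, matrix(FALSE, 4, 4)), "zero pixels")
})

test_that("single-element fit recovers a known area within 3 sigma", {
  set.seed(11)
  y <- rpois(det$n_channels, expected_spectrum(det, c(Fe = 5e4), bg = 5))
  fit <- fit_spectrum(xrf_spectrum(y), "Fe", det)
  fe <- fit_counts(fit, "Fe")
  expect_lt(abs(fe$s - 5e4), 3 * fe$sigma_s)
  expect_gt(fe$sigma_s, 0)
})

test_that("fit of pure background is consistent with zero counts", {
  set.seed(12)
  y <- rpois(det$n_channels, 10)
  fe <- fit_counts(fit_spectrum(xrf_spectrum(y), "Fe", det), "Fe")
  expect_lt(fe$s, 3 * fe$sigma_s)  # amplitudes are clamped at >= 0
})

test_that("overlapping P/S/Ca triple is separated within 3 sigma each", {
  set.seed(13)
  y <- rpois(det$n_channels,
             expected_spectrum(det, c(P = 1e4, S = 1e4, Ca = 1e4), bg = 20))
  fit <- fit_spectrum(xrf_spectrum(y), c("P", "S", "Ca"), det)
  for (el in c("P", "S", "Ca")) {
    r <- fit_counts(fit, el)
    expect_lt(abs(r$s - 1e4), 3 * r$sigma_s, label = el)
  }
  expect_lt(fit$chi2_red, 2)
})

test_that("coincident lines are rejected as a singular design", {
  # same element twice is collapsed; craft two detectors sharing an energy
  expect_error(fit_spectrum(xrf_spectrum(rep(1, det$n_channels)),
                            c("Mn", "Fe"), det), "Mn")
  det2 <- det
  det2$lines$ka_kev[det2$lines$element == "S"] <-
    det2$lines$ka_kev[det2$lines$element == "P"] + 1e-4
  expect_error(fit_spectrum(xrf_spectrum(rep(1, det$n_channels)),
                            c("P", "S"), det2), "singular design")
})

test_that("sum-then-fit equals fit-then-sum on noiseless data", {
  # linear amplitude solve with unit weights: exact additivity
  y1 <- expected_spectrum(det, c(Fe = 200, S = 300), bg = 2)
  y2 <- expected_spectrum(det, c(Fe = 700, S = 100), bg = 2)
  f1 <- fit_counts(fit_spectrum(xrf_spectrum(y1), c("Fe", "S"), det,
                                weights = "none"), "Fe")
  f2 <- fit_counts(fit_spectrum(xrf_spectrum(y2), c("Fe", "S"), det,
                                weights = "none"), "Fe")
  fsum <- fit_counts(fit_spectrum(xrf_spectrum(y1 + y2), c("Fe", "S"), det,
                                  weights = "none"), "Fe")
  expect_equal(fsum$s, f1$s + f2$s, tolerance = 1e-8)
  # N identical pixels scale the amplitude N-fold
  f10 <- fit_counts(fit_spectrum(xrf_spectrum(10 * y1), c("Fe", "S"), det,
                                 weights = "none"), "Fe")
  expect_equal(f10$s, 10 * f1$s, tolerance = 1e-8)
})

test_that("sigma_S shrinks as 1/sqrt(n_pixels) at fixed per-pixel rate", {
  sig_at <- function(n_px) {
    y <- n_px * expected_spectrum(det, c(Fe = 50), bg = 1)
    fit_counts(fit_spectrum(xrf_spectrum(round(y), n_pixels = n_px),
                            "Fe", det), "Fe")$sigma_s
  }
  s1 <- sig_at(100); s2 <- sig_at(400)
  # relative sigma should halve when pixels quadruple
  expect_equal((s1 / (100 * 50)) / (s2 / (400 * 50)), 2, tolerance = 0.05)
})

test_that("per-pixel maps recover a uniform rate and flag empty pixels", {
  set.seed(21)
  det_fe <- detector_model(c("Fe", "S"), n_channels = 512, gain_kev = 0.02)
  maps_in <- list(Fe = element_map(matrix(50, 6, 6), "Fe", 50),
                  S = element_map(matrix(20, 6, 6), "S", 50))
  st <- render_spectra(maps_in, det_fe, seed = 3)
  maps <- per_pixel_maps(st, c("Fe", "S"), det_fe)
  m <- mean(maps$Fe$counts, na.rm = TRUE)
  se <- sd(as.vector(maps$Fe$counts), na.rm = TRUE) / 6
  expect_lt(abs(m - 50), 3 * se)
  # all-zero stack -> all-zero maps
  st0 <- spectrum_stack(array(0L, dim = c(3, 3, 512)), gain_kev = 0.02)
  det0 <- detector_model("Fe", n_channels = 512, gain_kev = 0.02)
  maps0 <- per_pixel_maps(st0, "Fe", det0)
  expect_true(all(maps0$Fe$counts == 0))
})

test_that("snip background option fits a curved continuum", {
  set.seed(31)
  det_snip <- detector_model(c("Fe"), background = "snip")
  e <- nanoxrf:::channel_energies(det_snip)
  curved <- 40 * exp(-e / 3)
  y <- rpois(det_snip$n_channels,
             curved + 2e4 * nanoxrf:::element_profile(det_snip, "Fe"))
  fe <- fit_counts(fit_spectrum(xrf_spectrum(y), "Fe", det_snip), "Fe")
  expect_lt(abs(fe$s - 2e4), 4 * fe$sigma_s)
})
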