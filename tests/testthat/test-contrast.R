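cc <- function(s, n, sigma = sqrt(s), el = "Fe", cl = "cytoplasm") {
  compartment_counts(el, s, sigma, n, compartment = cl, neuron_id = "n1")
}
ref <- function(s, n, sigma = sqrt(s), el = "Fe") {
  compartment_counts(el, s, sigma, n, compartment = "nucleus",
                     neuron_id = "n1")
}

test_that("delta and sigma_delta follow the count-rate contrast formulas", {
  # equal rates -> Delta = 0
  expect_equal(delta(cc(200, 100), ref(100, 50))$delta, 0)
  # direct substitution: S_i=200,N_i=100 vs S_n=100,N_n=100
  d <- delta(cc(200, 100), ref(100, 100))
  expect_equal(d$delta, 1.0)
  expect_equal(d$sigma_delta, 2 * sqrt(1 / 200 + 1 / 100), tolerance = 1e-12)
  expect_equal(d$sigma_delta, 0.2449, tolerance = 1e-3)
})

test_that("zero-count compartments follow the stated conventions", {
  expect_error(delta(cc(10, 5), ref(0, 5)), "zero counts")
  d <- delta(cc(0, 5, sigma = NA), ref(100, 5))
  expect_equal(d$delta, -1)
  expect_true(d$zero_counts_flag)
  expect_true(is.na(d$sigma_delta))
  expect_error(delta(cc(10, 5, el = "Fe"), ref(10, 5, el = "Zn")),
               "different elements")
})

test_that("antisymmetry: (Delta_in + 1)(Delta_ni + 1) = 1", {
  set.seed(7)
  for (k in 1:20) {
    a <- cc(rpois(1, 500) + 1, sample(50:200, 1))
    b <- ref(rpois(1, 300) + 1, sample(50:200, 1))
    expect_equal((delta(a, b)$delta + 1) * (delta(b, a)$delta + 1), 1,
                 tolerance = 1e-12)
  }
})

test_that("scaling behavior of delta and its uncertainty", {
  a <- cc(400, 100); b <- ref(300, 150)
  d0 <- delta(a, b)
  # multiply all S and sigma_S by c: Delta unchanged, sigma unchanged
  sc <- 7
  d1 <- delta(cc(400 * sc, 100, sigma = sc * sqrt(400)),
              ref(300 * sc, 150, sigma = sc * sqrt(300)))
  expect_equal(d1$delta, d0$delta)
  expect_equal(d1$sigma_delta, d0$sigma_delta)
  # with Poisson sigma = sqrt(S), sigma_delta shrinks as 1/sqrt(c)
  d2 <- delta(cc(400 * sc, 100), ref(300 * sc, 150))
  expect_equal(d2$delta, d0$delta)
  expect_equal(d2$sigma_delta, d0$sigma_delta / sqrt(sc), tolerance = 1e-12)
})

test_that("aggregation applies the 30% filter and triplicate rule", {
  mk <- function(d, rel) {
    structure(list(delta = d, sigma_delta = rel * abs(d), element = "Fe",
                   compartment = "cytoplasm", reference = "nucleus",
                   neuron_id = "x", n_pixels_i = 10L, n_pixels_n = 10L,
                   zero_counts_flag = FALSE), class = "contrast_result")
  }
  agg <- aggregate_contrast(list(mk(0.60, 0.1), mk(0.70, 0.1), mk(0.68, 0.1)))
  expect_true(agg$reportable)
  expect_equal(agg$mean_delta, 0.66)
  expect_equal(agg$sd_delta, sd(c(0.60, 0.70, 0.68)))
  expect_equal(agg$sd_delta, 0.053, tolerance = 1e-2)
  # one imprecise entry drops the set below triplicate
  agg2 <- aggregate_contrast(list(mk(0.60, 0.1), mk(0.70, 0.1),
                                  mk(0.65, 0.5)))
  expect_false(agg2$reportable)
  expect_equal(agg2$n_included, 2L)
  expect_match(agg2$exclusion_reasons, "relative uncertainty")
  # negative contrasts survive the |Delta| filter
  agg3 <- aggregate_contrast(list(mk(-0.4, 0.1), mk(-0.5, 0.1),
                                  mk(-0.45, 0.1)))
  expect_true(agg3$reportable)
  expect_lt(agg3$mean_delta, 0)
  # empty input
  agg4 <- aggregate_contrast(list())
  expect_false(agg4$reportable)
  expect_equal(agg4$n_included, 0L)
  # mixed pairs error
  bad <- mk(0.5, 0.1); bad$compartment <- "RER"
  expect_error(aggregate_contrast(list(mk(0.5, 0.1), bad)), "mix")
})

test_that("uniform Si channel gives contrasts consistent with zero", {
  # Si membrane is spatially uniform: internal control
  spec <- phantom_preset("neuron-ctrl", grid_shape = c(96, 96), seed = 31,
                         granules = NULL)
  ph <- generate_phantom(spec)
  masks <- ph$truth$masks
  refm <- nuclear_reference_mask(masks)
  n <- compartment_counts_from_map(ph$maps$Si, refm, class = "nucleus")
  for (cl in c("cytoplasm", "nucleolus")) {
    d <- delta(compartment_counts_from_map(ph$maps$Si,
                                           mask_binary(masks, cl),
                                           class = cl), n)
    expect_lt(abs(d$delta), 3 * d$sigma_delta, label = paste("Si", cl))
  }
})

test_that("contrast_table exports one tidy row per measurement", {
  a <- delta(cc(400, 100), ref(300, 150))
  b <- delta(cc(0, 5, sigma = NA), ref(100, 5))
  tab <- contrast_table(list(a, b))
  expect_equal(nrow(tab), 2)
  expect_true(tab$included_flag[1])
  expect_false(tab$included_flag[2])
  expect_equal(tab$exclusion_reason[2], "missing sigma_delta")
  expect_named(tab, c("element", "compartment", "reference", "delta",
                      "sigma_delta", "n_pixels", "neuron_id",
                      "included_flag", "exclusion_reason"))
})
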