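flat_map <- function(value, grid = c(100, 100), el = "Fe") {
  element_map(matrix(value, grid[1], grid[2]), el, 50)
}

test_that("a constructed hot block is found with the exact k-sigma threshold", {
  m <- matrix(100, 100, 100)
  m[50:52, 50:52] <- 500
  fe <- element_map(m, "Fe", 50)
  s <- flat_map(100, el = "S")
  labels <- detect_granules(fe, s, matrix(TRUE, 100, 100))
  # brute-force threshold: stats computed over all cytoplasm pixels,
  # hot block included
  thr <- mean(m) + 2 * sd(as.vector(m))
  expect_equal(unname(attr(labels, "thresholds")["Fe"]), thr)
  expect_equal(thr, 124.35, tolerance = 1e-3)
  expect_equal(max(labels), 1L)
  expect_equal(sum(labels == 1L), 9L)
  expect_equal(attr(labels, "enriched_element"), "Fe")
})

test_that("detection input contracts are enforced", {
  fe <- flat_map(10); s <- flat_map(10, el = "S")
  expect_error(detect_granules(fe, s, matrix(FALSE, 100, 100)),
               "empty cytoplasm")
  expect_error(detect_granules(fe, s, matrix(TRUE, 100, 100), k = 0),
               "k must be > 0")
})

test_that("detection is invariant under global rescaling of a map", {
  set.seed(9)
  base <- matrix(rpois(2500, 50), 50, 50)
  base[20:22, 20:22] <- 400
  cyto <- matrix(TRUE, 50, 50)
  s <- flat_map(10, c(50, 50), "S")
  l1 <- detect_granules(element_map(base, "Fe", 50), s, cyto)
  l2 <- detect_granules(element_map(base * 13, "Fe", 50), s, cyto)
  expect_identical(as.vector(l1), as.vector(l2))
})

test_that("inserted phantom granules are all recovered with faithful areas", {
  # 10 granules of radius >= 2 px at ~5x the cytoplasmic background
  g <- granule_spec(n = 10, radius_nm = c(110, 160),
                    core_rates = c(S = 120, Fe = 120), rim_rates = NULL)
  spec <- two_compartment_spec(c(Fe = 30, S = 30), c(Fe = 30, S = 30),
                               grid = c(128, 128), seed = 23, granules = g)
  ph <- generate_phantom(spec)
  cyto <- mask_binary(ph$truth$masks, "cytoplasm")
  labels <- detect_granules(ph$maps$Fe, ph$maps$S, cyto)
  gt <- ph$truth$granule_table
  found <- 0
  for (i in seq_len(nrow(gt))) {
    lab <- labels[gt$center_row[i] + 1, gt$center_col[i] + 1]
    if (lab > 0) {
      found <- found + 1
      n_det <- sum(labels == lab)
      perim <- 2 * pi * gt$radius_px[i] + 4
      expect_lt(abs(n_det - gt$n_core_px[i]), perim)
    }
  }
  expect_equal(found, 10)
  # labels are disjoint, within the cytoplasm
  expect_true(all(cyto[labels > 0]))
})

test_that("granule measurements: area, conservation and morphology ordering", {
  m <- matrix(100, 60, 60)
  fe <- m; s <- m
  # granule 1: 9 px uniform in both
  fe[10:12, 10:12] <- 600; s[10:12, 10:12] <- 600
  # granule 2: S-rich core with Fe-rich rim (5x5 with 3x3 core)
  s[30:34, 30:34] <- 300; s[31:33, 31:33] <- 800
  fe[30:34, 30:34] <- 900; fe[31:33, 31:33] <- 150
  cyto <- matrix(TRUE, 60, 60)
  maps <- list(Fe = element_map(fe, "Fe", 50), S = element_map(s, "S", 50),
               Si = element_map(matrix(400, 60, 60), "Si", 50))
  labels <- detect_granules(maps$Fe, maps$S, cyto)
  expect_equal(max(labels), 2L)
  rec <- measure_granules(labels, maps, cyto, std = calibration_standard())
  rec <- rec[order(rec$centroid_row), ]
  # 9 px at 50 nm -> 0.0225 um^2, small class
  expect_equal(rec$area_um2[1], 9 * 0.05^2)
  expect_equal(rec$size_class[1], "small")
  expect_equal(rec$n_px[2], 25)
  expect_equal(rec$size_class[2], "small")  # 0.0625 < 0.07
  # rim/core granule: Fe more heterogeneous than S
  expect_gt(rec$fe_rsd[2], rec$s_rsd[2])
  # uniform granule: near-zero relative spread
  expect_equal(rec$fe_rsd[1], 0)
  # conservation: granule + background counts = cytoplasm counts, exactly
  expect_identical(rec$fe_counts[1] + rec$fe_counts[2] +
                     sum(fe[cyto & labels == 0]), sum(fe[cyto]))
  # background ratios exceed 1 for enriched granules
  expect_gt(rec$fe_over_bgd[1], 1)
  # Fe/S mass ratio defined and positive
  expect_true(all(rec$fe_s_ratio > 0))
})

test_that("zero-S granules keep an undefined Fe/S ratio but are retained", {
  fe <- matrix(100, 40, 40); fe[5:7, 5:7] <- 900
  s <- matrix(0, 40, 40)
  maps <- list(Fe = element_map(fe, "Fe", 50), S = element_map(s, "S", 50))
  labels <- detect_granules(maps$Fe, maps$S, matrix(TRUE, 40, 40))
  rec <- measure_granules(labels, maps, matrix(TRUE, 40, 40))
  expect_equal(nrow(rec), 1)
  expect_true(is.na(rec$fe_s_ratio))
})

test_that("summaries split sizes at 0.07 um^2 and order conditions correctly", {
  rec <- data.frame(id = 1:3, condition = "CTRL", n_px = c(8, 16, 36),
                    area_um2 = c(0.02, 0.04, 0.09),
                    size_class = c("small", "small", "large"),
                    fe_counts = 1, s_counts = 1, fe_am = 1, s_am = 1,
                    fe_s_ratio = c(0.1, 0.2, 0.3),
                    fe_over_bgd = c(1.5, 2, 2.5),
                    s_over_bgd = c(2, 2, 2), fe_rsd = 0.1, s_rsd = 0.1,
                    centroid_row = 0, centroid_col = 0,
                    enriched_element = "Fe")
  sm <- summarize_granules(rec)
  all_row <- sm[sm$size_class == "all", ]
  expect_equal(all_row$n, 3)
  expect_equal(all_row$mean_area_um2, 0.05)
  expect_equal(sm$n[sm$size_class == "small"], 2)
  expect_equal(sm$n[sm$size_class == "large"], 1)
  # empty condition gives an n = 0 summary, not an error
  sm0 <- summarize_granules(rec[0, ])
  expect_equal(sm0$n[1], 0)
})

test_that("asyn-like phantom granules are larger, more Fe-rich and more heterogeneous", {
  run_one <- function(preset, cond, seed) {
    spec <- phantom_preset(preset, grid_shape = c(160, 160), seed = seed)
    ph <- generate_phantom(spec)
    cyto <- mask_binary(ph$truth$masks, "cytoplasm")
    labels <- detect_granules(ph$maps$Fe, ph$maps$S, cyto)
    measure_granules(labels, ph$maps, cyto, std = calibration_standard(),
                     condition = cond)
  }
  rec <- rbind(run_one("neuron-ctrl", "CTRL", 51),
               run_one("neuron-asyn", "ASYN", 52))
  sm <- summarize_granules(rec)
  ctrl <- sm[sm$condition == "CTRL" & sm$size_class == "all", ]
  asyn <- sm[sm$condition == "ASYN" & sm$size_class == "all", ]
  expect_gt(asyn$mean_fe_s_ratio, ctrl$mean_fe_s_ratio)
  expect_gt(asyn$mean_area_um2, ctrl$mean_area_um2)
  # across-granule Fe variability increases under overexpression while the
  # S variability stays comparable between conditions
  expect_gt(asyn$rel_sd_fe, ctrl$rel_sd_fe)
  expect_lt(abs(asyn$rel_sd_s - ctrl$rel_sd_s), 0.5)
})

test_that("co-localization fractions are in [0,1] and flag unmatched granules", {
  labels <- matrix(0L, 30, 30)
  labels[5:8, 5:8] <- 1L    # overlaps lipofuscin
  labels[20:22, 20:22] <- 2L  # matches nothing
  tem <- matrix(0L, 30, 30); tem[4:9, 4:9] <- 1L
  tm <- region_mask(tem, c(lipofuscin = 1L), 50)
  co <- colocalize_granules(labels, tm)
  expect_true(all(co$overlap_fraction >= 0 & co$overlap_fraction <= 1))
  expect_true(co$colocalized[1])
  expect_false(co$colocalized[2])
})

test_that("8-connected labelling joins diagonals; 4-connected does not", {
  b <- matrix(FALSE, 5, 5)
  b[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE
  expect_equal(max(label_components(b, 8L)), 1L)
  expect_equal(max(label_components(b, 4L)), 3L)
})
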