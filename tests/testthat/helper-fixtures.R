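# Shared fixtures, all generated in code.

# small two-compartment phantom spec: concentric "nucleus" in "cytoplasm"
# with explicit rates; no organelles, optional granules
two_compartment_spec <- function(rates_nucleus, rates_cytoplasm,
                                 grid = c(96, 96), seed = 1L,
                                 granules = NULL) {
  cen <- (grid - 1) / 2
  shapes <- list(
    list(class = "neuropil", type = "background"),
    list(class = "cytoplasm", type = "ellipse", center = cen,
         radii = 0.42 * grid, theta = 0),
    list(class = "nucleus", type = "ellipse", center = cen,
         radii = 0.18 * grid, theta = 0)
  )
  phantom_spec(grid_shape = grid, pixel_size_nm = 50,
               compartments = shapes,
               composition = list(neuropil = rates_cytoplasm,
                                  cytoplasm = rates_cytoplasm,
                                  nucleus = rates_nucleus),
               granules = granules, seed = seed)
}

# uniform single-class spec over the whole grid
uniform_spec <- function(rates, grid = c(64, 64), seed = 1L) {
  phantom_spec(grid_shape = grid, pixel_size_nm = 50,
               compartments = list(list(class = "neuropil",
                                        type = "background")),
               composition = list(neuropil = rates), seed = seed)
}

# noiseless synthetic spectrum with given element areas + flat background
expected_spectrum <- function(det, areas, bg = 0) {
  y <- rep(bg, det$n_channels)
  for (el in names(areas)) {
    y <- y + areas[[el]] * nanoxrf:::element_profile(det, el)
  }
  y
}
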