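#' Assemble a run configuration
#'
#' A single configuration object drives the end-to-end analysis. Inputs may
#' be pre-fitted element maps (a directory of TIFF + JSON pairs) or a full
#' spectrum stack to be fitted per pixel. The calibration standard is
#' optional: without it the contrast stage still runs and the ppm/areal-mass
#' columns are simply absent.
#'
#' @param maps_dir directory of element-map TIFFs (one per element), or NULL.
#' @param stack_path spectrum-stack TIFF (used when `maps_dir` is NULL).
#' @param mask_path label-mask TIFF of compartment classes (TEM-derived or
#'   phantom truth).
#' @param fiducials_path CSV of fiducial pairs for TEM -> XRF registration,
#'   or NULL when the mask is already on the XRF grid.
#' @param standard_path calibration-standard JSON, or NULL; `NA` selects the
#'   packaged synthetic record.
#' @param elements elements to analyze (and to fit, when starting from a
#'   stack).
#' @param scan_mode pixel-pitch preset: `"coarse"` (400 nm), `"fine"`
#'   (50 nm), `"very-fine"` (25 nm); informational, the rasters' sidecars
#'   are authoritative.
#' @param k granule-threshold stringency in SD units.
#' @param t_cm section thickness in cm (default 500 nm).
#' @param rho_g_cm3 section density (default 1).
#' @param max_rms alignment gate in pixels (default 1).
#' @param seed integer seed for any stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return a `run_config` list.
#' @export
run_config <- function(maps_dir = NULL, stack_path = NULL, mask_path,
                       fiducials_path = NULL, standard_path = NA,
                       elements = c("Si", "P", "S", "Ca", "Fe", "Zn"),
                       scan_mode = c("fine", "coarse", "very-fine"),
                       k = 2, t_cm = 5e-5, rho_g_cm3 = 1, max_rms = 1,
                       seed = 1L, out_dir) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(k > 0, t_cm > 0, rho_g_cm3 > 0)
  if (is.null(maps_dir) && is.null(stack_path)) {
    stop("either maps_dir or stack_path must be given")
  }
  for (p in c(maps_dir, stack_path, mask_path, fiducials_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  }
  if (!is.null(standard_path) && !is.na(standard_path) &&
      !file.exists(standard_path)) {
    stop("input does not exist: ", standard_path)
  }
  structure(list(maps_dir = maps_dir, stack_path = stack_path,
                 mask_path = mask_path, fiducials_path = fiducials_path,
                 standard_path = standard_path, elements = elements,
                 scan_mode = scan_mode, k = k, t_cm = t_cm,
                 rho_g_cm3 = rho_g_cm3, max_rms = max_rms,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

pipeline_log <- function(lines, log_path) {
  stamp <- format(Sys.time(), "%H:%M:%S")
  for (l in lines) {
    message("[nanoxrf ", stamp, "] ", l)
    cat("[", stamp, "] ", l, "\n", file = log_path, sep = "", append = TRUE)
  }
}

#' Run the full analysis pipeline
#'
#' Map ingest (or per-pixel fit) -> mask registration -> compartment counting
#' -> contrasts vs the nuclear reference -> areal-mass/ppm quantification ->
#' granule detection and measurement. Writes tidy CSVs, a granule label
#' TIFF, a log and a reproducibility manifest under `config$out_dir`. A
#' stage failure aborts with the stage name; inputs are never mutated.
#'
#' @param config a [run_config()].
#' @return named list of the main tables (`contrasts`, `quantities`,
#'   `granules`, `granule_summary`) plus `manifest`, invisibly-written to
#'   disk as side effect.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  warnings_seen <- character(0)
  note <- function(...) pipeline_log(paste0(...), log_path)
  stage <- function(name, expr) {
    note("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  maps <- stage("ingest", {
    if (!is.null(config$maps_dir)) {
      tifs <- list.files(config$maps_dir, pattern = "\\.tiff?$",
                         full.names = TRUE)
      tifs <- tifs[!grepl("mask|labels|stack", basename(tifs))]
      ms <- lapply(tifs, read_element_map)
      stats::setNames(ms, vapply(ms, `[[`, "", "element"))
    } else {
      stack <- read_spectrum_stack(config$stack_path)
      per_pixel_maps(stack, config$elements, detector_model(config$elements))
    }
  })
  maps <- maps[intersect(config$elements, names(maps))]
  if (length(maps) == 0) stop("pipeline stage 'ingest' failed: no element maps")

  masks <- stage("alignment", {
    m <- read_region_mask(config$mask_path)
    if (!is.null(config$fiducials_path)) {
      fid <- read_fiducials(config$fiducials_path)
      tf <- estimate_similarity(fid)
      rep <- check_alignment(tf, config$max_rms)
      note(sprintf("similarity: scale %.4f rot %.4f rad rms %.3f px (%s)",
                   tf$scale, tf$rotation, tf$rms_residual,
                   if (rep$pass) "pass" else "FAIL"))
      if (!rep$pass) {
        warnings_seen <- c(warnings_seen,
                            sprintf("alignment rms %.3f px exceeds %.1f px",
                                    tf$rms_residual, config$max_rms))
      }
      apply_transform(m, tf, dim(maps[[1]]$counts))
    } else m
  })

  std <- stage("calibration", {
    if (is.null(config$standard_path)) {
      warnings_seen <- c(warnings_seen,
                          "no calibration standard: areal masses and ppm not computed")
      note("no calibration standard configured; skipping quantification")
      NULL
    } else if (is.na(config$standard_path)) {
      calibration_standard()
    } else {
      calibration_standard(config$standard_path)
    }
  })

  contrasts <- stage("contrast", {
    ref_mask <- nuclear_reference_mask(masks)
    if (!any(ref_mask)) stop("nuclear reference mask is empty")
    classes <- setdiff(names(masks$class_table), "nucleus")
    res <- list()
    for (el in names(maps)) {
      n_ref <- compartment_counts_from_map(maps[[el]], ref_mask,
                                           class = "nucleus")
      for (cl in classes) {
        bin <- mask_binary(masks, cl)
        if (!any(bin)) next
        ci <- compartment_counts_from_map(maps[[el]], bin, class = cl)
        res <- c(res, list(delta(ci, n_ref)))
      }
    }
    res
  })
  contrast_df <- contrast_table(contrasts)
  utils::write.csv(contrast_df, file.path(config$out_dir, "contrasts.csv"),
                   row.names = FALSE)

  quant_df <- NULL
  if (!is.null(std)) {
    quant_df <- stage("quantify", {
      if (!"Si" %in% names(maps)) {
        stop("internal Si standard absent (no Si map)")
      }
      rows <- list()
      for (cl in names(masks$class_table)) {
        bin <- if (cl == "nucleus") nuclear_reference_mask(masks) else
          mask_binary(masks, cl)
        if (!any(bin)) next
        s_si <- sum(maps[["Si"]]$counts[bin], na.rm = TRUE)
        for (el in setdiff(names(maps), "Si")) {
          s <- sum(maps[[el]]$counts[bin], na.rm = TRUE)
          q <- areal_mass(s, s_si, std, el)
          rows <- c(rows, list(
            data.frame(compartment = cl, element = el, n_px = sum(bin),
                       s = s, am_ng_cm2 = q$am, eps_ng_cm2 = q$eps,
                       eps_pct = 100 * q$eps_rel,
                       c_ppm = to_ppm(q$am, config$t_cm, config$rho_g_cm3))))
        }
      }
      do.call(rbind, rows)
    })
    utils::write.csv(quant_df, file.path(config$out_dir, "quantities.csv"),
                     row.names = FALSE)
  }

  granule_df <- granule_summary <- NULL
  if (all(c("Fe", "S") %in% names(maps)) &&
      "cytoplasm" %in% names(masks$class_table)) {
    gran <- stage("granules", {
      cyto <- mask_binary(masks, "cytoplasm")
      labels <- detect_granules(maps[["Fe"]], maps[["S"]], cyto,
                                k = config$k)
      rec <- measure_granules(labels, maps, cyto, std = std)
      list(labels = labels, records = rec)
    })
    granule_df <- gran$records
    granule_summary <- summarize_granules(granule_df)
    utils::write.csv(granule_df, file.path(config$out_dir, "granules.csv"),
                     row.names = FALSE)
    utils::write.csv(granule_summary,
                     file.path(config$out_dir, "granule_summary.csv"),
                     row.names = FALSE)
    gl <- pmin(gran$labels, 255L)
    write_region_mask(region_mask(gl,
                                  stats::setNames(seq_len(max(1, max(gl))),
                                                  paste0("granule_",
                                                         seq_len(max(1, max(gl))))),
                                  maps[[1]]$pixel_size_nm),
                      file.path(config$out_dir, "granule_labels.tif"))
    note(sprintf("granules: %d detected", nrow(granule_df)))
  } else {
    note("granule stage skipped (needs Fe and S maps and a cytoplasm class)")
  }

  manifest <- stage("manifest", {
    cfg_json <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(config)[order(names(unclass(config)))],
                         cfg_json, auto_unbox = TRUE, null = "null")
    man <- list(
      package_version = as.character(utils::packageVersion("nanoxrf")),
      config = unclass(config),
      config_md5 = unname(tools::md5sum(cfg_json)),
      seed = config$seed,
      records = list(contrasts = nrow(contrast_df),
                     quantities = if (is.null(quant_df)) 0L else nrow(quant_df),
                     granules = if (is.null(granule_df)) 0L else nrow(granule_df)),
      warnings = warnings_seen)
    path <- file.path(config$out_dir, "manifest.json")
    tmp <- paste0(path, ".tmp")
    jsonlite::write_json(man, tmp, auto_unbox = TRUE, null = "null")
    file.rename(tmp, path)  # atomic publish at run end
    man
  })
  note("done")
  invisible(list(contrasts = contrast_df, quantities = quant_df,
                 granules = granule_df, granule_summary = granule_summary,
                 manifest = manifest))
}

#' Write a phantom dataset in the formats the pipeline reads
#'
#' Generates a phantom (from a [phantom_spec()] or a [phantom_preset()]
#' name), and writes element-map TIFFs, the truth label mask, a small set of
#' exact corner fiducials and, optionally, a rendered spectrum stack.
#'
#' @param spec a [phantom_spec()] or a preset name string.
#' @param out_dir output directory.
#' @param seed overrides the spec seed when not NULL.
#' @param write_spectra also render and write a full spectrum stack
#'   (memory-heavy for large grids; default FALSE).
#' @param ... passed to [phantom_preset()] when `spec` is a name.
#' @return list with `paths` (named vector) and `truth`, invisibly.
#' @export
simulate_bundle <- function(spec, out_dir, seed = NULL,
                            write_spectra = FALSE, ...) {
  if (is.character(spec)) spec <- phantom_preset(spec, ...)
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(spec)
  paths <- c()
  for (el in names(ph$maps)) {
    p <- file.path(out_dir, paste0("map_", el, ".tif"))
    write_element_map(ph$maps[[el]], p)
    paths[paste0("map_", el)] <- p
  }
  p <- file.path(out_dir, "mask_truth.tif")
  write_region_mask(ph$truth$masks, p)
  paths["mask"] <- p
  gs <- spec$grid_shape
  corners <- cbind(c(2, gs[2] - 3, 2, gs[2] - 3),
                   c(2, 2, gs[1] - 3, gs[1] - 3))
  fid <- fiducial_set(corners, corners)
  paths["fiducials"] <- write_fiducials(fid,
                                        file.path(out_dir, "fiducials.csv"))
  if (!is.null(ph$truth$granule_table)) {
    utils::write.csv(ph$truth$granule_table,
                     file.path(out_dir, "granule_truth.csv"),
                     row.names = FALSE)
    paths["granule_truth"] <- file.path(out_dir, "granule_truth.csv")
  }
  if (write_spectra) {
    det <- detector_model(names(ph$maps))
    stack <- render_spectra(ph$maps, det, seed = spec$seed)
    paths["stack"] <- write_spectrum_stack(stack,
                                           file.path(out_dir, "stack.tif"))
  }
  invisible(list(paths = paths, truth = ph$truth, spec = spec))
}
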