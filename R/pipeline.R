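#' Default pipeline configuration
#'
#' A single nested list (serialisable to YAML) holding every tolerance and
#' threshold the pipeline stages consume, with per-stage seeds derived from
#' one root seed so each stage can be replayed on its own.
#'
#' @param root_seed integer root seed.
#' @param out_dir artifact output directory (`NULL` = nothing written).
#' @return A `pipeline_config` list.
#' @export
default_config <- function(root_seed = 1L, out_dir = NULL) {
  structure(list(
    root_seed = root_seed,
    out_dir = out_dir,
    design = list(origins = 6L, fruit_per_origin = 10L,
                  regions_per_fruit = 10L),
    raster = list(shape = c(160L, 160L), mm_per_px = 1.0),
    noise_frac = 0.01,
    preprocess = list(window_len = 11L, poly_order = 2L,
                      lo = 420, hi = 1600, boundary = 1000),
    availability = list(spec = "dense"),
    selection = list(top_n = 20L, r_threshold = 0.8, max_keep = 6L,
                     stale_limit = 5L, k_neighbors = 10L),
    mlp = list(lr = 0.3, max_val_fail = 15L, mse_goal = 1e-4,
               max_epochs = 500L, n_hidden = 4L, n_replicates = 20L),
    registration = list(jitter_sd = 0.5),
    map = list(threshold_method = "fixed", threshold = 0.2,
               threshold_high = 0.8),
    n_map_fruit = 2L
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_into(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  out <- merge_into(unclass(base), cfg)
  class(out) <- "pipeline_config"
  out
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[chemmap:%s] %s", stage, paste0(..., collapse = "")))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages end to end: simulate (reference table, availability,
#' ROI spectra through the forward optics model), preprocess (smoothing,
#' trimming, dual-sensor fusion), register (landmark scene for one slice,
#' all three transform families, best-family selection), select
#' (both wavelength-selection procedures for each of the four traits and
#' both modalities), calibrate (replicate MLPs on the winning sets), and
#' map (pixel-wise prediction for held-out validation fruit with
#' region-wise errors and Tukey letters). Only calibration and
#' cross-validation rows ever reach wavelength selection and model
#' training; validation fruit influence nothing upstream of the final
#' evaluation.
#'
#' @param config a [default_config()]-style list.
#' @param traits traits to calibrate (default all four).
#' @param quiet suppress stage log messages.
#' @return A list with per-stage artifacts: `reference`, `availability`,
#'   `spectra`, `plan`, `registration`, `selections`, `models`, `maps`,
#'   `region_errors`, `report`.
#' @export
run_pipeline <- function(config = default_config(),
                         traits = c("mc", "ssc", "ta", "cc"),
                         quiet = FALSE) {
  log_ <- if (quiet) function(...) invisible() else pipeline_log
  tcol <- trait_columns()

  # --- simulate ----------------------------------------------------------
  seed_sim <- derive_seed(config$root_seed, "simulate")
  log_("simulate", "seed ", seed_sim)
  ref <- generate_reference_table(design = config$design, seed = seed_sim)
  avail <- if (identical(config$availability$spec, "dense")) {
    generate_availability_table("dense")
  } else {
    generate_availability_table("sparse",
                                seed = derive_seed(config$root_seed,
                                                   "availability"))
  }
  optics <- optics_model(noise_frac = config$noise_frac)

  # per-ROI spectra through the forward model on each sensor's native grid,
  # with spectral noise emulating the pixel-binned acquisition
  chem <- list(mc = ref$mc_pct, ssc = ref$ssc_pct, ta = ref$ta_gpct,
               cc = ref$cc_mg100gdm)
  make_sensor_spectra <- function(sensor) {
    wl <- sensor_grid(sensor)
    R <- forward_reflectance(optics, chem, wl)
    with_seed(derive_seed(config$root_seed, paste0("spectra_", sensor)), {
      sdv <- rep(config$noise_frac * 0.2, length(wl))
      edge <- wl < 420 | wl > 1600
      sdv[edge] <- sdv[edge] * optics$edge_inflation
      R <- R + matrix(stats::rnorm(length(R), 0,
                                   rep(sdv, each = nrow(R))),
                      nrow(R))
    })
    colnames(R) <- sprintf("r%04d", wl)
    attr(R, "wavelengths") <- wl
    R
  }
  vis_raw <- make_sensor_spectra("vis")
  nir_raw <- make_sensor_spectra("nir")

  # --- preprocess --------------------------------------------------------
  log_("preprocess", "smoothing window ", config$preprocess$window_len)
  vis_s <- smooth_savitzky_golay(vis_raw, config$preprocess$window_len,
                                 config$preprocess$poly_order)
  nir_s <- smooth_savitzky_golay(nir_raw, config$preprocess$window_len,
                                 config$preprocess$poly_order)
  attr(vis_s, "wavelengths") <- attr(vis_raw, "wavelengths")
  attr(nir_s, "wavelengths") <- attr(nir_raw, "wavelengths")
  spectra <- fuse_sensors(vis_s, nir_s,
                          boundary = config$preprocess$boundary,
                          lo = config$preprocess$lo,
                          hi = config$preprocess$hi)

  # --- register (demonstration on one slice) -----------------------------
  seed_reg <- derive_seed(config$root_seed, "register")
  fruit1 <- ref[ref$origin == 1 & ref$fruit == 1, ]
  field1 <- generate_chemistry_field(fruit1, config$raster$shape,
                                     config$raster$mm_per_px)
  true_T <- transform2d(matrix(c(1.02, 0.05, 3.0,
                                 -0.03, 0.98, -2.0,
                                 0, 0, 1), 3, 3, byrow = TRUE), "affine")
  scene <- generate_landmark_scene(field1, true_T,
                                   jitter_sd = config$registration$jitter_sd,
                                   seed = seed_reg)
  reports <- lapply(c("nonreflective_similarity", "affine", "projective"),
                    function(k) {
                      Tk <- fit_transform(scene$control$src,
                                          scene$control$dst, k)
                      registration_errors(Tk, scene$control, scene$check)
                    })
  best_kind <- select_best_transform(reports)
  log_("register", "best transform: ", best_kind)

  # --- partition + select ------------------------------------------------
  plan <- partition_dataset(ref, seed = derive_seed(config$root_seed,
                                                    "partition"))
  train_rows <- which(plan$assignment != "validation")
  sel_cfg <- config$selection
  selections <- list()
  for (t in traits) {
    yt <- chem[[t]]
    for (mod in c("filter", "light_source")) {
      for (meth in c("rank", "subset")) {
        res <- select_wavelengths(
          spectra[train_rows, , drop = FALSE], yt[train_rows],
          avail, modality = mod, method = meth,
          top_n = sel_cfg$top_n, r_threshold = sel_cfg$r_threshold,
          max_keep = sel_cfg$max_keep, stale_limit = sel_cfg$stale_limit,
          k_neighbors = sel_cfg$k_neighbors)
        res$composition <- t
        selections[[paste(t, mod, meth, sep = ".")]] <- res
      }
    }
  }
  log_("select", length(selections), " selection results")

  # --- calibrate ---------------------------------------------------------
  models <- list()
  metrics <- list()
  for (t in traits) {
    sets <- unique(lapply(
      selections[grep(paste0("^", t, "\\."), names(selections))],
      function(s) s$wavelengths))
    names(sets) <- vapply(sets, function(s)
      paste(sub("^r0*", "", s), collapse = "+"), character(1))
    rs <- replicate_and_select(
      sets, spectra, chem[[t]], plan,
      n_replicates = config$mlp$n_replicates,
      hyper = config$mlp[c("lr", "max_val_fail", "mse_goal", "max_epochs")],
      n_hidden = config$mlp$n_hidden,
      seed = derive_seed(config$root_seed, paste0("mlp_", t)),
      evaluate_validation = TRUE)
    models[[t]] <- rs$best_model
    metrics[[t]] <- rs$metrics
    log_("calibrate", t, ": best set ", rs$best_set)
  }

  # --- map validation fruit ----------------------------------------------
  n_map <- min(config$n_map_fruit, nrow(plan$validation_fruit))
  map_fruit <- plan$validation_fruit[seq_len(n_map), ]
  maps <- list(); roi_masks <- list()
  region_errors <- list()
  for (i in seq_len(n_map)) {
    o <- map_fruit$origin[i]; fnum <- map_fruit$fruit[i]
    key <- paste(o, fnum, sep = "_")
    rowsf <- ref[ref$origin == o & ref$fruit == fnum, ]
    fieldf <- generate_chemistry_field(rowsf, config$raster$shape,
                                       config$raster$mm_per_px)
    # render both sensors noiselessly at map scale, calibrate and fuse
    cubes <- lapply(c("vis", "nir"), function(sn) {
      g <- generate_hypercube(fieldf, optics, sn,
                              seed = derive_seed(config$root_seed,
                                                 paste0("cube_", key, sn)),
                              noise_frac = config$noise_frac)
      calibrate_reflectance(g$raw, g$white, g$black)
    })
    flat_v <- flatten_hypercube(cubes[[1]])
    flat_n <- flatten_hypercube(cubes[[2]])
    flat <- fuse_sensors(flat_v, flat_n,
                         boundary = config$preprocess$boundary,
                         lo = config$preprocess$lo,
                         hi = config$preprocess$hi)
    attr(flat, "shape") <- config$raster$shape
    band490 <- unflatten_image(flat[, "r0490"], config$raster$shape)
    mask <- background_mask(band490, method = config$map$threshold_method,
                            threshold = config$map$threshold,
                            threshold_high = config$map$threshold_high)
    layoutf <- fieldf$layout
    roi_masks[[key]] <- build_roi_mask(layoutf$centers,
                                       config$raster$shape)
    maps_f <- lapply(traits, function(t) {
      predict_map(models[[t]], flat, mask, config$raster$shape,
                  composition = t)
    })
    names(maps_f) <- traits
    maps[[key]] <- maps_f
  }
  for (t in traits) {
    mt <- lapply(maps, `[[`, t)
    region_errors[[t]] <- regionwise_errors(mt, roi_masks, ref,
                                            trait_col = tcol[[t]])
  }
  log_("map", n_map, " validation fruit mapped")

  report <- list(
    best_transform = best_kind,
    registration = reports,
    selected = lapply(selections, function(s)
      list(composition = s$composition, modality = s$modality,
           method = s$method, wavelengths_nm = s$wavelengths_nm,
           per_wavelength_r = unname(s$per_wavelength_r),
           merit = s$merit %||% NA_real_)),
    metrics = metrics
  )
  out <- list(config = config, reference = ref, availability = avail,
              spectra = spectra, plan = plan,
              registration = reports, best_transform = best_kind,
              selections = selections, models = models,
              metrics = metrics, maps = maps, roi_masks = roi_masks,
              region_errors = region_errors, report = report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference_table(ref, file.path(config$out_dir, "reference.csv"))
    write_availability_table(avail,
                             file.path(config$out_dir, "availability.csv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (t in names(region_errors)) {
      utils::write.csv(region_errors[[t]]$table,
                       file.path(config$out_dir,
                                 paste0("region_errors_", t, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Serialize an MLP calibration model to JSON
#'
#' Stores weights, scalers, wavelengths, hyperparameters, seed and the
#' stopping record; [load_model_json()] restores a working model.
#'
#' @param model an `mlp_calibration`.
#' @param path JSON file path.
#' @export
save_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$theta <- as.numeric(m$theta)
  m$scalers <- lapply(m$scalers, unlist)
  structure(m, class = "mlp_calibration")
}
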