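# default nested scenario configuration; every recognised key appears here
default_config_template <- function() {
  list(
    scenario = "artery",
    initial_temperature = NULL,     # 37 for artery, 22 for phantom
    materials_file = NULL,          # optional override of the property table
    grid = list(spacing = 0.25e-3, extents = c(12e-3, 14e-3, 14e-3)),
    geometry = list(lumen_diameter = 4.1e-3, wall_thickness = 0.5e-3,
                    tissue_radius = 10e-3, padding_radius = 25e-3),
    electrode = list(outer_diameter = 0.61e-3, shell_thickness = 0.1e-3,
                     length = 3e-3, separation = 1.5e-3,
                     window_width = 1e-3, window_length = 2.5e-3),
    gel_depth = 6e-3,
    drive = list(v_pp = 60, frequency = 5e5, duration = 60),
    perfusion = list(blood_density = 1050, blood_heat_capacity = 3617,
                     perfusion_rate = 0, arterial_temperature = 37),
    flow = list(velocity = 0.7, enabled = TRUE, blood_mode = "advective",
                direction = 1),
    damage = list(damage_temperature = 60, damage_time = 1,
                  necrosis_temperature = 100, enthalpy_change = 0),
    solver = list(dt = NA, resolve_dT = 1, resolve_interval = 1,
                  resolve_min = 0.25, tol = 1e-6,
                  maxit = 50000, max_temperature = 150, verbose = FALSE),
    output = list(dir = NULL, vtk = FALSE, seed = 1, imaging_noise_sd = 4)
  )
}

# recursively merge user values into the template, rejecting unknown keys
merge_config <- function(template, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(template))
      stop("unknown configuration key: ", paste0(path, key))
    if (is.list(template[[key]]) && !is.null(names(template[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", paste0(path, key), " must be a mapping")
      template[[key]] <- merge_config(template[[key]], user[[key]],
                                      paste0(path, key, "/"))
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      template[key] <- list(val)  # keeps explicit NULLs
    }
  }
  template
}

#' Read and validate a scenario configuration
#'
#' YAML key/value configuration covering scenario type, grid, geometry,
#' electrode, drive, perfusion, flow, damage and solver settings.  Unknown
#' keys are rejected; omitted keys take the packaged defaults (the artery
#' scenario at 0.25 mm spacing with advective blood).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @param overrides optional named list merged on top (same schema).
#' @return a validated \code{scenario_config}.
#' @export
read_scenario_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config_template()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  if (!cfg$scenario %in% c("artery", "phantom"))
    stop("scenario must be 'artery' or 'phantom'")
  if (is.null(cfg$initial_temperature))
    cfg$initial_temperature <- if (cfg$scenario == "artery") 37 else 22
  structure(cfg, class = "scenario_config")
}

#' Serialise a scenario configuration to YAML
#'
#' \code{read_scenario_config(write_scenario_config(cfg))} round-trips.
#'
#' @param config a \code{scenario_config}.
#' @param path output YAML path.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# build the voxel model described by a config
build_scenario_model <- function(config) {
  grid <- grid_spec(config$grid$spacing, config$grid$extents)
  el <- do.call(electrode_spec, config$electrode[
    names(config$electrode) != "window_orientation"])
  if (config$scenario == "artery") {
    geo <- do.call(artery_geometry, config$geometry)
    m <- build_artery_model(grid, geo, el)
    m$initial_temperature <- config$initial_temperature
    m
  } else {
    build_phantom_model(grid, el, gel_depth = config$gel_depth,
                        initial_temperature = config$initial_temperature)
  }
}

#' Run a scenario end to end
#'
#' Geometry, coupled electro-thermal solve, damage classification and
#' reporting.  When an output directory is configured, writes the power
#' report and zone report (delimited text), the per-solve log, the final
#' fields as VTK (optional) and, for the phantom scenario, a synthetic
#' top-view photograph of the damage mask with its HSB measurement.
#'
#' @param config a \code{scenario_config} (or a path to one).
#' @param keep_fields keep the full 3D fields in the returned bundle.
#' @return a \code{scenario_result} bundle.
#' @export
run_scenario <- function(config, keep_fields = TRUE) {
  if (is.character(config)) config <- read_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  stage <- "geometry"
  result <- tryCatch({
    model <- build_scenario_model(config)
    stage <- "coupled solve"
    drive <- do.call(drive_signal, config$drive)
    perf <- do.call(perfusion_params, config$perfusion)
    flow <- do.call(flow_params, config$flow)
    dmg <- do.call(damage_params, config$damage)
    ctl <- do.call(solver_controls, config$solver)
    tab <- material_table(config$materials_file)
    res <- run_coupled(model, drive, perf, flow, dmg,
                       t_end = drive$duration, controls = ctl, table = tab)
    stage <- "reporting"
    bundle <- list(config = config, report = res$report, log = res$log,
                   power = res$report$power,
                   extents_mm = res$report$extents_mm,
                   volume_mm3 = res$report$volume_mm3,
                   result = if (keep_fields) res else NULL)
    outdir <- config$output$dir
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      pr <- res$report$power
      write.table(data.frame(v_pp = pr$v_pp, v_rms = pr$v_rms,
                             current_mA = pr$current_mA,
                             power_W = pr$power_W),
                  file.path(outdir, "power_report.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      e <- res$report$extents_mm
      write.table(data.frame(length_mm = e[["length"]],
                             width_mm = e[["width"]],
                             height_mm = e[["height"]],
                             volume_mm3 = res$report$volume_mm3,
                             necrosis = res$report$necrosis_any),
                  file.path(outdir, "zone_report.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(res$log, file.path(outdir, "log.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      if (isTRUE(config$output$vtk))
        write_vtk_grid(file.path(outdir, "fields.vtk"), model$grid,
                       list(labels = res$model$labels,
                            temperature = res$state$T,
                            potential = res$solution$V,
                            joule = res$solution$q,
                            damage = res$report$mask))
      if (config$scenario == "phantom") {
        top <- mask_top_view(res$report$mask, axis = 3L)
        img <- render_synthetic_tcp(top, spacing_mm = model$grid$spacing * 1e3,
                                    scale = 86,
                                    noise_sd = config$output$imaging_noise_sd,
                                    seed = config$output$seed)
        write_phantom_image(img, file.path(outdir, "phantom_topview.png"))
        meas <- measure_ablated_region(hsb_threshold(img), img$scale)
        write.table(as.data.frame(meas),
                    file.path(outdir, "phantom_measurement.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    bundle
  }, error = function(e) {
    stop(sprintf("scenario failed during %s: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  class(result) <- "scenario_result"
  result
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$config$scenario))
  print(x$report)
  invisible(x)
}

#' Compare two scenario result bundles
#'
#' Relative differences (percent of the larger magnitude) for peak current,
#' peak power and zone extents.
#'
#' @param a,b \code{scenario_result} bundles.
#' @return data.frame with columns quantity, a, b, rel_diff_pct.
#' @export
compare_runs <- function(a, b) {
  for (x in list(a, b))
    if (!inherits(x, "scenario_result") || is.null(x$power) ||
        is.null(x$extents_mm))
      stop("compare_runs expects two complete scenario_result bundles")
  rows <- rbind(
    data.frame(quantity = "current_mA", a = a$power$current_mA,
               b = b$power$current_mA),
    data.frame(quantity = "power_W", a = a$power$power_W, b = b$power$power_W),
    data.frame(quantity = "length_mm", a = a$extents_mm[["length"]],
               b = b$extents_mm[["length"]]),
    data.frame(quantity = "width_mm", a = a$extents_mm[["width"]],
               b = b$extents_mm[["width"]]),
    data.frame(quantity = "height_mm", a = a$extents_mm[["height"]],
               b = b$extents_mm[["height"]]),
    data.frame(quantity = "volume_mm3", a = a$volume_mm3, b = b$volume_mm3))
  rows$rel_diff_pct <- ifelse(
    rows$a == rows$b, 0,
    100 * abs(rows$a - rows$b) / pmax(abs(rows$a), abs(rows$b)))
  rows
}

#' Path to a bundled scenario configuration
#'
#' Shipped configurations: \code{"artery_reference"} (0.25 mm spacing,
#' advective blood, the headline scenario), \code{"artery_coarse"} and
#' \code{"artery_noflow_coarse"} (0.4 mm quick runs), \code{"phantom_reference"},
#' \code{"phantom_coarse"} and \code{"zero_drive"}.
#'
#' @param name configuration name (without extension).
#' @return file path.
#' @export
bundled_config <- function(name) {
  system.file("extdata", "configs", paste0(name, ".yaml"),
              package = "rfablate", mustWork = TRUE)
}
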