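#' Thermal damage parameters
#'
#' Temperature-threshold damage model: a tissue voxel is classified as
#' ablated after a cumulative dwell of \code{damage_time} seconds at or
#' above \code{damage_temperature}, or immediately if it ever reaches the
#' necrosis temperature.  The enthalpy change is zero, so no latent-heat
#' term modifies the bioheat solve.
#'
#' @param damage_temperature C.
#' @param damage_time cumulative dwell, s.
#' @param necrosis_temperature instant-kill threshold, C.
#' @param enthalpy_change J/kg (kept as metadata; must be 0).
#' @param necrosis_instant_kill logical: treat reaching the necrosis
#'   temperature as immediate ablation (default) or ignore it for
#'   classification.
#' @export
damage_params <- function(damage_temperature = 60, damage_time = 1,
                          necrosis_temperature = 100, enthalpy_change = 0,
                          necrosis_instant_kill = TRUE) {
  if (necrosis_temperature <= damage_temperature)
    stop("necrosis_temperature must exceed damage_temperature")
  if (damage_time < 0) stop("damage_time must be nonnegative")
  structure(list(damage_temperature = damage_temperature,
                 damage_time = damage_time,
                 necrosis_temperature = necrosis_temperature,
                 enthalpy_change = enthalpy_change,
                 necrosis_instant_kill = isTRUE(necrosis_instant_kill)),
            class = "damage_params")
}

#' Classify ablated voxels
#'
#' A voxel is ablated iff its cumulative time at or above the damage
#' temperature reaches the damage time, or (when instant kill is enabled)
#' its running maximum temperature ever reached the necrosis temperature.
#' Only tissue voxels (artery wall, connective tissue, gel) can be ablated.
#'
#' @param state a \code{thermal_state} carrying the dwell history.
#' @param params a \code{\link{damage_params}}.
#' @param model the \code{voxel_model}.
#' @return logical array.
#' @export
classify_damage <- function(state, params = damage_params(), model) {
  mask <- state$time_above >= params$damage_time
  if (params$necrosis_instant_kill)
    mask <- mask | state$Tmax >= params$necrosis_temperature
  mask & array(as.vector(model$labels) %in% TISSUE_LABELS, model$grid$n)
}

#' Ablation-zone bounding box and volume
#'
#' Axis-aligned bounding box of the union of the largest connected
#' components (face connectivity) of the damage mask, reported in
#' millimetres.  A bipolar lesion often consists of two elongated lobes,
#' one per electrode; with \code{lobes = 2} the box spans both, matching
#' the convention that the long dimension runs along the electrode pair.
#' Components are ranked by size with ties broken by smallest voxel index.
#'
#' @param mask logical voxel array.
#' @param grid the \code{\link{grid_spec}}.
#' @param lobes number of largest components to include in the box.
#' @param axes names of the grid axes reported as (length, width, height);
#'   the default maps width to the electrode axis (x), height to the
#'   direction the windows face.
#' @return list with \code{extents_mm} (named length/width/height),
#'   \code{volume_mm3} (all ablated voxels), \code{n_components},
#'   \code{voxels}.
#' @export
zone_extents <- function(mask, grid, lobes = 2L,
                         axes = c(length = "z", width = "x", height = "y")) {
  stopifnot(identical(dim(mask), grid$n))
  h_mm <- grid$spacing * 1e3
  vol <- sum(mask) * h_mm^3
  if (!any(mask)) {
    ext <- c(length = 0, width = 0, height = 0)
    return(list(extents_mm = ext, volume_mm3 = 0, n_components = 0L,
                voxels = 0L))
  }
  comp <- label_components_cpp(grid$n, as.vector(mask))
  ord <- order(comp$sizes, decreasing = TRUE)  # stable: ties keep discovery order
  keep <- ord[seq_len(min(lobes, length(ord)))]
  sel <- array(comp$labels %in% keep, grid$n)
  idx <- which(sel, arr.ind = TRUE)
  span <- apply(idx, 2, function(v) diff(range(v)) + 1L) * h_mm
  names(span) <- c("x", "y", "z")
  ext <- c(length = unname(span[axes[["length"]]]),
           width = unname(span[axes[["width"]]]),
           height = unname(span[axes[["height"]]]))
  list(extents_mm = ext, volume_mm3 = vol,
       n_components = length(comp$sizes), voxels = sum(mask))
}

#' Assemble the ablation-zone report
#'
#' @param state final \code{thermal_state}.
#' @param model the \code{voxel_model}.
#' @param params a \code{\link{damage_params}}.
#' @param power a \code{\link{power_report}} (peak over the run).
#' @param lobes see \code{\link{zone_extents}}.
#' @return an \code{ablation_zone_report}.
#' @export
ablation_report <- function(state, model, params = damage_params(),
                            power = NULL, lobes = 2L) {
  mask <- classify_damage(state, params, model)
  axes <- if (identical(model$scenario, "phantom"))
    c(length = "y", width = "x", height = "z")
  else
    c(length = "z", width = "x", height = "y")
  ze <- zone_extents(mask, model$grid, lobes = lobes, axes = axes)
  structure(list(mask = mask, extents_mm = ze$extents_mm,
                 volume_mm3 = ze$volume_mm3,
                 n_components = ze$n_components,
                 necrosis_any = any(state$Tmax >= params$necrosis_temperature),
                 params = params, power = power),
            class = "ablation_zone_report")
}

#' @export
print.ablation_zone_report <- function(x, ...) {
  e <- x$extents_mm
  cat(sprintf("<ablation_zone_report> %.2f x %.2f x %.2f mm (length x width x height), %.1f mm^3\n",
              e[["length"]], e[["width"]], e[["height"]], x$volume_mm3))
  if (!is.null(x$power)) cat(" ", format(x$power), "\n")
  if (x$necrosis_any) cat("  necrosis temperature reached\n")
  invisible(x)
}

#' Top-view projection of a damage mask
#'
#' Collapses a 3D mask along one axis (logical any), giving the silhouette
#' a photograph of the phantom surface would show.
#'
#' @param mask logical 3D array.
#' @param axis axis to project along (3 = z, the phantom depth).
#' @return logical matrix.
#' @export
mask_top_view <- function(mask, axis = 3L) {
  apply(mask, setdiff(1:3, axis), any)
}
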