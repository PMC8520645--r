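# cached copy of the bundled material table
.materials_env <- new.env(parent = emptyenv())

#' Material property table at 500 kHz
#'
#' Electrical and thermal constants for every material label in the voxel
#' model: relative permittivity, electrical conductivity at the reference
#' temperature (S/m), density (kg/m^3), heat capacity (J/(kg C)), thermal
#' conductivity (W/(m C)) and the linear conductivity temperature
#' coefficient (1/C, nonzero for artery wall, connective tissue and the
#' tissue-mimicking gel).  The gel carries the connective-tissue electrical
#' conductivity with water-like thermal constants; the permittivity column
#' is informational only — at 500 kHz dielectric loss is negligible and the
#' solver uses purely resistive conduction.
#'
#' @param file optional path to a user override table with the same columns.
#' @return data.frame, one row per material.
#' @export
material_table <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.materials_env$table)) {
      path <- system.file("extdata", "materials_500khz.tsv",
                          package = "rfablate", mustWork = TRUE)
      .materials_env$table <- read.delim(path, stringsAsFactors = FALSE)
    }
    return(.materials_env$table)
  }
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("material", "relative_permittivity", "sigma", "density",
            "heat_capacity", "thermal_conductivity", "temp_coefficient")
  if (!all(need %in% names(tab)))
    stop("material table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Look up the properties of one material
#'
#' @param material material tag, e.g. \code{"artery_wall"}.
#' @param frequency drive frequency in Hz; only the tabulated 500 kHz point
#'   is available.
#' @param table optionally a table from \code{\link{material_table}}.
#' @return a \code{material_props} list with fields \code{sigma0},
#'   \code{relative_permittivity}, \code{density}, \code{heat_capacity},
#'   \code{thermal_conductivity}, \code{temp_coefficient} and
#'   \code{sigma_T_bounds} (the 30-80 C validity range of the
#'   conductivity-temperature law).
#' @export
get_properties <- function(material, frequency = 5e5, table = material_table()) {
  if (!isTRUE(all.equal(frequency, 5e5)))
    stop("unsupported frequency: properties are tabulated at 500 kHz only")
  row <- table[table$material == material, ]
  if (nrow(row) != 1L)
    stop("unknown material tag: ", material)
  structure(list(material = material,
                 relative_permittivity = row$relative_permittivity,
                 sigma0 = row$sigma,
                 density = row$density,
                 heat_capacity = row$heat_capacity,
                 thermal_conductivity = row$thermal_conductivity,
                 temp_coefficient = row$temp_coefficient,
                 sigma_T_bounds = c(30, 80)),
            class = "material_props")
}

#' Temperature-dependent electrical conductivity
#'
#' Linear law sigma(T) = sigma0 * (1 + k1 * dT) with
#' dT = clamp(T, 30, 80) - T_ref.  The temperature is clamped to the 30-80 C
#' range over which the linear coefficient was measured, so the law is
#' constant (not extrapolated) outside it and the function is total.
#'
#' @param props a \code{material_props} from \code{\link{get_properties}}.
#' @param T temperature(s), degrees C (vectorised).
#' @param T_ref reference temperature, degrees C (body temperature).
#' @return conductivity in S/m.
#' @export
conductivity_at_temperature <- function(props, T, T_ref = 37) {
  b <- props$sigma_T_bounds %||% c(30, 80)
  dT <- pmin(pmax(T, b[1]), b[2]) - T_ref
  props$sigma0 * (1 + props$temp_coefficient * dT)
}

#' Pennes perfusion parameters
#'
#' Coefficients of the volumetric perfusion sink
#' rho_b * Cp_b * omega_b * (T_b - T) applied to the artery wall and
#' connective tissue.  The default perfusion rate is zero (no value is
#' tabulated for periarterial connective tissue); the term is exposed so
#' its sensitivity can be explored.
#'
#' @param blood_density kg/m^3.
#' @param blood_heat_capacity J/(kg C).
#' @param perfusion_rate volumetric exchange rate omega_b, 1/s.
#' @param arterial_temperature T_b, degrees C.
#' @export
perfusion_params <- function(blood_density = 1050, blood_heat_capacity = 3617,
                             perfusion_rate = 0, arterial_temperature = 37) {
  if (perfusion_rate < 0) stop("perfusion_rate must be nonnegative")
  if (arterial_temperature < 30 || arterial_temperature > 45)
    stop("arterial_temperature must lie in [30, 45] C")
  structure(list(blood_density = blood_density,
                 blood_heat_capacity = blood_heat_capacity,
                 perfusion_rate = perfusion_rate,
                 arterial_temperature = arterial_temperature),
            class = "perfusion_params")
}

# conductivity below which a voxel is treated as a perfect insulator
SIGMA_CUTOFF <- 1e-6

# per-voxel material property vectors, in label-code order
material_vectors <- function(table = material_table()) {
  m <- table[match(MAT_NAMES, table$material), ]
  list(sigma0 = m$sigma, k1 = m$temp_coefficient, density = m$density,
       heat_capacity = m$heat_capacity, k_thermal = m$thermal_conductivity)
}

#' Per-voxel conductivity field at a given temperature
#'
#' Applies the linear conductivity-temperature law per voxel according to
#' its material label.  Materials below a small conductivity cutoff
#' (insulator coating, ambient air) are set to exactly zero so the electric
#' solve treats them as non-conducting.
#'
#' @param model a \code{voxel_model}.
#' @param T temperature field (array matching the grid) or a scalar, C.
#' @param T_ref reference temperature of the conductivity law, C.
#' @param table material table.
#' @return numeric array of conductivities, S/m.
#' @export
sigma_field <- function(model, T = model$initial_temperature, T_ref = 37,
                        table = material_table()) {
  mv <- material_vectors(table)
  lab <- as.vector(model$labels)
  s0 <- mv$sigma0[lab]
  k1 <- mv$k1[lab]
  if (length(T) == 1L) T <- rep(T, length(lab))
  dT <- pmin(pmax(as.vector(T), 30), 80) - T_ref
  s <- s0 * (1 + k1 * dT)
  s[s0 < SIGMA_CUTOFF] <- 0
  dim(s) <- model$grid$n
  s
}
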