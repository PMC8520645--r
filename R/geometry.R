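#' Regular voxel grid specification
#'
#' Cell-centred uniform grid with the domain centre at the origin.  Voxel
#' centres lie at \code{-extent + (i - 1/2) * spacing}.
#'
#' @param spacing voxel edge length in metres (uniform in all directions).
#' @param extents numeric length-3, domain half-lengths along x, y, z (m).
#' @return object of class \code{grid_spec} with the voxel counts \code{n}.
#' @export
grid_spec <- function(spacing, extents) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, is.numeric(extents),
            length(extents) == 3L)
  if (spacing <= 0) stop("grid spacing must be positive")
  if (any(extents < 10 * spacing))
    stop("every domain half-length must be at least 10 voxels (10 * spacing)")
  n <- as.integer(round(2 * extents / spacing))
  if (any(n < 20L)) stop("grid must have at least 20 voxels along each axis")
  # effective half-lengths of the realised grid (n may round)
  structure(list(spacing = spacing, extents = n * spacing / 2, n = n),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %.4g mm\n",
              x$n[1], x$n[2], x$n[3], x$spacing * 1e3))
  invisible(x)
}

# voxel-centre coordinates along each axis (metres); the centred form keeps
# mirror-image coordinate pairs exactly equal in floating point
voxel_centers <- function(grid) {
  lapply(1:3, function(a)
    (seq_len(grid$n[a]) - (grid$n[a] + 1) / 2) * grid$spacing)
}

# full coordinate arrays (one numeric vector per axis, length prod(n))
coordinate_fields <- function(grid) {
  cc <- voxel_centers(grid)
  n <- grid$n
  list(x = rep(cc[[1]], times = n[2] * n[3]),
       y = rep(rep(cc[[2]], each = n[1]), times = n[3]),
       z = rep(cc[[3]], each = n[1] * n[2]))
}

#' Renal artery geometry parameters
#'
#' Concentric-cylinder description of the target anatomy: a blood-filled
#' lumen, a thin artery wall, connective tissue to \code{tissue_radius},
#' and a connective-tissue padding shell out to \code{padding_radius}
#' standing in for an unbounded surround (the outer boundary is grounded
#' and held at body temperature).  The artery axis is the x axis.
#'
#' @param lumen_diameter internal artery diameter, m.
#' @param wall_thickness artery wall (intima + media) thickness, m.
#' @param tissue_radius radius of the explicitly modelled connective tissue, m.
#' @param padding_radius outer truncation radius of the padding shell, m.
#' @param artery_axis axis name; only \code{"x"} is supported.
#' @export
artery_geometry <- function(lumen_diameter = 4.1e-3, wall_thickness = 0.5e-3,
                            tissue_radius = 10e-3, padding_radius = 25e-3,
                            artery_axis = "x") {
  if (!identical(artery_axis, "x"))
    stop("the artery axis is fixed to the x axis in this implementation")
  if (lumen_diameter <= 0 || wall_thickness <= 0)
    stop("lumen diameter and wall thickness must be positive")
  if (tissue_radius <= lumen_diameter / 2 + wall_thickness)
    stop("tissue_radius must exceed the outer wall radius")
  if (padding_radius <= tissue_radius)
    stop("padding_radius must exceed tissue_radius")
  structure(list(lumen_diameter = lumen_diameter,
                 wall_thickness = wall_thickness,
                 tissue_radius = tissue_radius,
                 padding_radius = padding_radius,
                 artery_axis = "x"),
            class = "artery_geometry")
}

#' Bipolar electrode pair specification
#'
#' Two coaxial metal tube electrodes on an insulating carrier, separated
#' edge-to-edge along the device axis.  Each tube is insulation-coated
#' except for a rectangular exposed window (axial length x circumferential
#' arc width) facing \code{window_orientation}.
#'
#' @param outer_diameter tube outside diameter, m.
#' @param shell_thickness metal shell thickness, m.
#' @param length electrode length, m; length-1 or length-2 (per electrode).
#' @param separation edge-to-edge axial gap between the electrodes, m.
#' @param window_width circumferential arc width of the exposed window, m.
#' @param window_length axial length of the exposed window, m.
#' @param window_orientation unit vector (in the plane normal to the device
#'   axis) that the windows face; defaults to +y, toward the artery wall.
#' @export
electrode_spec <- function(outer_diameter = 0.61e-3, shell_thickness = 0.1e-3,
                           length = 3e-3, separation = 1.5e-3,
                           window_width = 1e-3, window_length = 2.5e-3,
                           window_orientation = c(0, 1, 0)) {
  if (shell_thickness >= outer_diameter / 2)
    stop("shell_thickness must be smaller than the tube radius")
  if (window_width > pi * outer_diameter)
    stop("window_width exceeds the tube circumference")
  if (length(length) == 1L) length <- rep(length, 2L)
  if (any(window_length > length))
    stop("window_length must not exceed the electrode length")
  if (separation <= 0) stop("electrode separation must be positive")
  w <- window_orientation / sqrt(sum(window_orientation^2))
  structure(list(outer_diameter = outer_diameter,
                 shell_thickness = shell_thickness, length = length,
                 separation = separation, window_width = window_width,
                 window_length = window_length, window_orientation = w),
            class = "electrode_spec")
}

# internal constructor shared by the two scenario builders
new_voxel_model <- function(grid, labels, eid, exposed, scenario, extra = list()) {
  n <- grid$n
  dim(labels) <- n; dim(eid) <- n; dim(exposed) <- n
  terminal_pos <- exposed & eid == 2L
  terminal_neg <- exposed & eid == 1L
  m <- c(list(grid = grid, labels = labels, eid = eid, exposed = exposed,
              terminal_pos = terminal_pos, terminal_neg = terminal_neg,
              scenario = scenario), extra)
  class(m) <- "voxel_model"
  if (!any(terminal_pos) || !any(terminal_neg))
    stop("a terminal mask is empty: the grid spacing cannot resolve the ",
         "electrode window (limiting dimension: window_width = ",
         format(extra$electrodes$window_width), " m)")
  m
}

# axial placement of the electrode pair: edge-to-edge gap centred on x = 0
electrode_spans <- function(electrodes) {
  len <- electrodes$length
  x_in <- c(-electrodes$separation / 2 - len[1], electrodes$separation / 2)
  x_out <- c(-electrodes$separation / 2, electrodes$separation / 2 + len[2])
  list(x_in = x_in, x_out = x_out, xc = (x_in + x_out) / 2)
}

# carve the two tube electrodes into precomputed label/eid/exposed vectors.
# The metal shell is voxelised as a ring of |r - r_mid| <= max(t, h)/2 so a
# shell thinner than one voxel is still captured at coarse spacing; the
# Dirichlet region (eid) is the full enclosed cylinder (the shell and its
# insulating core are one equipotential body).
carve_electrodes <- function(labels, eid, exposed, co, grid, electrodes,
                             center_perp, axis_w) {
  h <- grid$spacing
  od <- electrodes$outer_diameter
  r_mid <- (od - electrodes$shell_thickness) / 2
  t_eff <- max(electrodes$shell_thickness, h)
  sp <- electrode_spans(electrodes)
  half_angle <- electrodes$window_width / od  # (w/2) / (od/2)
  dy <- co$y - center_perp[1]
  dz <- co$z - center_perp[2]
  re <- sqrt(dy^2 + dz^2)
  for (e in 1:2) {
    span <- co$x >= sp$x_in[e] & co$x <= sp$x_out[e]
    ring <- span & abs(re - r_mid) <= t_eff / 2
    interior <- span & re < r_mid - t_eff / 2
    labels[interior] <- MAT[["insulator"]]
    labels[ring] <- MAT[["electrode_metal"]]
    eid[ring | interior] <- e
    cosang <- ifelse(re > 0, (dy * axis_w[1] + dz * axis_w[2]) / re, 1)
    win <- ring & cosang >= cos(half_angle) &
      abs(co$x - sp$xc[e]) <= electrodes$window_length / 2
    exposed[win] <- TRUE
  }
  list(labels = labels, eid = eid, exposed = exposed)
}

# Embedded-boundary description of the exposed electrode windows: every
# grid face between a Dirichlet electrode cell and a conducting tissue/gel
# cell whose midpoint lies inside a window gets conductance
# sigma_tissue * h^2 / d, with d the distance from the tissue cell centre
# to the analytic tube surface (clamped to [h/4, h]).  This resolves the
# sub-voxel constriction at the tangent electrode-wall (or electrode-gel)
# contact that a staircase voxelisation misses.
build_contacts <- function(grid, labels, eid, electrodes, center_perp, axis_w) {
  n <- grid$n
  h <- grid$spacing
  N <- prod(n)
  co <- coordinate_fields(grid)
  stride <- c(1L, n[1], n[1] * n[2])
  r_out <- electrodes$outer_diameter / 2
  sp <- electrode_spans(electrodes)
  half_angle <- electrodes$window_width / electrodes$outer_diameter
  wl <- electrodes$window_length
  dy <- co$y - center_perp[1]
  dz <- co$z - center_perp[2]
  re <- sqrt(dy^2 + dz^2)
  conducting <- as.vector(labels) %in% c(MAT[["blood"]], MAT[["artery_wall"]],
                                         MAT[["connective_tissue"]],
                                         MAT[["gel"]])
  eidv <- as.vector(eid)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    idx_ax <- ((seq_len(N) - 1L) %/% stride[ax]) %% n[ax] + 1L
    v <- which(idx_ax < n[ax])
    w <- v + stride[ax]
    cand <- (eidv[v] > 0L & conducting[w]) | (eidv[w] > 0L & conducting[v])
    v <- v[cand]; w <- w[cand]
    metal_first <- eidv[v] > 0L
    mside <- ifelse(metal_first, v, w)
    tside <- ifelse(metal_first, w, v)
    e <- eidv[mside]
    fx <- co$x[v] + if (ax == 1) h / 2 else 0
    fy <- co$y[v] + if (ax == 2) h / 2 else 0
    fz <- co$z[v] + if (ax == 3) h / 2 else 0
    fdy <- fy - center_perp[1]
    fdz <- fz - center_perp[2]
    fre <- sqrt(fdy^2 + fdz^2)
    cosang <- ifelse(fre > 0, (fdy * axis_w[1] + fdz * axis_w[2]) / fre, 1)
    inwin <- cosang >= cos(half_angle) &
      abs(fx - sp$xc[e]) <= wl / 2 &
      fx >= sp$x_in[e] & fx <= sp$x_out[e]
    d <- pmin(pmax(re[tside] - r_out, h / 4), h)
    out[[ax]] <- list(index = v[inwin], tissue = tside[inwin], d = d[inwin],
                      electrode = e[inwin])
  }
  out
}

#' Build the voxelised artery scenario
#'
#' Concentric cylindrical regions (blood lumen, artery wall, connective
#' tissue out to the domain boundary) about the x axis, with the bipolar
#' electrode pair pressed against the inner wall so that the exposed
#' windows are in contact with it.  The electrode at larger x is the
#' positive terminal.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param artery an \code{\link{artery_geometry}}.
#' @param electrodes an \code{\link{electrode_spec}}.
#' @return a \code{voxel_model}.
#' @export
build_artery_model <- function(grid, artery = artery_geometry(),
                               electrodes = electrode_spec()) {
  h <- grid$spacing
  if (electrodes$window_width <= 0 || h > electrodes$window_width / 2)
    stop("grid spacing too coarse to resolve the electrode window ",
         "(limiting dimension: window_width = ",
         format(electrodes$window_width), " m)")
  lumen_r <- artery$lumen_diameter / 2
  if (electrodes$outer_diameter > artery$lumen_diameter)
    stop("electrode does not fit inside the artery lumen")
  span <- electrodes$separation / 2 + max(electrodes$length)
  if (span > grid$extents[1])
    stop("electrode pair does not fit along the domain axis")
  w <- electrodes$window_orientation
  if (abs(w[1]) > 1e-12)
    stop("window_orientation must be normal to the artery (x) axis")
  co <- coordinate_fields(grid)
  r <- sqrt(co$y^2 + co$z^2)
  labels <- rep(MAT[["connective_tissue"]], length(r))
  labels[r < lumen_r] <- MAT[["blood"]]
  labels[r >= lumen_r & r < lumen_r + artery$wall_thickness] <-
    MAT[["artery_wall"]]
  eid <- integer(length(r))
  exposed <- logical(length(r))
  # electrode axis offset so the tube touches the inner wall on the window side
  center_perp <- (lumen_r - electrodes$outer_diameter / 2) * c(w[2], w[3])
  cv <- carve_electrodes(labels, eid, exposed, co, grid, electrodes,
                         center_perp, c(w[2], w[3]))
  contacts <- build_contacts(grid, cv$labels, cv$eid, electrodes,
                             center_perp, c(w[2], w[3]))
  new_voxel_model(grid, cv$labels, cv$eid, cv$exposed, "artery",
                  list(artery = artery, electrodes = electrodes,
                       contacts = contacts,
                       initial_temperature = 37,
                       electric_boundary = "grounded",
                       thermal_boundary = "dirichlet",
                       flow_axis = "x"))
}

#' Build the voxelised bench phantom scenario
#'
#' A half-space of thermochromic gel (z < 0) under ambient air, with the
#' bipolar electrode pair resting on the gel surface and the exposed
#' windows facing down into the gel.  The outer boundary is electrically
#' insulating (the circuit closes between the two electrodes) and held at
#' the initial temperature thermally.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param electrodes an \code{\link{electrode_spec}}; the window orientation
#'   is forced to face downward.
#' @param gel_depth gel thickness below the surface, m; must be at least
#'   five electrode diameters.
#' @param initial_temperature bench temperature, degrees C.
#' @return a \code{voxel_model}.
#' @export
build_phantom_model <- function(grid, electrodes = electrode_spec(),
                                gel_depth = 6e-3, initial_temperature = 22) {
  h <- grid$spacing
  if (electrodes$window_width <= 0 || h > electrodes$window_width / 2)
    stop("grid spacing too coarse to resolve the electrode window ",
         "(limiting dimension: window_width = ",
         format(electrodes$window_width), " m)")
  if (gel_depth < 5 * electrodes$outer_diameter)
    stop("gel_depth must be at least 5 electrode outer diameters")
  span <- electrodes$separation / 2 + max(electrodes$length)
  if (span > grid$extents[1])
    stop("electrode pair does not fit along the domain axis")
  if (grid$extents[3] < gel_depth)
    stop("domain half-height must cover the gel depth")
  co <- coordinate_fields(grid)
  labels <- rep(MAT[["ambient"]], length(co$x))
  labels[co$z < 0 & co$z >= -gel_depth] <- MAT[["gel"]]
  eid <- integer(length(co$x))
  exposed <- logical(length(co$x))
  electrodes$window_orientation <- c(0, 0, -1)
  # tube resting on the surface: axis at z = +OD/2, windows facing -z
  center_perp <- c(0, electrodes$outer_diameter / 2)
  cv <- carve_electrodes(labels, eid, exposed, co, grid, electrodes,
                         center_perp, c(0, -1))
  contacts <- build_contacts(grid, cv$labels, cv$eid, electrodes,
                             center_perp, c(0, -1))
  new_voxel_model(grid, cv$labels, cv$eid, cv$exposed, "phantom",
                  list(electrodes = electrodes, contacts = contacts,
                       gel_depth = gel_depth,
                       initial_temperature = initial_temperature,
                       electric_boundary = "insulated",
                       thermal_boundary = "dirichlet",
                       flow_axis = NA_character_))
}

#' @export
print.voxel_model <- function(x, ...) {
  counts <- table(factor(MAT_NAMES[as.vector(x$labels)], levels = MAT_NAMES))
  cat(sprintf("<voxel_model> scenario '%s', %d x %d x %d voxels @ %.3g mm\n",
              x$scenario, x$grid$n[1], x$grid$n[2], x$grid$n[3],
              x$grid$spacing * 1e3))
  for (nm in names(counts)) if (counts[[nm]] > 0)
    cat(sprintf("  %-18s %d\n", nm, counts[[nm]]))
  cat(sprintf("  terminals: %d (+) / %d (-) exposed metal voxels\n",
              sum(x$terminal_pos), sum(x$terminal_neg)))
  invisible(x)
}

#' Inter-electrode mirror symmetry plane
#'
#' For a symmetric two-electrode construction, returns the midplane between
#' the electrodes (normal to the device axis) across which the voxel labels
#' are mirror images; returns \code{NULL} when the model has no such plane
#' (for example, unequal electrode lengths).
#'
#' @param model a \code{voxel_model}.
#' @return \code{list(normal = "x", position = 0)} or \code{NULL}.
#' @export
mirror_symmetry_plane <- function(model) {
  lab <- model$labels
  rev_x <- lab[rev(seq_len(dim(lab)[1])), , , drop = FALSE]
  eid_m <- model$eid[rev(seq_len(dim(lab)[1])), , , drop = FALSE]
  swapped <- eid_m
  swapped[eid_m == 1L] <- 2L
  swapped[eid_m == 2L] <- 1L
  if (identical(c(rev_x), c(lab)) && identical(c(swapped), c(model$eid)))
    list(normal = "x", position = 0)
  else
    NULL
}

# face adjacency count between two logical voxel masks (6-neighbourhood)
mask_face_adjacency <- function(a, b) {
  n <- dim(a)
  cnt <- 0L
  shift_pairs <- function(m, axis, by) {
    idx <- lapply(n, seq_len)
    idx[[axis]] <- idx[[axis]] + by
    keep <- idx[[axis]] >= 1L & idx[[axis]] <= n[axis]
    list(keep = keep, idx = idx)
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    ia <- lapply(n, seq_len)
    ib <- lapply(n, seq_len)
    if (by == 1L) {
      ia[[axis]] <- seq_len(n[axis] - 1L)
      ib[[axis]] <- seq_len(n[axis] - 1L) + 1L
    } else {
      ia[[axis]] <- seq_len(n[axis] - 1L) + 1L
      ib[[axis]] <- seq_len(n[axis] - 1L)
    }
    cnt <- cnt + sum(do.call(`[`, c(list(a), ia)) &
                       do.call(`[`, c(list(b), ib)))
  }
  cnt
}
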