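# hand-built voxel models and cached heavy runs shared across test files

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# uniform box of one material with two opposite full x-faces as terminals
make_slab_model <- function(nx = 30L, ny = 20L, nz = 20L, h = 1e-4,
                            material = "connective_tissue",
                            boundary = "insulated") {
  n <- as.integer(c(nx, ny, nz))
  g <- structure(list(spacing = h, extents = n * h / 2, n = n),
                 class = "grid_spec")
  lab <- array(rfablate:::MAT[[material]], n)
  eid <- array(0L, n)
  expm <- array(FALSE, n)
  lab[1, , ] <- 4L; lab[nx, , ] <- 4L
  eid[1, , ] <- 1L; eid[nx, , ] <- 2L
  expm[c(1L, nx), , ] <- TRUE
  structure(list(grid = g, labels = lab, eid = eid, exposed = expm,
                 terminal_pos = expm & eid == 2L,
                 terminal_neg = expm & eid == 1L,
                 scenario = "slab", initial_temperature = 37,
                 electric_boundary = boundary,
                 thermal_boundary = "dirichlet"),
            class = "voxel_model")
}

slab_sigma <- function(model, sigma = 0.5) {
  s <- array(sigma, model$grid$n)
  s[model$eid > 0L] <- 1e9
  s
}

# concentric-cylinder resistor: inner rod terminal 1, outer shell terminal 2
make_cylinder_model <- function(nx = 20L, nr = 121L, h = 1e-4,
                                r1_vox = 15, r2_vox = 55) {
  n <- as.integer(c(nx, nr, nr))
  g <- structure(list(spacing = h, extents = n * h / 2, n = n),
                 class = "grid_spec")
  cy <- (seq_len(nr) - (nr + 1) / 2) * h
  r2d <- sqrt(outer(cy^2, cy^2, "+"))
  r <- array(rep(r2d, each = nx), n)
  lab <- array(3L, n)
  eid <- array(0L, n)
  lab[r <= r1_vox * h] <- 4L; eid[r <= r1_vox * h] <- 1L
  lab[r >= r2_vox * h] <- 4L; eid[r >= r2_vox * h] <- 2L
  expm <- eid > 0L
  structure(list(grid = g, labels = lab, eid = eid, exposed = expm,
                 terminal_pos = expm & eid == 2L,
                 terminal_neg = expm & eid == 1L,
                 scenario = "cylinder", initial_temperature = 37,
                 electric_boundary = "insulated",
                 thermal_boundary = "dirichlet"),
            class = "voxel_model")
}

# uniform single-material block with no electrodes (bioheat unit tests)
make_block_model <- function(n1 = 24L, h = 2e-4, material = "connective_tissue",
                             thermal_boundary = "insulated", T0 = 37) {
  n <- as.integer(rep(n1, 3))
  g <- structure(list(spacing = h, extents = n * h / 2, n = n),
                 class = "grid_spec")
  lab <- array(rfablate:::MAT[[material]], n)
  structure(list(grid = g, labels = lab, eid = array(0L, n),
                 exposed = array(FALSE, n),
                 terminal_pos = array(FALSE, n), terminal_neg = array(FALSE, n),
                 scenario = "block", initial_temperature = T0,
                 electric_boundary = "insulated",
                 thermal_boundary = thermal_boundary),
            class = "voxel_model")
}

# small, fast artery scenario used by symmetry/flow/coupling tests
small_artery_config <- function(...) {
  read_scenario_config(overrides = modifyList(list(
    grid = list(spacing = 0.4e-3, extents = c(8e-3, 6.4e-3, 6.4e-3)),
    drive = list(duration = 10),
    solver = list(resolve_interval = 2)), list(...)))
}

run_small_artery <- function(blood_mode = "advective", name = blood_mode) {
  cached(paste0("small_artery_", name), {
    cfg <- small_artery_config(
      flow = list(enabled = !identical(blood_mode, "static"),
                  blood_mode = blood_mode))
    run_scenario(cfg)
  })
}

# reference-resolution runs shared by the acceptance tests
reference_artery_run <- function() {
  cached("reference_artery",
         run_scenario(read_scenario_config(bundled_config("artery_reference"))))
}

reference_phantom_run <- function() {
  cached("reference_phantom",
         run_scenario(read_scenario_config(bundled_config("phantom_reference"))))
}
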