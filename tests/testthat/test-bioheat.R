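test_that("uniform state with matching boundary is a steady state", {
  m <- make_block_model(thermal_boundary = "dirichlet")
  st <- thermal_state(m, 37)
  st2 <- step_thermal(st, m, q = 0, dt = 0.5 * stable_time_step(m))
  expect_equal(max(abs(st2$T - 37)), 0)
  expect_equal(st2$t, 0.5 * stable_time_step(m))
})

test_that("adiabatic uniform heating rises at q/(rho Cp)", {
  m <- make_block_model(material = "connective_tissue",
                        thermal_boundary = "insulated")
  p <- get_properties("connective_tissue")
  q <- 5e5  # W/m^3
  dt <- 0.5 * stable_time_step(m)
  st <- thermal_state(m, 37)
  nstep <- 20L
  for (i in seq_len(nstep)) st <- step_thermal(st, m, q = q, dt = dt)
  T_exact <- 37 + nstep * dt * q / (p$density * p$heat_capacity)
  expect_lt(max(abs(st$T - T_exact)) / (T_exact - 37), 1e-3)
})

test_that("perfusion-only dynamics approach Tb + q/(wb rho_b Cp_b) exponentially", {
  m <- make_block_model(material = "connective_tissue",
                        thermal_boundary = "insulated")
  p <- get_properties("connective_tissue")
  perf <- perfusion_params(perfusion_rate = 0.01)
  q <- 2e4
  wsink <- perf$perfusion_rate * perf$blood_density * perf$blood_heat_capacity
  rate <- wsink / (p$density * p$heat_capacity)
  T_inf <- 37 + q / wsink
  dt <- min(0.5 * stable_time_step(m, perfusion = perf), 0.05 / rate)
  st <- thermal_state(m, 37)
  t_end <- 1.5 / rate
  nstep <- ceiling(t_end / dt)
  for (i in seq_len(nstep)) st <- step_thermal(st, m, q = q, perfusion = perf,
                                               dt = dt)
  T_exact <- T_inf + (37 - T_inf) * exp(-rate * st$t)
  expect_lt(max(abs(st$T - T_exact)) / (T_inf - 37), 0.01)
})

test_that("closed box conserves thermal energy and obeys the maximum principle", {
  m <- make_block_model(n1 = 20L, thermal_boundary = "insulated")
  set.seed(11)
  T0 <- array(37 + 5 * runif(prod(m$grid$n)), m$grid$n)
  st <- thermal_state(m, T0)
  dt <- 0.9 * stable_time_step(m)
  for (i in 1:30) st <- step_thermal(st, m, q = 0, dt = dt)
  expect_lt(abs(mean(st$T) - mean(T0)), 1e-10 * mean(T0))
  expect_gte(min(st$T), min(T0) - 1e-12)
  expect_lte(max(st$T), max(T0) + 1e-12)
})

test_that("scaling the source never lowers the temperature anywhere", {
  m <- make_block_model(n1 = 20L, thermal_boundary = "dirichlet")
  set.seed(7)
  q1 <- array(3e5 * runif(prod(m$grid$n)), m$grid$n)
  dt <- 0.8 * stable_time_step(m)
  s1 <- thermal_state(m); s2 <- thermal_state(m)
  for (i in 1:25) {
    s1 <- step_thermal(s1, m, q = q1, dt = dt)
    s2 <- step_thermal(s2, m, q = 2 * q1, dt = dt)
    expect_true(all(s2$T >= s1$T - 1e-12))
  }
})

test_that("time steps beyond the stability bound are refused with the bound", {
  m <- make_block_model()
  dt_max <- stable_time_step(m)
  st <- thermal_state(m)
  expect_error(step_thermal(st, m, dt = 2 * dt_max), "stability bound")
})

test_that("dwell tracker accumulates only at or above the damage temperature", {
  m <- make_block_model(thermal_boundary = "insulated")
  p <- get_properties("connective_tissue")
  dt <- 0.5 * stable_time_step(m)
  # heat fast enough to cross 60 C
  q <- (61 - 37) * p$density * p$heat_capacity / (10 * dt)
  st <- thermal_state(m, 37)
  for (i in 1:12) st <- step_thermal(st, m, q = q, dt = dt)
  expect_true(all(st$Tmax > 60))
  expect_true(all(st$time_above > 0))
  expect_true(all(st$time_above <= st$t))
  expect_equal(max(st$time_above), 3 * dt)  # steps 10..12 are at/above 60
})

test_that("zero drive leaves the coupled run at body temperature", {
  res <- run_scenario(read_scenario_config(bundled_config("zero_drive")))
  r <- res$result
  expect_equal(max(abs(r$state$T - 37)), 0)
  expect_equal(r$report$volume_mm3, 0)
  expect_equal(r$report$power$power_W, 0)
  expect_equal(unname(r$report$extents_mm), c(0, 0, 0))
})

test_that("no-flow run is mirror symmetric; flow breaks symmetry downstream only", {
  rs <- run_small_artery("static")$result
  Tf <- rs$state$T
  Tm <- Tf[rev(seq_len(dim(Tf)[1])), , ]
  rngT <- diff(range(Tf))
  expect_lt(max(abs(Tf - Tm)), 0.01 * rngT)

  ra <- run_small_artery("advective")$result
  Ta <- ra$state$T
  # bulk lumen blood stays at body temperature
  expect_lt(abs(lumen_bulk_temperature(ra) - 37), 0.2)
  # warming is biased downstream (+x): compare wall temperature integrals
  lab <- ra$model$labels
  co <- rfablate:::coordinate_fields(ra$model$grid)
  xv <- array(co$x, dim(Ta))
  wall <- lab == rfablate:::MAT[["artery_wall"]]
  up <- sum(Ta[wall & xv < 0] - 37)
  down <- sum(Ta[wall & xv > 0] - 37)
  expect_gt(down, up)
})

test_that("clamped blood mode holds the lumen at the arterial temperature", {
  rc <- run_small_artery("clamped")$result
  blood <- rc$model$labels == rfablate:::MAT[["blood"]]
  expect_equal(max(abs(rc$state$T[blood] - 37)), 0)
})

test_that("halving the time step and coupling cadence changes the outcome by well under 1%", {
  base <- run_small_artery("advective")$result
  cfg <- small_artery_config(
    flow = list(enabled = TRUE, blood_mode = "advective"),
    solver = list(dt = 0.25 * stable_time_step(base$model,
                                               flow = flow_params()),
                  resolve_interval = 1, resolve_min = 0.125))
  half <- run_scenario(cfg)$result
  dT_base <- max(base$state$T) - 37
  dT_half <- max(half$state$T) - 37
  expect_lt(abs(dT_half - dT_base) / dT_base, 0.01)
})

test_that("runaway temperatures abort with a diagnostic", {
  cfg <- small_artery_config(drive = list(v_pp = 600, duration = 10))
  expect_error(run_scenario(cfg), "model validity")
})
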