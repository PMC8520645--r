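test_that("damage parameters are validated", {
  expect_error(damage_params(necrosis_temperature = 50), "necrosis")
  expect_error(damage_params(damage_time = -1), "nonnegative")
})

test_that("threshold semantics: dwell below temperature or time never ablates", {
  m <- make_block_model(n1 = 20L)
  st <- thermal_state(m)
  p <- damage_params()
  # 59.9 C held for 60 s: temperature threshold unmet, no dwell accumulates
  st$Tmax[] <- 59.9
  st$time_above[] <- 0
  expect_equal(sum(classify_damage(st, p, m)), 0)
  # 61 C for only 0.5 s: dwell threshold unmet
  st$Tmax[] <- 61
  st$time_above[] <- 0.5
  expect_equal(sum(classify_damage(st, p, m)), 0)
  # cumulative dwell of 1 s ablates
  st$time_above[] <- 1
  expect_equal(sum(classify_damage(st, p, m)), prod(m$grid$n))
  # touching the necrosis temperature once ablates regardless of dwell
  st$time_above[] <- 0
  st$Tmax[] <- 100
  expect_equal(sum(classify_damage(st, p, m)), prod(m$grid$n))
  expect_equal(sum(classify_damage(
    st, damage_params(necrosis_instant_kill = FALSE), m)), 0)
})

test_that("only tissue labels can be ablated", {
  g <- grid_spec(0.4e-3, c(8e-3, 6.4e-3, 6.4e-3))
  m <- build_artery_model(g)
  st <- thermal_state(m)
  st$time_above[] <- 10  # everything hot
  mask <- classify_damage(st, damage_params(), m)
  lab <- as.vector(m$labels)
  expect_true(all(lab[as.vector(mask)] %in% c(2L, 3L, 6L)))
  expect_equal(sum(mask[m$labels == 1L]), 0)  # blood never ablated
  expect_equal(sum(mask[m$eid > 0L]), 0)      # electrodes never ablated
})

test_that("zone extents handle empty, single-voxel and ellipsoid masks", {
  g <- grid_spec(0.25e-3, c(6e-3, 6e-3, 6e-3))
  empty <- array(FALSE, g$n)
  ze <- zone_extents(empty, g)
  expect_equal(unname(ze$extents_mm), c(0, 0, 0))
  expect_equal(ze$volume_mm3, 0)

  one <- empty
  one[10, 12, 14] <- TRUE
  z1 <- zone_extents(one, g)
  expect_equal(unname(z1$extents_mm), c(0.25, 0.25, 0.25))
  expect_equal(z1$volume_mm3, 0.25^3)

  # ellipsoid with semi-axes (x, y, z) = (5, 2, 2) mm:
  # width (x) = 10 mm, height (y) = 4 mm, length (z) = 4 mm
  co <- rfablate:::coordinate_fields(g)
  ell <- array((co$x / 5e-3)^2 + (co$y / 2e-3)^2 + (co$z / 2e-3)^2 <= 1, g$n)
  ze2 <- zone_extents(ell, g)
  h_mm <- 0.25
  expect_lt(abs(ze2$extents_mm[["width"]] - 10), h_mm + 1e-9)
  expect_lt(abs(ze2$extents_mm[["height"]] - 4), h_mm + 1e-9)
  expect_lt(abs(ze2$extents_mm[["length"]] - 4), h_mm + 1e-9)
  v_exact <- 4 / 3 * pi * 5 * 2 * 2
  expect_lt(abs(ze2$volume_mm3 / v_exact - 1), 0.05)
})

test_that("the bounding box spans the two largest lobes only", {
  g <- grid_spec(0.25e-3, c(6e-3, 6e-3, 6e-3))
  m <- array(FALSE, g$n)
  m[10:15, 20:24, 20:24] <- TRUE          # lobe A (150 voxels)
  m[30:36, 20:24, 20:24] <- TRUE          # lobe B (175 voxels)
  m[44, 40, 40] <- TRUE                   # stray speck
  ze <- zone_extents(m, g, lobes = 2L)
  expect_equal(ze$n_components, 3L)
  expect_equal(ze$extents_mm[["width"]], (36 - 10 + 1) * 0.25)
  expect_equal(ze$extents_mm[["height"]], 5 * 0.25)
  # volume still counts every ablated voxel
  expect_equal(ze$volume_mm3, sum(m) * 0.25^3)
})

test_that("damage mask is monotone in time and in threshold", {
  m <- make_block_model(n1 = 20L, thermal_boundary = "dirichlet")
  set.seed(3)
  q <- array(6e6 * runif(prod(m$grid$n))^2, m$grid$n)
  dt <- 0.8 * stable_time_step(m)
  st <- thermal_state(m)
  prev <- NULL
  p <- damage_params(damage_time = 3 * dt)
  for (i in 1:40) {
    st <- step_thermal(st, m, q = q, dt = dt, damage = p)
    mask <- classify_damage(st, p, m)
    if (!is.null(prev)) expect_true(all(mask[prev]))  # never shrinks
    prev <- mask
  }
  # raising the damage temperature can only shrink the mask
  hotter <- damage_params(damage_temperature = 70, damage_time = 3 * dt)
  st2 <- thermal_state(m)
  for (i in 1:40) st2 <- step_thermal(st2, m, q = q, dt = dt, damage = hotter)
  m60 <- classify_damage(st, p, m)
  m70 <- classify_damage(st2, hotter, m)
  expect_true(all(m60[m70]))
})

test_that("component ranking is deterministic under ties", {
  g <- grid_spec(0.25e-3, c(6e-3, 6e-3, 6e-3))
  m <- array(FALSE, g$n)
  m[5:6, 5, 5] <- TRUE    # two equal-size lobes; first by voxel index wins
  m[40:41, 40, 40] <- TRUE
  z1 <- zone_extents(m, g, lobes = 1L)
  expect_equal(z1$extents_mm[["width"]], 2 * 0.25)
  # identical on repeat
  expect_identical(z1, zone_extents(m, g, lobes = 1L))
})

test_that("top view projects the mask like a photograph", {
  mk <- array(FALSE, c(4L, 5L, 3L))
  mk[2, 3, 2] <- TRUE
  tv <- mask_top_view(mk, axis = 3L)
  expect_equal(dim(tv), c(4L, 5L))
  expect_true(tv[2, 3])
  expect_equal(sum(tv), 1)
})
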