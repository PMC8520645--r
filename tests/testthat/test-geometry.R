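test_that("artery wall voxelises to a 0.5 mm annulus within one voxel", {
  h <- 0.25e-3
  g <- grid_spec(h, c(5e-3, 4e-3, 4e-3))
  m <- build_artery_model(g)
  co <- rfablate:::coordinate_fields(g)
  r <- sqrt(co$y^2 + co$z^2)
  rw <- r[as.vector(m$labels) == rfablate:::MAT[["artery_wall"]]]
  lumen_r <- 4.1e-3 / 2
  expect_true(min(rw) >= lumen_r - h & min(rw) <= lumen_r + h)
  expect_true(max(rw) <= lumen_r + 0.5e-3 + h &
                max(rw) >= lumen_r + 0.5e-3 - h)
  # inside the lumen only blood or electrode; outside the wall only connective
  expect_true(all(as.vector(m$labels)[r < lumen_r - h] %in% c(1L, 4L, 5L)))
  expect_true(all(as.vector(m$labels)[r > lumen_r + 0.5e-3 + h] == 3L))
})

test_that("unresolvable window and infeasible geometry raise errors", {
  g <- grid_spec(0.4e-3, rep(8e-3, 3))
  expect_error(build_artery_model(g, electrodes = electrode_spec(window_width = 0)),
               "window")
  expect_error(build_artery_model(grid_spec(0.6e-3, rep(13e-3, 3))),
               "window_width")
  expect_error(artery_geometry(tissue_radius = 2e-3), "tissue_radius")
  expect_error(artery_geometry(padding_radius = 5e-3), "padding_radius")
  expect_error(electrode_spec(shell_thickness = 0.4e-3), "shell_thickness")
  expect_error(electrode_spec(window_length = 4e-3), "window_length")
})

test_that("electrode metal voxel volume approaches the analytic shell volume", {
  # fine local grid so the 0.1 mm shell is resolved
  h <- 0.05e-3
  g <- grid_spec(h, c(4.5e-3, 2.5e-3, 1e-3))
  m <- build_artery_model(g)
  n_metal <- sum(m$labels == rfablate:::MAT[["electrode_metal"]])
  od <- 0.61e-3; id <- od - 2 * 0.1e-3
  v_exact <- pi / 4 * (od^2 - id^2) * 3e-3 * 2
  expect_lt(abs(n_metal * h^3 / v_exact - 1), 0.20)
})

test_that("phantom model is a gel half-space with window contact", {
  g <- grid_spec(0.4e-3, c(9e-3, 6.4e-3, 6.4e-3))
  m <- build_phantom_model(g, gel_depth = 6e-3)
  co <- rfablate:::coordinate_fields(g)
  below <- co$z < 0 & co$z >= -6e-3
  lab <- as.vector(m$labels)
  # all voxels below the surface are gel except the dipping electrode parts
  expect_true(all(lab[below] %in% c(rfablate:::MAT[["gel"]], 4L, 5L)))
  expect_true(all(lab[!below] %in% c(rfablate:::MAT[["ambient"]], 4L, 5L)))
  expect_equal(sum(lab %in% c(1L, 2L, 3L)), 0)  # no blood or artery labels
  # both terminals couple to gel through at least one window contact face
  for (e in 1:2) {
    faces <- 0L
    for (ax in 1:3) {
      ct <- m$contacts[[ax]]
      faces <- faces + sum(ct$electrode == e &
                             lab[ct$tissue] == rfablate:::MAT[["gel"]])
    }
    expect_gt(faces, 0)
  }
  expect_error(build_phantom_model(g, gel_depth = 2e-3), "gel_depth")
})

test_that("mirror symmetry plane is found exactly when present", {
  g <- grid_spec(0.4e-3, c(8e-3, 6.4e-3, 6.4e-3))
  m <- build_artery_model(g)
  pl <- mirror_symmetry_plane(m)
  expect_equal(pl$normal, "x")
  expect_equal(pl$position, 0)
  # unequal electrode lengths break the symmetry
  mu <- build_artery_model(g, electrodes = electrode_spec(length = c(3e-3, 2.6e-3)))
  expect_null(mirror_symmetry_plane(mu))
  # the phantom construction is mirror symmetric too
  gp <- grid_spec(0.4e-3, c(9e-3, 6.4e-3, 6.4e-3))
  mp <- build_phantom_model(gp, gel_depth = 6e-3)
  expect_equal(mirror_symmetry_plane(mp)$position, 0)
})

test_that("terminal masks are disjoint, in metal, and never touch", {
  g <- grid_spec(0.25e-3, c(6e-3, 4e-3, 4e-3))
  m <- build_artery_model(g)
  expect_gt(sum(m$terminal_pos), 0)
  expect_gt(sum(m$terminal_neg), 0)
  expect_equal(sum(m$terminal_pos & m$terminal_neg), 0)
  metal <- m$labels == rfablate:::MAT[["electrode_metal"]]
  expect_true(all(metal[m$terminal_pos]))
  expect_true(all(metal[m$terminal_neg]))
  expect_equal(rfablate:::mask_face_adjacency(m$eid == 1L, m$eid == 2L), 0)
})

test_that("model construction is a pure function of its inputs", {
  g <- grid_spec(0.4e-3, c(8e-3, 6.4e-3, 6.4e-3))
  m1 <- build_artery_model(g)
  m2 <- build_artery_model(g)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$contacts, m2$contacts)
  p1 <- build_phantom_model(g, gel_depth = 6e-3)
  p2 <- build_phantom_model(g, gel_depth = 6e-3)
  expect_identical(p1$labels, p2$labels)
})

test_that("region volumes converge toward analytic cylinder volumes", {
  vol_err <- function(h) {
    g <- grid_spec(h, c(5e-3, 5e-3, 5e-3))
    m <- build_artery_model(g)
    # blood cross-section away from the electrodes (|x| > 4 mm)
    co <- rfablate:::coordinate_fields(g)
    far <- abs(co$x) > 4e-3
    n_slices <- length(unique(co$x[far]))
    a_meas <- sum(as.vector(m$labels)[far] == 1L) * h^2 / n_slices
    abs(a_meas / (pi * (4.1e-3 / 2)^2) - 1)
  }
  # staircase error oscillates between single halvings; across a 4x
  # refinement it must at least halve
  e1 <- vol_err(0.5e-3)
  e2 <- vol_err(0.125e-3)
  expect_lte(e2, e1 / 2)
  expect_lt(e2, 0.02)
})
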