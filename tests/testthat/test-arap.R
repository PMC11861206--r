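make_state <- function(seed = 21, ...) {
  leaf <- generate_leaf(leaf_params(seed = seed, ...))
  mesh <- sqrt3_subdivide(normalize_mesh(triangulate_grid(leaf)), 1L)
  list(mesh = mesh, state = arap_initialize(mesh))
}

test_that("a planar mesh is already an ARAP optimum", {
  mesh3 <- triangulate_grid(flat_rect_leaf(n = 6))
  st <- arap_initialize(mesh3)
  expect_true(all(st$cs[, 1] == 1 & st$cs[, 2] == 0))
  ## the initial map is an isometry: every Jacobian is a pure rotation, so
  ## one local step drives the energy to zero
  expect_lt(arap_local_step(st)$energy, 1e-18)
  fl <- arap_flatten(mesh3)
  expect_lt(utils::tail(fl$trace, 1), 1e-18)
  ## congruent to the input up to rigid motion: compare edge lengths
  d3 <- dist(mesh3$vertices)
  d2 <- dist(fl$mesh2d$vertices)
  expect_equal(as.vector(d2), as.vector(d3), tolerance = 1e-9)
  expect_equal(fl$report$area_ratio, 1, tolerance = 1e-12)
})

test_that("the local step is the Frobenius-nearest rotation", {
  ## brute-force oracle over a theta grid
  nearest_rot_bf <- function(J) {
    th <- seq(0, 2 * pi, length.out = 100001)
    obj <- (J[1, 1] - cos(th))^2 + (J[1, 2] + sin(th))^2 +
           (J[2, 1] - sin(th))^2 + (J[2, 2] - cos(th))^2
    th[which.min(obj)]
  }
  run <- make_state()
  st <- run$state
  ## inject handcrafted Jacobians into the first rows
  st$J[1, ] <- c(2, 0, 0, 1)                       # diag(2,1) -> identity
  phi <- 0.6
  st$J[2, ] <- c(cos(phi), -sin(phi), sin(phi), cos(phi))  # rotation -> itself
  st2 <- arap_local_step(st)
  expect_equal(st2$cs[1, ], c(1, 0), tolerance = 1e-9)
  expect_equal(atan2(st2$cs[2, 2], st2$cs[2, 1]), phi, tolerance = 1e-9)
  for (t in 3:6) {
    th_bf <- nearest_rot_bf(matrix(st$J[t, ], 2, byrow = TRUE))
    th <- atan2(st2$cs[t, 2], st2$cs[t, 1]) %% (2 * pi)
    expect_equal(th, th_bf, tolerance = 1e-3)
  }
  expect_lte(st2$energy, st$energy + 1e-12)
})

test_that("the global step minimizes exactly and depends only on the rotations", {
  run <- make_state(seed = 22, bend_curvature = 0.04, fold_amp = 0.2)
  st <- arap_local_step(run$state)
  e0 <- st$energy
  st_a <- st
  st_a$u <- st$u + matrix(rnorm(length(st$u), 0, 0.3), ncol = 2)
  st_b <- st
  st_b$u <- st$u + matrix(rnorm(length(st$u), 0, 0.3), ncol = 2)
  ga <- arap_global_step(st_a)
  gb <- arap_global_step(st_b)
  expect_equal(ga$u, gb$u, tolerance = 1e-9)
  expect_lte(ga$energy, e0 + 1e-12)
  ## exact minimizer: repeating the global step with the same rotations
  ## changes nothing
  gc <- arap_global_step(ga)
  expect_equal(gc$u, ga$u, tolerance = 1e-10)
  expect_equal(gc$energy, ga$energy, tolerance = 1e-12)
})

test_that("the energy trace is monotonically non-increasing", {
  for (seed in c(31, 32)) {
    run <- suppressWarnings(
      arap_flatten(sqrt3_subdivide(normalize_mesh(triangulate_grid(
        generate_leaf(leaf_params(seed = seed, fold_amp = 0.25,
                                  twist_total = 0.3)))), 2L)))
    expect_true(all(diff(run$trace) <= 1e-12 * max(run$trace[1], 1)))
    expect_true(all(run$trace >= 0))
  }
})

test_that("a developable bent leaf flattens with unit area ratio", {
  p_bent <- leaf_params(bend_curvature = 0.03, twist_total = 0, wave_amp = 0,
                        fold_amp = 0, seed = 40)
  mesh <- sqrt3_subdivide(normalize_mesh(triangulate_grid(
    generate_leaf(p_bent))), 2L)
  fl <- suppressWarnings(arap_flatten(mesh))
  expect_equal(fl$report$area_ratio, 1, tolerance = 1e-3)
  ## analytic unrolling oracle: the same leaf generated without bend is the
  ## exact development of the bent surface
  p_flat <- p_bent
  p_flat$bend_curvature <- 0
  unrolled <- sqrt3_subdivide(normalize_mesh(triangulate_grid(
    generate_leaf(p_flat))), 2L)
  expect_equal(mesh_area(fl$mesh2d), mesh_area(unrolled), tolerance = 0.01)
})

test_that("flattening is invariant to rigid motions of the 3D input", {
  leaf <- generate_leaf(leaf_params(seed = 44, bend_curvature = 0.03,
                                    fold_amp = 0.15))
  mesh <- sqrt3_subdivide(normalize_mesh(triangulate_grid(leaf)), 1L)
  th <- 1.1; ph <- 0.4
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  moved <- mesh
  moved$vertices <- mesh$vertices %*% (rz %*% rx) + 2
  u1 <- suppressWarnings(arap_flatten(mesh))$mesh2d$vertices
  u2 <- suppressWarnings(arap_flatten(moved))$mesh2d$vertices
  expect_equal(u2, u1, tolerance = 1e-5)
})

test_that("the output 2D mesh sits in the canonical frame", {
  run <- suppressWarnings(process_leaf(generate_leaf(leaf_params(seed = 45))))
  u <- run$mesh2d$vertices
  expect_equal(colMeans(u), c(0, 0), tolerance = 1e-9)
  expect_gt(u[run$mesh2d$tip_index, 1], 0)
  expect_gt(u[run$mesh2d$grid[1, 1], 2], 0)
  expect_gt(sum(leafatlas:::face_areas_signed(u, run$mesh2d$faces)), 0)
})

test_that("fold maps are zero on planes, bounded, and localized where folds are", {
  pm3 <- triangulate_grid(flat_rect_leaf())
  pm2 <- planar_mesh2d(flat_rect_leaf())
  fm <- fold_colormap(pm3, pm2)
  expect_true(all(fm$values == 0))

  ## folds concentrated toward the base (lower) half by construction
  leaf <- generate_leaf(leaf_params(bend_curvature = 0, twist_total = 0,
                                    wave_amp = 0, fold_amp = 0.6,
                                    seed = 50))
  mesh <- sqrt3_subdivide(normalize_mesh(triangulate_grid(leaf)), 1L)
  fl <- suppressWarnings(arap_flatten(mesh))
  fm2 <- fold_colormap(mesh, fl$mesh2d)
  expect_true(all(fm2$values >= 0 & fm2$values <= pi / 2 + 1e-12))
  cx <- colMeans(matrix(fl$mesh2d$vertices[t(mesh$faces), 1], nrow = 3))
  expect_gt(mean(fm2$values[cx < 0]), mean(fm2$values[cx > 0]))

  expect_error(fold_colormap(mesh, pm2), "topology mismatch")
})
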