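test_that("width and chain features of a rectangular leaf are exact", {
  mesh <- planar_mesh2d(flat_rect_leaf(n = 5, length_cm = 20, width_cm = 4))
  wf <- width_features(mesh)
  expect_equal(unname(wf["WA"]), 4)
  expect_equal(unname(wf["WM"]), 4)
  expect_equal(unname(wf["WV"]), 0)
  expect_equal(unname(wf["WP"]), 0)        # tie resolved toward the base
  em <- edge_and_midvein_features(mesh)
  expect_equal(unname(em["ML"]), 20, tolerance = 1e-12)
  expect_equal(unname(em["MOA"]), 0, tolerance = 1e-9)
  expect_equal(unname(em["MTA"]), 0, tolerance = 1e-9)
  expect_equal(unname(em["MTV"]), 0, tolerance = 1e-12)
  ## body rectangle (16 x 4) plus the 4-triangle tip fan (base 4, height 4)
  expect_equal(unname(area_feature(mesh)), 16 * 4 + 0.5 * 4 * 4,
               tolerance = 1e-9)
})

test_that("straight-margin triangular leaves have zero offset angles", {
  mesh <- planar_mesh2d(triangle_leaf())
  em <- edge_and_midvein_features(mesh)
  expect_equal(unname(em[c("LOA", "ROA", "MOA", "MTA", "MTV")]),
               rep(0, 5), tolerance = 1e-9)
  ## analytic tip angle: last transect margins at x = 15, y = +-0.5,
  ## tip at (18, 0) => half-angle atan(0.5 / 3)
  expect_equal(unname(em["LTA"]), 2 * atan(0.5 / 3), tolerance = 1e-12)
})

test_that("widest-position and arc-length features recover generator truth", {
  rec <- recovery_population()
  ml <- rec$features[, "ML"]; wm <- rec$features[, "WM"]
  wp <- rec$features[, "WP"]
  expect_true(all(abs(ml / rec$truth$length_cm - 1) < 0.02))
  expect_true(all(abs(wm / rec$truth$max_width_cm - 1) < 0.02))
  expect_true(all(abs(wp - rec$truth$widest_frac) < 0.05))
})

test_that("folding is zero on planes and pi/2 at a right dihedral", {
  pm <- triangulate_grid(flat_rect_leaf())
  ff <- folding_features(pm)
  expect_equal(ff$FA, 0)
  expect_equal(ff$FV, 0)

  ## two faces sharing an edge at a 90-degree dihedral; oracle by direct
  ## normal computation: n1 = +z, n2 = +y, alpha = arccos(0)
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(2, 1, 4))
  dihedral <- leaf_mesh(v, f, roles = rep("interior", 4))
  ffd <- folding_features(dihedral)
  expect_equal(ffd$FA, pi / 2)
  expect_equal(ffd$FV, 0)

  ## reflection insensitivity: flipping one face's orientation changes nothing
  f2 <- rbind(c(1, 2, 3), c(1, 2, 4))
  expect_equal(folding_features(leaf_mesh(v, f2, rep("interior", 4)))$FA,
               pi / 2)

  ## the flattened 2D mesh always has zero folding
  run <- suppressWarnings(process_leaf(generate_leaf(leaf_params(seed = 61))))
  expect_equal(folding_features(run$mesh2d)$FA, 0)
})

test_that("contour features match analytic values on circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 2001)
  circ <- sample_contour(cbind(cos(th), sin(th)), 600)
  cf <- contour_features(circ)
  expect_equal(unname(cf[c("TP", "RUP", "LUP", "RLP", "LLP", "BP")]),
               rep(1, 6), tolerance = 1e-4)
  expect_equal(unname(cf["L"]), 2, tolerance = 1e-4)
  expect_equal(unname(cf["W"]), 2, tolerance = 1e-4)
  expect_equal(unname(cf["UL"]), 0, tolerance = 1e-6)
  expect_equal(unname(cf["LW"]), 1, tolerance = 1e-4)

  ## ellipse oracle: mean radius over the tip sector by numeric integration
  a <- 3; b <- 1
  r_th <- function(t) a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
  tip_mean <- stats::integrate(r_th, -pi / 12, pi / 12)$value / (pi / 6)
  ec <- sample_contour(ellipse_polygon(a, b), 600)
  ecf <- contour_features(ec)
  ## discrete 51-ray mean vs continuous integral: O(1/rays) agreement
  expect_equal(unname(ecf["TP"]), tip_mean, tolerance = 5e-3)
  expect_equal(unname(ecf["BP"]), tip_mean, tolerance = 5e-3)
  ## continuum symmetry, up to the one-ray sector-size asymmetry
  expect_lt(abs(ecf["UL"]), 0.01)
})

test_that("the full vector has 29 features with exact definitional identities", {
  run <- suppressWarnings(process_leaf(generate_leaf(leaf_params(seed = 62))))
  f <- run$features
  expect_identical(names(f), feature_names())
  expect_length(f, 29L)
  expect_true(all(is.finite(f)))
  expect_identical(unname(f["LWR"]), unname(f["ML"] / f["WA"]))
  expect_identical(unname(f["LW"]), unname(f["L"] / f["W"]))
  expect_identical(unname(f["UL"]), unname(f["UP"] - f["LP"]))
  expect_true(f["WP"] >= 0 && f["WP"] <= 1)
  expect_true(f["FA"] >= 0 && f["FA"] <= pi / 2)
  expect_true(f["LTA"] > 0 && f["LTA"] < pi)
})

test_that("features transform covariantly under uniform scaling", {
  leaf <- generate_leaf(leaf_params(seed = 63))
  leaf2 <- leaf
  leaf2$transects <- leaf$transects * 2
  leaf2$tip <- leaf$tip * 2
  f1 <- suppressWarnings(process_leaf(leaf))$features
  f2 <- suppressWarnings(process_leaf(leaf2))$features
  lengths_cm <- c("LL", "RL", "ML", "WA", "WM", "TP", "RUP", "LUP", "RLP",
                  "LLP", "BP", "UP", "LP", "L", "W", "UL")
  expect_equal(f2[lengths_cm], 2 * f1[lengths_cm], tolerance = 1e-6)
  expect_equal(unname(f2["A"]), unname(4 * f1["A"]), tolerance = 1e-6)
  expect_equal(unname(f2["WV"]), unname(4 * f1["WV"]), tolerance = 1e-6)
  dimensionless <- c("WP", "LWR", "LTA", "LOA", "ROA", "MOA", "MTA", "MTV",
                     "FA", "FV", "LW")
  expect_equal(f2[dimensionless], f1[dimensionless], tolerance = 1e-6)
})

test_that("mirroring a leaf swaps left/right features and fixes the rest", {
  ## planar leaf with deliberately asymmetric wavy margins, so left/right
  ## features differ; the mirrored acquisition reverses each transect
  n <- 9
  tt <- (seq_len(n) - 1) / n
  tr <- array(0, c(n, 5, 3))
  for (i in seq_len(n)) {
    left <- 2.5 + 0.5 * sin(6 * tt[i])
    right <- -2.5 + 0.3 * cos(5 * tt[i])
    tr[i, , 1] <- tt[i] * 24 + c(0.2, 0.1, 0, 0.1, 0.2) * sin(3 * tt[i])
    tr[i, , 2] <- seq(left, right, length.out = 5)
  }
  leaf <- digitized_leaf(tr, c(24, 0, 0))
  mirrored <- leaf
  mirrored$transects <- leaf$transects[, 5:1, ]   # reverse the columns
  f1 <- suppressWarnings(process_leaf(leaf))$features
  f2 <- suppressWarnings(process_leaf(mirrored))$features
  swaps <- rbind(c("LL", "RL"), c("LOA", "ROA"), c("LUP", "RUP"),
                 c("LLP", "RLP"))
  for (i in seq_len(nrow(swaps))) {
    expect_equal(unname(f2[swaps[i, 1]]), unname(f1[swaps[i, 2]]),
                 tolerance = 0.02)
    expect_equal(unname(f2[swaps[i, 2]]), unname(f1[swaps[i, 1]]),
                 tolerance = 0.02)
  }
  expect_gt(abs(f1["LL"] - f1["RL"]), 0.01)   # genuinely asymmetric fixture
  for (nm in c("ML", "A", "FA", "WM", "WP"))
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 0.02)
})
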