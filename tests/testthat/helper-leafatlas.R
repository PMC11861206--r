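# Shared fixtures: simple analytic leaves and cached heavy runs.

## planar rectangular leaf grid: constant width, straight margins,
## left column (col 1) at +y, tip ahead of the last transect on the midline
flat_rect_leaf <- function(n = 5, length_cm = 20, width_cm = 4) {
  tt <- (seq_len(n) - 1) / n * length_cm
  offs <- seq(width_cm / 2, -width_cm / 2, length.out = 5)
  tr <- array(0, c(n, 5, 3))
  for (i in seq_len(n)) {
    tr[i, , 1] <- tt[i]
    tr[i, , 2] <- offs
  }
  digitized_leaf(tr, c(length_cm, 0, 0))
}

## planar triangular leaf: width shrinks linearly to zero toward the tip,
## so both margins and the midvein are straight lines
triangle_leaf <- function(n = 6, length_cm = 18, base_width_cm = 6) {
  tt <- (seq_len(n) - 1) / n
  offs <- seq(0.5, -0.5, length.out = 5)
  tr <- array(0, c(n, 5, 3))
  for (i in seq_len(n)) {
    tr[i, , 1] <- tt[i] * length_cm
    tr[i, , 2] <- offs * base_width_cm * (1 - tt[i])
  }
  digitized_leaf(tr, c(length_cm, 0, 0))
}

## 2D mesh straight from a planar digitized leaf (no ARAP involved)
planar_mesh2d <- function(leaf) {
  m <- triangulate_grid(leaf)
  leaf_mesh(m$vertices[, 1:2], m$faces, m$roles, grid = m$grid,
            tip_index = m$tip_index, scale_to_cm = 1)
}

## closed polygon approximating an ellipse, centered at the origin
ellipse_polygon <- function(a = 3, b = 1, k = 2000) {
  th <- seq(0, 2 * pi, length.out = k + 1)
  cbind(a * cos(th), b * sin(th))
}

## heavyweight shared runs, computed once per test session
la_cache <- new.env(parent = emptyenv())

default_population_run <- function() {
  if (is.null(la_cache$pop100)) {
    pop <- generate_population(population_spec(master_seed = 1))
    res <- suppressWarnings(run_pipeline(pop$leaves))
    la_cache$pop100 <- list(pop = pop, res = res)
  }
  la_cache$pop100
}

## 50 single-replicate leaves at the generator's default deformation
## magnitudes, flattened; per-leaf 2D/3D area ratios and energy traces
area_population <- function() {
  if (is.null(la_cache$area50)) {
    pop <- generate_population(
      population_spec(n_lines = 50, replicates = 1, master_seed = 7))
    runs <- lapply(pop$leaves,
                   function(lf) suppressWarnings(process_leaf(lf)))
    la_cache$area50 <- list(
      ratios = vapply(runs, function(r) r$area_ratio, numeric(1)),
      traces = lapply(runs, function(r) r$trace))
  }
  la_cache$area50
}

## 30 noise-free leaves with known ground truth for parameter recovery
recovery_population <- function() {
  if (is.null(la_cache$rec30)) {
    pop <- generate_population(
      population_spec(n_lines = 30, replicates = 1, noise_ratio = 0,
                      jitter_cm = 0, master_seed = 11))
    feats <- t(vapply(pop$leaves, function(lf)
      suppressWarnings(process_leaf(lf))$features, numeric(29)))
    la_cache$rec30 <- list(truth = pop$truth, features = feats)
  }
  la_cache$rec30
}
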