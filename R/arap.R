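#' As-rigid-as-possible planar parameterization
#'
#' Flattens a 3D leaf mesh to the plane by minimizing the ARAP energy
#' `E(u, L) = sum_t A_t * ||J_t(u) - L_t||_F^2`, where `A_t` is the 3D area
#' of triangle `t`, `J_t` the 2x2 Jacobian of the planar map `u` relative
#' to a per-triangle isometric 2D frame of the 3D triangle, and `L_t` a
#' 2x2 rotation. The energy is minimized by local/global alternation:
#' the local step projects each `J_t` onto the rotations, the global step
#' solves one sparse least-squares system for `u` with all `L_t` fixed.
#' Both steps are exact minimizers over their block, so the energy is
#' monotonically non-increasing.
#'
#' @name arap
NULL

## Per-triangle reference frames: areas A_t and the 2x2 inverse local
## coordinate matrix M_t (stored as columns m11, m21, m12, m22) such that
## J_t = [u1-u0 | u2-u0] %*% M_t.
arap_frames <- function(vertices, faces) {
  x0 <- vertices[faces[, 1], , drop = FALSE]
  v1 <- vertices[faces[, 2], , drop = FALSE] - x0
  v2 <- vertices[faces[, 3], , drop = FALSE] - x0
  if (ncol(vertices) == 2L) { v1 <- cbind(v1, 0); v2 <- cbind(v2, 0) }
  l1 <- row_norms(v1)
  if (any(l1 < 1e-14)) stop("degenerate triangle (zero-length edge)")
  e1 <- v1 / l1
  nrm <- cross3(v1, v2)
  A <- row_norms(nrm) / 2
  if (any(A < 1e-14)) stop("degenerate (zero-area) triangle")
  e2 <- cross3(nrm, e1)
  e2 <- e2 / row_norms(e2)
  x2x <- rowSums(v2 * e1)
  x2y <- rowSums(v2 * e2)
  det <- l1 * x2y
  list(A = A,
       M = cbind(m11 = x2y / det, m21 = rep(0, length(l1)),
                 m12 = -x2x / det, m22 = l1 / det))
}

arap_jacobians <- function(u, faces, M) {
  U1 <- u[faces[, 2], , drop = FALSE] - u[faces[, 1], , drop = FALSE]
  U2 <- u[faces[, 3], , drop = FALSE] - u[faces[, 1], , drop = FALSE]
  cbind(J11 = U1[, 1] * M[, "m11"] + U2[, 1] * M[, "m21"],
        J12 = U1[, 1] * M[, "m12"] + U2[, 1] * M[, "m22"],
        J21 = U1[, 2] * M[, "m11"] + U2[, 2] * M[, "m21"],
        J22 = U1[, 2] * M[, "m12"] + U2[, 2] * M[, "m22"])
}

arap_energy_of <- function(J, cs, A) {
  sum(A * ((J[, "J11"] - cs[, 1])^2 + (J[, "J12"] + cs[, 2])^2 +
           (J[, "J21"] - cs[, 2])^2 + (J[, "J22"] - cs[, 1])^2))
}

## Sparse gradient operator: 2T rows (two Jacobian columns per triangle)
## plus one centroid gauge row, V columns. Weighted by sqrt(A_t).
arap_gradient <- function(faces, frames, nv) {
  M <- frames$M
  sa <- sqrt(frames$A)
  m <- nrow(faces)
  a1 <- cbind(-(M[, "m11"] + M[, "m21"]), M[, "m11"], M[, "m21"]) * sa
  a2 <- cbind(-(M[, "m12"] + M[, "m22"]), M[, "m12"], M[, "m22"]) * sa
  i <- c(rep(seq_len(m), 3L), rep(m + seq_len(m), 3L),
         rep(2L * m + 1L, nv))
  j <- c(as.vector(faces), as.vector(faces), seq_len(nv))
  x <- c(as.vector(a1), as.vector(a2),
         rep(sqrt(mean(frames$A)) / nv, nv))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(2L * m + 1L, nv))
}

#' Initialize an ARAP state
#'
#' Computes per-triangle reference frames from the 3D mesh, assembles and
#' factors the global-step system, and produces an initial planar map by
#' least-squares conformal flattening (two pinned vertices: midvein base
#' and tip), falling back to projection onto the two principal axes if the
#' conformal solve degenerates. All `L_t` start as identity rotations.
#'
#' @param mesh a 3D disk-topology [leaf_mesh()] with positive face areas.
#' @return an object of class `arap_state` with fields `u` (planar map),
#'   `cs` (per-triangle rotation as cos/sin columns), `A`, `J`, `energy`.
#' @export
arap_initialize <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  frames <- arap_frames(v, f)
  G <- arap_gradient(f, frames, nv)
  GtG <- Matrix::crossprod(G)
  fact <- Matrix::Cholesky(GtG, LDL = FALSE, perm = TRUE)
  u <- tryCatch(lscm_init(v, f, frames, mesh), error = function(e) NULL)
  if (is.null(u) || any(!is.finite(u)) ||
      sum(abs(face_areas_signed(u, f))) < 1e-12) {
    pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
    u <- pc$x[, 1:2, drop = FALSE]
  }
  if (sum(face_areas_signed(u, f)) < 0) u[, 2] <- -u[, 2]
  u <- sweep(u, 2, colMeans(u))
  cs <- cbind(rep(1, nrow(f)), rep(0, nrow(f)))
  J <- arap_jacobians(u, f, frames$M)
  structure(list(u = u, cs = cs, A = frames$A, M = frames$M, J = J,
                 faces = f, G = G, chol = fact,
                 energy = arap_energy_of(J, cs, frames$A)),
            class = "arap_state")
}

## Least-squares conformal (LSCM) initial map with two pinned vertices.
lscm_init <- function(v, f, frames, mesh) {
  nv <- nrow(v)
  m <- nrow(f)
  M <- frames$M
  sa <- sqrt(frames$A)
  a0 <- cbind(-(M[, "m11"] + M[, "m21"]), -(M[, "m12"] + M[, "m22"]))
  a1 <- cbind(M[, "m11"], M[, "m12"])
  a2 <- cbind(M[, "m21"], M[, "m22"])
  ## rows: per triangle r1 = J11 - J22, r2 = J12 + J21 (x-part cols 1..nv,
  ## y-part cols nv+1..2nv)
  trip_i <- c(rep(seq_len(m), 6L), rep(m + seq_len(m), 6L))
  trip_j <- c(f[, 1], f[, 2], f[, 3], nv + f[, 1], nv + f[, 2], nv + f[, 3],
              f[, 1], f[, 2], f[, 3], nv + f[, 1], nv + f[, 2], nv + f[, 3])
  trip_x <- c(a0[, 1] * sa, a1[, 1] * sa, a2[, 1] * sa,
              -a0[, 2] * sa, -a1[, 2] * sa, -a2[, 2] * sa,
              a0[, 2] * sa, a1[, 2] * sa, a2[, 2] * sa,
              a0[, 1] * sa, a1[, 1] * sa, a2[, 1] * sa)
  Afull <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(2L * m, 2L * nv))
  p1 <- if (!is.null(mesh$grid)) mesh$grid[1, 3] else which.min(v[, 1])
  p2 <- mesh$tip_index %||% which.max(v[, 1])
  if (p1 == p2) stop("cannot pin: coincident pin vertices")
  d <- sqrt(sum((v[p2, ] - v[p1, ])^2))
  pin_cols <- c(p1, p2, nv + p1, nv + p2)
  pin_vals <- c(0, d, 0, 0)
  free <- setdiff(seq_len(2L * nv), pin_cols)
  rhs_fix <- Afull[, pin_cols, drop = FALSE] %*% pin_vals
  Af <- Afull[, free, drop = FALSE]
  sol <- Matrix::solve(Matrix::crossprod(Af),
                       Matrix::crossprod(Af, -rhs_fix))
  uu <- numeric(2L * nv)
  uu[pin_cols] <- pin_vals
  uu[free] <- as.numeric(sol)
  cbind(uu[seq_len(nv)], uu[nv + seq_len(nv)])
}

#' ARAP local step: project Jacobians onto rotations
#'
#' Sets each `L_t` to the rotation nearest `J_t` in Frobenius norm (the
#' closed-form 2x2 polar factor). The energy never increases.
#'
#' @param state an `arap_state`.
#' @return the updated state.
#' @export
arap_local_step <- function(state) {
  J <- state$J
  ang <- atan2(J[, "J21"] - J[, "J12"], J[, "J11"] + J[, "J22"])
  state$cs <- cbind(cos(ang), sin(ang))
  state$energy <- arap_energy_of(J, state$cs, state$A)
  state
}

#' ARAP global step: solve for the planar map with rotations fixed
#'
#' Minimizes the energy over all planar maps `u` with the `L_t` fixed,
#' via the prefactored sparse normal equations; the translation gauge is
#' fixed by pinning the vertex centroid to the origin. The energy never
#' increases.
#'
#' @param state an `arap_state`.
#' @return the updated state.
#' @export
arap_global_step <- function(state) {
  sa <- sqrt(state$A)
  cs <- state$cs
  bx <- c(sa * cs[, 1], -sa * cs[, 2], 0)
  by <- c(sa * cs[, 2], sa * cs[, 1], 0)
  ux <- Matrix::solve(state$chol, Matrix::crossprod(state$G, bx))
  uy <- Matrix::solve(state$chol, Matrix::crossprod(state$G, by))
  state$u <- cbind(as.numeric(ux), as.numeric(uy))
  state$J <- arap_jacobians(state$u, state$faces, state$M)
  state$energy <- arap_energy_of(state$J, cs, state$A)
  state
}

#' Flatten a 3D leaf mesh by ARAP parameterization
#'
#' Alternates [arap_local_step()] and [arap_global_step()] until the
#' relative energy decrease falls below `tol` or `max_iters` is reached.
#' The output 2D mesh shares topology, roles and `scale_to_cm` with the
#' input and is re-oriented to the canonical frame (centroid at the
#' origin, tip toward +x, left edge at y > 0).
#'
#' @param mesh a normalized, subdivided 3D [leaf_mesh()].
#' @param tol relative energy-decrease stopping threshold.
#' @param max_iters maximum number of local/global alternations.
#' @return a list with `mesh2d` (the flat [leaf_mesh()]), `report` (a
#'   distortion report with `area_ratio`, `per_face_area_ratio`,
#'   `per_face_angle_distortion`), `trace` (energy after every global
#'   step), `iterations`, and `converged`.
#' @export
arap_flatten <- function(mesh, tol = 1e-6, max_iters = 200L) {
  state <- arap_initialize(mesh)
  trace <- numeric(0)
  prev <- state$energy
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(max_iters)) {
    state <- arap_local_step(state)
    state <- arap_global_step(state)
    trace <- c(trace, state$energy)
    iters <- i
    if (prev - state$energy <= tol * max(prev, 1e-300) ||
        state$energy < 1e-14) {
      converged <- TRUE
      break
    }
    prev <- state$energy
  }
  if (!converged)
    warning("ARAP did not reach tol in ", max_iters, " iterations")
  u <- canonical_2d(state$u, mesh)
  mesh2d <- leaf_mesh(u, mesh$faces, mesh$roles, grid = mesh$grid,
                      tip_index = mesh$tip_index,
                      scale_to_cm = mesh$scale_to_cm)
  area3 <- face_areas(mesh$vertices, mesh$faces)
  area2 <- face_areas(u, mesh$faces)
  resid <- sqrt((state$J[, "J11"] - state$cs[, 1])^2 +
                (state$J[, "J12"] + state$cs[, 2])^2 +
                (state$J[, "J21"] - state$cs[, 2])^2 +
                (state$J[, "J22"] - state$cs[, 1])^2)
  report <- list(area_ratio = sum(area2) / sum(area3),
                 per_face_area_ratio = area2 / area3,
                 per_face_angle_distortion = resid)
  list(mesh2d = mesh2d, report = report, trace = trace,
       iterations = iters, converged = converged)
}

## Canonical 2D frame: orientation-repair (left edge at y > 0 via winding),
## centroid at origin, principal axis to x with the tip at +x.
canonical_2d <- function(u, mesh) {
  f <- mesh$faces
  if (sum(face_areas_signed(u, f)) < 0) u[, 2] <- -u[, 2]
  u <- sweep(u, 2, colMeans(u))
  pc <- stats::prcomp(u, center = FALSE, scale. = FALSE)
  r <- pc$rotation
  if (!is.null(mesh$tip_index) && (u %*% r)[mesh$tip_index, 1] < 0)
    r[, 1] <- -r[, 1]
  r[, 2] <- c(-r[2, 1], r[1, 1])   # right-handed: rotation only
  u <- u %*% r
  if (!is.null(mesh$grid) && u[mesh$grid[1, 1], 2] < 0) u[, 2] <- -u[, 2]
  dimnames(u) <- NULL
  u
}

#' Per-face fold field for visualization
#'
#' Computes the per-face folding angle (mean angle between a 3D face's
#' normal and its edge-neighbors' normals, as in [folding_features()]) and
#' attaches it to the flattened 2D layout for plotting.
#'
#' @param mesh3d,mesh2d the 3D mesh and its ARAP-flattened 2D counterpart
#'   (matching topology).
#' @return a list of class `fold_map` with `values` (per-face angles in
#'   `[0, pi/2]`) and `mesh2d`.
#' @export
fold_colormap <- function(mesh3d, mesh2d) {
  if (!identical(dim(mesh3d$faces), dim(mesh2d$faces)) ||
      !all(mesh3d$faces == mesh2d$faces))
    stop("topology mismatch between 3D and 2D meshes")
  ff <- folding_features(mesh3d)
  structure(list(values = ff$per_face, mesh2d = mesh2d),
            class = "fold_map")
}

#' @export
plot.fold_map <- function(x, n_colors = 100L, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "red"))(n_colors)
  v <- x$mesh2d$vertices * x$mesh2d$scale_to_cm
  f <- x$mesh2d$faces
  idx <- 1L + as.integer((n_colors - 1L) *
    (x$values - min(x$values)) / max(max(x$values) - min(x$values), 1e-12))
  graphics::plot(range(v[, 1]), range(v[, 2]), type = "n", asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)", ...)
  for (t in seq_len(nrow(f)))
    graphics::polygon(v[f[t, ], 1], v[f[t, ], 2], col = pal[idx[t]],
                      border = NA)
  invisible(x)
}
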