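# Internal vectorised geometry helpers shared across modules.
# Vertices are row-matrices (n x 2 or n x 3); faces are m x 3 integer matrices.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

## Per-face normals (not normalised) of a 3D mesh; rows of zero length flag
## degenerate faces.
face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cross3(b - a, c_ - a)
}

## Unsigned triangle areas; works for 2D (shoelace) and 3D (cross product).
face_areas <- function(vertices, faces) {
  if (ncol(vertices) == 2L) {
    a <- vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 2], , drop = FALSE]
    c_ <- vertices[faces[, 3], , drop = FALSE]
    abs((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])) / 2
  } else {
    row_norms(face_normals(vertices, faces)) / 2
  }
}

## Signed areas of 2D triangles (positive = counter-clockwise winding).
face_areas_signed <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  ((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
   (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])) / 2
}

## Shoelace area of a closed 2D polygon given in order (signed; CCW > 0).
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## Arc length of an open polyline given as an ordered point matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(row_norms(diff(pts)))
}

## Sum of absolute turning (exterior) angles along an ordered polyline.
polyline_turning <- function(pts) {
  if (nrow(pts) < 3L) return(0)
  d <- diff(pts)
  len <- row_norms(d)
  keep <- len > 0
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2L) return(0)
  u <- d / row_norms(d)
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  sum(acos(pmin(1, pmax(-1, dots))))
}

## Edge table of a triangle mesh. Returns a list with the unique undirected
## edges, the per-face edge ids, and the number of faces sharing each edge.
mesh_edges <- function(faces) {
  m <- nrow(faces)
  ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key_lo <- pmin(ea[, 1], ea[, 2])
  key_hi <- pmax(ea[, 1], ea[, 2])
  key <- paste(key_lo, key_hi)
  ids <- match(key, unique(key))
  n_edges <- max(ids)
  count <- tabulate(ids, n_edges)
  first <- match(seq_len(n_edges), ids)
  list(
    edges = cbind(key_lo[first], key_hi[first]),
    face_edge = matrix(ids, nrow = m, ncol = 3),
    edge_face_count = count,
    half_face = rep(seq_len(m), 3L),   # face owning each half-edge
    half_edge = ids                    # undirected edge id of each half-edge
  )
}

## Face adjacency across shared edges: list of integer vectors per face.
face_adjacency <- function(faces) {
  et <- mesh_edges(faces)
  m <- nrow(faces)
  adj <- vector("list", m)
  ord <- order(et$half_edge)
  he <- et$half_edge[ord]
  hf <- et$half_face[ord]
  runs <- rle(he)
  pos <- cumsum(runs$lengths)
  start <- c(1L, head(pos, -1L) + 1L)
  for (k in seq_along(runs$values)) {
    if (runs$lengths[k] == 2L) {
      f1 <- hf[start[k]]; f2 <- hf[pos[k]]
      adj[[f1]] <- c(adj[[f1]], f2)
      adj[[f2]] <- c(adj[[f2]], f1)
    }
  }
  adj
}

## Boundary edges (belonging to exactly one face), as an m x 2 index matrix.
boundary_edges <- function(faces) {
  et <- mesh_edges(faces)
  et$edges[et$edge_face_count == 1L, , drop = FALSE]
}

## Chain boundary edges into a single closed loop of vertex indices
## (first vertex not repeated at the end). Errors if the boundary is not a
## single loop.
boundary_loop <- function(faces) {
  be <- boundary_edges(faces)
  if (nrow(be) == 0L) stop("mesh has no boundary (not disk topology)")
  nb <- max(be)
  nxt <- vector("list", nb)
  for (i in seq_len(nrow(be))) {
    nxt[[be[i, 1]]] <- c(nxt[[be[i, 1]]], be[i, 2])
    nxt[[be[i, 2]]] <- c(nxt[[be[i, 2]]], be[i, 1])
  }
  deg <- lengths(nxt)
  if (any(deg[deg > 0] != 2L))
    stop("boundary is not a simple loop (non-manifold boundary vertex)")
  start <- be[1, 1]
  loop <- integer(nrow(be))
  loop[1] <- start
  prev <- -1L
  cur <- start
  for (i in seq_len(nrow(be))[-1]) {
    cand <- nxt[[cur]]
    nxt_v <- cand[cand != prev][1]
    loop[i] <- nxt_v
    prev <- cur
    cur <- nxt_v
  }
  ## closed loop must return to start and consume all boundary edges
  if (!any(nxt[[cur]] == start))
    stop("mesh boundary does not close into a single loop")
  if (length(unique(loop)) != nrow(be))
    stop("mesh has more than one boundary loop")
  loop
}

## Interior angle at vertex b of the triangle/path a-b-c.
interior_angle <- function(a, b, c_) {
  u <- a - b; v <- c_ - b
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
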