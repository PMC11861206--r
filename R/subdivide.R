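#' sqrt(3) triangle subdivision
#'
#' One iteration inserts a vertex at every face centroid (role `inserted`),
#' connects it to the face's three corners, flips every interior
#' pre-iteration edge, and relaxes interior pre-iteration vertices toward
#' the average of their neighbors:
#' `p' = (1 - a_n) p + (a_n / n) * sum(neighbors)` with
#' `a_n = (4 - 2 cos(2 pi / n)) / 9` for vertex degree `n`. Boundary
#' vertices are held fixed so the leaf contour is preserved exactly. Face
#' count triples per iteration; pre-existing vertex indices and role tags
#' are preserved.
#'
#' @param mesh a manifold triangle disk [leaf_mesh()].
#' @param iterations number of subdivision passes (the pipeline default is
#'   2, multiplying the face count by 9).
#' @return the subdivided [leaf_mesh()].
#' @export
sqrt3_subdivide <- function(mesh, iterations = 1L) {
  if (iterations < 0) stop("iterations must be >= 0")
  out <- mesh
  for (it in seq_len(iterations)) out <- sqrt3_once(out)
  out
}

sqrt3_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  et <- mesh_edges(f)
  if (any(et$edge_face_count > 2L))
    stop("non-manifold edge in mesh")
  boundary_v <- unique(as.vector(et$edges[et$edge_face_count == 1L, ,
                                          drop = FALSE]))

  ## vertex 1-ring adjacency from undirected edges
  ed <- et$edges
  nbr_from <- c(ed[, 1], ed[, 2])
  nbr_to <- c(ed[, 2], ed[, 1])
  deg <- tabulate(nbr_from, nv)
  nbr_sum <- rowsum(v[nbr_to, , drop = FALSE], nbr_from)
  nbr_sum_full <- matrix(0, nv, ncol(v))
  nbr_sum_full[sort(unique(nbr_from)), ] <- nbr_sum

  relaxed <- v
  interior <- setdiff(which(deg > 0L), boundary_v)
  if (length(interior)) {
    n <- deg[interior]
    an <- (4 - 2 * cos(2 * pi / n)) / 9
    relaxed[interior, ] <- (1 - an) * v[interior, , drop = FALSE] +
      (an / n) * nbr_sum_full[interior, , drop = FALSE]
  }

  centroids <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                v[f[, 3], , drop = FALSE]) / 3
  new_v <- rbind(relaxed, centroids)
  cid <- function(face) nv + face

  ## directed half-edges in face order with owning face
  m <- nrow(f)
  he_a <- c(f[, 1], f[, 2], f[, 3])
  he_b <- c(f[, 2], f[, 3], f[, 1])
  he_f <- rep(seq_len(m), 3L)
  he_e <- et$half_edge

  ord <- order(he_e)
  ea <- he_a[ord]; eb <- he_b[ord]; ef <- he_f[ord]; ee <- he_e[ord]
  runs <- rle(ee)
  stopifnot(all(runs$lengths <= 2L))
  last <- cumsum(runs$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  single <- runs$lengths == 1L

  ## boundary edges keep their split triangle (a, b, centroid)
  fb <- cbind(ea[first[single]], eb[first[single]], cid(ef[first[single]]))
  ## interior edges are flipped: (a, c2, c1) and (b, c1, c2) where the
  ## half-edge a->b lives in the face of centroid c1
  i1 <- first[!single]; i2 <- last[!single]
  c1 <- cid(ef[i1]); c2 <- cid(ef[i2])
  fi <- rbind(cbind(ea[i1], c2, c1), cbind(eb[i1], c1, c2))

  leaf_mesh(new_v, rbind(fb, fi),
            roles = c(mesh$roles, rep("inserted", m)),
            grid = mesh$grid, tip_index = mesh$tip_index,
            scale_to_cm = mesh$scale_to_cm)
}
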