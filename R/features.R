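#' Edge and midvein features
#'
#' Polyline features of the three role-tagged chains (left margin, right
#' margin, midvein, each running from its base vertex through the original
#' digitizer vertices to the tip) of the flattened leaf:
#' \describe{
#'   \item{LL, RL, ML}{arc lengths of the left-edge, right-edge and
#'     midvein chains (cm); ML is the leaf length.}
#'   \item{LOA, ROA, MOA}{sums of absolute turning angles between
#'     consecutive segments of each chain (rad).}
#'   \item{MTA, MTV}{mean and population variance of the unsigned angle
#'     between each midvein segment and the base-to-tip chord (rad,
#'     rad^2).}
#'   \item{LTA}{interior angle at the tip vertex between its two adjacent
#'     boundary vertices (rad).}
#' }
#'
#' @param mesh2d a role-tagged 2D [leaf_mesh()] in canonical orientation.
#' @return named numeric vector with the nine features above.
#' @export
edge_and_midvein_features <- function(mesh2d) {
  g <- mesh2d$grid
  if (is.null(g) || is.null(mesh2d$tip_index))
    stop("mesh is missing role chains (grid/tip bookkeeping)")
  s <- mesh2d$scale_to_cm
  v <- mesh2d$vertices
  chain <- function(col) v[c(g[, col], mesh2d$tip_index), , drop = FALSE]
  left <- chain(1L); right <- chain(5L); mid <- chain(3L)

  seg <- diff(mid)
  chord <- mid[nrow(mid), ] - mid[1, ]
  uchord <- chord / sqrt(sum(chord^2))
  useg <- seg / row_norms(seg)
  ang <- acos(clamp(useg %*% uchord, -1, 1))

  loop <- boundary_loop(mesh2d$faces)
  ti <- match(mesh2d$tip_index, loop)
  nb <- loop[c((ti - 2L) %% length(loop) + 1L, ti %% length(loop) + 1L)]
  lta <- interior_angle(v[nb[1], ], v[mesh2d$tip_index, ], v[nb[2], ])

  c(LL = polyline_length(left) * s,
    RL = polyline_length(right) * s,
    ML = polyline_length(mid) * s,
    LOA = polyline_turning(left),
    ROA = polyline_turning(right),
    MOA = polyline_turning(mid),
    MTA = mean(ang),
    MTV = mean((ang - mean(ang))^2),
    LTA = lta)
}

#' Width features
#'
#' Widths are measured at the original digitizer transect stations
#' (tracked through subdivision and flattening) as the 2D distance between
#' the left-edge and right-edge vertex of each transect:
#' WA = mean width, WM = max width, WV = population variance (cm^2),
#' WP = midvein arc length from the base to the widest station divided by
#' the midvein length (ties resolved toward the base), LWR = ML / WA.
#'
#' @param mesh2d a role-tagged 2D [leaf_mesh()].
#' @return named numeric vector `WA, WM, WV, WP, LWR`.
#' @export
width_features <- function(mesh2d) {
  g <- mesh2d$grid
  if (is.null(g) || nrow(g) < 2L) stop("need >= 2 transect stations")
  s <- mesh2d$scale_to_cm
  v <- mesh2d$vertices
  widths <- row_norms(v[g[, 5], , drop = FALSE] -
                      v[g[, 1], , drop = FALSE]) * s
  mid <- v[c(g[, 3], mesh2d$tip_index), , drop = FALSE]
  seglen <- c(0, cumsum(row_norms(diff(mid)))) * s
  ml <- seglen[length(seglen)]
  istar <- which.max(widths)          # which.max takes the first maximum
  c(WA = mean(widths),
    WM = max(widths),
    WV = mean((widths - mean(widths))^2),
    WP = seglen[istar] / ml,
    LWR = ml / mean(widths))
}

#' Leaf area from the triangle mesh
#'
#' Sum of all triangular facet areas, in cm^2. For comparison with the
#' classical allometric estimate `leaf length x max width x 0.75`, use
#' `ML * WM * 0.75` from the other feature sets.
#'
#' @param mesh2d a 2D [leaf_mesh()].
#' @return scalar `A` (cm^2).
#' @export
area_feature <- function(mesh2d) c(A = mesh_area(mesh2d))

#' Folding degree of a 3D leaf surface
#'
#' For each face `i` with `n_i` edge-adjacent faces the per-face fold is
#' the mean of `alpha(N_i, N_ij)` over its neighbors, where
#' `alpha(x, y) = arccos(|x . y| / (|x| |y|))` uses the absolute dot
#' product so the measure ignores normal orientation. `FA` is the mean of
#' the per-face folds over all faces and `FV` their population variance.
#' Folding is a property of the 3D surface: a planar (or flattened 2D)
#' mesh gives exactly 0.
#'
#' @param mesh a 3D (or 2D, embedded at z = 0) [leaf_mesh()].
#' @return list with `FA`, `FV` and the `per_face` fold field.
#' @export
folding_features <- function(mesh) {
  v <- mesh$vertices
  if (ncol(v) == 2L) v <- cbind(v, 0)
  nrm <- face_normals(v, mesh$faces)
  nrm <- nrm / row_norms(nrm)
  adj <- face_adjacency(mesh$faces)
  per_face <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) return(NA_real_)
    d <- abs(nrm[nb, , drop = FALSE] %*% nrm[i, ])
    mean(acos(clamp(d, 0, 1)))
  }, numeric(1))
  if (anyNA(per_face)) {
    warning("faces with no neighbors excluded from folding")
    per_face <- per_face[!is.na(per_face)]
  }
  list(FA = mean(per_face), FV = mean((per_face - mean(per_face))^2),
       per_face = per_face)
}

#' Radial contour features
#'
#' Mean ray lengths of the six contour parts plus their combinations:
#' `TP, RUP, LUP, RLP, LLP, BP` are the mean distances of each part's
#' sampling points from the leaf center; `UP`/`LP` pool both upper/both
#' lower parts; `L = TP + BP`; `W = (LUP + LLP + RUP + RLP) / 2`;
#' `UL = UP - LP`; `LW = L / W`. All distances in cm.
#'
#' @param contour a [sampled_contour()].
#' @param parts partition from [segment_contour()] (default partition used
#'   when omitted).
#' @return named numeric vector of the 12 contour features.
#' @export
contour_features <- function(contour, parts = segment_contour(contour)) {
  radii <- row_norms(contour$points)
  md <- function(idx, nm) {
    if (length(idx) == 0L) stop("empty contour part: ", nm)
    mean(radii[idx])
  }
  tp <- md(parts$tip, "tip"); bp <- md(parts$base, "base")
  lup <- md(parts$upper_left, "upper_left")
  rup <- md(parts$upper_right, "upper_right")
  llp <- md(parts$lower_left, "lower_left")
  rlp <- md(parts$lower_right, "lower_right")
  up <- mean(radii[c(parts$upper_left, parts$upper_right)])
  lp <- mean(radii[c(parts$lower_left, parts$lower_right)])
  l <- tp + bp
  w <- (lup + llp + rup + rlp) / 2
  c(TP = tp, RUP = rup, LUP = lup, RLP = rlp, LLP = llp, BP = bp,
    UP = up, LP = lp, L = l, W = w, UL = up - lp, LW = l / w)
}

#' Names of the 29 leaf-shape features
#' @return character vector of the 29 feature identifiers in table order.
#' @export
feature_names <- function() {
  c("LL", "RL", "ML", "WA", "WM", "WV", "WP", "LWR", "LTA", "LOA", "ROA",
    "MOA", "MTA", "MTV", "A", "FA", "FV",
    "TP", "RUP", "LUP", "RLP", "LLP", "BP", "UP", "LP", "L", "W", "UL", "LW")
}

#' Extract the full 29-feature vector of a leaf
#'
#' Combines [edge_and_midvein_features()], [width_features()],
#' [area_feature()], [folding_features()] (computed on the 3D mesh) and
#' [contour_features()] into the complete 29-feature phenotype. The
#' definitional identities `LWR = ML/WA`, `LW = L/W` and `UL = UP - LP`
#' hold exactly.
#'
#' @param mesh2d the flattened 2D [leaf_mesh()].
#' @param mesh3d the matching subdivided 3D [leaf_mesh()].
#' @param contour the leaf's [sampled_contour()].
#' @return named numeric vector of length 29 (see [feature_names()]).
#' @export
extract_all <- function(mesh2d, mesh3d, contour) {
  em <- edge_and_midvein_features(mesh2d)
  wf <- width_features(mesh2d)
  fold <- folding_features(mesh3d)
  cf <- contour_features(contour)
  out <- c(em[c("LL", "RL", "ML")], wf[c("WA", "WM", "WV", "WP", "LWR")],
           em[c("LTA", "LOA", "ROA", "MOA", "MTA", "MTV")],
           area_feature(mesh2d), FA = fold$FA, FV = fold$FV, cf)
  out["LWR"] <- out["ML"] / out["WA"]   # definitional identity, exact
  stopifnot(identical(names(out), feature_names()))
  out
}
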