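#' Raw-mesh screening features
#'
#' The four quick phenotypes used to compare replicate samples within an
#' inbred line before any heavy processing: midvein length (cm), maximum
#' transect width (cm), their aspect ratio, and the raw-mesh average
#' normal angle (the folding degree FA of [folding_features()] computed on
#' the raw mesh).
#'
#' @param mesh a raw 3D [leaf_mesh()] with role tags and grid indices.
#' @return named numeric vector `c(length, width, aspect, angle)`.
#' @export
raw_screen_features <- function(mesh) {
  if (is.null(mesh$grid) || !any(mesh$roles == "midvein"))
    stop("missing role tags / grid on mesh")
  s <- mesh$scale_to_cm
  mid_chain <- c(mesh$grid[, 3], mesh$tip_index)
  len <- polyline_length(mesh$vertices[mid_chain, , drop = FALSE]) * s
  widths <- row_norms(mesh$vertices[mesh$grid[, 5], , drop = FALSE] -
                      mesh$vertices[mesh$grid[, 1], , drop = FALSE]) * s
  wid <- max(widths)
  ang <- folding_features(mesh)$FA
  c(length = len, width = wid, aspect = len / wid, angle = ang)
}

#' Screen replicate samples within inbred lines
#'
#' Within each 3-sample line group, pairwise Euclidean distances are
#' computed on the four screening features after min-max scaling each
#' feature to `[0, 1]` over the whole dataset. If one sample's distances to
#' both others exceed the remaining pair's mutual distance by more than
#' `threshold`, that sample is flagged as excluded. Groups of one or two
#' samples are never screened.
#'
#' @param records data frame with columns `line_id`, `sample_id`, `length`,
#'   `width`, `aspect`, `angle` (one row per sample).
#' @param threshold divergence threshold on scaled distances (default 0.1).
#' @return `records` with added columns `excluded` (logical) and `reason`.
#' @export
screen_replicates <- function(records, threshold = 0.1) {
  if (nrow(records) == 0L) stop("empty group: no screening records")
  feats <- as.matrix(records[, c("length", "width", "aspect", "angle")])
  if (any(!is.finite(feats))) stop("non-finite screening features")
  if (any(feats[, c("length", "width")] <= 0))
    stop("length/width must be strictly positive")
  rng <- apply(feats, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1     # constant feature contributes zero distance
  scaled <- sweep(sweep(feats, 2, rng[1, ]), 2, span, "/")
  records$excluded <- FALSE
  records$reason <- ""
  for (grp in split(seq_len(nrow(records)), records$line_id)) {
    if (length(grp) != 3L) next
    d <- as.matrix(stats::dist(scaled[grp, , drop = FALSE]))
    fires <- vapply(1:3, function(k) {
      oth <- setdiff(1:3, k)
      all(d[k, oth] > d[oth[1], oth[2]] + threshold)
    }, logical(1))
    if (any(fires)) {
      k <- which(fires)
      if (length(k) > 1L) k <- k[which.max(rowMeans(d)[k])]
      records$excluded[grp[k]] <- TRUE
      records$reason[grp[k]] <-
        sprintf("divergent replicate (distances %.3f/%.3f vs pair %.3f)",
                d[k, setdiff(1:3, k)][1], d[k, setdiff(1:3, k)][2],
                d[setdiff(1:3, k)[1], setdiff(1:3, k)[2]])
    }
  }
  records
}

#' Normalize a leaf mesh into the canonical frame
#'
#' Principal axes of the vertex cloud are aligned to x, y, z (largest
#' variance along x), with signs fixed so the tip has the largest x
#' coordinate and the left-edge base vertex has positive y; the z axis
#' completes a right-handed frame. The centroid moves to the origin and the
#' mesh is uniformly scaled so all coordinates lie in `[-1, 1]` with
#' equality attained; `scale_to_cm` records the inverse scale.
#'
#' @param mesh a 3D [leaf_mesh()] with tip role.
#' @return the normalized [leaf_mesh()].
#' @export
normalize_mesh <- function(mesh) {
  v <- mesh$vertices
  stopifnot(ncol(v) == 3L)
  ctr <- colMeans(v)
  cen <- sweep(v, 2, ctr)
  pc <- stats::prcomp(cen, center = FALSE, scale. = FALSE)
  if (pc$sdev[2] < 1e-12 * max(pc$sdev[1], 1e-300))
    stop("degenerate geometry: vertex cloud is (near) collinear")
  rot <- pc$rotation
  co <- cen %*% rot
  tip <- mesh$tip_index
  if (is.null(tip)) stop("mesh has no tip vertex")
  if (co[tip, 1] < 0) rot[, 1] <- -rot[, 1]
  lb <- if (!is.null(mesh$grid)) mesh$grid[1, 1] else which.min(co[, 1])
  co <- cen %*% rot
  if (co[lb, 2] < 0) rot[, 2] <- -rot[, 2]
  rot[, 3] <- c(rot[2, 1] * rot[3, 2] - rot[3, 1] * rot[2, 2],
                rot[3, 1] * rot[1, 2] - rot[1, 1] * rot[3, 2],
                rot[1, 1] * rot[2, 2] - rot[2, 1] * rot[1, 2])
  co <- cen %*% rot
  dimnames(co) <- NULL
  s <- max(abs(co))
  out <- mesh
  out$vertices <- co / s
  out$scale_to_cm <- mesh$scale_to_cm * s
  out
}
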