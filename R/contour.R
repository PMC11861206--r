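#' Extract the ordered boundary polyline of a flat leaf mesh
#'
#' Boundary edges are the edges belonging to exactly one face; they are
#' chained into a single closed loop oriented counter-clockwise. Errors if
#' the mesh has more than one boundary loop.
#'
#' @param mesh2d a 2D [leaf_mesh()].
#' @return a `(k + 1) x 2` matrix of boundary points in centimeters, in
#'   CCW order, with the first point repeated as the last (closed chain).
#' @export
extract_boundary <- function(mesh2d) {
  stopifnot(ncol(mesh2d$vertices) == 2L)
  loop <- boundary_loop(mesh2d$faces)
  pts <- mesh2d$vertices[loop, , drop = FALSE] * mesh2d$scale_to_cm
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  rbind(pts, pts[1, ])
}

#' Radially sampled leaf contours
#'
#' A `sampled_contour` holds `resolution` ordered 2D points (cm); point
#' `k` (1-based) lies on the ray from the center `(0, 0)` at angle
#' `2 pi (k - 1) / resolution`.
#'
#' @param points an `R x 2` matrix of contour points (cm).
#' @param line_id,sample_id identity labels.
#' @return an object of class `sampled_contour`.
#' @export
sampled_contour <- function(points, line_id = "L0", sample_id = "S0") {
  points <- as.matrix(points)
  structure(list(points = points, resolution = nrow(points),
                 line_id = as.character(line_id),
                 sample_id = as.character(sample_id)),
            class = "sampled_contour")
}

#' @exportS3Method base::print
print.sampled_contour <- function(x, ...) {
  cat(sprintf("<sampled_contour> line=%s sample=%s: %d rays\n",
              x$line_id, x$sample_id, x$resolution))
  invisible(x)
}

#' Sample a closed boundary by rays from the leaf center
#'
#' For each of `resolution` ray angles `2 pi k / resolution` a ray from
#' the origin is intersected with every boundary segment; the intersection
#' farthest from the origin is kept, yielding the outer silhouette.
#'
#' @param boundary closed boundary polyline (first point repeated last),
#'   e.g. from [extract_boundary()]; must enclose the origin.
#' @param resolution number of rays (default 600).
#' @param line_id,sample_id labels carried to the result.
#' @return a [sampled_contour()].
#' @export
sample_contour <- function(boundary, resolution = 600L,
                           line_id = "L0", sample_id = "S0") {
  stopifnot(resolution >= 3L)
  p <- boundary[-nrow(boundary), , drop = FALSE]
  q <- boundary[-1L, , drop = FALSE]
  if (abs(polygon_area(p)) < 1e-300) stop("degenerate boundary polygon")
  ## winding test: origin must be inside the polygon
  ang_p <- atan2(p[, 2], p[, 1])
  ang_q <- atan2(q[, 2], q[, 1])
  dw <- ang_q - ang_p
  dw <- dw - 2 * pi * round(dw / (2 * pi))
  if (abs(sum(dw)) < pi) stop("no intersection: origin outside the contour")
  e <- q - p
  ks <- seq_len(resolution) - 1L
  theta <- 2 * pi * ks / resolution
  dx <- cos(theta); dy <- sin(theta)
  tol <- 1e-12
  ## cross(d, e), cross(p, e), cross(p, d) as angle x segment matrices
  den <- outer(dx, e[, 2]) - outer(dy, e[, 1])
  num_r <- matrix(p[, 1] * e[, 2] - p[, 2] * e[, 1],
                  nrow = resolution, ncol = nrow(p), byrow = TRUE)
  num_t <- outer(dy, p[, 1]) - outer(dx, p[, 2])
  ok <- abs(den) > tol
  r <- ifelse(ok, num_r / den, NA_real_)
  tt <- ifelse(ok, num_t / den, NA_real_)
  valid <- ok & !is.na(tt) & tt >= -tol & tt <= 1 + tol & r > tol
  r[!valid] <- -Inf
  rmax <- apply(r, 1L, max)
  if (any(!is.finite(rmax))) {
    bad <- theta[which(!is.finite(rmax))[1]]
    stop(sprintf("ray at angle %.6f rad has no boundary intersection", bad))
  }
  sampled_contour(cbind(rmax * dx, rmax * dy), line_id, sample_id)
}

#' Average sampled contours point-wise
#'
#' Takes the arithmetic mean of the coordinates at each ray index. With
#' `group = "line"` one averaged model per inbred line is returned; with
#' `group = "all"` a single population-average model tagged `"ALL"`.
#'
#' @param samples a list of [sampled_contour()]s sharing one resolution.
#' @param group `"line"` or `"all"`.
#' @return a list of [sampled_contour()]s (named by line) for
#'   `group = "line"`; a single [sampled_contour()] for `group = "all"`.
#' @export
average_contours <- function(samples, group = c("line", "all")) {
  group <- match.arg(group)
  res <- vapply(samples, function(s) s$resolution, numeric(1))
  if (length(unique(res)) != 1L)
    stop("mixed contour resolutions: ", paste(unique(res), collapse = ", "))
  avg <- function(ss, id) {
    pts <- Reduce(`+`, lapply(ss, function(s) s$points)) / length(ss)
    sampled_contour(pts, line_id = id, sample_id = "MEAN")
  }
  if (group == "all") return(avg(samples, "ALL"))
  ids <- vapply(samples, function(s) s$line_id, character(1))
  lapply(split(samples, ids), function(ss) avg(ss, ss[[1]]$line_id))
}

#' Partition a sampled contour into six angular parts
#'
#' In the canonical frame (tip toward +x, left edge at y > 0) the rays are
#' partitioned by angle into: tip (`|angle| <= theta_tip`), base
#' (`|angle - pi| <= theta_base`), and the remaining left half split at
#' `pi/2` into upper-left (toward the tip) and lower-left, mirrored on the
#' right. Every sampled point is assigned to exactly one part.
#'
#' @param contour a [sampled_contour()].
#' @param theta_tip,theta_base half-widths of the tip and base sectors in
#'   radians (defaults 15 degrees).
#' @return named list of integer index vectors: `tip`, `upper_left`,
#'   `lower_left`, `base`, `lower_right`, `upper_right`.
#' @export
segment_contour <- function(contour, theta_tip = pi / 12,
                            theta_base = pi / 12) {
  if (theta_tip <= 0 || theta_base <= 0 ||
      theta_tip >= pi / 2 || theta_base >= pi / 2)
    stop("sector config error: tip/base half-widths must lie in (0, pi/2)")
  R <- contour$resolution
  theta <- 2 * pi * (seq_len(R) - 1L) / R
  a <- theta - 2 * pi * (theta > pi)   # wrap to (-pi, pi]
  parts <- list(
    tip = which(abs(a) <= theta_tip),
    upper_left = which(a > theta_tip & a <= pi / 2),
    lower_left = which(a > pi / 2 & a < pi - theta_base),
    base = which(abs(abs(a) - pi) <= theta_base | a == pi),
    lower_right = which(a > -(pi - theta_base) & a < -pi / 2),
    upper_right = which(a >= -pi / 2 & a < -theta_tip))
  if (length(unlist(parts)) != R || anyDuplicated(unlist(parts)))
    stop("sector config error: parts do not partition the rays")
  parts
}
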