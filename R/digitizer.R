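#' Digitized-leaf point grids
#'
#' A `digitized_leaf` holds the ordered 3D point grid recorded by a tracked
#' digitizer probe over a maize ear leaf: `n` transects of 5 points each,
#' crossing the leaf perpendicular to the midvein from base to tip, plus a
#' single tip point, so that the total point count is `5 * n + 1`.
#'
#' @param transects numeric array of transect points: either an `n x 5 x 3`
#'   array or a `(5n) x 3` matrix in acquisition order (transect by transect,
#'   left to right within each transect). Units are centimeters.
#' @param tip length-3 numeric vector, the leaf-tip point (cm).
#' @param line_id,sample_id character labels for the inbred line and the
#'   replicate sample.
#' @return An object of class `digitized_leaf` with fields `transects`
#'   (`n x 5 x 3` array), `tip`, `line_id`, `sample_id`.
#' @examples
#' leaf <- generate_leaf(leaf_params(n_transects = 13, seed = 1))
#' n_points(leaf)  # 66
#' @export
digitized_leaf <- function(transects, tip, line_id = "L0", sample_id = "S0") {
  if (is.matrix(transects)) {
    if (ncol(transects) != 3L || nrow(transects) %% 5L != 0L)
      stop("malformed grid: transect matrix must be (5n) x 3")
    n <- nrow(transects) / 5L
    transects <- aperm(array(t(transects), dim = c(3L, 5L, n)), c(3, 2, 1))
  }
  stopifnot(length(dim(transects)) == 3L, dim(transects)[2] == 5L,
            dim(transects)[3] == 3L)
  n <- dim(transects)[1]
  if (n < 2L) stop("too few transects: need n >= 2, got ", n)
  tip <- as.numeric(tip)
  stopifnot(length(tip) == 3L)
  pts <- rbind(matrix(aperm(transects, c(2, 1, 3)), ncol = 3L), tip)
  if (anyDuplicated(pts) > 0L)
    stop("invalid grid: coincident points")
  structure(list(transects = transects, tip = tip,
                 line_id = as.character(line_id),
                 sample_id = as.character(sample_id)),
            class = "digitized_leaf")
}

#' @rdname digitized_leaf
#' @param leaf a `digitized_leaf`.
#' @export
n_transects <- function(leaf) dim(leaf$transects)[1]

#' @rdname digitized_leaf
#' @export
n_points <- function(leaf) 5L * n_transects(leaf) + 1L

#' All points of a digitized leaf in acquisition order
#'
#' Rows are the 5 points of each transect (left to right, base transect
#' first) followed by the tip point.
#'
#' @param leaf a `digitized_leaf`.
#' @return a `(5n + 1) x 3` numeric matrix (cm).
#' @export
leaf_points <- function(leaf) {
  n <- n_transects(leaf)
  m <- matrix(NA_real_, 5L * n + 1L, 3L)
  for (i in seq_len(n))
    m[(5L * (i - 1L) + 1L):(5L * i), ] <- leaf$transects[i, , ]
  m[5L * n + 1L, ] <- leaf$tip
  m
}

#' @exportS3Method base::print
print.digitized_leaf <- function(x, ...) {
  cat(sprintf("<digitized_leaf> line=%s sample=%s: %d transects, %d points\n",
              x$line_id, x$sample_id, n_transects(x), n_points(x)))
  invisible(x)
}

#' Read a digitizer grid file
#'
#' Grid files hold one point per line (`x y z`, whitespace or comma
#' separated, centimeters) in acquisition order; lines starting with `#` are
#' comments. The row count must equal `5n + 1` for some `n >= 2`: five
#' points per transect from base to tip, then the tip point.
#'
#' @param path path to a grid text file.
#' @param line_id,sample_id labels; default to values parsed from `# line:`
#'   / `# sample:` header comments when present, else the file name.
#' @return a [digitized_leaf()].
#' @export
read_digitized_leaf <- function(path, line_id = NULL, sample_id = NULL) {
  raw <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", raw, value = TRUE)
  grab <- function(key) {
    hit <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^\\s*#\\s*", key, "\\s*:\\s*"), "", hit[1])
    else NULL
  }
  if (is.null(line_id)) line_id <- grab("line")
  if (is.null(sample_id)) sample_id <- grab("sample")
  base <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(line_id)) line_id <- base
  if (is.null(sample_id)) sample_id <- base
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  pts <- do.call(rbind, lapply(strsplit(trimws(body), "[,[:space:]]+"), function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 3L || anyNA(v)) stop("malformed grid row in ", path)
    v
  }))
  k <- nrow(pts)
  if (k %% 5L != 1L)
    stop("malformed grid: ", k, " points is not of the form 5n + 1")
  n <- (k - 1L) %/% 5L
  if (n < 2L) stop("too few transects: need n >= 2, got ", n)
  digitized_leaf(pts[seq_len(5L * n), , drop = FALSE], pts[k, ],
                 line_id = line_id, sample_id = sample_id)
}

#' Write a digitizer grid file
#'
#' @param leaf a [digitized_leaf()].
#' @param path output path.
#' @export
write_digitized_leaf <- function(leaf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# line: ", leaf$line_id),
               paste0("# sample: ", leaf$sample_id)), con)
  pts <- leaf_points(leaf)
  writeLines(apply(pts, 1L, function(p)
    paste(formatC(p, format = "g", digits = 12), collapse = " ")), con)
  invisible(path)
}

#' Indexed triangle leaf meshes
#'
#' A `leaf_mesh` is an indexed triangle mesh with per-vertex role tags and
#' bookkeeping that survives normalization, subdivision and flattening:
#' `vertices` (`V x 3`, or `V x 2` once flattened), `faces` (`F x 3` integer),
#' `roles` (one of `midvein`, `left_edge`, `right_edge`, `tip`, `interior`,
#' `inserted` per vertex), `grid` (the `n x 5` matrix of original digitizer
#' vertex indices), `tip_index`, and `scale_to_cm` (multiply coordinates by
#' this to recover centimeters; 1 for raw meshes).
#'
#' @param vertices numeric matrix of coordinates.
#' @param faces integer matrix of vertex index triples.
#' @param roles character vector of per-vertex tags.
#' @param grid integer `n x 5` matrix of original grid vertex indices.
#' @param tip_index integer index of the tip vertex.
#' @param scale_to_cm positive scalar restoring centimeters.
#' @return an object of class `leaf_mesh`.
#' @export
leaf_mesh <- function(vertices, faces, roles, grid = NULL, tip_index = NULL,
                      scale_to_cm = 1) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(faces), nrow = nrow(faces))
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face references an invalid vertex index")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("face with repeated vertex indices")
  stopifnot(length(roles) == nrow(vertices), scale_to_cm > 0)
  structure(list(vertices = vertices, faces = faces,
                 roles = as.character(roles), grid = grid,
                 tip_index = tip_index, scale_to_cm = scale_to_cm),
            class = "leaf_mesh")
}

#' @exportS3Method base::print
print.leaf_mesh <- function(x, ...) {
  cat(sprintf("<leaf_mesh> %dD, %d vertices, %d faces, scale_to_cm=%.4g\n",
              ncol(x$vertices), nrow(x$vertices), nrow(x$faces),
              x$scale_to_cm))
  invisible(x)
}

#' Total mesh surface area
#'
#' Sum of triangle areas, in cm^2 (the stored `scale_to_cm` is applied).
#'
#' @param mesh a [leaf_mesh()].
#' @return scalar area in cm^2.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh$vertices, mesh$faces)) * mesh$scale_to_cm^2
}

#' Triangulate a digitizer grid into the raw 3D leaf mesh
#'
#' Between consecutive transects each of the 4 quads is split into two
#' triangles along the diagonal from its lower-left to upper-right corner;
#' the tip is joined to the last transect by a 4-triangle fan. Vertex roles
#' are assigned from the grid columns: column 1 is the left edge, column 3
#' the midvein, column 5 the right edge.
#'
#' @param leaf a [digitized_leaf()].
#' @return a [leaf_mesh()] with `8(n-1) + 4` faces.
#' @export
triangulate_grid <- function(leaf) {
  n <- n_transects(leaf)
  verts <- leaf_points(leaf)
  vid <- function(i, j) 5L * (i - 1L) + j
  tip <- 5L * n + 1L
  faces <- matrix(0L, 8L * (n - 1L) + 4L, 3L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in 1:4) {
      ll <- vid(i, j); lr <- vid(i, j + 1L)
      ul <- vid(i + 1L, j); ur <- vid(i + 1L, j + 1L)
      faces[k + 1L, ] <- c(ll, ur, ul)
      faces[k + 2L, ] <- c(ll, lr, ur)
      k <- k + 2L
    }
  }
  for (j in 1:4) {
    faces[k + 1L, ] <- c(vid(n, j), vid(n, j + 1L), tip)
    k <- k + 1L
  }
  areas <- face_areas(verts, faces)
  if (any(areas <= 1e-14)) {
    bad <- which(areas <= 1e-14)[1]
    tr <- if (bad <= 8L * (n - 1L)) (bad - 1L) %/% 8L + 1L else n
    stop("degenerate (zero-area) triangle near transect ", tr)
  }
  roles <- rep("interior", 5L * n + 1L)
  roles[vid(seq_len(n), 1L)] <- "left_edge"
  roles[vid(seq_len(n), 3L)] <- "midvein"
  roles[vid(seq_len(n), 5L)] <- "right_edge"
  roles[tip] <- "tip"
  grid <- outer(seq_len(n), 1:5, vid)
  leaf_mesh(verts, faces, roles, grid = grid, tip_index = tip,
            scale_to_cm = 1)
}
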