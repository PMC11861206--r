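#' Write and read leaf meshes (OBJ / ASCII PLY)
#'
#' Meshes are stored in Wavefront OBJ (`v`/`f` records, triangles only) or
#' ASCII PLY. 2D meshes are written with `z = 0`. The leaf-specific
#' metadata that neither format carries -- vertex role tags, the original
#' digitizer grid indices, the tip index, `scale_to_cm`, and whether the
#' mesh is 2D -- goes to a JSON sidecar at `<path>.json`; [read_mesh()]
#' restores it when the sidecar exists.
#'
#' @param mesh a [leaf_mesh()].
#' @param path output file path; the sidecar is written at `<path>.json`.
#' @param format `"obj"` or `"ply"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- tolower(format %||% sub("^.*\\.", "", path))
  if (!format %in% c("obj", "ply"))
    stop("unsupported mesh format: ", format)
  v <- mesh$vertices
  is2d <- ncol(v) == 2L
  if (is2d) v <- cbind(v, 0)
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  fmt_row <- function(p) paste(formatC(p, format = "g", digits = 12),
                               collapse = " ")
  if (format == "obj") {
    writeLines("# leafatlas mesh", con)
    writeLines(paste("v", apply(v, 1, fmt_row)), con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(v, 1, fmt_row), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  side <- list(roles = mesh$roles, is2d = is2d,
               scale_to_cm = mesh$scale_to_cm)
  if (!is.null(mesh$grid)) side$grid <- mesh$grid
  if (!is.null(mesh$tip_index)) side$tip_index <- mesh$tip_index
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  format <- tolower(format %||% sub("^.*\\.", "", path))
  if (!format %in% c("obj", "ply"))
    stop("unsupported mesh format: ", format)
  lines <- readLines(path, warn = FALSE)
  if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    ftok <- strsplit(fl, "\\s+")
    if (any(lengths(ftok) != 4L))
      stop("unsupported element: non-triangle face in ", path)
    f <- do.call(rbind, lapply(ftok, function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else {
    hdr_end <- match("end_header", trimws(lines))
    if (is.na(hdr_end)) stop("malformed PLY header in ", path)
    hdr <- lines[seq_len(hdr_end)]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", hdr, value = TRUE)))
    body <- lines[(hdr_end + 1L):length(lines)]
    v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    if (any(vapply(ftok, function(x) x[1] != "3", logical(1))))
      stop("unsupported element: non-triangle face in ", path)
    f <- do.call(rbind, lapply(ftok, function(x) as.integer(x[2:4]) + 1L))
  }
  sidecar <- paste0(path, ".json")
  roles <- rep("interior", nrow(v))
  grid <- NULL; tip_index <- NULL; scale_to_cm <- 1; is2d <- FALSE
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    roles <- side$roles
    is2d <- isTRUE(side$is2d)
    scale_to_cm <- side$scale_to_cm %||% 1
    if (!is.null(side$grid)) grid <- matrix(as.integer(side$grid),
                                            nrow = nrow(side$grid))
    tip_index <- side$tip_index
  }
  if (is2d) v <- v[, 1:2, drop = FALSE]
  leaf_mesh(v, f, roles, grid = grid, tip_index = tip_index,
            scale_to_cm = scale_to_cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
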