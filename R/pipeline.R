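#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end pipeline. Defaults are
#' the method's canonical constants: screening threshold 0.1, two sqrt(3)
#' subdivision iterations, ARAP tolerance 1e-6 with at most 200
#' iterations, contour resolution 600, clustering threshold 0.25, weight
#' grid 0 to 3 in steps of 0.5, and semantic match threshold 0.9.
#'
#' @param screen_threshold replicate-screening divergence threshold.
#' @param subdiv_iters sqrt(3) subdivision iterations.
#' @param arap_tol,arap_max_iters ARAP stopping parameters.
#' @param resolution contour sampling resolution.
#' @param cluster_threshold feature-clustering cut height.
#' @param weight_grid candidate raw weights for the greedy search.
#' @param match_threshold semantic lookup acceptance threshold.
#' @param seed master seed for synthetic input.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(screen_threshold = 0.1, subdiv_iters = 2L,
                            arap_tol = 1e-6, arap_max_iters = 200L,
                            resolution = 600L, cluster_threshold = 0.25,
                            weight_grid = seq(0, 3, by = 0.5),
                            match_threshold = 0.9, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Process one digitized leaf through the geometric stages
#'
#' Triangulates the grid, normalizes, subdivides, ARAP-flattens, samples
#' the contour and extracts the 29 features.
#'
#' @param leaf a [digitized_leaf()].
#' @param config a [pipeline_config()].
#' @return list with `mesh3d` (subdivided normalized mesh), `mesh2d`,
#'   `contour`, `features` (named 29-vector), `area_ratio`, `trace`.
#' @export
process_leaf <- function(leaf, config = pipeline_config()) {
  mesh <- triangulate_grid(leaf)
  mesh <- normalize_mesh(mesh)
  mesh <- sqrt3_subdivide(mesh, config$subdiv_iters)
  flat <- arap_flatten(mesh, tol = config$arap_tol,
                       max_iters = config$arap_max_iters)
  boundary <- extract_boundary(flat$mesh2d)
  ## ray origin is the mesh centroid (0,0); boundary is in cm, origin safe
  contour <- sample_contour(boundary, resolution = config$resolution,
                            line_id = leaf$line_id,
                            sample_id = leaf$sample_id)
  feats <- extract_all(flat$mesh2d, mesh, contour)
  list(mesh3d = mesh, mesh2d = flat$mesh2d, contour = contour,
       features = feats, area_ratio = flat$report$area_ratio,
       trace = flat$trace)
}

#' Run the full phenotyping pipeline
#'
#' Executes screening, normalization, subdivision, ARAP flattening,
#' contour sampling, feature extraction, semantic feature selection,
#' greedy weight search, atlas construction and leave-one-out Top-X
#' evaluation over a set of digitized leaves.
#'
#' @param leaves list of [digitized_leaf()]s (e.g. from
#'   [generate_population()] or [read_digitized_leaf()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory to write stage artifacts (screening
#'   report, feature table, atlas entries, run report as CSV/JSON).
#' @param select_override optional character vector forcing the semantic
#'   feature selection.
#' @return list with `screening`, `feature_table`, `area_ratios`,
#'   `model`, `atlas`, `report` (stage counts, mean area ratio, rTop-X
#'   curves for weighted and unweighted features).
#' @export
run_pipeline <- function(leaves, config = pipeline_config(),
                         out_dir = NULL, select_override = NULL) {
  n_in <- length(leaves)

  ## replicate screening on raw meshes
  raw <- lapply(leaves, triangulate_grid)
  recs <- do.call(rbind, lapply(seq_along(leaves), function(i) {
    f <- raw_screen_features(raw[[i]])
    data.frame(line_id = leaves[[i]]$line_id,
               sample_id = leaves[[i]]$sample_id,
               length = f["length"], width = f["width"],
               aspect = f["aspect"], angle = f["angle"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  recs <- screen_replicates(recs, threshold = config$screen_threshold)
  keep <- which(!recs$excluded)
  leaves <- leaves[keep]

  processed <- lapply(leaves, process_leaf, config = config)
  feats <- do.call(rbind, lapply(processed, function(p) as.data.frame(t(p$features))))
  table <- data.frame(
    line_id = vapply(leaves, function(x) x$line_id, character(1)),
    sample_id = vapply(leaves, function(x) x$sample_id, character(1)),
    feats, stringsAsFactors = FALSE)
  area_ratios <- vapply(processed, function(p) p$area_ratio, numeric(1))

  dist <- feature_distance_matrix(table)
  sel <- cluster_and_select(dist, threshold = config$cluster_threshold,
                            override = select_override)
  model <- greedy_weight_search(table, sel$selected,
                                grid = config$weight_grid)
  model$threshold <- config$cluster_threshold

  contours <- average_contours(lapply(processed, function(p) p$contour),
                               group = "line")
  mat <- as.matrix(table[, feature_names()])
  vectors <- rowsum(mat, table$line_id) /
    as.vector(table(table$line_id)[sort(unique(table$line_id))])
  atlas <- build_atlas(vectors, contours, model)

  S <- standardize_semantic(mat, model)
  xs <- seq_len(min(10L, nrow(atlas$entries)))
  r_weighted <- loo_topx(S, table$line_id, model$weights, xs)
  r_unweighted <- loo_topx(S, table$line_id,
                           rep(1, length(model$selected)), xs)
  report <- list(
    n_input = n_in, n_screened_out = n_in - length(keep),
    n_retained = length(keep),
    mean_area_ratio = mean(area_ratios),
    min_area_ratio = min(area_ratios),
    n_lines = nrow(atlas$entries),
    rtopx_weighted = setNames(r_weighted, paste0("rTop-", xs)),
    rtopx_unweighted = setNames(r_unweighted, paste0("rTop-", xs)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(recs, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    utils::write.csv(table, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(atlas$entries, file.path(out_dir, "atlas_entries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(model = list(selected = model$selected,
                        weights = as.list(model$weights),
                        standardization = model$standardization,
                        threshold = model$threshold),
           report = report),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    for (id in names(atlas$contours)) {
      ct <- atlas$contours[[id]]
      utils::write.csv(
        data.frame(ray_index = seq_len(ct$resolution) - 1L,
                   angle_rad = 2 * pi * (seq_len(ct$resolution) - 1L) /
                     ct$resolution,
                   x_cm = ct$points[, 1], y_cm = ct$points[, 2]),
        file.path(out_dir, paste0("contour_", id, ".csv")),
        row.names = FALSE)
    }
  }

  list(screening = recs, feature_table = table, area_ratios = area_ratios,
       model = model, atlas = atlas, report = report)
}
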