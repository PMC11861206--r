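#' Pearson-distance matrix between features
#'
#' Distance between two feature columns is `1 - r`, where `r` is their
#' Pearson correlation over the leaves; the range is `[0, 2]` with 0 on
#' the diagonal.
#'
#' @param table feature table: data frame with `line_id`, `sample_id` and
#'   the 29 feature columns (see [feature_names()]), one row per leaf.
#' @return symmetric distance matrix over the feature columns.
#' @export
feature_distance_matrix <- function(table) {
  feats <- intersect(feature_names(), names(table))
  m <- as.matrix(table[, feats, drop = FALSE])
  if (nrow(m) < 3L) stop("need at least 3 leaves")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature column: ",
         paste(feats[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Semantic feature models
#'
#' A `semantic_model` bundles the selected feature identifiers, their
#' normalized non-negative weights (summing to 1), the per-feature min-max
#' standardization ranges estimated on the reference population, and the
#' clustering threshold used for selection.
#'
#' @param selected character vector of distinct feature identifiers.
#' @param weights numeric weights (normalized to sum 1); `NULL` for
#'   uniform.
#' @param standardization list with numeric vectors `min` and `max` per
#'   selected feature.
#' @param threshold clustering cut height used during selection.
#' @return object of class `semantic_model`.
#' @export
semantic_model <- function(selected, weights = NULL, standardization = NULL,
                           threshold = 0.25) {
  selected <- as.character(selected)
  stopifnot(!anyDuplicated(selected), all(selected %in% feature_names()))
  if (is.null(weights)) weights <- rep(1 / length(selected), length(selected))
  stopifnot(length(weights) == length(selected), all(weights >= 0))
  if (sum(weights) == 0) stop("degenerate weights: all zero")
  weights <- weights / sum(weights)
  structure(list(selected = selected, weights = setNames(weights, selected),
                 standardization = standardization, threshold = threshold),
            class = "semantic_model")
}

#' @exportS3Method base::print
print.semantic_model <- function(x, ...) {
  cat(sprintf("<semantic_model> %d features, threshold %.3g\n",
              length(x$selected), x$threshold))
  print(round(x$weights, 3))
  invisible(x)
}

#' Select semantic features by correlation clustering
#'
#' Agglomerative clustering with average linkage on the Pearson distance
#' matrix, cut at `threshold`; each cluster contributes its medoid (the
#' member with the smallest mean distance to the rest of its cluster) as
#' the representative semantic feature. An `override` vector of feature
#' identifiers replaces the automatic selection when supplied.
#'
#' @param dist distance matrix from [feature_distance_matrix()].
#' @param threshold dendrogram cut height (default 0.25).
#' @param override optional character vector forcing the selection.
#' @return a [semantic_model()] with uniform weights (selection only).
#' @export
cluster_and_select <- function(dist, threshold = 0.25, override = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!is.null(override))
    return(semantic_model(override, threshold = threshold))
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  cl <- stats::cutree(hc, h = threshold)
  reps <- vapply(split(names(cl), cl), function(members) {
    if (length(members) == 1L) return(members)
    sub <- dist[members, members, drop = FALSE]
    members[which.min(rowMeans(sub))]
  }, character(1))
  sel <- colnames(dist)[sort(match(reps, colnames(dist)))]
  semantic_model(sel, threshold = threshold)
}

## Min-max standardization of a semantic matrix to [0, 1] over the
## reference population (queries may fall slightly outside).
standardize_semantic <- function(mat, model) {
  st <- model$standardization
  if (is.null(st)) stop("model has no standardization ranges")
  sel <- model$selected
  span <- st$max - st$min
  span[span == 0] <- 1
  sweep(sweep(mat[, sel, drop = FALSE], 2, st$min[sel]), 2, span[sel], "/")
}

fit_standardization <- function(mat, selected) {
  m <- mat[, selected, drop = FALSE]
  list(min = setNames(apply(m, 2, min), selected),
       max = setNames(apply(m, 2, max), selected))
}

## Leave-one-replicate-out Top-X evaluation used as the greedy objective.
## S: standardized semantic matrix (leaves x k); labels: line ids;
## w: raw weights. Queries from single-sample lines are skipped (their
## gallery would be empty). Returns the vector of rTop-X for X in `xs`.
loo_topx <- function(S, labels, w, xs = 1:10) {
  Sw <- sweep(S, 2, w, "*")
  lines <- sort(unique(labels))
  li <- match(labels, lines)
  sums <- rowsum(Sw, li)
  counts <- tabulate(li, length(lines))
  means <- sums / counts
  Gn <- means / pmax(row_norms(means), 1e-300)
  qn <- Sw / pmax(row_norms(Sw), 1e-300)
  sims <- qn %*% t(Gn)                       # queries x lines
  keep <- counts[li] >= 2L
  ranks <- rep(NA_integer_, nrow(S))
  for (q in which(keep)) {
    l <- li[q]
    own <- (sums[l, ] - Sw[q, ]) / (counts[l] - 1L)
    s_own <- sum(own * qn[q, ]) / max(sqrt(sum(own^2)), 1e-300)
    sv <- sims[q, ]
    sv[l] <- s_own
    ranks[q] <- 1L + sum(sv > sv[l]) + sum(sv == sv[l] & seq_along(sv) < l)
  }
  r <- ranks[keep]
  vapply(xs, function(x) mean(r <= x), numeric(1))
}

#' Greedy grid search for semantic feature weights
#'
#' For each selected feature in turn, its raw weight is set to each value
#' of the grid (`0, 0.5, ..., 3` by default) while all other raw weights
#' stay at 1, and the identification ability -- the mean of rTop-1
#' through rTop-10 under leave-one-replicate-out evaluation against
#' per-line gallery means -- is measured. The best grid value per feature
#' (ties resolved toward the smaller weight) is recorded; the assembled
#' raw vector is normalized to sum 1.
#'
#' @param table feature table with `line_id` and the feature columns; at
#'   least 2 lines with 2 or more samples each.
#' @param selected character vector of semantic feature identifiers (e.g.
#'   from [cluster_and_select()]).
#' @param grid candidate raw weights (default `seq(0, 3, by = 0.5)`).
#' @return a [semantic_model()] with fitted weights, standardization
#'   ranges, and the raw grid weights in attribute `raw_weights`.
#' @export
greedy_weight_search <- function(table, selected, grid = seq(0, 3, by = 0.5)) {
  mat <- as.matrix(table[, selected, drop = FALSE])
  labels <- as.character(table$line_id)
  st <- fit_standardization(mat, selected)
  span <- st$max - st$min
  span[span == 0] <- 1
  S <- sweep(sweep(mat, 2, st$min), 2, span, "/")
  k <- length(selected)
  xs <- seq_len(min(10L, length(unique(labels))))
  raw <- numeric(k)
  for (i in seq_len(k)) {
    scores <- vapply(grid, function(g) {
      w <- rep(1, k)
      w[i] <- g
      mean(loo_topx(S, labels, w, xs))
    }, numeric(1))
    raw[i] <- grid[which.max(scores)]   # first max = smallest weight on ties
  }
  if (sum(raw) == 0) stop("degenerate weights: all grid optima are zero")
  model <- semantic_model(selected, weights = raw / sum(raw),
                          standardization = st)
  attr(model, "raw_weights") <- setNames(raw, selected)
  model
}

#' Composite 2D leaf-shape index
#'
#' `L2D` is the weighted sum of the min-max standardized semantic
#' features, `sum_i w_i * v_i`, with weights summing to 1; it grows as
#' the leaf's semantic characteristics become more pronounced (longer,
#' wider, more curved). `modulus = TRUE` computes the Euclidean modulus
#' `||w o v||` of the weighted vector instead.
#'
#' @param v_f named numeric vector of raw semantic feature values.
#' @param model a fitted [semantic_model()].
#' @param modulus use the root-sum-of-squares variant.
#' @return scalar index value.
#' @export
compute_L2D <- function(v_f, model, modulus = FALSE) {
  if (!all(model$selected %in% names(v_f)))
    stop("feature mismatch between vector and model")
  z <- as.numeric(standardize_semantic(rbind(v_f[model$selected]), model))
  wz <- model$weights * z
  if (modulus) sqrt(sum(wz^2)) else sum(wz)
}

#' Build the ranked 2D leaf-shape atlas
#'
#' Entries (one per inbred line: the line's averaged contour and mean
#' semantic vector) are ranked ascending by their L2D index; ties are
#' broken by line id, so the atlas is independent of input order.
#'
#' @param vectors matrix of per-line mean raw semantic feature values
#'   (rows named by line id, columns at least the model's features).
#' @param contours named list of per-line averaged [sampled_contour()]s.
#' @param model a fitted [semantic_model()].
#' @return object of class `leaf_atlas` with `entries` (data frame
#'   `line_id, L2D, rank`), `vectors` (standardized semantic matrix),
#'   `contours` and `model`.
#' @export
build_atlas <- function(vectors, contours, model) {
  ids <- rownames(vectors)
  if (anyDuplicated(ids)) stop("duplicate line_id in atlas input")
  Z <- standardize_semantic(vectors, model)
  l2d <- as.numeric(Z %*% model$weights)
  ord <- order(l2d, ids)
  entries <- data.frame(line_id = ids[ord], L2D = l2d[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(entries = entries, vectors = Z[ord, , drop = FALSE],
                 contours = contours[entries$line_id], model = model),
            class = "leaf_atlas")
}

#' @exportS3Method base::print
print.leaf_atlas <- function(x, ...) {
  cat(sprintf("<leaf_atlas> %d lines, %d semantic features\n",
              nrow(x$entries), length(x$model$selected)))
  print(head(x$entries, 5))
  invisible(x)
}

#' Plot a leaf-shape atlas as concentric contour rings
#'
#' Averaged line contours are drawn on concentric rings ordered by L2D
#' (smallest index innermost).
#'
#' @param x a `leaf_atlas`.
#' @param max_lines draw at most this many entries (evenly thinned).
#' @param ... passed to [graphics::plot()].
#' @export
plot.leaf_atlas <- function(x, max_lines = 60L, ...) {
  n <- nrow(x$entries)
  pick <- unique(round(seq(1, n, length.out = min(n, max_lines))))
  rad <- seq_along(pick)
  lim <- max(rad) * 1.3
  graphics::plot(c(-lim, lim), c(-lim, lim), type = "n", asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  for (j in seq_along(pick)) {
    e <- x$entries[pick[j], ]
    ct <- x$contours[[e$line_id]]
    if (is.null(ct)) next
    ang <- 2 * pi * (j - 1) / length(pick)
    pts <- ct$points / max(row_norms(ct$points)) * 0.45
    ctr <- rad[j] * c(cos(ang), sin(ang))
    graphics::polygon(pts[, 1] + ctr[1], pts[, 2] + ctr[2],
                      border = "darkgreen")
  }
  invisible(x)
}

#' Identify the inbred line of a query leaf
#'
#' Ranks atlas lines by the cosine similarity between the element-wise
#' weighted standardized semantic vectors of the query and of each atlas
#' entry; ties are broken by line id.
#'
#' @param query named numeric vector of raw semantic feature values for
#'   one leaf.
#' @param atlas a [build_atlas()] result.
#' @param model semantic model (defaults to the atlas's own).
#' @return data frame `line_id, similarity` sorted by decreasing
#'   similarity.
#' @export
identify_line <- function(query, atlas, model = atlas$model) {
  z <- as.numeric(standardize_semantic(rbind(query[model$selected]), model))
  wq <- model$weights * z
  nq <- sqrt(sum(wq^2))
  if (nq < 1e-300) stop("undefined similarity: zero-norm weighted query")
  WG <- sweep(atlas$vectors, 2, model$weights, "*")
  ng <- row_norms(WG)
  if (any(ng < 1e-300)) stop("undefined similarity: zero-norm atlas entry")
  sims <- as.numeric(WG %*% wq) / (ng * nq)
  ord <- order(-sims, atlas$entries$line_id)
  data.frame(line_id = atlas$entries$line_id[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}

#' Look up a leaf-shape model from semantic features
#'
#' Returns the best-matching atlas entry (with its averaged contour for
#' drawing) when the top weighted cosine similarity reaches
#' `match_threshold`; otherwise `NULL` -- the requested leaf shape "does
#' not exist" in the atlas.
#'
#' @inheritParams identify_line
#' @param match_threshold minimum similarity to accept (default 0.9).
#' @return list with `line_id`, `similarity`, `L2D`, `rank`, `contour`,
#'   or `NULL`.
#' @export
lookup_by_semantics <- function(query, atlas, model = atlas$model,
                                match_threshold = 0.9) {
  ranked <- identify_line(query, atlas, model)
  if (ranked$similarity[1] < match_threshold) return(NULL)
  e <- atlas$entries[atlas$entries$line_id == ranked$line_id[1], ]
  list(line_id = e$line_id, similarity = ranked$similarity[1],
       L2D = e$L2D, rank = e$rank, contour = atlas$contours[[e$line_id]])
}

#' Top-X identification accuracy
#'
#' Fraction of labeled query leaves whose true line appears among the X
#' most similar atlas entries.
#'
#' @param queries matrix of raw semantic vectors (one row per query leaf,
#'   columns covering the model features).
#' @param labels character vector of true line ids per query.
#' @param atlas a [build_atlas()] result.
#' @param X positive integer (or vector of them).
#' @return named numeric vector of rates in `[0, 1]`, one per X.
#' @export
top_x_accuracy <- function(queries, labels, atlas, X = 1L) {
  if (any(X < 1)) stop("X must be >= 1")
  stopifnot(all(labels %in% atlas$entries$line_id))
  ranks <- vapply(seq_len(nrow(queries)), function(q) {
    ranked <- identify_line(queries[q, ], atlas)
    match(labels[q], ranked$line_id)
  }, numeric(1))
  setNames(vapply(X, function(x) mean(ranks <= x), numeric(1)),
           paste0("rTop-", X))
}
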