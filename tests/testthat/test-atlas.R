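# synthetic feature tables with controlled correlation structure
fake_table <- function(n = 40, seed = 7, mutate = identity) {
  set.seed(seed)
  m <- matrix(rnorm(n * 29), n, 29, dimnames = list(NULL, feature_names()))
  m <- mutate(m)
  data.frame(line_id = rep(sprintf("L%02d", seq_len(n / 2)), each = 2),
             sample_id = sprintf("S%03d", seq_len(n)), m,
             stringsAsFactors = FALSE)
}

test_that("the feature distance is 1 - Pearson correlation on [0, 2]", {
  tbl <- fake_table(mutate = function(m) {
    m[, "RL"] <- -m[, "LL"]          # perfect anticorrelation
    m[, "WA"] <- m[, "ML"]           # perfect correlation
    m
  })
  d <- feature_distance_matrix(tbl)
  expect_equal(dim(d), c(29L, 29L))
  expect_equal(unname(diag(d)), rep(0, 29))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
  expect_equal(d["LL", "RL"], 2)
  expect_equal(d["ML", "WA"], 0)
  tbl$FA <- 1
  expect_error(feature_distance_matrix(tbl), "constant feature column: FA")
})

test_that("clustering at extreme thresholds keeps 1 or all 29 features", {
  d <- feature_distance_matrix(fake_table())
  expect_length(cluster_and_select(d, threshold = 2.1)$selected, 1L)
  expect_length(cluster_and_select(d, threshold = 1e-9)$selected, 29L)
  expect_error(cluster_and_select(d, threshold = 0), "positive")
})

test_that("perfectly correlated features merge first and only one survives", {
  tbl <- fake_table(mutate = function(m) {
    m[, "RL"] <- m[, "LL"] + rnorm(nrow(m), 0, 1e-3)
    m
  })
  sel <- cluster_and_select(feature_distance_matrix(tbl), 0.25)$selected
  expect_false(all(c("LL", "RL") %in% sel))
  expect_true(any(c("LL", "RL") %in% sel))
})

test_that("semantic models normalize weights and reject degenerate input", {
  sm <- semantic_model(c("ML", "WA"), weights = c(3, 1))
  expect_equal(unname(sm$weights), c(0.75, 0.25))
  expect_equal(sum(sm$weights), 1, tolerance = 1e-12)
  expect_error(semantic_model(c("ML", "WA"), weights = c(0, 0)),
               "degenerate")
  expect_error(semantic_model(c("ML", "ML")), "anyDuplicated")
})

test_that("the greedy search stays on the 7-value grid and finds informative features", {
  grid <- eval(formals(greedy_weight_search)$grid)
  expect_equal(grid, c(0, 0.5, 1, 1.5, 2, 2.5, 3))
  expect_length(grid, 7L)

  ## 20 lines x 3 reps: only ML carries the line signal, others pure noise
  set.seed(42)
  n_lines <- 20L
  line_mean <- runif(n_lines, 40, 90)
  tbl <- data.frame(
    line_id = rep(sprintf("L%02d", 1:n_lines), each = 3),
    ML = rep(line_mean, each = 3) + rnorm(3 * n_lines, 0, 0.5),
    WA = rnorm(3 * n_lines), FA = rnorm(3 * n_lines),
    LTA = rnorm(3 * n_lines), stringsAsFactors = FALSE)
  model <- greedy_weight_search(tbl, c("ML", "WA", "FA", "LTA"))
  raw <- attr(model, "raw_weights")
  expect_true(all(raw %in% grid))
  expect_equal(sum(model$weights), 1, tolerance = 1e-9)
  expect_equal(names(which.max(model$weights)), "ML")
})

test_that("equal raw weights normalize to uniform regardless of the grid value", {
  for (g in c(0.5, 2)) {
    sm <- semantic_model(c("ML", "WA", "FA"), weights = rep(g, 3))
    expect_equal(unname(sm$weights), rep(1 / 3, 3))
  }
})

test_that("L2D is the weighted sum of standardized features, monotone in each", {
  st <- list(min = setNames(c(0, 0), c("ML", "WA")),
             max = setNames(c(10, 2), c("ML", "WA")))
  sm <- semantic_model(c("ML", "WA"), weights = c(0.6, 0.4),
                       standardization = st)
  expect_equal(compute_L2D(c(ML = 0, WA = 0), sm), 0)
  expect_equal(compute_L2D(c(ML = 10, WA = 2), sm), 1)
  expect_equal(compute_L2D(c(ML = 5, WA = 1), sm), 0.5)
  expect_gt(compute_L2D(c(ML = 6, WA = 1), sm),
            compute_L2D(c(ML = 5, WA = 1), sm))
  ## modulus variant
  expect_equal(compute_L2D(c(ML = 10, WA = 2), sm, modulus = TRUE),
               sqrt(0.6^2 + 0.4^2))
  expect_error(compute_L2D(c(LL = 1), sm), "feature mismatch")
})

## small atlas built from explicit vectors: L2D driven by ML
toy_atlas <- function(n = 15) {
  ## widths run against lengths so no two weighted vectors are collinear
  ## (cosine similarity cannot separate proportional vectors)
  ml <- seq(10, 80, length.out = n)
  vecs <- cbind(ML = ml, WA = seq(4, 2, length.out = n))
  rownames(vecs) <- sprintf("L%02d", seq_len(n))
  st <- list(min = setNames(c(0, 0), c("ML", "WA")),
             max = setNames(c(80, 4), c("ML", "WA")))
  model <- semantic_model(c("ML", "WA"), weights = c(0.9, 0.1),
                          standardization = st)
  list(atlas = build_atlas(vecs, list(), model), vecs = vecs, model = model)
}

test_that("atlases rank by L2D ascending and ignore input order", {
  ta <- toy_atlas()
  expect_equal(nrow(ta$atlas$entries), 15L)
  expect_equal(ta$atlas$entries$rank, 1:15)
  expect_true(!is.unsorted(ta$atlas$entries$L2D))
  perm <- sample(nrow(ta$vecs))
  atlas2 <- build_atlas(ta$vecs[perm, ], list(), ta$model)
  expect_equal(atlas2$entries, ta$atlas$entries)
  ## rank follows the dominant feature
  expect_gt(cor(ta$atlas$entries$rank,
                ta$vecs[ta$atlas$entries$line_id, "ML"],
                method = "spearman"), 0.9)
  dup <- ta$vecs
  rownames(dup) <- rep("L01", nrow(dup))
  expect_error(build_atlas(dup, list(), ta$model), "duplicate line_id")
})

test_that("identification is exact on self-queries and scale-invariant", {
  ta <- toy_atlas()
  for (id in c("L01", "L08", "L15")) {
    r <- identify_line(ta$vecs[id, ], ta$atlas)
    expect_equal(r$line_id[1], id)
    expect_equal(r$similarity[1], 1.0, tolerance = 1e-12)
  }
  ## cosine similarity is invariant to positive scaling of the
  ## (standardized) query: use an identity standardization to see it
  st <- list(min = setNames(c(0, 0), c("ML", "WA")),
             max = setNames(c(1, 1), c("ML", "WA")))
  model <- semantic_model(c("ML", "WA"), weights = c(0.5, 0.5),
                          standardization = st)
  vecs <- cbind(ML = c(1, 0.2), WA = c(0.1, 0.9))
  rownames(vecs) <- c("A", "B")
  atl <- build_atlas(vecs, list(), model)
  q <- c(ML = 0.8, WA = 0.3)
  expect_equal(identify_line(q, atl)$similarity,
               identify_line(3 * q, atl)$similarity, tolerance = 1e-12)
  expect_error(identify_line(c(ML = 0, WA = 0), atl), "zero-norm")
})

test_that("semantic lookup honors the 0.9 match threshold", {
  st <- list(min = setNames(c(0, 0), c("ML", "WA")),
             max = setNames(c(1, 1), c("ML", "WA")))
  model <- semantic_model(c("ML", "WA"), weights = c(0.5, 0.5),
                          standardization = st)
  vecs <- cbind(ML = c(1, 0), WA = c(0, 1))
  rownames(vecs) <- c("A", "B")
  ct <- list(A = sampled_contour(cbind(1:4, 1:4), "A"),
             B = sampled_contour(cbind(1:4, 0:3), "B"))
  atl <- build_atlas(vecs, ct, model)
  hit <- lookup_by_semantics(c(ML = 1, WA = 0), atl)
  expect_equal(hit$line_id, "A")
  expect_equal(hit$similarity, 1, tolerance = 1e-12)
  expect_s3_class(hit$contour, "sampled_contour")
  ## query at 45 degrees: best similarity cos(pi/4) < 0.9 -> no match
  expect_null(lookup_by_semantics(c(ML = 1, WA = 1), atl))
  ## consistency with the ranked identification
  expect_equal(hit$line_id,
               identify_line(c(ML = 1, WA = 0), atl)$line_id[1])
})

test_that("Top-X accuracy is monotone, exact for copies, and 1 at full X", {
  ta <- toy_atlas()
  labels <- rownames(ta$vecs)
  acc <- top_x_accuracy(ta$vecs, labels, ta$atlas, X = c(1, 3, 5, 15))
  expect_equal(unname(acc[1]), 1.0)
  expect_true(all(diff(acc) >= 0))
  expect_equal(unname(acc[4]), 1.0)
  expect_error(top_x_accuracy(ta$vecs, labels, ta$atlas, X = 0), "X must be")
  ## noisy queries: still monotone, true label somewhere in the ranking
  set.seed(1)
  noisy <- ta$vecs + matrix(rnorm(length(ta$vecs), 0, 5), nrow(ta$vecs))
  accn <- top_x_accuracy(noisy, labels, ta$atlas, X = c(1, 5, 15))
  expect_true(all(diff(accn) >= 0))
  expect_equal(unname(accn[3]), 1.0)
})
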