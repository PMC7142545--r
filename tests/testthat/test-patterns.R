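test_that("row z-scoring centres, scales, and drops constant rows", {
  tm <- toy_type_matrix(rbind(a = c(1, 2, 3), b = c(4, 4, 4),
                              c = c(0, 10, 5)))
  expect_warning(z <- zscore_rows(tm), "zero-variance")
  expect_equal(attr(z, "dropped"), "b")
  expect_equal(rowMeans(z$values), c(a = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(z$values, 1, sd), c(a = 1, c = 1),
               tolerance = 1e-12)
  set.seed(41)
  big <- toy_type_matrix(matrix(runif(100 * 15), nrow = 100))
  zb <- zscore_rows(big)
  expect_true(all(abs(rowMeans(zb$values)) < 1e-10))
})

test_that("k-means recovers planted well-separated profiles at k = 2", {
  set.seed(42)
  up <- rep(c(5, -5), c(7, 8)); down <- -up
  v <- rbind(t(replicate(10, up + rnorm(15, 0, 0.3))),
             t(replicate(12, down + rnorm(15, 0, 0.3))))
  tm <- toy_type_matrix(v)
  fit <- kmeans_patterns(zscore_rows(tm), k = 2, seed = 5)
  cl <- fit$assignments$cluster
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:22])), 1L)
  expect_false(cl[1] == cl[11])
  # larger cluster gets label 1
  expect_equal(cl[11], 1L)
})

test_that("k-means is seeded, best-of-inits, and handles edge cases", {
  set.seed(43)
  tm <- toy_type_matrix(matrix(rnorm(60 * 15), nrow = 60))
  a <- kmeans_patterns(tm, k = 4, n_init = 10, seed = 9)
  b <- kmeans_patterns(tm, k = 4, n_init = 10, seed = 9)
  expect_identical(a$assignments, b$assignments)
  # returned objective is the best over every initialisation tried
  expect_equal(a$tot_withinss, min(a$init_withinss))
  expect_true(all(a$init_withinss >= a$tot_withinss))
  # k = 1: single cluster, centroid = column means
  one <- kmeans_patterns(tm, k = 1, n_init = 2, seed = 1)
  expect_true(all(one$assignments$cluster == 1L))
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(tm$values)))
  expect_error(kmeans_patterns(tm, k = 61), "exceeds")
})

test_that("clustering after z-scoring ignores per-gene affine scale", {
  set.seed(44)
  v <- matrix(rnorm(40 * 15), nrow = 40)
  tm <- toy_type_matrix(v)
  rescaled <- toy_type_matrix(v * runif(40, 0.5, 20) + runif(40, -5, 5))
  a <- kmeans_patterns(zscore_rows(tm), k = 3, seed = 2)
  b <- kmeans_patterns(zscore_rows(rescaled), k = 3, seed = 2)
  expect_identical(a$assignments, b$assignments)
})

test_that("average-linkage merges follow a hand-computed trace", {
  # genes at positions 0, 1, 5 on a line: d(1,2)=1, d(1,3)=5, d(2,3)=4;
  # first merge {1,2} at height 1, then join 3 at (5+4)/2 = 4.5
  tm <- toy_type_matrix(rbind(a = c(0, 0, 0), b = c(1, 0, 0),
                              c = c(5, 0, 0)))
  ho <- hierarchical_order(tm, distance = "euclidean",
                           linkage = "average")
  expect_equal(ho$gene_hclust$height, c(1, 4.5))
  expect_equal(sort(ho$gene_hclust$merge[1, ]), c(-2, -1))
})

test_that("identical samples sit on adjacent leaves", {
  set.seed(45)
  v <- matrix(runif(30 * 6, 0, 10), nrow = 30)
  v[, 4] <- v[, 2]                      # duplicate one sample
  em <- toy_expr(v)
  ho <- hierarchical_order(em, distance = "euclidean")
  pos <- match(c(2, 4), ho$sample_order)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("sample dendrogram splits the 15 types by sex on planted data", {
  ds <- generate_dataset(sim_config(seed = 1))
  tm <- log_transform(filter_expressed(aggregate_types(ds$expr), 0.5))
  ho <- hierarchical_order(tm)
  grp <- cutree(ho$sample_hclust, 2)
  sex <- morph_sex(tm$types$morph)
  expect_equal(length(unique(grp)), 2L)
  expect_true(all(tapply(sex, grp, function(s) length(unique(s))) == 1))
})

test_that("degenerate matrices are rejected", {
  flat <- toy_type_matrix(matrix(1, 3, 3))
  expect_error(hierarchical_order(flat), "constant")
  expect_error(hierarchical_order(toy_type_matrix(matrix(1:3, ncol = 1))),
               "at least 2")
})
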