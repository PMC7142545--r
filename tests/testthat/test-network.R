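test_that("MI is symmetric and invariant under monotone transforms", {
  set.seed(31)
  x <- rnorm(120); y <- 0.6 * x + rnorm(120)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # ranks are untouched by strictly increasing maps
  expect_identical(mutual_information(x, y),
                   mutual_information(exp(x), y))
  expect_identical(mutual_information(x, y),
                   mutual_information(x, y^3 + 5 * y))
})

test_that("MI vanishes for independent data and is exact for y = x", {
  set.seed(32)
  expect_lt(mutual_information(rnorm(2000), rnorm(2000)), 0.1)
  # perfect dependence on an equal-frequency grid: plug-in ln(B) with
  # the Miller-Madow term (1 - B) / (2n) subtracted
  x <- runif(64)
  expect_equal(mutual_information(x, x, bins = 8),
               log(8) - (1 - 8) / (2 * 64), tolerance = 1e-12)
  expect_equal(mutual_information(x, log(x), bins = 8),
               log(8) - (1 - 8) / (2 * 64), tolerance = 1e-12)
})

test_that("MI tracks the bivariate-Gaussian closed form", {
  n <- 2000
  est <- vapply(c(0, 0.5, 0.9), function(rho) {
    set.seed(33)
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mutual_information(x, y)
  }, 1.0)
  truth <- -0.5 * log(1 - c(0, 0.5, 0.9)^2)
  expect_true(all(abs(est - truth) < 0.1))
  expect_true(all(diff(est) > 0))       # monotone in rho
})

test_that("MI input contracts are enforced", {
  expect_error(mutual_information(1:10, 1:9), "equal length")
  expect_error(mutual_information(1:5, 1:5), "at least 8")
  expect_error(mutual_information(c(1:9, NA), 1:10), "missing")
  expect_warning(z <- mutual_information(rep(1, 20), rnorm(20)),
                 "constant")
  expect_equal(z, 0)
})

test_that("the all-pairs network has the complete-graph edge count", {
  set.seed(34)
  em <- toy_expr(matrix(rnorm(5 * 15, 10, 2), nrow = 5))
  net <- mi_matrix(em, rownames(em$values))
  expect_equal(nrow(network_edges(net)), 5 * 4 / 2)
  net2 <- mi_matrix(em, rownames(em$values)[1:2])
  expect_equal(nrow(network_edges(net2)), 1L)
  expect_error(mi_matrix(em, rownames(em$values)[1]), "at least 2")
  expect_error(mi_matrix(em, c("nope", rownames(em$values)[1])), "nope")
})

test_that("planted-module MI stands clear of a column-shuffled null", {
  ds <- generate_dataset(sim_config(n_genes = 60, n_replicates = 4,
                                    n_specific_genes = 0, n_modules = 1,
                                    module_size = 15,
                                    n_markers_per_morph = 0,
                                    n_sex_genes = 0, seed = 35))
  members <- ds$truth$module_members[[1]]$genes
  net <- mi_matrix(ds$expr, members)
  planted_mi <- network_edges(net)$mi
  shuffled <- ds$expr$values
  set.seed(36)
  for (i in seq_len(nrow(shuffled)))
    shuffled[i, ] <- sample(shuffled[i, ])
  null_net <- mi_matrix(expr_matrix(shuffled, ds$expr$samples), members)
  null_mi <- network_edges(null_net)$mi
  expect_lt(quantile(null_mi, 0.95), min(planted_mi))
})

test_that("DPI prunes the weakest edge of a triangle and respects ties", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.9
  M[1, 3] <- M[3, 1] <- 0.8
  M[2, 3] <- M[3, 2] <- 0.5
  pr <- dpi_prune(toy_network(M))
  expect_equal(unname(pr$pruned[2, 3]), TRUE)
  expect_equal(sum(pr$pruned), 2L)       # one undirected edge
  # all-equal triangle: no strict minimum, nothing pruned
  Meq <- matrix(0.7, 3, 3); diag(Meq) <- 0
  expect_equal(sum(dpi_prune(toy_network(Meq))$pruned), 0L)
  expect_error(dpi_prune(toy_network(M), tolerance = -0.1),
               "non-negative")
})

test_that("DPI matches an exhaustive triangle scan on random graphs", {
  set.seed(37)
  for (trial in 1:100) {
    M <- matrix(0, 10, 10)
    w <- runif(45)
    M[upper.tri(M)] <- w
    M <- M + t(M)
    tol <- sample(c(0, 0.1), 1)
    got <- dpi_prune(toy_network(M), tol)$pruned
    expect_identical(unname(got), dpi_brute_force(M, tol))
  }
})

test_that("DPI is idempotent and only removes edges", {
  set.seed(38)
  M <- matrix(0, 12, 12)
  M[upper.tri(M)] <- runif(66)
  M <- M + t(M)
  once <- dpi_prune(toy_network(M))
  twice <- dpi_prune(once)
  expect_identical(once$pruned, twice$pruned)
  expect_true(all(once$mi == M))
})

test_that("core-gene calls follow the degree and mean-MI rule", {
  # star: hub with 25 leaves, every spoke at MI 0.5
  k <- 26
  M <- matrix(0, k, k)
  M[1, 2:k] <- M[2:k, 1] <- 0.5
  core <- call_core_genes(toy_network(M))
  expect_true(core$is_core[1])
  expect_equal(core$degree[1], 25L)
  expect_false(any(core$is_core[-1]))
  expect_equal(core$degree[-1], rep(1L, 25))
  # mean MI at 0.35 fails the strict mean clause
  M2 <- M * 0.7                                # spokes at 0.35
  core2 <- call_core_genes(toy_network(M2), edge_mi_min = 0.3)
  expect_equal(core2$degree[1], 25L)
  expect_false(core2$is_core[1])
})

test_that("raising core thresholds never adds a core gene", {
  set.seed(39)
  M <- matrix(0, 30, 30)
  M[upper.tri(M)] <- runif(435, 0, 0.9)
  M <- M + t(M)
  net <- dpi_prune(toy_network(M))
  base <- call_core_genes(net, 0.1, 3, 0.2)
  for (args in list(list(0.1, 5, 0.2), list(0.1, 3, 0.4),
                    list(0.3, 3, 0.2))) {
    tighter <- call_core_genes(net, args[[1]], args[[2]], args[[3]])
    expect_true(all(base$is_core | !tighter$is_core))
  }
})

test_that("network export round-trips through edge list and GML", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.9
  M[1, 3] <- M[3, 1] <- 0.7
  M[2, 4] <- M[4, 2] <- 0.55
  M[3, 4] <- M[4, 3] <- 0.2
  net <- toy_network(M, nodes = c("ga", "gb", "gc", "gd"))

  f1 <- tempfile(fileext = ".tsv")
  export_network(net, f1, display_mi_min = 0.5)
  tab <- read.delim(f1)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$mi, c(0.9, 0.7, 0.55))

  f2 <- tempfile(fileext = ".gml")
  export_network(net, f2, display_mi_min = 0.5, format = "gml")
  g <- igraph::read_graph(f2, format = "gml")
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), 3L)
  expect_setequal(round(igraph::E(g)$weight, 6), c(0.9, 0.7, 0.55))
  expect_setequal(igraph::V(g)$degree, c(2, 2, 1, 1))

  # nothing above threshold: nodes only
  f3 <- tempfile(fileext = ".gml")
  export_network(net, f3, display_mi_min = 0.95, format = "gml")
  g3 <- igraph::read_graph(f3, format = "gml")
  expect_equal(igraph::gorder(g3), 4L)
  expect_equal(igraph::gsize(g3), 0L)
})
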