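test_that("pearson matrix matches hand values and handles constant genes", {
  X <- make_expression(rbind(c(1, 2, 3, 4),
                             c(1, 3, 2, 4),
                             c(3, 5, 7, 9),
                             c(5, 5, 5, 5)),
                       genes = c("a", "b", "c", "const"))
  des <- condition_design(setNames(c("normal", "normal", "cancer", "cancer"),
                                   colnames(X)))
  # need >= 3 samples in the chosen condition
  expect_error(pearson_matrix(X, des, "normal"), "at least 3")

  X8 <- cbind(X, X + 0.001 * matrix(seq_len(16), 4))
  colnames(X8) <- paste0("s", 1:8)
  des8 <- make_design(X8, 4)
  expect_warning(R <- pearson_matrix(X8[, ], des8, "cancer"), "constant")
  expect_equal(unname(R["a", "b"]), 0.8, tolerance = 1e-12)  # hand Pearson
  expect_equal(unname(R["a", "c"]), 1)   # affine image: r = 1
  expect_equal(unname(R["a", "const"]), 0)
  expect_true(isSymmetric(unclass(R)))
  expect_equal(unname(diag(R)), rep(1, 4))
})

test_that("hard thresholding is strict and respects the mode", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  R["a", "b"] <- R["b", "a"] <- 0.8     # boundary: not connected
  R["a", "c"] <- R["c", "a"] <- -0.9
  R["b", "c"] <- R["c", "b"] <- 0.85
  signed <- build_dcn(R, 0.8, "signed")
  expect_equal(edge_count(signed), 1)
  expect_equal(signed$adjacency["b", "c"], 1)
  expect_equal(signed$adjacency["a", "b"], 0)
  unsigned <- build_dcn(R, 0.8, "unsigned")
  expect_equal(edge_count(unsigned), 2)
  expect_equal(unsigned$adjacency["a", "c"], 1)
  # unsigned edges are a superset of signed edges
  expect_true(all(unsigned$adjacency >= signed$adjacency))
  expect_equal(unname(diag(signed$adjacency)), rep(0, 3))
  expect_error(build_dcn(R, 1.2), "tau")
  # edge count agrees with a direct threshold scan
  set.seed(3)
  R2 <- cor(matrix(rnorm(200), 10, 20))
  expect_equal(edge_count(build_dcn(R2, 0.3, "signed")),
               sum(R2[upper.tri(R2)] > 0.3))
})

test_that("topology statistics match hand values on canonical graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  ts <- topology_stats(tri)
  expect_equal(unname(ts$clustering), rep(1, 3))
  expect_equal(as.integer(ts$path_length_histogram["1"]), 3)

  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  dimnames(path) <- list(letters[1:3], letters[1:3])
  tp <- topology_stats(path)
  expect_equal(unname(tp$clustering["b"]), 0)
  expect_equal(as.integer(tp$path_length_histogram[c("1", "2")]), c(2, 1))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  dimnames(star) <- list(letters[1:4], letters[1:4])
  st <- topology_stats(star)
  expect_equal(unname(st$clustering["a"]), 0)
  expect_equal(unname(st$degree), c(3, 1, 1, 1))
  # leaves have k < 2, so TC = 0 by convention; hub's partners are leaves
  expect_equal(unname(st$topological_coefficient[c("b", "c", "d")]),
               rep(0, 3))
})

test_that("topology statistics equal the brute-force oracle on random graphs", {
  set.seed(20)
  for (i in 1:50) {
    A <- random_adjacency(sample(5:40, 1), runif(1, 0.05, 0.4))
    got <- topology_stats(A)
    want <- topology_oracle(A)
    expect_equal(unname(got$degree), want$degree)
    expect_equal(unname(got$clustering), want$clustering, tolerance = 1e-12)
    expect_equal(unname(got$topological_coefficient),
                 want$topological_coefficient, tolerance = 1e-12)
    expect_identical(as.integer(got$path_length_histogram),
                     as.integer(want$path_length_histogram))
  }
})

test_that("sample clustering separates planted conditions", {
  p <- simulation_params(500, 9, de_gene_count = 50, de_effect = 2, seed = 71)
  sim <- simulate_expression(p)
  cl <- cluster_samples(sim$expression, k = 2)
  truth_lab <- as.integer(sim$design$assignment[names(cl$partition)] == "I")
  expect_equal(mclust::adjustedRandIndex(cl$partition, truth_lab), 1)
  # order invariance (up to labels)
  perm <- sample(ncol(sim$expression))
  cl2 <- cluster_samples(sim$expression[, perm], k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$partition,
                                         cl2$partition[names(cl$partition)]),
               1)
  expect_error(cluster_samples(sim$expression, k = 100), "exceeds")
})

test_that("SIF export round-trips and lists isolated nodes", {
  A <- matrix(0, 4, 4, dimnames = list(c("d", "c", "b", "a"),
                                       c("d", "c", "b", "a")))
  A["d", "c"] <- A["c", "d"] <- 1
  A["d", "b"] <- A["b", "d"] <- 1
  A["c", "b"] <- A["b", "c"] <- 1
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(A, sif)
  lines <- readLines(sif)
  expect_length(lines, 4)  # 3 triangle edges + 1 isolated node
  expect_identical(lines[4], "a")
  # lexicographic node order within each edge, sorted lines
  expect_identical(lines[1:3], c("b\tcoexp\tc", "b\tcoexp\td", "c\tcoexp\td"))
  back <- read_sif(sif, gene_ids = rownames(A))
  expect_identical(back[rownames(A), colnames(A)], A)
  # empty network: isolated nodes only
  E <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  export_network(E, sif)
  expect_identical(readLines(sif), c("x", "y"))
})
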