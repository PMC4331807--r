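test_that("gene scatter and relative difference match hand evaluation", {
  # x_I = (2,4), x_U = (1,3): a = (1/2 + 1/2)/2 = 0.5, SS = 2 + 2 = 4
  X <- make_expression(matrix(c(2, 4, 1, 3), 1), samples = paste0("s", 1:4))
  d <- make_design(X, n1 = 2)
  expect_equal(unname(gene_scatter(X, d)), sqrt(2), tolerance = 1e-12)

  # x_I = (3,3), x_U = (1,1), s0 = 0.5: d = 2 / 0.5 = 4
  X2 <- make_expression(matrix(c(3, 3, 1, 1), 1), samples = paste0("s", 1:4))
  d2 <- make_design(X2, n1 = 2)
  expect_equal(unname(gene_scatter(X2, d2)), 0)
  expect_equal(unname(relative_difference(X2, d2, s0 = 0.5)), 4,
               tolerance = 1e-12)
  expect_error(relative_difference(X2, d2, s0 = 0), "g1")

  # scale equivariance of s; d = 0 for equal group means
  expect_equal(unname(gene_scatter(2 * X, d)), 2 * sqrt(2))
  X3 <- make_expression(matrix(c(1, 5, 2, 4), 1), samples = paste0("s", 1:4))
  expect_equal(unname(relative_difference(X3, make_design(X3, 2), 1)), 0)
})

test_that("label swap negates d exactly", {
  set.seed(10)
  X <- make_expression(matrix(rnorm(30 * 8), 30, 8))
  des <- make_design(X, 4)
  d1 <- relative_difference(X, des, s0 = 0.2)
  d2 <- relative_difference(X, swap_design(des), s0 = 0.2)
  expect_identical(d1, -d2)
})

test_that("with s0 = 0, d equals the pooled-variance t statistic", {
  set.seed(11)
  for (rep in 1:100) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    X <- make_expression(matrix(rnorm(15 * (n1 + n2)), 15))
    des <- make_design(X, n1)
    d <- relative_difference(X, des, s0 = 0)
    tstat <- apply(X, 1, function(v) {
      t.test(v[1:n1], v[(n1 + 1):(n1 + n2)], var.equal = TRUE)$statistic
    })
    expect_equal(unname(d), unname(tstat), tolerance = 1e-10)
  }
})

test_that("balanced permutations obey the near-half rule", {
  d <- condition_design(c(a = "I", b = "I", c = "U", e = "U"))
  # enumeration: of the 6 splits of 4 samples into 2+2, exactly those with
  # one original-I sample in pseudo-I are balanced -> 4
  expect_warning(perms <- balanced_permutations(d, 10, seed = 1),
                 "4 distinct")
  expect_length(perms, 4)
  orig_I <- which(d$assignment == "I")
  for (p in perms) {
    expect_length(p, 2)  # pseudo-group sizes preserved
    expect_equal(sum(p %in% orig_I), 1)
  }
  # the identity permutation (both I samples in pseudo-I) is not balanced
  expect_false(any(vapply(perms, setequal, logical(1), orig_I)))

  # larger design: requested N distinct balanced permutations, each balanced
  d2 <- condition_design(setNames(rep(c("I", "U"), each = 9),
                                  paste0("s", 1:18)))
  perms2 <- balanced_permutations(d2, 50, seed = 2)
  expect_length(perms2, 50)
  expect_false(any(duplicated(lapply(perms2, paste, collapse = ","))))
  counts <- vapply(perms2, function(p) sum(p <= 9), numeric(1))
  expect_true(all(abs(counts - 4.5) <= 0.5))
})

test_that("expected relative difference is the rank-wise permutation mean", {
  X <- make_expression(matrix(c(5, 1, 0,
                                4, 2, 1,
                                1, 0, 3,
                                0, 1, 2), 3, 4),
                       samples = paste0("s", 1:4))
  des <- make_design(X, 2)
  perms <- structure(list(c(1L, 3L), c(2L, 4L)), class = "balanced_perms",
                     samples = colnames(X))
  # hand evaluation: d for each split, sorted descending, then averaged
  hand_d <- function(iI) {
    iU <- setdiff(1:4, iI)
    st <- dcnet:::sam_stats(X, iI, iU)
    unname(sort(st$diff / (st$s + 0.1), decreasing = TRUE))
  }
  expect_equal(expected_relative_difference(X, des, perms, s0 = 0.1),
               (hand_d(c(1, 3)) + hand_d(c(2, 4))) / 2)
  # single permutation: d_E is that permutation's sorted d
  one <- structure(list(c(1L, 3L)), class = "balanced_perms",
                   samples = colnames(X))
  expect_equal(expected_relative_difference(X, des, one, 0.1),
               hand_d(c(1, 3)))
  # monotone non-increasing in rank
  dE <- expected_relative_difference(X, des, perms, 0.1)
  expect_true(all(diff(dE) <= 0))
})

test_that("delta calling follows the asymmetric scan rule", {
  d <- c(g1 = 5, g2 = 1.5, g3 = 0, g4 = -1, g5 = -6)
  dE <- c(2.5, 1.4, 0, -0.9, -2.5)
  # displacements by rank: (2.5, 0.1, 0, -0.1, -3.5)
  res <- call_significant(d, dE, delta = 2)
  expect_equal(res$cut_up, 5)
  expect_equal(res$cut_low, -6)
  expect_equal(res$calls, c(g1 = "up", g2 = "none", g3 = "none",
                            g4 = "none", g5 = "down"))
  res2 <- call_significant(d, dE, delta = 0.05)
  expect_equal(res2$cut_up, 1.5)
  expect_equal(res2$cut_low, -1)
  expect_equal(unname(res2$calls), c("up", "up", "none", "down", "down"))
  # delta above the largest displacement calls nothing
  res3 <- call_significant(d, dE, delta = 4)
  expect_true(all(res3$calls == "none"))
  expect_true(is.na(res3$cut_up) && is.na(res3$cut_low))
})

test_that("call sets shrink monotonically in delta", {
  set.seed(12)
  p <- simulation_params(120, 6, de_gene_count = 20, de_effect = 2, seed = 5)
  sim <- simulate_expression(p)
  fit <- run_sam(sim$expression, sim$design, nperms = 50, seed = 9)
  d <- setNames(fit$table$d, fit$table$gene_id)
  prev <- NULL
  for (delta in c(0, 0.2, 0.5, 1, 2, 4)) {
    called <- names(which(call_significant(d, fit$d_E, delta)$calls != "none"))
    if (!is.null(prev)) expect_true(all(called %in% prev))
    prev <- called
  }
})

test_that("s0 selection is deterministic and tames low-scatter genes", {
  p <- simulation_params(200, 8, seed = 31)
  sim <- simulate_expression(p)
  # compress the scatter of half the genes to create a variance gradient
  X <- sim$expression
  X[1:100, ] <- (X[1:100, ] - rowMeans(X[1:100, ])) * 0.05 + 8
  s0a <- choose_s0(X, sim$design)
  s0b <- choose_s0(X, sim$design)
  expect_identical(s0a, s0b)
  expect_gt(as.numeric(s0a), 0)
  d_raw <- relative_difference(X, sim$design, s0 = 0)
  d_reg <- relative_difference(X, sim$design, s0 = as.numeric(s0a))
  low <- 1:100
  expect_lt(max(abs(d_reg[low])), max(abs(d_raw[low])))
  # degenerate all-equal scatter falls back to 0 with a warning
  Xc <- make_expression(matrix(rep(c(1, 2, 3, 4), each = 25), 25, 4))
  expect_warning(s0c <- choose_s0(Xc, make_design(Xc, 2)), "equal")
  expect_equal(as.numeric(s0c), 0)
})

test_that("permutation FDR is near 1 on null data and 0 with no calls", {
  p <- simulation_params(300, 9, seed = 41)
  sim <- simulate_expression(p)
  fit <- run_sam(sim$expression, sim$design, nperms = 60, delta = 0.05,
                 seed = 13)
  n_called <- sum(fit$table$call != "none")
  expect_gt(n_called, 0)
  expect_gt(fit$fdr_estimate, 0.5)
  fit2 <- run_sam(sim$expression, sim$design, nperms = 60, delta = 10,
                  seed = 13)
  expect_equal(sum(fit2$table$call != "none"), 0)
  expect_equal(fit2$fdr_estimate, 0)
})

test_that("run_sam is reproducible and exchanges calls under label swap", {
  p <- simulation_params(80, 6, de_gene_count = 10, de_effect = 3, seed = 8)
  sim <- simulate_expression(p)
  a <- run_sam(sim$expression, sim$design, nperms = 40, delta = 1, seed = 4)
  b <- run_sam(sim$expression, sim$design, nperms = 40, delta = 1, seed = 4)
  expect_identical(a$table, b$table)
  expect_identical(a$fdr_estimate, b$fdr_estimate)
  # with all balanced permutations enumerated, swapping labels exchanges
  # the up and down call sets
  sw <- suppressWarnings(
    run_sam(sim$expression, swap_design(sim$design), nperms = 1e6,
            delta = 1, seed = 4, s0 = a$s0))
  ref <- suppressWarnings(
    run_sam(sim$expression, sim$design, nperms = 1e6,
            delta = 1, seed = 4, s0 = a$s0))
  expect_identical(ref$table$gene_id[ref$table$call == "up"],
                   sw$table$gene_id[sw$table$call == "down"])
  expect_identical(ref$table$gene_id[ref$table$call == "down"],
                   sw$table$gene_id[sw$table$call == "up"])
})
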