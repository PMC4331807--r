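make_r <- function(vals, genes) {
  R <- diag(length(genes))
  dimnames(R) <- list(genes, genes)
  for (v in vals) R[v[[1]], v[[2]]] <- R[v[[2]], v[[1]]] <- v[[3]]
  R
}

test_that("candidate links follow the strict T1/T2 rule", {
  genes <- c("a", "b", "c", "d")
  rn <- make_r(list(list("a", "b", 0.1), list("a", "c", 0.3),
                    list("b", "c", 0.9), list("c", "d", 0.25)), genes)
  rc <- make_r(list(list("a", "b", 0.9), list("a", "c", 0.95),
                    list("b", "c", 0.1), list("c", "d", 0.8)), genes)
  cand <- find_candidate_links(rn, rc)
  # a|b qualifies; a|c fails r_normal < 0.3 (strict); c|d fails r_cancer > 0.8
  expect_equal(nrow(cand), 1)
  expect_equal(cand$gene_a, "a")
  expect_equal(cand$gene_b, "b")
  expect_equal(cand$delta_z, atanh(0.9) - atanh(0.1))
  # loss direction only with both_directions
  both <- find_candidate_links(rn, rc, both_directions = TRUE)
  expect_equal(nrow(both), 2)
  expect_setequal(both$direction, c("gain", "loss"))
  # identical matrices yield no links
  expect_equal(nrow(find_candidate_links(rn, rn)), 0)
  rn2 <- rn
  rownames(rn2)[1] <- colnames(rn2)[1] <- "z"
  expect_error(find_candidate_links(rn2, rc), "same gene set")
})

test_that("candidate set is monotone in the thresholds", {
  set.seed(30)
  p <- simulation_params(
    60, 12, modules = list(list(size = 6, r_cancer = 0.9, r_normal = 0)),
    seed = 12)
  sim <- simulate_expression(p)
  rn <- pearson_matrix(sim$expression, sim$design, "normal")
  rc <- pearson_matrix(sim$expression, sim$design, "cancer")
  base <- find_candidate_links(rn, rc, t1 = 0.3, t2 = 0.8)
  tighter_t2 <- find_candidate_links(rn, rc, t1 = 0.3, t2 = 0.9)
  tighter_t1 <- find_candidate_links(rn, rc, t1 = 0.15, t2 = 0.8)
  key <- function(df) pair_key(df$gene_a, df$gene_b)
  expect_true(all(key(tighter_t2) %in% key(base)))
  expect_true(all(key(tighter_t1) %in% key(base)))
})

test_that("permutation p-values are deterministic, bounded and exact for tiny designs", {
  p <- simulation_params(
    20, 20, modules = list(list(size = 4, r_cancer = 0.95, r_normal = 0)),
    seed = 77)
  sim <- simulate_expression(p)
  rn <- pearson_matrix(sim$expression, sim$design, "normal")
  rc <- pearson_matrix(sim$expression, sim$design, "cancer")
  cand <- find_candidate_links(rn, rc)
  expect_gt(nrow(cand), 0)
  a <- permutation_test(sim$expression, sim$design, cand, B = 999, seed = 5)
  b <- permutation_test(sim$expression, sim$design, cand, B = 999, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_true(all(a$p_value >= 1 / 1000))
  # a strongly planted link attains the minimum attainable p
  expect_equal(min(a$p_value), 1 / 1000)

  # tiny design: all C(8,4) = 70 splits enumerated, p = count / 70
  p2 <- simulation_params(10, 4, seed = 9)
  sim2 <- simulate_expression(p2)
  rn2 <- pearson_matrix(sim2$expression, sim2$design, "normal")
  rc2 <- pearson_matrix(sim2$expression, sim2$design, "cancer")
  g <- rownames(sim2$expression)[1:2]
  links <- data.frame(gene_a = g[1], gene_b = g[2],
                      delta_z = atanh(rc2[g[1], g[2]]) - atanh(rn2[g[1], g[2]]))
  res <- permutation_test(sim2$expression, sim2$design, links, B = 100,
                          seed = 1)
  expect_true(attr(res, "exact"))
  expect_equal(attr(res, "B_used"), choose(8, 4))
  expect_true(res$p_value >= 1 / 70)
  expect_equal(res$p_value * 70, round(res$p_value * 70))
})

test_that("BH adjustment matches hand computation", {
  expect_equal(adjust_pvalues(0.02), 0.02)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  adj <- adjust_pvalues(c(0.001, 0.5, 0.04))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_error(adjust_pvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("subnetwork assembly and degrees are consistent", {
  links <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                      p_value = c(0.001, 0.2, 0.004))
  sub <- build_subnetwork(links, alpha = 0.05, use_adjusted = FALSE)
  expect_equal(nrow(sub$links), 2)
  # brute-force degree recount
  recount <- table(c(sub$links$gene_a, sub$links$gene_b))
  expect_equal(sub$degrees[names(recount)],
               setNames(as.integer(recount), names(recount)))
  expect_equal(nrow(build_subnetwork(links, alpha = 1e-9,
                                     use_adjusted = FALSE)$links), 0)
  all_sig <- build_subnetwork(links, alpha = 1, use_adjusted = FALSE)
  expect_equal(nrow(all_sig$links), 3)
})

test_that("hub ranking breaks ties by gene ID and flags rank-k ties", {
  # star K_{1,5}: the center is the unique hub
  links <- data.frame(gene_a = rep("hub", 5),
                      gene_b = paste0("leaf", 1:5),
                      p_value = rep(0.001, 5))
  sub <- build_subnetwork(links, use_adjusted = FALSE)
  h <- hub_genes(sub, top_k = 1)
  expect_equal(h$gene_id, "hub")
  expect_false(attr(h, "tied_at_k"))
  # two disjoint triangles: all six nodes share degree 2
  tri <- data.frame(gene_a = c("a", "a", "b", "x", "x", "y"),
                    gene_b = c("b", "c", "c", "y", "z", "z"),
                    p_value = rep(0.001, 6))
  sub2 <- build_subnetwork(tri, use_adjusted = FALSE)
  h2 <- hub_genes(sub2, top_k = 2)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$gene_id, c("a", "b"))  # tie broken by gene ID
  expect_true(attr(h2, "tied_at_k"))
  # min_degree mode
  h3 <- hub_genes(sub2, min_degree = 2)
  expect_equal(nrow(h3), 6)
})

test_that("planted differential links are recovered with few false positives", {
  p <- simulation_params(
    120, 30, modules = list(list(size = 10, r_cancer = 0.9, r_normal = 0)),
    seed = 55)
  sim <- simulate_expression(p)
  rn <- pearson_matrix(sim$expression, sim$design, "normal")
  rc <- pearson_matrix(sim$expression, sim$design, "cancer")
  cand <- find_candidate_links(rn, rc)
  cand <- permutation_test(sim$expression, sim$design, cand, B = 499,
                           seed = 56)
  cand$p_adjusted <- adjust_pvalues(cand$p_value)
  sub <- build_subnetwork(cand, alpha = 0.05)
  m <- recovery_metrics(pair_key(sub$links$gene_a, sub$links$gene_b),
                        sim$truth, "links")
  expect_gte(m$sensitivity, 0.8)
  expect_lte(m$false_discovery_proportion, 0.1)
  h <- hub_genes(sub)
  module_genes <- names(sim$truth$module_membership)[
    sim$truth$module_membership == 1]
  expect_true(all(h$gene_id %in% module_genes))
})
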