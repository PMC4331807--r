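# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (matrix products, igraph) so they can
# vouch for them.

# Random Erdos-Renyi binary symmetric adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.2) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  A
}

# Neighbor sets within m steps by per-node breadth-first search over
# explicit frontiers (no matrix algebra, no igraph).
bfs_reachable <- function(A, m) {
  n <- nrow(A)
  lapply(seq_len(n), function(i) {
    dist <- rep(Inf, n)
    dist[i] <- 0
    frontier <- i
    step <- 0
    while (length(frontier) > 0 && step < m) {
      step <- step + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (dist[w] > step) {
            dist[w] <- step
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    setdiff(which(dist <= m), i)
  })
}

# Set-based (G)TOM oracle straight from the neighbor-set definition.
gtom_oracle <- function(A, m) {
  n <- nrow(A)
  sets <- bfs_reachable(A, m)
  t_mat <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      t_mat[i, j] <- (inter + A[i, j]) /
        (min(length(sets[[i]]), length(sets[[j]])) + 1 - A[i, j])
    }
  }
  dimnames(t_mat) <- dimnames(A)
  t_mat
}

# All-pairs shortest-path distances by per-node BFS.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[i] <- 0
    frontier <- i
    step <- 0
    while (length(frontier) > 0) {
      step <- step + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (dist[w] > step) {
            dist[w] <- step
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[i, ] <- dist
  }
  D
}

# Brute-force topology statistics: triangle-count clustering, neighbor-set
# topological coefficient, distance histogram.
topology_oracle <- function(A) {
  n <- nrow(A)
  k <- unname(rowSums(A))
  clustering <- numeric(n)
  tc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (k[i] >= 2) {
      tri <- 0
      for (u in nb) for (v in nb) if (u < v && A[u, v] == 1) tri <- tri + 1
      clustering[i] <- 2 * tri / (k[i] * (k[i] - 1))
      vals <- numeric(0)
      for (j in seq_len(n)) {
        if (j == i) next
        shared <- length(intersect(nb, which(A[j, ] == 1)))
        if (shared >= 1 || A[i, j] == 1) {
          vals <- c(vals, (shared + A[i, j]) / k[i])
        }
      }
      if (length(vals)) tc[i] <- mean(vals)
    }
  }
  D <- bfs_distances(A)
  du <- D[upper.tri(D)]
  du <- du[is.finite(du) & du > 0]
  list(degree = k, clustering = clustering, topological_coefficient = tc,
       path_length_histogram = table(du))
}

# Plain numeric matrix from a tom_matrix (drops class and order attribute).
tom_values <- function(T_mat) {
  x <- unclass(T_mat)
  attr(x, "order") <- NULL
  x
}

# Small expression fixture: genes x samples with named dims.
make_expression <- function(values, genes = NULL, samples = NULL) {
  X <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(X)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(X)))
  dimnames(X) <- list(genes, samples)
  X
}

# Balanced two-group design over the columns of X: first n1 samples are
# cancer (I), the rest normal (U).
make_design <- function(X, n1 = ncol(X) / 2) {
  samples <- colnames(X)
  condition_design(stats::setNames(
    c(rep("I", n1), rep("U", length(samples) - n1)), samples))
}

# Null permutation p-values for differential correlation: `n_datasets`
# independent pure-noise simulations, `links_per_dataset` disjoint gene
# pairs each, tested with B label permutations. Returns the pooled
# p-values.
null_link_pvalues <- function(n_datasets, links_per_dataset, n_per_cond,
                              B, seed) {
  n_genes <- 2 * links_per_dataset
  unlist(lapply(seq_len(n_datasets), function(d) {
    sim <- simulate_expression(simulation_params(
      n_genes = n_genes, n_samples_per_condition = n_per_cond,
      seed = seed + d))
    X <- sim$expression
    rn <- pearson_matrix(X, sim$design, "normal")
    rc <- pearson_matrix(X, sim$design, "cancer")
    g <- rownames(X)
    a <- g[seq(1, n_genes, by = 2)]
    b <- g[seq(2, n_genes, by = 2)]
    links <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                        stringsAsFactors = FALSE)
    links$delta_z <- atanh(rc[cbind(links$gene_a, links$gene_b)]) -
      atanh(rn[cbind(links$gene_a, links$gene_b)])
    permutation_test(X, sim$design, links, B = B, seed = seed + 1000 + d)$p_value
  }))
}

# Two-sided Kolmogorov statistic against the uniform distribution.
ks_uniform_stat <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(pmax(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p)))
}
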