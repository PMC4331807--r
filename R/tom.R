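# Topological overlap and module detection.
#
# On a binary symmetric adjacency A with zero diagonal, the topological
# overlap of two nodes measures how much their neighborhoods agree:
#   t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),  l_ij = sum_u a_iu a_uj
# with t_ii = 1. The m-th order generalization (GTOMm) replaces direct
# neighborhoods with the sets N_m(i) of nodes reachable from i within m
# steps (excluding i itself); GTOM1 coincides with TOM exactly. Modules
# are detected by average-linkage clustering of the dissimilarity 1 - t.

#' Topological overlap matrix
#'
#' @param net A `dcn` or binary symmetric adjacency matrix with zero
#'   diagonal.
#' @return Object of class `tom_matrix`: symmetric matrix with unit
#'   diagonal and entries in `[0, 1]`; attribute `order` = 1.
#' @export
tom <- function(net) {
  A <- dcn_adjacency(net)
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  t_mat <- (L + A) / denom
  diag(t_mat) <- 1
  dimnames(t_mat) <- dimnames(A)
  structure(t_mat, order = 1L, class = "tom_matrix")
}

#' Nodes reachable within m steps
#'
#' N_m(i) is the set of nodes other than i at geodesic distance at most m
#' from i.
#'
#' @param net A `dcn` or binary adjacency matrix.
#' @param m Path-length bound (>= 1).
#' @return Named list of character vectors of gene IDs.
#' @export
reachable_sets <- function(net, m) {
  if (m < 1) stop_("m must be >= 1")
  A <- dcn_adjacency(net)
  D <- igraph::distances(dcn_graph(net))
  genes <- rownames(A)
  out <- lapply(seq_len(nrow(A)), function(i) {
    genes[which(D[i, ] <= m & seq_len(nrow(A)) != i)]
  })
  stats::setNames(out, genes)
}

#' Generalized topological overlap matrix of order m
#'
#' t^(m)_ij = (|N_m(i) n N_m(j)| + a_ij) /
#'            (min(|N_m(i)|, |N_m(j)|) + 1 - a_ij), with unit diagonal.
#' `gtom(net, 1)` equals `tom(net)` element-wise. With
#' `exclude_partner = TRUE` the partner node is removed from each
#' reachable set before counting (|N_m(i) \ \{j\}| in the denominator; the
#' intersection is unaffected since N_m(i) never contains i).
#'
#' @param net A `dcn` or binary adjacency matrix.
#' @param m Order (>= 1).
#' @param exclude_partner Use the partner-excluded variant of the
#'   denominator sets.
#' @return A `tom_matrix` with attribute `order` = m.
#' @export
gtom <- function(net, m = 1L, exclude_partner = FALSE) {
  if (m < 1) stop_("m must be >= 1")
  A <- dcn_adjacency(net)
  n <- nrow(A)
  D <- igraph::distances(dcn_graph(net))
  Rm <- (D <= m)
  diag(Rm) <- FALSE
  sizes <- rowSums(Rm)
  inter <- Rm %*% t(Rm) * 1
  if (exclude_partner) {
    size_i <- matrix(sizes, n, n) - Rm        # |N_m(i) \ {j}| per (i, j)
    size_j <- t(size_i)
    denom <- pmin(size_i, size_j) + 1 - A
  } else {
    denom <- outer(sizes, sizes, pmin) + 1 - A
  }
  t_mat <- (inter + A) / denom
  diag(t_mat) <- 1
  dimnames(t_mat) <- dimnames(A)
  structure(t_mat, order = as.integer(m), class = "tom_matrix")
}

#' Dissimilarity transform of a topological overlap matrix
#'
#' d_ij = 1 - t_ij with a zero diagonal.
#'
#' @param T_mat A `tom_matrix` (or any similarity matrix in `[0, 1]`).
#' @return Symmetric dissimilarity matrix.
#' @export
tom_dissimilarity <- function(T_mat) {
  d <- 1 - unclass(T_mat)
  diag(d) <- 0
  attr(d, "order") <- NULL
  d
}

#' Detect modules by clustering a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering with a static cut at height
#' `cut_height`; clusters smaller than `min_size` are left unassigned
#' (label 0). Surviving modules are renumbered by decreasing size, ties
#' by the smallest member gene ID.
#'
#' @param D Symmetric dissimilarity matrix with gene dimnames (e.g. from
#'   [tom_dissimilarity()]).
#' @param cut_height Static tree-cut height (default 0.95).
#' @param min_size Minimum module size (default 5).
#' @return Object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned), `cut_height`, `min_size` and `tree`
#'   (the `hclust` object, used for heatmap ordering).
#' @export
detect_modules <- function(D, cut_height = 0.95, min_size = 5L) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8)) {
    stop_("dissimilarity matrix must be symmetric")
  }
  D <- as.matrix(D)
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- stats::setNames(integer(length(raw)), names(raw))
  if (length(keep)) {
    # order surviving clusters by decreasing size, ties by smallest member
    first_member <- vapply(keep, function(cl) min(names(raw)[raw == cl]),
                           character(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (j in seq_along(ord)) {
      labels[raw == as.integer(ord[j])] <- j
    }
  }
  structure(list(labels = labels, cut_height = cut_height,
                 min_size = as.integer(min_size), tree = tree),
            class = "module_assignment")
}

#' Reorder a TOM for module heatmap display
#'
#' Genes are ordered by module label (assigned modules first, unassigned
#' last), and within each block by the clustering dendrogram's leaf order.
#' Returns the reordered matrix together with the module block boundaries
#' (cumulative end indices), ready for heatmap plotting.
#'
#' @param T_mat A `tom_matrix` (or similarity matrix) over the assigned
#'   genes.
#' @param assignment A `module_assignment` covering `T_mat`'s genes.
#' @return List with `matrix` (reordered), `order` (gene IDs in display
#'   order) and `boundaries` (named integer vector of block end indices).
#' @export
module_heatmap_data <- function(T_mat, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  genes <- rownames(T_mat)
  labels <- assignment$labels
  if (!setequal(genes, names(labels))) {
    stop_("assignment does not cover the matrix genes")
  }
  labels <- labels[genes]
  leaf_order <- assignment$tree$labels[assignment$tree$order]
  leaf_rank <- match(genes, leaf_order)
  ord <- order(ifelse(labels == 0, Inf, labels), leaf_rank)
  ordered_genes <- genes[ord]
  blocks <- labels[ord]
  ends <- cumsum(as.integer(table(factor(blocks, levels = unique(blocks)))))
  names(ends) <- as.character(unique(blocks))
  list(matrix = unclass(T_mat)[ordered_genes, ordered_genes],
       order = ordered_genes, boundaries = ends)
}
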