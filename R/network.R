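# Per-condition Pearson co-expression networks and topology diagnostics.

#' Pearson correlation matrix for one condition
#'
#' Correlations are computed over the chosen condition's samples only, so
#' the two condition networks describe genuinely distinct states. Genes
#' with zero variance in those samples get off-diagonal correlation 0 with
#' a warning (keeping the matrix total).
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @param condition `"cancer"`/`"I"` or `"normal"`/`"U"`.
#' @return Symmetric genes x genes correlation matrix with unit diagonal;
#'   attributes `condition` and `n_samples` record its provenance.
#' @export
pearson_matrix <- function(X, design, condition = c("cancer", "normal",
                                                    "I", "U")) {
  validate_expression(X, min_genes = 2L, min_samples = 4L)
  condition <- match.arg(condition)
  state <- if (condition %in% c("cancer", "I")) "I" else "U"
  idx <- design_indices(X, design)
  cols <- if (state == "I") idx$iI else idx$iU
  if (length(cols) < 3) {
    stop_("need at least 3 samples in condition ", condition)
  }
  Xs <- X[, cols, drop = FALSE]
  const <- apply(Xs, 1, function(v) diff(range(v)) == 0)
  R <- suppressWarnings(stats::cor(t(Xs)))
  if (any(const)) {
    warning(sum(const), " constant gene(s) assigned correlation 0",
            call. = FALSE)
  }
  R[is.na(R)] <- 0
  diag(R) <- 1
  structure(R, condition = state, n_samples = length(cols))
}

#' Build a hard-threshold co-expression network
#'
#' Connects a gene pair when its correlation strictly exceeds `tau`
#' (signed mode) or when `|r|` strictly exceeds `tau` (unsigned mode). The
#' diagonal is forced to zero.
#'
#' @param R Symmetric correlation matrix with gene dimnames.
#' @param tau Threshold in (0, 1); default 0.8.
#' @param mode `"signed"` (default, edge iff r > tau) or `"unsigned"`
#'   (edge iff |r| > tau).
#' @return Object of class `dcn`: list with binary symmetric `adjacency`
#'   (0/1 matrix, zero diagonal), `tau`, `mode` and the source `condition`.
#' @export
build_dcn <- function(R, tau = 0.8, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop_("tau must lie strictly between 0 and 1")
  }
  if (!isSymmetric(unname(unclass(R)), tol = 1e-8)) {
    stop_("correlation matrix must be symmetric")
  }
  A <- if (mode == "signed") (R > tau) * 1 else (abs(R) > tau) * 1
  diag(A) <- 0
  dimnames(A) <- dimnames(R)
  structure(list(adjacency = A, tau = tau, mode = mode,
                 condition = attr(R, "condition")),
            class = "dcn")
}

# Internal: validated binary symmetric adjacency from a dcn or raw matrix.
dcn_adjacency <- function(net) {
  A <- if (inherits(net, "dcn")) net$adjacency else net
  if (!is.matrix(A) || !all(A %in% c(0, 1))) {
    stop_("adjacency must be a binary matrix")
  }
  if (!isSymmetric(unname(A))) stop_("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop_("adjacency diagonal must be zero")
  A
}

dcn_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(dcn_adjacency(net),
                                      mode = "undirected", diag = FALSE)
}

#' Number of edges in a network
#' @param net A `dcn` or binary adjacency matrix.
#' @return Integer edge count.
#' @export
edge_count <- function(net) {
  A <- dcn_adjacency(net)
  sum(A) / 2
}

#' Topology statistics of a co-expression network
#'
#' Per node: degree k_i, local clustering coefficient
#' C_i = 2 * triangles(i) / (k_i (k_i - 1)) (0 when k_i < 2), and the
#' topological coefficient TC_i: for nodes with k_i >= 2, the mean over
#' partners j (nodes sharing at least one neighbor with i, or adjacent to
#' i) of (|N1(i) n N1(j)| + a_ij) / k_i; 0 otherwise. Also returns the
#' histogram of finite shortest-path lengths over connected pairs and the
#' mean clustering coefficient by degree.
#'
#' @param net A `dcn` or binary adjacency matrix.
#' @return List with `degree`, `clustering`, `topological_coefficient`
#'   (named vectors), `path_length_histogram` (named counts of unordered
#'   connected pairs by distance) and `clustering_by_degree` (data frame).
#' @export
topology_stats <- function(net) {
  A <- dcn_adjacency(net)
  n <- nrow(A)
  genes <- rownames(A)
  k <- rowSums(A)
  g <- dcn_graph(net)
  C <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(C) <- genes

  # shared-neighbor counts
  L <- A %*% A
  TC <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    partners <- which((L[i, ] > 0 | A[i, ] == 1) & seq_len(n) != i)
    if (length(partners) == 0) next
    TC[i] <- mean((L[i, partners] + A[i, partners]) / k[i])
  }
  names(TC) <- genes

  D <- igraph::distances(g)
  du <- D[upper.tri(D)]
  du <- du[is.finite(du) & du > 0]
  hist <- if (length(du)) table(du) else table(numeric(0))

  cbd <- if (any(k > 0)) {
    agg <- stats::aggregate(C[k > 0], by = list(degree = k[k > 0]), FUN = mean)
    stats::setNames(agg, c("degree", "mean_clustering"))
  } else {
    data.frame(degree = numeric(0), mean_clustering = numeric(0))
  }

  list(degree = stats::setNames(k, genes), clustering = C,
       topological_coefficient = TC,
       path_length_histogram = hist,
       clustering_by_degree = cbd)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage agglomeration on the distance 1 - r between sample
#' expression profiles (Pearson r across genes), cut into `k` clusters.
#' Genes are centered first (each gene's mean subtracted), the usual
#' convention for expression heatmaps: it removes the gene-level baseline
#' so that the between-sample correlations reflect condition-driven
#' deviations rather than shared expression levels.
#'
#' @param X Genes x samples matrix.
#' @param k Number of clusters (default 2).
#' @param center_genes Subtract each gene's mean before correlating
#'   (default TRUE).
#' @return List with `partition` (named cluster labels) and `tree`
#'   (the `hclust` object).
#' @export
cluster_samples <- function(X, k = 2L, center_genes = TRUE) {
  validate_expression(X, min_genes = 2L, min_samples = 2L)
  if (k > ncol(X)) stop_("k exceeds the number of samples")
  if (center_genes) X <- X - rowMeans(X)
  R <- suppressWarnings(stats::cor(X))
  R[is.na(R)] <- 0
  diag(R) <- 1
  tree <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(partition = stats::cutree(tree, k = k), tree = tree)
}

#' Export a network as SIF plus node attributes
#'
#' Writes a Cytoscape-style SIF edge file (`geneA<TAB>coexp<TAB>geneB`,
#' each undirected edge once with nodes in lexicographic order; isolated
#' nodes as bare single-field lines) and, optionally, a node-attribute TSV.
#'
#' @param net A `dcn` or binary adjacency matrix.
#' @param sif_path Path for the SIF file.
#' @param node_attrs Optional data frame of per-gene attributes with a
#'   `gene_id` column (e.g. degree, regulation, hub flag).
#' @param attr_path Path for the attribute TSV (required when `node_attrs`
#'   is given).
#' @return `sif_path`, invisibly.
#' @export
export_network <- function(net, sif_path, node_attrs = NULL,
                           attr_path = NULL) {
  A <- dcn_adjacency(net)
  genes <- rownames(A)
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  lines <- character(0)
  if (nrow(idx) > 0) {
    a <- genes[idx[, 1]]
    b <- genes[idx[, 2]]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    lines <- sort(paste(lo, "coexp", hi, sep = "\t"))
  }
  isolated <- genes[rowSums(A) == 0]
  writeLines(c(lines, isolated), sif_path)
  if (!is.null(node_attrs)) {
    if (is.null(attr_path)) stop_("attr_path required with node_attrs")
    utils::write.table(node_attrs, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sif_path)
}

#' Read a SIF file back into a binary adjacency matrix
#'
#' @param path SIF file written by [export_network()].
#' @param gene_ids Optional full gene universe (so isolated nodes absent
#'   from the file can be included).
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
read_sif <- function(path, gene_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (!all(widths %in% c(1L, 3L))) {
    stop_("malformed SIF line: ", lines[which(!widths %in% c(1L, 3L))[1]])
  }
  edge <- fields[widths == 3L]
  nodes <- unique(c(unlist(fields[widths == 1L]),
                    unlist(lapply(edge, function(f) f[c(1, 3)]))))
  genes <- if (is.null(gene_ids)) sort(nodes) else gene_ids
  if (!all(nodes %in% genes)) stop_("SIF contains nodes outside gene_ids")
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (f in edge) {
    A[f[1], f[3]] <- 1
    A[f[3], f[1]] <- 1
  }
  diag(A) <- 0
  A
}
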