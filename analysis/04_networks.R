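#!/usr/bin/env Rscript
# Stage 4: per-condition co-expression networks over the screened DEGs.
#
# Builds the normal-state and cancer-state networks by hard-thresholding
# the condition-specific Pearson correlations at tau = 0.8 (edge iff
# r > 0.8), writes SIF files for network viewers, compares the two
# networks' topology (degree, clustering coefficient, topological
# coefficient, shortest-path histogram) and checks that average-linkage
# clustering of the samples recovers the two-class split.

suppressPackageStartupMessages(library(dcnet))

out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

X <- read_expression("results/preprocess/expression_normalized.tsv")
design <- read_design("results/data/design.tsv")
sam_tab <- utils::read.delim("results/sam/sam_genes.tsv")
degs <- sam_tab$gene_id[sam_tab$call != "none"]
Xd <- X[rownames(X) %in% degs, , drop = FALSE]
message(sprintf("network universe: %d DEGs", nrow(Xd)))

for (cond in c("normal", "cancer")) {
  R <- pearson_matrix(Xd, design, cond)
  net <- build_dcn(R, tau = 0.8, mode = "signed")
  topo <- topology_stats(net)
  reg <- sam_tab$call[match(rownames(Xd), sam_tab$gene_id)]
  export_network(net, file.path(out, paste0("network_", cond, ".sif")),
                 node_attrs = data.frame(gene_id = rownames(Xd),
                                         degree = topo$degree,
                                         regulation = reg),
                 attr_path = file.path(out, paste0("nodes_", cond, ".tsv")))
  utils::write.table(
    data.frame(distance = names(topo$path_length_histogram),
               pairs = as.integer(topo$path_length_histogram)),
    file.path(out, paste0("path_lengths_", cond, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(topo$clustering_by_degree,
    file.path(out, paste0("clustering_by_degree_", cond, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s network: %d edges, mean clustering %.3f, mean degree %.2f",
    cond, edge_count(net), mean(topo$clustering), mean(topo$degree)))
}

cl <- cluster_samples(Xd, k = 2)
split <- split(names(cl$partition), cl$partition)
message("2-way sample split: {", paste(split[[1]], collapse = ","),
        "} vs {", paste(split[[2]], collapse = ","), "}")
agree <- length(unique(design$assignment[split[[1]]])) == 1 &&
  length(unique(design$assignment[split[[2]]])) == 1
message("split matches the normal/cancer design exactly: ", agree)
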