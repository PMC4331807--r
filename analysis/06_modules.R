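#!/usr/bin/env Rscript
# Stage 6: module detection by topological overlap.
#
# For each condition network the (generalized) topological overlap matrix
# is computed on the binary adjacency, turned into the dissimilarity
# 1 - TOM, clustered with average linkage and cut at a static height;
# modules smaller than 4 genes are left unassigned. The reordered TOM and
# module boundaries are written for heatmap display, and the two
# conditions' module structures are compared.

suppressPackageStartupMessages(library(dcnet))

out <- "results/modules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

X <- read_expression("results/preprocess/expression_normalized.tsv")
design <- read_design("results/data/design.tsv")
sam_tab <- utils::read.delim("results/sam/sam_genes.tsv")
degs <- sam_tab$gene_id[sam_tab$call != "none"]
Xd <- X[rownames(X) %in% degs, , drop = FALSE]

assignments <- list()
for (cond in c("normal", "cancer")) {
  net <- build_dcn(pearson_matrix(Xd, design, cond), tau = 0.8)
  T_mat <- gtom(net, m = 1)
  ma <- detect_modules(tom_dissimilarity(T_mat), cut_height = 0.95,
                       min_size = 4)
  assignments[[cond]] <- ma
  hm <- module_heatmap_data(T_mat, ma)
  utils::write.table(hm$matrix,
                     file.path(out, paste0("tom_ordered_", cond, ".tsv")),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(as.list(hm$boundaries),
                       file.path(out, paste0("boundaries_", cond, ".json")),
                       auto_unbox = TRUE)
  sizes <- table(ma$labels[ma$labels > 0])
  message(sprintf("%s state: %d module(s)%s", cond, max(ma$labels),
                  if (length(sizes)) paste0(" of sizes ",
                                            paste(sizes, collapse = ", "))
                  else ""))
}

utils::write.table(
  data.frame(gene_id = names(assignments$cancer$labels),
             module_normal = unname(
               assignments$normal$labels[names(assignments$cancer$labels)]),
             module_cancer = unname(assignments$cancer$labels)),
  file.path(out, "module_assignment.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

truth <- jsonlite::read_json("results/data/truth.json")
module_genes <- names(truth$module_membership)[
  unlist(truth$module_membership) == 1]
in_cancer_mod <- assignments$cancer$labels[
  names(assignments$cancer$labels) %in% module_genes]
message(sprintf(
  "planted module: %d/%d genes assigned to one cancer-state module",
  max(0L, max(table(in_cancer_mod[in_cancer_mod > 0]), 0)),
  length(module_genes)))
message("normal-state assignment of those genes: ",
        paste(assignments$normal$labels[module_genes[
          module_genes %in% names(assignments$normal$labels)]],
          collapse = ","))
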