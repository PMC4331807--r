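#!/usr/bin/env Rscript
# Stage 1: generate the study dataset.
#
# Two-condition expression matrix emulating a small bladder-cancer
# microarray study: 9 normal + 9 cancer arrays, 500 genes on the log2
# scale. Planted structure, recorded as ground truth for later stages:
#   - 50 DEGs with 2.5-sigma mean shifts in cancer (alternating up/down);
#   - one 10-gene module co-expressed only in cancer (population r = 0.9)
#     whose genes are also strongly up-regulated (6 sigma) so they pass the DEG screen
#     that the network stages operate behind.

suppressPackageStartupMessages(library(dcnet))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- simulation_params(
  n_genes = 500, n_samples_per_condition = 9,
  de_gene_count = 50, de_effect = 2.5,
  modules = list(list(size = 10, r_cancer = 0.9, r_normal = 0,
                      de_effect = 6)),
  noise_sd = 1, baseline_mean = 8, seed = 20260924)
sim <- simulate_expression(params)

write_expression(sim$expression, file.path(out, "expression.tsv"))
write_design(sim$design, file.path(out, "design.tsv"))
jsonlite::write_json(
  list(de_genes = as.list(sim$truth$de_genes),
       planted_links = sim$truth$planted_links,
       module_membership = as.list(sim$truth$module_membership)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d genes x %d samples (%d + %d)",
                nrow(sim$expression), ncol(sim$expression),
                sim$design$n2, sim$design$n1))
message(sprintf("planted: %d DEGs, %d within-module links",
                length(sim$truth$de_genes),
                length(sim$truth$planted_links)))
message("wrote ", out, "/{expression.tsv, design.tsv, truth.json}")
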