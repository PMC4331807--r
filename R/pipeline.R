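# End-to-end orchestration: one validated config drives
# normalize -> filter -> SAM -> per-condition DCNs -> differential links
# -> subnetwork + hubs -> TOM/GTOM modules, writing every artifact and
# returning a run report whose counts mirror the written files.

config_defaults <- function() {
  list(
    normalize = TRUE,
    filter_quantile = 0.2,
    sam = list(nperms = 100L, delta = 2.5, s0 = NULL),
    network = list(tau = 0.8, mode = "signed", genes = "degs"),
    diffnet = list(t1 = 0.3, t2 = 0.8, b = 1000L, alpha = 0.05,
                   use_adjusted = TRUE, both_directions = FALSE),
    modules = list(gtom_order = 1L, cut_height = 0.95, min_size = 5L),
    seed = 1L
  )
}

merge_section <- function(defaults, given, section, errors) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    errors$msgs <- c(errors$msgs,
                     paste0("unknown key(s) in ", section, ": ",
                            paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, given[names(given) %in% names(defaults)])
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills in the documented
#' defaults (tau = 0.8, T1 = 0.3, T2 = 0.8, nperms = 100, delta = 2.5,
#' ...), rejects unknown keys, and reports all range violations together.
#'
#' @param config Path to a YAML file, or a list with the same structure:
#'   top-level keys `input` (`matrix`, `design` paths) or `simulation`
#'   (arguments for [simulation_params()]), plus optional `normalize`,
#'   `filter_quantile`, `sam`, `network`, `diffnet`, `modules`, `seed`,
#'   `output_dir`.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_("config must be a list or YAML file path")
  errors <- new.env()
  errors$msgs <- character(0)

  top_known <- c("input", "simulation", "normalize", "filter_quantile",
                 "sam", "network", "diffnet", "modules", "seed",
                 "output_dir")
  unknown <- setdiff(names(config), top_known)
  if (length(unknown)) {
    errors$msgs <- c(errors$msgs, paste0("unknown key(s): ",
                                         paste(unknown, collapse = ", ")))
  }
  if (is.null(config$input) && is.null(config$simulation)) {
    errors$msgs <- c(errors$msgs,
                     "config needs either `input` paths or `simulation` parameters")
  }

  d <- config_defaults()
  out <- list(input = config$input, simulation = config$simulation,
              output_dir = config$output_dir)
  out$normalize <- if (is.null(config$normalize)) d$normalize else
    isTRUE(config$normalize)
  out$filter_quantile <- if (is.null(config$filter_quantile))
    d$filter_quantile else config$filter_quantile
  out$seed <- as.integer(if (is.null(config$seed)) d$seed else config$seed)
  for (sec in c("sam", "network", "diffnet", "modules")) {
    given <- if (is.null(config[[sec]])) list() else config[[sec]]
    out[[sec]] <- merge_section(d[[sec]], given, sec, errors)
  }

  check <- function(ok, msg) if (!ok) errors$msgs <- c(errors$msgs, msg)
  check(out$filter_quantile >= 0 && out$filter_quantile < 1,
        "filter_quantile must lie in [0, 1)")
  check(out$sam$nperms >= 1, "sam$nperms must be >= 1")
  check(out$sam$delta >= 0, "sam$delta must be >= 0")
  check(out$network$tau > 0 && out$network$tau < 1,
        "network$tau must lie in (0, 1)")
  check(out$network$mode %in% c("signed", "unsigned"),
        "network$mode must be 'signed' or 'unsigned'")
  check(out$network$genes %in% c("degs", "all"),
        "network$genes must be 'degs' or 'all'")
  check(out$diffnet$t1 > 0 && out$diffnet$t1 < 1,
        "diffnet$t1 must lie in (0, 1)")
  check(out$diffnet$t2 > 0 && out$diffnet$t2 < 1,
        "diffnet$t2 must lie in (0, 1)")
  check(out$diffnet$b >= 100, "diffnet$b must be >= 100")
  check(out$diffnet$alpha > 0 && out$diffnet$alpha <= 1,
        "diffnet$alpha must lie in (0, 1]")
  check(out$modules$gtom_order >= 1, "modules$gtom_order must be >= 1")
  check(out$modules$cut_height > 0 && out$modules$cut_height <= 1,
        "modules$cut_height must lie in (0, 1]")
  check(out$modules$min_size >= 1, "modules$min_size must be >= 1")

  if (length(errors$msgs)) {
    stop_("invalid configuration:\n  - ",
          paste(errors$msgs, collapse = "\n  - "))
  }
  structure(out, class = "pipeline_config")
}

#' Run the integrated differential co-expression pipeline
#'
#' Executes, in order: load or simulate -> median normalization -> weak
#' gene filter -> SAM DEG selection -> per-condition Pearson DCNs over
#' the DEG set (or all genes) -> topology statistics -> sample clustering
#' -> candidate differential links -> permutation significance + BH ->
#' differential subnetwork and hubs -> TOM/GTOM module detection per
#' condition. Every artifact is written under `output_dir` (when given)
#' and the returned report's summary counts are computed from the same
#' objects that were written.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: parameters, per-stage summary counts
#'   (DEGs up/down, edges per condition, candidate and significant links,
#'   hubs, modules per condition), hub table, and the stage objects
#'   themselves under `$objects`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fn, name) {
    if (!is.null(out_dir)) fn(file.path(out_dir, name))
  }

  truth <- NULL
  if (!is.null(cfg$simulation)) {
    say("simulating expression data")
    params <- do.call(simulation_params, cfg$simulation)
    sim <- simulate_expression(params)
    X <- sim$expression
    design <- sim$design
    truth <- sim$truth
    emit(function(p) write_expression(X, p), "expression.tsv")
    emit(function(p) write_design(design, p), "design.tsv")
  } else {
    X <- read_expression(cfg$input$matrix)
    design <- read_design(cfg$input$design)
  }

  if (cfg$normalize) X <- median_normalize(X)
  if (cfg$filter_quantile > 0) X <- filter_genes(X, cfg$filter_quantile)
  emit(function(p) write_expression(X, p), "expression_processed.tsv")

  say("running SAM (", cfg$sam$nperms, " balanced permutations)")
  fit <- run_sam(X, design, nperms = cfg$sam$nperms, delta = cfg$sam$delta,
                 seed = cfg$seed, s0 = cfg$sam$s0)
  degs <- sam_degs(fit)
  emit(function(p) utils::write.table(fit$table, p, sep = "\t",
                                      quote = FALSE, row.names = FALSE),
       "sam_genes.tsv")
  emit(function(p) jsonlite::write_json(
    list(s0 = fit$s0, delta = fit$delta, cut_up = fit$cut_up,
         cut_low = fit$cut_low, fdr_estimate = fit$fdr_estimate,
         nperms = fit$nperms, seed = fit$seed),
    p, auto_unbox = TRUE, digits = NA, na = "null"), "sam_summary.json")

  universe <- if (cfg$network$genes == "degs") names(degs) else rownames(X)
  if (length(universe) < 3) {
    stop_("pipeline stage 'network': fewer than 3 genes in the network ",
          "universe (", length(universe), " DEGs); use network$genes = 'all' ",
          "or relax delta")
  }
  Xn <- X[universe, , drop = FALSE]

  say("building per-condition networks over ", length(universe), " genes")
  r_normal <- pearson_matrix(Xn, design, "normal")
  r_cancer <- pearson_matrix(Xn, design, "cancer")
  net_normal <- build_dcn(r_normal, cfg$network$tau, cfg$network$mode)
  net_cancer <- build_dcn(r_cancer, cfg$network$tau, cfg$network$mode)
  topo_normal <- topology_stats(net_normal)
  topo_cancer <- topology_stats(net_cancer)
  clust <- cluster_samples(Xn, k = 2L)
  emit(function(p) export_network(net_normal, p), "network_normal.sif")
  emit(function(p) export_network(net_cancer, p), "network_cancer.sif")

  say("screening differential links (T1=", cfg$diffnet$t1,
      ", T2=", cfg$diffnet$t2, ")")
  cand <- find_candidate_links(r_normal, r_cancer, cfg$diffnet$t1,
                               cfg$diffnet$t2,
                               both_directions = cfg$diffnet$both_directions)
  if (nrow(cand) > 0) {
    cand <- permutation_test(Xn, design, cand, B = cfg$diffnet$b,
                             seed = cfg$seed + 1L)
    cand$p_adjusted <- adjust_pvalues(cand$p_value)
  } else {
    cand$p_value <- numeric(0)
    cand$p_adjusted <- numeric(0)
  }
  subnet <- build_subnetwork(cand, alpha = cfg$diffnet$alpha,
                             use_adjusted = cfg$diffnet$use_adjusted)
  hubs <- hub_genes(subnet)
  emit(function(p) utils::write.table(cand, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE),
       "differential_links.tsv")
  if (!is.null(out_dir) && nrow(subnet$links) > 0) {
    genes_sub <- sort(unique(c(subnet$links$gene_a, subnet$links$gene_b)))
    A <- matrix(0, length(genes_sub), length(genes_sub),
                dimnames = list(genes_sub, genes_sub))
    A[cbind(subnet$links$gene_a, subnet$links$gene_b)] <- 1
    A <- pmax(A, t(A))
    attrs <- data.frame(gene_id = genes_sub,
                        degree = as.integer(subnet$degrees[genes_sub]),
                        hub = genes_sub %in% hubs$gene_id)
    export_network(A, file.path(out_dir, "subnetwork.sif"),
                   node_attrs = attrs,
                   attr_path = file.path(out_dir, "subnetwork_nodes.tsv"))
  }

  say("detecting modules (GTOM order ", cfg$modules$gtom_order, ")")
  detect_for <- function(net) {
    T_mat <- gtom(net, cfg$modules$gtom_order)
    detect_modules(tom_dissimilarity(T_mat),
                   cut_height = cfg$modules$cut_height,
                   min_size = cfg$modules$min_size)
  }
  mod_normal <- detect_for(net_normal)
  mod_cancer <- detect_for(net_cancer)
  emit(function(p) utils::write.table(
    data.frame(gene_id = names(mod_cancer$labels),
               module_normal = unname(mod_normal$labels[names(mod_cancer$labels)]),
               module_cancer = unname(mod_cancer$labels)),
    p, sep = "\t", quote = FALSE, row.names = FALSE), "modules.tsv")

  counts <- list(
    genes_analyzed = nrow(X),
    degs_up = sum(fit$table$call == "up"),
    degs_down = sum(fit$table$call == "down"),
    network_genes = length(universe),
    edges_normal = edge_count(net_normal),
    edges_cancer = edge_count(net_cancer),
    candidate_links = nrow(cand),
    significant_links = nrow(subnet$links),
    hubs = nrow(hubs),
    modules_normal = max(0L, mod_normal$labels),
    modules_cancer = max(0L, mod_cancer$labels)
  )
  report <- structure(list(
    parameters = unclass(cfg)[c("normalize", "filter_quantile", "sam",
                                "network", "diffnet", "modules", "seed")],
    counts = counts,
    hubs = hubs,
    sample_partition = clust$partition,
    truth = truth,
    objects = list(expression = X, design = design, sam = fit,
                   r_normal = r_normal, r_cancer = r_cancer,
                   net_normal = net_normal, net_cancer = net_cancer,
                   topology = list(normal = topo_normal,
                                   cancer = topo_cancer),
                   links = cand, subnetwork = subnet,
                   modules = list(normal = mod_normal,
                                  cancer = mod_cancer))),
    class = "run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(c(list(version = "0.1.0"), counts),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Differential co-expression pipeline run\n")
  c_ <- x$counts
  cat(sprintf("  genes analyzed: %d | DEGs: %d up, %d down\n",
              c_$genes_analyzed, c_$degs_up, c_$degs_down))
  cat(sprintf("  network genes: %d | edges: %d (normal), %d (cancer)\n",
              c_$network_genes, c_$edges_normal, c_$edges_cancer))
  cat(sprintf("  differential links: %d candidate, %d significant | hubs: %d\n",
              c_$candidate_links, c_$significant_links, c_$hubs))
  cat(sprintf("  modules: %d (normal), %d (cancer)\n",
              c_$modules_normal, c_$modules_cancer))
  invisible(x)
}
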