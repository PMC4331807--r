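# Synthetic two-condition expression data with planted ground truth.
#
# Each planted co-expression module follows a single-factor model: in the
# condition where the module is active, member genes share a per-sample
# latent factor f ~ N(0,1) with common loading lambda, on top of i.i.d.
# N(0, sigma^2) noise. The population within-module correlation is then
# lambda^2/(lambda^2 + sigma^2), so lambda = sigma*sqrt(r/(1-r)) plants an
# exact target correlation r. Differential expression is an additive mean
# shift (in units of the noise SD) applied to the cancer samples only.

#' Parameters for the synthetic-data generator
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_condition Samples per condition (>= 3).
#' @param de_gene_count Number of planted differentially expressed genes;
#'   their shifts alternate up/down so both calling cutoffs are exercised.
#' @param de_effect Mean shift of planted DE genes, in units of `noise_sd`.
#' @param modules List of module descriptors, each a list with `size`
#'   (>= 2), `r_cancer` and `r_normal` (target within-module correlations
#'   in `[0, 1)` for the cancer and normal condition) and optionally
#'   `de_effect` (mean shift of the module's genes in cancer, default 0).
#' @param noise_sd Noise standard deviation (> 0).
#' @param baseline_mean Baseline log2 intensity added to every entry.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated `sim_params` object.
#' @export
simulation_params <- function(n_genes,
                              n_samples_per_condition,
                              de_gene_count = 0L,
                              de_effect = 0,
                              modules = list(),
                              noise_sd = 1,
                              baseline_mean = 8,
                              seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_samples_per_condition = as.integer(n_samples_per_condition),
            de_gene_count = as.integer(de_gene_count),
            de_effect = de_effect,
            modules = lapply(modules, function(m) {
              list(size = as.integer(m$size),
                   r_cancer = m$r_cancer,
                   r_normal = if (is.null(m$r_normal)) 0 else m$r_normal,
                   de_effect = if (is.null(m$de_effect)) 0 else m$de_effect)
            }),
            noise_sd = noise_sd,
            baseline_mean = baseline_mean,
            seed = as.integer(seed))
  if (p$n_samples_per_condition < 3) {
    stop_("n_samples_per_condition must be >= 3")
  }
  if (p$noise_sd <= 0) stop_("noise_sd must be positive")
  if (p$de_gene_count < 0) stop_("de_gene_count must be >= 0")
  for (m in p$modules) {
    if (m$size < 2) stop_("module sizes must be >= 2")
    for (r in c(m$r_cancer, m$r_normal)) {
      if (r < 0 || r >= 1) stop_("target correlations must lie in [0, 1)")
    }
  }
  if (p$de_gene_count + sum(vapply(p$modules, `[[`, integer(1), "size")) >
      p$n_genes) {
    stop_("de_gene_count plus total module size exceeds n_genes")
  }
  structure(p, class = "sim_params")
}

# Loading that plants population correlation r at noise SD sigma.
factor_loading <- function(r, sigma) sigma * sqrt(r / (1 - r))

#' Simulate a two-condition expression matrix with planted truth
#'
#' Genes are laid out as: planted DE genes first (alternating +/- shift),
#' then module blocks in order, then pure-noise genes. Sample IDs encode
#' the condition for readability (`N..`/`C..`) but downstream code must use
#' the returned design, never parse IDs.
#'
#' @param params A `sim_params` object from [simulation_params()].
#' @return List with `expression` (genes x samples matrix), `design`
#'   (a `condition_design`; cancer samples are state I) and `truth`, a
#'   `sim_truth` list carrying `de_genes` (named sign vector),
#'   `planted_links` (canonical pair keys of within-module pairs whose
#'   population correlations satisfy the default differential-link rule
#'   r_normal < 0.3 and r_cancer > 0.8) and `module_membership`
#'   (named integer vector, 0 = background).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_genes
  ns <- params$n_samples_per_condition
  sigma <- params$noise_sd
  wg <- max(4L, nchar(as.character(n)))
  ws <- max(2L, nchar(as.character(ns)))
  gene_ids <- sprintf(paste0("G%0", wg, "d"), seq_len(n))
  normal_ids <- sprintf(paste0("N%0", ws, "d"), seq_len(ns))
  cancer_ids <- sprintf(paste0("C%0", ws, "d"), seq_len(ns))
  sample_ids <- c(normal_ids, cancer_ids)
  i_normal <- seq_len(ns)
  i_cancer <- ns + seq_len(ns)

  set.seed(params$seed)
  X <- params$baseline_mean +
    matrix(stats::rnorm(n * 2L * ns, sd = sigma), nrow = n,
           dimnames = list(gene_ids, sample_ids))

  membership <- stats::setNames(integer(n), gene_ids)
  de_sign <- numeric(0)

  if (params$de_gene_count > 0) {
    idx <- seq_len(params$de_gene_count)
    signs <- rep_len(c(1, -1), params$de_gene_count)
    X[idx, i_cancer] <- X[idx, i_cancer] + signs * params$de_effect * sigma
    de_sign <- stats::setNames(signs, gene_ids[idx])
  }

  planted_links <- character(0)
  offset <- params$de_gene_count
  for (k in seq_along(params$modules)) {
    m <- params$modules[[k]]
    idx <- offset + seq_len(m$size)
    offset <- offset + m$size
    membership[idx] <- k
    # factors drawn unconditionally to keep the RNG stream independent of
    # the target correlations
    f_normal <- stats::rnorm(ns)
    f_cancer <- stats::rnorm(ns)
    if (m$r_normal > 0) {
      X[idx, i_normal] <- X[idx, i_normal] +
        factor_loading(m$r_normal, sigma) * rep(f_normal, each = m$size)
    }
    if (m$r_cancer > 0) {
      X[idx, i_cancer] <- X[idx, i_cancer] +
        factor_loading(m$r_cancer, sigma) * rep(f_cancer, each = m$size)
    }
    if (m$de_effect != 0) {
      X[idx, i_cancer] <- X[idx, i_cancer] + m$de_effect * sigma
      de_sign <- c(de_sign,
                   stats::setNames(rep(sign(m$de_effect), m$size),
                                   gene_ids[idx]))
    }
    if (m$r_cancer > 0.8 && m$r_normal < 0.3) {
      pairs <- utils::combn(gene_ids[idx], 2)
      planted_links <- c(planted_links, pair_key(pairs[1, ], pairs[2, ]))
    }
  }

  design <- condition_design(stats::setNames(
    c(rep("normal", ns), rep("cancer", ns)), sample_ids))
  truth <- structure(list(de_genes = de_sign,
                          planted_links = planted_links,
                          module_membership = membership),
                     class = "sim_truth")
  list(expression = X, design = design, truth = truth)
}

#' Sensitivity and false discovery proportion against planted truth
#'
#' @param predicted For `mode = "links"`, a character vector of canonical
#'   pair keys (see [pair_key()]) or a 2-column matrix/data frame of gene
#'   pairs; for `mode = "degs"`, a character vector of gene IDs.
#' @param truth A `sim_truth` from [simulate_expression()].
#' @param mode `"links"` or `"degs"`.
#' @return List with `sensitivity` = |predicted n truth| / |truth| and
#'   `false_discovery_proportion` = |predicted \ truth| / max(|predicted|, 1)
#'   (0 for an empty prediction, by convention).
#' @export
recovery_metrics <- function(predicted, truth, mode = c("links", "degs")) {
  stopifnot(inherits(truth, "sim_truth"))
  mode <- match.arg(mode)
  truth_set <- if (mode == "links") truth$planted_links else
    names(truth$de_genes)
  if (length(truth_set) == 0) {
    stop_("truth contains no planted ", mode)
  }
  if (mode == "links" && (is.matrix(predicted) || is.data.frame(predicted))) {
    predicted <- as.matrix(predicted)
    predicted <- if (nrow(predicted) == 0) character(0) else
      pair_key(predicted[, 1], predicted[, 2])
  }
  predicted <- unique(as.character(predicted))
  hits <- sum(predicted %in% truth_set)
  list(sensitivity = hits / length(truth_set),
       false_discovery_proportion =
         (length(predicted) - hits) / max(length(predicted), 1L))
}
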