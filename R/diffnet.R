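# Differential links between the two condition networks: candidate
# detection by the T1/T2 correlation rule, permutation significance on the
# Fisher-z correlation difference, BH adjustment, subnetwork assembly and
# hub ranking.

atanh_clamped <- function(r) atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))

#' Find candidate differential links
#'
#' A gene pair is a differential link when its Pearson correlation is
#' strictly below `t1` in the normal state and strictly above `t2` in the
#' cancer state (gain of co-expression). With `both_directions = TRUE` the
#' symmetric loss-of-co-expression case (above `t2` in normal, below `t1`
#' in cancer) is also reported.
#'
#' @param r_normal,r_cancer Symmetric correlation matrices over the same
#'   genes (e.g. from [pearson_matrix()]).
#' @param t1 Low-correlation threshold (default 0.3).
#' @param t2 High-correlation threshold (default 0.8).
#' @param both_directions Also report loss-of-correlation links.
#' @return Data frame with one row per candidate link: `gene_a`, `gene_b`
#'   (lexicographic), `r_normal`, `r_cancer`,
#'   `delta_z` = atanh(r_cancer) - atanh(r_normal), and `direction`.
#' @export
find_candidate_links <- function(r_normal, r_cancer, t1 = 0.3, t2 = 0.8,
                                 both_directions = FALSE) {
  if (!identical(rownames(r_normal), rownames(r_cancer))) {
    stop_("the two correlation matrices must share the same gene set")
  }
  genes <- rownames(r_normal)
  ut <- upper.tri(r_normal)
  gain <- ut & r_normal < t1 & r_cancer > t2
  sel <- which(gain, arr.ind = TRUE)
  dir <- rep("gain", nrow(sel))
  if (both_directions) {
    loss <- ut & r_cancer < t1 & r_normal > t2
    sel_l <- which(loss, arr.ind = TRUE)
    sel <- rbind(sel, sel_l)
    dir <- c(dir, rep("loss", nrow(sel_l)))
  }
  a <- genes[sel[, 1]]
  b <- genes[sel[, 2]]
  rn <- r_normal[sel]
  rc <- r_cancer[sel]
  out <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                    r_normal = rn, r_cancer = rc,
                    delta_z = atanh_clamped(rc) - atanh_clamped(rn),
                    direction = dir, stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Permutation test for differential links
#'
#' The per-link statistic is the Fisher-z correlation difference
#' delta_z = atanh(r_cancer) - atanh(r_normal). The null is generated by
#' reshuffling the condition labels over samples (preserving group sizes;
#' one global relabeling per draw, applied to every link, so the joint
#' gene structure is kept) and recomputing delta_z. Two-sided p-values use
#' the add-one rule p = (#\{|dz_perm| >= |dz_obs|\} + 1)/(B + 1); when the
#' number of distinct label splits is at most `B` the splits are
#' enumerated exhaustively and p = #\{|dz_perm| >= |dz_obs|\}/#splits
#' (the observed split is one of them, so p > 0 either way).
#'
#' @param X Genes x samples matrix (the same one used to build the
#'   correlation matrices).
#' @param design A `condition_design` (state I = cancer).
#' @param links Data frame with `gene_a`, `gene_b`, `delta_z` columns, as
#'   from [find_candidate_links()].
#' @param B Number of Monte-Carlo permutations (>= 100).
#' @param seed Integer seed.
#' @return `links` with a `p_value` column appended; attributes `B_used`
#'   and `exact` record how the null was generated.
#' @export
permutation_test <- function(X, design, links, B = 1000L, seed = 1L) {
  if (nrow(links) == 0) stop_("links must be nonempty")
  if (B < 100) stop_("B must be >= 100")
  validate_expression(X, min_genes = 2L, min_samples = 6L)
  idx <- design_indices(X, design)
  if (length(idx$iI) < 3 || length(idx$iU) < 3) {
    stop_("permutation test needs at least 3 samples per condition")
  }
  genes <- unique(c(links$gene_a, links$gene_b))
  if (!all(genes %in% rownames(X))) {
    stop_("links refer to genes absent from the matrix")
  }
  Xg <- X[genes, , drop = FALSE]
  n <- ncol(Xg)
  n1 <- length(idx$iI)
  ia <- match(links$gene_a, genes)
  ib <- match(links$gene_b, genes)
  flat <- cbind(ia, ib)
  obs <- abs(links$delta_z)

  total_splits <- choose(n, n1)
  exact <- total_splits <= B
  splits <- if (exact) {
    utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(as.integer(seed))
    replicate(B, sample.int(n, n1), simplify = FALSE)
  }
  count <- numeric(nrow(links))
  for (sp in splits) {
    Rc <- suppressWarnings(stats::cor(t(Xg[, sp, drop = FALSE])))
    Rn <- suppressWarnings(stats::cor(t(Xg[, -sp, drop = FALSE])))
    Rc[is.na(Rc)] <- 0
    Rn[is.na(Rn)] <- 0
    dz <- atanh_clamped(Rc[flat]) - atanh_clamped(Rn[flat])
    count <- count + (abs(dz) >= obs)
  }
  p <- if (exact) count / length(splits) else (count + 1) / (length(splits) + 1)
  links$p_value <- p
  attr(links, "B_used") <- length(splits)
  attr(links, "exact") <- exact
  links
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method Adjustment method (only `"benjamini_hochberg"`).
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = "benjamini_hochberg") {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_("p-values must lie in (0, 1]")
  }
  method <- match.arg(method)
  stats::p.adjust(p, method = "BH")
}

#' Assemble the differential co-expression subnetwork
#'
#' Keeps the links whose (adjusted) p-value is at most `alpha` and
#' computes each gene's degree within the retained link set.
#'
#' @param links Data frame from [permutation_test()]; if `use_adjusted`
#'   and no `p_adjusted` column exists, BH adjustment is applied first.
#' @param alpha Significance level (default 0.05).
#' @param use_adjusted Test the BH-adjusted p-values (default) rather than
#'   the raw ones.
#' @return Object of class `diff_subnetwork`: list with `links` (kept
#'   rows), `degrees` (named, every incident gene) and `alpha`. An empty
#'   subnetwork is allowed.
#' @export
build_subnetwork <- function(links, alpha = 0.05, use_adjusted = TRUE) {
  if (!"p_value" %in% names(links)) stop_("links lack p-values")
  if (use_adjusted && !"p_adjusted" %in% names(links)) {
    links$p_adjusted <- adjust_pvalues(links$p_value)
  }
  crit <- if (use_adjusted) links$p_adjusted else links$p_value
  kept <- links[crit <= alpha, , drop = FALSE]
  degrees <- if (nrow(kept)) {
    tab <- table(c(kept$gene_a, kept$gene_b))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(links = kept, degrees = degrees, alpha = alpha),
            class = "diff_subnetwork")
}

#' Rank hub genes of the differential subnetwork
#'
#' Nodes are ranked by subnetwork degree (descending), ties broken by gene
#' ID. Either the `top_k` highest-ranked genes are returned (with a flag
#' when further genes tie with the k-th degree and were cut off), or all
#' genes with degree at least `min_degree`.
#'
#' @param subnet A `diff_subnetwork`.
#' @param top_k Number of hubs to report (default 6); ignored when
#'   `min_degree` is given.
#' @param min_degree Optional degree floor.
#' @return Data frame `gene_id, degree` in rank order, with attribute
#'   `tied_at_k` (TRUE when ties at the k-th degree were truncated).
#' @export
hub_genes <- function(subnet, top_k = 6L, min_degree = NULL) {
  stopifnot(inherits(subnet, "diff_subnetwork"))
  deg <- subnet$degrees
  if (length(deg) == 0) {
    return(structure(data.frame(gene_id = character(0), degree = integer(0)),
                     tied_at_k = FALSE))
  }
  ord <- order(-deg, names(deg))
  ranked <- data.frame(gene_id = names(deg)[ord],
                       degree = as.integer(deg[ord]),
                       stringsAsFactors = FALSE)
  if (!is.null(min_degree)) {
    out <- ranked[ranked$degree >= min_degree, , drop = FALSE]
    return(structure(out, tied_at_k = FALSE))
  }
  k <- min(top_k, nrow(ranked))
  out <- ranked[seq_len(k), , drop = FALSE]
  tied <- nrow(ranked) > k && ranked$degree[k + 1L] == ranked$degree[k]
  structure(out, tied_at_k = tied)
}
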