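# Significance Analysis of Microarrays (two-class, unpaired).
#
# Per-gene relative difference d(i) = (mean_I - mean_U) / (s(i) + s0), with
# the gene-specific scatter s(i) the pooled-SD-based standard error of the
# mean difference, a small positive fudge factor s0 stabilising d for
# low-variance genes, an expected relative difference d_E(i) obtained by
# rank-averaging d over balanced label permutations, and asymmetric
# delta-based calling cutoffs with a permutation FDR estimate.

# Core statistics for one split of samples into pseudo-groups I and U.
sam_stats <- function(X, iI, iU) {
  n1 <- length(iI)
  n2 <- length(iU)
  mI <- rowMeans(X[, iI, drop = FALSE])
  mU <- rowMeans(X[, iU, drop = FALSE])
  ssI <- rowSums((X[, iI, drop = FALSE] - mI)^2)
  ssU <- rowSums((X[, iU, drop = FALSE] - mU)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(diff = mI - mU, s = sqrt(a * (ssI + ssU)))
}

#' Gene-specific scatter s(i)
#'
#' The pooled within-group standard deviation scaled to the standard error
#' of the mean difference:
#' s(i) = sqrt(a * (SS_I + SS_U)) with a = (1/n1 + 1/n2)/(n1 + n2 - 2).
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @return Named nonnegative numeric vector, one value per gene.
#' @export
gene_scatter <- function(X, design) {
  validate_expression(X, min_genes = 1L, min_samples = 4L)
  idx <- design_indices(X, design)
  if (length(idx$iI) < 2 || length(idx$iU) < 2) {
    stop_("each condition needs at least 2 samples")
  }
  st <- sam_stats(X, idx$iI, idx$iU)
  stats::setNames(st$s, rownames(X))
}

#' Relative difference d(i)
#'
#' d(i) = (mean_I(i) - mean_U(i)) / (s(i) + s0). Antisymmetric under a
#' label swap.
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @param s0 Nonnegative fudge factor (expression units).
#' @return Named numeric vector of relative differences.
#' @export
relative_difference <- function(X, design, s0 = 0) {
  validate_expression(X, min_genes = 1L, min_samples = 4L)
  if (s0 < 0) stop_("s0 must be nonnegative")
  idx <- design_indices(X, design)
  st <- sam_stats(X, idx$iI, idx$iU)
  denom <- st$s + s0
  if (any(denom == 0)) {
    g <- rownames(X)[which(denom == 0)[1]]
    stop_("s(i) + s0 is zero for gene ", g,
          "; use a positive s0 or remove constant genes")
  }
  stats::setNames(st$diff / denom, rownames(X))
}

#' Choose the fudge factor s0
#'
#' Percentile search in the SAM convention: for each candidate percentile
#' alpha in \{0, 0.05, ..., 1\} of the s(i) distribution, genes are split
#' into windows by s-quantile and the median absolute deviation of
#' d = diff/(s + s0_alpha) is computed per window; the alpha minimising the
#' coefficient of variation of these MADs is chosen. Deterministic.
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @return The chosen s0 (a percentile of the s distribution), with the
#'   percentile attached as attribute `"alpha"`.
#' @export
choose_s0 <- function(X, design) {
  idx <- design_indices(X, design)
  st <- sam_stats(X, idx$iI, idx$iU)
  if (nrow(X) < 20) {
    warning("s0 selection is unreliable below 20 genes", call. = FALSE)
  }
  if (diff(range(st$s)) == 0) {
    warning("all gene scatters are equal; returning s0 = 0", call. = FALSE)
    return(structure(0, alpha = NA_real_))
  }
  alphas <- seq(0, 1, by = 0.05)
  n_windows <- max(2L, min(100L, floor(nrow(X) / 5)))
  breaks <- unique(stats::quantile(st$s, seq(0, 1, length.out = n_windows + 1)))
  win <- cut(st$s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(alphas, function(a) {
    s0 <- stats::quantile(st$s, a, names = FALSE)
    d <- st$diff / (st$s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  best <- alphas[which.min(cv)]
  structure(stats::quantile(st$s, best, names = FALSE), alpha = best)
}

#' Balanced label permutations
#'
#' A permutation reassigns samples to pseudo-groups of the original sizes
#' (n1, n2); it is *balanced* when the number of original-I samples placed
#' in pseudo-group I is within 0.5 of n1/2, i.e. each pseudo-group mixes
#' the two original conditions as evenly as the sizes allow. When the
#' balanced set is small it is enumerated and sampled without replacement;
#' otherwise distinct balanced permutations are drawn uniformly at random.
#'
#' @param design A `condition_design`.
#' @param N Number of permutations requested (>= 1). If `N` exceeds the
#'   number of distinct balanced permutations, all of them are returned
#'   with a warning.
#' @param seed Integer seed for the sampling step.
#' @return Object of class `balanced_perms`: a list of integer vectors,
#'   each giving the sample indices (in the design's sample order) that
#'   form pseudo-group I.
#' @export
balanced_permutations <- function(design, N, seed = 1L) {
  stopifnot(inherits(design, "condition_design"))
  if (N < 1) stop_("N must be >= 1")
  samples <- names(design$assignment)
  n <- length(samples)
  n1 <- design$n1
  orig_I <- design$assignment == "I"
  is_balanced <- function(idx) abs(sum(orig_I[idx]) - n1 / 2) <= 0.5

  total_splits <- choose(n, n1)
  set.seed(as.integer(seed))
  if (total_splits <= 2e5) {
    all_splits <- utils::combn(n, n1, simplify = FALSE)
    balanced <- Filter(is_balanced, all_splits)
    if (N >= length(balanced)) {
      if (N > length(balanced)) {
        warning("only ", length(balanced),
                " distinct balanced permutations exist; returning all",
                call. = FALSE)
      }
      perms <- balanced
    } else {
      perms <- balanced[sample.int(length(balanced), N)]
    }
  } else {
    # rejection-sample distinct balanced splits
    seen <- new.env(hash = TRUE)
    perms <- vector("list", N)
    got <- 0L
    while (got < N) {
      idx <- sort(sample.int(n, n1))
      if (!is_balanced(idx)) next
      key <- paste(idx, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      perms[[got]] <- idx
    }
  }
  structure(perms, class = "balanced_perms", samples = samples)
}

# d statistic for every permutation: genes x nperms matrix.
perm_d_matrix <- function(X, design, perms, s0) {
  samples <- attr(perms, "samples")
  # permutation indices refer to the design's sample order
  Xo <- X[, samples, drop = FALSE]
  n <- ncol(Xo)
  vapply(perms, function(iI) {
    st <- sam_stats(Xo, iI, setdiff(seq_len(n), iI))
    st$diff / (st$s + s0)
  }, numeric(nrow(Xo)))
}

#' Expected relative difference d_E(i)
#'
#' For each permutation p the relative differences d_p are sorted in
#' decreasing order, so that d_p(i) is the i-th largest value; d_E(i) is
#' the mean of the i-th largest values over permutations. By construction
#' d_E is non-increasing in the rank i.
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @param perms A `balanced_perms` object.
#' @param s0 Fudge factor.
#' @return Numeric vector of length `nrow(X)`, indexed by rank.
#' @export
expected_relative_difference <- function(X, design, perms, s0 = 0) {
  stopifnot(inherits(perms, "balanced_perms"), length(perms) > 0)
  dp <- perm_d_matrix(X, design, perms, s0)
  sorted <- apply(dp, 2, sort, decreasing = TRUE)
  rowMeans(matrix(sorted, nrow = nrow(X)))
}

#' Call significant genes at displacement delta
#'
#' Genes are ranked by d (decreasing, ties by input order) and aligned with
#' d_E by rank. Scanning from the most positive rank, the up cutoff is the
#' smallest observed d among ranks displaced above the d = d_E line by more
#' than delta; all genes with d >= cut_up are called up. The down side is
#' symmetric from the most negative rank. The two cutoffs are asymmetric in
#' general.
#'
#' @param d Named per-gene relative differences.
#' @param d_E Expected relative differences by rank (same length).
#' @param delta Nonnegative displacement threshold.
#' @return List with `calls` (named character vector in
#'   \{"up", "down", "none"\}), `cut_up` and `cut_low` (NA when no rank
#'   exceeds delta on that side).
#' @export
call_significant <- function(d, d_E, delta) {
  if (length(d) != length(d_E)) stop_("d and d_E must have equal length")
  if (delta < 0) stop_("delta must be nonnegative")
  ord <- order(d, decreasing = TRUE)
  ds <- d[ord]
  disp <- ds - d_E
  up_ranks <- which(disp > delta)
  down_ranks <- which(-disp > delta)
  cut_up <- if (length(up_ranks)) min(ds[up_ranks]) else NA_real_
  cut_low <- if (length(down_ranks)) max(ds[down_ranks]) else NA_real_
  calls <- rep("none", length(d))
  names(calls) <- names(d)
  if (!is.na(cut_up)) calls[d >= cut_up] <- "up"
  if (!is.na(cut_low)) calls[d <= cut_low & calls == "none"] <- "down"
  list(calls = calls, cut_up = cut_up, cut_low = cut_low)
}

#' Permutation estimate of the false discovery rate
#'
#' The median (optionally the mean) over permutations of the number of
#' permuted d values falling beyond the calling cutoffs, divided by the
#' observed number of calls; 0 when nothing was called.
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @param perms A `balanced_perms` object.
#' @param s0 Fudge factor used for the observed d.
#' @param cut_up,cut_low Cutoffs from [call_significant()] (NA = no cutoff
#'   on that side).
#' @param n_called Observed number of significant calls.
#' @param use_median Use the median of exceedance counts (default) rather
#'   than the mean.
#' @return Estimated FDR (nonnegative; may exceed 1 on null data).
#' @export
estimate_fdr <- function(X, design, perms, s0, cut_up, cut_low, n_called,
                         use_median = TRUE) {
  if (n_called == 0) return(0)
  dp <- perm_d_matrix(X, design, perms, s0)
  fdr_from_perm(dp, cut_up, cut_low, n_called, use_median)
}

fdr_from_perm <- function(dp, cut_up, cut_low, n_called, use_median = TRUE) {
  if (n_called == 0) return(0)
  exceed <- matrix(FALSE, nrow(dp), ncol(dp))
  if (!is.na(cut_up)) exceed <- exceed | dp >= cut_up
  if (!is.na(cut_low)) exceed <- exceed | dp <= cut_low
  counts <- colSums(exceed)
  centre <- if (use_median) stats::median(counts) else mean(counts)
  centre / n_called
}

#' Run the full SAM procedure
#'
#' Composes scatter, fudge-factor selection, balanced permutations,
#' expected relative difference, delta calling and the permutation FDR.
#'
#' @param X Genes x samples matrix.
#' @param design A `condition_design`.
#' @param nperms Number of balanced permutations (default 100).
#' @param delta Calling threshold (default 2.5).
#' @param seed Integer seed for permutation sampling.
#' @param s0 Optional fixed fudge factor; default `NULL` selects it with
#'   [choose_s0()].
#' @return Object of class `sam_result`: a list with `table` (data frame
#'   `gene_id, d, s, call`), `d_E`, `s0`, `delta`, `cut_up`, `cut_low`,
#'   `fdr_estimate`, `nperms`, `seed`, and the permutation d matrix
#'   `d_perm` (genes x permutations) for delta re-scans.
#' @export
run_sam <- function(X, design, nperms = 100L, delta = 2.5, seed = 1L,
                    s0 = NULL) {
  validate_expression(X)
  if (is.null(s0)) s0 <- as.numeric(choose_s0(X, design))
  perms <- balanced_permutations(design, nperms, seed = seed)
  d <- relative_difference(X, design, s0)
  dp <- perm_d_matrix(X, design, perms, s0)
  sorted <- apply(dp, 2, sort, decreasing = TRUE)
  d_E <- rowMeans(matrix(sorted, nrow = nrow(X)))
  cs <- call_significant(d, d_E, delta)
  n_called <- sum(cs$calls != "none")
  fdr <- fdr_from_perm(dp, cs$cut_up, cs$cut_low, n_called)
  structure(list(
    table = data.frame(gene_id = rownames(X), d = unname(d),
                       s = unname(gene_scatter(X, design)),
                       call = unname(cs$calls), stringsAsFactors = FALSE),
    d_E = d_E, s0 = s0, delta = delta,
    cut_up = cs$cut_up, cut_low = cs$cut_low,
    fdr_estimate = fdr, nperms = length(perms), seed = as.integer(seed),
    d_perm = dp), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  up <- sum(x$table$call == "up")
  down <- sum(x$table$call == "down")
  cat("SAM result: ", nrow(x$table), " genes, ", x$nperms,
      " balanced permutations\n", sep = "")
  cat(sprintf("  s0 = %.4g, delta = %.3g -> %d up, %d down (est. FDR %.3g)\n",
              x$s0, x$delta, up, down, x$fdr_estimate))
  invisible(x)
}

#' Re-call a SAM fit across a grid of delta values
#'
#' Reuses the stored permutation d matrix, so scanning deltas is cheap.
#' Useful for picking a delta that achieves a target estimated FDR.
#'
#' @param fit A `sam_result`.
#' @param deltas Numeric vector of delta values.
#' @return Data frame with one row per delta: calls up/down, total calls,
#'   cutoffs and the estimated FDR.
#' @export
sam_delta_table <- function(fit, deltas) {
  stopifnot(inherits(fit, "sam_result"))
  d <- stats::setNames(fit$table$d, fit$table$gene_id)
  rows <- lapply(deltas, function(delta) {
    cs <- call_significant(d, fit$d_E, delta)
    n_called <- sum(cs$calls != "none")
    data.frame(delta = delta,
               n_up = sum(cs$calls == "up"),
               n_down = sum(cs$calls == "down"),
               n_called = n_called,
               cut_up = cs$cut_up, cut_low = cs$cut_low,
               fdr_estimate = fdr_from_perm(fit$d_perm, cs$cut_up,
                                            cs$cut_low, n_called))
  })
  do.call(rbind, rows)
}

#' Genes called at a given delta
#'
#' @param fit A `sam_result`.
#' @param delta Optional delta overriding the fit's; default uses the
#'   fit's calls.
#' @return Named character vector of calls restricted to called genes.
#' @export
sam_degs <- function(fit, delta = NULL) {
  stopifnot(inherits(fit, "sam_result"))
  calls <- stats::setNames(fit$table$call, fit$table$gene_id)
  if (!is.null(delta)) {
    d <- stats::setNames(fit$table$d, fit$table$gene_id)
    calls <- call_significant(d, fit$d_E, delta)$calls
  }
  calls[calls != "none"]
}
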