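# Internal helpers shared across modules.

#' Canonical key for an unordered gene pair
#'
#' Pairs are stored throughout the package as `"A|B"` strings with the two
#' gene IDs in lexicographic order, so that sets of undirected links can be
#' compared with plain set operations.
#'
#' @param a,b Character vectors of gene IDs (recycled).
#' @return Character vector of canonical pair keys.
#' @export
pair_key <- function(a, b) {
  ifelse(as.character(a) < as.character(b),
         paste(a, b, sep = "|"),
         paste(b, a, sep = "|"))
}

# Split canonical pair keys back into a 2-column character matrix.
split_pair_key <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- t(vapply(parts, function(p) p[1:2], character(2)))
  colnames(out) <- c("gene_a", "gene_b")
  out
}

stop_ <- function(...) stop(..., call. = FALSE)

# Validate a genes x samples expression matrix.
validate_expression <- function(X, min_genes = 2L, min_samples = 4L) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop_("expression matrix must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(X))) {
    dup <- rownames(X)[duplicated(rownames(X))][1]
    stop_("duplicate gene ID: ", dup)
  }
  if (anyDuplicated(colnames(X))) {
    dup <- colnames(X)[duplicated(colnames(X))][1]
    stop_("duplicate sample ID: ", dup)
  }
  if (nrow(X) < min_genes) stop_("need at least ", min_genes, " genes")
  if (ncol(X) < min_samples) stop_("need at least ", min_samples, " samples")
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop_("non-finite value at gene ", rownames(X)[bad[1]],
          ", sample ", colnames(X)[bad[2]],
          " (impute or remove missing values first)")
  }
  invisible(X)
}

# Column indices of condition I (cancer) and U (normal) samples in X,
# checking that the design covers exactly X's samples.
design_indices <- function(X, design) {
  stopifnot(inherits(design, "condition_design"))
  samples <- colnames(X)
  if (!setequal(samples, names(design$assignment))) {
    stop_("design samples do not match matrix samples")
  }
  cond <- design$assignment[samples]
  list(iI = which(cond == "I"), iU = which(cond == "U"))
}
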