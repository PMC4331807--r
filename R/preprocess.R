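# Expression-matrix I/O and preprocessing: TSV read/write, condition
# designs, per-array median centering, weak-gene filtering and the normal
# Q-Q diagnostic.

#' Construct a two-condition sample design
#'
#' Maps each sample to one of two states: `I` (the perturbed/cancer state)
#' or `U` (the unaffected/normal state). The spellings `cancer`/`normal`
#' are accepted and mapped to `I`/`U`.
#'
#' @param conditions Named character vector: sample ID -> condition, with
#'   values in `c("I", "U", "cancer", "normal")`.
#' @return An object of class `condition_design` with fields `assignment`
#'   (named vector of `"I"`/`"U"`), `n1` (number of I samples) and `n2`
#'   (number of U samples).
#' @export
condition_design <- function(conditions) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop_("conditions must be named by unique sample IDs")
  }
  map <- c(I = "I", U = "U", cancer = "I", normal = "U")
  if (!all(conditions %in% names(map))) {
    bad <- setdiff(unique(conditions), names(map))
    stop_("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  assignment <- map[as.character(conditions)]
  names(assignment) <- names(conditions)
  n1 <- sum(assignment == "I")
  n2 <- sum(assignment == "U")
  if (n1 < 2 || n2 < 2) {
    stop_("each condition needs at least 2 samples (got I=", n1, ", U=", n2, ")")
  }
  structure(list(assignment = assignment, n1 = n1, n2 = n2),
            class = "condition_design")
}

#' Swap the two condition labels of a design
#'
#' Useful for antisymmetry checks: the relative difference d(i) is exactly
#' negated under a label swap.
#'
#' @param design A `condition_design`.
#' @return A `condition_design` with I and U exchanged.
#' @export
swap_design <- function(design) {
  swapped <- ifelse(design$assignment == "I", "U", "I")
  names(swapped) <- names(design$assignment)
  condition_design(swapped)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs, a first column of gene IDs, and
#' tab-separated numeric log2 intensities. Parse problems (duplicate IDs,
#' ragged rows, non-numeric cells) are reported with their location.
#' Missing cells (`NA`/empty) are rejected unless `impute = TRUE`, in
#' which case they are filled with the gene's median over observed
#' samples (downstream correlation and permutation code assumes complete
#' matrices).
#'
#' @param path Path to the TSV file.
#' @param impute Impute missing cells with the per-gene median instead of
#'   failing (default FALSE).
#' @return Numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path, impute = FALSE) {
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop_("expression file needs a header and >=1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading gene_id column name
  body_width <- length(fields[[2]])
  sample_ids <- if (length(header) == body_width) header[-1] else header
  n_samp <- body_width - 1L
  if (length(sample_ids) != n_samp) {
    stop_("header has ", length(sample_ids), " sample IDs but rows have ",
          n_samp, " value columns")
  }
  if (anyDuplicated(sample_ids)) {
    stop_("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1])
  }
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != body_width)) {
    i <- which(widths != body_width)[1]
    stop_("ragged row at line ", i + 1L, ": expected ", body_width,
          " fields, found ", widths[i])
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop_("duplicate gene ID: ", gene_ids[duplicated(gene_ids)][1])
  }
  missing_tokens <- c("", "NA", "na", "NaN")
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(n_samp))
  )
  vals <- if (n_samp == 1L) matrix(vals, nrow = 1) else vals
  X <- t(matrix(vals, nrow = n_samp,
                dimnames = list(sample_ids, gene_ids)))
  if (anyNA(X)) {
    raw <- t(vapply(body, function(f) f[-1], character(n_samp)))
    is_missing <- is.na(X) & raw %in% missing_tokens
    if (any(is.na(X) & !is_missing)) {
      bad <- which(is.na(X) & !is_missing, arr.ind = TRUE)[1, ]
      stop_("non-numeric cell at gene ", rownames(X)[bad[1]],
            ", sample ", colnames(X)[bad[2]])
    }
    if (!impute) {
      bad <- which(is_missing, arr.ind = TRUE)[1, ]
      stop_("missing value at gene ", rownames(X)[bad[1]],
            ", sample ", colnames(X)[bad[2]],
            " (set impute = TRUE for per-gene median imputation)")
    }
    for (i in which(rowSums(is_missing) > 0)) {
      obs <- X[i, !is_missing[i, ]]
      if (length(obs) == 0) stop_("gene ", rownames(X)[i],
                                  " has no observed values")
      X[i, is_missing[i, ]] <- stats::median(obs)
    }
  }
  validate_expression(X, min_genes = 1L, min_samples = 1L)
  X
}

#' Write an expression matrix to TSV at full precision
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(X))` reproduces `X` bit-exactly.
#'
#' @param X Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  validate_expression(X, min_genes = 1L, min_samples = 1L)
  header <- paste(c("gene_id", colnames(X)), collapse = "\t")
  rows <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], sprintf("%.17g", X[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample design file
#'
#' Two-column TSV `sample_id<TAB>condition` with conditions spelled
#' `normal`/`cancer` (a header row is optional).
#'
#' @param path Path to the design TSV.
#' @return A `condition_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2) stop_("design file must have exactly 2 columns")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  conditions <- tab[[2]]
  names(conditions) <- tab[[1]]
  condition_design(conditions)
}

#' Write a sample design file
#'
#' @param design A `condition_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  lab <- ifelse(design$assignment == "I", "cancer", "normal")
  writeLines(c("sample_id\tcondition",
               paste(names(design$assignment), lab, sep = "\t")), path)
  invisible(path)
}

#' Median-center each array
#'
#' Shifts every sample column additively so that its median equals the
#' median of the original per-sample medians. On log-scale intensities this
#' removes array-to-array location offsets while preserving within-sample
#' gene differences exactly; it is idempotent.
#'
#' @param X Numeric genes x samples matrix.
#' @return Matrix of the same shape with aligned column medians.
#' @export
median_normalize <- function(X) {
  validate_expression(X, min_genes = 1L, min_samples = 1L)
  med <- apply(X, 2, stats::median)
  target <- stats::median(med)
  sweep(X, 2, med - target, "-")
}

#' Drop weakly expressed genes
#'
#' Keeps genes whose across-sample median strictly exceeds the given
#' quantile of all gene medians (quantile 0 keeps every gene). Gene order
#' is preserved.
#'
#' @param X Numeric genes x samples matrix.
#' @param min_median_quantile Quantile of gene medians in `[0, 1)`.
#' @return The filtered matrix.
#' @export
filter_genes <- function(X, min_median_quantile = 0.2) {
  validate_expression(X, min_genes = 1L, min_samples = 1L)
  q <- min_median_quantile
  if (!is.numeric(q) || length(q) != 1 || q < 0 || q >= 1) {
    stop_("min_median_quantile must be a single number in [0, 1)")
  }
  if (q == 0) return(X)
  med <- apply(X, 1, stats::median)
  keep <- med > stats::quantile(med, q, names = FALSE)
  if (!any(keep)) stop_("gene filter removed every gene")
  X[keep, , drop = FALSE]
}

#' Normal Q-Q diagnostic points for pooled expression values
#'
#' Pools all matrix entries, sorts them, and pairs them with standard
#' normal quantiles at plotting positions (i - 0.5)/n. Used to inspect how
#' close the (normalized) intensity distribution is to Gaussian.
#'
#' @param X Numeric genes x samples matrix (or any numeric vector).
#' @return `data.frame` with columns `theoretical` and `sample`.
#' @export
qq_points <- function(X) {
  v <- sort(as.numeric(X))
  n <- length(v)
  if (n < 3) stop_("need at least 3 values for a Q-Q diagnostic")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n), sample = v)
}
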