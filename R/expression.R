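#' Construct an expression matrix with an observed-entry mask
#'
#' Wraps a samples x genes matrix of (normalized) expression values together
#' with a logical mask of observed entries. Missing values may be encoded as
#' `NA` in `values` (the default mask) or supplied explicitly; masked entries
#' never enter any fitting or scoring computation.
#'
#' @param values numeric matrix, samples in rows and genes in columns. `NA`
#'   entries are treated as missing unless `mask` is given.
#' @param mask logical matrix of the same shape; `TRUE` marks an observed
#'   entry. Defaults to `!is.na(values)`.
#' @param sample_ids,gene_ids character vectors of row / column labels;
#'   default to the dimnames of `values` or `sample_1...` / `gene_1...`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `mask`, `sample_ids`, `gene_ids`.
#' @export
#' @examples
#' z <- matrix(c(1, NA, 3, 4), 2, 2)
#' em <- expression_matrix(z)
#' sum(em$mask)
expression_matrix <- function(values, mask = NULL,
                              sample_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(values))) {
    stop("`mask` and `values` must have identical dimensions.", call. = FALSE)
  }
  mask[is.na(values)] <- FALSE
  if (anyNA(mask)) mask[is.na(mask)] <- FALSE

  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("id lengths must match matrix dimensions.", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids.", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids.", call. = FALSE)

  if (nrow(values) > 0 && ncol(values) > 0) {
    if (any(rowSums(mask) == 0)) {
      warning("some samples have no observed entries; they carry no information.",
              call. = FALSE)
    }
    if (any(colSums(mask) == 0)) {
      warning("some genes have no observed entries; their loadings will be zero.",
              call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  dimnames(mask) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, mask = mask,
         sample_ids = sample_ids, gene_ids = gene_ids),
    class = "expression_matrix"
  )
}

#' Coerce to an expression matrix
#'
#' @param x a matrix, data frame, or `expression_matrix`.
#' @param ... passed to [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
as_expression_matrix <- function(x, ...) {
  if (inherits(x, "expression_matrix")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  expression_matrix(x, ...)
}

#' @export
print.expression_matrix <- function(x, ...) {
  n_obs <- sum(x$mask)
  cat(sprintf(
    "<expression_matrix> %d samples x %d genes, %d observed entries (%.1f%%)\n",
    nrow(x$values), ncol(x$values), n_obs,
    100 * n_obs / max(1, length(x$mask))
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
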