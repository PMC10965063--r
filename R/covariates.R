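#' Construct a single covariate block
#'
#' A covariate block pairs a design matrix over samples with a kind:
#' `"categorical"` (one indicator column per level), `"interaction"`
#' (indicator over the crossed levels of two categorical parents),
#' `"observation"` (the identity design, one level per sample), or
#' `"continuous"` (a single column of raw covariate values).
#'
#' Categorical, interaction and observation designs are stored internally as
#' a level-index vector (one level per sample); use [design_matrix()] to
#' materialize the indicator matrix.
#'
#' @param name block label.
#' @param design an N x L indicator matrix (exactly one 1 per row) for
#'   categorical kinds, or an N-vector / N x 1 matrix of raw values for a
#'   continuous covariate.
#' @param kind one of `"categorical"`, `"interaction"`, `"observation"`,
#'   `"continuous"`.
#' @param level_ids labels for the L levels (ignored for continuous blocks,
#'   whose single "level" is the block name).
#'
#' @return An object of class `covariate_block`.
#' @export
covariate_block <- function(name, design,
                            kind = c("categorical", "interaction",
                                     "observation", "continuous"),
                            level_ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    x <- as.numeric(design)
    if (length(x) == 0) stop("continuous design is empty.", call. = FALSE)
    return(new_covariate_block(name, kind,
                               idx = NULL, x = x, n = length(x),
                               level_ids = name))
  }
  design <- as.matrix(design)
  if (!all(design %in% c(0, 1)) || any(rowSums(design) != 1)) {
    stop(sprintf("block '%s': categorical designs need exactly one 1 per row.",
                 name), call. = FALSE)
  }
  if (kind == "observation" &&
      !(nrow(design) == ncol(design) && all(design == diag(nrow(design))))) {
    stop(sprintf("block '%s': observation design must be the identity.", name),
         call. = FALSE)
  }
  idx <- max.col(design)
  if (is.null(level_ids)) level_ids <- colnames(design)
  if (is.null(level_ids)) level_ids <- paste0(name, "_", seq_len(ncol(design)))
  if (length(level_ids) != ncol(design)) {
    stop("level_ids length must equal the number of design columns.",
         call. = FALSE)
  }
  new_covariate_block(name, kind, idx = idx, x = NULL, n = nrow(design),
                      level_ids = as.character(level_ids))
}

new_covariate_block <- function(name, kind, idx, x, n, level_ids) {
  structure(
    list(name = name, kind = kind, idx = idx, x = x, n = n,
         level_ids = level_ids),
    class = "covariate_block"
  )
}

## level-indexed constructor used by generators and covariate_blocks()
block_from_index <- function(name, idx, level_ids,
                             kind = "categorical") {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > length(level_ids))) {
    stop("level index out of range.", call. = FALSE)
  }
  new_covariate_block(name, kind, idx = idx, x = NULL, n = length(idx),
                      level_ids = as.character(level_ids))
}

#' Number of levels of a covariate block
#' @param block a `covariate_block`.
#' @return integer, the number of latent rows the block contributes.
#' @export
n_levels <- function(block) {
  if (block$kind == "continuous") 1L else length(block$level_ids)
}

#' Materialize a block's design matrix
#'
#' @param block a `covariate_block`.
#' @return the N x L indicator matrix (or N x 1 column for a continuous
#'   block) with level ids as column names.
#' @export
design_matrix <- function(block) {
  if (block$kind == "continuous") {
    return(matrix(block$x, ncol = 1, dimnames = list(NULL, block$name)))
  }
  L <- n_levels(block)
  out <- matrix(0, block$n, L, dimnames = list(NULL, block$level_ids))
  out[cbind(seq_len(block$n), block$idx)] <- 1
  out
}

#' @export
print.covariate_block <- function(x, ...) {
  cat(sprintf("<covariate_block> '%s' (%s): %d samples, %d level(s)\n",
              x$name, x$kind, x$n, n_levels(x)))
  invisible(x)
}

#' Build covariate blocks from a sample table
#'
#' Turns a data frame of per-sample covariates into the list of design
#' blocks used by [insider()]. Categorical columns become indicator blocks
#' with levels ordered by first appearance; interaction terms `"a:b"` cross
#' two categorical columns with levels ordered a-major (all levels of `b`
#' for the first level of `a`, then the second, ...), keeping empty
#' combinations so the interaction block always has `L_a * L_b` rows.
#'
#' @param data data frame of covariates, one row per sample, in the same
#'   order as the expression matrix rows (or carrying `id_col` to align).
#' @param categorical character vector of categorical column names.
#' @param continuous character vector of continuous column names.
#' @param interactions character vector of `"a:b"` interaction terms over
#'   categorical columns.
#' @param observation logical; add a per-sample (identity-design) block
#'   named `"observation"` to capture variation from unmodeled sources.
#' @param sample_ids optional sample ids to align/label rows.
#'
#' @return A named list of `covariate_block` objects.
#' @export
#' @examples
#' cov <- data.frame(phenotype = c("ctl", "ctl", "dis", "dis"),
#'                   tissue = c("a", "b", "a", "b"))
#' blocks <- covariate_blocks(cov, categorical = c("phenotype", "tissue"),
#'                            interactions = "phenotype:tissue")
#' names(blocks)
covariate_blocks <- function(data,
                             categorical = NULL,
                             continuous = NULL,
                             interactions = NULL,
                             observation = FALSE,
                             sample_ids = NULL) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(categorical, continuous), names(data))
  if (length(missing_cols)) {
    stop("covariate columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  blocks <- list()
  lev <- list()
  idx <- list()
  for (col in categorical) {
    vals <- as.character(data[[col]])
    levels_col <- unique(vals)
    lev[[col]] <- levels_col
    idx[[col]] <- match(vals, levels_col)
    blocks[[col]] <- block_from_index(col, idx[[col]], levels_col,
                                      kind = "categorical")
  }
  for (term in interactions) {
    parents <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parents) != 2 || !all(parents %in% categorical)) {
      stop(sprintf(
        "interaction '%s' must cross two declared categorical columns.", term),
        call. = FALSE)
    }
    a <- parents[1]; b <- parents[2]
    La <- length(lev[[a]]); Lb <- length(lev[[b]])
    # a-major ordering over the full La x Lb grid, empty cells kept
    combo_idx <- (idx[[a]] - 1L) * Lb + idx[[b]]
    combo_ids <- as.vector(t(outer(lev[[a]], lev[[b]], paste, sep = ":")))
    blocks[[term]] <- block_from_index(term, combo_idx, combo_ids,
                                       kind = "interaction")
  }
  for (col in continuous) {
    blocks[[col]] <- covariate_block(col, as.numeric(data[[col]]),
                                     kind = "continuous")
  }
  if (isTRUE(observation)) {
    n <- nrow(data)
    ids <- if (!is.null(sample_ids)) as.character(sample_ids) else
      paste0("sample_", seq_len(n))
    blocks[["observation"]] <- block_from_index("observation", seq_len(n),
                                                ids, kind = "observation")
  }
  if (length(blocks) == 0) stop("no covariate blocks requested.", call. = FALSE)
  blocks
}

## per-sample latent contribution of one block given its factor matrix
block_contribution <- function(block, B) {
  if (block$kind == "continuous") {
    outer(block$x, drop(B))
  } else {
    B[block$idx, , drop = FALSE]
  }
}
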