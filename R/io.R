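## Delimited-text IO: expression matrices (TSV/CSV, NA/empty = missing),
## covariate tables aligned to expression sample order, and fit
## directories (one TSV per factor block + loadings + a JSON manifest)
## that round-trip at full double precision.

delim_for <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from a delimited file
#'
#' Expects TSV or CSV (optionally gzip-compressed) with sample ids in the
#' first column and gene ids in the header; empty cells, `NA` or `NaN`
#' mark missing entries.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  tab <- readr::read_delim(path, delim = delim_for(path),
                           show_col_types = FALSE, progress = FALSE,
                           na = c("", "NA", "NaN"))
  if (ncol(tab) < 2) stop("expression file needs id column + genes.",
                          call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in expression file.",
                               call. = FALSE)
  genes <- names(tab)[-1]
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression file.",
                                 call. = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_matrix(vals, sample_ids = ids, gene_ids = genes)
}

#' Write an expression matrix to a delimited file
#'
#' Masked entries are written as `NA`, so a write/read round trip
#' preserves both values and mask.
#'
#' @param x an `expression_matrix` (or matrix).
#' @param path output path (`.tsv` or `.csv`, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  vals <- x$values
  vals[!x$mask] <- NA
  df <- data.frame(sample_id = x$sample_ids,
                   as.data.frame(format_full(vals)),
                   check.names = FALSE)
  names(df) <- c("sample_id", x$gene_ids)
  readr::write_delim(df, path, delim = delim_for(path), na = "NA",
                     progress = FALSE)
  invisible(path)
}

## %.17g survives a double -> text -> double round trip exactly
format_full <- function(m) {
  out <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  out[is.na(m)] <- NA
  out
}

#' Read a covariate table and build design blocks
#'
#' Reads a delimited table whose first column holds sample ids, aligns its
#' rows to the expression matrix's sample order, and builds the requested
#' covariate blocks (see [covariate_blocks()]).
#'
#' @param path file path (TSV/CSV).
#' @param sample_ids sample ids of the expression matrix, in order; every
#'   id must be present exactly once in the covariate table.
#' @inheritParams covariate_blocks
#' @return named list of `covariate_block`s.
#' @export
read_covariates <- function(path, sample_ids,
                            categorical = NULL, continuous = NULL,
                            interactions = NULL, observation = FALSE) {
  tab <- readr::read_delim(path, delim = delim_for(path),
                           show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  pos <- match(as.character(sample_ids), ids)
  if (anyNA(pos)) {
    stop("covariate table is missing sample ids: ",
         paste(utils::head(sample_ids[is.na(pos)], 5), collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[pos, , drop = FALSE]
  covariate_blocks(tab, categorical = categorical, continuous = continuous,
                   interactions = interactions, observation = observation,
                   sample_ids = sample_ids)
}

#' Write a fitted model to a directory
#'
#' Writes one TSV per factor block (level ids + K metagene columns), the
#' gene loadings (metagenes x genes), the per-sample design assignments,
#' and a JSON manifest with hyperparameters, loss trace and seed. All
#' numbers are written with 17 significant digits so [read_fit()] inverts
#' the write exactly.
#'
#' @param fit an `insider_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "insider_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fit$blocks)) {
    B <- fit$factors[[nm]]
    df <- data.frame(level_id = fit$blocks[[nm]]$level_ids,
                     as.data.frame(format_full(B)), check.names = FALSE)
    names(df) <- c("level_id", paste0("metagene_", seq_len(ncol(B))))
    readr::write_tsv(df, file.path(dir, paste0("block_", sanitize(nm), ".tsv")),
                     progress = FALSE)
  }
  V <- fit$loadings
  dfv <- data.frame(metagene = paste0("metagene_", seq_len(nrow(V))),
                    as.data.frame(format_full(V)), check.names = FALSE)
  names(dfv) <- c("metagene", fit$gene_ids)
  readr::write_tsv(dfv, file.path(dir, "loadings.tsv"), progress = FALSE)

  assign_df <- data.frame(sample_id = fit$sample_ids)
  for (nm in names(fit$blocks)) {
    b <- fit$blocks[[nm]]
    assign_df[[nm]] <- if (b$kind == "continuous") sprintf("%.17g", b$x) else
      b$level_ids[b$idx]
  }
  readr::write_tsv(assign_df, file.path(dir, "design.tsv"), progress = FALSE)

  manifest <- list(
    package = "insider",
    hyperparams = fit$hyperparams,
    n_iter = fit$n_iter,
    converged = fit$converged,
    loss_trace = fit$loss_trace,
    blocks = lapply(fit$blocks, function(b)
      list(name = b$name, kind = b$kind, n_levels = n_levels(b))),
    empty_levels = fit$empty_levels,
    gene_ids = fit$gene_ids,
    sample_ids = fit$sample_ids
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

sanitize <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

## exact double parsing: read as text, convert with R's correctly-rounded
## strtod (readr's fast float path can be one ulp off)
read_matrix_exact <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  out <- matrix(as.numeric(out), nrow = nrow(tab))
  attr(out, "ids") <- as.character(tab[[1]])
  out
}

#' Read a fitted model from a directory written by [write_fit()]
#'
#' @param dir the fit directory.
#' @return an `insider_fit` (without the training mask, which is not
#'   serialized; [holdout_rmse()] on a restored fit requires refitting).
#' @export
read_fit <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no manifest.json in '%s'; not a fit directory.", dir),
         call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  design_path <- file.path(dir, "design.tsv")
  if (!file.exists(design_path)) {
    stop(sprintf("missing design.tsv in '%s'.", dir), call. = FALSE)
  }
  assign_df <- readr::read_tsv(design_path, show_col_types = FALSE,
                               progress = FALSE,
                               col_types = readr::cols(.default = "c"))
  blocks <- list()
  factors <- list()
  for (nm in names(man$blocks)) {
    meta <- man$blocks[[nm]]
    path <- file.path(dir, paste0("block_", sanitize(nm), ".tsv"))
    if (!file.exists(path)) {
      stop(sprintf("missing factor file for block '%s' in '%s'.", nm, dir),
           call. = FALSE)
    }
    B <- read_matrix_exact(path)
    level_ids <- attr(B, "ids")
    attr(B, "ids") <- NULL
    if (meta$kind == "continuous") {
      blocks[[nm]] <- covariate_block(nm, as.numeric(assign_df[[nm]]),
                                      kind = "continuous")
    } else {
      idx <- match(assign_df[[nm]], level_ids)
      blocks[[nm]] <- block_from_index(nm, idx, level_ids, kind = meta$kind)
    }
    factors[[nm]] <- B
  }
  V <- read_matrix_exact(file.path(dir, "loadings.tsv"))
  attr(V, "ids") <- NULL
  structure(
    list(blocks = blocks, factors = factors, loadings = V,
         hyperparams = man$hyperparams,
         loss_trace = man$loss_trace, n_iter = man$n_iter,
         converged = man$converged, mask = NULL,
         empty_levels = man$empty_levels,
         sample_ids = as.character(man$sample_ids),
         gene_ids = as.character(man$gene_ids)),
    class = "insider_fit"
  )
}
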