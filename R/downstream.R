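## Post-fit interpretation: adjusted expression per covariate, metagene
## variance ranking/exclusion, interaction and contrast profiles, and
## quantile gene sets for external enrichment tools.

get_block <- function(fit, block_name) {
  if (!block_name %in% names(fit$blocks)) {
    stop(sprintf("unknown block '%s'; available: %s.", block_name,
                 paste(names(fit$blocks), collapse = ", ")), call. = FALSE)
  }
  block_name
}

check_metagenes <- function(fit, metagenes) {
  K <- fit$hyperparams$K
  if (is.null(metagenes)) return(seq_len(K))
  metagenes <- as.integer(metagenes)
  if (any(metagenes < 1L | metagenes > K)) {
    stop(sprintf("metagene indices must be in 1..%d.", K), call. = FALSE)
  }
  metagenes
}

#' Adjusted expression profile of one covariate
#'
#' The product of one covariate block's factor matrix with the shared gene
#' loadings, `B[, S] V[S, ]`: the expression attributable to that covariate
#' with all other covariates' variation controlled. An optional metagene
#' subset `S` restricts the profile to selected metagenes.
#'
#' @param fit an `insider_fit`.
#' @param block_name which covariate block.
#' @param metagenes optional integer vector of metagene indices (default
#'   all); an empty vector yields the zero matrix.
#' @return numeric matrix, levels x genes.
#' @export
adjusted_expression <- function(fit, block_name, metagenes = NULL) {
  stopifnot(inherits(fit, "insider_fit"))
  block_name <- get_block(fit, block_name)
  S <- check_metagenes(fit, metagenes)
  B <- fit$factors[[block_name]]
  out <- if (length(S) == 0) {
    matrix(0, nrow(B), ncol(fit$loadings))
  } else {
    B[, S, drop = FALSE] %*% fit$loadings[S, , drop = FALSE]
  }
  dimnames(out) <- list(fit$blocks[[block_name]]$level_ids, fit$gene_ids)
  out
}

#' Rank metagenes by their variance across a block's levels
#'
#' Computes, for each metagene, the variance of its factor values across
#' the levels of the chosen block (e.g. across development stages or brain
#' regions), and ranks metagenes from most to least variable. High-variance
#' metagenes drive differences between the block's levels; the least
#' variable ones are candidates for exclusion.
#'
#' @inheritParams adjusted_expression
#' @return tibble with columns `metagene`, `variance`, sorted descending.
#' @export
metagene_variance_ranking <- function(fit, block_name) {
  stopifnot(inherits(fit, "insider_fit"))
  block_name <- get_block(fit, block_name)
  B <- fit$factors[[block_name]]
  v <- apply(B, 2, stats::var)
  tab <- tibble::tibble(metagene = seq_along(v), variance = v)
  tab[order(-tab$variance, tab$metagene), ]
}

#' Metagene subset after excluding the least variable ones
#'
#' @inheritParams adjusted_expression
#' @param n_exclude how many of the lowest-variance metagenes (for this
#'   block) to drop.
#' @return integer vector of kept metagene indices, ascending.
#' @export
exclude_low_variance_metagenes <- function(fit, block_name, n_exclude) {
  stopifnot(inherits(fit, "insider_fit"))
  K <- fit$hyperparams$K
  n_exclude <- as.integer(n_exclude)
  if (n_exclude < 0L || n_exclude > K) {
    stop(sprintf("`n_exclude` must be in 0..%d.", K), call. = FALSE)
  }
  rk <- metagene_variance_ranking(fit, block_name)
  dropped <- utils::tail(rk$metagene, n_exclude)
  sort(setdiff(seq_len(K), dropped))
}

resolve_level <- function(block, level) {
  if (is.character(level)) {
    i <- match(level, block$level_ids)
    if (is.na(i)) {
      stop(sprintf("level '%s' not found in block '%s'.", level, block$name),
           call. = FALSE)
    }
    return(i)
  }
  i <- as.integer(level)
  if (i < 1L || i > n_levels(block)) {
    stop(sprintf("level index %d out of range for block '%s'.", i,
                 block$name), call. = FALSE)
  }
  i
}

#' Gene expression profile of one interaction level
#'
#' Multiplies the interaction factor row for one (e.g. phenotype, tissue)
#' combination by the gene loadings, optionally restricted to a metagene
#' subset — the expression attributable to that specific combination.
#'
#' @inheritParams adjusted_expression
#' @param level level id (e.g. `"diseased:tissue_3"`) or index into the
#'   block's levels.
#' @param block_name the interaction block; defaults to the first block of
#'   kind `"interaction"`.
#' @return named numeric vector over genes.
#' @export
interaction_profile <- function(fit, level, block_name = NULL,
                                metagenes = NULL) {
  stopifnot(inherits(fit, "insider_fit"))
  if (is.null(block_name)) {
    kinds <- vapply(fit$blocks, function(b) b$kind, "")
    idx <- which(kinds == "interaction")
    if (length(idx) == 0) stop("fit has no interaction block.", call. = FALSE)
    block_name <- names(fit$blocks)[idx[1]]
  }
  block_name <- get_block(fit, block_name)
  i <- resolve_level(fit$blocks[[block_name]], level)
  adj <- adjusted_expression(fit, block_name, metagenes)
  stats::setNames(adj[i, ], fit$gene_ids)
}

#' Contrast profile between two levels of a covariate
#'
#' The difference of adjusted expression between two levels of a block
#' (e.g. dementia minus control), `(B[a, S] - B[b, S]) V[S, ]`, optionally
#' over a selected metagene subset.
#'
#' @inheritParams adjusted_expression
#' @param level_a,level_b level ids or indices; the profile is
#'   `level_a - level_b`.
#' @return named numeric vector over genes.
#' @export
contrast_profile <- function(fit, block_name, level_a, level_b,
                             metagenes = NULL) {
  stopifnot(inherits(fit, "insider_fit"))
  block_name <- get_block(fit, block_name)
  block <- fit$blocks[[block_name]]
  ia <- resolve_level(block, level_a)
  ib <- resolve_level(block, level_b)
  adj <- adjusted_expression(fit, block_name, metagenes)
  stats::setNames(adj[ia, ] - adj[ib, ], fit$gene_ids)
}

#' Upper and lower quantile gene sets of a profile
#'
#' Extracts the genes in the upper and lower `q` tails of a profile (by
#' default the 2.5% tails), e.g. for external enrichment analysis. Set
#' sizes are `ceiling(q * M)` (capped so the two sets stay disjoint); ties
#' are broken by gene order.
#'
#' @param profile numeric vector over genes (named, or names taken from
#'   `gene_ids`).
#' @param q tail fraction, in (0, 0.5); default 0.025.
#' @param gene_ids optional gene labels.
#' @return list with character vectors `upper` and `lower`.
#' @export
quantile_gene_sets <- function(profile, q = 0.025, gene_ids = NULL) {
  if (!is.numeric(q) || q <= 0 || q >= 0.5) {
    stop("`q` must be in (0, 0.5).", call. = FALSE)
  }
  profile <- drop(as.matrix(profile))
  m <- length(profile)
  if (is.null(gene_ids)) gene_ids <- names(profile)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(m))
  n_tail <- min(ceiling(q * m), floor(m / 2))
  lower_ord <- order(profile, seq_len(m))
  upper_ord <- order(-profile, seq_len(m))
  lower_idx <- lower_ord[seq_len(n_tail)]
  # keep the sets disjoint even under whole-profile ties
  upper_pool <- setdiff(upper_ord, lower_idx)
  upper_idx <- upper_pool[seq_len(n_tail)]
  list(upper = gene_ids[sort(upper_idx)],
       lower = gene_ids[sort(lower_idx)])
}
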