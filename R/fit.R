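## Alternating block coordinate descent:
##  - every covariate block has a closed-form ridge update per level, with
##    masked normal equations (per-sample observation patterns are exact);
##  - each gene's loading column solves an elastic-net subproblem by
##    randomized coordinate descent with screening, warm-started;
##  - stop on relative objective change < tol (tested from iteration 2 on).

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## bookkeeping derived from the mask, computed once per fit
mask_info <- function(data) {
  mask <- data$mask
  Z0 <- data$values
  Z0[!mask] <- 0
  has_missing <- !all(mask)
  list(
    Z0 = Z0,
    mask = mask,
    has_missing = has_missing,
    miss_lin = if (has_missing) which(!mask) else integer(0),
    miss_by_row = if (has_missing)
      lapply(seq_len(nrow(mask)), function(s) which(!mask[s, ])) else NULL,
    miss_by_col = if (has_missing)
      lapply(seq_len(ncol(mask)), function(m) which(!mask[, m])) else NULL,
    row_obs = rowSums(mask),
    col_obs = colSums(mask)
  )
}

## per-sample Gram corrections C_s = V[, miss_s] V[, miss_s]^T for samples
## with unobserved genes; NULL when data are complete
gram_corrections <- function(V, mi) {
  if (!mi$has_missing) return(NULL)
  lapply(mi$miss_by_row, function(ms) {
    if (length(ms) == 0) NULL else tcrossprod(V[, ms, drop = FALSE])
  })
}

solve_ridge <- function(G, rhs, lambda, what) {
  K <- nrow(G)
  out <- tryCatch(
    solve(G + diag(lambda, K), rhs),
    error = function(e) {
      stop(sprintf(paste0(
        "singular ridge system in %s; set lambda > 0 ",
        "(e.g. 0.1) to avoid singularity in matrix inverse."), what),
        call. = FALSE)
    })
  out
}

## Closed-form ridge update for one categorical / interaction / observation
## block. `Zt` is the residual target with this block's contribution removed
## and masked entries zeroed. Levels with zero observed entries keep their
## previous rows (flagged via attribute "skipped").
update_block_closed <- function(block, Zt, V, VVt, corr, lambda, B_prev,
                                row_obs) {
  K <- nrow(V)
  RHS_all <- tcrossprod(V, Zt)                     # K x N
  idx <- block$idx
  L <- n_levels(block)
  counts <- tabulate(idx, nbins = L)
  rhs <- matrix(0, L, K)
  rs <- rowsum(t(RHS_all), group = idx)
  rhs[sort(unique(idx)), ] <- rs
  obs_lev <- rep(0, L)
  ol <- rowsum(row_obs, group = idx)
  obs_lev[sort(unique(idx))] <- ol

  corr_lev <- NULL
  if (!is.null(corr)) {
    corr_lev <- vector("list", L)
    for (s in seq_along(idx)) {
      Cs <- corr[[s]]
      if (!is.null(Cs)) {
        j <- idx[s]
        corr_lev[[j]] <- if (is.null(corr_lev[[j]])) Cs else corr_lev[[j]] + Cs
      }
    }
  }

  B <- B_prev
  skipped <- integer(0)
  for (j in seq_len(L)) {
    if (obs_lev[j] == 0) {           # empty level or fully masked samples
      skipped <- c(skipped, j)
      next
    }
    G <- counts[j] * VVt
    if (!is.null(corr_lev) && !is.null(corr_lev[[j]])) G <- G - corr_lev[[j]]
    B[j, ] <- solve_ridge(G, rhs[j, ], lambda,
                          sprintf("block '%s' level %d", block$name, j))
  }
  attr(B, "skipped") <- skipped
  B
}

## Closed-form ridge update for a continuous covariate's 1 x K factor row.
update_block_continuous <- function(block, Zt, V, VVt, corr, lambda, B_prev) {
  x <- block$x
  rhs <- drop(V %*% crossprod(Zt, x))
  G <- sum(x^2) * VVt
  if (!is.null(corr)) {
    for (s in seq_along(x)) {
      if (!is.null(corr[[s]]) && x[s] != 0) G <- G - x[s]^2 * corr[[s]]
    }
  }
  q <- solve_ridge(G, rhs, lambda, sprintf("continuous block '%s'", block$name))
  matrix(q, 1, nrow(V))
}

## Screening rule for one gene's elastic-net subproblem: discard component j
## when |e_j^T z_m| < alpha (2 lambda - lambda_max), lambda_max = max_j
## |e_j^T z_m|. Strict inequality; vacuous when the threshold is <= 0.
## `b` is the correlation vector E_obs^T z_obs.
screen_gene <- function(b, lambda, alpha) {
  ab <- abs(b)
  lambda_max <- max(ab)
  thr <- alpha * (2 * lambda - lambda_max)
  discarded <- if (thr > 0) which(ab < thr) else integer(0)
  list(discarded = discarded, lambda_max = lambda_max)
}

## Randomized coordinate descent on 1/2 v'Av - b'v + l2/2 |v|^2 + l1 |v|_1
## over the `active` coordinates, to KKT tolerance. The inner loop is
## compiled (src/cd_enet.cpp) with a self-contained PRNG, so solves are
## deterministic given `seed` and independent of R's RNG state.
cd_enet <- function(A, b, l1, l2, v, active, seed = 1, kkt_tol = 1e-8,
                    max_sweep = 10000L) {
  if (length(active) == 0) return(v)
  .cd_enet_cpp(A, b, l1, l2, v, as.integer(active), as.numeric(seed),
               kkt_tol, as.integer(max_sweep))
}

## Solve all M elastic-net columns of V given the combined predictor E.
## With alpha = 0 and complete data this is one closed-form ridge solve.
update_loadings <- function(E, Z0, mi, lambda_v, alpha, V_prev, base_seed,
                            kkt_tol = 1e-8, collect_screening = FALSE) {
  K <- ncol(E)
  M <- ncol(Z0)
  if (!mi$has_missing && alpha == 0) {
    A <- crossprod(E) + diag(lambda_v, K)
    V <- tryCatch(solve(A, crossprod(E, Z0)), error = function(e)
      stop("singular ridge system in loading update; set lambda > 0.",
           call. = FALSE))
    return(list(V = V, screening = NULL))
  }
  EtE <- crossprod(E)
  EtZ <- crossprod(E, Z0)
  if (!collect_screening) {
    V <- .update_loadings_cpp(E, EtE, EtZ,
                              if (mi$has_missing) mi$miss_by_col else NULL,
                              as.integer(mi$col_obs), lambda_v, alpha,
                              V_prev, as.numeric(base_seed), kkt_tol,
                              10000L)
    return(list(V = V, screening = NULL))
  }
  V <- V_prev
  l1 <- lambda_v * alpha
  l2 <- lambda_v * (1 - alpha)
  reports <- vector("list", M)
  for (m in seq_len(M)) {
    if (mi$col_obs[m] == 0) {            # no observed entries for this gene
      V[, m] <- 0
      next
    }
    A <- EtE
    if (mi$has_missing) {
      ms <- mi$miss_by_col[[m]]
      if (length(ms)) A <- A - crossprod(E[ms, , drop = FALSE])
    }
    b <- EtZ[, m]
    if (alpha == 0) {
      V[, m] <- tryCatch(solve(A + diag(lambda_v, K), b), error = function(e)
        stop(sprintf("singular ridge system for gene %d; set lambda > 0.", m),
             call. = FALSE))
      next
    }
    scr <- screen_gene(b, lambda_v, alpha)
    active <- setdiff(seq_len(K), scr$discarded)
    v <- V[, m]
    v[scr$discarded] <- 0
    gene_seed <- (base_seed + 104729 * m) %% 2147483629
    v <- cd_enet(A, b, l1, l2, v, active, seed = gene_seed,
                 kkt_tol = kkt_tol)
    if (length(scr$discarded)) {
      # safety check: the screening rule is not provably safe, so verify the
      # KKT conditions of the discarded set and fall back to the full solve
      g <- b - drop(A %*% v)
      if (any(abs(g[scr$discarded]) > l1 + kkt_tol)) {
        v <- cd_enet(A, b, l1, l2, v, seq_len(K), seed = gene_seed + 1,
                     kkt_tol = kkt_tol)
        scr$discarded <- integer(0)
      }
    }
    V[, m] <- v
    if (collect_screening) {
      reports[[m]] <- list(gene_index = m, discarded = scr$discarded,
                           lambda_max = scr$lambda_max)
    }
  }
  list(V = V, screening = reports)
}

#' Fit the covariate-aware sparse factorization
#'
#' Decomposes an expression matrix into per-covariate latent blocks sharing
#' one gene-loading matrix: \eqn{\hat Z = (\sum_b X_b B_b) V}, minimizing
#' the squared error over observed entries plus a ridge penalty
#' (`lambda`) on every factor block and an elastic-net penalty (`lambda_v`,
#' `alpha`) on the loadings. Optimization is alternating block coordinate
#' descent: each block row has an exact masked ridge update; each loading
#' column is solved by randomized coordinate descent with safe screening
#' (closed form when `alpha = 0`). Iterations stop when the relative change
#' of the objective falls below `tol` or at `max_iter`.
#'
#' @param data an `expression_matrix`, or a numeric matrix with `NA`
#'   marking missing entries.
#' @param design a list of [covariate_block()]s (see [covariate_blocks()]).
#' @param K latent rank: the number of metagenes.
#' @param lambda ridge penalty on all factor blocks (default 0.1; small
#'   positive values also guard the matrix inverses).
#' @param alpha elastic-net mixing for the gene loadings, in \[0, 1\]
#'   (0 = ridge, 1 = lasso).
#' @param lambda_v penalty weight on the gene loadings; defaults to
#'   `lambda`.
#' @param tol relative-change stopping threshold on the objective
#'   (default 1e-10).
#' @param max_iter iteration cap.
#' @param seed integer seed controlling initialization and the coordinate
#'   descent order; fits are deterministic given the seed.
#' @param init_sd standard deviation of the N(0, `init_sd`) initialization.
#' @param verbose print the objective each iteration.
#'
#' @return An object of class `insider_fit`: a list with `blocks` (the
#'   design), `factors` (named list of levels x K matrices), `loadings`
#'   (K x genes), `hyperparams`, `loss_trace`, `n_iter`, `converged`,
#'   `mask` (the training mask), and `empty_levels` (per block, level
#'   indices that had no observed samples and were never updated).
#' @seealso [reconstruct()], [insider_objective()], [tune_insider()],
#'   [adjusted_expression()]
#' @export
#' @examples
#' sim <- simulate_linear_design(noise = 0.25, seed = 1)
#' fit <- insider(sim$Z, sim$design, K = 10, lambda = 0.1, max_iter = 20)
#' rmse(reconstruct(fit), sim$truth)
insider <- function(data, design, K,
                    lambda = 0.1, alpha = 0, lambda_v = lambda,
                    tol = 1e-10, max_iter = 500L, seed = 1L,
                    init_sd = 0.001, verbose = FALSE) {
  data <- as_expression_matrix(data)
  if (inherits(design, "covariate_block")) design <- list(design)
  if (length(design) == 0) stop("empty design: at least one covariate block.",
                                call. = FALSE)
  nms <- vapply(design, function(b) b$name, "")
  if (anyDuplicated(nms)) stop("covariate block names must be unique.",
                               call. = FALSE)
  names(design) <- nms
  N <- nrow(data$values); M <- ncol(data$values)
  for (b in design) {
    if (b$n != N) {
      stop(sprintf("block '%s' has %d rows but the data has %d samples.",
                   b$name, b$n, N), call. = FALSE)
    }
  }
  stopifnot(K >= 1, lambda >= 0, lambda_v >= 0, alpha >= 0, alpha <= 1,
            tol > 0, max_iter >= 1)
  K <- as.integer(K)

  ## update order: categorical/interaction blocks as declared, then
  ## per-sample observation blocks, then continuous, then the loadings
  kinds <- vapply(design, function(b) b$kind, "")
  order_idx <- c(which(kinds %in% c("categorical", "interaction")),
                 which(kinds == "observation"),
                 which(kinds == "continuous"))

  set.seed(seed)
  factors <- lapply(design, function(b)
    matrix(stats::rnorm(n_levels(b) * K, 0, init_sd), n_levels(b), K))
  V <- matrix(stats::rnorm(K * M, 0, init_sd), K, M)

  mi <- mask_info(data)
  Z0 <- mi$Z0
  E_total <- predictor_matrix(design, factors, K)
  loss_trace <- numeric(0)
  skipped <- lapply(design, function(b) integer(0))
  penalty_const <- function() {
    0.5 * lambda * sum(vapply(factors, function(B) sum(B^2), 0)) +
      lambda_v * (0.5 * (1 - alpha) * sum(V^2) + alpha * sum(abs(V)))
  }

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    VVt <- tcrossprod(V)
    corr <- gram_corrections(V, mi)

    for (bi in order_idx) {
      block <- design[[bi]]
      contrib <- block_contribution(block, factors[[bi]])
      A <- E_total - contrib
      Zt <- Z0 - A %*% V
      if (mi$has_missing) Zt[mi$miss_lin] <- 0
      if (block$kind == "continuous") {
        B_new <- update_block_continuous(block, Zt, V, VVt, corr, lambda,
                                         factors[[bi]])
      } else {
        B_new <- update_block_closed(block, Zt, V, VVt, corr, lambda,
                                     factors[[bi]], mi$row_obs)
        skipped[[bi]] <- attr(B_new, "skipped")
        attr(B_new, "skipped") <- NULL
      }
      factors[[bi]] <- B_new
      E_total <- A + block_contribution(block, B_new)
    }

    up <- update_loadings(E_total, Z0, mi, lambda_v, alpha, V,
                          base_seed = seed + iter)
    V <- up$V

    resid <- Z0 - E_total %*% V
    if (mi$has_missing) resid[mi$miss_lin] <- 0
    loss <- 0.5 * sum(resid^2) + penalty_const()
    if (!is.finite(loss)) {
      stop(sprintf("non-finite objective at iteration %d.", iter),
           call. = FALSE)
    }
    loss_trace <- c(loss_trace, loss)
    if (verbose) {
      message(sprintf("iter %4d  objective %.8g", iter, loss))
    }
    if (iter >= 2) {
      prev <- loss_trace[iter - 1L]
      rel <- abs(loss - prev) / max(abs(prev), .Machine$double.eps)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }

  structure(
    list(blocks = design, factors = factors, loadings = V,
         hyperparams = list(K = K, lambda = lambda, alpha = alpha,
                            lambda_v = lambda_v, tol = tol,
                            max_iter = as.integer(max_iter),
                            seed = as.integer(seed), init_sd = init_sd),
         loss_trace = loss_trace, n_iter = iter, converged = converged,
         mask = data$mask, empty_levels = skipped,
         sample_ids = data$sample_ids, gene_ids = data$gene_ids),
    class = "insider_fit"
  )
}

#' @export
print.insider_fit <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "<insider_fit> K = %d, lambda = %g, alpha = %g, %d iteration(s)%s\n",
    hp$K, hp$lambda, hp$alpha, x$n_iter,
    if (x$converged) " (converged)" else ""))
  cat(sprintf("  blocks: %s\n", paste(names(x$blocks), collapse = ", ")))
  cat(sprintf("  %d samples x %d genes, final objective %.6g\n",
              length(x$sample_ids), length(x$gene_ids),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Root mean squared error on held-out entries
#'
#' Scores a fit on entries that were withheld from training: the square
#' root of the mean squared difference between the data and the model
#' reconstruction over the `holdout_mask` entries.
#'
#' @param fit an `insider_fit`.
#' @param data the `expression_matrix` holding the held-out values.
#' @param holdout_mask logical matrix selecting the held-out entries; must
#'   be disjoint from the mask the model was trained on.
#' @return non-negative number.
#' @export
holdout_rmse <- function(fit, data, holdout_mask) {
  stopifnot(inherits(fit, "insider_fit"))
  data <- as_expression_matrix(data)
  if (!identical(dim(holdout_mask), dim(data$values))) {
    stop("holdout mask shape mismatch.", call. = FALSE)
  }
  if (sum(holdout_mask) == 0) stop("empty holdout set.", call. = FALSE)
  if (any(holdout_mask & fit$mask)) {
    stop("holdout mask overlaps the training mask.", call. = FALSE)
  }
  Zhat <- reconstruct(fit)
  rmse(data$values, Zhat, mask = holdout_mask)
}
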