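## Hyperparameter selection protocol: hold out a fraction of observed
## entries, pick the rank K on a grid with short ridge-only runs, then pick
## {lambda, alpha} on a grid, optionally refit on all observed entries.

#' Split observed entries into train and test masks
#'
#' Randomly draws `fraction` of the observed entries (without replacement)
#' as a held-out test set; the rest form the training mask.
#'
#' @param data an `expression_matrix` (or matrix with `NA` = missing).
#' @param fraction fraction of observed entries to hold out, in (0, 1).
#' @param seed integer seed; the split is a pure function of
#'   (data, fraction, seed).
#' @return list with logical matrices `train_mask` and `test_mask`
#'   (disjoint; union = observed mask).
#' @export
split_holdout <- function(data, fraction = 0.1, seed = 1L) {
  data <- as_expression_matrix(data)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1).", call. = FALSE)
  }
  obs <- which(data$mask)
  n_test <- round(fraction * length(obs))
  if (n_test < 1) stop("holdout fraction selects no entries.", call. = FALSE)
  set.seed(seed)
  test_idx <- sample(obs, n_test)
  test_mask <- matrix(FALSE, nrow(data$values), ncol(data$values))
  test_mask[test_idx] <- TRUE
  train_mask <- data$mask & !test_mask
  if (any(rowSums(train_mask) == 0) || any(colSums(train_mask) == 0)) {
    warning("holdout split left a sample or gene with no training entries.",
            call. = FALSE)
  }
  list(train_mask = train_mask, test_mask = test_mask)
}

tuning_run_rmse <- function(data, design, split, K, lambda, alpha,
                            tune_iter, seed) {
  train <- expression_matrix(data$values, mask = split$train_mask,
                             sample_ids = data$sample_ids,
                             gene_ids = data$gene_ids)
  fit <- insider(train, design, K = K, lambda = lambda, alpha = alpha,
                 max_iter = tune_iter, seed = seed)
  holdout_rmse(fit, data, split$test_mask)
}

#' Select the latent rank on a grid by held-out RMSE
#'
#' For each candidate rank, runs a short ridge-only fit (`alpha = 0`,
#' `lambda = 0.1`, `tune_iter` iterations) on the training entries and
#' scores RMSE on the held-out entries; returns the rank with the lowest
#' test RMSE, ties broken toward the smaller rank.
#'
#' @param data an `expression_matrix`.
#' @param design list of covariate blocks.
#' @param k_grid candidate ranks (default 10 to 30 by 2).
#' @param fraction holdout fraction of observed entries.
#' @param tune_iter iterations per tuning run (default 30).
#' @param lambda,alpha penalties used during rank selection (defaults 0.1
#'   and 0).
#' @param seed seed for the split and the tuning fits.
#' @param split optional precomputed split from [split_holdout()].
#' @return list with `K` (selected rank) and `rmse` (tibble of K, rmse).
#' @export
select_rank <- function(data, design, k_grid = seq(10, 30, by = 2),
                        fraction = 0.1, tune_iter = 30L,
                        lambda = 0.1, alpha = 0, seed = 1L, split = NULL) {
  data <- as_expression_matrix(data)
  if (length(k_grid) == 0) stop("empty rank grid.", call. = FALSE)
  if (is.null(split)) split <- split_holdout(data, fraction, seed)
  rmses <- vapply(k_grid, function(K)
    tuning_run_rmse(data, design, split, K, lambda, alpha, tune_iter, seed),
    0)
  tab <- tibble::tibble(K = as.integer(k_grid), rmse = rmses)
  best <- tab$K[tab$rmse == min(tab$rmse)]
  list(K = min(best), rmse = tab, split = split)
}

#' Select the regularization pair on a grid by held-out RMSE
#'
#' Fixes the rank and evaluates every `{lambda, alpha}` combination with a
#' short fit on the training entries; returns the pair with the lowest
#' test RMSE, ties broken toward stronger regularization (larger `lambda`,
#' then larger `alpha`).
#'
#' @inheritParams select_rank
#' @param K the (already selected) latent rank.
#' @param lambda_grid,alpha_grid candidate penalty values.
#' @return list with `lambda`, `alpha`, and `rmse` (tibble over the grid).
#' @export
select_regularization <- function(data, design, K,
                                  lambda_grid = c(0.1, 1, 10, 100),
                                  alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                                  fraction = 0.1, tune_iter = 30L,
                                  seed = 1L, split = NULL) {
  data <- as_expression_matrix(data)
  if (length(lambda_grid) == 0 || length(alpha_grid) == 0) {
    stop("empty regularization grid.", call. = FALSE)
  }
  if (is.null(split)) split <- split_holdout(data, fraction, seed)
  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rmses <- vapply(seq_len(nrow(grid)), function(i)
    tuning_run_rmse(data, design, split, K, grid$lambda[i], grid$alpha[i],
                    tune_iter, seed), 0)
  tab <- tibble::tibble(lambda = grid$lambda, alpha = grid$alpha,
                        rmse = rmses)
  best <- tab[tab$rmse == min(tab$rmse), ]
  best <- best[order(-best$lambda, -best$alpha), ][1, ]
  list(lambda = best$lambda, alpha = best$alpha, rmse = tab, split = split)
}

#' Full hyperparameter selection and final fit
#'
#' Runs the two-stage protocol on one shared holdout split: rank selection
#' on `k_grid` (short ridge-only runs), then `{lambda, alpha}` selection at
#' the chosen rank, then (optionally) a full fit at the selected
#' hyperparameters on all observed entries.
#'
#' @inheritParams select_rank
#' @param lambda_grid,alpha_grid grids for the second stage.
#' @param refit fit at the selected hyperparameters on train + holdout
#'   (all observed entries) and return the fit (default `TRUE`).
#' @param max_iter,tol passed to the final fit.
#' @return list of class `insider_tune` with `K`, `lambda`, `alpha`, the
#'   two RMSE tables (`rank_rmse`, `reg_rmse`), the `split`, and (when
#'   `refit`) the final `fit`.
#' @export
tune_insider <- function(data, design, k_grid = seq(10, 30, by = 2),
                         lambda_grid = c(0.1, 1, 10, 100),
                         alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                         fraction = 0.1, tune_iter = 30L, seed = 1L,
                         refit = TRUE, max_iter = 500L, tol = 1e-10) {
  data <- as_expression_matrix(data)
  split <- split_holdout(data, fraction, seed)
  rk <- select_rank(data, design, k_grid, fraction, tune_iter,
                    seed = seed, split = split)
  rg <- select_regularization(data, design, rk$K, lambda_grid, alpha_grid,
                              fraction, tune_iter, seed = seed, split = split)
  out <- list(K = rk$K, lambda = rg$lambda, alpha = rg$alpha,
              rank_rmse = rk$rmse, reg_rmse = rg$rmse, split = split,
              seed = seed)
  if (refit) {
    out$fit <- insider(data, design, K = rk$K, lambda = rg$lambda,
                       alpha = rg$alpha, max_iter = max_iter, tol = tol,
                       seed = seed)
  }
  structure(out, class = "insider_tune")
}

#' @export
print.insider_tune <- function(x, ...) {
  cat(sprintf("<insider_tune> selected K = %d, lambda = %g, alpha = %g\n",
              x$K, x$lambda, x$alpha))
  invisible(x)
}
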