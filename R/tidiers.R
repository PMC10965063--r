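#' Tidy a fitted factorization into a long tibble
#'
#' With `what = "factors"`, one row per (block, level, metagene) giving
#' the latent factor value; with `what = "loadings"`, one row per
#' (metagene, gene) giving the gene loading.
#'
#' @param x an `insider_fit`.
#' @param what `"factors"` or `"loadings"`.
#' @param block optional block name(s) to restrict `"factors"` output.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.insider_fit <- function(x, what = c("factors", "loadings"),
                             block = NULL, ...) {
  what <- match.arg(what)
  if (what == "loadings") {
    V <- x$loadings
    return(tibble::tibble(
      metagene = rep(seq_len(nrow(V)), times = ncol(V)),
      gene = rep(x$gene_ids, each = nrow(V)),
      loading = as.vector(V)))
  }
  blocks <- if (is.null(block)) names(x$blocks) else block
  out <- lapply(blocks, function(nm) {
    nm <- get_block(x, nm)
    B <- x$factors[[nm]]
    tibble::tibble(
      block = nm,
      level = rep(x$blocks[[nm]]$level_ids, times = ncol(B)),
      metagene = rep(seq_len(ncol(B)), each = nrow(B)),
      value = as.vector(B))
  })
  dplyr::bind_rows(out)
}

#' One-row summary of a fitted factorization
#'
#' @param x an `insider_fit`.
#' @param ... unused.
#' @return tibble with the hyperparameters, iteration count, convergence
#'   flag, and final objective value.
#' @export
glance.insider_fit <- function(x, ...) {
  tibble::tibble(
    K = x$hyperparams$K,
    lambda = x$hyperparams$lambda,
    alpha = x$hyperparams$alpha,
    lambda_v = x$hyperparams$lambda_v,
    n_iter = x$n_iter,
    converged = x$converged,
    objective = utils::tail(x$loss_trace, 1)
  )
}

#' Plot the objective trace of a fit
#'
#' @param object an `insider_fit`.
#' @param ... unused.
#' @return a ggplot of objective vs iteration (log10 y scale).
#' @export
autoplot.insider_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss_trace),
                       objective = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "penalized objective",
                  title = "Block coordinate descent objective trace") +
    ggplot2::theme_minimal()
}

#' Plot held-out RMSE over the tuning grids
#'
#' @param object an `insider_tune` from [tune_insider()].
#' @param ... unused.
#' @return a ggplot: test RMSE vs rank, and a tile panel over the
#'   regularization grid.
#' @export
autoplot.insider_tune <- function(object, ...) {
  df <- object$rank_rmse
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K, linetype = "dashed") +
    ggplot2::labs(x = "rank K", y = "held-out RMSE",
                  title = "Rank selection by held-out entry RMSE") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
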