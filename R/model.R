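## Model core: reconstruction Zhat = (sum_b X_b B_b) V and the penalized
## squared-error objective over observed entries.

## combined predictor matrix E = sum_b X_b B_b (N x K)
predictor_matrix <- function(blocks, factors, K = NULL) {
  stopifnot(length(blocks) > 0)
  n <- blocks[[1]]$n
  if (is.null(K)) K <- ncol(factors[[1]])
  E <- matrix(0, n, K)
  for (nm in names(blocks)) {
    B <- factors[[nm]]
    if (is.null(B)) stop(sprintf("no factor matrix for block '%s'.", nm),
                         call. = FALSE)
    if (ncol(B) != K) {
      stop(sprintf("block '%s': factor matrix has %d columns, expected K = %d.",
                   nm, ncol(B), K), call. = FALSE)
    }
    Lb <- n_levels(blocks[[nm]])
    if (nrow(B) != Lb) {
      stop(sprintf("block '%s': factor matrix has %d rows, expected %d levels.",
                   nm, nrow(B), Lb), call. = FALSE)
    }
    E <- E + block_contribution(blocks[[nm]], B)
  }
  E
}

#' Reconstruct the model's fitted expression matrix
#'
#' Returns the full low-rank reconstruction
#' \eqn{\hat Z = (\sum_b X_b B_b) V}: every covariate block's design matrix
#' times its factor matrix, summed, times the shared gene loadings. The
#' full matrix is returned regardless of which entries were observed.
#'
#' @param fit an `insider_fit` from [insider()].
#' @return numeric matrix, samples x genes.
#' @export
reconstruct <- function(fit) {
  stopifnot(inherits(fit, "insider_fit"))
  E <- predictor_matrix(fit$blocks, fit$factors, K = fit$hyperparams$K)
  out <- E %*% fit$loadings
  dimnames(out) <- list(fit$sample_ids, fit$gene_ids)
  out
}

#' @export
fitted.insider_fit <- function(object, ...) reconstruct(object)

#' Penalized objective of a fit on a data matrix
#'
#' Computes
#' \deqn{\tfrac12 \sum_{(s,m)\,\mathrm{observed}} (z_{sm}-\hat z_{sm})^2
#'   + \tfrac{\lambda}{2} \sum_b \|B_b\|_F^2
#'   + \lambda_1\big(\tfrac{1-\alpha}{2}\|V\|_F^2 + \alpha\,|V|_1\big),}
#' the loss minimized by [insider()]. Only mask-true entries enter the data
#' term; every factor block (including a per-sample block) is ridge
#' penalized with weight `lambda`, and the gene loadings carry the
#' elastic-net penalty with weight `lambda_v` and mixing `alpha`.
#'
#' @param fit an `insider_fit`.
#' @param data an `expression_matrix` (or matrix with `NA` = missing).
#' @return a single non-negative number.
#' @export
insider_objective <- function(fit, data) {
  stopifnot(inherits(fit, "insider_fit"))
  data <- as_expression_matrix(data)
  hp <- fit$hyperparams
  Zhat <- reconstruct(fit)
  if (!identical(dim(Zhat), dim(data$values))) {
    stop("data dimensions do not match the fit.", call. = FALSE)
  }
  resid <- data$values - Zhat
  resid[!data$mask] <- 0
  data_term <- 0.5 * sum(resid^2)
  ridge_term <- 0.5 * hp$lambda * sum(vapply(fit$factors,
                                             function(B) sum(B^2), 0))
  V <- fit$loadings
  enet_term <- hp$lambda_v *
    (0.5 * (1 - hp$alpha) * sum(V^2) + hp$alpha * sum(abs(V)))
  data_term + ridge_term + enet_term
}

## root mean squared difference, optionally over a mask
#' Root mean squared error between two matrices
#'
#' @param a,b numeric matrices of identical shape (or a scalar for `a`).
#' @param mask optional logical matrix selecting the entries to score;
#'   default scores all entries.
#' @return the RMSE, a non-negative number.
#' @export
rmse <- function(a, b, mask = NULL) {
  if (length(a) == 1) a <- matrix(a, nrow(b), ncol(b))
  if (!identical(dim(a), dim(b))) stop("shape mismatch in rmse().",
                                       call. = FALSE)
  d <- a - b
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(b))) stop("mask shape mismatch in rmse().",
                                            call. = FALSE)
    d <- d[mask]
    if (length(d) == 0) stop("mask selects no entries.", call. = FALSE)
  }
  sqrt(mean(d^2))
}
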