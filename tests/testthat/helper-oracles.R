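# Independent oracles: scalar-loop implementations of the model equations
# and a proximal-gradient elastic-net solver, kept deliberately naive so
# they share no code path with the package internals.

# elementwise-loop reconstruction: zhat[s, m] = sum_b (B_b row for s) . v_m
loop_reconstruct <- function(blocks, factors, V) {
  n <- blocks[[1]]$n
  m <- ncol(V)
  out <- matrix(0, n, m)
  for (s in seq_len(n)) {
    for (g in seq_len(m)) {
      acc <- 0
      for (nm in names(blocks)) {
        b <- blocks[[nm]]
        row <- if (b$kind == "continuous") {
          b$x[s] * factors[[nm]][1, ]
        } else {
          factors[[nm]][b$idx[s], ]
        }
        acc <- acc + sum(row * V[, g])
      }
      out[s, g] <- acc
    }
  }
  out
}

# triple-loop penalized objective
loop_objective <- function(blocks, factors, V, Z, mask, lambda, lambda_v,
                           alpha) {
  zhat <- loop_reconstruct(blocks, factors, V)
  data_term <- 0
  for (s in seq_len(nrow(Z))) {
    for (g in seq_len(ncol(Z))) {
      if (mask[s, g]) data_term <- data_term + (Z[s, g] - zhat[s, g])^2
    }
  }
  ridge <- 0
  for (B in factors) ridge <- ridge + sum(B^2)
  0.5 * data_term + 0.5 * lambda * ridge +
    lambda_v * (0.5 * (1 - alpha) * sum(V^2) + alpha * sum(abs(V)))
}

# proximal gradient (ISTA) on 1/2||z - E v||^2 + l2/2||v||^2 + l1|v|_1,
# run to tight convergence; independent of the package's CD solver
prox_enet <- function(E, z, l1, l2, max_iter = 200000, tol = 1e-12) {
  K <- ncol(E)
  v <- rep(0, K)
  A <- crossprod(E)
  b <- crossprod(E, z)
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values) + l2 + 1e-12
  for (i in seq_len(max_iter)) {
    g <- drop(A %*% v) - b + l2 * v
    u <- v - g / L
    v_new <- sign(u) * pmax(abs(u) - l1 / L, 0)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v
}

enet_objective <- function(E, z, l1, l2, v) {
  0.5 * sum((z - E %*% v)^2) + 0.5 * l2 * sum(v^2) + l1 * sum(abs(v))
}

# per-level masked ridge oracle: stack the observed entries of the level's
# rows into one long least-squares problem in the K loading coefficients
level_ridge_oracle <- function(rows, Zt, mask, V, lambda) {
  X <- NULL
  y <- NULL
  for (s in rows) {
    obs <- which(mask[s, ])
    X <- rbind(X, t(V[, obs, drop = FALSE]))
    y <- c(y, Zt[s, obs])
  }
  drop(solve(crossprod(X) + diag(lambda, nrow(V)), crossprod(X, y)))
}

# build a small random fit object directly (no optimization involved)
make_fit <- function(blocks, factors, V, lambda = 0.1, alpha = 0,
                     lambda_v = lambda, mask = NULL) {
  n <- blocks[[1]]$n
  m <- ncol(V)
  structure(
    list(blocks = blocks, factors = factors, loadings = V,
         hyperparams = list(K = ncol(factors[[1]]), lambda = lambda,
                            alpha = alpha, lambda_v = lambda_v,
                            tol = 1e-10, max_iter = 1L, seed = 1L,
                            init_sd = 0.001),
         loss_trace = numeric(0), n_iter = 0L, converged = FALSE,
         mask = if (is.null(mask)) matrix(TRUE, n, m) else mask,
         empty_levels = lapply(blocks, function(b) integer(0)),
         sample_ids = paste0("sample_", seq_len(n)),
         gene_ids = paste0("gene_", seq_len(m))),
    class = "insider_fit"
  )
}

# small random design: two categorical blocks over n samples
random_blocks <- function(n, l1 = 3, l2n = 2) {
  list(
    A = block_from_index_test("A", rep_len(seq_len(l1), n),
                              paste0("a", seq_len(l1))),
    B = block_from_index_test("B", rep_len(seq_len(l2n), n),
                              paste0("b", seq_len(l2n)))
  )
}

block_from_index_test <- function(name, idx, level_ids,
                                  kind = "categorical") {
  L <- length(level_ids)
  d <- matrix(0, length(idx), L)
  d[cbind(seq_along(idx), idx)] <- 1
  covariate_block(name, d, kind = kind, level_ids = level_ids)
}

random_factors <- function(blocks, K, sd = 1) {
  lapply(blocks, function(b) matrix(rnorm(n_levels(b) * K, 0, sd),
                                    n_levels(b), K))
}
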