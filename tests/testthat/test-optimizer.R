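# Block updates, the elastic-net loading solver, screening, and the full
# alternating fit.

test_that("categorical block update solves its ridge normal equations", {
  # K = 1, V = (1, 1), lambda = 0, one level, rows (1,1) and (3,3):
  # (2 * 2)^{-1} (2 + 6) = 2
  blk <- block_from_index_test("g", c(1L, 1L), "only")
  V <- matrix(c(1, 1), 1, 2)
  Zt <- rbind(c(1, 1), c(3, 3))
  B <- insider:::update_block_closed(blk, Zt, V, tcrossprod(V), NULL,
                                     lambda = 0, B_prev = matrix(0, 1, 1),
                                     row_obs = c(2, 2))
  expect_equal(unname(B[1, 1]), 2)

  # huge ridge shrinks all rows toward zero
  B_inf <- insider:::update_block_closed(blk, Zt, V, tcrossprod(V), NULL,
                                         lambda = 1e12,
                                         B_prev = matrix(1, 1, 1),
                                         row_obs = c(2, 2))
  expect_lt(abs(B_inf[1, 1]), 1e-10)
})

test_that("masked categorical update matches the per-level ridge oracle", {
  set.seed(21)
  n <- 12; m <- 6; K <- 3
  idx <- rep_len(1:3, n)
  blk <- block_from_index_test("g", idx, paste0("l", 1:3))
  V <- matrix(rnorm(K * m), K, m)
  Zt_full <- matrix(rnorm(n * m), n, m)
  mask <- matrix(runif(n * m) > 0.2, n, m)
  Zt <- Zt_full; Zt[!mask] <- 0
  corr <- lapply(seq_len(n), function(s) {
    ms <- which(!mask[s, ])
    if (length(ms) == 0) NULL else tcrossprod(V[, ms, drop = FALSE])
  })
  lambda <- 0.3
  B <- insider:::update_block_closed(blk, Zt, V, tcrossprod(V), corr,
                                     lambda, matrix(0, 3, K),
                                     row_obs = rowSums(mask))
  for (j in 1:3) {
    expect_equal(unname(B[j, ]),
                 level_ridge_oracle(which(idx == j), Zt_full, mask, V,
                                    lambda),
                 tolerance = 1e-8)
  }
})

test_that("observation update recovers rows under the identity loadings", {
  n <- 5; K <- 3
  blk <- block_from_index_test("obs", seq_len(n), paste0("s", 1:n),
                               kind = "observation")
  V <- diag(K)                          # M = K
  Zt <- matrix(rnorm(n * K), n, K)
  B <- insider:::update_block_closed(blk, Zt, V, tcrossprod(V), NULL,
                                     lambda = 0, matrix(0, n, K),
                                     row_obs = rep(K, n))
  expect_equal(unname(B), Zt, tolerance = 1e-10, ignore_attr = TRUE)

  # a fully masked row keeps its previous value
  mask <- matrix(TRUE, n, K); mask[2, ] <- FALSE
  Zt2 <- Zt; Zt2[2, ] <- 0
  corr <- lapply(seq_len(n), function(s)
    if (s == 2) tcrossprod(V) else NULL)
  prev <- matrix(9, n, K)
  B2 <- insider:::update_block_closed(blk, Zt2, V, tcrossprod(V), corr,
                                      0.1, prev, row_obs = rowSums(mask))
  expect_equal(unname(B2[2, ]), rep(9, K))
  expect_equal(attr(B2, "skipped"), 2L)
})

test_that("continuous update reduces to the observation update and scales", {
  set.seed(31)
  n <- 7; m <- 5; K <- 2
  V <- matrix(rnorm(K * m), K, m)
  Zt <- matrix(rnorm(n * m), n, m)
  lambda <- 0.2
  # indicator of sample 3 reduces to that sample's ridge row update
  x_ind <- as.numeric(seq_len(n) == 3)
  blk <- covariate_block("c", x_ind, kind = "continuous")
  q <- insider:::update_block_continuous(blk, Zt, V, tcrossprod(V), NULL,
                                         lambda, matrix(0, 1, K))
  u3 <- solve(tcrossprod(V) + diag(lambda, K), V %*% Zt[3, ])
  expect_equal(drop(q), drop(u3), tolerance = 1e-10)

  # homogeneity at lambda = 0: scaling x by c scales q by 1/c
  x <- rnorm(n)
  b1 <- covariate_block("c", x, kind = "continuous")
  b2 <- covariate_block("c", 3 * x, kind = "continuous")
  q1 <- insider:::update_block_continuous(b1, Zt, V, tcrossprod(V), NULL,
                                          0, matrix(0, 1, K))
  q2 <- insider:::update_block_continuous(b2, Zt, V, tcrossprod(V), NULL,
                                          0, matrix(0, 1, K))
  expect_equal(drop(q2), drop(q1) / 3, tolerance = 1e-8)

  # masked entries removed exactly: vectorized ridge oracle
  mask <- matrix(runif(n * m) > 0.25, n, m)
  Zt0 <- Zt; Zt0[!mask] <- 0
  corr <- lapply(seq_len(n), function(s) {
    ms <- which(!mask[s, ])
    if (length(ms) == 0) NULL else tcrossprod(V[, ms, drop = FALSE])
  })
  q3 <- insider:::update_block_continuous(b1, Zt0, V, tcrossprod(V), corr,
                                          lambda, matrix(0, 1, K))
  X <- NULL; y <- NULL
  for (s in seq_len(n)) {
    obs <- which(mask[s, ])
    X <- rbind(X, x[s] * t(V[, obs, drop = FALSE]))
    y <- c(y, Zt[s, obs])
  }
  q_oracle <- solve(crossprod(X) + diag(lambda, K), crossprod(X, y))
  expect_equal(drop(q3), drop(q_oracle), tolerance = 1e-8)

  expect_error(
    insider:::update_block_continuous(
      covariate_block("c", rep(0, n), kind = "continuous"),
      Zt, V, tcrossprod(V), NULL, 0, matrix(0, 1, K)),
    "lambda")
})

test_that("loading update: ridge closed form, lasso null, prox oracle", {
  # E = (1, 1)', z = (1, 3), lambda_v = 0, alpha = 0 -> v = 2
  E <- matrix(1, 2, 1)
  em <- expression_matrix(matrix(c(1, 3), 2, 1))
  mi <- insider:::mask_info(em)
  up <- insider:::update_loadings(E, mi$Z0, mi, lambda_v = 0, alpha = 0,
                                  V_prev = matrix(0, 1, 1), base_seed = 1)
  expect_equal(unname(up$V[1, 1]), 2, tolerance = 1e-12)

  # alpha = 1 with penalty at lambda_max fully shrinks the column
  set.seed(5)
  E2 <- matrix(rnorm(20 * 4), 20, 4)
  z <- rnorm(20)
  lam_max <- max(abs(crossprod(E2, z)))
  em2 <- expression_matrix(matrix(z, ncol = 1))
  mi2 <- insider:::mask_info(em2)
  up2 <- insider:::update_loadings(E2, mi2$Z0, mi2, lambda_v = lam_max,
                                   alpha = 1,
                                   V_prev = matrix(0.5, 4, 1),
                                   base_seed = 1)
  expect_equal(unname(up2$V[, 1]), rep(0, 4))

  # random instances: objective within 1e-6 of a proximal-gradient oracle,
  # and alpha = 0 equals the closed-form ridge solve to 1e-8
  for (alpha in c(0, 0.35, 1)) {
    lam <- 0.7
    up3 <- insider:::update_loadings(E2, mi2$Z0, mi2, lambda_v = lam,
                                     alpha = alpha,
                                     V_prev = matrix(0, 4, 1),
                                     base_seed = 3)
    v_hat <- up3$V[, 1]
    l1 <- lam * alpha; l2 <- lam * (1 - alpha)
    v_star <- prox_enet(E2, z, l1, l2)
    expect_lte(enet_objective(E2, z, l1, l2, v_hat),
               enet_objective(E2, z, l1, l2, v_star) + 1e-6)
    if (alpha == 0) {
      ridge <- solve(crossprod(E2) + diag(lam, 4), crossprod(E2, z))
      expect_equal(v_hat, drop(ridge), tolerance = 1e-8)
    }
  }
})

test_that("loading update honors per-gene masks and empty genes", {
  set.seed(6)
  n <- 20; m <- 6; K <- 3
  E <- matrix(rnorm(n * K), n, K)
  Z <- matrix(rnorm(n * m), n, m)
  mask <- matrix(runif(n * m) > 0.3, n, m)
  mask[, 6] <- FALSE                 # gene with no observations
  em <- suppressWarnings(expression_matrix(Z, mask = mask))
  mi <- insider:::mask_info(em)
  up <- insider:::update_loadings(E, mi$Z0, mi, lambda_v = 0.4, alpha = 0,
                                  V_prev = matrix(0, K, m), base_seed = 2)
  for (g in 1:5) {
    obs <- which(mask[, g])
    oracle <- solve(crossprod(E[obs, , drop = FALSE]) + diag(0.4, K),
                    crossprod(E[obs, , drop = FALSE], Z[obs, g]))
    expect_equal(unname(up$V[, g]), drop(oracle), tolerance = 1e-8)
  }
  expect_equal(unname(up$V[, 6]), rep(0, K))
})

test_that("screening is vacuous at alpha 0, strict at the boundary, safe", {
  b <- c(1, -2, 3)
  expect_length(insider:::screen_gene(b, lambda = 10, alpha = 0)$discarded, 0)
  # alpha = 1, lambda = lambda_max = 3: threshold 3; only the argmax
  # survives the strict inequality
  scr <- insider:::screen_gene(b, lambda = 3, alpha = 1)
  expect_equal(scr$lambda_max, 3)
  expect_equal(scr$discarded, c(1L, 2L))

  # safety: screened solutions equal unscreened coordinate descent
  set.seed(9)
  n <- 25; m <- 8; K <- 5
  E <- matrix(rnorm(n * K), n, K)
  Z <- matrix(rnorm(n * m), n, m)
  em <- expression_matrix(Z)
  mi <- insider:::mask_info(em)
  for (lam in c(2, 8, 20)) {
    alpha <- 0.8
    up <- insider:::update_loadings(E, mi$Z0, mi, lambda_v = lam,
                                    alpha = alpha,
                                    V_prev = matrix(0, K, m),
                                    base_seed = 4,
                                    collect_screening = TRUE)
    l1 <- lam * alpha; l2 <- lam * (1 - alpha)
    A <- crossprod(E)
    for (g in seq_len(m)) {
      bg <- drop(crossprod(E, Z[, g]))
      v_full <- insider:::cd_enet(A, bg, l1, l2, rep(0, K), seq_len(K),
                                  seed = 99)
      expect_equal(unname(up$V[, g]), v_full, tolerance = 1e-6)
      rep_g <- up$screening[[g]]
      expect_true(all(up$V[rep_g$discarded, g] == 0))
    }
  }
})

test_that("fit recovers noiseless data at the true rank", {
  set.seed(12)
  n <- 40; m <- 30; K <- 3
  blocks <- list(
    A = block_from_index_test("A", rep_len(1:8, n), paste0("a", 1:8)),
    B = block_from_index_test("B", rep_len(1:4, n), paste0("b", 1:4))
  )
  factors <- random_factors(blocks, K)
  V <- matrix(rnorm(K * m), K, m)
  truth <- insider:::predictor_matrix(blocks, factors, K) %*% V
  fit <- insider(truth, blocks, K = K, lambda = 1e-6, alpha = 0,
                 max_iter = 400, seed = 2)
  expect_lt(rmse(reconstruct(fit), truth), 1e-3)
})

test_that("fit objective is monotone non-increasing and deterministic", {
  set.seed(13)
  sim_blocks <- random_blocks(30, 5, 3)
  Z <- matrix(rnorm(30 * 20), 30, 20)
  Z[sample(600, 60)] <- NA
  fit1 <- suppressWarnings(insider(Z, sim_blocks, K = 3, lambda = 0.5,
                                   alpha = 0.4, max_iter = 40, seed = 7))
  expect_true(all(diff(fit1$loss_trace) <=
                    1e-10 * pmax(abs(fit1$loss_trace[-1]), 1)))
  fit2 <- suppressWarnings(insider(Z, sim_blocks, K = 3, lambda = 0.5,
                                   alpha = 0.4, max_iter = 40, seed = 7))
  expect_identical(fit1$loadings, fit2$loadings)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
})

test_that("fit is invariant to values hidden behind the mask", {
  set.seed(14)
  blocks <- random_blocks(20, 4, 2)
  Z <- matrix(rnorm(20 * 10), 20, 10)
  mask <- matrix(runif(200) > 0.25, 20, 10)
  Z2 <- Z; Z2[!mask] <- 77
  f1 <- insider(expression_matrix(Z, mask = mask), blocks, K = 2,
                lambda = 0.2, alpha = 0.3, max_iter = 25, seed = 3)
  f2 <- insider(expression_matrix(Z2, mask = mask), blocks, K = 2,
                lambda = 0.2, alpha = 0.3, max_iter = 25, seed = 3)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$factors, f2$factors)
})

test_that("fits are equivariant under sample permutation", {
  set.seed(15)
  n <- 24
  idx_a <- rep_len(1:4, n); idx_b <- rep_len(1:3, n)
  Z <- matrix(rnorm(n * 12), n, 12)
  blocks <- list(A = block_from_index_test("A", idx_a, paste0("a", 1:4)),
                 B = block_from_index_test("B", idx_b, paste0("b", 1:3)))
  perm <- sample(n)
  blocks_p <- list(A = block_from_index_test("A", idx_a[perm],
                                             paste0("a", 1:4)),
                   B = block_from_index_test("B", idx_b[perm],
                                             paste0("b", 1:3)))
  f <- insider(Z, blocks, K = 2, lambda = 0.3, max_iter = 20, seed = 4)
  fp <- insider(Z[perm, ], blocks_p, K = 2, lambda = 0.3, max_iter = 20,
                seed = 4)
  expect_equal(f$factors, fp$factors, tolerance = 1e-10)
  expect_equal(f$loadings, fp$loadings, tolerance = 1e-10)
  expect_equal(reconstruct(f)[perm, ], reconstruct(fp),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("fit raises on empty designs and singular lambda-0 systems", {
  Z <- matrix(rnorm(20), 5, 4)
  expect_error(insider(Z, list(), K = 2), "empty design")
  blocks <- list(A = block_from_index_test("A", rep(1L, 5), "a1"))
  # K larger than the observed count with lambda = 0 cannot be inverted
  Zs <- matrix(rnorm(10), 5, 2)
  expect_error(insider(Zs, blocks, K = 3, lambda = 0, alpha = 0,
                       max_iter = 3, seed = 1),
               "lambda")
})

test_that("holdout_rmse scores only the held-out entries", {
  set.seed(16)
  blocks <- random_blocks(10, 3, 2)
  Z <- matrix(rnorm(10 * 8), 10, 8)
  holdout <- matrix(FALSE, 10, 8)
  holdout[sample(80, 8)] <- TRUE
  train <- expression_matrix(Z, mask = !holdout)
  fit <- insider(train, blocks, K = 2, lambda = 0.2, max_iter = 15,
                 seed = 2)
  r <- holdout_rmse(fit, expression_matrix(Z), holdout)
  zhat <- reconstruct(fit)
  expect_equal(r, sqrt(mean((Z[holdout] - zhat[holdout])^2)),
               tolerance = 1e-12)

  # perfect reconstruction and the 2-unit single entry case
  fitp <- fit
  fitp$loadings <- fit$loadings
  expect_equal(holdout_rmse(fit, expression_matrix(zhat), holdout), 0)
  expect_error(holdout_rmse(fit, expression_matrix(Z),
                            matrix(FALSE, 10, 8)), "empty")
  overlap <- !holdout
  expect_error(holdout_rmse(fit, expression_matrix(Z), overlap),
               "overlaps")
})

test_that("rmse handles scalars, masks, and the loop oracle", {
  A <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(rmse(A, A), 0)
  expect_equal(rmse(matrix(0), matrix(2)), 2)
  B <- matrix(rnorm(4), 2, 2)
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  acc <- c()
  for (i in 1:2) for (j in 1:2) if (mask[i, j])
    acc <- c(acc, (A[i, j] - B[i, j])^2)
  expect_equal(rmse(A, B, mask), sqrt(mean(acc)))
})
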