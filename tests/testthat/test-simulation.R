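# Generators for the four simulation designs and the scoring machinery.

test_that("the factorization design has the stated shapes and silencing", {
  sim <- simulate_insider_design(noise = 0.5, seed = 2)
  expect_equal(dim(sim$Z$values), c(250, 200))
  expect_length(sim$silenced, 60)                 # 30% of 200 genes
  expect_true(all(sim$truth[, sim$silenced] == 0))
  expect_equal(names(sim$design), c("E", "F", "interaction"))
  expect_equal(n_levels(sim$design$E), 50)
  expect_equal(n_levels(sim$design$F), 5)
  expect_equal(n_levels(sim$design$interaction), 250)

  # noiseless limit and the noise moment (sd parameterization)
  sim0 <- simulate_insider_design(noise = 0, seed = 2)
  expect_equal(sim0$Z$values, sim0$truth, ignore_attr = TRUE)
  resid <- sim$Z$values - sim$truth
  expect_equal(stats::var(as.vector(resid)), 0.25, tolerance = 0.05)
})

test_that("the trilinear design flattens n-major and contracts exactly", {
  sim <- simulate_sda_design(noise = 0, seed = 3)
  expect_equal(dim(sim$truth), c(250, 200))
  E <- sim$truth_blocks$E; F_ <- sim$truth_blocks$F; V <- sim$truth_blocks$V
  # row (n, l) sits at (n-1)*5 + l and equals (E_n * F_l) V
  for (pick in list(c(1, 1), c(7, 3), c(50, 5))) {
    n_i <- pick[1]; l_i <- pick[2]
    row <- (n_i - 1) * 5 + l_i
    manual <- vapply(seq_len(200), function(g)
      sum(E[n_i, ] * F_[l_i, ] * V[, g]), 0)
    expect_equal(unname(sim$truth[row, ]), manual, tolerance = 1e-12)
  }
  expect_equal(sim$Z$values, sim$truth, ignore_attr = TRUE)
})

test_that("the linear design equals the per-gene group-effect oracle", {
  sim <- simulate_linear_design(noise = 0, seed = 4)
  expect_equal(dim(sim$truth), c(100, 200))
  E <- sim$truth_blocks$E; F_ <- sim$truth_blocks$F
  idx_e <- sim$design$E$idx; idx_f <- sim$design$F$idx
  for (s in c(1, 37, 100)) {
    expect_equal(unname(sim$truth[s, ]), E[idx_e[s], ] + F_[idx_f[s], ],
                 tolerance = 1e-12)
  }
})

test_that("missing-design patterns reproduce the cohort structure", {
  sim <- simulate_missing_design(noise = 0.25, pattern = "structured",
                                 seed = 5)
  expect_equal(dim(sim$Z$values), c(400, 1000))
  expect_length(sim$missing_rows, 171)            # 229 available of 400
  # every donor keeps between 4 and 8 of its 8 tissues
  donor_of_row <- rep(1:50, each = 8)
  kept <- tabulate(donor_of_row[-sim$missing_rows], nbins = 50)
  expect_true(all(kept >= 4 & kept <= 8))
  # 27 healthy vs 23 diseased donors, phenotype-major interaction levels
  expect_equal(n_levels(sim$design$phenotype), 2)
  expect_equal(sum(sim$design$phenotype$idx == 1), 27 * 8)
  expect_equal(n_levels(sim$design[["phenotype:tissue"]]), 16)
  # 5% of the available entries masked on top of the missing rows
  n_avail <- 229 * 1000
  expect_equal(sum(sim$entry_mask), round(0.05 * n_avail))
  expect_false(any(sim$entry_mask & sim$row_mask))
  expect_equal(sum(sim$Z$mask), n_avail - sum(sim$entry_mask))
  # truth is retained everywhere, including missing rows
  expect_false(anyNA(sim$truth))

  rand <- simulate_missing_design(noise = 0.25, pattern = "random",
                                  seed = 5)
  expect_length(rand$missing_rows, 171)
  expect_true(all(tabulate(donor_of_row[-rand$missing_rows], 50) >= 1))

  ent <- simulate_missing_design(noise = 0.25, pattern = "entries_only",
                                 seed = 5)
  expect_length(ent$missing_rows, 0)
  expect_equal(sum(ent$entry_mask), round(0.05 * 400 * 1000))
})

test_that("baseline_rmse is the grand-mean reference error", {
  # truth constant at the train mean gives zero
  Z <- matrix(c(1, 3, 5, 7), 2, 2)
  train <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  eval_m <- !train
  expect_equal(baseline_rmse(matrix(2, 2, 2), Z, train, eval_m), 0)
  # hand-computed 2x2: mean(1,3) = 2; truth (4, 6) -> sqrt(mean(4, 16))
  truth <- matrix(c(0, 0, 4, 6), 2, 2)
  expect_equal(baseline_rmse(truth, Z, train, eval_m),
               sqrt(mean(c(2^2, 4^2))))
})

test_that("ridge comparator hits OLS at lambda 0 and means at the limit", {
  set.seed(61)
  n <- 30; m <- 5
  blk <- list(A = block_from_index_test("A", rep_len(1:3, n),
                                        paste0("a", 1:3)))
  eff <- matrix(rnorm(3 * m), 3, m)
  Z <- eff[rep_len(1:3, n), ]
  rb0 <- fit_ridge_baseline(Z, blk, lambda_grid = 0)
  expect_equal(rb0$pred, Z, tolerance = 1e-8)

  rb_inf <- fit_ridge_baseline(Z, blk, lambda_grid = 1e10)
  mu <- colMeans(Z)
  expect_equal(rb_inf$pred, matrix(mu, n, m, byrow = TRUE),
               tolerance = 1e-5)

  # masked normal-equation oracle on a random instance
  Zr <- Z + matrix(rnorm(n * m), n, m)
  mask <- matrix(runif(n * m) > 0.2, n, m)
  lam <- 0.7
  rb <- fit_ridge_baseline(expression_matrix(Zr, mask = mask), blk,
                           lambda_grid = lam, train_mask = mask)
  X <- cbind(1, design_matrix(blk$A)[, -1])
  for (g in c(1, 4)) {
    obs <- which(mask[, g])
    A <- crossprod(X[obs, ]) + diag(c(0, lam, lam))
    beta <- solve(A, crossprod(X[obs, ], Zr[obs, g]))
    expect_equal(rb$pred[, g], drop(X %*% beta), tolerance = 1e-8)
  }
})

test_that("run_table assembles tidy summaries across seeds", {
  tab <- run_table("insider", noises = 0.25, seeds = 1:2, max_iter = 40)
  expect_s3_class(tab, "tbl_df")
  expect_setequal(tab$model, c("with_interaction", "without_interaction"))
  expect_true(all(tab$n_seeds == 2))
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), 4)
  # the interaction fit must dominate the misspecified one on this design
  wi <- tab$mean_rmse[tab$model == "with_interaction"]
  wo <- tab$mean_rmse[tab$model == "without_interaction"]
  expect_lt(wi, 0.2 * wo)
})
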