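## Simulation designs used to validate the factorization, mirroring four
## generative settings: (i) the model's own design with a per-sample
## interaction, (ii) a trilinear tensor design flattened to a matrix,
## (iii) a multivariate linear (full-rank per-gene) design, and (iv) a
## large donor/phenotype/tissue design with structured missing samples.
##
## In all generators `noise` is the standard deviation of the additive
## Gaussian noise (the tables these designs reproduce scale linearly in
## the noise parameter, which identifies it as an SD).

new_sim <- function(Z, truth, design, truth_blocks, noise, seed, extra) {
  structure(
    c(list(Z = Z, truth = truth, design = design,
           truth_blocks = truth_blocks, noise = noise, seed = seed),
      extra),
    class = "insider_sim"
  )
}

#' @export
print.insider_sim <- function(x, ...) {
  cat(sprintf("<insider_sim> %d x %d, noise sd %g, blocks: %s\n",
              nrow(x$truth), ncol(x$truth), x$noise,
              paste(names(x$design), collapse = ", ")))
  invisible(x)
}

## shared 250-sample layout: 50 levels of E with 5 samples each, F cycling
## 1..5 within each E level, so every (E, F) combination occurs exactly once
ef_layout <- function() {
  list(idx_e = rep(seq_len(50), each = 5),
       idx_f = rep(seq_len(5), times = 50))
}

ef_design <- function(layout, n) {
  combo_ids <- paste0("E", layout$idx_e, ":F", layout$idx_f)
  list(
    E = block_from_index("E", layout$idx_e, paste0("E", seq_len(50))),
    F = block_from_index("F", layout$idx_f, paste0("F", seq_len(5))),
    interaction = block_from_index("interaction", seq_len(n), combo_ids,
                                   kind = "interaction")
  )
}

#' Simulate from the factorization's own generative design
#'
#' A 250 x 200 expression matrix from two categorical covariates (50 and 5
#' levels), their per-sample interaction, and a shared rank-5 gene loading
#' matrix: `Z = (X_E E + X_F F + X_R R) V + noise`, with all latent
#' matrices standard normal and a fraction of gene columns silenced
#' (their loading columns zeroed, so the true signal for those genes is
#' exactly zero).
#'
#' @param noise standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @param silenced_frac fraction of genes silenced (default 0.3).
#' @return An `insider_sim`: `Z` (expression matrix), `truth` (noiseless
#'   signal), `design` (blocks `E`, `F`, `interaction`), `truth_blocks`,
#'   `silenced` (silenced gene indices), `noise`, `seed`.
#' @export
simulate_insider_design <- function(noise = 0.25, seed = 1L,
                                    silenced_frac = 0.3) {
  stopifnot(noise >= 0)
  set.seed(seed)
  n <- 250L; m <- 200L; k <- 5L
  lay <- ef_layout()
  E <- matrix(stats::rnorm(50 * k), 50, k)
  F_ <- matrix(stats::rnorm(5 * k), 5, k)
  R <- matrix(stats::rnorm(n * k), n, k)
  V <- matrix(stats::rnorm(k * m), k, m)
  silenced <- sort(sample(m, round(silenced_frac * m)))
  V[, silenced] <- 0
  truth <- (E[lay$idx_e, ] + F_[lay$idx_f, ] + R) %*% V
  Z <- truth + matrix(stats::rnorm(n * m, 0, noise), n, m)
  new_sim(expression_matrix(Z), truth, ef_design(lay, n),
          list(E = E, F = F_, R = R, V = V), noise, seed,
          list(silenced = silenced))
}

#' Simulate from a trilinear (tensor) design, flattened
#'
#' A 50 x 5 x 200 tensor `T[n, l, g] = sum_c E[n, c] F[l, c] V[c, g]`
#' (rank 5, standard normal factors) plus noise, flattened over its first
#' two dimensions in n-major order (all 5 second-dimension levels of the
#' first level, then the second, ...) into a 250 x 200 matrix with the two
#' categorical design blocks attached. The factorization's own model is
#' misspecified for this signal unless the interaction block is included.
#'
#' @inheritParams simulate_insider_design
#' @return An `insider_sim` with blocks `E`, `F`, `interaction`.
#' @export
simulate_sda_design <- function(noise = 0.25, seed = 1L) {
  stopifnot(noise >= 0)
  set.seed(seed)
  n <- 250L; m <- 200L; k <- 5L
  lay <- ef_layout()
  E <- matrix(stats::rnorm(50 * k), 50, k)
  F_ <- matrix(stats::rnorm(5 * k), 5, k)
  V <- matrix(stats::rnorm(k * m), k, m)
  scores <- E[lay$idx_e, ] * F_[lay$idx_f, ]      # row (n,l): E_n * F_l
  truth <- scores %*% V
  Z <- truth + matrix(stats::rnorm(n * m, 0, noise), n, m)
  new_sim(expression_matrix(Z), truth, ef_design(lay, n),
          list(E = E, F = F_, V = V, scores = scores), noise, seed,
          list())
}

#' Simulate from a multivariate linear design
#'
#' A 100 x 200 matrix `Z = X_E E + X_F F + noise` with two categorical
#' covariates (20 and 5 levels) and per-gene standard normal coefficient
#' matrices `E` (20 x 200) and `F` (5 x 200). The truth has no low-rank
#' structure across genes, so this probes the factorization under
#' misspecification against a per-gene ridge regression.
#'
#' @inheritParams simulate_insider_design
#' @return An `insider_sim` with blocks `E` and `F` (no interaction).
#' @export
simulate_linear_design <- function(noise = 0.25, seed = 1L) {
  stopifnot(noise >= 0)
  set.seed(seed)
  n <- 100L; m <- 200L
  idx_e <- rep(seq_len(20), each = 5)
  idx_f <- rep(seq_len(5), times = 20)
  E <- matrix(stats::rnorm(20 * m), 20, m)
  F_ <- matrix(stats::rnorm(5 * m), 5, m)
  truth <- E[idx_e, ] + F_[idx_f, ]
  Z <- truth + matrix(stats::rnorm(n * m, 0, noise), n, m)
  design <- list(
    E = block_from_index("E", idx_e, paste0("E", seq_len(20))),
    F = block_from_index("F", idx_f, paste0("F", seq_len(5)))
  )
  new_sim(expression_matrix(Z), truth, design,
          list(E = E, F = F_), noise, seed, list())
}

#' Simulate the donor/phenotype/tissue design with missing data
#'
#' 50 donors x 8 tissues = 400 sample slots over 1000 genes, with donor,
#' phenotype (27 healthy / 23 diseased donors), tissue, and
#' phenotype-by-tissue interaction blocks sharing rank-5 standard normal
#' factors: `R = (X_D D + X_P P + X_T T + X_W W) V`, `Z = R + noise`.
#' Missingness patterns:
#' \describe{
#'   \item{`"structured"`}{whole sample rows removed per donor (each donor
#'     keeps a uniform-random subset of at least 4 of its 8 tissues,
#'     calibrated so `n_available` rows remain — default 229, i.e. 42.75%
#'     of rows missing), then `entry_frac` of the remaining entries masked.}
#'   \item{`"random"`}{the same number of whole rows removed at random
#'     (each donor keeps at least one row), then `entry_frac` entries
#'     masked.}
#'   \item{`"entries_only"`}{no rows removed; `entry_frac` of all entries
#'     masked at random.}
#' }
#' The noiseless truth is retained for every row and entry, so recovery
#' can be scored on the missing entries and on the missing rows.
#'
#' @inheritParams simulate_insider_design
#' @param pattern one of `"structured"`, `"random"`, `"entries_only"`.
#' @param entry_frac fraction of remaining entries masked (default 0.05).
#' @param n_available target number of available rows for the structured
#'   and random patterns (default 229 of 400).
#' @return An `insider_sim` with blocks `donor`, `phenotype`, `tissue`,
#'   `phenotype:tissue`, plus `missing_rows` (row indices), `row_mask`
#'   (logical matrix covering all entries of missing rows), `entry_mask`
#'   (the masked single entries), and `Z`'s mask marking what is observed.
#' @export
simulate_missing_design <- function(noise = 0.25,
                                    pattern = c("structured", "random",
                                                "entries_only"),
                                    seed = 1L, entry_frac = 0.05,
                                    n_available = 229L) {
  pattern <- match.arg(pattern)
  stopifnot(noise >= 0, entry_frac >= 0, entry_frac < 1)
  set.seed(seed)
  n_donor <- 50L; n_tissue <- 8L; n_phen <- 2L
  n <- n_donor * n_tissue; m <- 1000L; k <- 5L
  idx_d <- rep(seq_len(n_donor), each = n_tissue)
  idx_t <- rep(seq_len(n_tissue), times = n_donor)
  phen_of_donor <- rep(c(1L, 2L), c(27L, 23L))    # healthy, diseased
  idx_p <- phen_of_donor[idx_d]
  idx_w <- (idx_p - 1L) * n_tissue + idx_t        # phenotype-major

  D <- matrix(stats::rnorm(n_donor * k), n_donor, k)
  P <- matrix(stats::rnorm(n_phen * k), n_phen, k)
  T_ <- matrix(stats::rnorm(n_tissue * k), n_tissue, k)
  W <- matrix(stats::rnorm(n_phen * n_tissue * k), n_phen * n_tissue, k)
  V <- matrix(stats::rnorm(k * m), k, m)
  truth <- (D[idx_d, ] + P[idx_p, ] + T_[idx_t, ] + W[idx_w, ]) %*% V
  Z <- truth + matrix(stats::rnorm(n * m, 0, noise), n, m)

  missing_rows <- integer(0)
  if (pattern == "structured") {
    n_available <- as.integer(n_available)
    stopifnot(n_available >= 4L * n_donor, n_available <= n)
    # every donor keeps >= 4 tissues; the extra kept slots (beyond 4 each)
    # are spread uniformly over donors, capped at 8 per donor
    extra_slots <- rep(seq_len(n_donor), times = n_tissue - 4L)
    extra <- sample(extra_slots, n_available - 4L * n_donor)
    keep_count <- 4L + tabulate(extra, nbins = n_donor)
    for (d in seq_len(n_donor)) {
      kept_tissues <- sample(n_tissue, keep_count[d])
      dropped <- setdiff(seq_len(n_tissue), kept_tissues)
      missing_rows <- c(missing_rows, (d - 1L) * n_tissue + dropped)
    }
    missing_rows <- sort(missing_rows)
  } else if (pattern == "random") {
    n_missing <- n - as.integer(n_available)
    repeat {
      missing_rows <- sort(sample(n, n_missing))
      if (all(tabulate(idx_d[-missing_rows], nbins = n_donor) >= 1)) break
    }
  }

  row_mask <- matrix(FALSE, n, m)
  if (length(missing_rows)) row_mask[missing_rows, ] <- TRUE

  avail <- !row_mask
  entry_mask <- matrix(FALSE, n, m)
  if (entry_frac > 0) {
    avail_idx <- which(avail)
    entry_mask[sample(avail_idx, round(entry_frac * length(avail_idx)))] <- TRUE
  }
  obs_mask <- avail & !entry_mask
  Zna <- Z
  Zna[!obs_mask] <- NA

  design <- list(
    donor = block_from_index("donor", idx_d, paste0("donor_", seq_len(n_donor))),
    phenotype = block_from_index("phenotype", idx_p, c("healthy", "diseased")),
    tissue = block_from_index("tissue", idx_t,
                              paste0("tissue_", seq_len(n_tissue))),
    `phenotype:tissue` = block_from_index(
      "phenotype:tissue", idx_w,
      as.vector(t(outer(c("healthy", "diseased"),
                        paste0("tissue_", seq_len(n_tissue)),
                        paste, sep = ":"))),
      kind = "interaction")
  )
  suppressWarnings(
    new_sim(expression_matrix(Zna), truth, design,
            list(D = D, P = P, T = T_, W = W, V = V), noise, seed,
            list(pattern = pattern, missing_rows = missing_rows,
                 row_mask = row_mask, entry_mask = entry_mask,
                 noisy_full = Z))
  )
}

#' No-model baseline RMSE
#'
#' The root-mean-square difference between the true signal on the
#' evaluation entries and the scalar mean of the observed data over the
#' training entries — the error of predicting every entry by the grand
#' mean.
#'
#' @param truth numeric matrix of the noiseless signal.
#' @param Z numeric matrix of observed data (or `expression_matrix`).
#' @param train_mask logical matrix: entries whose mean forms the
#'   prediction.
#' @param eval_mask logical matrix: entries on which the error is scored.
#' @return non-negative number.
#' @export
baseline_rmse <- function(truth, Z, train_mask, eval_mask) {
  if (inherits(Z, "expression_matrix")) Z <- Z$values
  mu <- mean(Z[train_mask])
  rmse(mu, truth, mask = eval_mask)
}

#' Per-gene ridge regression comparator
#'
#' Fits, for every gene, a ridge regression of expression on the given
#' categorical blocks (unpenalized intercept, drop-first dummy coding per
#' block), with one shared penalty chosen by RMSE on validation entries,
#' then refit on training + validation entries. This is the classical
#' per-gene linear-model comparator for the factorization: at
#' `lambda = 0` it is per-gene OLS; as `lambda` grows the predictions
#' shrink to the per-gene mean of the training entries.
#'
#' @param Z `expression_matrix` or matrix of observed data.
#' @param design list of categorical covariate blocks used as predictors.
#' @param lambda_grid candidate ridge penalties.
#' @param train_mask,val_mask logical matrices: training entries and
#'   validation entries for penalty selection. If `val_mask` is `NULL` the
#'   first penalty in the grid is used directly.
#' @return list with `pred` (the full fitted matrix), `lambda` (chosen
#'   penalty), `val_rmse` (tibble of penalty vs validation RMSE).
#' @export
fit_ridge_baseline <- function(Z, design,
                               lambda_grid = 10^seq(-3, 2),
                               train_mask = NULL, val_mask = NULL) {
  Zm <- if (inherits(Z, "expression_matrix")) Z$values else as.matrix(Z)
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(design, function(b)
               design_matrix(b)[, -1, drop = FALSE])))
  n <- nrow(Zm); m <- ncol(Zm); p <- ncol(X)
  pen <- c(0, rep(1, p - 1))            # intercept unpenalized
  if (is.null(train_mask)) train_mask <- !is.na(Zm)

  ridge_predict <- function(fit_mask, lambda) {
    pred <- matrix(0, n, m)
    complete <- all(fit_mask)
    if (complete) {
      A <- crossprod(X) + diag(lambda * pen, p)
      Ai <- tryCatch(solve(A), error = function(e)
        stop("singular ridge system; use lambda > 0.", call. = FALSE))
      B <- Ai %*% crossprod(X, Zm)
      return(X %*% B)
    }
    Z0 <- Zm
    Z0[!fit_mask] <- 0
    XtZ <- crossprod(X, Z0)
    XtX <- crossprod(X)
    for (g in seq_len(m)) {
      ms <- which(!fit_mask[, g])
      A <- XtX
      if (length(ms)) A <- A - crossprod(X[ms, , drop = FALSE])
      beta <- tryCatch(solve(A + diag(lambda * pen, p), XtZ[, g]),
                       error = function(e)
                         stop("singular ridge system; use lambda > 0.",
                              call. = FALSE))
      pred[, g] <- X %*% beta
    }
    pred
  }

  val_tab <- NULL
  lambda <- lambda_grid[1]
  if (!is.null(val_mask) && length(lambda_grid) > 1) {
    vr <- vapply(lambda_grid, function(l) {
      pred <- ridge_predict(train_mask, l)
      rmse(Zm, pred, mask = val_mask)
    }, 0)
    val_tab <- tibble::tibble(lambda = lambda_grid, rmse = vr)
    lambda <- lambda_grid[which.min(vr)]
  }
  final_mask <- if (is.null(val_mask)) train_mask else train_mask | val_mask
  pred <- ridge_predict(final_mask, lambda)
  list(pred = pred, lambda = lambda, val_rmse = val_tab)
}
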