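test_that("one noiseless latent variable is recovered exactly", {
  set.seed(20)
  # orthogonal centered columns: the single informative direction is then
  # exactly the first PLS component
  X <- qr.Q(qr(scale(matrix(rnorm(10 * 6), 10), scale = FALSE)))
  y <- 2 + 3 * X[, 4]
  fit <- qsar_pls(X, y, ncomp = 1)
  expect_equal(fit$r2[1], 1, tolerance = 1e-8)
  expect_equal(unname(fitted(fit)), unname(y), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(12), 4)
  expect_error(qsar_pls(X, rep(1, 4)), "constant")
  expect_error(qsar_pls(X, 1:4, ncomp = 4), "exceeds")
  expect_error(qsar_pls(X[1:2, ], 1:2), "at least 3")
})

test_that("PLS at full rank equals ordinary least squares", {
  set.seed(21)
  X <- matrix(rnorm(15 * 5), 15)
  y <- X %*% c(1, -2, 0.5, 0, 1.5) + rnorm(15, 0, 0.2)
  fit <- qsar_pls(X, y, ncomp = 5)
  b_ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(unname(coef(fit)), b_ols, tolerance = 1e-6)
})

test_that("NIPALS coefficients match the Krylov-subspace oracle", {
  # independent route: PLS with k components equals regression on the
  # k-dimensional Krylov space spanned by {X'y, (X'X)X'y, ...}
  set.seed(22)
  X <- matrix(rnorm(8 * 20), 8)
  y <- as.numeric(X[, 1] - X[, 2] + 0.5 * X[, 3] + rnorm(8, 0.0, 0.05))
  for (k in 1:3) {
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    S <- crossprod(Xc)
    s <- crossprod(Xc, yc)
    K <- s
    for (j in seq_len(k - 1)) K <- cbind(K, S %*% K[, ncol(K)])
    Q <- qr.Q(qr(K))
    b_oracle <- as.numeric(Q %*% solve(t(Q) %*% S %*% Q, t(Q) %*% s))
    fit <- qsar_pls(X, y, ncomp = k)
    expect_equal(unname(fit$B[, k]), b_oracle, tolerance = 1e-6,
                 label = paste("k =", k))
  }
})

test_that("LOO cross-validation equals an explicit refit loop", {
  set.seed(23)
  n <- 10
  X <- matrix(rnorm(n * 30), n)
  y <- as.numeric(X[, 1] - X[, 5] + rnorm(n, 0, 0.3))
  nc <- 3
  cv <- cross_validate(X, y, ncomp = nc, scheme = "loo")
  press <- numeric(nc)
  for (i in seq_len(n)) {
    f <- qsar_pls(X[-i, ], y[-i], ncomp = nc)
    for (k in seq_len(nc))
      press[k] <- press[k] +
        (y[i] - predict(f, X[i, , drop = FALSE], ncomp = min(k, f$ncomp)))^2
  }
  q2_oracle <- 1 - press / sum((y - mean(y))^2)
  expect_equal(cv$q2, q2_oracle, tolerance = 1e-10)
  expect_equal(cv$sdep, sqrt(press / n), tolerance = 1e-10)
})

test_that("a noiseless planted model cross-validates almost perfectly", {
  set.seed(24)
  # two latent factors generate both X and y: the perfect-model limit
  Tm <- matrix(rnorm(10 * 2), 10)
  X <- Tm %*% matrix(rnorm(2 * 8), 2)
  y <- as.numeric(X %*% rnorm(8))
  cv <- cross_validate(X, y, ncomp = 3, scheme = "loo")
  expect_gt(max(cv$q2), 0.999)
})

test_that("pure-noise responses rarely cross-validate", {
  # Monte-Carlo null: for random X and y at n = 12 the LOO q2 is typically
  # well below zero and clears 0.2 in the large majority of draws
  set.seed(25)
  n <- 12
  q2 <- replicate(50, {
    X <- matrix(rnorm(n * 10), n)
    y <- rnorm(n)
    cross_validate(X, y, ncomp = 1, scheme = "loo")$q2[1]
  })
  expect_gte(mean(q2 < 0.2), 0.9)
  expect_lt(median(q2), 0)
})

test_that("q2 never exceeds r2 on the same model and data", {
  set.seed(26)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 15), 12)
    y <- X[, 1] + rnorm(12, 0, 0.5)
    nc <- 3
    fit <- qsar_pls(X, y, ncomp = nc)
    cv <- cross_validate(X, y, ncomp = nc, scheme = "loo")
    expect_true(all(cv$q2 <= fit$r2[seq_len(nc)] + 1e-12))
  }
})

test_that("LSO averages over random partitions deterministically", {
  set.seed(27)
  X <- matrix(rnorm(15 * 12), 15)
  y <- X[, 2] + rnorm(15, 0, 0.2)
  a <- cross_validate(X, y, ncomp = 2, scheme = "lso", groups = 5,
                      repeats = 4, seed = 3)
  b <- cross_validate(X, y, ncomp = 2, scheme = "lso", groups = 5,
                      repeats = 4, seed = 3)
  expect_identical(a$q2, b$q2)
  expect_error(cross_validate(X, y, ncomp = 2, scheme = "lso", groups = 20),
               "groups")
})

test_that("Y-scrambling with identity permutations reproduces the true fit", {
  set.seed(28)
  X <- matrix(rnorm(10 * 12), 10)
  y <- X[, 1] + rnorm(10, 0, 0.2)
  fit <- qsar_pls(X, y, ncomp = 2)
  ys <- y_scramble(X, y, ncomp = 2,
                   perms = list(seq_along(y), seq_along(y)))
  expect_equal(ys$r2_ys, fit$r2[fit$ncomp], tolerance = 1e-12)
})

test_that("Y-scrambling is deterministic and separates from the true model", {
  set.seed(29)
  X <- matrix(rnorm(14 * 20), 14)
  y <- as.numeric(X[, 1] - X[, 2] + rnorm(14, 0, 0.2))
  a <- y_scramble(X, y, ncomp = 2, n_perm = 10, seed = 5)
  b <- y_scramble(X, y, ncomp = 2, n_perm = 10, seed = 5)
  expect_identical(a$trace, b$trace)
  true_q2 <- max(cross_validate(X, y, ncomp = 2, scheme = "loo")$q2)
  expect_lt(a$q2_ys_loo, true_q2)
  expect_error(y_scramble(X, y, n_perm = 5), "at least 10")
})

test_that("FFD keeps planted signal columns and sheds noise columns", {
  set.seed(30)
  n <- 24
  Xsig <- matrix(rnorm(n * 5), n)
  Xnoise <- matrix(rnorm(n * 45), n)
  X <- cbind(Xsig, Xnoise)
  y <- as.numeric(Xsig %*% c(1, -1, 1, -1, 1) + rnorm(n, 0, 0.2))
  sel <- ffd_select(X, y, ncomp = 3, seed = 5)
  expect_gte(sum(sel$keep[1:5]), 4)
  expect_gt(sum(!sel$keep[6:50]), 45 / 2)
  expect_length(sel$keep, 50)                 # dummies never in the mask
  expect_length(sel$dummy_effects, 10)
})

test_that("FFD with uncertain retention keeps an all-informative matrix", {
  set.seed(31)
  n <- 24
  # orthogonalized columns each carrying independent signal: none detrimental
  X <- qr.Q(qr(matrix(rnorm(n * 12), n))) * sqrt(n)
  y <- as.numeric(X %*% rep(1, 12) + rnorm(n, 0, 0.05))
  sel <- ffd_select(X, y, ncomp = 5, seed = 5, design_mult = 4,
                    keep_uncertain = TRUE)
  expect_gte(sum(sel$keep), ceiling(0.9 * 12))
  expect_error(ffd_select(X[, 1:5], y, seed = 1), "skip FFD")
  expect_error(ffd_select(X, y, dummy_ratio = 0.8), "dummy_ratio")
})

test_that("FFD is deterministic under its seed", {
  set.seed(32)
  X <- matrix(rnorm(16 * 20), 16)
  y <- X[, 1] + rnorm(16, 0, 0.3)
  expect_identical(ffd_select(X, y, seed = 11)$keep,
                   ffd_select(X, y, seed = 11)$keep)
})

test_that("prediction reports satisfy the definition identities", {
  set.seed(33)
  X <- matrix(rnorm(10 * 5), 10)
  y <- as.numeric(X %*% c(1, -1, 0, 0.5, 0))
  fit <- qsar_pls(X, y, ncomp = 5)  # full-rank limit: exact on noiseless data
  # predicting TR itself: near-perfect on noiseless data
  rep_tr <- prediction_report(fit, X, y)
  expect_lt(rep_tr$aaep, 1e-6)
  expect_equal(rep_tr$q2_pred, 1, tolerance = 1e-10)
  # a model predicting the TR mean scores q2_pred = 0 by definition
  q2_mean <- 1 - sum((rep(fit$y_mean, 10) - y)^2) / sum((y - fit$y_mean)^2)
  expect_equal(q2_mean, 0)
  expect_error(predict(fit, X[, 1:3]), "mismatch")
})

test_that("external q2_pred is anchored on the training mean", {
  set.seed(34)
  X <- matrix(rnorm(12 * 8), 12)
  y <- as.numeric(X[, 1] + rnorm(12, 0, 0.1))
  fit <- qsar_pls(X[1:8, ], y[1:8], ncomp = 2)
  rep_ts <- prediction_report(fit, X[9:12, ], y[9:12])
  yhat <- predict(fit, X[9:12, ])
  expect_equal(rep_ts$q2_pred,
               1 - sum((yhat - y[9:12])^2) /
                 sum((y[9:12] - mean(y[1:8]))^2))
  expect_equal(rep_ts$aaep, mean(abs(yhat - y[9:12])))
})

test_that("coefficient maps invert the descriptor indexing", {
  ser <- make_aligned_series(8, 1, seed = 40)
  lat <- structure(list(origin = c(-3, -3, -3), spacing = 3,
                        dims = c(3L, 3L, 3L)), class = "mif_lattice")
  blocks <- compute_mif_series(ser$molecules, lat, "OH2")
  X <- assemble_X(blocks, "BOTH")
  keep <- apply(X, 2, sd) > 1e-8
  Xk <- mifqsar:::subset_columns(X, keep)
  y <- as.numeric(Xk %*% rnorm(ncol(Xk), 0, 0.1)) + 5
  fit <- qsar_pls(Xk, y, ncomp = 3)
  map <- coefficient_map(fit)
  expect_named(map, c("STE", "ELE"))
  # masked flatten of the map gives back the coefficient vector
  idx <- attr(Xk, "field_index")
  d <- lat$dims
  lin <- 1L + idx$ix + d[1] * (idx$iy + d[2] * idx$iz)
  flat <- ifelse(idx$kind == "STE", map$STE[lin], map$ELE[lin])
  expect_equal(flat, unname(coef(fit)))
  # STE-only model yields exactly one grid
  Xs <- mifqsar:::subset_columns(X, keep & attr(X, "field_index")$kind == "STE")
  fit_s <- qsar_pls(Xs, y, ncomp = 2)
  expect_named(coefficient_map(fit_s), "STE")
})

test_that("a weight planted on one grid point dominates its map", {
  ser <- make_aligned_series(12, 1, seed = 41)
  pa <- plant_activity(ser, weight_sparsity = 1, noise_sd = 0, seed = 42)
  pt <- pretreat(pa$X)
  fit <- qsar_pls(pt$X, pa$activities,
                  ncomp = min(3, ncol(pt$X)))
  map <- coefficient_map(fit)
  idx <- attr(pa$X, "field_index")
  j <- pa$columns[1]
  d <- pa$lattice$dims
  lin <- 1L + idx$ix[j] + d[1] * (idx$iy[j] + d[2] * idx$iz[j])
  kind <- idx$kind[j]
  expect_equal(sign(map[[kind]][lin]), sign(pa$weights[j]))
})
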