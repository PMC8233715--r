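test_that("a single latent factor fits an exactly one-dimensional target", {
  fx <- latent_fixture(n = 25, p = 12, rank = 1, noise = 0)
  m <- fit_pls(fx$X, fx$y, 1)
  pred <- predict(m, fx$X)
  expect_lt(max(abs(pred - fx$y)), 1e-9)
  expect_equal(r_squared(fx$y, pred), 1, tolerance = 1e-12)
})

test_that("full-rank PLS reproduces the least-squares oracle", {
  set.seed(11)
  n <- 20; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  m <- fit_pls(X, y, p)  # F = rank of centered X (p < n-1)
  # independent oracle: normal equations on centered data
  Xc <- scale(X, scale = FALSE)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  pred_ols <- mean(y) + Xc %*% b_ols
  expect_equal(predict(m, X), as.vector(pred_ols), tolerance = 1e-6)
})

test_that("fitting is invariant to sample order and linear in new spectra", {
  fx <- latent_fixture(n = 30, p = 10, rank = 3, noise = 0.1)
  m <- fit_pls(fx$X, fx$y, 4)
  perm <- sample(nrow(fx$X))
  m2 <- fit_pls(fx$X[perm, ], fx$y[perm], 4)
  expect_equal(m$b, m2$b, tolerance = 1e-10)
  # centering identity: the calibration mean spectrum predicts y_mean
  expect_equal(predict(m, colMeans(fx$X)), mean(fx$y), tolerance = 1e-10)
  # affinity in X
  x1 <- fx$X[1, ]; x2 <- fx$X[2, ]; a <- 0.3
  expect_equal(predict(m, a * x1 + (1 - a) * x2),
               a * predict(m, x1) + (1 - a) * predict(m, x2),
               tolerance = 1e-10)
  # unit equivariance in y
  m_kg <- fit_pls(fx$X, fx$y * 1000, 4)
  expect_equal(predict(m_kg, fx$X), 1000 * predict(m, fx$X),
               tolerance = 1e-8)
})

test_that("NIPALS scores are orthogonal and deflation shrinks X", {
  fx <- latent_fixture(n = 30, p = 12, rank = 4, noise = 0.2)
  m <- fit_pls(fx$X, fx$y, 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # coefficient identity: b reproduces factor-wise predictions
  Xc <- sweep(fx$X, 2, m$x_mean)
  expect_equal(as.vector(Xc %*% m$b) + m$y_mean, predict(m, fx$X),
               tolerance = 1e-8)
  # calibration R2 is non-decreasing in the number of factors
  r2 <- vapply(1:6, function(k)
    r_squared(fx$y, predict(m, fx$X, n_factors = k)), numeric(1))
  expect_true(all(diff(r2) > -1e-10))
})

test_that("parameter recovery: high-SNR linear spectra return the true direction", {
  set.seed(12)
  n <- 80; p <- 60
  b_true <- sin(seq(0, 3 * pi, length.out = p))
  X <- matrix(rnorm(n * p), n, p)
  y_clean <- X %*% b_true
  y <- y_clean + rnorm(n, 0, sd(y_clean) / 100)  # SNR 100
  m <- fit_pls(X, y, 15)
  expect_gt(cor(m$b, b_true), 0.99)
})

test_that("cross-validated factor selection finds the latent rank", {
  fx <- latent_fixture(n = 60, p = 20, rank = 2, noise = 0)
  f <- select_factors(fx$X, fx$y, F_max = 10, folds = 10, seed = 3)
  expect_equal(as.integer(f), 2)
  expect_identical(f, select_factors(fx$X, fx$y, 10, 10, seed = 3))
  # pure-noise target: the parsimonious one-factor model is selected
  set.seed(13)
  Xn <- matrix(rnorm(60 * 20), 60, 20)
  yn <- rnorm(60)
  expect_equal(as.integer(select_factors(Xn, yn, 10, 10, seed = 3)), 1)
})

test_that("Hotelling H is zero at the centroid with the stated mean identity", {
  fx <- latent_fixture(n = 24, p = 10, rank = 3, noise = 0.3)
  m <- fit_pls(fx$X, fx$y, 3)
  h0 <- hotelling_h(m, matrix(m$x_mean, 1))
  expect_equal(h0$H, 0, tolerance = 1e-12)
  h <- hotelling_h(m, fx$X)
  n <- nrow(fx$X)
  expect_equal(mean(h$H), 3 * (n - 1) / n, tolerance = 1e-8)
  expect_identical(h$outlier, h$H > 10)
  # brute-force oracle on a small instance: standardized score distance
  Tn <- sweep(fx$X, 2, m$x_mean) %*% m$proj
  H_oracle <- vapply(seq_len(n), function(i)
    sum(Tn[i, ]^2 / apply(m$scores, 2, var)), numeric(1))
  expect_equal(h$H, H_oracle, tolerance = 1e-10)
})

test_that("outlier removal drops gross artifacts and reduces SEC", {
  fx <- latent_fixture(n = 40, p = 12, rank = 2, noise = 0.05)
  # with a threshold no sample exceeds, the refit is the plain fit
  h_all <- hotelling_h(fit_pls(fx$X, fx$y, 2), fx$X)
  thr <- max(h_all$H) + 1
  clean <- remove_outliers_refit(fx$X, fx$y, 2, threshold = thr)
  expect_length(clean$removed, 0)
  expect_equal(clean$model$b, fit_pls(fx$X, fx$y, 2)$b)
  X_bad <- fx$X
  X_bad[5, ] <- X_bad[5, ] * 50  # gross spectral artifact
  res <- remove_outliers_refit(X_bad, fx$y, 2, threshold = 10)
  expect_true(5 %in% res$removed)
  keep <- setdiff(seq_len(40), res$removed)
  sec_after <- sec(fx$y[keep], predict(res$model, X_bad[keep, ]), 2)
  m_dirty <- fit_pls(X_bad, fx$y, 2)
  sec_before <- sec(fx$y, predict(m_dirty, X_bad), 2)
  expect_lt(sec_after, sec_before)
  # refusal path: removal may not leave too few samples
  fx2 <- latent_fixture(n = 6, p = 5, rank = 2, noise = 0.01, seed = 5)
  expect_warning(r2 <- remove_outliers_refit(fx2$X, fx2$y, 3,
                                             threshold = 0.5),
                 "too few")
  expect_length(r2$removed, 0)
})

test_that("JSON serialization round-trips predictions", {
  fx <- latent_fixture(n = 30, p = 10, rank = 2, noise = 0.1)
  m <- fit_pls(fx$X, fx$y, 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_pls_model(m, path, chain_spec = "Offset|SNV", grid = tiny_grid(10))
  back <- load_pls_model(path)
  expect_equal(predict(back$model, fx$X), predict(m, fx$X),
               tolerance = 1e-12)
  expect_identical(back$chain_spec, "Offset|SNV")
  expect_equal(wavelengths(back$grid), wavelengths(tiny_grid(10)))
})

test_that("degenerate inputs are rejected", {
  fx <- latent_fixture()
  expect_error(fit_pls(fx$X, rep(1, nrow(fx$X)), 2), "zero variance")
  expect_error(fit_pls(fx$X, fx$y, nrow(fx$X)), "exceeds")
  m <- fit_pls(fx$X, fx$y, 2)
  expect_error(predict(m, fx$X[, 1:5]), "mismatch")
})
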