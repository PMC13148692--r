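test_that("SIMPLS reproduces least squares at full rank", {
  set.seed(3)
  Z <- matrix(rnorm(10 * 3), 10, 3)
  Y <- rnorm(10)
  fit <- simpls_fit(Z, Y, 3)
  ols <- unname(coef(lm(Y ~ Z)))
  expect_equal(fit$coef, ols[-1], tolerance = 1e-8)
  expect_equal(fit$intercept, ols[1], tolerance = 1e-8)
  # scores mutually orthogonal
  TT <- crossprod(fit$T)
  expect_equal(max(abs(TT - diag(diag(TT)))), 0, tolerance = 1e-8)
  # loadings unit-norm
  expect_equal(colSums(fit$A^2), rep(1, ncol(fit$A)), tolerance = 1e-10)
  # univariate collapse: K = 1, p = 1 gives the simple regression slope
  z1 <- matrix(rnorm(15), 15, 1); y1 <- 2 * z1[, 1] + rnorm(15)
  f1 <- simpls_fit(z1, y1, 1)
  expect_equal(f1$coef, unname(coef(lm(y1 ~ z1))[2]), tolerance = 1e-10)
})

test_that("sparse PLS interpolates between dense PLS and single-variable fits", {
  set.seed(4)
  Z <- matrix(rnorm(12 * 6), 12, 6)
  Y <- rnorm(12)
  dense <- simpls_fit(Z, Y, 3)
  expect_equal(spls_fit(Z, Y, 3, 0)$coef, dense$coef, tolerance = 1e-12)
  # lambda near 1: at most one survivor per component
  s99 <- spls_fit(Z, Y, 3, 0.999)
  expect_lte(length(s99$active), 3)
  # planted signal: only variable 1 correlates with Y
  Zp <- matrix(rnorm(20 * 5), 20, 5)
  Yp <- 2 * Zp[, 1] + rnorm(20, 0, 0.05)
  sp <- spls_fit(Zp, Yp, 1, 0.8)
  expect_identical(sp$active, 1L)
  expect_equal(which(sp$coef != 0), 1L)
})

test_that("first-component active sets are nested along the sparsity path", {
  set.seed(6)
  Z <- matrix(rnorm(15 * 10), 15, 10)
  Y <- rnorm(15)
  lams <- seq(0.1, 0.95, by = 0.05)
  acts <- lapply(lams, function(l) spls_fit(Z, Y, 1, l)$active)
  for (i in seq_along(lams)[-1]) {
    expect_true(all(acts[[i]] %in% acts[[i - 1]]))
  }
})

test_that("association measure converts coefficients to per-doubling factors", {
  expect_equal(association_percent(1.338), 33.8)
  am <- association_measure(c(0, 1, -1))
  expect_equal(am$factor, c(1, 2, 0.5))
  expect_equal(am$percent, c(0, 100, -50))
})

test_that("fit summaries agree with a direct sums-of-squares computation", {
  td <- toy_model_data(n = 12, p = 4, beta1 = 1.5, sigma = 0.3, seed = 8)
  mm <- build_model_matrices(td$y, td$z, td$quarters)
  fit <- simpls_fit(mm$v, mm$u, 2)
  sm <- fit_summary(fit, mm)
  u_hat <- drop(mm$v %*% fit$coef) + fit$intercept
  y_hat <- mm$g_y * exp(u_hat)
  r2o <- 1 - sum((mm$y - y_hat)^2) / sum((mm$y - mean(mm$y))^2)
  expect_equal(sm$r2_orig, r2o, tolerance = 1e-10)
  n <- 12; K <- sm$K
  expect_equal(sm$r2_orig_adj, 1 - (1 - r2o) * (n - 1) / (n - 1 - K),
               tolerance = 1e-10)
  # a perfect (noiseless, saturated) fit scores one on both scales
  td0 <- toy_model_data(n = 12, p = 2, beta1 = 1, sigma = 0, seed = 9)
  mm0 <- build_model_matrices(td0$y, td0$z, td0$quarters)
  f0 <- simpls_fit(mm0$v, mm0$u, 2)
  sm0 <- fit_summary(f0, mm0)
  expect_equal(sm0$r2_log, 1, tolerance = 1e-8)
  expect_equal(sm0$r2_orig, 1, tolerance = 1e-8)
  expect_error(fit_summary(fit, within(mm, {u <- u[1:3]; v <- v[1:3, ]; y <- y[1:3]; g_y <- g_y[1:3]})),
               "too few")
})

test_that("density predictions round-trip the generative model when noiseless", {
  td <- toy_model_data(n = 16, p = 3, beta1 = 1.2, sigma = 0, seed = 10)
  mm <- build_model_matrices(td$y, td$z, td$quarters)
  fit <- simpls_fit(mm$v, mm$u, 3)
  pred <- predict_density(fit, mm$v, mm$g_y)
  expect_equal(unname(pred), mm$y, tolerance = 1e-6)
  # zero coefficients predict the seasonal mean exactly
  null_fit <- fit
  null_fit$coef <- rep(0, length(fit$coef)); null_fit$intercept <- 0
  expect_equal(unname(predict_density(null_fit, mm$v, mm$g_y)), mm$g_y)
  expect_error(predict_density(fit, mm$v[, 1:2], mm$g_y), "do not match")
})

test_that("prediction is equivariant to relabelling ASVs", {
  td <- toy_model_data(n = 12, p = 5, beta1 = 1, sigma = 0.1, seed = 12)
  mm <- build_model_matrices(td$y, td$z, td$quarters)
  fit <- simpls_fit(mm$v, mm$u, 2)
  perm <- c(3, 1, 5, 2, 4)
  fit_p <- simpls_fit(mm$v[, perm], mm$u, 2)
  pred <- predict_density(fit, mm$v, mm$g_y)
  pred_p <- predict_density(fit_p, mm$v[, perm], mm$g_y)
  expect_equal(pred, pred_p, tolerance = 1e-10)
})
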