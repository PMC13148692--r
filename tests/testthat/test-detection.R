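test_that("uniform-key likelihood and AIC follow their closed forms", {
  x <- c(100, 900, 1700)
  fit <- fit_detection_function(x, w = 2400, key = "uniform")
  expect_equal(fit$logLik, -3 * log(2400))
  expect_equal(fit$AIC, 2 * 0 - 2 * fit$logLik)
  expect_equal(fit$p_hat, rep(1, 3))
  expect_equal(average_detection_probability(fit), 1)
  # AIC definition holds with free parameters too
  set.seed(41)
  hn <- fit_detection_function(r_halfnormal_distances(80, 1000, 2400),
                               w = 2400, key = "half-normal")
  expect_equal(hn$AIC, 2 * hn$df - 2 * hn$logLik)
  expect_equal(hn$df, 1L)
  expect_error(fit_detection_function(numeric(0), 2400), "no sightings")
})

test_that("half-normal scale is recovered from simulated distances", {
  set.seed(42)
  x <- r_halfnormal_distances(500, 1000, 2400)
  fit <- fit_detection_function(x, w = 2400, key = "half-normal")
  sig_hat <- exp(fit$par[1])
  se_sig <- sig_hat * sqrt(fit$vcov[1, 1])  # delta method from log scale
  expect_lt(abs(sig_hat - 1000), 3 * se_sig)
  expect_true(fit$converged)
})

test_that("average detection probability matches the half-normal closed form", {
  set.seed(43)
  x <- r_halfnormal_distances(200, 900, 2400)
  fit <- fit_detection_function(x, w = 2400, key = "half-normal")
  sig <- exp(fit$par[1])
  p_quad <- average_detection_probability(fit)
  # sqrt(pi/2) * (sigma/w) * erf(w / (sigma sqrt 2)), erf via pnorm
  p_closed <- sqrt(pi / 2) * (sig / 2400) * (2 * pnorm(2400 / sig) - 1)
  expect_equal(unname(p_quad[1]), p_closed, tolerance = 1e-6)
  # p_hat increases with the scale parameter
  p_wide <- average_detection_probability(fit, sigma = sig * 2)
  expect_gt(p_wide, p_quad[1])
  expect_true(all(fit$p_hat > 0 & fit$p_hat <= 1))
})

test_that("Cramer-von Mises statistic and p-value behave correctly", {
  # hand-evaluated 4-point example
  u <- c(0.1, 0.3, 0.6, 0.9)
  w2_hand <- 1 / 48 + sum((u - c(1, 3, 5, 7) / 8)^2)
  res <- cvm_gof(u)
  expect_equal(res$statistic, w2_hand)
  # perfectly uniform quantiles attain the minimum 1/(12n)
  n <- 10
  res_min <- cvm_gof((2 * (1:n) - 1) / (2 * n))
  expect_equal(res_min$statistic, 1 / (12 * n))
  # asymptotic distribution reproduces the classical critical values
  expect_equal(1 - whalecomp:::pcvm_asymptotic(0.461), 0.05, tolerance = 0.01)
  expect_equal(1 - whalecomp:::pcvm_asymptotic(0.743), 0.01, tolerance = 0.005)
  expect_error(cvm_gof(numeric(0)), "no fitted")
})

test_that("CvM p-values are calibrated", {
  # exact-null calibration: CDF values that truly are uniform give uniform
  # p-values from the asymptotic reference distribution
  set.seed(44)
  pv <- replicate(200, cvm_gof(runif(100))$p_value)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  # composite null (scale refitted per replicate) is conservative, never
  # anti-conservative: well-specified models are rarely rejected
  pv_fit <- replicate(40, {
    x <- r_halfnormal_distances(100, 1100, 2400)
    fit <- fit_detection_function(x, w = 2400, key = "half-normal")
    cvm_gof(fit)$p_value
  })
  expect_gt(mean(pv_fit > 0.05), 0.85)
})

test_that("forward AIC selection respects its acceptance contract", {
  set.seed(45)
  x <- r_halfnormal_distances(300, 1000, 2400)
  best <- select_detection_model(x, w = 2400)
  trace <- attr(best, "trace")
  expect_true(is.data.frame(trace) && nrow(trace) >= 3)
  # never returns a model beaten by a fitted candidate
  expect_lte(best$AIC, min(trace$AIC[trace$accepted], na.rm = TRUE))
  # rejected adjustment terms are recorded but not kept
  rej <- trace[!trace$accepted & is.finite(trace$AIC), , drop = FALSE]
  if (nrow(rej)) expect_true(all(rej$AIC >= best$AIC - 1e-9))
  # a half-normal family model should win on half-normal data
  expect_true(best$key %in% c("half-normal", "uniform"))
})

test_that("covariate models shift the scale parameter through the log link", {
  set.seed(46)
  n <- 400
  grp <- rep(c(0, 1), each = n / 2)
  sig <- ifelse(grp == 1, 1500, 700)
  x <- numeric(n)
  for (i in seq_len(n)) x[i] <- r_halfnormal_distances(1, sig[i], 2400)
  fit <- fit_detection_function(x, 2400, "half-normal",
                                covariates = data.frame(grp = grp))
  expect_true(fit$converged)
  # per-sighting sigma larger in the wide group
  expect_gt(mean(fit$sigma[grp == 1]), mean(fit$sigma[grp == 0]))
  expect_equal(fit$df, 2L)
})
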