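test_that("thresholded Jaccard counts recurring taxa over the union", {
  # direct-count example: a appears 3x, b and c once; threshold 1.5; union 3
  sets <- list(c("a", "b"), "a", c("a", "c"))
  expect_equal(thresholded_jaccard(sets, 0.5), 1 / 3)
  # identical non-empty sets are perfectly consistent
  expect_equal(thresholded_jaccard(list(c("x", "y"), c("x", "y")), 0.5), 1)
  # pairwise-disjoint singletons never recur
  expect_equal(thresholded_jaccard(list("a", "b", "c"), 0.5), 0)
  # all-empty is flagged undefined
  expect_warning(j <- thresholded_jaccard(list(character(0), character(0))),
                 "empty")
  expect_true(is.na(j))
})

test_that("the Jaccard index is non-increasing in the threshold", {
  set.seed(31)
  sets <- replicate(6, sample(letters[1:8], sample(2:5, 1)), simplify = FALSE)
  alphas <- seq(0.1, 1, by = 0.1)
  js <- vapply(alphas, function(a) thresholded_jaccard(sets, a), numeric(1))
  expect_true(all(diff(js) <= 1e-12))
})

test_that("naive baselines carry forward and average within quarters", {
  y <- c(2, 5, 7)          # three summers in chronological order
  q <- rep("summer", 3)
  expect_equal(naive_predictions(y, q, "lag")[3], 5)
  expect_equal(naive_predictions(y, q, "lag")[1], 5)  # nearest subsequent
  expect_equal(naive_predictions(c(1, 4, 2), rep("w", 3), "mean")[3], 2)
  # constant series: both baselines exact
  yc <- rep(3, 6); qc <- rep(c("w", "s"), 3)
  expect_equal(naive_predictions(yc, qc, "lag"), yc)
  expect_equal(naive_predictions(yc, qc, "mean"), yc)
  expect_error(naive_predictions(c(1, 2), c("w", "s"), "lag"), "quarter absent")
  # arithmetic-mean variant
  expect_equal(naive_predictions(c(1, 4, 7), rep("w", 3), "mean",
                                 mean_type = "arithmetic")[3], 2.5)
})

test_that("percent reduction follows its definition and scale invariance", {
  expect_equal(reduction_vs_baseline(1, 2), 50)
  expect_equal(reduction_vs_baseline(2, 2), 0)
  expect_equal(reduction_vs_baseline(0, 2), 100)
  expect_equal(reduction_vs_baseline(1 * 3.7, 2 * 3.7), 50)
  expect_error(reduction_vs_baseline(1, 0))
})

test_that("leave-one-out predictions match an arithmetic oracle", {
  td <- toy_model_data(n = 12, p = 4, beta1 = 1.5, sigma = 0.1, seed = 32)
  pr <- loo_predictions(td$y, td$z, td$quarters, selected = 1L, K = 1)
  m <- attr(pr, "metrics")
  expect_equal(m$rmspe_log, sqrt(mean((pr$u_obs - pr$u_pred)^2)),
               tolerance = 1e-12)
  expect_equal(m$rmspe_orig, sqrt(mean((pr$obs - pr$pred)^2)),
               tolerance = 1e-12)
  # constant series with an intercept-only model: zero error
  yc <- rep(2.5, 8)
  zc <- matrix(exp(rnorm(8 * 3, 0, 0.3)), 8, 3,
               dimnames = list(NULL, paste0("asv", 1:3)))
  qc <- rep(c("w", "s"), 4)
  prc <- loo_predictions(yc, zc, qc, selected = integer(0), K = 1)
  expect_equal(attr(prc, "metrics")$rmspe_orig, 0, tolerance = 1e-12)
})

test_that("noiseless synthetic predictions approach the truth", {
  td <- toy_model_data(n = 16, p = 3, beta1 = 1, sigma = 0, seed = 33)
  pr <- loo_predictions(td$y, td$z, td$quarters, selected = 1L, K = 1,
                        clamp = FALSE)
  expect_lt(attr(pr, "metrics")$rmspe_log, 1e-6)
  # range clamping only ever pulls predictions toward the training range
  prc <- loo_predictions(td$y, td$z, td$quarters, selected = 1L, K = 1)
  expect_true(all(prc$u_pred <= pmax(pr$u_pred, max(pr$u_obs)) + 1e-9))
})

test_that("outer validation yields one stable set per cruise, deterministically", {
  td <- toy_model_data(n = 12, p = 5, beta1 = 2.5, sigma = 0.2, seed = 34)
  sets <- outer_validation(td$y, td$z, td$quarters, K = 2,
                           lambda_grid = c(0.6, 0.8))
  expect_length(sets, 12)
  expect_length(attr(sets, "errors"), 0)
  sets2 <- outer_validation(td$y, td$z, td$quarters, K = 2,
                            lambda_grid = c(0.6, 0.8))
  expect_identical(lapply(sets, `[[`, "selected"),
                   lapply(sets2, `[[`, "selected"))
})

test_that("bootstrap intervals bracket the point prediction sensibly", {
  td <- toy_model_data(n = 12, p = 3, beta1 = 1, sigma = 0.2, seed = 35)
  set.seed(1)
  bi <- bootstrap_intervals(td$y, td$z, td$quarters, fold = 5, selected = 1L,
                            K = 1, B = 60, level = 0.9)
  expect_lte(bi$lower, bi$upper)
  expect_true(bi$pred >= 0)
  expect_error(bootstrap_intervals(td$y, td$z, td$quarters, 5, 1L, B = 10),
               "B >= 50")
  # degenerate training data give a degenerate interval
  yc <- rep(4, 9); qc <- rep(c("w", "s", "f"), 3)
  zc <- matrix(1, 9, 2, dimnames = list(NULL, c("a", "b")))
  set.seed(2)
  bic <- bootstrap_intervals(yc, zc, qc, fold = 1, selected = integer(0),
                             K = 1, B = 50)
  expect_equal(bic$lower, bic$upper, tolerance = 1e-8)
  expect_equal(bic$pred, 4, tolerance = 1e-8)
})

test_that("annotation overlap partitions labels by species multiplicity", {
  ov <- annotation_overlap(list(blue = c("a", "b", "c"), fin = c("a", "b"),
                                humpback = c("a", "d")))
  expect_equal(ov["all_three", "count"], 1)
  expect_equal(ov["exactly_two", "count"], 1)
  expect_equal(ov["unique", "count"], 2)
  members <- attr(ov, "members")
  expect_identical(members$all_three, "a")
  expect_identical(members$exactly_two, "b")
  expect_setequal(members$unique, c("c", "d"))
  # identical sets: all shared; disjoint sets: all unique
  same <- annotation_overlap(list(s1 = "x", s2 = "x", s3 = "x"))
  expect_equal(same["all_three", "percent"], 100)
  disj <- annotation_overlap(list(s1 = "x", s2 = "y", s3 = "z"))
  expect_equal(disj["unique", "percent"], 100)
})
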