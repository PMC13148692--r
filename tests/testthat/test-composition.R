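test_that("prevalence filtering keeps the interior band and drops the edges", {
  # 10 samples x 4 ASVs with prevalences 0%, 10%, 90%, 100%
  m <- cbind(a = rep(0L, 10),
             b = c(3L, rep(0L, 9)),
             c = c(rep(2L, 9), 0L),
             d = rep(5L, 10))
  res <- filter_prevalence(m, lo = 0.01, hi = 0.99)
  expect_identical(res$retained, c("b", "c"))

  # an ASV present in 5 of 743 samples (0.67%) falls under the default floor
  m2 <- cbind(rare = c(rep(1L, 5), rep(0L, 738)),
              mid = rep(c(1L, 0L), length.out = 743),
              base = rep(1L, 743))
  res2 <- filter_prevalence(m2)
  expect_false("rare" %in% res2$retained)
  expect_true("mid" %in% res2$retained)

  # interior prevalence always retained; empty result errors
  expect_error(filter_prevalence(cbind(x = rep(1L, 10))), "no candidates")
})

test_that("GBM zero imputation matches the closed-form replacement", {
  m <- rbind(s1 = c(0L, 5L, 5L), s2 = c(3L, 3L, 4L))
  colnames(m) <- c("a", "b", "c")
  out <- impute_zeros_gbm(m, s = 1, prior = c(1, 1, 1) / 3)
  # zero entry: t_j * s / (n + s) = (1/3) / 11 = 1/33; nonzero rescaled
  expect_equal(out["s1", "a"], 1 / 33)
  expect_equal(out["s1", "b"], 0.5 * (1 - 1 / 33))
  # a sample with no zeros passes through as raw proportions
  expect_equal(out["s2", ], c(a = 0.3, b = 0.3, c = 0.4))
})

test_that("imputed proportion matrices are strictly positive closed compositions", {
  set.seed(5)
  m <- matrix(rpois(200, 1.2), 20, 10)
  m[1, ] <- m[1, ] + 1L  # guard against a zero row
  keep <- colSums(m) > 0
  out <- impute_zeros_gbm(m[, keep, drop = FALSE])
  expect_true(all(out > 0))
  expect_equal(unname(rowSums(out)), rep(1, nrow(out)), tolerance = 1e-12)
  expect_error(impute_zeros_gbm(cbind(a = c(0L, 0L), b = c(2L, 3L))),
               "zero count in every sample")
})

test_that("aggregation weights follow inverse spatial density and close to one", {
  md <- data.frame(cruise = "c1", station = c("A", "A", "B"),
                   depth = "surface", stringsAsFactors = FALSE)
  w <- aggregation_weights(md)
  expect_equal(w, c(0.25, 0.25, 0.5))
  # single sample gets weight one
  expect_equal(aggregation_weights(data.frame(cruise = "c1", station = "A",
                                              depth = "DCM")), 1)
  # always positive, sum to one per cruise
  md2 <- data.frame(cruise = rep(c("c1", "c2"), c(3, 2)),
                    station = c("A", "A", "B", "C", "D"),
                    depth = c("surface", "DCM", "surface", "DCM", "surface"))
  pr <- matrix(runif(5 * 4, 0.01, 1), 5, 4)
  pr <- pr / rowSums(pr)
  w2 <- aggregation_weights(md2, pr)
  expect_true(all(w2 > 0))
  expect_equal(as.numeric(tapply(w2, md2$cruise, sum)), c(1, 1),
               tolerance = 1e-12)
})

test_that("cruise aggregation is a weighted geometric mean", {
  pr <- rbind(c(0.1, 0.9), c(0.4, 0.6))
  colnames(pr) <- c("a", "b")
  x <- aggregate_to_cruise(pr, c(0.5, 0.5), c("c1", "c1"))
  expect_equal(unname(x["c1", "a"]), sqrt(0.1 * 0.4))
  # degenerate weight returns the first sample; identical samples idempotent
  x2 <- aggregate_to_cruise(pr, c(1, 0), c("c1", "c1"))
  expect_equal(unname(x2["c1", ]), unname(pr[1, ]))
  x3 <- aggregate_to_cruise(pr[c(1, 1), ], c(0.3, 0.7), c("c1", "c1"))
  expect_equal(unname(x3["c1", ]), unname(pr[1, ]))
  expect_error(aggregate_to_cruise(rbind(c(0, 1)), 1, "c1"), "impute")
})

test_that("typical-abundance ratios center on the cruise geometric mean", {
  tr <- typical_ratio(c(0.1, 0.2, 0.4))
  expect_equal(tr$g, 0.2)
  expect_equal(tr$z, c(0.5, 1, 2))
  expect_equal(typical_ratio(rep(0.25, 4))$z, rep(1, 4))
  # CLR centering identity: per-cruise log z sums to zero
  set.seed(2)
  x <- matrix(runif(3 * 8, 0.01, 1), 3, 8)
  zz <- typical_ratio(x)
  expect_equal(rowSums(log(zz$z)), rep(0, 3), tolerance = 1e-10)
})

test_that("downstream ratios are invariant to per-sample count scaling", {
  # exact scale invariance on zero-free tables (imputation untouched)
  set.seed(9)
  m <- matrix(rpois(30 * 12, 4), 30, 12) + 1L
  md <- data.frame(cruise = rep(c("c1", "c2", "c3"), each = 10),
                   station = rep(sprintf("st%d", 1:5), 6),
                   depth = rep(c("surface", "DCM"), 15))
  a <- compose_cruises(m, md, lo = 0.05, hi = 1)
  b <- compose_cruises(m * 7L, md, lo = 0.05, hi = 1)
  expect_equal(a$z, b$z, tolerance = 1e-10)
})

test_that("imputation preserves ratios among a sample's observed parts", {
  set.seed(10)
  m <- matrix(rpois(20 * 8, 2), 20, 8)
  m[1, ] <- m[1, ] + 1L
  m <- m[, colSums(m) > 0, drop = FALSE]
  out <- impute_zeros_gbm(m)
  pr <- m / rowSums(m)
  for (i in 1:5) {
    obs <- which(m[i, ] > 0)
    if (length(obs) >= 2) {
      expect_equal(out[i, obs[1]] / out[i, obs[2]],
                   pr[i, obs[1]] / pr[i, obs[2]], tolerance = 1e-12)
    }
  }
})
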