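test_that("the survey design matches its configuration", {
  cfg <- sim_config(seed = 61, p_asvs = 20, driver_count = 2)
  d <- simulate_design(cfg)
  expect_equal(nrow(d$cruises), 25)
  nt <- table(d$effort$cruise)
  expect_true(all(nt >= 2 & nt <= 7))
  # two samples per station (one per depth)
  per_station <- table(paste(d$samples$cruise, d$samples$transect,
                             d$samples$station))
  expect_true(all(per_station == 2))
  # degenerate layout: one transect per cruise
  d1 <- simulate_design(sim_config(seed = 61, transect_range = c(1, 1),
                                   p_asvs = 5, driver_count = 0))
  expect_true(all(table(d1$effort$cruise) == 1))
  # a quarter represented in fewer than 2 years is an invalid design
  expect_error(simulate_design(sim_config(n_years = 2, n_cruises = 5,
                                          p_asvs = 5, driver_count = 0)),
               "fewer than 2 years")
})

test_that("generated datasets are deterministic in the seed", {
  a <- quick_sim(seed = 62, p_asvs = 40, driver_count = 2)
  b <- quick_sim(seed = 62, p_asvs = 40, driver_count = 2)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sightings, b$sightings)
  expect_identical(a$truth$beta, b$truth$beta)
  c2 <- quick_sim(seed = 63, p_asvs = 40, driver_count = 2)
  expect_false(identical(a$counts, c2$counts))
})

test_that("sample counts close to the library size", {
  ds <- quick_sim(seed = 64, p_asvs = 30, driver_count = 0,
                  library_size = 5000)
  expect_true(all(rowSums(ds$counts) == 5000))
})

test_that("the density generator follows the log-contrast structure exactly", {
  cfg <- sim_config(seed = 65, p_asvs = 60, driver_count = 3, sigma_eps = 0)
  design <- simulate_design(cfg)
  comp <- simulate_compositions(cfg, design)
  dens <- simulate_density(cfg, design, comp$anomalies)
  q <- design$cruises$quarter
  eff <- cfg$seasonal_density_effects
  # log(D / seasonal mean) equals the planted linear predictor when eps = 0
  lhs <- log(dens$true_density$D / (cfg$base_density * eff[q]))
  rhs <- drop(dens$v %*% dens$beta)
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  # least-squares on the planted anomalies recovers beta to machine precision
  fit <- lm(lhs ~ dens$v - 1)
  expect_equal(unname(coef(fit)), unname(dens$beta), tolerance = 1e-8)
  # doubling one driver's ratio multiplies density by 2^beta
  i <- 1
  v2 <- dens$v; v2[i, 1] <- v2[i, 1] + log(2)
  lhs2 <- drop(v2 %*% dens$beta)
  expect_equal(unname(exp(lhs2[i] - rhs[i])), unname(2^dens$beta[1]),
               tolerance = 1e-12)
})

test_that("a null configuration produces a flat deterministic series", {
  cfg <- sim_config(seed = 66, p_asvs = 30, driver_count = 0, sigma_eps = 0,
                    seasonal_density_effects = c(winter = 1, spring = 1,
                                                 summer = 1, fall = 1))
  ds <- generate_dataset(cfg)
  expect_equal(ds$truth$true_density$D, rep(cfg$base_density, 25),
               tolerance = 1e-12)
})

test_that("driver anomalies create excess between-cruise variance", {
  ds <- quick_sim(seed = 67, p_asvs = 200, driver_count = 5,
                  anomaly_sd = 0.7)
  comp <- compose_cruises(ds$counts, ds$metadata, lo = 1e-9, hi = 1)
  z <- comp$z[ds$design$cruises$cruise, ]
  lv <- log(z)
  vars <- apply(lv, 2, var)
  drv <- paste0("asv", ds$truth$drivers)
  expect_gt(median(vars[drv]), median(vars[setdiff(colnames(z), drv)]))
  # with no drivers there is no such excess (variance-ratio close to 1)
  ds0 <- quick_sim(seed = 67, p_asvs = 200, driver_count = 0)
  comp0 <- compose_cruises(ds0$counts, ds0$metadata, lo = 1e-9, hi = 1)
  v0 <- apply(log(comp0$z), 2, var)
  expect_lt(abs(log(median(v0) / median(vars[setdiff(colnames(z), drv)]))), 1)
})

test_that("zero density yields zero sightings and w must be positive", {
  cfg <- sim_config(seed = 68, p_asvs = 5, driver_count = 0)
  design <- simulate_design(cfg)
  td <- data.frame(cruise = design$cruises$cruise, D = 0)
  sgt <- simulate_sightings(cfg, design, td)
  expect_equal(nrow(sgt$sightings), 0)
  cfg_bad <- cfg; cfg_bad$truncation_w <- -5
  expect_error(simulate_sightings(cfg_bad, design, td), "positive")
})

test_that("uniform detection leaves observed distances uniform on [0, w]", {
  cfg <- sim_config(seed = 69, p_asvs = 5, driver_count = 0,
                    base_density = 60,
                    detection = list(key = "uniform", sigma = NULL, b = NULL,
                                     beaufort_effect = 0))
  design <- simulate_design(cfg)
  td <- data.frame(cruise = design$cruises$cruise, D = 60)
  sgt <- simulate_sightings(cfg, design, td)
  expect_gt(nrow(sgt$sightings), 500)
  ks <- ks.test(sgt$sightings$distance / cfg$truncation_w, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("half-normal acceptance shapes the observed distance distribution", {
  cfg <- sim_config(seed = 70, p_asvs = 5, driver_count = 0,
                    base_density = 120,
                    detection = list(key = "half-normal", sigma = 1200,
                                     b = NULL, beaufort_effect = 0))
  design <- simulate_design(cfg)
  td <- data.frame(cruise = design$cruises$cruise, D = 120)
  sgt <- simulate_sightings(cfg, design, td)
  x <- sgt$sightings$distance
  expect_gt(length(x), 800)
  # binned chi-square against the half-normal density on [0, w]
  br <- seq(0, 2400, length.out = 9)
  obs <- table(cut(x, br))
  pr <- diff(pnorm(br, 0, 1200)) / (pnorm(2400, 0, 1200) - 0.5)
  chi <- chisq.test(as.numeric(obs), p = pr / sum(pr))
  expect_gt(chi$p.value, 0.001)
})

test_that("empirical proportions converge to the latent composition", {
  cfg <- sim_config(seed = 71, n_cruises = 8, n_years = 2, p_asvs = 10,
                    driver_count = 0, library_size = 2e5)
  design <- simulate_design(cfg)
  comp <- simulate_compositions(cfg, design)
  pr <- comp$counts / rowSums(comp$counts)
  # multinomial noise at this depth is at most a few parts per thousand
  expect_lt(max(abs(pr - comp$latent)), 0.005)
})
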