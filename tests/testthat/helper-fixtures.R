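# Small fixtures built in code for unit tests.

# toy cruise-level ratio matrix with a planted predictor in column 1
toy_model_data <- function(n = 12, p = 6, beta1 = 1, sigma = 0, seed = 1) {
  set.seed(seed)
  quarters <- rep(c("winter", "spring", "summer", "fall"), length.out = n)
  lz <- matrix(rnorm(n * p, 0, 0.5), n, p,
               dimnames = list(sprintf("c%02d", 1:n), paste0("asv", 1:p)))
  z <- exp(lz)
  g_z <- apply(z, 2, function(col) {
    gm <- tapply(log(col), quarters, mean)
    exp(gm[quarters])
  })
  v1 <- log(z[, 1] / g_z[, 1])
  gy <- c(winter = 1, spring = 2, summer = 4, fall = 0.5)
  y <- gy[quarters] * exp(beta1 * v1 + rnorm(n, 0, sigma))
  list(y = unname(y), z = z, quarters = quarters, beta1 = beta1)
}

# sighting/effort tables for a two-transect cruise
toy_survey <- function(distances, sizes = rep(1, length(distances)),
                       cruise = "c01", transect = "t01", L = 100) {
  list(sightings = data.frame(cruise = cruise, transect = transect,
                              species = "sim", distance = distances,
                              size = sizes, stringsAsFactors = FALSE),
       effort = data.frame(cruise = unique(cruise), transect = unique(transect),
                           length = L, stringsAsFactors = FALSE))
}

# distances drawn from a half-normal detection process by rejection
r_halfnormal_distances <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, w)
    keep <- runif(2 * n) < exp(-x^2 / (2 * sigma^2))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

quick_sim <- function(seed = 1, ...) {
  generate_dataset(sim_config(seed = seed, ...))
}
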