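#' Configuration for the synthetic survey generator
#'
#' Bundles all parameters of the joint survey / sighting / ASV generator.
#' Defaults emulate the quarterly California Current survey design the
#' pipeline targets: 25 quarterly cruises over 7 years, 2-7 transects per
#' cruise with 2-4 stations each sampled at two depths (surface and deep
#' chlorophyll maximum), several hundred to several thousand candidate ASVs
#' with seasonal and spatial compositional structure, a small planted driver
#' subset linking community anomalies to whale density, sparse seasonal
#' sightings generated through a half-normal detection process truncated at
#' 2400 m, and mostly-singleton groups.
#'
#' @param n_years number of survey years (default 7).
#' @param quarters quarter labels cycled within each year.
#' @param n_cruises number of cruises kept, in chronological order (default
#'   25; the year-quarter grid is truncated to this count).
#' @param transect_range,station_range integer ranges for transects per
#'   cruise and stations per transect.
#' @param transect_length_range on-effort length per transect, km.
#' @param library_size sequencing reads per sample (default 50000).
#' @param p_asvs number of candidate ASVs (default 500).
#' @param driver_count number of planted driver ASVs (default 5).
#' @param beta_range range of absolute per-doubling coefficients for the
#'   drivers (signs random), default [1, 2].
#' @param anomaly_sd s.d. (natural-log scale) of per-cruise driver
#'   abundance anomalies, default 0.7 (about one doubling).
#' @param seasonal_density_effects named per-quarter multiplicative density
#'   factors.
#' @param base_density baseline density, individuals per 1000 km^2.
#' @param sigma_eps residual s.d. of the log density anomaly (default 0.2).
#' @param detection list with \code{key}, \code{sigma} (m), optional
#'   \code{b} (hazard-rate shape) and \code{beaufort_effect} on log sigma.
#' @param truncation_w truncation distance, m (default 2400).
#' @param mean_group_size target mean of the zero-truncated Poisson group
#'   size (default 1.2, mostly singletons).
#' @param seed integer seed; all randomness flows through it, with
#'   per-component substreams derived deterministically.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_years = 7,
                       quarters = c("winter", "spring", "summer", "fall"),
                       n_cruises = 25,
                       transect_range = c(2, 7),
                       station_range = c(2, 4),
                       transect_length_range = c(150, 350),
                       library_size = 50000,
                       p_asvs = 500,
                       driver_count = 5,
                       beta_range = c(1, 2),
                       anomaly_sd = 0.7,
                       seasonal_density_effects = c(winter = 0.3, spring = 0.8,
                                                    summer = 2.5, fall = 0.6),
                       base_density = 2,
                       sigma_eps = 0.2,
                       detection = list(key = "half-normal", sigma = 1200,
                                        b = NULL, beaufort_effect = 0),
                       truncation_w = 2400,
                       mean_group_size = 1.2,
                       seed = 1) {
  cfg <- list(n_years = n_years, quarters = quarters, n_cruises = n_cruises,
              transect_range = transect_range, station_range = station_range,
              transect_length_range = transect_length_range,
              library_size = library_size, p_asvs = p_asvs,
              driver_count = driver_count, beta_range = beta_range,
              anomaly_sd = anomaly_sd,
              seasonal_density_effects = seasonal_density_effects,
              base_density = base_density, sigma_eps = sigma_eps,
              detection = detection, truncation_w = truncation_w,
              mean_group_size = mean_group_size, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$p_asvs >= cfg$driver_count, cfg$driver_count >= 0,
            cfg$library_size > 0, cfg$truncation_w > 0,
            cfg$n_cruises >= 1, cfg$sigma_eps >= 0, cfg$anomaly_sd >= 0)
  if (!all(names(cfg$seasonal_density_effects) %in% cfg$quarters) &&
      !is.null(names(cfg$seasonal_density_effects))) {
    stop("seasonal_density_effects must be named by quarter")
  }
  invisible(cfg)
}

# Drivers are planted among ASVs in the intermittent-prevalence band:
# expected per-sample count (from the baseline field alone) between 0.5 and
# 3 reads, i.e. detectable in many samples but absent from others. Taxa in
# this band survive both sides of the prevalence filter and are the kind
# whose between-cruise variation can carry a density signal; ubiquitous or
# near-absent taxa cannot.
sim_pick_drivers <- function(baseline, config) {
  if (config$driver_count == 0) return(integer(0))
  expected <- config$library_size * exp(baseline) / sum(exp(baseline))
  eligible <- which(expected >= 2 & expected <= 6)
  if (length(eligible) < config$driver_count) {
    eligible <- order(abs(log(expected) - log(3.5)))[
      seq_len(max(config$driver_count, 10))]
  }
  sort(sample(eligible, config$driver_count))
}

# deterministic per-component substreams from the master seed
sim_substreams <- function(seed, n = 5) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(2^30, n)
}

#' Simulate the survey layout
#'
#' One cruise per (year, quarter) cell in chronological order, truncated to
#' the configured cruise count; each cruise carries a random number of
#' transects with on-effort lengths, each transect a ladder of stations with
#' an onshore-offshore position in [0, 1], and each station two samples (one
#' per depth stratum). Quarter labels are assigned by configuration, not by
#' date, so labelling anomalies in real survey calendars are representable.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cruises} (cruise, year, quarter), \code{effort}
#'   (cruise, transect, length) and \code{samples} (sample, cruise,
#'   transect, station, depth, offshore).
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  grid <- expand.grid(quarter = config$quarters, year = seq_len(config$n_years),
                      stringsAsFactors = FALSE)[, c("year", "quarter")]
  grid <- grid[seq_len(min(nrow(grid), config$n_cruises)), , drop = FALSE]
  if (nrow(grid) < config$n_cruises) {
    stop("invalid design: fewer year-quarter cells than requested cruises")
  }
  yrs_per_q <- tapply(grid$year, grid$quarter, function(v) length(unique(v)))
  if (any(yrs_per_q < 2)) {
    stop("invalid design: quarter(s) represented in fewer than 2 years: ",
         paste(names(yrs_per_q)[yrs_per_q < 2], collapse = ", "))
  }
  set.seed(sim_substreams(config$seed)[1])
  cruises <- data.frame(cruise = sprintf("c%02d", seq_len(nrow(grid))),
                        year = grid$year, quarter = grid$quarter,
                        stringsAsFactors = FALSE)
  effort <- NULL
  samples <- NULL
  for (i in seq_len(nrow(cruises))) {
    nt <- sample(seq(config$transect_range[1], config$transect_range[2]), 1)
    lens <- stats::runif(nt, config$transect_length_range[1],
                         config$transect_length_range[2])
    effort <- rbind(effort, data.frame(cruise = cruises$cruise[i],
                                       transect = sprintf("t%02d", seq_len(nt)),
                                       length = lens, stringsAsFactors = FALSE))
    for (k in seq_len(nt)) {
      ns <- sample(seq(config$station_range[1], config$station_range[2]), 1)
      off <- (seq_len(ns) - 0.5) / ns
      for (l in seq_len(ns)) {
        samples <- rbind(samples, data.frame(
          cruise = cruises$cruise[i], transect = sprintf("t%02d", k),
          station = sprintf("st%02d_%02d", k, l),
          depth = c("surface", "DCM"), offshore = off[l],
          stringsAsFactors = FALSE))
      }
    }
  }
  samples$sample <- sprintf("s%04d", seq_len(nrow(samples)))
  list(cruises = cruises, effort = effort,
       samples = samples[, c("sample", "cruise", "transect", "station",
                             "depth", "offshore")])
}

#' Simulate sample-level ASV counts
#'
#' Logistic-normal composition model: each ASV has a latent log abundance
#' composed of a baseline, a quarter effect, an onshore-offshore gradient,
#' a depth effect, a per-cruise driver anomaly (driver ASVs only) and
#' per-sample Gaussian noise; sample proportions are the softmax of the
#' latent field and counts are multinomial draws of the library size, so
#' zeros arise naturally for rare ASVs.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design output of \code{\link{simulate_design}}.
#' @return list with \code{counts} (samples x ASVs integer matrix, rownames
#'   sample ids), \code{metadata} (the design's samples table),
#'   \code{drivers} (planted ASV indices), \code{anomalies} (cruises x
#'   drivers matrix of natural-log abundance anomalies) and \code{latent}
#'   (samples x ASVs latent proportions underlying the multinomial draws).
#' @export
simulate_compositions <- function(config, design) {
  set.seed(sim_substreams(config$seed)[2])
  p <- config$p_asvs
  smp <- design$samples
  n_s <- nrow(smp)
  cruises <- design$cruises$cruise
  qmap <- stats::setNames(design$cruises$quarter, cruises)
  baseline <- stats::rnorm(p, 0, 2)
  qeff <- matrix(stats::rnorm(length(config$quarters) * p, 0, 0.7),
                 nrow = length(config$quarters),
                 dimnames = list(config$quarters, NULL))
  slope <- stats::rnorm(p, 0, 0.5)
  depth_eff <- stats::rnorm(p, 0, 0.5)
  drivers <- sim_pick_drivers(baseline, config)
  anomalies <- matrix(0, length(cruises), length(drivers),
                      dimnames = list(cruises,
                                      if (length(drivers)) paste0("asv", drivers)))
  if (length(drivers)) {
    anomalies[] <- stats::rnorm(length(anomalies), 0, config$anomaly_sd)
  }
  counts <- matrix(0L, n_s, p,
                   dimnames = list(smp$sample, paste0("asv", seq_len(p))))
  latent <- matrix(NA_real_, n_s, p, dimnames = dimnames(counts))
  for (i in seq_len(n_s)) {
    cr <- smp$cruise[i]
    lat <- baseline + qeff[qmap[cr], ] + slope * smp$offshore[i] +
      depth_eff * (smp$depth[i] == "DCM") + stats::rnorm(p, 0, 0.3)
    if (length(drivers)) lat[drivers] <- lat[drivers] + anomalies[cr, ]
    pr <- exp(lat - max(lat))
    pr <- pr / sum(pr)
    latent[i, ] <- pr
    counts[i, ] <- stats::rmultinom(1, config$library_size, pr)[, 1]
  }
  list(counts = counts, metadata = smp, drivers = drivers,
       anomalies = anomalies, latent = latent)
}

#' Simulate per-cruise true density
#'
#' Generative counterpart of the seasonally adjusted log-contrast model:
#' \code{log(D_i / m_q(i)) = sum_j beta_j v_ij + eps_i}, where m_q is the
#' quarter's seasonal mean density, v_ij is driver j's seasonally centered
#' log abundance anomaly on cruise i, and eps ~ Normal(0, sigma_eps^2). A
#' doubling of a driver's anomaly ratio multiplies median density by
#' 2^beta_j.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design output of \code{\link{simulate_design}}.
#' @param anomalies cruises x drivers anomaly matrix from
#'   \code{\link{simulate_compositions}} (generated internally when NULL).
#' @return list with \code{true_density} (data.frame cruise, quarter, D),
#'   \code{beta} (per-driver coefficients), \code{drivers}, \code{v}
#'   (seasonally centered anomalies), \code{eps}, \code{seasonal_means}.
#' @export
simulate_density <- function(config, design, anomalies = NULL) {
  drivers <- integer(0)
  if (is.null(anomalies)) {
    comp_seed <- sim_substreams(config$seed)[2]
    set.seed(comp_seed)
    # reproduce only the driver layout and anomalies of the composition stream
    if (config$driver_count > 0) {
      # replay the composition stream far enough to recover the driver layout
      baseline <- stats::rnorm(config$p_asvs, 0, 2)
      invisible(stats::rnorm(length(config$quarters) * config$p_asvs, 0, 0.7))
      invisible(stats::rnorm(config$p_asvs, 0, 0.5))
      invisible(stats::rnorm(config$p_asvs, 0, 0.5))
      drivers <- sim_pick_drivers(baseline, config)
      anomalies <- matrix(stats::rnorm(nrow(design$cruises) * length(drivers),
                                       0, config$anomaly_sd),
                          nrow(design$cruises), length(drivers),
                          dimnames = list(design$cruises$cruise,
                                          paste0("asv", drivers)))
    } else {
      anomalies <- matrix(0, nrow(design$cruises), 0,
                          dimnames = list(design$cruises$cruise, NULL))
    }
  } else {
    drivers <- as.integer(sub("asv", "", colnames(anomalies)))
  }
  set.seed(sim_substreams(config$seed)[3])
  q <- design$cruises$quarter
  eff <- config$seasonal_density_effects
  if (is.null(names(eff))) names(eff) <- config$quarters
  seasonal_means <- config$base_density * eff[config$quarters]
  beta <- numeric(ncol(anomalies))
  if (length(beta)) {
    beta <- stats::runif(length(beta), config$beta_range[1], config$beta_range[2]) *
      sample(c(-1, 1), length(beta), replace = TRUE)
  }
  v <- anomalies
  if (ncol(v)) {
    for (qq in unique(q)) {
      idx <- q == qq
      v[idx, ] <- sweep(v[idx, , drop = FALSE], 2,
                        colMeans(v[idx, , drop = FALSE]))
    }
  }
  eps <- stats::rnorm(nrow(design$cruises), 0, config$sigma_eps)
  logD <- log(seasonal_means[q]) +
    (if (ncol(v)) drop(v %*% beta) else 0) + eps
  list(true_density = data.frame(cruise = design$cruises$cruise, quarter = q,
                                 D = exp(unname(logD)),
                                 stringsAsFactors = FALSE),
       beta = stats::setNames(beta, colnames(anomalies)),
       drivers = drivers, v = v, eps = eps,
       seasonal_means = seasonal_means[config$quarters])
}

# zero-truncated Poisson sampler with target mean m (solves for the
# underlying Poisson rate)
rztpois <- function(n, mean_target) {
  if (mean_target <= 1) return(rep(1L, n))
  mu <- stats::uniroot(function(m) m / (1 - exp(-m)) - mean_target,
                       c(1e-8, mean_target * 2 + 5))$root
  u <- stats::runif(n, stats::ppois(0, mu), 1)
  stats::qpois(u, mu)
}

#' Simulate line-transect sightings from true densities
#'
#' Groups are placed in each transect's surveyed strip as a Poisson process
#' with intensity matching the cruise's true density (converted through the
#' strip area 2 w L and the mean group size); each group draws a uniform
#' perpendicular distance on [0, w], sighting covariates and a
#' zero-truncated Poisson group size, and is detected with probability
#' g(x, z) under the configured key function (rejection sampling, so
#' accepted distances follow the key's shape). A cruise with zero density
#' yields zero sightings.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design output of \code{\link{simulate_design}}.
#' @param true_density data.frame (cruise, D) from
#'   \code{\link{simulate_density}}.
#' @return list with \code{sightings} (cruise, transect, species, distance,
#'   size, beaufort, swell, height) and \code{effort} (the design effort
#'   table).
#' @export
simulate_sightings <- function(config, design, true_density) {
  if (config$truncation_w <= 0) stop("truncation distance must be positive")
  set.seed(sim_substreams(config$seed)[4])
  w <- config$truncation_w
  det <- config$detection
  es <- if (config$mean_group_size <= 1) 1 else
    config$mean_group_size
  out <- NULL
  D <- stats::setNames(true_density$D, true_density$cruise)
  for (r in seq_len(nrow(design$effort))) {
    cr <- design$effort$cruise[r]
    L <- design$effort$length[r]
    lambda <- (D[cr] / 1000) * 2 * (w / 1000) * L / es
    n_grp <- stats::rpois(1, lambda)
    if (n_grp == 0) next
    x <- stats::runif(n_grp, 0, w)
    beaufort <- sample(0:5, n_grp, replace = TRUE,
                       prob = c(0.05, 0.15, 0.3, 0.3, 0.15, 0.05))
    swell <- round(stats::runif(n_grp, 0.3, 3), 1)
    height <- sample(c("low", "mid", "high"), n_grp, replace = TRUE)
    sizes <- rztpois(n_grp, config$mean_group_size)
    be <- if (is.null(det$beaufort_effect)) 0 else det$beaufort_effect
    sigma_g <- if (!is.null(det$sigma)) det$sigma * exp(be * beaufort) else NULL
    gx <- eval_detfun(x, w, det$key, sigma_g, det$b)
    keep <- stats::runif(n_grp) < gx
    if (!any(keep)) next
    out <- rbind(out, data.frame(
      cruise = cr, transect = design$effort$transect[r], species = "sim",
      distance = x[keep], size = sizes[keep], beaufort = beaufort[keep],
      swell = swell[keep], height = height[keep], stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(cruise = character(0), transect = character(0),
                      species = character(0), distance = numeric(0),
                      size = integer(0), beaufort = integer(0),
                      swell = numeric(0), height = character(0),
                      stringsAsFactors = FALSE)
  }
  list(sightings = out, effort = design$effort)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs the design, composition, density and sighting generators in order
#' on deterministic substreams of a single seed, and assembles the recorded
#' ground truth needed for parameter-recovery and null-calibration tests.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_dataset}: list with \code{design},
#'   \code{counts}, \code{metadata}, \code{sightings}, \code{effort} and
#'   \code{truth} (drivers, beta, true densities, seasonally centered
#'   anomalies, seasonal means, detection parameters).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  design <- simulate_design(config)
  comp <- simulate_compositions(config, design)
  dens <- simulate_density(config, design, comp$anomalies)
  sgt <- simulate_sightings(config, design, dens$true_density)
  structure(list(design = design, counts = comp$counts,
                 metadata = comp$metadata, sightings = sgt$sightings,
                 effort = sgt$effort,
                 truth = list(drivers = comp$drivers, beta = dens$beta,
                              true_density = dens$true_density,
                              v = dens$v, eps = dens$eps,
                              anomalies = comp$anomalies,
                              seasonal_means = dens$seasonal_means,
                              detection = config$detection,
                              truncation_w = config$truncation_w)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic survey dataset:", nrow(x$design$cruises), "cruises,",
      nrow(x$counts), "samples x", ncol(x$counts), "ASVs,",
      nrow(x$sightings), "sightings,", length(x$truth$drivers),
      "planted drivers\n")
  invisible(x)
}
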