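#' Per-cruise density from line-transect sightings
#'
#' Horvitz-Thompson-style density estimator for each cruise:
#' \code{y_i = 1 / (2 L_i w) * sum_g s_g / p_hat_g(z_g)}, where L_i is the
#' on-effort transect length on cruise i (km), w the truncation distance
#' (m), s_g the group size of detection g and p_hat_g its average detection
#' probability given covariates. Units are converted internally so the
#' result is individuals per 1000 km^2. Cruises in the effort table with no
#' detections get density exactly zero.
#'
#' @param sightings data.frame with columns \code{cruise}, \code{transect},
#'   \code{distance} (m) and \code{size}; must be the same table (same row
#'   order) the detection function was fitted to.
#' @param effort data.frame with columns \code{cruise}, \code{transect} and
#'   \code{length} (km).
#' @param fit fitted \code{detection_fit} (provides w and per-sighting
#'   p_hat).
#' @return object of class \code{density_series}: data.frame with columns
#'   \code{cruise}, \code{n} (detections), \code{individuals}, \code{y}
#'   (individuals per 1000 km^2).
#' @export
estimate_density <- function(sightings, effort, fit) {
  stopifnot(inherits(fit, "detection_fit"))
  w_km <- fit$w / 1000
  inside <- sightings$distance <= fit$w & sightings$distance >= 0
  s <- sightings[inside, , drop = FALSE]
  if (nrow(s) != fit$n) {
    stop("sightings do not match the fitted detection function (after truncation)")
  }
  p_hat <- fit$p_hat
  if (any(p_hat <= 0 | p_hat > 1 + 1e-8)) stop("invalid detection probabilities")
  L_by_cruise <- tapply(effort$length, effort$cruise, sum)
  cruises <- names(L_by_cruise)
  missing_eff <- setdiff(unique(as.character(s$cruise)), cruises)
  if (length(missing_eff)) {
    stop("missing effort for cruise(s) with sightings: ",
         paste(missing_eff, collapse = ", "))
  }
  hts <- tapply(s$size / p_hat, as.character(s$cruise), sum)
  out <- data.frame(cruise = cruises,
                    n = as.integer(tapply(rep(1, nrow(s)), as.character(s$cruise),
                                          sum)[cruises]),
                    individuals = as.numeric(tapply(s$size, as.character(s$cruise),
                                                    sum)[cruises]),
                    y = NA_real_, stringsAsFactors = FALSE)
  out$n[is.na(out$n)] <- 0L
  out$individuals[is.na(out$individuals)] <- 0
  ht <- as.numeric(hts[cruises])
  ht[is.na(ht)] <- 0
  out$y <- 1000 * ht / (2 * as.numeric(L_by_cruise) * w_km)
  class(out) <- c("density_series", "data.frame")
  out
}

#' Variance components of per-cruise density estimates
#'
#' Combines two sources of uncertainty per cruise: (1) encounter-rate
#' variance between transect lines, via an effort-weighted between-transect
#' estimator of var(n/L), and (2) detection-function variance, via the delta
#' method applied to the detection-parameter MLEs (inverse observed
#' information). Squared coefficients of variation add:
#' \code{cv^2(y) = cv^2(encounter) + cv^2(detection)}. Cruises with a single
#' transect have no between-transect information; their encounter component
#' is flagged unavailable and the combined variance reports the detection
#' component only, with a warning.
#'
#' @inheritParams estimate_density
#' @return data.frame with columns \code{cruise}, \code{y}, \code{cv_er}
#'   (encounter-rate CV), \code{cv_det}, \code{cv}, \code{variance},
#'   \code{se}, \code{er_available}.
#' @export
density_variance <- function(sightings, effort, fit) {
  dens <- estimate_density(sightings, effort, fit)
  inside <- sightings$distance <= fit$w & sightings$distance >= 0
  s <- sightings[inside, , drop = FALSE]
  out <- data.frame(cruise = dens$cruise, y = dens$y, cv_er = NA_real_,
                    cv_det = NA_real_, cv = NA_real_, variance = NA_real_,
                    se = NA_real_, er_available = NA, stringsAsFactors = FALSE)
  single_transect <- character(0)
  for (i in seq_len(nrow(out))) {
    cr <- out$cruise[i]
    eff <- effort[as.character(effort$cruise) == cr, , drop = FALSE]
    Kt <- nrow(eff)
    L <- sum(eff$length)
    n_k <- vapply(as.character(eff$transect), function(tr)
      sum(s$size[as.character(s$cruise) == cr & as.character(s$transect) == tr]),
      numeric(1))
    n_tot <- sum(n_k)
    out$er_available[i] <- Kt >= 2
    if (out$y[i] == 0) {
      out[i, c("cv_er", "cv_det", "cv", "variance", "se")] <- 0
      next
    }
    if (Kt >= 2) {
      R <- n_tot / L
      var_R <- Kt / (L^2 * (Kt - 1)) * sum(eff$length * (n_k / eff$length - R)^2)
      out$cv_er[i] <- if (R > 0) sqrt(var_R) / R else 0
    } else {
      single_transect <- c(single_transect, cr)
    }
    out$cv_det[i] <- detection_cv(fit, s, cr)
    cv2 <- (if (is.na(out$cv_er[i])) 0 else out$cv_er[i]^2) + out$cv_det[i]^2
    out$cv[i] <- sqrt(cv2)
    out$variance[i] <- (out$cv[i] * out$y[i])^2
    out$se[i] <- sqrt(out$variance[i])
  }
  if (length(single_transect)) {
    warning("encounter-rate variance unavailable (single transect) for cruise(s): ",
            paste(single_transect, collapse = ", "),
            "; reporting detection component only")
  }
  out
}

# delta-method CV of sum_g s_g / p_hat_g over the detection parameters
detection_cv <- function(fit, s, cruise) {
  rows <- which(as.character(s$cruise) == cruise)
  if (!length(rows)) return(0)
  if (fit$df == 0 || any(!is.finite(fit$vcov))) return(0)
  ht <- function(par) {
    n_cov <- if (is.null(fit$X)) 0L else ncol(fit$X)
    pp <- unpack_pars(par, fit$key, n_cov, length(fit$adjustment))
    sigma <- if (!is.null(pp$lsig)) {
      if (n_cov > 0) exp(pp$lsig + drop(fit$X %*% pp$covb)) else
        rep(exp(pp$lsig), fit$n)
    } else NULL
    mu <- detfun_integral(fit$w, fit$key, sigma, pp$b, fit$adjustment, pp$alpha)
    if (length(mu) == 1) mu <- rep(mu, fit$n)
    sum(s$size[rows] / (mu[rows] / fit$w))
  }
  g0 <- ht(fit$par)
  if (g0 <= 0) return(0)
  h <- pmax(abs(fit$par), 1) * 1e-4
  grad <- vapply(seq_along(fit$par), function(j) {
    pp <- fit$par; pm <- fit$par
    pp[j] <- pp[j] + h[j]; pm[j] <- pm[j] - h[j]
    (ht(pp) - ht(pm)) / (2 * h[j])
  }, numeric(1))
  v <- drop(t(grad) %*% fit$vcov %*% grad)
  if (!is.finite(v) || v < 0) return(0)
  sqrt(v) / g0
}
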