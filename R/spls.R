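#' Build seasonally adjusted log-contrast model matrices
#'
#' Assembles the response and predictor matrices of the log-contrast model:
#' the response is \code{u_i = log(y_i / g(i,y))} and the predictors are
#' \code{v_ij = log(z_ij / g(i,z_j))}, with all seasonal geometric means
#' computed on the training partition only (no leakage from held-out
#' cruises). Zero densities are handled by the half-minimum offset rule of
#' \code{\link{zero_offset}}, with delta derived from the training cruises.
#'
#' @param y per-cruise density estimates (non-negative).
#' @param z cruises x ASVs matrix of typical-abundance ratios (positive).
#' @param quarters quarter label per cruise.
#' @param heldout integer or logical index of held-out cruises (empty for a
#'   full-data fit).
#' @param delta optional explicit zero-density offset.
#' @return list with \code{u} (response, all cruises), \code{v} (predictor
#'   matrix), \code{g_y}, \code{g_z} (training seasonal means per cruise),
#'   \code{train}, \code{heldout}, \code{delta}, \code{y} (offset response on
#'   the original scale), \code{quarters}.
#' @export
build_model_matrices <- function(y, z, quarters, heldout = integer(0),
                                 delta = NULL) {
  stopifnot(length(y) == nrow(z), length(quarters) == length(y))
  if (is.logical(heldout)) heldout <- which(heldout)
  n <- length(y)
  train <- setdiff(seq_len(n), heldout)
  off <- zero_offset(y, partition = train, delta = delta)
  y_off <- off$values
  g_y <- seasonal_geometric_means(y_off, quarters, partition = train)
  g_z <- seasonal_gm_matrix(z, quarters, train)
  u <- log(y_off / g_y)
  v <- log(z / g_z)
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("non-finite model matrix entries")
  list(u = u, v = v, g_y = g_y, g_z = g_z, train = train, heldout = heldout,
       delta = off$delta, y = y_off, quarters = quarters)
}

#' Partial least squares regression by SIMPLS
#'
#' Fits a univariate-response PLS regression with K latent components using
#' the SIMPLS algorithm: loadings are extracted sequentially to maximize
#' squared covariance with the response under a unit-norm constraint and a
#' predictor-covariance orthogonality constraint against previous components
#' (equivalently, scores are mutually orthogonal). Coefficients on the
#' original predictors are back-propagated as
#' \code{beta = A (T'T)^{-1} T'Y} with \code{T = Z A}.
#'
#' @param Z n x p predictor matrix.
#' @param Y response vector of length n.
#' @param K number of latent components, \code{K <= min(n - 1, p)}.
#' @param center logical; center columns of Z and Y internally (default
#'   TRUE). The intercept is recovered from the centering means.
#' @param tol relative tolerance for declaring a component degenerate; if a
#'   component degenerates the fit stops early and returns the achieved
#'   components.
#' @return object of class \code{simpls_fit}: loadings \code{A} (p x K_used,
#'   unit-norm columns), scores \code{T} (orthogonal), \code{coef},
#'   \code{intercept}, \code{fitted}, \code{residuals}, \code{K},
#'   \code{K_used}, centering means.
#' @export
simpls_fit <- function(Z, Y, K, center = TRUE, tol = 1e-12) {
  Z <- as.matrix(Z)
  Y <- as.numeric(Y)
  n <- nrow(Z); p <- ncol(Z)
  stopifnot(length(Y) == n, K >= 1)
  K <- min(K, n - 1L, p)
  z_mean <- if (center) colMeans(Z) else rep(0, p)
  y_mean <- if (center) mean(Y) else 0
  Zc <- sweep(Z, 2, z_mean)
  Yc <- Y - y_mean
  s <- drop(crossprod(Zc, Yc))
  s0 <- sqrt(sum(s^2))
  A <- matrix(0, p, K)
  Tm <- matrix(0, n, K)
  V <- matrix(0, p, K)
  k_used <- 0L
  for (k in seq_len(K)) {
    nr <- sqrt(sum(s^2))
    if (!is.finite(nr) || nr <= tol * max(s0, 1)) break
    a <- s / nr
    t_k <- drop(Zc %*% a)
    tt <- sum(t_k^2)
    if (tt <= tol * max(sum(Zc^2), 1)) break
    k_used <- k + 0L
    A[, k] <- a
    Tm[, k] <- t_k
    pl <- drop(crossprod(Zc, t_k)) / tt
    v <- pl
    if (k > 1) {
      for (j in seq_len(k - 1)) v <- v - V[, j] * sum(V[, j] * pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv <= tol) break
    v <- v / nv
    V[, k] <- v
    s <- s - v * sum(v * s)
  }
  if (k_used == 0L) {
    beta <- rep(0, p)
    A <- matrix(0, p, 0); Tm <- matrix(0, n, 0)
  } else {
    A <- A[, seq_len(k_used), drop = FALSE]
    Tm <- Tm[, seq_len(k_used), drop = FALSE]
    gam <- drop(crossprod(Tm, Yc)) / colSums(Tm^2)
    beta <- drop(A %*% gam)
  }
  intercept <- y_mean - sum(z_mean * beta)
  fitted <- drop(Z %*% beta) + intercept
  structure(list(A = A, T = Tm, coef = beta, intercept = intercept,
                 fitted = fitted, residuals = Y - fitted,
                 K = K, K_used = k_used, z_mean = z_mean, y_mean = y_mean,
                 var_names = colnames(Z)),
            class = "simpls_fit")
}

#' Sparse partial least squares via component-wise soft thresholding
#'
#' Sparse variant of \code{\link{simpls_fit}}. For each component the
#' direction surrogate (the current deflated covariance vector between
#' predictors and response) is soft-thresholded at \code{lambda} times its
#' largest absolute entry, shrinking small loadings exactly to zero. The
#' active set is the union of surviving variables across components; final
#' coefficients come from a dense SIMPLS refit restricted to the active set
#' (set \code{refit = FALSE} to use the sparse loadings directly).
#'
#' @inheritParams simpls_fit
#' @param lambda sparsity fraction in [0, 1): 0 reproduces SIMPLS; values
#'   near 1 keep only each component's dominant variable.
#' @param refit logical, refit a dense PLS on the active set (default TRUE).
#' @return object of class \code{spls_fit} (inherits \code{simpls_fit}) with
#'   additional fields \code{active} (integer indices), \code{lambda},
#'   \code{empty} (TRUE when no variable survives).
#' @export
spls_fit <- function(Z, Y, K, lambda, center = TRUE, refit = TRUE,
                     tol = 1e-12) {
  Z <- as.matrix(Z)
  Y <- as.numeric(Y)
  stopifnot(lambda >= 0, lambda < 1)
  n <- nrow(Z); p <- ncol(Z)
  K <- min(K, n - 1L, p)
  z_mean <- if (center) colMeans(Z) else rep(0, p)
  y_mean <- if (center) mean(Y) else 0
  Zc <- sweep(Z, 2, z_mean)
  Yc <- Y - y_mean
  s <- drop(crossprod(Zc, Yc))
  s0 <- sqrt(sum(s^2))
  V <- matrix(0, p, K)
  active <- logical(p)
  for (k in seq_len(K)) {
    nr <- sqrt(sum(s^2))
    if (!is.finite(nr) || nr <= tol * max(s0, 1)) break
    thr <- lambda * max(abs(s))
    r <- sign(s) * pmax(abs(s) - thr, 0)
    surv <- abs(s) > thr
    if (!any(surv)) break
    active <- active | surv
    a <- r / sqrt(sum(r^2))
    t_k <- drop(Zc %*% a)
    tt <- sum(t_k^2)
    if (tt <= tol * max(sum(Zc^2), 1)) break
    pl <- drop(crossprod(Zc, t_k)) / tt
    v <- pl
    if (k > 1) {
      for (j in seq_len(k - 1)) v <- v - V[, j] * sum(V[, j] * pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv <= tol) break
    V[, k] <- v / nv
    s <- s - V[, k] * sum(V[, k] * s)
  }
  act <- which(active)
  if (!length(act)) {
    fit <- list(A = matrix(0, p, 0), T = matrix(0, n, 0), coef = rep(0, p),
                intercept = y_mean, fitted = rep(y_mean, n),
                residuals = Y - y_mean, K = K, K_used = 0L,
                z_mean = z_mean, y_mean = y_mean, var_names = colnames(Z),
                active = integer(0), lambda = lambda, empty = TRUE)
    class(fit) <- c("spls_fit", "simpls_fit")
    return(fit)
  }
  kk <- min(K, length(act), n - 1L)
  sub <- simpls_fit(Z[, act, drop = FALSE], Y, kk, center = center, tol = tol)
  beta <- rep(0, p)
  beta[act] <- sub$coef
  A <- matrix(0, p, ncol(sub$A))
  A[act, ] <- sub$A
  fit <- list(A = A, T = sub$T, coef = beta, intercept = sub$intercept,
              fitted = sub$fitted, residuals = sub$residuals, K = K,
              K_used = sub$K_used, z_mean = z_mean, y_mean = y_mean,
              var_names = colnames(Z), active = act, lambda = lambda,
              empty = FALSE)
  class(fit) <- c("spls_fit", "simpls_fit")
  fit
}

#' @export
print.simpls_fit <- function(x, ...) {
  cat("PLS fit:", x$K_used, "of", x$K, "components;",
      sum(x$coef != 0), "nonzero coefficients\n")
  invisible(x)
}

#' Association measure per doubling of relative abundance
#'
#' Converts a log-contrast coefficient into the multiplicative change in
#' median seasonally adjusted density associated with a doubling of an ASV's
#' seasonally adjusted relative abundance: factor \code{2^beta} (log-ratio
#' elasticities are invariant to the logarithm base, so the natural-log model
#' coefficient is used directly as the per-doubling exponent), together with
#' the equivalent percent change.
#'
#' @param beta numeric vector of model coefficients.
#' @return data.frame with columns \code{beta}, \code{factor} (= 2^beta) and
#'   \code{percent} (= 100 * (factor - 1)).
#' @export
association_measure <- function(beta) {
  stopifnot(all(is.finite(beta)))
  f <- 2^beta
  data.frame(beta = beta, factor = f, percent = 100 * (f - 1))
}

#' Percent change implied by a reported association factor
#'
#' Inverse convenience of \code{\link{association_measure}}: a reported
#' multiplicative factor m per doubling corresponds to a
#' \code{100 * (m - 1)} percent change in median density.
#'
#' @param factor multiplicative association measure (e.g. 1.338).
#' @return percent change per doubling.
#' @export
association_percent <- function(factor) 100 * (factor - 1)

#' Fit summaries on the log-ratio and original density scales
#'
#' Adjusted R-squared of a fitted log-contrast model on the log-ratio scale
#' (response u vs fitted u-hat) and on the original density scale, where
#' fitted densities are reconstructed as \code{g(i,y) * exp(u_hat)}. The
#' adjustment uses the number of latent components as the model degrees of
#' freedom.
#'
#' @param fit a \code{simpls_fit}/\code{spls_fit} on the model matrices.
#' @param mm model matrices from \code{\link{build_model_matrices}}.
#' @return list with \code{r2_log}, \code{r2_log_adj}, \code{r2_orig},
#'   \code{r2_orig_adj}, \code{K}.
#' @export
fit_summary <- function(fit, mm) {
  n <- length(mm$u)
  K <- max(fit$K_used, 1L)
  if (n <= K + 1) stop("too few observations to adjust R-squared")
  u_hat <- drop(mm$v %*% fit$coef) + fit$intercept
  r2 <- function(obs, pred) {
    sse <- sum((obs - pred)^2)
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) return(if (sse == 0) 1 else 0)
    1 - sse / sst
  }
  adj <- function(r2v) 1 - (1 - r2v) * (n - 1) / (n - 1 - K)
  y_hat <- mm$g_y * exp(u_hat)
  r2l <- r2(mm$u, u_hat)
  r2o <- r2(mm$y, y_hat)
  list(r2_log = r2l, r2_log_adj = adj(r2l),
       r2_orig = r2o, r2_orig_adj = adj(r2o), K = K)
}

#' Predict density on the original scale
#'
#' Combines a fitted log-contrast model with (training-partition) seasonal
#' geometric means: \code{y_hat = g(i,y) * exp(b0 + sum_j beta_j v_ij)}.
#'
#' @param fit fitted \code{simpls_fit}/\code{spls_fit}.
#' @param v matrix (or vector) of seasonally adjusted log-ratio predictors
#'   with the same columns the model was fit on.
#' @param g_y seasonal geometric mean density per prediction row.
#' @return predicted densities on the original scale.
#' @export
predict_density <- function(fit, v, g_y) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) != length(fit$coef)) {
    stop("predictor columns do not match the fitted model")
  }
  if (!is.null(fit$var_names) && !is.null(colnames(v)) &&
      !identical(colnames(v), fit$var_names)) {
    if (!all(fit$var_names %in% colnames(v))) {
      stop("ASV present in model but missing in new data")
    }
    v <- v[, fit$var_names, drop = FALSE]
  }
  drop(g_y * exp(drop(v %*% fit$coef) + fit$intercept))
}
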