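#' Selection probabilities along a sparsity path
#'
#' Estimates, for every candidate ASV j and every sparsity value lambda on a
#' grid, the probability that sparse PLS selects that ASV:
#' \code{pi_j(lambda) = P(beta_j^lambda != 0)}. Probabilities are estimated
#' by exhaustive leave-one-out subsampling: for each of the n folds the
#' seasonal adjustments are recomputed on the n - 1 training cruises (so
#' held-out cruises never inform the seasonal averages), a sparse PLS model
#' is fit at every lambda, and the nonzero pattern is recorded. The
#' procedure is deterministic given the data and grids.
#'
#' @param y per-cruise densities (non-negative; zero-offset rule applied
#'   internally per fold).
#' @param z cruises x ASVs typical-abundance ratio matrix.
#' @param quarters quarter label per cruise.
#' @param lambda_grid sparsity grid; default 21 points on [0.5, 0.95].
#' @param K number of latent components for the sparse fits.
#' @param exclude optional cruises excluded from the whole procedure (used
#'   by the nested outer validation); folds then run over the remainder.
#' @param subsample \code{"loo"} (default): exhaustive leave-one-out folds,
#'   fully deterministic; or \code{"half"}: \code{B} random quarter-stratified
#'   half-subsamples, the scheme the per-family error-rate theory assumes.
#' @param B number of half-subsamples when \code{subsample = "half"}.
#' @param subsample_seed seed for the half-subsampling draws.
#' @return object of class \code{selection_path}: list with \code{pi}
#'   (p x n_lambda matrix of selection probabilities), \code{q} (mean
#'   active-set size per lambda), \code{lambda_grid}, \code{n_folds},
#'   \code{failed} (failed fold count), \code{p}.
#' @export
selection_probabilities <- function(y, z, quarters,
                                    lambda_grid = default_lambda_grid(),
                                    K = 4, exclude = integer(0),
                                    subsample = c("loo", "half"), B = 100,
                                    subsample_seed = 1) {
  subsample <- match.arg(subsample)
  n_all <- length(y)
  if (is.logical(exclude)) exclude <- which(exclude)
  avail <- setdiff(seq_len(n_all), exclude)
  if (length(avail) < 3) stop("need at least 3 cruises for leave-one-out folds")
  if (subsample == "loo") {
    heldout_sets <- lapply(avail, function(f) c(f, exclude))
  } else {
    qs <- as.character(quarters)
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(subsample_seed)
    heldout_sets <- lapply(seq_len(B), function(b) {
      keep <- unlist(lapply(split(avail, qs[avail]), function(ix)
        ix[sample.int(length(ix), max(1, floor(length(ix) / 2)))]),
        use.names = FALSE)
      c(setdiff(avail, keep), exclude)
    })
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  folds <- seq_along(heldout_sets)
  p <- ncol(z)
  nl <- length(lambda_grid)
  sel <- matrix(0, p, nl)
  qsum <- numeric(nl)
  ok <- 0L
  failures <- character(0)
  for (f in folds) {
    res <- tryCatch({
      mm <- build_model_matrices(y, z, quarters, heldout = heldout_sets[[f]])
      Zt <- mm$v[mm$train, , drop = FALSE]
      Yt <- mm$u[mm$train]
      ind <- matrix(FALSE, p, nl)
      qf <- numeric(nl)
      for (l in seq_len(nl)) {
        fit <- spls_fit(Zt, Yt, K, lambda_grid[l])
        nz <- fit$coef != 0
        ind[, l] <- nz
        qf[l] <- sum(nz)
      }
      list(ind = ind, q = qf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("fold %d: %s", f, conditionMessage(res)))
    } else {
      sel <- sel + res$ind
      qsum <- qsum + res$q
      ok <- ok + 1L
    }
  }
  if (ok < 0.9 * length(folds)) {
    stop("more than 10% of leave-one-out folds failed:\n",
         paste(failures, collapse = "\n"))
  }
  if (length(failures)) {
    warning(length(failures), " fold(s) dropped from selection probabilities")
  }
  structure(list(pi = sel / ok, q = qsum / ok, lambda_grid = lambda_grid,
                 n_folds = ok, failed = length(failures), p = p,
                 var_names = colnames(z)),
            class = "selection_path")
}

#' Default sparsity grid
#'
#' 21 equally spaced values on [0.5, 0.95].
#' @return numeric vector.
#' @export
default_lambda_grid <- function() seq(0.5, 0.95, length.out = 21)

#' Sparsity region controlling the per-family error rate
#'
#' Applies the stability-selection heuristic bounding the expected number of
#' falsely selected variables: a grid value lambda is admissible when
#' \code{q_lambda^2 / ((2 pi_max - 1) p) <= pfer}, where \code{q_lambda} is
#' the average active-set size at lambda and p the number of candidates. The
#' returned region is the interval of admissible grid points.
#'
#' @param path a \code{selection_path}.
#' @param pi_max selection-probability threshold (> 0.5), default 0.9.
#' @param pfer per-family error-rate bound, default 0.5.
#' @param strict logical; if TRUE (default) an empty region is an error with
#'   a diagnostic of the smallest attainable bound, if FALSE an empty region
#'   is returned as a zero-length vector.
#' @return numeric vector of admissible lambda values (possibly empty when
#'   \code{strict = FALSE}), with attribute \code{"bound"} giving the PFER
#'   bound per grid point.
#' @export
lambda_region_pfer <- function(path, pi_max = 0.9, pfer = 0.5, strict = TRUE) {
  stopifnot(inherits(path, "selection_path"), pi_max > 0.5)
  bound <- path$q^2 / ((2 * pi_max - 1) * path$p)
  adm <- which(bound <= pfer)
  if (!length(adm)) {
    if (strict) {
      stop(sprintf(
        "no admissible lambda: minimum attainable PFER bound is %.3g (level %.3g)",
        min(bound), pfer))
    }
    out <- numeric(0)
  } else {
    out <- path$lambda_grid[min(adm):max(adm)]
    # keep only the admissible points inside the containing interval
    out <- out[out %in% path$lambda_grid[adm]]
  }
  attr(out, "bound") <- bound
  out
}

#' Stable set of frequently selected ASVs
#'
#' Variables whose selection probability reaches \code{pi_max} for at least
#' one lambda in the region: \code{S = {j : max_{lambda in Lambda}
#' pi_j(lambda) >= pi_max}}.
#'
#' @param path a \code{selection_path}.
#' @param region lambda region from \code{\link{lambda_region_pfer}} (may be
#'   empty, giving an empty stable set).
#' @param pi_max selection-probability threshold, default 0.9.
#' @return object of class \code{stable_set}: list with \code{selected}
#'   (integer indices), \code{names}, \code{pi_max}, \code{region},
#'   \code{p}, \code{pi_profile} (max selection probability over the region,
#'   per selected variable).
#' @export
stable_set <- function(path, region, pi_max = 0.9) {
  stopifnot(inherits(path, "selection_path"))
  if (length(region)) {
    cols <- match(region, path$lambda_grid)
    if (anyNA(cols)) stop("region contains lambda values off the grid")
    pmax_j <- apply(path$pi[, cols, drop = FALSE], 1, max)
    sel <- which(pmax_j >= pi_max)
    prof <- pmax_j[sel]
  } else {
    sel <- integer(0)
    prof <- numeric(0)
  }
  structure(list(selected = sel,
                 names = if (!is.null(path$var_names)) path$var_names[sel] else NULL,
                 pi_max = pi_max, region = as.numeric(region), p = path$p,
                 pi_profile = prof),
            class = "stable_set")
}

#' @export
print.stable_set <- function(x, ...) {
  cat("Stable set:", length(x$selected), "of", x$p, "candidates (pi_max =",
      x$pi_max, ")\n")
  invisible(x)
}

#' One full stability-selection pass
#'
#' Convenience wrapper: selection probabilities over the lambda grid, PFER
#' region, and stable set, for fixed K.
#'
#' @inheritParams selection_probabilities
#' @inheritParams lambda_region_pfer
#' @return list with \code{path}, \code{region}, \code{set}.
#' @export
stability_selection <- function(y, z, quarters, K = 4,
                                lambda_grid = default_lambda_grid(),
                                pi_max = 0.9, pfer = 0.5,
                                exclude = integer(0),
                                subsample = c("loo", "half"), B = 100,
                                subsample_seed = 1) {
  path <- selection_probabilities(y, z, quarters, lambda_grid, K,
                                  exclude = exclude, subsample = subsample,
                                  B = B, subsample_seed = subsample_seed)
  region <- lambda_region_pfer(path, pi_max, pfer, strict = FALSE)
  set <- stable_set(path, region, pi_max)
  list(path = path, region = region, set = set)
}

#' Choose the number of latent components by leave-one-out MSPE
#'
#' For each K on the grid, runs the full stability-selection pass, fits a
#' dense SIMPLS model on the resulting stable set, and scores it by
#' leave-one-out mean squared prediction error on the log-ratio scale with
#' seasonal adjustments recomputed per fold. Returns the MSPE-minimizing K
#' (ties break toward the smaller K).
#'
#' @inheritParams stability_selection
#' @param K_grid candidate component counts, default 4:12.
#' @param mspe_scale scale on which leave-one-out prediction error is
#'   scored: \code{"log"} (default; the model's log-ratio scale) or
#'   \code{"original"} (density scale, where exponential back-transform
#'   overshoot is penalized more heavily).
#' @return list with \code{K} (selected), \code{mspe} (named per-K vector),
#'   \code{sets} (stable set per K).
#' @export
select_num_components <- function(y, z, quarters, K_grid = 4:12,
                                  lambda_grid = default_lambda_grid(),
                                  pi_max = 0.9, pfer = 0.5,
                                  exclude = integer(0),
                                  mspe_scale = c("log", "original")) {
  mspe_scale <- match.arg(mspe_scale)
  n_all <- length(y)
  if (is.logical(exclude)) exclude <- which(exclude)
  folds <- setdiff(seq_len(n_all), exclude)
  K_grid <- K_grid[K_grid >= 1 & K_grid <= length(folds) - 2]
  if (!length(K_grid)) stop("empty component grid after bounds check")
  mspe <- rep(NA_real_, length(K_grid))
  names(mspe) <- K_grid
  sets <- vector("list", length(K_grid))
  for (i in seq_along(K_grid)) {
    K <- K_grid[i]
    res <- tryCatch({
      ss <- stability_selection(y, z, quarters, K, lambda_grid, pi_max, pfer,
                                exclude = exclude)
      sel <- ss$set$selected
      err <- vapply(folds, function(f) {
        mm <- build_model_matrices(y, z, quarters, heldout = c(f, exclude))
        if (length(sel)) {
          kk <- min(K, length(sel), length(mm$train) - 1L)
          fit <- simpls_fit(mm$v[mm$train, sel, drop = FALSE],
                            mm$u[mm$train], kk)
          u_hat <- sum(mm$v[f, sel] * fit$coef) + fit$intercept
        } else {
          u_hat <- mean(mm$u[mm$train])
        }
        if (mspe_scale == "log") {
          (mm$u[f] - u_hat)^2
        } else {
          (mm$y[f] - mm$g_y[f] * exp(u_hat))^2
        }
      }, numeric(1))
      list(mspe = mean(err), set = ss$set)
    }, error = function(e) e)
    if (inherits(res, "error")) next
    mspe[i] <- res$mspe
    sets[[i]] <- res$set
  }
  if (all(is.na(mspe))) stop("stability selection failed for every K on the grid")
  best <- which(mspe == min(mspe, na.rm = TRUE))[1]
  list(K = K_grid[best], mspe = mspe, sets = sets, set = sets[[best]])
}
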