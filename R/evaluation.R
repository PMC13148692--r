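#' Outer leave-one-out validation of stability selection
#'
#' Repeats the entire stability-selection procedure n times, holding out one
#' cruise at a time; each pass runs its inner leave-one-out folds on the
#' remaining n - 1 cruises. The n resulting stable sets are compared for
#' consistency with \code{\link{thresholded_jaccard}}.
#'
#' @inheritParams stability_selection
#' @return list of \code{stable_set} objects, one per held-out cruise; folds
#'   that fail carry a \code{NULL} with the error message in
#'   \code{attr(,"errors")}.
#' @export
outer_validation <- function(y, z, quarters, K = 4,
                             lambda_grid = default_lambda_grid(),
                             pi_max = 0.9, pfer = 0.5) {
  n <- length(y)
  if (n < 3) stop("need at least 3 cruises")
  sets <- vector("list", n)
  errs <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(
      stability_selection(y, z, quarters, K, lambda_grid, pi_max, pfer,
                          exclude = i)$set,
      error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("fold %d: %s", i, conditionMessage(res)))
    } else {
      sets[[i]] <- res
    }
  }
  attr(sets, "errors") <- errs
  sets
}

#' Thresholded Jaccard consistency index
#'
#' Given n selected sets S_1..S_n, the fraction of the union that recurs in
#' at least a fraction alpha of the sets:
#' \code{J = #\{j : sum_i 1\{j in S_i\} >= n * alpha\} / #union}. Measures
#' how robust variable selection is to data perturbation.
#'
#' @param sets list of \code{stable_set} objects, or a list of vectors of
#'   selected identifiers.
#' @param alpha recurrence threshold in (0, 1], default 0.5.
#' @return J in [0, 1]; \code{NA} (with a warning) when every set is empty.
#' @export
thresholded_jaccard <- function(sets, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  ids <- lapply(sets, function(s) {
    if (is.null(s)) return(NULL)
    if (inherits(s, "stable_set")) {
      if (!is.null(s$names)) s$names else s$selected
    } else s
  })
  ids <- ids[!vapply(ids, is.null, logical(1))]
  n <- length(ids)
  if (n == 0) stop("no selected sets supplied")
  all_ids <- unlist(ids, use.names = FALSE)
  if (!length(all_ids)) {
    warning("all selected sets are empty; Jaccard index undefined")
    return(NA_real_)
  }
  counts <- table(unlist(lapply(ids, unique)))
  sum(counts >= n * alpha) / length(counts)
}

#' Leave-one-out density predictions
#'
#' Per held-out cruise: refit a dense SIMPLS model restricted to a stable
#' set on the remaining cruises (seasonal adjustments and zero-density
#' offsets recomputed from the training partition), then predict the
#' held-out cruise's density on the original scale via
#' \code{\link{predict_density}}. The stable set is either fixed (default,
#' the full-data stable set) or re-selected per fold by passing the sets
#' from \code{\link{outer_validation}}.
#'
#' @inheritParams stability_selection
#' @param selected integer indices of the stable set, or a list of per-fold
#'   \code{stable_set} objects for re-selection mode.
#' @param K number of latent components for the refits.
#' @param clamp logical (default TRUE): constrain each predicted log
#'   seasonal deviation to the range observed on the training cruises. The
#'   exponential back-transform to the density scale amplifies any
#'   extrapolation beyond the observed deviation range into unbounded
#'   overshoot, so out-of-range point predictions are truncated.
#' @return object of class \code{loo_predictions}: data.frame with columns
#'   \code{cruise}, \code{quarter}, \code{obs}, \code{pred} (original
#'   scale), \code{u_obs}, \code{u_pred} (log-ratio scale), plus attribute
#'   \code{metrics} with RMSPE and Pearson correlation on both scales.
#' @export
loo_predictions <- function(y, z, quarters, selected, K = 4, clamp = TRUE) {
  n <- length(y)
  per_fold <- is.list(selected) && !inherits(selected, "stable_set")
  out <- data.frame(cruise = seq_len(n), quarter = as.character(quarters),
                    obs = y, pred = NA_real_, u_obs = NA_real_,
                    u_pred = NA_real_)
  for (f in seq_len(n)) {
    sel <- if (per_fold) {
      s <- selected[[f]]
      if (inherits(s, "stable_set")) s$selected else s
    } else if (inherits(selected, "stable_set")) selected$selected else selected
    mm <- build_model_matrices(y, z, quarters, heldout = f)
    if (length(sel)) {
      kk <- min(K, length(sel), length(mm$train) - 1L)
      fit <- simpls_fit(mm$v[mm$train, sel, drop = FALSE], mm$u[mm$train], kk)
      u_hat <- sum(mm$v[f, sel] * fit$coef) + fit$intercept
    } else {
      u_hat <- mean(mm$u[mm$train])
    }
    if (clamp) {
      u_hat <- min(max(u_hat, min(mm$u[mm$train])), max(mm$u[mm$train]))
    }
    out$u_obs[f] <- mm$u[f]
    out$u_pred[f] <- u_hat
    out$pred[f] <- max(mm$g_y[f] * exp(u_hat) - mm$delta, 0)
  }
  attr(out, "metrics") <- prediction_metrics(out)
  class(out) <- c("loo_predictions", "data.frame")
  out
}

# RMSPE and correlation on log-ratio and original scales
prediction_metrics <- function(df) {
  list(rmspe_log = sqrt(mean((df$u_obs - df$u_pred)^2)),
       rmspe_orig = sqrt(mean((df$obs - df$pred)^2)),
       cor_log = suppressWarnings(stats::cor(df$u_obs, df$u_pred)),
       cor_orig = suppressWarnings(stats::cor(df$obs, df$pred)))
}

#' Naive baseline predictions
#'
#' Forecasting baselines used for context: the \code{"lag"} method carries
#' forward the chronologically nearest prior observation from the held-out
#' cruise's quarter among training cruises (nearest subsequent when no prior
#' exists); the \code{"mean"} method imputes the training-quarter seasonal
#' average (geometric by default, consistent with the pipeline's seasonal
#' means; arithmetic via \code{mean_type}). Cruises are assumed ordered
#' chronologically.
#'
#' @param y per-cruise densities.
#' @param quarters quarter labels.
#' @param method \code{"lag"} or \code{"mean"}.
#' @param mean_type \code{"geometric"} (default) or \code{"arithmetic"}.
#' @return numeric vector of leave-one-out baseline predictions.
#' @export
naive_predictions <- function(y, quarters, method = c("lag", "mean"),
                              mean_type = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  mean_type <- match.arg(mean_type)
  n <- length(y)
  quarters <- as.character(quarters)
  pred <- numeric(n)
  for (f in seq_len(n)) {
    train <- setdiff(seq_len(n), f)
    same_q <- train[quarters[train] == quarters[f]]
    if (!length(same_q)) stop("quarter absent from training partition")
    if (method == "lag") {
      prior <- same_q[same_q < f]
      pred[f] <- if (length(prior)) y[max(prior)] else y[min(same_q)]
    } else {
      if (mean_type == "arithmetic") {
        pred[f] <- mean(y[same_q])
      } else {
        off <- zero_offset(y, partition = train)
        pred[f] <- max(exp(mean(log(off$values[same_q]))) - off$delta, 0)
      }
    }
  }
  pred
}

#' Percent reduction in prediction error versus a baseline
#'
#' \code{100 * (baseline - model) / baseline}; positive values mean the
#' model predicts better than the baseline.
#'
#' @param model_rmspe model prediction error.
#' @param baseline_rmspe baseline prediction error (must be positive).
#' @return percent reduction.
#' @export
reduction_vs_baseline <- function(model_rmspe, baseline_rmspe) {
  stopifnot(baseline_rmspe > 0)
  100 * (baseline_rmspe - model_rmspe) / baseline_rmspe
}

#' Bootstrap percentile interval for a held-out prediction
#'
#' Quantifies prediction uncertainty for one held-out cruise: training
#' cruises are resampled with replacement within quarters (stratified, so no
#' quarter is emptied), the stable-set SIMPLS model is refit on each
#' resample, and the held-out cruise is re-predicted. The percentile
#' interval is formed on the log scale and back-transformed.
#'
#' @inheritParams loo_predictions
#' @param fold index of the held-out cruise.
#' @param selected integer indices of the (fixed) stable set.
#' @param B number of bootstrap resamples, default 200 (minimum 50).
#' @param level interval level, default 0.90.
#' @return list with \code{pred} (point prediction), \code{lower},
#'   \code{upper}, \code{level}, \code{B}.
#' @export
bootstrap_intervals <- function(y, z, quarters, fold, selected, K = 4,
                                B = 200, level = 0.90) {
  stopifnot(B >= 50, level > 0, level < 1)
  n <- length(y)
  quarters <- as.character(quarters)
  train <- setdiff(seq_len(n), fold)
  if (inherits(selected, "stable_set")) selected <- selected$selected
  point <- loo_one(y, z, quarters, fold, selected, K)
  by_q <- split(train, quarters[train])
  preds <- vapply(seq_len(B), function(b) {
    for (attempt in 1:100) {
      idx <- unlist(lapply(by_q, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      if (all(unique(quarters) %in% unique(c(quarters[idx], quarters[fold])))) break
      if (attempt == 100) stop("bootstrap resample kept emptying a quarter")
    }
    y2 <- c(y[idx], y[fold])
    z2 <- z[c(idx, fold), , drop = FALSE]
    q2 <- c(quarters[idx], quarters[fold])
    loo_one(y2, z2, q2, length(y2), selected, K)
  }, numeric(1))
  qs <- stats::quantile(log(preds + 1e-12), c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  list(pred = point, lower = exp(qs[1]) - 1e-12, upper = exp(qs[2]) - 1e-12,
       level = level, B = B)
}

# one train/predict cycle: fit on all but `fold`, predict `fold`; the log
# deviation is clamped to the training-observed range (see loo_predictions)
loo_one <- function(y, z, quarters, fold, selected, K, clamp = TRUE) {
  mm <- build_model_matrices(y, z, quarters, heldout = fold)
  if (length(selected)) {
    kk <- min(K, length(selected), length(mm$train) - 1L)
    fit <- simpls_fit(mm$v[mm$train, selected, drop = FALSE], mm$u[mm$train], kk)
    u_hat <- sum(mm$v[fold, selected] * fit$coef) + fit$intercept
  } else {
    u_hat <- mean(mm$u[mm$train])
  }
  if (clamp) {
    u_hat <- min(max(u_hat, min(mm$u[mm$train])), max(mm$u[mm$train]))
  }
  max(mm$g_y[fold] * exp(u_hat) - mm$delta, 0)
}

#' Cross-species overlap of taxonomic annotations
#'
#' Partitions the union of annotation labels selected by per-species models
#' into labels shared by all three species, by exactly two, and unique to
#' one, with counts and percentages.
#'
#' @param species_sets named list (length 3) of character vectors of
#'   annotation labels, one per species (union across markers).
#' @return data.frame with rows \code{all_three}, \code{exactly_two},
#'   \code{unique}, columns \code{count} and \code{percent}, plus attribute
#'   \code{"members"} listing the labels in each cell.
#' @export
annotation_overlap <- function(species_sets) {
  stopifnot(length(species_sets) == 3)
  sets <- lapply(species_sets, unique)
  all_labels <- unique(unlist(sets))
  member_count <- vapply(all_labels, function(l)
    sum(vapply(sets, function(s) l %in% s, logical(1))), numeric(1))
  groups <- list(all_three = all_labels[member_count == 3],
                 exactly_two = all_labels[member_count == 2],
                 unique = all_labels[member_count == 1])
  counts <- vapply(groups, length, numeric(1))
  out <- data.frame(count = counts,
                    percent = 100 * counts / max(length(all_labels), 1))
  rownames(out) <- names(groups)
  attr(out, "members") <- groups
  out
}
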