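#' Seasonal geometric means
#'
#' For each cruise i, the geometric mean of \code{values} over the index set
#' I(i) of cruises sharing i's quarter, optionally restricted to a training
#' partition. Seasonal adjustment divides each cruise's value by this mean,
#' so adjusted values read as deviations from the seasonal average.
#'
#' @param values positive numeric vector, one value per cruise.
#' @param quarters quarter label per cruise (character or factor).
#' @param partition optional logical or integer index of cruises forming the
#'   active (training) partition over which means are computed. Defaults to
#'   all cruises. Every quarter present in \code{quarters} must retain at
#'   least one cruise in the partition.
#' @return numeric vector g(i, .) of the same length as \code{values}: for
#'   every cruise (inside or outside the partition) the geometric mean of the
#'   partition cruises in its quarter.
#' @export
seasonal_geometric_means <- function(values, quarters, partition = NULL) {
  stopifnot(length(values) == length(quarters))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be positive and finite (apply a zero offset first)")
  }
  quarters <- as.character(quarters)
  idx <- seq_along(values)
  if (is.null(partition)) partition <- idx
  if (is.logical(partition)) partition <- which(partition)
  gm_by_q <- tapply(log(values[partition]), quarters[partition], mean)
  missing_q <- setdiff(unique(quarters), names(gm_by_q))
  if (length(missing_q)) {
    stop("quarter(s) with zero cruises in the partition: ",
         paste(missing_q, collapse = ", "))
  }
  exp(as.numeric(gm_by_q[quarters]))
}

#' Seasonal log-ratio adjustment
#'
#' Divides each value by its seasonal geometric mean: \code{value / g(i,.)}.
#' A ratio of 0.5 means the cruise's value was half its quarter's seasonal
#' average.
#'
#' @inheritParams seasonal_geometric_means
#' @param g optional precomputed seasonal means; computed from
#'   \code{values}/\code{quarters} if omitted.
#' @return vector of seasonal ratios.
#' @export
seasonal_adjust <- function(values, quarters, g = NULL) {
  if (is.null(g)) g <- seasonal_geometric_means(values, quarters)
  values / g
}

#' Partition-aware seasonal adjustment
#'
#' Recomputes seasonal geometric means using only training cruises, then
#' adjusts every cruise (training and held-out) by the training-quarter
#' means. Used inside cross-validation so held-out cruises never leak into
#' the seasonal averages.
#'
#' @inheritParams seasonal_geometric_means
#' @param heldout logical or integer index of held-out cruises.
#' @return list with \code{ratio} (adjusted values for all cruises) and
#'   \code{g} (training-only seasonal means, one per cruise).
#' @export
partition_aware_adjust <- function(values, quarters, heldout) {
  n <- length(values)
  if (is.logical(heldout)) heldout <- which(heldout)
  train <- setdiff(seq_len(n), heldout)
  g <- seasonal_geometric_means(values, quarters, partition = train)
  list(ratio = values / g, g = g)
}

# Column-wise seasonal geometric means for a positive matrix (cruises x
# vars), computed from the training rows only and expanded to all rows.
seasonal_gm_matrix <- function(z, quarters, train) {
  quarters <- as.character(quarters)
  if (any(z <= 0)) stop("matrix entries must be positive")
  lz <- log(as.matrix(z))
  qt <- quarters[train]
  if (!all(unique(quarters) %in% unique(qt))) {
    stop("quarter(s) with zero cruises in the partition")
  }
  sums <- rowsum(lz[train, , drop = FALSE], qt)
  cnts <- as.numeric(table(qt)[rownames(sums)])
  gm <- sums / cnts
  exp(gm[quarters, , drop = FALSE])
}

#' Offset for zero densities
#'
#' Log-ratio seasonal adjustment requires positive values, but cruises with
#' no sightings of a species have estimated density exactly zero. The offset
#' rule adds delta = half the smallest nonzero value (computed on the active
#' partition) to every value whenever any zero is present, preserving order.
#'
#' @param values non-negative numeric vector.
#' @param partition optional index restricting which values define delta.
#' @param delta optional explicit offset overriding the rule.
#' @return list with \code{values} (offset-adjusted) and \code{delta} used.
#' @export
zero_offset <- function(values, partition = NULL, delta = NULL) {
  if (is.null(partition)) partition <- seq_along(values)
  if (is.logical(partition)) partition <- which(partition)
  if (is.null(delta)) {
    if (any(values == 0)) {
      nz <- values[partition][values[partition] > 0]
      if (!length(nz)) stop("all values zero; no offset can be derived")
      delta <- min(nz) / 2
    } else {
      delta <- 0
    }
  }
  list(values = values + delta, delta = delta)
}
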