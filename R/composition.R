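#' Filter ASVs by prevalence
#'
#' Removes rare and ubiquitous amplicon sequence variants (ASVs) before
#' compositional analysis. Prevalence is the fraction of all samples, pooled
#' across cruises, in which an ASV was detected (count > 0). ASVs detected in
#' fewer than \code{lo} or more than \code{hi} of samples carry too little
#' between-cruise variation to be useful predictors and are dropped.
#'
#' @param counts integer matrix, samples x ASVs; rownames are sample ids,
#'   colnames are ASV ids.
#' @param lo,hi prevalence bounds as fractions in [0, 1]; an ASV is retained
#'   iff \code{lo <= prevalence <= hi} (boundaries inclusive). Defaults 0.01
#'   and 0.99.
#' @return list with \code{counts} (filtered matrix) and \code{retained}
#'   (character vector of retained ASV ids).
#' @export
filter_prevalence <- function(counts, lo = 0.01, hi = 0.99) {
  counts <- as_count_matrix(counts)
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  prev <- colMeans(counts > 0)
  keep <- prev >= lo & prev <= hi
  if (!any(keep)) {
    stop("no candidates survive filtering")
  }
  list(counts = counts[, keep, drop = FALSE], retained = colnames(counts)[keep])
}

#' Geometric Bayesian-multiplicative zero imputation
#'
#' Replaces zero counts with small positive proportions so log-ratio
#' transforms are defined, under the working assumption that every retained
#' ASV was physically present in every sample. For a sample with total count
#' n and prior strength s, a zero entry for ASV j becomes
#' \code{t_j * s / (n + s)} where \code{t_j} is a prior proportion for ASV j;
#' observed (nonzero) entries are rescaled multiplicatively so each sample's
#' proportions still sum to one. Ratios among observed parts are preserved.
#'
#' @param counts filtered count matrix, samples x ASVs; every ASV must be
#'   observed in at least one sample.
#' @param s prior strength (Dirichlet total mass). The default (NULL) uses
#'   the Bayes-Laplace mass s = J (one pseudocount spread over the J ASVs),
#'   so a zero is imputed at roughly its taxon's typical proportion scaled
#'   by J/n, i.e. within a few logs of the 1/n detection limit. A fixed
#'   small s with deep libraries (s = 1 at n ~ 50000) imputes values many
#'   orders of magnitude below the detection limit, and those log-scale
#'   outliers dominate downstream geometric aggregation.
#' @param prior either \code{"gm"} (default: per-ASV geometric mean of
#'   observed nonzero per-sample proportions, renormalized) or a numeric
#'   vector of prior proportions of length \code{ncol(counts)}.
#' @return numeric matrix of strictly positive proportions, rows summing to 1.
#' @export
impute_zeros_gbm <- function(counts, s = NULL, prior = "gm") {
  counts <- as_count_matrix(counts)
  if (any(rowSums(counts) <= 0)) stop("every sample must have positive total count")
  if (any(colSums(counts) == 0)) {
    stop("ASV with zero count in every sample; apply prevalence filtering first")
  }
  props <- counts / rowSums(counts)
  if (is.character(prior) && identical(prior, "gm")) {
    t_j <- apply(props, 2, function(p) exp(mean(log(p[p > 0]))))
    t_j <- t_j / sum(t_j)
  } else {
    t_j <- as.numeric(prior)
    if (length(t_j) != ncol(counts) || any(t_j <= 0)) {
      stop("prior must be a positive vector of length ncol(counts)")
    }
    t_j <- t_j / sum(t_j)
  }
  if (is.null(s)) s <- ncol(counts)
  out <- props
  n_tot <- rowSums(counts)
  for (i in seq_len(nrow(counts))) {
    z <- counts[i, ] == 0
    if (!any(z)) next
    repl <- t_j[z] * s / (n_tot[i] + s)
    out[i, z] <- repl
    out[i, !z] <- props[i, !z] * (1 - sum(repl))
  }
  stopifnot(all(out > 0))
  out
}

#' Per-cruise sample aggregation weights
#'
#' Weights used when aggregating sample-level compositions to the cruise
#' level. The spatial factor is inversely proportional to local sampling
#' density (1 / number of samples sharing the sample's station). The depth
#' factor assigns weight \code{r} to deep-chlorophyll-maximum (DCM) samples
#' and \code{1 - r} to surface samples, with \code{r} chosen on a grid over
#' [0, 1] to maximize the Shannon entropy (alpha diversity) of the aggregated
#' cruise composition; ties break toward larger \code{r} (favoring DCM).
#'
#' @param metadata data.frame with columns \code{cruise}, \code{station},
#'   \code{depth} (values \code{"surface"} or \code{"DCM"}), one row per
#'   sample, in the row order of the proportion matrix.
#' @param proportions optional samples x ASVs proportion matrix used for the
#'   entropy criterion; if omitted (or only one depth stratum is present) the
#'   depth factor is uniform.
#' @param r_grid grid of candidate DCM weights; the default spans
#'   \code{[0.05, 0.95]} so every sample keeps positive weight.
#' @return numeric vector of weights, positive and summing to 1 within each
#'   cruise, named by sample (rownames of \code{proportions} if available).
#' @export
aggregation_weights <- function(metadata, proportions = NULL,
                                r_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(c("cruise", "station", "depth") %in% names(metadata)))
  n <- nrow(metadata)
  if (n == 0L) stop("cruise with zero samples")
  w <- numeric(n)
  for (cr in unique(metadata$cruise)) {
    idx <- which(metadata$cruise == cr)
    st <- metadata$station[idx]
    spatial <- 1 / as.numeric(table(st)[as.character(st)])
    depth <- metadata$depth[idx]
    two_strata <- length(unique(depth)) > 1L
    if (two_strata && !is.null(proportions)) {
      ent <- vapply(r_grid, function(r) {
        df <- ifelse(depth == "DCM", r, 1 - r)
        wi <- spatial * df
        if (sum(wi) <= 0) return(-Inf)
        wi <- wi / sum(wi)
        ok <- wi > 0
        x <- exp(colSums(log(proportions[idx[ok], , drop = FALSE]) * wi[ok]))
        x <- x / sum(x)
        -sum(x * log(x))
      }, numeric(1))
      # ties toward DCM: pick the largest r attaining the max
      r_best <- max(r_grid[ent >= max(ent) - 1e-12])
      df <- ifelse(depth == "DCM", r_best, 1 - r_best)
    } else {
      df <- rep(1, length(idx))
    }
    wi <- spatial * df
    w[idx] <- wi / sum(wi)
  }
  if (!is.null(proportions) && !is.null(rownames(proportions))) {
    names(w) <- rownames(proportions)
  }
  w
}

#' Aggregate sample proportions to cruise-level averages
#'
#' Weighted geometric mean of per-sample relative abundances within each
#' cruise: \code{x_ij = prod_samples x_ij(sample)^w(sample)}. Requires
#' strictly positive proportions (impute zeros first) and weights that sum to
#' one within each cruise.
#'
#' @param proportions samples x ASVs strictly positive proportion matrix.
#' @param weights per-sample weights (see \code{\link{aggregation_weights}}).
#' @param cruise cruise id per sample.
#' @return matrix cruises x ASVs of aggregated average relative abundances.
#' @export
aggregate_to_cruise <- function(proportions, weights, cruise) {
  if (any(proportions <= 0)) stop("zero proportion encountered; impute zeros before aggregating")
  stopifnot(length(weights) == nrow(proportions), length(cruise) == nrow(proportions))
  cruises <- unique(cruise)
  out <- matrix(NA_real_, length(cruises), ncol(proportions),
                dimnames = list(as.character(cruises), colnames(proportions)))
  for (cr in cruises) {
    idx <- which(cruise == cr)
    wi <- weights[idx]
    if (abs(sum(wi) - 1) > 1e-8) stop("weights must sum to 1 within each cruise")
    out[as.character(cr), ] <- exp(colSums(log(proportions[idx, , drop = FALSE]) * wi))
  }
  out
}

#' Typical-abundance ratios (centered log-ratio scaling)
#'
#' For each cruise, divides every ASV's aggregated average relative abundance
#' by the geometric mean across all retained ASVs on that cruise:
#' \code{z_ij = x_ij / g_i} with \code{g_i = (prod_j x_ij)^(1/J)}. A value of
#' z = 2 means the ASV is twice as abundant as the typical ASV on that
#' cruise. Logs are taken downstream, in the model matrices.
#'
#' @param x cruises x ASVs matrix of positive aggregated abundances, or a
#'   single cruise's numeric vector.
#' @return list with \code{z} (same shape as \code{x}) and \code{g}
#'   (per-cruise geometric means).
#' @export
typical_ratio <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  stopifnot(all(x > 0))
  g <- exp(rowMeans(log(x)))
  z <- x / g
  if (vec) z <- drop(z)
  list(z = z, g = g)
}

#' Full sample-to-cruise composition pipeline
#'
#' Convenience wrapper chaining prevalence filtering, geometric
#' Bayesian-multiplicative zero imputation, aggregation-weight construction,
#' weighted geometric aggregation to cruise level, and typical-abundance
#' scaling, for a single marker.
#'
#' @param counts samples x ASVs count matrix.
#' @param metadata per-sample data.frame with \code{cruise}, \code{station},
#'   \code{depth}.
#' @param lo,hi prevalence bounds, see \code{\link{filter_prevalence}}.
#' @param s GBM prior strength.
#' @return object of class \code{cruise_composition}: list with \code{x}
#'   (cruise x ASV average abundances), \code{z} (typical-abundance ratios),
#'   \code{g} (per-cruise geometric means), \code{retained}, \code{weights}.
#' @export
compose_cruises <- function(counts, metadata, lo = 0.01, hi = 0.99, s = NULL) {
  stopifnot(nrow(counts) == nrow(metadata))
  filt <- filter_prevalence(counts, lo, hi)
  props <- impute_zeros_gbm(filt$counts, s = s)
  w <- aggregation_weights(metadata, props)
  x <- aggregate_to_cruise(props, w, metadata$cruise)
  tr <- typical_ratio(x)
  structure(list(x = x, z = tr$z, g = tr$g, retained = filt$retained,
                 weights = w),
            class = "cruise_composition")
}

#' @export
print.cruise_composition <- function(x, ...) {
  cat("Cruise-level composition:", nrow(x$x), "cruises x", ncol(x$x),
      "retained ASVs\n")
  invisible(x)
}

# coerce a count input (data.frame or matrix) to a numeric matrix with names
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("negative counts")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("asv", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  counts
}
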