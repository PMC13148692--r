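#' Read an ASV count table
#'
#' Reads a samples x ASVs count matrix from TSV or BIOM. TSV orientation is
#' auto-detected from the header of the first column: \code{"sample"} means
#' rows are samples, \code{"asv"} means rows are ASVs (the table is
#' transposed on read). Duplicate sample ids and negative counts are
#' rejected.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"biom"} (requires the
#'   biomformat package).
#' @return integer matrix, samples x ASVs.
#' @export
read_asv_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biomformat package is required to read BIOM files")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    m <- t(m)  # biom stores observations (ASVs) as rows
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    id_col <- tolower(names(df)[1])
    if (!id_col %in% c("sample", "asv")) {
      stop("cannot detect orientation: first column must be named 'sample' or 'asv'")
    }
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    if (id_col == "asv") m <- t(m)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (!is.numeric(m)) stop("non-numeric counts")
  if (any(m < 0)) stop("negative counts are not valid")
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV count table as TSV
#'
#' @param counts samples x ASVs matrix.
#' @param path output path.
#' @param orientation \code{"samples"} (rows are samples, first column
#'   \code{sample}) or \code{"asvs"} (transposed, first column \code{asv}).
#' @export
write_asv_table <- function(counts, path, orientation = c("samples", "asvs")) {
  orientation <- match.arg(orientation)
  if (orientation == "asvs") {
    df <- data.frame(asv = colnames(counts), t(counts), check.names = FALSE)
  } else {
    df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' CSV with required columns \code{sample}, \code{cruise}, \code{station},
#' \code{depth} (and any extras such as \code{transect} or \code{marker}).
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "cruise", "station", "depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in metadata")
  df
}

#' Read whale sighting records
#'
#' CSV with columns \code{cruise}, \code{transect}, \code{species},
#' \code{distance} (perpendicular, m), \code{size} (group size),
#' \code{beaufort}, \code{swell}, \code{height}. Rows beyond the truncation
#' distance are retained at read time; truncation is analytical.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sightings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cruise", "transect", "species", "distance", "size")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sightings missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$distance < 0)) stop("negative perpendicular distance")
  if (any(df$size < 1)) stop("group size must be at least 1")
  df
}

#' Read survey effort
#'
#' CSV with columns \code{cruise}, \code{transect}, \code{length} (km).
#' @param path file path.
#' @return validated data.frame.
#' @export
read_effort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cruise", "transect", "length")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("effort missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$length <= 0)) stop("effort length must be positive")
  df
}

#' Write sightings / effort tables
#' @param df table to write.
#' @param path output path.
#' @rdname write_survey_tables
#' @export
write_sightings <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_tables
#' @export
write_effort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Either supply file
#' paths (\code{sightings}, \code{effort}, \code{asv_table},
#' \code{metadata}) or set \code{simulate = TRUE} to run on a synthetic
#' dataset generated from \code{sim} (a \code{\link{sim_config}}).
#'
#' @param sightings,effort,asv_table,metadata input file paths (CSV/TSV).
#' @param simulate logical; generate inputs synthetically.
#' @param sim a \code{\link{sim_config}} used when \code{simulate = TRUE}.
#' @param truncation_w truncation distance (m), default 2400.
#' @param prevalence_lo,prevalence_hi prevalence filter bounds.
#' @param gbm_s prior strength for zero imputation.
#' @param lambda_grid sparsity grid.
#' @param pi_max selection-probability threshold.
#' @param pfer per-family error-rate level.
#' @param K number of latent components, or \code{NULL} to choose by
#'   leave-one-out MSPE over \code{K_grid}.
#' @param K_grid candidate component counts (default 4:12).
#' @param alpha threshold for the Jaccard consistency index.
#' @param outer logical; run the (expensive) nested outer validation.
#' @param bootstrap_B bootstrap resamples per held-out prediction (0 to
#'   skip intervals).
#' @param bootstrap_level interval level.
#' @param use_covariates logical; offer sighting covariates to the
#'   detection-function search.
#' @param seed integer seed.
#' @param out_dir optional output directory for artifact files.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sightings = NULL, effort = NULL, asv_table = NULL,
                            metadata = NULL, simulate = is.null(sightings),
                            sim = sim_config(),
                            truncation_w = 2400,
                            prevalence_lo = 0.01, prevalence_hi = 0.99,
                            gbm_s = 1,
                            lambda_grid = default_lambda_grid(),
                            pi_max = 0.9, pfer = 0.5,
                            K = NULL, K_grid = 4:12, alpha = 0.5,
                            outer = FALSE, bootstrap_B = 0,
                            bootstrap_level = 0.9,
                            use_covariates = FALSE,
                            seed = 1, out_dir = NULL) {
  structure(list(sightings = sightings, effort = effort,
                 asv_table = asv_table, metadata = metadata,
                 simulate = simulate, sim = sim,
                 truncation_w = truncation_w,
                 prevalence_lo = prevalence_lo, prevalence_hi = prevalence_hi,
                 gbm_s = gbm_s, lambda_grid = lambda_grid, pi_max = pi_max,
                 pfer = pfer, K = K, K_grid = K_grid, alpha = alpha,
                 outer = outer, bootstrap_B = bootstrap_B,
                 bootstrap_level = bootstrap_level,
                 use_covariates = use_covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys map to \code{\link{pipeline_config}} arguments; a
#' \code{sim} block maps to \code{\link{sim_config}} arguments.
#'
#' @param path YAML file path.
#' @return \code{pipeline_config}.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the full analysis: (1) obtain sightings, effort and ASV
#' inputs (from files or the synthetic generator); (2) select and fit a
#' detection function and estimate per-cruise density with variance
#' components; (3) build cruise-level typical-abundance ratios from the
#' count table; (4) run stability selection (with leave-one-out MSPE choice
#' of the component count when \code{K} is NULL) and fit the final SIMPLS
#' log-contrast model on the stable set; (5) validate by leave-one-out
#' prediction against lag and seasonal-mean baselines, optionally with the
#' nested outer validation and bootstrap intervals. Deterministic given the
#' seed. When \code{out_dir} is set, summary CSV/JSON artifacts are
#' written.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{pipeline_result}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (config$simulate) {
    ds <- generate_dataset(config$sim)
    sightings <- ds$sightings
    effort <- ds$effort
    counts <- ds$counts
    metadata <- ds$metadata
    cruise_order <- ds$design$cruises$cruise
    quarters <- ds$design$cruises$quarter
    truth <- ds$truth
  } else {
    sightings <- read_sightings(config$sightings)
    effort <- read_effort(config$effort)
    counts <- read_asv_table(config$asv_table)
    metadata <- read_sample_metadata(config$metadata)
    counts <- counts[metadata$sample, , drop = FALSE]
    cruise_order <- unique(metadata$cruise)
    if (is.null(metadata$quarter)) stop("metadata must carry a quarter column")
    quarters <- metadata$quarter[match(cruise_order, metadata$cruise)]
    truth <- NULL
  }

  # stage 1: detection + density
  covars <- NULL
  if (config$use_covariates && nrow(sightings) > 0) {
    covars <- sightings[, intersect(c("beaufort", "swell", "height", "size"),
                                    names(sightings)), drop = FALSE]
    covars$height <- factor(covars$height)
  }
  det_fit <- select_detection_model(sightings$distance, config$truncation_w,
                                    covariates = covars)
  dens_full <- fit_detection_function(sightings$distance, config$truncation_w,
                                      det_fit$key, det_fit$adjustment)
  dens <- density_variance(sightings, effort, det_fit)
  y <- dens$y[match(cruise_order, dens$cruise)]
  if (anyNA(y)) stop("density stage: cruise mismatch between effort and design")

  # stage 2: composition
  comp <- compose_cruises(counts, metadata, config$prevalence_lo,
                          config$prevalence_hi, config$gbm_s)
  z <- comp$z[cruise_order, , drop = FALSE]

  # stage 3: selection + model
  if (is.null(config$K)) {
    ksel <- select_num_components(y, z, quarters, config$K_grid,
                                  config$lambda_grid, config$pi_max,
                                  config$pfer)
    K <- ksel$K
    set <- ksel$set
  } else {
    K <- config$K
    ksel <- NULL
    set <- stability_selection(y, z, quarters, K, config$lambda_grid,
                               config$pi_max, config$pfer)$set
  }
  mm <- build_model_matrices(y, z, quarters)
  sel <- set$selected
  if (length(sel)) {
    kk <- min(K, length(sel), length(y) - 1L)
    fit <- simpls_fit(mm$v[, sel, drop = FALSE], mm$u, kk)
    coef_full <- numeric(ncol(z))
    coef_full[sel] <- fit$coef
    fitq <- fit
    fitq$coef <- coef_full
    fitq$var_names <- colnames(z)
    summ <- fit_summary(fitq, mm)
    assoc <- association_measure(fit$coef)
    assoc$asv <- colnames(z)[sel]
  } else {
    fitq <- NULL
    summ <- NULL
    assoc <- NULL
  }

  # stage 4: validation
  preds <- loo_predictions(y, z, quarters, sel, K)
  metrics <- attr(preds, "metrics")
  base_lag <- naive_predictions(y, quarters, "lag")
  base_mean <- naive_predictions(y, quarters, "mean")
  rmspe_lag <- sqrt(mean((y - base_lag)^2))
  rmspe_mean <- sqrt(mean((y - base_mean)^2))
  reductions <- c(lag = reduction_vs_baseline(metrics$rmspe_orig, rmspe_lag),
                  mean = reduction_vs_baseline(metrics$rmspe_orig, rmspe_mean))
  outer_sets <- NULL
  jaccard <- NULL
  if (config$outer) {
    outer_sets <- outer_validation(y, z, quarters, K, config$lambda_grid,
                                   config$pi_max, config$pfer)
    jaccard <- thresholded_jaccard(outer_sets, config$alpha)
  }
  intervals <- NULL
  if (config$bootstrap_B >= 50 && length(sel)) {
    intervals <- lapply(seq_along(y), function(f)
      bootstrap_intervals(y, z, quarters, f, sel, K,
                          B = config$bootstrap_B,
                          level = config$bootstrap_level))
  }

  res <- structure(list(detection = det_fit, density = dens, composition = comp,
                        y = y, z = z, quarters = quarters, K = K,
                        K_selection = ksel, stable_set = set, model = fitq,
                        fit_summary = summ, associations = assoc,
                        predictions = preds, metrics = metrics,
                        baselines = list(lag = base_lag, mean = base_mean,
                                         rmspe_lag = rmspe_lag,
                                         rmspe_mean = rmspe_mean),
                        reductions = reductions, outer_sets = outer_sets,
                        jaccard = jaccard, intervals = intervals,
                        truth = truth, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat("  cruises:", length(x$y), " candidate ASVs:", ncol(x$z), "\n")
  cat("  detection:", x$detection$key, "(AIC", round(x$detection$AIC, 2), ")\n")
  cat("  stable set:", length(x$stable_set$selected), "ASVs; K =", x$K, "\n")
  if (!is.null(x$fit_summary)) {
    cat(sprintf("  adjusted R2: %.3f (log) / %.3f (original)\n",
                x$fit_summary$r2_log_adj, x$fit_summary$r2_orig_adj))
  }
  cat(sprintf("  LOO RMSPE: %.3f (log) / %.3f (original); reduction vs lag %.1f%%, vs mean %.1f%%\n",
              x$metrics$rmspe_log, x$metrics$rmspe_orig,
              x$reductions["lag"], x$reductions["mean"]))
  if (!is.null(x$jaccard)) cat(sprintf("  selection consistency J = %.3f\n", x$jaccard))
  invisible(x)
}

# write summary artifacts (CSV + JSON) for a pipeline run
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$density, file.path(out_dir, "density.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cruise = rownames(res$z), res$z,
                              check.names = FALSE),
                   file.path(out_dir, "composition_z.csv"), row.names = FALSE)
  if (!is.null(res$associations)) {
    utils::write.csv(res$associations[, c("asv", "beta", "factor", "percent")],
                     file.path(out_dir, "stable_set.csv"), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(res$predictions),
                   file.path(out_dir, "loo_predictions.csv"), row.names = FALSE)
  model <- list(K = res$K,
                stable_set = res$stable_set$names,
                pi_max = res$stable_set$pi_max,
                region = res$stable_set$region,
                coefficients = if (!is.null(res$model)) {
                  stats::setNames(res$model$coef[res$stable_set$selected],
                                  res$stable_set$names)
                } else NULL,
                intercept = if (!is.null(res$model)) res$model$intercept else NULL,
                fit_summary = res$fit_summary,
                metrics = res$metrics,
                reductions = as.list(res$reductions),
                jaccard = res$jaccard,
                seed = res$config$seed)
  jsonlite::write_json(model, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
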