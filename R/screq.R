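#' Pipeline configuration
#'
#' Collects every tunable of the imputation pipeline with the standard
#' defaults: 2000 subsampled cells for distribution learning, 100
#' histogram bins / equalization levels, half-matrix windows sliding by
#' their own size (4 non-overlapping ROIs), and the three candidate
#' target densities at their printed fit bounds.
#'
#' @param subsample_rows cells used for distribution learning (default
#'   2000).
#' @param bins histogram bins and equalization levels (default 100).
#' @param window_frac,step_frac,grid_override ROI geometry, see
#'   [make_roi_grid()].
#' @param clip_limit optional histogram clip limit, see [equalize_all()].
#' @param families candidate distribution families.
#' @param fit_bounds named list of `c(start, lower, upper)` per family.
#' @param use_autoencoder denoise the subsample before fitting (default
#'   `TRUE`); `FALSE` fits the empirical distribution directly.
#' @param resample consistency resampling applied after a non-overlapping
#'   tiling pass: `"seam"` (default) smooths only the window seams via
#'   [seam_resample()]; `"full"` applies [bilinear_resample()] to the
#'   whole matrix; `"none"` skips the step.  With overlapping windows the
#'   per-element average already imposes consistency and this setting is
#'   ignored.
#' @param randomize permute rows and columns before imputation and
#'   restore them after (default `FALSE`).
#' @param cdf_extra_norm see [roi_cdf()].
#' @param autoencoder an [autoencoder_config()].
#' @return a list of class `"screq_config"`.
#' @export
screq_config <- function(subsample_rows = 2000L, bins = 100L,
                         window_frac = 0.5, step_frac = window_frac,
                         grid_override = NULL, clip_limit = NULL,
                         families = c("gaussian", "rayleigh", "exponential"),
                         fit_bounds = .default_fit_bounds(),
                         use_autoencoder = TRUE,
                         resample = c("seam", "full", "none"),
                         randomize = FALSE, cdf_extra_norm = FALSE,
                         autoencoder = autoencoder_config()) {
  if (subsample_rows <= 0 || bins < 2L)
    stop("subsample_rows must be positive and bins >= 2")
  resample <- match.arg(resample)
  structure(list(subsample_rows = as.integer(subsample_rows),
                 bins = as.integer(bins), window_frac = window_frac,
                 step_frac = step_frac, grid_override = grid_override,
                 clip_limit = clip_limit, families = families,
                 fit_bounds = fit_bounds, use_autoencoder = use_autoencoder,
                 resample = resample, randomize = randomize,
                 cdf_extra_norm = cdf_extra_norm, autoencoder = autoencoder),
            class = "screq_config")
}

# master seed -> independent per-stage seeds (subsample/training already
# offset inside learn_distribution; permutation gets its own)
.stage_seeds <- function(seed) {
  if (is.null(seed)) return(list(learn = NULL, permute = NULL))
  with_seed(seed, {
    s <- sample.int(2^31 - 3L, 2L)
    list(learn = s[1L], permute = s[2L])
  })
}

#' Impute a dropout-affected expression matrix
#'
#' The main entry point.  Learns the denoised target expression
#' distribution from a random subsample of `x` (autoencoder
#' reconstruction, histogram, parametric density fit), then remaps every
#' sliding-window ROI of `x` onto that distribution by discrete
#' inverse-sampling histogram equalization; with non-overlapping windows
#' a final bilinear resampling imposes cross-window consistency.  Works
#' on raw counts and normalized data alike; no library-size
#' normalization is applied internally.
#'
#' @param x expression matrix, cells in rows, genes in columns (see
#'   [read_matrix()] for file input).
#' @param config a [screq_config()].
#' @param seed master seed; fixes subsampling, training, and the optional
#'   permutation, making the run bit-reproducible.
#' @return an object of class `"screq"` with components `imputed` (the
#'   recovered matrix), `observed` (the input), `fit` (the
#'   `"fitted_distribution"`), `grid`, `config`, `seed` and
#'   `loss_history`.  Use [fitted()], [coef()], [summary()], [plot()] on
#'   it.
#' @examples
#' set.seed(1)
#' x <- matrix(rpois(600, 3), 30, 20)
#' fit <- screq(x, screq_config(subsample_rows = 30,
#'                              autoencoder = autoencoder_config(max_epochs = 2)),
#'              seed = 1)
#' fit
#' @export
screq <- function(x, config = screq_config(), seed = NULL) {
  cl <- match.call()
  x <- expression_matrix(x)
  stopifnot(inherits(config, "screq_config"))
  seeds <- .stage_seeds(seed)
  perm <- NULL
  work <- x
  if (config$randomize) {
    pr <- permute_matrix(x, seed = seeds$permute)
    work <- pr$matrix
    perm <- pr$record
  }
  fit <- learn_distribution(work, n_rows = config$subsample_rows,
                            n_bins = config$bins,
                            autoencoder = if (config$use_autoencoder)
                              config$autoencoder else NULL,
                            families = config$families,
                            bounds = config$fit_bounds, seed = seeds$learn)
  grid <- make_roi_grid(nrow(work), ncol(work),
                        window_frac = config$window_frac,
                        step_frac = config$step_frac,
                        grid_override = config$grid_override)
  shat <- equalize_all(work, grid, fit, levels = config$bins,
                       clip_limit = config$clip_limit,
                       cdf_extra_norm = config$cdf_extra_norm)
  sbar <- .consistency_resample(shat, grid, config$resample)
  if (!is.null(perm)) sbar <- unpermute_matrix(sbar, perm)
  structure(list(imputed = sbar, observed = x, fit = fit, grid = grid,
                 config = config, seed = seed, permutation = perm,
                 loss_history = attr(fit, "loss_history"), call = cl),
            class = "screq")
}

#' @export
print.screq <- function(x, ...) {
  cat("Self-consistent expression recovery\n")
  cat(sprintf("  matrix: %d cells x %d genes\n",
              nrow(x$observed), ncol(x$observed)))
  cat(sprintf("  target distribution: %s (lambda = %.4g, fit rmse = %.4g)\n",
              x$fit$family, x$fit$lambda, x$fit$rmse))
  cat(sprintf("  ROI grid: %d region(s)%s\n", length(x$grid$rois),
              if (isTRUE(x$grid$overlap)) ", overlapping" else ""))
  if (!is.null(x$permutation)) cat("  row/column randomization applied\n")
  invisible(x)
}

#' @export
summary.screq <- function(object, ...) {
  zf_in <- mean(object$observed == 0)
  zf_out <- mean(object$imputed == 0)
  s <- list(dims = dim(object$observed), fit = object$fit,
            n_rois = length(object$grid$rois),
            zero_fraction_observed = zf_in, zero_fraction_imputed = zf_out,
            final_loss = if (!is.null(object$loss_history))
              utils::tail(object$loss_history, 1L) else NA_real_,
            seed = object$seed)
  class(s) <- "summary.screq"
  s
}

#' @export
print.summary.screq <- function(x, ...) {
  cat(sprintf("screq imputation of a %d x %d matrix\n", x$dims[1L], x$dims[2L]))
  print(x$fit)
  cat(sprintf("  ROIs: %d\n", x$n_rois))
  cat(sprintf("  zero fraction: %.3f observed -> %.3f imputed\n",
              x$zero_fraction_observed, x$zero_fraction_imputed))
  if (is.finite(x$final_loss))
    cat(sprintf("  final autoencoder training loss: %.6g\n", x$final_loss))
  invisible(x)
}

#' @export
coef.screq <- function(object, ...) {
  stats::setNames(object$fit$lambda, object$fit$family)
}

#' @export
fitted.screq <- function(object, ...) object$imputed

#' @export
residuals.screq <- function(object, ...) object$imputed - object$observed

#' Apply a learned distribution to new data
#'
#' Equalizes `newdata` against the distribution learned for `object`,
#' without refitting; this is the mechanism behind multi-batch
#' imputation, where one batch serves as the reference.  With
#' `newdata = NULL` the imputed matrix of the original fit is returned.
#'
#' @param object an [screq()] fit.
#' @param newdata optional expression matrix with the same gene space.
#' @param seed seed for the optional randomization of the new matrix.
#' @param ... unused.
#' @return imputed matrix.
#' @export
predict.screq <- function(object, newdata = NULL, seed = NULL, ...) {
  if (is.null(newdata)) return(object$imputed)
  newdata <- expression_matrix(newdata)
  cfg <- object$config
  perm <- NULL
  work <- newdata
  if (cfg$randomize) {
    pr <- permute_matrix(newdata, seed = seed)
    work <- pr$matrix; perm <- pr$record
  }
  grid <- make_roi_grid(nrow(work), ncol(work), window_frac = cfg$window_frac,
                        step_frac = cfg$step_frac,
                        grid_override = cfg$grid_override)
  shat <- equalize_all(work, grid, object$fit, levels = cfg$bins,
                       clip_limit = cfg$clip_limit,
                       cdf_extra_norm = cfg$cdf_extra_norm)
  sbar <- .consistency_resample(shat, grid, cfg$resample)
  if (!is.null(perm)) sbar <- unpermute_matrix(sbar, perm)
  sbar
}

# post-tiling consistency step; overlapping grids are already blended
.consistency_resample <- function(shat, grid, mode) {
  if (grid$overlap || length(grid$rois) < 2L || mode == "none") return(shat)
  switch(mode,
         seam = seam_resample(shat, grid),
         full = bilinear_resample(shat))
}

#' Diagnostic plot of a fit
#'
#' Left: histogram of the normalized denoised subsample with the fitted
#' density overlaid.  Right: value histograms of the observed and imputed
#' matrices (log1p scale).
#'
#' @param x an [screq()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.screq <- function(x, ...) {
  h <- attr(x$fit, "histogram")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  centers <- (h$bin_edges[-1L] + h$bin_edges[-length(h$bin_edges)]) / 2
  width <- diff(h$bin_edges)
  graphics::plot(centers, h$p, type = "h", xlab = "normalized expression",
                 ylab = "probability", main = "denoised distribution", ...)
  graphics::lines(centers,
                  .family_pdf(x$fit$family, centers, x$fit$lambda) * width,
                  col = 2, lwd = 2)
  graphics::legend("topright", sprintf("%s(lambda=%.3g)", x$fit$family,
                                       x$fit$lambda),
                   col = 2, lwd = 2, bty = "n")
  graphics::hist(log1p(x$imputed), breaks = 50, col = "grey",
                 main = "imputed values", xlab = "log1p(expression)")
  invisible(x)
}

# ---- permutation utilities --------------------------------------------------

#' Randomly permute the rows and columns of a matrix
#'
#' Optional pre-imputation randomization: a random bijection is applied
#' to each axis and recorded so that [unpermute_matrix()] restores the
#' original layout exactly.
#'
#' @param x matrix.
#' @param seed integer seed.
#' @return list with `matrix` (permuted) and `record` (class
#'   `"permutation_record"`: `row_perm`, `col_perm`, `seed`).
#' @export
permute_matrix <- function(x, seed = NULL) {
  x <- as.matrix(x)
  with_seed(seed, {
    rp <- sample.int(nrow(x)); cp <- sample.int(ncol(x))
    list(matrix = x[rp, cp, drop = FALSE],
         record = structure(list(row_perm = rp, col_perm = cp, seed = seed),
                            class = "permutation_record"))
  })
}

#' Invert a recorded permutation
#'
#' @param x matrix previously permuted with [permute_matrix()].
#' @param record the matching `"permutation_record"`.
#' @return matrix with the original row/column order restored.
#' @export
unpermute_matrix <- function(x, record) {
  stopifnot(inherits(record, "permutation_record"))
  x <- as.matrix(x)
  if (nrow(x) != length(record$row_perm) || ncol(x) != length(record$col_perm))
    stop("permutation record does not match the matrix dimensions")
  x[order(record$row_perm), order(record$col_perm), drop = FALSE]
}

# ---- multi-batch workflow ---------------------------------------------------

#' Impute and integrate multiple batches
#'
#' Learns the target distribution on one reference batch only, applies it
#' to equalize every batch independently (with per-batch randomization
#' when enabled), standardizes each batch per gene to z-scores
#' (zero-variance genes map to 0), and row-concatenates the result.
#'
#' @param batches list of expression matrices sharing the same genes, in
#'   the same column order.
#' @param reference_index which batch to learn the distribution from
#'   (default 1).
#' @param config a [screq_config()].
#' @param seed master seed.
#' @return list with `integrated` (z-scored, row-concatenated matrix),
#'   `imputed` (per-batch imputed matrices before z-scoring), `fit` and
#'   `reference_index`.
#' @export
batch_impute <- function(batches, reference_index = 1L,
                         config = screq_config(), seed = NULL) {
  stopifnot(is.list(batches), length(batches) >= 1L)
  batches <- lapply(batches, expression_matrix)
  genes <- colnames(batches[[1L]])
  for (i in seq_along(batches))
    if (!identical(colnames(batches[[i]]), genes)) {
      off <- setdiff(union(colnames(batches[[i]]), genes),
                     intersect(colnames(batches[[i]]), genes))
      stop("batch ", i, " gene identifiers do not align with the reference; ",
           "offenders: ", paste(utils::head(off, 5L), collapse = ", "))
    }
  if (reference_index < 1L || reference_index > length(batches))
    stop("reference_index out of range")
  ref_fit <- screq(batches[[reference_index]], config = config, seed = seed)
  imputed <- vector("list", length(batches))
  for (i in seq_along(batches)) {
    imputed[[i]] <- if (i == reference_index) ref_fit$imputed
      else predict(ref_fit, batches[[i]],
                   seed = if (is.null(seed)) NULL else seed + i)
  }
  zscored <- lapply(imputed, function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2L, stats::sd)
    z <- sweep(m, 2L, mu)
    z <- sweep(z, 2L, ifelse(sd > 0, sd, 1), "/")
    z[, sd == 0] <- 0
    z
  })
  list(integrated = do.call(rbind, zscored), imputed = imputed,
       fit = ref_fit$fit, reference_index = reference_index)
}
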