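# ---- distribution families on the normalized [0, 1] value domain -----------
#
# Three candidate shapes for the denoised expression distribution, each with
# a single decay/scale parameter lambda, all normalized on the nonnegative
# fit domain:
#   gaussian    f(x) = 2/(lambda*sqrt(pi)) * exp(-(x/lambda)^2)  (half-Gaussian)
#   rayleigh    f(x) = 2x/lambda^2         * exp(-(x/lambda)^2)
#   exponential f(x) = lambda * exp(-lambda*x)
# The half-Gaussian carries the factor 2 that makes it a density on [0, Inf)
# (its CDF is erf(x/lambda)); without it no lambda can fit half-Gaussian data
# and parameter recovery is impossible.  The equalization step uses the
# matching erfinv quantile function.

.erfinv <- function(p) stats::qnorm((p + 1) / 2) / sqrt(2)

.family_pdf <- function(family, x, lambda) {
  switch(family,
         gaussian = 2 * exp(-(x / lambda)^2) / (lambda * sqrt(pi)),
         rayleigh = 2 * x / lambda^2 * exp(-(x / lambda)^2),
         exponential = lambda * exp(-lambda * x),
         stop("unknown family: ", family))
}

.family_cdf <- function(family, x, lambda) {
  switch(family,
         gaussian = 2 * stats::pnorm(x * sqrt(2) / lambda) - 1,  # erf(x/lambda)
         rayleigh = 1 - exp(-(x / lambda)^2),
         exponential = 1 - exp(-lambda * x),
         stop("unknown family: ", family))
}

.family_quantile <- function(family, p, lambda) {
  switch(family,
         gaussian = lambda * .erfinv(p),
         rayleigh = lambda * sqrt(-log1p(-p)),
         exponential = -log1p(-p) / lambda,
         stop("unknown family: ", family))
}

# printed fit bounds: (start, lower, upper) per family
.default_fit_bounds <- function() {
  list(gaussian = c(start = 0.2, lower = 0.01, upper = 1),
       rayleigh = c(start = 0.2, lower = 0.01, upper = 1),
       exponential = c(start = 5, lower = 5, upper = 20))
}

#' Randomly subsample rows of an expression matrix
#'
#' Uniform without-replacement selection of `n_rows` cells (all genes
#' kept), used to limit the cost of the distribution-learning step.  When
#' the matrix has fewer rows than requested, all rows are returned.
#'
#' @param x expression matrix, cells in rows.
#' @param n_rows number of cells to keep (default 2000).
#' @param seed integer seed.
#' @return matrix with `min(n_rows, nrow(x))` rows, in original row order.
#' @export
subsample_matrix <- function(x, n_rows = 2000L, seed = NULL) {
  x <- expression_matrix(x)
  if (length(n_rows) != 1L || n_rows <= 0)
    stop("n_rows must be a positive integer")
  if (n_rows >= nrow(x)) return(x)
  keep <- with_seed(seed, sort(sample.int(nrow(x), n_rows)))
  x[keep, , drop = FALSE]
}

#' Histogram of the values of a matrix
#'
#' Linear equal-width binning of all matrix elements over their observed
#' range (or a supplied one), normalized to a probability vector.  A
#' constant matrix yields a single degenerate bin with probability 1.
#'
#' @param x numeric matrix (or vector).
#' @param n_bins number of bins (default 100).
#' @param range optional `c(lo, hi)` binning range; values outside are
#'   counted in the end bins.
#' @return a list of class `"histogram_model"` with `bin_edges` (length
#'   `n_bins + 1`), `p` (probabilities), `counts` and `total`.
#' @export
compute_histogram <- function(x, n_bins = 100L, range = NULL) {
  v <- as.numeric(x)
  if (anyNA(v) || any(!is.finite(v)))
    stop("values must be finite")
  if (is.null(range)) range <- base::range(v)
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) {
    return(structure(list(bin_edges = c(lo, hi), p = 1, counts = length(v),
                          total = length(v)), class = "histogram_model"))
  }
  idx <- .to_levels(v, lo, hi, n_bins) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = seq(lo, hi, length.out = n_bins + 1L),
                 p = counts / length(v), counts = counts, total = length(v)),
            class = "histogram_model")
}

# map values to integer levels 0..L-1 by equal-width binning on [lo, hi]
.to_levels <- function(v, lo, hi, L) {
  k <- floor((v - lo) / (hi - lo) * L)
  pmin(pmax(k, 0), L - 1L)
}

#' Fit a parametric density to a histogram
#'
#' For each candidate family the single parameter lambda is chosen to
#' minimize the root-mean-square error between the family density
#' evaluated at the bin centres (times the bin width, converting density
#' to bin mass) and the histogram probabilities, within the family's
#' bounds.  The family with the smallest RMSE wins.  Printed defaults:
#' half-Gaussian and Rayleigh start 0.2 on `[0.01, 1]`; exponential
#' start 5 on `[5, 20]` — calibrated for histograms on a `[0, 1]` value
#' domain.
#'
#' @param hist a [compute_histogram()] result on a `[0, 1]`-normalized
#'   value domain.
#' @param families candidate families, subset of
#'   `c("gaussian", "rayleigh", "exponential")`.
#' @param bounds named list of `c(start, lower, upper)` per family; see
#'   defaults above.
#' @return a list of class `"fitted_distribution"`: `family`, `lambda`,
#'   `rmse`, `fit_domain`, plus the per-family diagnostics in `all_fits`.
#' @export
fit_distribution <- function(hist,
                             families = c("gaussian", "rayleigh", "exponential"),
                             bounds = .default_fit_bounds()) {
  stopifnot(inherits(hist, "histogram_model"))
  families <- match.arg(families, several.ok = TRUE)
  if (length(hist$p) < 3L)
    stop("histogram too degenerate to fit (fewer than 3 bins)")
  edges <- hist$bin_edges
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  width <- diff(edges)
  p <- hist$p
  rmse_fun <- function(family) function(lambda)
    sqrt(mean((.family_pdf(family, centers, lambda) * width - p)^2))
  fits <- lapply(families, function(fam) {
    b <- bounds[[fam]]
    if (is.null(b)) stop("no bounds supplied for family ", fam)
    obj <- rmse_fun(fam)
    if (b[["lower"]] >= b[["upper"]]) {
      lambda <- b[["lower"]]
    } else {
      opt <- stats::optimize(obj, lower = b[["lower"]], upper = b[["upper"]],
                             tol = 1e-9)
      lambda <- opt$minimum
      # optimize() can miss a boundary minimum by its tolerance
      for (cand in c(b[["lower"]], b[["upper"]]))
        if (obj(cand) < obj(lambda)) lambda <- cand
    }
    list(family = fam, lambda = lambda, rmse = obj(lambda))
  })
  names(fits) <- families
  rmses <- vapply(fits, `[[`, numeric(1L), "rmse")
  if (all(!is.finite(rmses)))
    stop("density fitting failed for all families: ",
         paste(sprintf("%s (rmse=%g)", families, rmses), collapse = ", "))
  best <- fits[[which.min(rmses)]]
  structure(list(family = best$family, lambda = best$lambda, rmse = best$rmse,
                 fit_domain = base::range(edges), all_fits = fits),
            class = "fitted_distribution")
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(sprintf("Fitted expression distribution: %s (lambda = %.4g, rmse = %.4g)\n",
              x$family, x$lambda, x$rmse))
  invisible(x)
}

#' Learn the target expression distribution of a matrix
#'
#' Chains the distribution-learning steps: subsample rows, denoise with
#' the autoencoder (optional), normalize the reconstruction to `[0, 1]`,
#' histogram it and fit the candidate densities.
#'
#' @param x expression matrix, cells in rows.
#' @param n_rows subsample size (default 2000).
#' @param n_bins histogram bins (default 100).
#' @param autoencoder an [autoencoder_config()], or `NULL` to fit the
#'   empirical (non-denoised) distribution directly.
#' @param families,bounds passed to [fit_distribution()].
#' @param seed integer seed for subsampling and training.
#' @return a `"fitted_distribution"` with attributes `histogram` (the
#'   fitted histogram) and `loss_history` (autoencoder training loss per
#'   epoch, if used).
#' @export
learn_distribution <- function(x, n_rows = 2000L, n_bins = 100L,
                               autoencoder = autoencoder_config(),
                               families = c("gaussian", "rayleigh", "exponential"),
                               bounds = .default_fit_bounds(), seed = NULL) {
  s_s <- subsample_matrix(x, n_rows, seed = seed)
  loss <- NULL
  if (!is.null(autoencoder)) {
    ae <- train_autoencoder(s_s, autoencoder,
                            seed = if (is.null(seed)) NULL else seed + 1L)
    s_o <- ae$reconstruction
    loss <- ae$loss_history
  } else {
    s_o <- s_s
  }
  # min-max to [0, 1], keeping the natural zero when values are nonnegative
  lo <- min(0, min(s_o)); hi <- max(s_o)
  if (hi <= lo) stop("denoised matrix is constant; nothing to fit")
  s_norm <- (s_o - lo) / (hi - lo)
  hist <- compute_histogram(s_norm, n_bins = n_bins, range = c(0, 1))
  fit <- fit_distribution(hist, families = families, bounds = bounds)
  attr(fit, "histogram") <- hist
  attr(fit, "loss_history") <- loss
  fit
}
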