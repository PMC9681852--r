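#' Build a sliding-window grid of regions of interest
#'
#' Partitions (or, with `step_frac < window_frac`, slides a window over)
#' a `q x m` matrix into rectangular ROIs.  With the defaults
#' (`window_frac = 0.5`, step equal to the window) the matrix is tiled
#' into 4 non-overlapping quadrants; remainders from non-divisible
#' dimensions are absorbed into the last tile of each axis.
#'
#' @param q,m matrix dimensions (cells, genes).
#' @param window_frac window size as a fraction of each dimension
#'   (default 0.5).
#' @param step_frac sliding step as a fraction of each dimension;
#'   defaults to `window_frac` (non-overlapping tiling).
#' @param grid_override optional `c(rows, cols)`: partition into an
#'   explicit tiling with that many tiles per axis instead.
#' @return a list of class `"roi_grid"`: `window`, `step`, `overlap`
#'   (logical) and `rois`, a list of `c(row_start, row_end, col_start,
#'   col_end)` 1-based inclusive index ranges covering the matrix.
#' @examples
#' length(make_roi_grid(100, 200)$rois)    # 4
#' length(make_roi_grid(48, 10, grid_override = c(24, 2))$rois)  # 48
#' @export
make_roi_grid <- function(q, m, window_frac = 0.5, step_frac = window_frac,
                          grid_override = NULL) {
  if (q < 1L || m < 1L) stop("matrix dimensions must be positive")
  if (!is.null(grid_override)) {
    axes <- list(.tile_axis(q, grid_override[1L]),
                 .tile_axis(m, grid_override[2L]))
    window <- c(NA_integer_, NA_integer_)
    overlap <- FALSE
  } else {
    if (window_frac <= 0 || window_frac > 1 || step_frac <= 0)
      stop("window_frac must be in (0, 1] and step_frac positive")
    window <- c(min(q, ceiling(q * window_frac)), min(m, ceiling(m * window_frac)))
    step <- if (isTRUE(all.equal(step_frac, window_frac))) window
            else c(max(1L, ceiling(q * step_frac)), max(1L, ceiling(m * step_frac)))
    overlap <- any(step < window)
    if (window[1L] >= q && window[2L] >= m) {
      warning("window covers the whole matrix; using a single ROI")
      return(structure(list(window = c(q, m), step = c(q, m), overlap = FALSE,
                            rois = list(c(1L, q, 1L, m))),
                       class = "roi_grid"))
    }
    axes <- if (!overlap)
      list(.tile_axis(q, max(1L, round(q / window[1L]))),
           .tile_axis(m, max(1L, round(m / window[2L]))))
    else
      list(.slide_axis(q, window[1L], step[1L]),
           .slide_axis(m, window[2L], step[2L]))
  }
  rois <- list()
  for (r in seq_len(nrow(axes[[1L]])))
    for (cc in seq_len(nrow(axes[[2L]])))
      rois[[length(rois) + 1L]] <- unname(c(axes[[1L]][r, ], axes[[2L]][cc, ]))
  structure(list(window = window,
                 step = if (is.null(grid_override)) step else window,
                 overlap = overlap, rois = rois),
            class = "roi_grid")
}

# split 1..n into k contiguous tiles; the last absorbs the remainder
.tile_axis <- function(n, k) {
  k <- max(1L, min(as.integer(k), n))
  base <- n %/% k
  starts <- (seq_len(k) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, n)
  cbind(starts, ends)
}

# sliding windows of width w and step s; a final window is appended so the
# axis end is always covered
.slide_axis <- function(n, w, s) {
  starts <- seq(1L, max(1L, n - w + 1L), by = s)
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)
  cbind(starts, pmin(starts + w - 1L, n))
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("ROI grid: %d region(s)%s\n", length(x$rois),
              if (x$overlap) " (overlapping windows)" else ""))
  invisible(x)
}

#' Histogram of one ROI on the global level scale
#'
#' Discretizes the ROI values to `levels` equal-width levels spanning the
#' full matrix range (so histograms of different ROIs are comparable) and
#' normalizes the counts.
#'
#' @param values numeric matrix or vector: the ROI submatrix.
#' @param levels number of discretization levels L (default 100).
#' @param global_range `c(lo, hi)` range of the full matrix.
#' @return a `"histogram_model"` (see [compute_histogram()]).
#' @export
roi_histogram <- function(values, levels = 100L, global_range) {
  compute_histogram(values, n_bins = levels, range = global_range)
}

#' Cumulative distribution of a histogram
#'
#' Plain cumulative sum of the bin probabilities, reaching 1 at the last
#' level.  `extra_norm = TRUE` additionally divides by the ROI element
#' count (an alternative normalization retained for auditability; it caps
#' the CDF far below 1 and is not used by the pipeline).
#'
#' @param hist a `"histogram_model"`.
#' @param extra_norm apply the additional `1/N` factor (default `FALSE`).
#' @return nondecreasing numeric vector, last element 1 (when
#'   `extra_norm = FALSE`).
#' @export
roi_cdf <- function(hist, extra_norm = FALSE) {
  stopifnot(inherits(hist, "histogram_model"))
  f <- cumsum(hist$p)
  if (extra_norm) f <- f / hist$total
  f
}

#' Level-remapping lookup table for one ROI
#'
#' The discrete inverse-sampling transform at the heart of the method:
#' each level's cumulative probability `F(k)` is pushed through the
#' target family's quantile function (exponential
#' `-ln(1 - F)/lambda`, Rayleigh `lambda*sqrt(-ln(1 - F))`, half-Gaussian
#' `lambda*erfinv(F)`), then the resulting values are discretized onto
#' `{0, ..., L-1}` by scaling the largest to `L - 1` and flooring.  To
#' avoid the singularity at `F = 1`, `F` is clipped at `1 - eps` with the
#' half-count convention `eps = 1/(2N)`.
#'
#' @param cdf nondecreasing level CDF from [roi_cdf()].
#' @param target a `"fitted_distribution"`.
#' @param L number of levels (defaults to `length(cdf)`).
#' @param n_elements ROI element count used for the clipping constant;
#'   defaults to `1e6` when unknown.
#' @return a list of class `"equalization_transform"`: `lut` (integer
#'   levels, length L), `cdf`, `L`, `target`, `raw` (the continuous
#'   quantile values before discretization).
#' @export
equalization_transform <- function(cdf, target, L = length(cdf),
                                   n_elements = 1e6) {
  stopifnot(inherits(target, "fitted_distribution"))
  if (any(cdf > 1 + 1e-9) || any(diff(cdf) < -1e-12))
    stop("cdf must be nondecreasing and bounded by 1")
  eps <- 1 / (2 * n_elements)
  f_clip <- pmin(pmax(cdf, 0), 1 - eps)
  raw <- .family_quantile(target$family, f_clip, target$lambda)
  tmax <- raw[length(raw)]
  lut <- if (tmax > 0) pmin(floor(raw / tmax * (L - 1L) + 1e-9), L - 1L)
         else rep(0L, length(raw))
  structure(list(lut = as.integer(lut), cdf = cdf, L = as.integer(L),
                 target = target, raw = raw),
            class = "equalization_transform")
}

#' Apply a level-remapping transform to ROI values
#'
#' Values are discretized to levels on the global range, remapped through
#' the lookup table, and converted back to expression units on the same
#' range (level `L - 1` maps to the global maximum).  The lookup table is
#' monotone, so the rank order of distinct values is preserved.
#'
#' @param values ROI values (matrix or vector).
#' @param transform an [equalization_transform()].
#' @param global_range `c(lo, hi)` range used for the level scale.
#' @return remapped values, same shape as `values`.
#' @export
apply_transform <- function(values, transform, global_range) {
  stopifnot(inherits(transform, "equalization_transform"))
  lo <- global_range[1L]; hi <- global_range[2L]
  if (hi <= lo) return(values)
  k <- .to_levels(as.numeric(values), lo, hi, transform$L)
  out <- lo + transform$lut[k + 1L] / (transform$L - 1L) * (hi - lo)
  if (is.matrix(values)) out <- matrix(out, nrow(values), ncol(values),
                                       dimnames = dimnames(values))
  out
}

#' Equalize every ROI of a matrix against the target distribution
#'
#' Runs the per-ROI pipeline (level histogram, CDF, inverse-sampling
#' lookup table, remap) for every window position of the grid.  Where
#' windows overlap, per-element outputs are averaged.
#'
#' @param x expression matrix.
#' @param grid a [make_roi_grid()] grid covering `x`.
#' @param target a `"fitted_distribution"`.
#' @param levels number of discretization levels (default 100).  For
#'   integer matrices whose global range is below `levels`, the distinct
#'   integer values are used as levels instead.
#' @param clip_limit optional contrast-limiting clip: histogram
#'   probabilities are capped at `clip_limit / L` and the excess mass is
#'   redistributed uniformly before the CDF (default: no clipping).
#' @param cdf_extra_norm see [roi_cdf()].
#' @return the equalized matrix, same shape as `x`.
#' @export
equalize_all <- function(x, grid, target, levels = 100L, clip_limit = NULL,
                         cdf_extra_norm = FALSE) {
  x <- as.matrix(x)
  stopifnot(inherits(grid, "roi_grid"))
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(x)
  L <- as.integer(levels)
  # raw low-range integer data: use the integer values themselves as levels
  if (all(x == round(x)) && (hi - lo) < L) L <- as.integer(hi - lo) + 1L
  if (L < 2L) return(x)
  acc <- matrix(0, nrow(x), ncol(x))
  cnt <- matrix(0L, nrow(x), ncol(x))
  for (roi in grid$rois) {
    ri <- roi[1L]:roi[2L]; ci <- roi[3L]:roi[4L]
    sub <- x[ri, ci, drop = FALSE]
    h <- roi_histogram(sub, levels = L, global_range = c(lo, hi))
    p <- h$p
    if (!is.null(clip_limit)) p <- .clip_histogram(p, clip_limit)
    f <- cumsum(p)
    if (cdf_extra_norm) f <- f / h$total
    tr <- equalization_transform(f, target, L = L, n_elements = h$total)
    acc[ri, ci] <- acc[ri, ci] + apply_transform(sub, tr, c(lo, hi))
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) stop("ROI grid does not cover the matrix")
  out <- acc / cnt
  dimnames(out) <- dimnames(x)
  out
}

# CLAHE-style clip: cap bin mass at clip_limit/L, redistribute the excess
# uniformly (single pass), then renormalize
.clip_histogram <- function(p, clip_limit) {
  cap <- clip_limit / length(p)
  excess <- sum(pmax(p - cap, 0))
  p <- pmin(p, cap) + excess / length(p)
  p / sum(p)
}

#' Bilinear resampling for cross-window consistency
#'
#' Replaces every element by the average of its four diagonal neighbours,
#' with zero padding outside the matrix, smoothing the seams between
#' independently equalized windows.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @examples
#' bilinear_resample(matrix(1, 2, 2))   # every entry 1/4
#' @export
bilinear_resample <- function(x) {
  x <- as.matrix(x)
  q <- nrow(x); m <- ncol(x)
  pad <- matrix(0, q + 2L, m + 2L)
  pad[2L:(q + 1L), 2L:(m + 1L)] <- x
  out <- (pad[1L:q, 1L:m] + pad[1L:q, 3L:(m + 2L)] +
          pad[3L:(q + 2L), 3L:(m + 2L)] + pad[3L:(q + 2L), 1L:m]) / 4
  dimnames(out) <- dimnames(x)
  out
}

#' Resample only the seams between ROIs
#'
#' Applies [bilinear_resample()] along the rows and columns that border
#' an internal ROI boundary of the grid (one row/column on each side),
#' leaving the window interiors untouched.  This smooths the level jumps
#' where independently equalized windows meet without mixing unrelated
#' genes and cells away from the seams.
#'
#' @param x equalized matrix.
#' @param grid the [make_roi_grid()] grid that produced it.
#' @return matrix of the same shape.
#' @export
seam_resample <- function(x, grid) {
  x <- as.matrix(x)
  stopifnot(inherits(grid, "roi_grid"))
  q <- nrow(x); m <- ncol(x)
  row_bounds <- unique(vapply(grid$rois, `[`, numeric(1L), 2L))
  col_bounds <- unique(vapply(grid$rois, `[`, numeric(1L), 4L))
  seam_rows <- unique(unlist(lapply(row_bounds[row_bounds < q],
                                    function(b) c(b, b + 1L))))
  seam_cols <- unique(unlist(lapply(col_bounds[col_bounds < m],
                                    function(b) c(b, b + 1L))))
  if (length(seam_rows) == 0L && length(seam_cols) == 0L) return(x)
  full <- bilinear_resample(x)
  out <- x
  out[seam_rows, ] <- full[seam_rows, ]
  out[, seam_cols] <- full[, seam_cols]
  out
}
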