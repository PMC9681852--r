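#' Per-cell Pearson correlation with a reference
#'
#' Correlates each cell's gene expression vector in `estimate` with the
#' matching cell of `reference`, using the usual (m - 1) sample
#' convention.  Cells with zero variance in either matrix give `NA` (with
#' a warning).
#'
#' @param reference,estimate matrices of identical shape and identifier
#'   order, cells in rows.
#' @return numeric vector of length `nrow(reference)`.
#' @export
pearson_per_cell <- function(reference, estimate) {
  reference <- as.matrix(reference); estimate <- as.matrix(estimate)
  if (!identical(dim(reference), dim(estimate)))
    stop("reference and estimate must have identical dimensions")
  a <- reference - rowMeans(reference)
  b <- estimate - rowMeans(estimate)
  sa <- sqrt(rowSums(a^2)); sb <- sqrt(rowSums(b^2))
  rho <- rowSums(a * b) / (sa * sb)
  rho[sa == 0 | sb == 0] <- NA_real_
  if (anyNA(rho))
    warning(sprintf("%d cell(s) with zero variance; Pearson set to NA",
                    sum(is.na(rho))))
  unname(rho)
}

#' Percent change of mean correlation over observed data
#'
#' `100 * (rho_method - rho_observed) / rho_observed`: the improvement of
#' an imputation method's mean per-cell Pearson correlation relative to
#' leaving the observed data untouched.
#'
#' @param rho_method mean per-cell Pearson of the imputed data.
#' @param rho_observed mean per-cell Pearson of the observed data.
#' @return percent change (positive = improvement).
#' @export
percent_change <- function(rho_method, rho_observed) {
  if (rho_observed == 0)
    stop("percent change is undefined for rho_observed == 0")
  100 * (rho_method - rho_observed) / rho_observed
}

# ---- clustering agreement indices -------------------------------------------

# all permutations of 1..k (k! rows); used for the exact best label map
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

# maximum-agreement bijection cluster -> truth on a contingency table;
# exact for k <= 7, greedy beyond; ties broken by lowest index
.best_map <- function(tab) {
  k <- nrow(tab)
  if (k <= 7L) {
    perms <- .permutations(k)
    scores <- apply(perms, 1L, function(p)
      sum(tab[cbind(seq_len(k), p)]))
    perms[which.max(scores), ]
  } else {
    map <- integer(k)
    free <- rep(TRUE, ncol(tab))
    for (i in order(-apply(tab, 1L, max))) {
      j <- which(free)[which.max(tab[i, free])]
      map[i] <- j; free[j] <- FALSE
    }
    map
  }
}

# contingency-table pair counts used by ARI and Hubert's gamma
.pair_counts <- function(tab) {
  n <- sum(tab)
  list(M = choose(n, 2),
       a = sum(choose(tab, 2)),
       P = sum(choose(rowSums(tab), 2)),
       Q = sum(choose(colSums(tab), 2)))
}

.adjusted_rand <- function(tab) {
  pc <- .pair_counts(tab)
  expected <- pc$P * pc$Q / pc$M
  denom <- (pc$P + pc$Q) / 2 - expected
  if (denom == 0) return(0)
  (pc$a - expected) / denom
}

# normalized Hubert gamma: Pearson correlation of the two co-membership
# indicator matrices over all pairs
.hubert_gamma <- function(tab) {
  pc <- .pair_counts(tab)
  denom <- sqrt(pc$P * pc$Q * (pc$M - pc$P) * (pc$M - pc$Q))
  if (denom == 0) return(0)
  (pc$M * pc$a - pc$P * pc$Q) / denom
}

# NMI with arithmetic-mean normalization: 2 I(X;Y) / (H(X) + H(Y))
.nmi <- function(tab) {
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)
  2 * mi / (hx + hy)
}

# k-means++ seeding (squared-Euclidean D^2 weighting)
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) for (i in 2L:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[i, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[i, ])^2))
  }
  centers
}

#' Clustering-based quality metrics against ground-truth labels
#'
#' Clusters the rows of `x` with k-means (Euclidean distance, k-means++
#' seeding, `k` = number of distinct truth labels), repeated over
#' `n_init` independent initializations.  Cluster labels are matched to
#' the truth by the maximum-agreement bijection, and accuracy, NMI,
#' adjusted Rand and Hubert indices are computed from the mapped
#' contingency table of the best-inertia solution.  Per-initialization
#' accuracies are summarized by their mean and SD.
#'
#' @param x numeric matrix (cells x features), e.g. a PCA embedding.
#' @param truth_labels ground-truth class per row (>= 2 classes).
#' @param n_init number of k-means++ initializations (default 1000).
#' @param seed integer seed.
#' @param iter_max k-means iteration cap per run.
#' @return list with `accuracy`, `accuracy_mean`, `accuracy_sd`, `nmi`,
#'   `adjusted_rand`, `hubert`, `n_clusters`, `n_init` and `cluster`
#'   (mapped labels of the best run).
#' @export
cluster_metrics <- function(x, truth_labels, n_init = 1000L, seed = NULL,
                            iter_max = 100L) {
  x <- as.matrix(x)
  truth <- as.integer(factor(truth_labels))
  k <- length(unique(truth))
  if (k < 2L) stop("need at least 2 ground-truth classes")
  if (nrow(x) < k) stop("fewer samples than clusters")
  if (length(truth) != nrow(x)) stop("labels length must match rows of x")
  with_seed(seed, {
    best <- NULL; best_ss <- Inf
    accs <- numeric(n_init)
    for (r in seq_len(n_init)) {
      centers <- .kmeanspp_centers(x, k)
      km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                           iter.max = iter_max))
      tab <- table(factor(km$cluster, levels = seq_len(k)),
                   factor(truth, levels = seq_len(k)))
      map <- .best_map(tab)
      accs[r] <- sum(tab[cbind(seq_len(k), map)]) / length(truth)
      if (km$tot.withinss < best_ss) {
        best_ss <- km$tot.withinss
        best <- list(cluster = km$cluster, tab = tab, map = map, acc = accs[r])
      }
    }
    list(accuracy = best$acc,
         accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
         nmi = .nmi(best$tab), adjusted_rand = .adjusted_rand(best$tab),
         hubert = .hubert_gamma(best$tab),
         n_clusters = k, n_init = as.integer(n_init),
         cluster = unname(best$map[best$cluster]))
  })
}

#' Evaluate an imputation against dropout-free reference data
#'
#' Combines the per-cell Pearson correlations of observed and imputed
#' data with the reference, the percent change over observed, and (when
#' labels are given) clustering metrics on a PCA embedding of each
#' matrix.
#'
#' @param reference dropout-free matrix.
#' @param imputed imputation result, same shape.
#' @param observed optional dropout-affected input matrix.
#' @param labels optional ground-truth classes for clustering metrics.
#' @param n_pcs number of principal components for clustering (default 20).
#' @param n_init k-means initializations (default 50).
#' @param log_cpm embed on `log1p` of counts-per-10k rows before PCA
#'   (default `TRUE`), the standard scRNA-seq preprocessing; `FALSE` runs
#'   PCA on the raw values.
#' @param seed integer seed.
#' @return list with `pearson_imputed` (vector), `mean_pearson_imputed`,
#'   and when inputs allow: `mean_pearson_observed`, `percent_change`,
#'   `clusters_imputed`, `clusters_observed`.
#' @export
evaluate_imputation <- function(reference, imputed, observed = NULL,
                                labels = NULL, n_pcs = 20L, n_init = 50L,
                                log_cpm = TRUE, seed = NULL) {
  rho_imp <- pearson_per_cell(reference, imputed)
  out <- list(pearson_imputed = rho_imp,
              mean_pearson_imputed = mean(rho_imp, na.rm = TRUE))
  if (!is.null(observed)) {
    rho_obs <- pearson_per_cell(reference, observed)
    out$pearson_observed <- rho_obs
    out$mean_pearson_observed <- mean(rho_obs, na.rm = TRUE)
    out$percent_change <- percent_change(out$mean_pearson_imputed,
                                         out$mean_pearson_observed)
  }
  if (!is.null(labels)) {
    embed <- function(m) {
      if (log_cpm) {
        rs <- rowSums(m)
        m <- log1p(m / ifelse(rs > 0, rs, 1) * 1e4)
      }
      k <- min(n_pcs, ncol(m) - 1L, nrow(m) - 1L)
      stats::prcomp(m, rank. = k, center = TRUE, scale. = FALSE)$x
    }
    out$clusters_imputed <- cluster_metrics(embed(imputed), labels,
                                            n_init = n_init, seed = seed)
    if (!is.null(observed))
      out$clusters_observed <- cluster_metrics(embed(observed), labels,
                                               n_init = n_init, seed = seed)
  }
  out
}
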