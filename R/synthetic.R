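# Internal: evaluate `code` under a fixed RNG seed without disturbing the
# caller's RNG stream; seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Parameters for the group-structured count simulation
#'
#' The simulator emulates the "groups" scenario of Splat-style scRNA-seq
#' count generators: baseline gene means drawn from a Gamma distribution,
#' per-group differential expression through log-normal multiplicative
#' factors, log-normal library sizes, and Poisson counts around the
#' cell-scaled means.  Defaults give 5 groups of equal probability 0.2,
#' 2500 cells and 1200 genes.
#'
#' @param n_groups number of cell groups.
#' @param group_probs probability of each group (must sum to 1).
#' @param n_cells_per_group expected cells per group; the total number of
#'   cells is `n_groups * n_cells_per_group`.
#' @param n_genes number of genes.
#' @param gene_mean_shape,gene_mean_rate Gamma hyperparameters of the
#'   baseline gene means.
#' @param de_prob probability that a gene is differentially expressed in
#'   a given group.
#' @param de_factor_sd standard deviation (log scale) of the log-normal
#'   DE factors.
#' @param libsize_log_mean,libsize_log_sd log-normal library-size
#'   parameters (natural log scale).
#' @return a list of class `"group_sim_params"`.
#' @export
group_sim_params <- function(n_groups = 5L, group_probs = rep(1 / n_groups, n_groups),
                             n_cells_per_group = 500L, n_genes = 1200L,
                             gene_mean_shape = 0.6, gene_mean_rate = 0.3,
                             de_prob = 0.1, de_factor_sd = 0.4,
                             libsize_log_mean = 11, libsize_log_sd = 0.2) {
  if (length(group_probs) != n_groups)
    stop("group_probs must have length n_groups")
  if (abs(sum(group_probs) - 1) > 1e-8)
    stop("group_probs must sum to 1")
  if (any(c(n_groups, n_cells_per_group, n_genes) <= 0) ||
      any(c(gene_mean_shape, gene_mean_rate, libsize_log_sd) <= 0) ||
      de_prob < 0 || de_prob > 1 || de_factor_sd < 0)
    stop("invalid simulation parameter")
  structure(list(n_groups = as.integer(n_groups), group_probs = group_probs,
                 n_cells_per_group = as.integer(n_cells_per_group),
                 n_genes = as.integer(n_genes),
                 gene_mean_shape = gene_mean_shape, gene_mean_rate = gene_mean_rate,
                 de_prob = de_prob, de_factor_sd = de_factor_sd,
                 libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd),
            class = "group_sim_params")
}

#' Simulate group-structured scRNA-seq counts
#'
#' Draws an integer count matrix with known group labels and no dropout:
#' the dropout-free reference of the synthetic benchmark.  Each cell is
#' assigned a group with the configured probabilities; within a group,
#' gene means are the baseline Gamma means times that group's log-normal
#' DE factors; counts are Poisson around the library-size-scaled relative
#' means.
#'
#' @param params a [group_sim_params()] object.
#' @param seed integer seed for reproducibility.
#' @return a list with elements `reference` (cells x genes integer
#'   matrix), `observed` (identical to `reference`: no dropout applied),
#'   `labels` (integer group per cell) and `dropout` (`NULL`).
#' @examples
#' d <- simulate_groups(group_sim_params(n_groups = 2, n_cells_per_group = 20,
#'                                       n_genes = 50), seed = 1)
#' dim(d$reference); table(d$labels)
#' @export
simulate_groups <- function(params = group_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "group_sim_params"))
  with_seed(seed, {
    q <- params$n_groups * params$n_cells_per_group
    m <- params$n_genes
    base_mean <- stats::rgamma(m, shape = params$gene_mean_shape,
                               rate = params$gene_mean_rate)
    # per-group multiplicative DE factors, log-normal around 1
    de_fac <- matrix(1, params$n_groups, m)
    for (k in seq_len(params$n_groups)) {
      is_de <- stats::runif(m) < params$de_prob
      de_fac[k, is_de] <- exp(stats::rnorm(sum(is_de), 0, params$de_factor_sd))
    }
    labels <- sample.int(params$n_groups, q, replace = TRUE,
                         prob = params$group_probs)
    libsize <- stats::rlnorm(q, params$libsize_log_mean, params$libsize_log_sd)
    group_mean <- sweep(de_fac, 2L, base_mean, `*`)        # groups x genes
    group_prop <- group_mean / rowSums(group_mean)
    lam <- group_prop[labels, , drop = FALSE] * libsize    # cells x genes
    counts <- matrix(stats::rpois(q * m, lam), q, m)
    counts <- expression_matrix(counts)
    list(reference = counts, observed = counts, labels = labels, dropout = NULL)
  })
}

#' TPM-normalize an expression matrix
#'
#' Scales every cell (row) to sum to one million.  No gene-length
#' correction is applied, the standard convention for UMI/droplet counts.
#'
#' @param x expression matrix, cells in rows.
#' @return matrix of the same shape with all row sums equal to `1e6`.
#' @export
tpm_normalize <- function(x) {
  x <- expression_matrix(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop(sprintf("cell '%s' has zero total expression; cannot TPM-normalize",
                 rownames(x)[which(rs == 0)[1L]]))
  x * (1e6 / rs)
}

#' Build a dropout-free reference from raw counts
#'
#' Filters a raw count matrix to the portion that can be treated as true
#' expression: the data are TPM-normalized, then the top `gene_frac` of
#' genes ranked by the proportion of cells with nonzero expression and
#' the top `cell_frac` of cells ranked by library size (total raw counts,
#' computed before normalization) are retained.
#'
#' @param raw raw count matrix, cells in rows.
#' @param gene_frac fraction of genes to keep, in `[0.1, 0.2]`.
#' @param cell_frac fraction of cells to keep, in `[0.5, 0.6]`.
#' @param allow_any_frac set `TRUE` to allow fractions outside the
#'   protocol ranges (e.g. `gene_frac = 1` keeps everything).
#' @return TPM-scale reference matrix, identifiers preserved.
#' @export
build_reference <- function(raw, gene_frac = 0.15, cell_frac = 0.55,
                            allow_any_frac = FALSE) {
  raw <- expression_matrix(raw)
  if (nrow(raw) < 4L || ncol(raw) < 10L)
    stop("need at least 4 cells and 10 genes to build a reference")
  if (!allow_any_frac &&
      (gene_frac < 0.1 || gene_frac > 0.2 || cell_frac < 0.5 || cell_frac > 0.6))
    stop("gene_frac must lie in [0.1, 0.2] and cell_frac in [0.5, 0.6]; ",
         "set allow_any_frac = TRUE to override")
  libsize <- rowSums(raw)
  nonzero_prop <- colMeans(raw > 0)
  tpm <- tpm_normalize(raw)
  n_genes <- ceiling(gene_frac * ncol(raw))
  n_cells <- ceiling(cell_frac * nrow(raw))
  keep_genes <- sort(order(-nonzero_prop)[seq_len(n_genes)])  # stable in index
  keep_cells <- sort(order(-libsize)[seq_len(n_cells)])
  tpm[keep_cells, keep_genes, drop = FALSE]
}

# nominal efficiency (as a fraction) -> Gamma rate, at fixed shape 10
.efficiency_rates <- c(`10` = 100, `5` = 200, `2` = 500, `1` = 1000,
                       `0.5` = 2000, `0.2` = 5000, `0.1` = 10000)

#' Sample per-cell capture efficiencies
#'
#' Draws the cell-specific efficiency-loss factors tau_c from a Gamma
#' distribution with shape 10 and a rate chosen so that the mean
#' shape/rate equals the nominal efficiency: 10\% -> Gamma(10, 100),
#' 5\% -> Gamma(10, 200), 2\% -> Gamma(10, 500), 1\% -> Gamma(10, 1000),
#' 0.5\% -> Gamma(10, 2000), 0.2\% -> Gamma(10, 5000),
#' 0.1\% -> Gamma(10, 10000).
#'
#' @param level nominal efficiency in percent: one of 10, 5, 2, 1, 0.5,
#'   0.2, 0.1 (numeric, or a string such as `"1%"`).
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return a list of class `"dropout_model"` with fields `level`
#'   (efficiency fraction), `gamma_shape`, `gamma_rate`, `tau` and `seed`.
#' @export
sample_efficiency <- function(level, n_cells, seed = NULL) {
  key <- sub("%$", "", as.character(level))
  if (!key %in% names(.efficiency_rates))
    stop("efficiency level must be one of 10, 5, 2, 1, 0.5, 0.2, 0.1 (percent)")
  if (length(n_cells) != 1L || n_cells <= 0)
    stop("n_cells must be a positive integer")
  rate <- .efficiency_rates[[key]]
  tau <- with_seed(seed, stats::rgamma(n_cells, shape = 10, rate = rate))
  structure(list(level = as.numeric(key) / 100, gamma_shape = 10,
                 gamma_rate = rate, tau = tau, seed = seed),
            class = "dropout_model")
}

#' Apply gamma-Poisson efficiency loss to a reference matrix
#'
#' Generates observed (dropout-affected) data from true expression: entry
#' `[c, g]` is drawn `Poisson(tau_c * reference[c, g])`, emulating the
#' capture loss of low-efficiency protocols.  Smaller reference values
#' are more likely to drop to zero, and lower efficiencies give more
#' zeros overall.
#'
#' @param reference true-expression matrix, cells in rows.
#' @param model a [sample_efficiency()] dropout model with `tau` of
#'   length `nrow(reference)`.
#' @param seed integer seed for the Poisson draws.
#' @return integer matrix of observed counts, same shape and identifiers.
#' @export
apply_dropout <- function(reference, model, seed = NULL) {
  reference <- expression_matrix(reference)
  stopifnot(inherits(model, "dropout_model"))
  if (length(model$tau) != nrow(reference))
    stop("model$tau length must equal the number of cells")
  lam <- reference * model$tau
  obs <- with_seed(seed, matrix(stats::rpois(length(lam), lam),
                                nrow(reference), ncol(reference)))
  dimnames(obs) <- dimnames(reference)
  obs
}

#' Simulate a full dropout benchmark dataset
#'
#' Convenience wrapper chaining [simulate_groups()] and
#' [apply_dropout()]: the simulated counts form the dropout-free
#' reference and observed data are generated from them at the requested
#' efficiency.  Real datasets are TPM-converted before downsampling (see
#' [build_reference()]); simulated counts are used directly, matching the
#' count-scale zero inflation the benchmark is meant to exhibit —
#' `normalize = "tpm"` switches to a TPM-scale reference.
#'
#' @param params a [group_sim_params()] object.
#' @param efficiency nominal efficiency in percent (see
#'   [sample_efficiency()]).
#' @param normalize `"none"` (default) or `"tpm"`.
#' @param seed integer master seed.
#' @return list with `reference`, `observed` (counts), `labels` and
#'   `dropout` (the [sample_efficiency()] model used).
#' @export
simulate_benchmark <- function(params = group_sim_params(), efficiency = 1,
                               normalize = c("none", "tpm"), seed = NULL) {
  normalize <- match.arg(normalize)
  sim <- simulate_groups(params, seed = seed)
  ref <- if (normalize == "tpm") tpm_normalize(sim$reference) else sim$reference
  model <- sample_efficiency(efficiency, nrow(ref),
                             seed = if (is.null(seed)) NULL else seed + 1L)
  obs <- apply_dropout(ref, model,
                       seed = if (is.null(seed)) NULL else seed + 2L)
  list(reference = ref, observed = obs, labels = sim$labels, dropout = model)
}
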