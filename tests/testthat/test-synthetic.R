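test_that("group simulation has the configured shape, labels and determinism", {
  p <- group_sim_params(n_groups = 4L, n_cells_per_group = 30L, n_genes = 80L)
  d1 <- simulate_groups(p, seed = 3)
  d2 <- simulate_groups(p, seed = 3)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$labels, d2$labels)
  expect_equal(dim(d1$reference), c(120L, 80L))
  expect_equal(sort(unique(d1$labels)), 1:4)
  expect_true(all(d1$reference == round(d1$reference)))
  expect_identical(d1$observed, d1$reference)
  expect_null(d1$dropout)
})

test_that("default parameters give the five-group 2500 x 1200 benchmark", {
  p <- group_sim_params()
  expect_equal(p$n_groups, 5L)
  expect_equal(p$group_probs, rep(0.2, 5))
  d <- simulate_groups(p, seed = 1)
  expect_equal(dim(d$reference), c(2500L, 1200L))
  expect_equal(length(unique(d$labels)), 5L)
})

test_that("invalid group probabilities are rejected", {
  expect_error(group_sim_params(n_groups = 3, group_probs = c(0.5, 0.4, 0.3)),
               "sum to 1")
  expect_error(group_sim_params(n_groups = 2, group_probs = c(1)), "length")
})

test_that("without differential expression group means match the global mean", {
  p <- group_sim_params(n_groups = 3L, n_cells_per_group = 150L,
                        n_genes = 50L, de_prob = 0)
  d <- simulate_groups(p, seed = 5)
  # normalize out library size, then compare group means to the global mean
  cpm <- d$reference / rowSums(d$reference)
  glob <- colMeans(cpm)
  for (g in 1:3) {
    grp <- colMeans(cpm[d$labels == g, , drop = FALSE])
    n_g <- sum(d$labels == g)
    se <- apply(cpm[d$labels == g, , drop = FALSE], 2, sd) / sqrt(n_g)
    expect_lt(max(abs(grp - glob) / pmax(se, 1e-12)), 6)
  }
})

test_that("TPM normalization scales every cell to one million", {
  m <- tpm_normalize(matrix(c(1, 1, 2), 1, 3))
  expect_equal(unname(m[1, ]), c(250000, 250000, 500000))
  expect_equal(tpm_normalize(m), m)   # idempotent
  x <- rand_counts(20, 30, seed = 2) + 1
  expect_true(all(abs(rowSums(tpm_normalize(x)) - 1e6) < 1e-6))
  bad <- rbind(c(1, 2), c(0, 0))
  expect_error(tpm_normalize(bad), "cell_2")
})

test_that("reference building keeps the top-detected genes and largest cells", {
  # gene g nonzero in exactly g of 10 cells
  m <- matrix(0, 10, 10)
  for (g in 1:10) m[seq_len(g), g] <- 1
  m[1, ] <- m[1, ] + 1   # avoid all-zero rows, keeps ordering intact
  ref <- build_reference(m, gene_frac = 0.2, cell_frac = 0.5)
  expect_equal(colnames(ref), c("gene_9", "gene_10"))

  m2 <- matrix(1, 4, 10)
  m2 <- m2 * c(1, 2, 3, 4) / 10          # library sizes 1, 2, 3, 4
  ref2 <- build_reference(m2, gene_frac = 0.2, cell_frac = 0.5)
  expect_equal(rownames(ref2), c("cell_3", "cell_4"))

  expect_error(build_reference(m, gene_frac = 0.5, cell_frac = 0.5),
               "allow_any_frac")
  ref3 <- build_reference(m2, gene_frac = 1, cell_frac = 1,
                          allow_any_frac = TRUE)
  expect_equal(unname(ref3), unname(tpm_normalize(m2)))
})

test_that("efficiency levels map to the Gamma(10, rate) table", {
  rates <- c(`10` = 100, `5` = 200, `2` = 500, `1` = 1000,
             `0.5` = 2000, `0.2` = 5000, `0.1` = 10000)
  for (lvl in names(rates)) {
    mod <- sample_efficiency(as.numeric(lvl), 10, seed = 1)
    expect_equal(mod$gamma_shape, 10)
    expect_equal(mod$gamma_rate, unname(rates[lvl]))
    expect_equal(mod$level, as.numeric(lvl) / 100)
  }
  expect_error(sample_efficiency(3, 10), "must be one of")
  expect_error(sample_efficiency(1, 0), "positive")
  expect_identical(sample_efficiency("1%", 50, seed = 4)$tau,
                   sample_efficiency(1, 50, seed = 4)$tau)
})

test_that("sampled efficiencies concentrate on the nominal mean", {
  mod <- sample_efficiency(0.1, 1e5, seed = 2)
  se <- 0.001 / sqrt(10 * 1e5)     # sd of Gamma(10, 1e4) over sqrt(n)
  expect_lt(abs(mean(mod$tau) - 0.001), 3 * se)
  expect_true(all(mod$tau > 0))
})

test_that("dropout is Poisson thinning with the expected moments", {
  ref <- matrix(1000, 100, 100)
  mod <- sample_efficiency(1, 100, seed = 3)
  mod$tau <- rep(0.01, 100)
  obs <- apply_dropout(ref, mod, seed = 4)
  expect_true(all(obs == round(obs)))
  expect_lt(abs(mean(obs) - 10), 3 * sqrt(10 / 1e4))

  mod$tau[1] <- 0
  obs2 <- apply_dropout(ref, mod, seed = 4)
  expect_true(all(obs2[1, ] == 0))

  ref[2, ] <- 0
  obs3 <- apply_dropout(ref, mod, seed = 4)
  expect_true(all(obs3[2, ] == 0))

  mod$tau <- mod$tau[1:5]
  expect_error(apply_dropout(ref, mod), "length")
})

test_that("zero fraction rises as efficiency falls, and hits small values first", {
  ref <- simulate_groups(group_sim_params(n_groups = 2L, n_cells_per_group = 100L,
                                          n_genes = 200L), seed = 9)$reference
  zf <- sapply(c(10, 5, 2, 1, 0.5, 0.2, 0.1), function(lvl) {
    mod <- sample_efficiency(lvl, nrow(ref), seed = 21)
    mean(apply_dropout(ref, mod, seed = 22) == 0)
  })
  expect_true(all(diff(zf) >= 0))   # ordered from high to low efficiency

  mod <- sample_efficiency(1, nrow(ref), seed = 23)
  obs <- apply_dropout(ref, mod, seed = 24)
  lo <- ref > 0 & ref <= quantile(ref[ref > 0], 0.25)
  hi <- ref >= quantile(ref[ref > 0], 0.75)
  expect_gt(mean(obs[lo] == 0), mean(obs[hi] == 0))
})

test_that("benchmark wrapper wires reference, observed and dropout together", {
  d <- small_benchmark(seed = 13)
  expect_equal(dim(d$reference), dim(d$observed))
  expect_equal(length(d$labels), nrow(d$reference))
  expect_s3_class(d$dropout, "dropout_model")
  expect_gt(mean(d$observed == 0), mean(d$reference == 0))
  expect_identical(small_benchmark(seed = 13)$observed, d$observed)
})
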