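test_that("default grid tiles a matrix into four half-size quadrants", {
  g <- make_roi_grid(100, 200)
  expect_length(g$rois, 4L)
  sizes <- t(vapply(g$rois, function(r) c(r[2] - r[1] + 1, r[4] - r[3] + 1),
                    numeric(2)))
  expect_true(all(sizes[, 1] == 50 & sizes[, 2] == 100))
  expect_false(g$overlap)
})

test_that("grid overrides give explicit tilings", {
  g <- make_roi_grid(480, 100, grid_override = c(24, 2))
  expect_length(g$rois, 48L)
})

test_that("remainders are absorbed into the edge tiles", {
  g <- make_roi_grid(101, 201)
  expect_length(g$rois, 4L)
  last <- g$rois[[4]]
  expect_equal(c(last[2] - last[1] + 1, last[4] - last[3] + 1), c(51, 101))
  # every element covered exactly once
  cover <- matrix(0L, 101, 201)
  for (r in g$rois) cover[r[1]:r[2], r[3]:r[4]] <- cover[r[1]:r[2], r[3]:r[4]] + 1L
  expect_true(all(cover == 1L))
})

test_that("overlapping windows cover every element at least once", {
  g <- make_roi_grid(55, 37, window_frac = 0.5, step_frac = 0.25)
  expect_true(g$overlap)
  cover <- matrix(0L, 55, 37)
  for (r in g$rois) cover[r[1]:r[2], r[3]:r[4]] <- cover[r[1]:r[2], r[3]:r[4]] + 1L
  expect_true(all(cover >= 1L))
})

test_that("a window spanning the matrix collapses to one ROI with a warning", {
  expect_warning(g <- make_roi_grid(5, 5, window_frac = 1), "single ROI")
  expect_length(g$rois, 1L)
})

test_that("ROI histograms bin on the shared global range", {
  h <- roi_histogram(matrix(0, 4, 4), levels = 10, global_range = c(0, 9))
  expect_equal(h$p[1], 1)
  h2 <- roi_histogram(matrix(c(0, 0, 7, 7), 2, 2), levels = 100,
                      global_range = c(0, 7))
  expect_equal(h2$p[1], 0.5)
  expect_equal(h2$p[100], 0.5)
  expect_equal(sum(h2$p), 1)
})

test_that("the level CDF is the plain cumulative sum reaching one", {
  h <- list(p = c(0.5, 0.5), total = 10)
  class(h) <- "histogram_model"
  expect_equal(roi_cdf(h), c(0.5, 1.0))
  h1 <- list(p = 1, total = 4); class(h1) <- "histogram_model"
  expect_equal(roi_cdf(h1), 1)
  set.seed(2)
  p <- runif(50); p <- p / sum(p)
  hr <- list(p = p, total = 100); class(hr) <- "histogram_model"
  f <- roi_cdf(hr)
  expect_true(all(diff(f) >= 0))
  expect_equal(f[50], 1, tolerance = 1e-12)
  # printed alternative normalization retained for audit: capped at 1/N
  expect_equal(max(roi_cdf(hr, extra_norm = TRUE)), 1 / 100, tolerance = 1e-12)
})

test_that("the raw transform matches the inverse-sampling closed forms", {
  tr <- equalization_transform(c(0, 0.5, 1), make_target("exponential", 1),
                               L = 3, n_elements = 100)
  expect_equal(tr$raw[1], 0)                       # F = 0 maps to 0
  tr2 <- equalization_transform(c(1 - exp(-1), 1), make_target("exponential", 1),
                                L = 2, n_elements = 1e6)
  expect_equal(tr2$raw[1], 1)                      # -ln(e^-1) / 1
  expect_error(equalization_transform(c(0.5, 1.1), make_target("exponential", 10)),
               "bounded by 1")
})

test_that("luts equal the brute-force discretized inverse CDF for every family", {
  set.seed(8)
  for (spec in list(c("exponential", 10), c("rayleigh", 0.3),
                    c("gaussian", 0.3))) {
    fam <- spec[1]; lam <- as.numeric(spec[2])
    p <- runif(100); p <- p / sum(p)
    f <- cumsum(p)
    n_el <- 5000
    tr <- equalization_transform(f, make_target(fam, lam), L = 100,
                                 n_elements = n_el)
    expect_identical(tr$lut, oracle_lut(fam, lam, f, 100, n_el))
    expect_true(all(diff(tr$lut) >= 0))
    expect_equal(tr$lut[100], 99L)
  }
})

test_that("applying a transform is monotone and preserves constants", {
  tgt <- make_target("exponential", 10)
  const <- matrix(4, 3, 3)
  h <- roi_histogram(const, 100, c(0, 10))
  tr <- equalization_transform(roi_cdf(h), tgt, n_elements = 9)
  out <- apply_transform(const, tr, c(0, 10))
  expect_equal(length(unique(as.numeric(out))), 1L)

  set.seed(3)
  v <- matrix(runif(400, 0, 10), 20, 20)
  h2 <- roi_histogram(v, 100, c(0, 10))
  tr2 <- equalization_transform(roi_cdf(h2), tgt, n_elements = 400)
  out2 <- apply_transform(v, tr2, c(0, 10))
  ord <- order(v)
  expect_true(all(diff(out2[ord]) >= -1e-12))      # a <= b keeps a' <= b'
})

test_that("zeros with positive CDF mass impute to nonzero values", {
  v <- matrix(c(rep(0, 50), runif(50, 5, 10)), 10, 10)
  h <- roi_histogram(v, 100, c(0, 10))
  f <- roi_cdf(h)
  tr <- equalization_transform(f, make_target("exponential", 10),
                               n_elements = 100)
  # F(0) = 0.5 -> raw = ln(2)/10; rescaled level must be positive
  expect_equal(tr$raw[1], log(2) / 10)
  expect_gt(tr$lut[1], 0)
  out <- apply_transform(v, tr, c(0, 10))
  expect_true(all(out[v == 0] > 0))
})

test_that("a single-ROI grid reduces equalize_all to one global transform", {
  x <- matrix(runif(600, 0, 8), 20, 30)
  suppressWarnings(g1 <- make_roi_grid(20, 30, window_frac = 1))
  tgt <- make_target("rayleigh", 0.3)
  all1 <- equalize_all(x, g1, tgt, levels = 100)
  h <- roi_histogram(x, 100, range(x))
  tr <- equalization_transform(roi_cdf(h), tgt, n_elements = 600)
  expect_equal(unname(all1), unname(apply_transform(x, tr, range(x))))
})

test_that("non-overlapping quadrants are equalized independently", {
  set.seed(5)
  x <- matrix(runif(1600, 0, 3), 40, 40)
  g <- make_roi_grid(40, 40)
  tgt <- make_target("exponential", 10)
  full <- equalize_all(x, g, tgt, levels = 100)
  for (r in g$rois) {
    sub <- x[r[1]:r[2], r[3]:r[4]]
    h <- roi_histogram(sub, 100, range(x))
    tr <- equalization_transform(roi_cdf(h), tgt, n_elements = length(sub))
    expect_equal(unname(full[r[1]:r[2], r[3]:r[4]]),
                 unname(apply_transform(sub, tr, range(x))))
  }
})

test_that("quadrants with identical value multisets transform identically", {
  set.seed(6)
  q <- matrix(sample(0:9, 100, replace = TRUE), 10, 10)
  x <- rbind(cbind(q, q[, sample(10)]), cbind(q[sample(10), ], q))
  g <- make_roi_grid(20, 20)
  out <- equalize_all(x, g, make_target("exponential", 10), levels = 10)
  expect_equal(sort(as.numeric(out[1:10, 1:10])),
               sort(as.numeric(out[11:20, 11:20])))
})

test_that("equalization puts unevenly corrupted matrix blocks on one scale", {
  # top block captured at 2% efficiency, bottom block at 0.2%: the observed
  # blocks live on scales an order of magnitude apart; equalizing every ROI
  # to one target density must pull their summary statistics together
  sim <- simulate_groups(group_sim_params(n_groups = 3L, n_cells_per_group = 60L,
                                          n_genes = 120L), seed = 31)
  ref <- sim$reference
  mod <- sample_efficiency(2, nrow(ref), seed = 32)
  mod$tau[91:180] <- sample_efficiency(0.2, 90, seed = 33)$tau
  obs <- apply_dropout(ref, mod, seed = 34)
  g <- make_roi_grid(nrow(obs), ncol(obs))
  out <- equalize_all(obs, g, make_target("exponential", 10), levels = 100)
  rel_spread <- function(m, stat) {
    v <- vapply(g$rois, function(r) stat(m[r[1]:r[2], r[3]:r[4]]), numeric(1))
    (max(v) - min(v)) / mean(v)
  }
  expect_lt(rel_spread(out, mean), 0.5 * rel_spread(obs, mean))
  expect_lt(rel_spread(out, function(x) quantile(x, 0.9)),
            0.5 * rel_spread(obs, function(x) quantile(x, 0.9)))
})

test_that("overlapping windows blend by per-element averaging", {
  set.seed(9)
  x <- matrix(runif(900, 0, 5), 30, 30)
  g <- make_roi_grid(30, 30, window_frac = 0.5, step_frac = 0.25)
  out <- equalize_all(x, g, make_target("exponential", 10), levels = 50)
  expect_true(all(is.finite(out)) && all(out >= 0))
  # manual accumulation oracle
  acc <- matrix(0, 30, 30); cnt <- matrix(0, 30, 30)
  for (r in g$rois) {
    sub <- x[r[1]:r[2], r[3]:r[4]]
    h <- roi_histogram(sub, 50, range(x))
    tr <- equalization_transform(roi_cdf(h), make_target("exponential", 10),
                                 L = 50, n_elements = length(sub))
    acc[r[1]:r[2], r[3]:r[4]] <- acc[r[1]:r[2], r[3]:r[4]] +
      apply_transform(sub, tr, range(x))
    cnt[r[1]:r[2], r[3]:r[4]] <- cnt[r[1]:r[2], r[3]:r[4]] + 1
  }
  expect_equal(unname(out), acc / cnt)
})

test_that("histogram clipping caps bin mass and preserves normalization", {
  p <- c(0.9, 0.05, 0.05, 0, 0)
  pc <- screq:::.clip_histogram(p, clip_limit = 2)
  expect_equal(sum(pc), 1)
  expect_lt(max(pc), 0.9)
  x <- matrix(c(rep(0, 90), runif(10, 5, 10)), 10, 10)
  suppressWarnings(g <- make_roi_grid(10, 10, window_frac = 1))
  out_clip <- equalize_all(x, g, make_target("exponential", 10), levels = 20,
                           clip_limit = 2)
  expect_true(all(is.finite(out_clip)))
})

test_that("bilinear resampling matches the diagonal-average formula", {
  expect_equal(bilinear_resample(matrix(1, 2, 2)), matrix(0.25, 2, 2))
  # constant matrix: interior preserved, borders shrunk by zero padding
  cm <- bilinear_resample(matrix(3, 5, 5))
  expect_equal(cm[2:4, 2:4], matrix(3, 3, 3))
  expect_equal(cm[1, 1], 3 / 4)
  expect_equal(cm[1, 3], 3 / 2)
  # single interior spike spreads to its four diagonal neighbours
  sp <- matrix(0, 5, 5); sp[3, 3] <- 8
  out <- bilinear_resample(sp)
  expected <- matrix(0, 5, 5)
  expected[cbind(c(2, 2, 4, 4), c(2, 4, 2, 4))] <- 2
  expect_equal(out, expected)
})

test_that("seam resampling touches only window borders", {
  set.seed(10)
  x <- matrix(runif(400, 1, 5), 20, 20)
  g <- make_roi_grid(20, 20)
  out <- seam_resample(x, g)
  full <- bilinear_resample(x)
  seam <- c(10, 11)
  expect_equal(out[seam, ], full[seam, ])
  expect_equal(out[, seam], full[, seam])
  interior <- setdiff(1:20, seam)
  expect_equal(out[interior, interior], x[interior, interior])
})
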