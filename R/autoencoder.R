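#' Autoencoder configuration
#'
#' Settings of the three-layer (input, latent, output) denoising network
#' used to learn the expression distribution: a logistic-sigmoid encoder
#' to a `latent_dim`-dimensional bottleneck and a linear decoder back to
#' the gene space, trained with adam on the mean squared reconstruction
#' error plus an L2 weight penalty and a KL sparsity penalty on the mean
#' encoder activations.
#'
#' @param latent_dim latent dimension P (default 2).
#' @param encoder_activation `"sigmoid"` (default) or `"linear"`.
#' @param decoder_activation `"linear"` (default) or `"sigmoid"`.
#' @param l2_weight L2 weight-regularization coefficient (default 0.05).
#' @param sparsity_weight weight of the KL sparsity penalty (default 0.9).
#' @param sparsity_target target mean activation rho of the sparsity
#'   penalty (default 0.05).
#' @param learning_rate adam step size (default 1e-5).
#' @param max_epochs training epochs (default 20).
#' @param batch_size minibatch size (default 64).
#' @param init_range range of the uniform weight/bias initialization
#'   (default `c(0, 1)`).
#' @return a list of class `"autoencoder_config"`.
#' @export
autoencoder_config <- function(latent_dim = 2L,
                               encoder_activation = c("sigmoid", "linear"),
                               decoder_activation = c("linear", "sigmoid"),
                               l2_weight = 0.05, sparsity_weight = 0.9,
                               sparsity_target = 0.05,
                               learning_rate = 1e-5, max_epochs = 20L,
                               batch_size = 64L, init_range = c(0, 1)) {
  encoder_activation <- match.arg(encoder_activation)
  decoder_activation <- match.arg(decoder_activation)
  if (latent_dim < 1L || max_epochs < 1L || batch_size < 1L ||
      learning_rate <= 0)
    stop("invalid autoencoder configuration")
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_activation = encoder_activation,
                 decoder_activation = decoder_activation,
                 l2_weight = l2_weight, sparsity_weight = sparsity_weight,
                 sparsity_target = sparsity_target,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 init_range = init_range),
            class = "autoencoder_config")
}

.activate <- function(z, kind) if (kind == "sigmoid") stats::plogis(z) else z
.activate_grad <- function(a, kind) if (kind == "sigmoid") a * (1 - a) else 1

#' Train the denoising autoencoder
#'
#' Rows of the input (cells) are the training samples.  The matrix is
#' min-max scaled to `[0, 1]` internally; the returned reconstruction is
#' rescaled back to the input value range.  Training minimizes
#' `mean((x - x')^2)` per minibatch, plus `l2_weight/2 * sum(W^2)` over
#' both weight matrices and `sparsity_weight * sum(KL(rho || rho_hat))`
#' over the latent units, with the adam optimizer.
#'
#' @param x training matrix (cells x genes), typically a
#'   [subsample_matrix()] result.
#' @param config an [autoencoder_config()].
#' @param seed integer seed for initialization and minibatch shuffling.
#' @return a list of class `"autoencoder_fit"`: `reconstruction` (same
#'   shape and value range as `x`), `weights` (W, b, W2, b2),
#'   `loss_history` (mean epoch loss), `config`, and the internal
#'   `scale = c(lo, hi)`.
#' @export
train_autoencoder <- function(x, config = autoencoder_config(), seed = NULL) {
  x <- as.matrix(x)
  stopifnot(inherits(config, "autoencoder_config"))
  n <- nrow(x); m <- ncol(x); P <- config$latent_dim
  if (P >= m)
    stop("latent_dim must be smaller than the number of genes")
  lo <- min(x); hi <- max(x)
  X <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
  with_seed(seed, {
    ir <- config$init_range
    par <- list(W = matrix(stats::runif(P * m, ir[1L], ir[2L]), P, m),
                b = stats::runif(P, ir[1L], ir[2L]),
                W2 = matrix(stats::runif(m * P, ir[1L], ir[2L]), m, P),
                b2 = stats::runif(m, ir[1L], ir[2L]))
    adam_m <- lapply(par, function(p) p * 0)
    adam_v <- lapply(par, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L
    loss_history <- numeric(config$max_epochs)
    rho <- config$sparsity_target
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        nb <- nrow(Xb)
        ZH <- Xb %*% t(par$W) + rep(par$b, each = nb)
        H <- .activate(ZH, config$encoder_activation)            # nb x P
        ZO <- H %*% t(par$W2) + rep(par$b2, each = nb)
        O <- .activate(ZO, config$decoder_activation)            # nb x m
        R <- O - Xb
        mse <- mean(R^2)
        rho_hat <- pmin(pmax(colMeans(H), 1e-8), 1 - 1e-8)
        kl <- sum(rho * log(rho / rho_hat) +
                    (1 - rho) * log((1 - rho) / (1 - rho_hat)))
        loss <- mse + config$l2_weight / 2 *
          (sum(par$W^2) + sum(par$W2^2)) + config$sparsity_weight * kl
        if (!is.finite(loss))
          stop(sprintf(
            "non-finite training loss at epoch %d, batch %d (mse=%g, kl=%g)",
            epoch, bi, mse, kl))
        batch_losses[bi] <- loss
        dZO <- 2 * R / (nb * m) * .activate_grad(O, config$decoder_activation)
        gW2 <- t(dZO) %*% H + config$l2_weight * par$W2
        gb2 <- colSums(dZO)
        dH <- dZO %*% par$W2
        # sparsity penalty acts through the batch-mean activation
        dH <- dH + matrix(config$sparsity_weight *
                            (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / nb,
                          nb, P, byrow = TRUE)
        dZH <- dH * .activate_grad(H, config$encoder_activation)
        gW <- t(dZH) %*% Xb + config$l2_weight * par$W
        gb <- colSums(dZH)
        grads <- list(W = gW, b = gb, W2 = gW2, b2 = gb2)
        step <- step + 1L
        for (nm in names(par)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_history[epoch] <- mean(batch_losses)
    }
    H <- .activate(X %*% t(par$W) + rep(par$b, each = n),
                   config$encoder_activation)
    O <- .activate(H %*% t(par$W2) + rep(par$b2, each = n),
                   config$decoder_activation)
    recon <- O * (hi - lo) + lo
    dimnames(recon) <- dimnames(x)
    structure(list(reconstruction = recon, weights = par,
                   loss_history = loss_history, config = config,
                   scale = c(lo, hi)),
              class = "autoencoder_fit")
  })
}
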