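# Fully connected autoencoder (encoder widths n, n/2, n/4, d and the
# mirrored decoder), batch normalization + ReLU on all layers except the
# latent and output layers, mean-squared reconstruction loss, Adam, early
# stopping on a held-out validation split. Written directly in matrix
# algebra; gradients are verified against numerical differentiation in the
# test suite.

#' Autoencoder architecture and training specification
#'
#' @param d latent dimension (>= 1).
#' @param n_channels input width; layer widths scale proportionally
#'   (ratios 1 : 0.5 : 0.25 : d) so 64 channels give the 64-32-16-d
#'   bottleneck architecture.
#' @param batch minibatch size in frames (default 256).
#' @param max_epochs training epoch cap (default 400).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 50).
#' @param val_frac held-out validation fraction (default 0.3, i.e. a
#'   70/30 train/test split).
#' @param lr Adam learning rate (default 1e-3).
#' @return an object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(d, n_channels = 64, batch = 256,
                             max_epochs = 400, patience = 50,
                             val_frac = 0.3, lr = 1e-3) {
  stopifnot(d >= 1, n_channels >= 2)
  widths <- c(n_channels, max(2, round(n_channels / 2)),
              max(2, round(n_channels / 4)), d,
              max(2, round(n_channels / 4)), max(2, round(n_channels / 2)),
              n_channels)
  structure(
    list(d = as.integer(d), widths = widths,
         batchnorm = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
         batch = batch, max_epochs = max_epochs, patience = patience,
         val_frac = val_frac, lr = lr),
    class = "autoencoder_spec"
  )
}

ae_init_params <- function(spec) {
  lapply(seq_len(6), function(l) {
    n_in <- spec$widths[l]; n_out <- spec$widths[l + 1]
    p <- list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                         n_in, n_out),
              b = rep(0, n_out))
    if (spec$batchnorm[l]) {
      p$gamma <- rep(1, n_out); p$beta <- rep(0, n_out)
      p$rmean <- rep(0, n_out); p$rvar <- rep(1, n_out)
    }
    p
  })
}

BN_EPS <- 1e-5

# Column-wise shift/scale by recycling a per-unit vector down the rows
# (substantially faster than sweep() in the minibatch hot path).
col_add <- function(Z, v) Z + rep(v, each = nrow(Z))
col_mul <- function(Z, v) Z * rep(v, each = nrow(Z))

# Forward pass. training = TRUE uses batch statistics and returns the
# caches needed for backprop; training = FALSE uses the running statistics.
ae_forward <- function(params, spec, X, training = FALSE) {
  H <- X
  caches <- vector("list", 6)
  for (l in seq_len(6)) {
    p <- params[[l]]
    Z <- col_add(H %*% p$W, p$b)
    if (spec$batchnorm[l]) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
      } else {
        mu <- p$rmean; v <- p$rvar
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      Zh <- col_mul(col_add(Z, -mu), inv_sd)
      Y <- col_add(col_mul(Zh, p$gamma), p$beta)
      A <- (Y > 0) * Y
      caches[[l]] <- list(H_in = H, Zh = Zh, Y = Y, v = v, mu = mu)
    } else {
      A <- Z
      caches[[l]] <- list(H_in = H)
    }
    H <- A
  }
  list(out = H, caches = caches)
}

# Loss and gradients for one minibatch (training-mode batch statistics).
ae_loss_grad <- function(params, spec, X) {
  fw <- ae_forward(params, spec, X, training = TRUE)
  B <- nrow(X)
  n_out <- ncol(X)
  resid <- fw$out - X
  loss <- mean(resid^2)
  dH <- 2 * resid / (B * n_out)
  grads <- vector("list", 6)
  for (l in 6:1) {
    p <- params[[l]]
    cache <- fw$caches[[l]]
    if (spec$batchnorm[l]) {
      dY <- dH * (cache$Y > 0)
      dgamma <- colSums(dY * cache$Zh)
      dbeta <- colSums(dY)
      dZh <- col_mul(dY, p$gamma)
      inv_sd <- 1 / sqrt(cache$v + BN_EPS)
      s1 <- colSums(dZh)
      s2 <- colSums(dZh * cache$Zh)
      dZ <- col_mul(col_add(dZh * B, -s1) - col_mul(cache$Zh, s2),
                    inv_sd / B)
      grads[[l]] <- list(gamma = dgamma, beta = dbeta)
    } else {
      dZ <- dH
      grads[[l]] <- list()
    }
    grads[[l]]$W <- crossprod(cache$H_in, dZ)
    grads[[l]]$b <- colSums(dZ)
    dH <- dZ %*% t(p$W)
    if (spec$batchnorm[l]) {
      grads[[l]]$mu <- cache$mu
      grads[[l]]$v <- cache$v
    }
  }
  list(loss = loss, grads = grads)
}

ae_adam_init <- function(params) {
  lapply(params, function(p) {
    s <- list(W = list(m = p$W * 0, v = p$W * 0),
              b = list(m = p$b * 0, v = p$b * 0))
    if (!is.null(p$gamma)) {
      s$gamma <- list(m = p$gamma * 0, v = p$gamma * 0)
      s$beta <- list(m = p$beta * 0, v = p$beta * 0)
    }
    s
  })
}

ae_adam_step <- function(params, grads, state, t, lr,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_len(6)) {
    for (nm in intersect(names(state[[l]]), names(grads[[l]]))) {
      g <- grads[[l]][[nm]]
      state[[l]][[nm]]$m <- b1 * state[[l]][[nm]]$m + (1 - b1) * g
      state[[l]][[nm]]$v <- b2 * state[[l]][[nm]]$v + (1 - b2) * g^2
      mhat <- state[[l]][[nm]]$m / (1 - b1^t)
      vhat <- state[[l]][[nm]]$v / (1 - b2^t)
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    # running batch-norm statistics (momentum 0.9)
    if (!is.null(params[[l]]$rmean) && !is.null(grads[[l]]$mu)) {
      params[[l]]$rmean <- 0.9 * params[[l]]$rmean + 0.1 * grads[[l]]$mu
      params[[l]]$rvar <- 0.9 * params[[l]]$rvar + 0.1 * grads[[l]]$v
    }
  }
  list(params = params, state = state)
}

#' Train an autoencoder on a recording
#'
#' Per-channel z-scores the frames, splits them at random into train and
#' validation sets, and trains the bottleneck network by minibatch Adam on
#' the mean-squared reconstruction error, keeping the weights of the best
#' validation epoch (early stopping). Deterministic for a fixed seed.
#'
#' @param rec a [recording] whose channel count matches the architecture
#'   input width (the spec defaults rescale to `n_channels`).
#' @param d latent dimension, used when `spec` is not given.
#' @param spec an [autoencoder_spec]; defaults to
#'   `autoencoder_spec(d, n_channels(rec))`.
#' @param seed integer RNG seed.
#' @param verbose print progress every 25 epochs.
#' @return an object of class `autoencoder` with the trained parameters,
#'   the z-scoring constants, `history` (per-epoch train/validation MSE),
#'   `best_epoch` and `val_mse`.
#' @export
train_autoencoder <- function(rec, d = NULL, spec = NULL, seed = 1,
                              verbose = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(spec)) {
    if (is.null(d)) stop("supply either 'd' or an autoencoder_spec")
    spec <- autoencoder_spec(d, n_channels = n_channels(rec))
  }
  if (spec$widths[1] != n_channels(rec)) {
    stop("architecture input width (", spec$widths[1],
         ") does not match the recording (", n_channels(rec), " channels)")
  }
  X <- t(rec$data)
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl <= 0] <- 1
  X <- sweep(sweep(X, 2, center), 2, scl, "/")
  n <- nrow(X)
  if (n < 10 * spec$batch) {
    stop("need at least 10 batches of frames (", 10 * spec$batch,
         "), have ", n)
  }
  set.seed(seed)
  val_idx <- sample.int(n, round(spec$val_frac * n))
  Xtr <- X[-val_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]
  ntr <- nrow(Xtr)

  params <- ae_init_params(spec)
  adam <- ae_adam_init(params)
  step <- 0L
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  best <- list(val = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(ntr)
    nb <- ntr %/% spec$batch
    tr_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1) * spec$batch + 1):(bi * spec$batch)]
      lg <- ae_loss_grad(params, spec, Xtr[idx, , drop = FALSE])
      step <- step + 1L
      upd <- ae_adam_step(params, lg$grads, adam, step, spec$lr)
      params <- upd$params; adam <- upd$state
      tr_loss <- tr_loss + lg$loss
    }
    val_out <- ae_forward(params, spec, Xval, training = FALSE)$out
    val_mse <- mean((val_out - Xval)^2)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_mse = tr_loss / nb,
                                val_mse = val_mse))
    if (!is.finite(val_mse)) stop("NaN/Inf loss at epoch ", epoch,
                                  ": lower the learning rate")
    if (val_mse < best$val) {
      best <- list(val = val_mse, params = params, epoch = epoch)
    }
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %d: train %.5f val %.5f", epoch,
                      tr_loss / nb, val_mse))
    }
    if (epoch - best$epoch >= spec$patience) break
  }
  structure(
    list(spec = spec, params = best$params, center = center, scale = scl,
         history = history, best_epoch = best$epoch, val_mse = best$val,
         val_idx = val_idx, fs = rec$fs),
    class = "autoencoder"
  )
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> widths %s, best epoch %d/%d, validation MSE %.5f\n",
              paste(x$spec$widths, collapse = "-"), x$best_epoch,
              nrow(x$history), x$val_mse))
  invisible(x)
}

# Inference-mode forward of preprocessed frames through the full network.
ae_reconstruct <- function(ae, X) {
  ae_forward(ae$params, ae$spec, X, training = FALSE)$out
}

ae_preprocess <- function(ae, rec) {
  X <- t(rec$data)
  sweep(sweep(X, 2, ae$center), 2, ae$scale, "/")
}
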