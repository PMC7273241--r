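# A compact 1-D convolutional network engine for rhythm classification.
#
# Nine trainable layers: seven same-padded 1-D convolutions (kernel width 7,
# ReLU, x2 average-pool downsampling after each of the first six), global
# average pooling, then two fully connected layers ending in 2 logits.
# Global average pooling makes one architecture serve every input length
# (30-s down to 5-s windows). Training uses Adam with dropout on the hidden
# fully connected layer and an L2 penalty on all weights.
#
# Activations are stored as (time x batch) x channel matrices (time fastest
# within each batch block); the convolution forward/backward kernels live in
# src/conv1d.cpp and reduce to per-offset BLAS products.

.idx_cache <- new.env(parent = emptyenv())

pool_indices <- function(L, B) {
  key <- paste(L, B, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  L2 <- L %/% 2L
  poff <- rep.int((0:(B - 1)) * L, rep.int(L2, B))
  p1 <- poff + rep.int(seq(1L, 2L * L2, by = 2L), B)
  res <- list(pool1 = p1, pool2 = p1 + 1L, L2 = L2)
  .idx_cache[[key]] <- res
  res
}

#' Default CNN training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param l2_weight L2 penalty on all weights (not biases).
#' @param dropout_rate Dropout probability on the hidden fully connected
#'   layer during training.
#' @param seed Integer seed; training is a pure function of it.
#' @param channels Output channels of the seven convolutional layers.
#' @param kernel Convolution kernel width (samples).
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param timescale_range Training-time augmentation: each window is
#'   resampled by a factor drawn log-uniformly from this range (circular
#'   wrap), which changes the apparent pulse rate but not the relative
#'   interval irregularity, discouraging the network from keying on rate.
#'   `NULL` disables augmentation.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(epochs = 12, batch_size = 64, learning_rate = 1e-3,
                       l2_weight = 1e-4, dropout_rate = 0.5, seed = 1L,
                       channels = c(4, 4, 8, 8, 16, 16, 32), kernel = 7,
                       fc_hidden = 16, timescale_range = c(0.7, 1.43)) {
  stopifnot(length(channels) == 7, kernel %% 2 == 1, !is.null(seed))
  structure(
    list(epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, l2_weight = l2_weight,
         dropout_rate = dropout_rate, seed = as.integer(seed),
         channels = channels, kernel = as.integer(kernel),
         fc_hidden = fc_hidden, timescale_range = timescale_range),
    class = "cnn_config"
  )
}

# Random time-scale augmentation: resample each row of X by its own factor
# with linear interpolation and circular wrap.
augment_timescale <- function(X, range) {
  B <- nrow(X)
  L <- ncol(X)
  s <- exp(stats::runif(B, log(range[1]), log(range[2])))
  pos <- outer(s, 0:(L - 1)) %% L          # B x L fractional positions
  i0 <- floor(pos)
  frac <- pos - i0
  rows <- rep(seq_len(B), L)
  lo <- cbind(rows, as.vector(i0) + 1L)
  hi <- cbind(rows, (as.vector(i0) + 1L) %% L + 1L)
  matrix(X[lo] * (1 - as.vector(frac)) + X[hi] * as.vector(frac), B, L)
}

nn_new <- function(input_len, cfg) {
  ch <- cfg$channels
  k <- cfg$kernel
  cin <- c(1, ch[-7])
  params <- list()
  running <- list()
  for (l in 1:7) {
    fan_in <- k * cin[l]
    params[[paste0("Wc", l)]] <- matrix(
      stats::rnorm(fan_in * ch[l], 0, sqrt(2 / fan_in)), fan_in, ch[l]
    )
    params[[paste0("bc", l)]] <- numeric(ch[l])
    # batch-norm scale/shift and running statistics per channel
    params[[paste0("gc", l)]] <- rep(1, ch[l])
    params[[paste0("hc", l)]] <- numeric(ch[l])
    running[[paste0("mean", l)]] <- numeric(ch[l])
    running[[paste0("var", l)]] <- rep(1, ch[l])
  }
  params$Wf1 <- matrix(stats::rnorm(ch[7] * cfg$fc_hidden, 0, sqrt(2 / ch[7])),
                       ch[7], cfg$fc_hidden)
  params$bf1 <- numeric(cfg$fc_hidden)
  params$Wf2 <- matrix(stats::rnorm(cfg$fc_hidden * 2, 0, sqrt(2 / cfg$fc_hidden)),
                       cfg$fc_hidden, 2)
  params$bf2 <- numeric(2)
  list(params = params, running = running, cfg = cfg,
       input_len = as.integer(input_len))
}

# Batch normalization (src/conv1d.cpp): normalizes the (time x batch) rows
# of each channel column with batch statistics during training and running
# statistics at inference.
bn_fwd <- function(Y, gamma, beta, training, run_mean, run_var) {
  bn_fwd_cpp(Y, gamma, beta, training, run_mean, run_var)
}

bn_bwd <- function(dOut, bn, gamma) {
  bn_bwd_cpp(dOut, bn$xhat, bn$inv_std, gamma)
}

# Forward pass. X is an n x L matrix of per-segment z-scored samples.
# Returns logits, the penultimate (hidden FC) activations, and - when
# `training` - the caches needed for backprop.
nn_forward <- function(net, X, training = FALSE) {
  cfg <- net$cfg
  k <- cfg$kernel
  B <- nrow(X)
  L <- ncol(X)
  A <- matrix(as.vector(t(X)), ncol = 1)
  caches <- if (training) vector("list", 7) else NULL
  bn_stats <- if (training) vector("list", 7) else NULL
  for (l in 1:7) {
    W <- net$params[[paste0("Wc", l)]]
    b <- net$params[[paste0("bc", l)]]
    Y <- conv1d_fwd(A, W, b, L, B, k)
    bn <- bn_fwd(Y, net$params[[paste0("gc", l)]],
                 net$params[[paste0("hc", l)]], training,
                 net$running[[paste0("mean", l)]],
                 net$running[[paste0("var", l)]])
    mask <- bn$out > 0
    act <- bn$out * mask
    if (l < 7) {
      idx <- pool_indices(L, B)
      pooled <- (act[idx$pool1, , drop = FALSE] +
                   act[idx$pool2, , drop = FALSE]) / 2
    } else {
      idx <- NULL
      pooled <- act
    }
    if (training) {
      caches[[l]] <- list(A_in = A, mask = mask, L = L, B = B, idx = idx,
                          bn = bn[c("xhat", "inv_std")])
      bn_stats[[l]] <- bn[c("mu", "vr")]
    }
    A <- pooled
    L <- if (l < 7) idx$L2 else L
  }
  grp <- rep(seq_len(B), each = L)
  H <- rowsum(A, grp) / L
  Z1 <- H %*% net$params$Wf1
  Z1 <- Z1 + rep(net$params$bf1, each = B)
  mask1 <- Z1 > 0
  A1 <- Z1 * mask1
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop_mask <- matrix(stats::rbinom(length(A1), 1, keep) / keep,
                        nrow(A1), ncol(A1))
    A1 <- A1 * drop_mask
  }
  logits <- A1 %*% net$params$Wf2
  logits <- logits + rep(net$params$bf2, each = B)
  list(logits = logits, hidden = A1, H = H, mask1 = mask1,
       drop_mask = drop_mask, caches = caches, bn_stats = bn_stats,
       gap_L = L, B = B)
}

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

# Backward pass; y is 0/1 (1 = positive class, second logit column).
nn_backward <- function(net, fwd, y) {
  B <- fwd$B
  P <- softmax_rows(fwd$logits)
  loss <- mean(-log(pmax(P[cbind(seq_len(B), y + 1L)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(B), y + 1L)] <- dZ[cbind(seq_len(B), y + 1L)] - 1
  dZ <- dZ / B
  grads <- list()
  grads$Wf2 <- crossprod(fwd$hidden, dZ)
  grads$bf2 <- colSums(dZ)
  dA1 <- dZ %*% t(net$params$Wf2)
  if (!is.null(fwd$drop_mask)) dA1 <- dA1 * fwd$drop_mask
  dZ1 <- dA1 * fwd$mask1
  grads$Wf1 <- crossprod(fwd$H, dZ1)
  grads$bf1 <- colSums(dZ1)
  dH <- dZ1 %*% t(net$params$Wf1)
  L <- fwd$gap_L
  dA <- dH[rep(seq_len(B), each = L), , drop = FALSE] / L
  k <- net$cfg$kernel
  for (l in 7:1) {
    cc <- fwd$caches[[l]]
    if (l < 7) {
      dAct <- matrix(0, cc$L * cc$B, ncol(dA))
      dAct[cc$idx$pool1, ] <- dA / 2
      dAct[cc$idx$pool2, ] <- dA / 2
    } else {
      dAct <- dA
    }
    dBnOut <- dAct * cc$mask
    bnb <- bn_bwd(dBnOut, cc$bn, net$params[[paste0("gc", l)]])
    grads[[paste0("gc", l)]] <- bnb$dgamma
    grads[[paste0("hc", l)]] <- bnb$dbeta
    dY <- bnb$dY
    W <- net$params[[paste0("Wc", l)]]
    bw <- conv1d_bwd(cc$A_in, W, dY, cc$L, cc$B, k)
    grads[[paste0("Wc", l)]] <- bw$dW
    grads[[paste0("bc", l)]] <- as.numeric(bw$db)
    dA <- bw$dA
  }
  list(loss = loss, grads = grads)
}

# Train the network with Adam. X: n x L matrix; y: 0/1 integer labels.
nn_train <- function(X, y, cfg) {
  stopifnot(nrow(X) == length(y), length(unique(y)) == 2)
  with_seed(cfg$seed, {
    net <- nn_new(ncol(X), cfg)
    pn <- names(net$params)
    m <- lapply(net$params, function(p) p * 0)
    v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    n <- nrow(X)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        bidx <- perm[start:min(start + cfg$batch_size - 1, n)]
        if (length(bidx) < 2) next
        Xb <- X[bidx, , drop = FALSE]
        if (!is.null(cfg$timescale_range)) {
          Xb <- augment_timescale(Xb, cfg$timescale_range)
        }
        fwd <- nn_forward(net, Xb, training = TRUE)
        bk <- nn_backward(net, fwd, y[bidx])
        if (!is.finite(bk$loss)) {
          stop(sprintf("non-finite loss at epoch %d (step %d)", epoch, step))
        }
        step <- step + 1
        for (p in pn) {
          g <- bk$grads[[p]]
          if (substr(p, 1, 1) == "W" && cfg$l2_weight > 0) {
            g <- g + cfg$l2_weight * net$params[[p]]
          }
          m[[p]] <- b1 * m[[p]] + (1 - b1) * g
          v[[p]] <- b2 * v[[p]] + (1 - b2) * g^2
          mh <- m[[p]] / (1 - b1^step)
          vh <- v[[p]] / (1 - b2^step)
          net$params[[p]] <- net$params[[p]] -
            cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
        for (l in 1:7) {
          net$running[[paste0("mean", l)]] <-
            0.9 * net$running[[paste0("mean", l)]] + 0.1 * fwd$bn_stats[[l]]$mu
          net$running[[paste0("var", l)]] <-
            0.9 * net$running[[paste0("var", l)]] + 0.1 * fwd$bn_stats[[l]]$vr
        }
      }
    }
    net
  })
}

# Logits (no dropout) in prediction batches.
nn_logits <- function(net, X, batch = 256) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    out[idx, ] <- nn_forward(net, X[idx, , drop = FALSE])$logits
  }
  out
}

# Penultimate-layer (hidden FC, post-ReLU) activations.
nn_hidden <- function(net, X, batch = 256) {
  n <- nrow(X)
  out <- NULL
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    h <- nn_forward(net, X[idx, , drop = FALSE])$hidden
    if (is.null(out)) out <- matrix(NA_real_, n, ncol(h))
    out[idx, ] <- h
  }
  out
}

# Per-segment z-scoring, the CNN's input normalization.
normalize_segments <- function(M) {
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowMeans(M^2) - mu^2, 0))
  sdv[sdv == 0] <- 1
  (M - mu) / sdv
}
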