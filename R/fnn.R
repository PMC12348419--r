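# Dropout-regularized feedforward network for binary classification:
# input(m) -> dense 512 -> ReLU -> dropout -> dense 256 -> ReLU -> dropout
# -> dense 128 -> ReLU -> dropout -> dense 1 -> sigmoid, trained with Adam
# on binary cross-entropy. Pure-R implementation (no deep-learning backend
# in the environment); minibatch matrix ops are BLAS-bound and fast at the
# dataset sizes this package targets.

#' @noRd
fnn_init <- function(input_dim, hidden_sizes) {
  dims <- c(input_dim, hidden_sizes, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1L]),
      b = numeric(dims[l + 1L]))
  }
  layers
}

# forward pass at inference time (no dropout; inverted scaling at train
# time keeps expected activations equal)
#' @noRd
fnn_forward_prob <- function(net, X) {
  A <- as.matrix(X)
  n_hidden <- length(net) - 1L
  for (l in seq_len(n_hidden)) {
    A <- pmax(sweep(A %*% net[[l]]$W, 2, net[[l]]$b, "+"), 0)
  }
  z <- sweep(A %*% net[[n_hidden + 1L]]$W, 2, net[[n_hidden + 1L]]$b, "+")
  as.numeric(1 / (1 + exp(-z)))
}

# one Adam-trained run over the given data; returns the trained layers
#' @noRd
fnn_train <- function(X, y01, config) {
  n <- nrow(X)
  withr::with_seed(config$seed, {
    net <- fnn_init(ncol(X), config$hidden_sizes)
    L <- length(net)
    mom <- lapply(net, function(l) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    })
    keep <- 1 - config$dropout_rate
    lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[batch, , drop = FALSE]
        yb <- y01[batch]
        # forward with inverted dropout on hidden activations
        acts <- vector("list", L)     # post-activation inputs to layer l+1
        masks <- vector("list", L - 1L)
        A <- Xb
        for (l in seq_len(L - 1L)) {
          acts[[l]] <- A
          H <- pmax(sweep(A %*% net[[l]]$W, 2, net[[l]]$b, "+"), 0)
          mask <- matrix(runif(length(H)) < keep, nrow(H), ncol(H))
          A <- H * mask / keep
          masks[[l]] <- list(H = H, mask = mask)
        }
        acts[[L]] <- A
        z <- sweep(A %*% net[[L]]$W, 2, net[[L]]$b, "+")
        p <- 1 / (1 + exp(-z))
        # backward: dBCE/dz = (p - y) / batch size
        delta <- (p - yb) / length(batch)
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            back <- delta %*% t(net[[l]]$W)
            mk <- masks[[l - 1L]]
            back <- back * mk$mask / keep
            delta <- back * (mk$H > 0)
          }
          mm <- mom[[l]]
          mm$mW <- b1 * mm$mW + (1 - b1) * gW
          mm$vW <- b2 * mm$vW + (1 - b2) * gW^2
          mm$mb <- b1 * mm$mb + (1 - b1) * gb
          mm$vb <- b2 * mm$vb + (1 - b2) * gb^2
          net[[l]]$W <- net[[l]]$W -
            lr * (mm$mW / corr1) / (sqrt(mm$vW / corr2) + eps)
          net[[l]]$b <- net[[l]]$b -
            lr * (mm$mb / corr1) / (sqrt(mm$vb / corr2) + eps)
          mom[[l]] <- mm
        }
      }
    }
    net
  })
}

#' Fit the feedforward neural network
#'
#' Architecture and training protocol are fixed (no inner hyperparameter
#' search): three ReLU hidden layers of 512/256/128 units, each followed by
#' dropout at rate 0.5, a single sigmoid output, Adam on binary
#' cross-entropy, batch size 8, 50 epochs, deterministic shuffling given the
#' config seed. Preprocessing = variance filter + column z-scoring derived
#' from the training rows only.
#'
#' @param X Training `feature_matrix`.
#' @param y Binary labels aligned with `rownames(X)`; the positive class is
#'   the second sorted level.
#' @param config An [fnn_config()].
#' @return A fitted model of class `transpred_model` (kind `"fnn"`).
#' @export
fit_fnn <- function(X, y, config = fnn_config()) {
  X <- as.matrix(X)
  enc <- encode_labels(y)
  vf <- variance_filter(X)
  center <- colMeans(vf$X)
  scale_ <- apply(vf$X, 2, sd)
  scale_[scale_ == 0] <- 1
  prep <- list(kept = vf$kept, selected = vf$kept, center = center,
               scale = scale_)
  Xz <- apply_preprocessing(prep, X)
  net <- fnn_train(Xz, enc$y01, config)
  structure(list(kind = "fnn", prep = prep, net = net,
                 chosen = list(), levels = enc$levels, config = config),
            class = "transpred_model")
}
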