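# Minimal dense-network engine: Linear -> (BatchNorm) -> activation ->
# (inverted Dropout) blocks trained with Adam on softmax cross-entropy.
# Shared by the extraction head (which uses BatchNorm + dropout 0.3) and the
# two plain MLP classifiers (no BatchNorm, no dropout).
#
# Conventions: batches are row-major (n x p); layer weights W are out x in so
# a layer computes X %*% t(W) + b. BatchNorm uses biased batch variance with
# eps = 1e-5 and running statistics updated with momentum 0.1 for eval mode.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# sizes: c(in, h1, ..., out); bn/dropout are per *hidden* block (the output
# layer is always plain linear feeding softmax).
nn_init <- function(sizes, bn = FALSE, dropout = 0) {
  n_blocks <- length(sizes) - 1L
  bn <- rep_len(bn, n_blocks - 1L)
  dropout <- rep_len(dropout, n_blocks - 1L)
  layers <- vector("list", n_blocks)
  for (l in seq_len(n_blocks)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    # He initialization for ReLU blocks
    layers[[l]] <- list(
      W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
      b = numeric(n_out),
      hidden = l < n_blocks,
      bn = if (l < n_blocks && bn[l]) list(
        gamma = rep(1, n_out), beta = numeric(n_out),
        rmean = numeric(n_out), rvar = rep(1, n_out)
      ),
      dropout = if (l < n_blocks) dropout[l] else 0
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "bdefs_nn")
}

# Column-wise broadcast helpers (v recycled across rows of M).
row_bcast <- function(M, v, op) sweep(M, 2L, v, op)

nn_forward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  H <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    cache <- list(X_in = H)
    A <- H %*% t(ly$W)
    A <- row_bcast(A, ly$b, "+")
    if (!is.null(ly$bn)) {
      if (train) {
        mu <- colMeans(A)
        vv <- colMeans(A^2) - mu^2           # biased batch variance
        ivar <- 1 / sqrt(vv + BN_EPS)
        xhat <- row_bcast(row_bcast(A, mu, "-"), ivar, "*")
        net$layers[[l]]$bn$rmean <- (1 - BN_MOMENTUM) * ly$bn$rmean + BN_MOMENTUM * mu
        net$layers[[l]]$bn$rvar  <- (1 - BN_MOMENTUM) * ly$bn$rvar  + BN_MOMENTUM * vv
        cache$ivar <- ivar; cache$xhat <- xhat
      } else {
        ivar <- 1 / sqrt(ly$bn$rvar + BN_EPS)
        xhat <- row_bcast(row_bcast(A, ly$bn$rmean, "-"), ivar, "*")
      }
      A <- row_bcast(row_bcast(xhat, ly$bn$gamma, "*"), ly$bn$beta, "+")
    }
    if (ly$hidden) {
      cache$pre_act <- A
      A[A < 0] <- 0
      if (train && ly$dropout > 0) {
        keep <- matrix(runif(length(A)) >= ly$dropout, nrow(A), ncol(A))
        A <- A * keep / (1 - ly$dropout)
        cache$drop_keep <- keep
      }
    }
    cache$out <- A
    caches[[l]] <- cache
    H <- A
  }
  logits <- H
  P <- softmax_rows(logits)
  list(net = net, probs = P, logits = logits, caches = caches)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# Mean cross-entropy; Y is a one-hot matrix.
nn_loss <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

nn_backward <- function(net, fwd, Y) {
  n <- nrow(Y)
  grads <- vector("list", length(net$layers))
  dH <- (fwd$probs - Y) / n
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cache <- fwd$caches[[l]]
    dA <- dH
    if (ly$hidden) {
      if (!is.null(cache$drop_keep)) dA <- dA * cache$drop_keep / (1 - ly$dropout)
      dA <- dA * (cache$pre_act > 0)
    }
    g <- list()
    if (!is.null(ly$bn)) {
      xhat <- cache$xhat; ivar <- cache$ivar
      g$gamma <- colSums(dA * xhat)
      g$beta <- colSums(dA)
      dxhat <- row_bcast(dA, ly$bn$gamma, "*")
      nb <- nrow(dA)
      ones <- matrix(1, nb, 1L)
      dA <- row_bcast(
        nb * dxhat - ones %*% t(colSums(dxhat)) -
          xhat * (ones %*% t(colSums(dxhat * xhat))),
        ivar / nb, "*")
    }
    g$W <- t(dA) %*% cache$X_in
    g$b <- colSums(dA)
    grads[[l]] <- g
    if (l > 1L) dH <- dA %*% ly$W
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    slots <- list(W = ly$W * 0, b = ly$b * 0)
    if (!is.null(ly$bn)) {
      slots$gamma <- ly$bn$gamma * 0
      slots$beta <- ly$bn$beta * 0
    }
    list(m = slots, v = slots, t = 0L)
  })
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    st <- opt[[l]]
    st$t <- st$t + 1L
    for (nm in names(st$m)) {
      g <- grads[[l]][[nm]]
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
      mhat <- st$m[[nm]] / (1 - beta1^st$t)
      vhat <- st$v[[nm]] / (1 - beta2^st$t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (nm %in% c("W", "b")) {
        net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] - upd
      } else {
        net$layers[[l]]$bn[[nm]] <- net$layers[[l]]$bn[[nm]] - upd
      }
    }
    opt[[l]] <- st
  }
  list(net = net, opt = opt)
}

# Mini-batch Adam training on softmax cross-entropy. Returns the trained net
# and the mean training loss per epoch. Randomness (shuffling, dropout) comes
# from the ambient RNG stream; callers seed it.
nn_train <- function(net, X, y_idx, n_classes, epochs, batch_size, lr) {
  n <- nrow(X)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y_idx)] <- 1
  opt <- adam_init(net)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fwd <- nn_forward(net, X[idx, , drop = FALSE], train = TRUE)
      net <- fwd$net  # running BN statistics updated in the forward pass
      ep_loss <- ep_loss + nn_loss(fwd$probs, Y[idx, , drop = FALSE]) * length(idx)
      grads <- nn_backward(net, fwd, Y[idx, , drop = FALSE])
      stepped <- adam_step(net, grads, opt, lr)
      net <- stepped$net; opt <- stepped$opt
    }
    losses[ep] <- ep_loss / n
  }
  list(net = net, loss_history = losses)
}

# Eval-mode activations of every block (used to read out the penultimate
# representation z2 and the softmax probabilities).
nn_activations <- function(net, X) {
  fwd <- nn_forward(net, X, train = FALSE)
  list(hidden = lapply(fwd$caches, `[[`, "out"), probs = fwd$probs)
}
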