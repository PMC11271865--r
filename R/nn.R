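# Minimal feed-forward neural network machinery: dense layers with ReLU,
# inverted dropout, a sigmoid output head trained by weighted cross-entropy
# with Adam and early stopping. Written in base R matrix algebra; gradients
# are verified against finite differences in the test suite.

nn_init_params <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(
      W = matrix(rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
        fan_in, sizes[l + 1L]
      ),
      b = rep(0, sizes[l + 1L])
    )
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. `dropout` > 0 with training=TRUE samples inverted-dropout
# masks on every hidden activation (also used for MC-dropout prediction).
nn_forward <- function(params, X, dropout = 0, training = FALSE) {
  L <- length(params)
  A <- X
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      H <- pmax(Z, 0)
      M <- NULL
      if (training && dropout > 0) {
        M <- matrix(rbinom(length(H), 1, 1 - dropout), nrow(H)) / (1 - dropout)
        H <- H * M
      }
      cache[[l]] <- list(A_prev = A, Z = Z, M = M)
      A <- H
    } else {
      cache[[l]] <- list(A_prev = A, Z = Z)
      A <- sigmoid(Z)
    }
  }
  list(p = as.numeric(A), cache = cache)
}

# Weighted binary cross-entropy (weights normalized inside).
nn_loss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  sum(w * (-y * log(p) - (1 - y) * log(1 - p))) / sum(w)
}

nn_backward <- function(params, fwd, y, w) {
  L <- length(params)
  grads <- vector("list", L)
  p <- fwd$p
  # d loss / d z_out for sigmoid + BCE
  delta <- matrix((p - y) * w / sum(w), ncol = 1)
  for (l in rev(seq_len(L))) {
    cc <- fwd$cache[[l]]
    grads[[l]] <- list(W = crossprod(cc$A_prev, delta), b = colSums(delta))
    if (l > 1) {
      dA <- delta %*% t(params[[l]]$W)
      prev <- fwd$cache[[l - 1]]
      if (!is.null(prev$M)) dA <- dA * prev$M
      delta <- dA * (prev$Z > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      if (nm == "W") g <- matrix(g, nrow(params[[l]]$W))
      m[[l]][[nm]] <- beta1 * m[[l]][[nm]] + (1 - beta1) * g
      v[[l]][[nm]] <- beta2 * v[[l]][[nm]] + (1 - beta2) * g^2
      mh <- m[[l]][[nm]] / (1 - beta1^t)
      vh <- v[[l]][[nm]] / (1 - beta2^t)
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, m = m, v = v)
}

# Generic minibatch training loop with early stopping on validation loss.
# `forward_fn(params, idx, training)` returns predictions + cache for the
# given training rows; `backward_fn(params, fwd, idx)` returns grads;
# `val_fn(params)` returns the validation loss.
train_loop <- function(params, n_train, forward_fn, backward_fn, val_fn,
                       batch_size, max_epochs, patience, lr,
                       weight_decay = 0) {
  m <- adam_init(params)
  v <- adam_init(params)
  t_step <- 0
  best <- list(loss = Inf, params = params, epoch = 0)
  history <- numeric(0)
  wait <- 0
  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n_train)
    starts <- seq(1, n_train, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n_train)]
      fwd <- forward_fn(params, idx, training = TRUE)
      grads <- backward_fn(params, fwd, idx)
      t_step <- t_step + 1
      upd <- adam_step(params, grads, m, v, t_step, lr)
      params <- upd$params
      m <- upd$m
      v <- upd$v
      if (weight_decay > 0) {
        for (l in seq_along(params)) {
          params[[l]]$W <- params[[l]]$W * (1 - weight_decay)
        }
      }
    }
    vl <- val_fn(params)
    if (!is.finite(vl)) {
      abort(sprintf("training diverged at epoch %d (learning rate %g)", epoch, lr),
        class = "msprog_divergence_error"
      )
    }
    history <- c(history, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(
    params = best$params, best_epoch = best$epoch,
    epochs_run = length(history), val_history = history, best_loss = best$loss
  )
}
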