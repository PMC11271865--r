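numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("class weights invert the label frequencies and sum to n", {
  w <- class_weights(c(1, 0, 0, 0))
  expect_equal(w, c(2, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(sum(w), 4)
  # balanced labels give unit weights
  expect_equal(class_weights(c(0, 1, 0, 1)), rep(1, 4))
  expect_true(all(class_weights(rbinom(50, 1, 0.5)) > 0))
  expect_error(class_weights(rep(1, 5)), class = "msprog_degenerate_label_error")
})

test_that("MLP backprop matches finite-difference gradients", {
  set.seed(7)
  X <- matrix(rnorm(5 * 4), 5, 4)
  y <- c(1, 0, 1, 1, 0)
  w <- c(1, 2, 1, 0.5, 1)
  params <- msprogbench:::nn_init_params(4, c(6, 5))
  fwd <- msprogbench:::nn_forward(params, X)
  grads <- msprogbench:::nn_backward(params, fwd, y, w)
  for (l in seq_along(params)) {
    fW <- function(Wflat) {
      p2 <- params
      p2[[l]]$W <- matrix(Wflat, nrow(params[[l]]$W))
      msprogbench:::nn_loss(msprogbench:::nn_forward(p2, X)$p, y, w)
    }
    expect_equal(
      as.numeric(grads[[l]]$W),
      numeric_grad(fW, as.numeric(params[[l]]$W)),
      tolerance = 1e-5
    )
    fb <- function(b) {
      p2 <- params
      p2[[l]]$b <- b
      msprogbench:::nn_loss(msprogbench:::nn_forward(p2, X)$p, y, w)
    }
    expect_equal(
      as.numeric(grads[[l]]$b),
      numeric_grad(fb, params[[l]]$b),
      tolerance = 1e-5
    )
  }
})

test_that("attention backprop matches finite-difference gradients", {
  set.seed(8)
  X <- matrix(rnorm(6 * 5), 6, 5) # one sequence, 6 steps, 5 channels
  y <- 1
  par <- msprogbench:::attn_init_params(5, 4, 2)
  fwd <- msprogbench:::attn_forward_one(par, X)
  dz <- (fwd$p - y) # weight 1
  g <- msprogbench:::attn_backward_one(par, fwd, dz)
  loss_with <- function(par2) {
    p <- msprogbench:::attn_forward_one(par2, X)$p
    msprogbench:::nn_loss(p, y, 1)
  }
  # spot-check every parameter family
  check <- function(get, set, gval) {
    f <- function(flat) {
      loss_with(set(par, flat))
    }
    expect_equal(as.numeric(gval), numeric_grad(f, as.numeric(get(par))),
      tolerance = 1e-4
    )
  }
  check(
    function(p) p$W_in,
    function(p, v) {
      p$W_in <- matrix(v, nrow(p$W_in))
      p
    }, g$W_in
  )
  check(
    function(p) p$w_out,
    function(p, v) {
      p$w_out <- v
      p
    }, g$w_out
  )
  for (l in 1:2) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
      check(
        function(p) p$layers[[l]][[nm]],
        function(p, v) {
          p$layers[[l]][[nm]] <- matrix(v, nrow(p$layers[[l]][[nm]]))
          p
        },
        g$layers[[l]][[nm]]
      )
    }
    check(
      function(p) p$layers[[l]]$b1,
      function(p, v) {
        p$layers[[l]]$b1 <- v
        p
      }, g$layers[[l]]$b1
    )
  }
})

make_vector_task <- function(n, d = 6, seed = 1, separable = FALSE, signal = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- paste0("f", 1:d)
  eta <- signal * X[, 1] - 0.5
  y <- if (separable) as.integer(eta > 0) else rbinom(n, 1, plogis(eta))
  list(X = X, y = y)
}

small_spec <- function(arch = "mlp", ...) {
  model_spec(arch,
    hidden_width = 16, n_hidden_layers = 2, max_epochs = 30,
    patience = 6, batch_size = 64, mc_samples = 20, time_embedding_dim = 8,
    ...
  )
}

test_that("training is reproducible and separable data is learned", {
  tr <- make_vector_task(400, separable = TRUE)
  va <- make_vector_task(200, seed = 2, separable = TRUE)
  te <- make_vector_task(200, seed = 3, separable = TRUE)
  m1 <- train_model(small_spec(), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  m2 <- train_model(small_spec(), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  p1 <- predict_proba(m1, te$X)
  p2 <- predict_proba(m2, te$X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gt(roc_auc(p1, te$y), 0.95)
})

test_that("labels independent of features give chance-level discrimination", {
  tr <- make_vector_task(600, signal = 0)
  va <- make_vector_task(300, seed = 2, signal = 0)
  te <- make_vector_task(400, seed = 3, signal = 0)
  m <- train_model(small_spec(), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  auc <- roc_auc(predict_proba(m, te$X), te$y)
  expect_gt(auc, 0.38)
  expect_lt(auc, 0.62)
})

test_that("the Bayesian network reduces to the MLP at zero dropout", {
  tr <- make_vector_task(300)
  va <- make_vector_task(150, seed = 2)
  m_mlp <- train_model(small_spec(dropout = 0), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  m_bnn <- m_mlp
  m_bnn$spec$architecture <- "bayesian_nn"
  m_bnn$spec$mc_samples <- 1
  expect_equal(predict_proba(m_bnn, va$X), predict_proba(m_mlp, va$X))
})

test_that("MC-dropout predictions are uncertain but stabilize with more samples", {
  tr <- make_vector_task(300)
  va <- make_vector_task(150, seed = 2)
  m <- train_model(small_spec("bayesian_nn", dropout = 0.3), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  # single stochastic passes differ across seeds
  m1 <- m
  m1$spec$mc_samples <- 1
  m2 <- m1
  m2$spec$seed <- m1$spec$seed + 99
  d1 <- mean(abs(predict_proba(m1, va$X) - predict_proba(m2, va$X)))
  expect_gt(d1, 0)
  # averaging many passes shrinks the seed-to-seed variability
  m3 <- m
  m3$spec$mc_samples <- 60
  m4 <- m3
  m4$spec$seed <- m3$spec$seed + 99
  d60 <- mean(abs(predict_proba(m3, va$X) - predict_proba(m4, va$X)))
  expect_lt(d60, d1 / 3)
  # and repeated calls with the same seed are deterministic
  expect_identical(predict_proba(m3, va$X), predict_proba(m3, va$X))
})

test_that("the continuous time embedding is injective and smooth", {
  t <- seq(-30, 0, by = 0.05)
  E <- continuous_time_embedding(t, 16)
  expect_equal(dim(E), c(length(t), 16))
  # t = 0 gives the alternating sin/cos pattern
  e0 <- continuous_time_embedding(0, 8)
  expect_equal(as.numeric(e0), rep(c(0, 1), 4))
  # no collisions on a dense grid over the clinical range
  expect_equal(nrow(unique(round(E, 8))), length(t))
  # continuity: small dt moves the embedding a little
  d <- sqrt(rowSums((continuous_time_embedding(t + 1e-4, 16) - E)^2))
  expect_lt(max(d), 1e-2)
  expect_error(continuous_time_embedding(0, 7), class = "msprog_config_error")
})

make_seq_task <- function(n, seed = 1, signal = 2) {
  # sequences whose mean edss channel drives the label
  set.seed(seed)
  feats <- matrix(rnorm(n * 3), n, 3)
  colnames(feats) <- c("a", "b", "c")
  seqs <- vector("list", n)
  y <- integer(n)
  for (i in seq_len(n)) {
    L <- sample(3:7, 1)
    times <- sort(-runif(L, 0, 5))
    level <- runif(1, -1, 1)
    m <- cbind(
      time = times, edss = level + rnorm(L, 0, 0.1),
      mask_edss = 1
    )
    seqs[[i]] <- m
    y[i] <- rbinom(1, 1, plogis(signal * 3 * level))
  }
  list(
    feats = feats, y = y,
    sequences = tibble::tibble(seq = seqs)
  )
}

test_that("the attention model learns a sequence-level signal", {
  tr <- make_seq_task(250, seed = 1)
  va <- make_seq_task(120, seed = 2)
  te <- make_seq_task(120, seed = 3)
  spec <- model_spec("temporal_attention",
    hidden_width = 8, n_attention_layers = 1, max_epochs = 30, patience = 6,
    batch_size = 64, time_embedding_dim = 8, dropout = 0
  )
  m <- train_model(spec, tr$feats, tr$y,
    validation = list(
      features = va$feats, labels = va$y, sequences = va$sequences
    ),
    sequences = tr$sequences
  )
  p <- predict_proba(m, te$feats, sequences = te$sequences)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(p, te$y), 0.8)
  # determinism
  m2 <- train_model(spec, tr$feats, tr$y,
    validation = list(
      features = va$feats, labels = va$y, sequences = va$sequences
    ),
    sequences = tr$sequences
  )
  expect_identical(p, predict_proba(m2, te$feats, sequences = te$sequences))
})

test_that("feature-layout mismatches are rejected at prediction time", {
  tr <- make_vector_task(200)
  va <- make_vector_task(100, seed = 2)
  m <- train_model(small_spec(), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  Xbad <- va$X
  attr(Xbad, "layout") <- "something-else"
  expect_error(predict_proba(m, Xbad), class = "msprog_version_error")
})

test_that("model summaries expose the training metadata", {
  tr <- make_vector_task(200)
  va <- make_vector_task(100, seed = 2)
  m <- train_model(small_spec(), tr$X, tr$y,
    validation = list(features = va$X, labels = va$y)
  )
  td <- tidy(m)
  expect_equal(nrow(td), m$meta$epochs_run)
  expect_equal(names(td), c("epoch", "val_loss"))
  gl <- glance(m)
  expect_equal(gl$architecture, "mlp")
  expect_gt(gl$n_parameters, 0)
})
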