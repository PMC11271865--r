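#' Specification of a probabilistic progression classifier
#'
#' @param architecture one of `"mlp"` (multi-layer perceptron on the
#'   static+dynamic feature vector), `"bayesian_nn"` (same architecture with
#'   Monte-Carlo dropout active at prediction time), or
#'   `"temporal_attention"` (continuous-time self-attention over the
#'   longitudinal sequence).
#' @param hidden_width width of hidden/attention layers (128 by default).
#' @param n_hidden_layers hidden depth for mlp/bayesian_nn (5 by default).
#' @param n_attention_layers attention blocks for temporal_attention (2).
#' @param dropout dropout rate in `[0, 1)`.
#' @param mc_samples stochastic forward passes averaged by the Bayesian
#'   network at prediction time.
#' @param learning_rate,batch_size,max_epochs,patience Adam optimizer
#'   settings with early stopping on the class-weighted validation loss.
#' @param weight_decay decoupled per-step multiplicative weight decay on
#'   the weight matrices (not biases); regularizes against memorizing the
#'   correlated, overlapping episodes of one patient.
#' @param time_embedding_dim dimension of the continuous temporal embedding
#'   (even).
#' @param max_seq_len longitudinal steps retained (most recent first).
#' @param seed integer; training and MC-dropout prediction are reproducible
#'   given the seed.
#' @return a `ms_model_spec` list.
#' @export
model_spec <- function(architecture = c("mlp", "bayesian_nn", "temporal_attention"),
                       hidden_width = 128, n_hidden_layers = 5,
                       n_attention_layers = 2, dropout = 0.1, mc_samples = 50,
                       learning_rate = 1e-3, batch_size = 256,
                       max_epochs = 100, patience = 10, weight_decay = 5e-3,
                       time_embedding_dim = 16, max_seq_len = 40, seed = 0) {
  architecture <- match.arg(architecture)
  stopifnot(
    hidden_width >= 1, n_hidden_layers >= 1, n_attention_layers >= 1,
    dropout >= 0, dropout < 1, mc_samples >= 1, learning_rate > 0
  )
  structure(
    list(
      architecture = architecture, hidden_width = hidden_width,
      n_hidden_layers = n_hidden_layers,
      n_attention_layers = n_attention_layers, dropout = dropout,
      mc_samples = mc_samples, learning_rate = learning_rate,
      batch_size = batch_size, max_epochs = max_epochs, patience = patience,
      weight_decay = weight_decay,
      time_embedding_dim = time_embedding_dim, max_seq_len = max_seq_len,
      seed = seed
    ),
    class = "ms_model_spec"
  )
}

#' Inverse-prevalence sample weights
#'
#' Weighs each sample proportionally to the inverse frequency of its label,
#' normalized so the weights sum to the sample size. Counteracts the mild
#' class imbalance of progression episodes.
#'
#' @param labels vector of 0/1 labels (both classes must be present).
#' @return numeric weight vector of the same length.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0 || n1 == n) {
    abort("both classes must be present to compute class weights",
      class = "msprog_degenerate_label_error"
    )
  }
  raw <- ifelse(labels == 1L, n / n1, n / (n - n1))
  raw * n / sum(raw)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

as_feature_input <- function(features) {
  if (is.matrix(features)) {
    return(features)
  }
  feature_matrix(features)
}

# Assemble attention inputs: per episode, the truncated sequence channels,
# the standardized static+dynamic vector repeated per step, and the
# continuous time embedding.
assemble_attention_inputs <- function(X_scaled, sequences, spec) {
  map(seq_len(nrow(X_scaled)), function(i) {
    m <- sequences$seq[[i]]
    if (nrow(m) > spec$max_seq_len) {
      m <- m[(nrow(m) - spec$max_seq_len + 1):nrow(m), , drop = FALSE]
    }
    emb <- continuous_time_embedding(m[, "time"], spec$time_embedding_dim)
    chan <- m[, -1, drop = FALSE]
    stat <- matrix(X_scaled[i, ], nrow(m), ncol(X_scaled), byrow = TRUE)
    cbind(chan, stat, emb)
  })
}

#' Train a probabilistic progression classifier
#'
#' Minimizes weighted binary cross-entropy with Adam, early-stopping on the
#' validation loss and restoring the best weights. Continuous features are
#' z-scored with statistics of the training fold only. Training is
#' reproducible given the seed in the model specification.
#'
#' @param spec a [model_spec()].
#' @param features training features: a tibble from
#'   [build_dynamic_features()] (or [build_static_features()]) or a numeric
#'   matrix.
#' @param labels 0/1 training labels.
#' @param weights sample weights (defaults to [class_weights()]).
#' @param validation list with elements `features`, `labels`, optional
#'   `weights` and (for the attention model) `sequences`: a held-out set,
#'   disjoint from training, used for early stopping.
#' @param sequences for `temporal_attention`: the output of
#'   [build_longitudinal_sequences()] aligned with `features` rows.
#' @return an `ms_model` object; score new data with [predict_proba()].
#' @export
train_model <- function(spec, features, labels, weights = NULL,
                        validation = NULL, sequences = NULL) {
  stopifnot(inherits(spec, "ms_model_spec"))
  if (is.null(validation)) {
    abort("a validation set is required for early stopping",
      class = "msprog_config_error"
    )
  }
  X <- as_feature_input(features)
  layout <- attr(X, "layout") %||% FEATURE_LAYOUT_VERSION
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y))
  w <- weights %||% class_weights(y)
  Xv <- as_feature_input(validation$features)
  yv <- as.numeric(validation$labels)
  wv <- validation$weights %||%
    (if (length(unique(yv)) == 2) class_weights(yv) else rep(1, length(yv)))

  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  Xvs <- apply_scaler(Xv, scaler)

  fit <- with_seed(spec$seed, {
    if (spec$architecture %in% c("mlp", "bayesian_nn")) {
      fit_mlp_core(spec, Xs, y, w, Xvs, yv, wv)
    } else {
      if (is.null(sequences) || is.null(validation$sequences)) {
        abort("temporal_attention requires training and validation sequences",
          class = "msprog_config_error"
        )
      }
      seqs <- assemble_attention_inputs(Xs, sequences, spec)
      seqs_v <- assemble_attention_inputs(Xvs, validation$sequences, spec)
      fit_attention_core(spec, seqs, y, w, seqs_v, yv, wv)
    }
  })

  structure(
    list(
      spec = spec, params = fit$params, scaler = scaler, layout = layout,
      feature_names = colnames(X),
      meta = list(
        best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
        val_history = fit$val_history, best_val_loss = fit$best_loss,
        n_train = nrow(X)
      )
    ),
    class = "ms_model"
  )
}

fit_mlp_core <- function(spec, Xs, y, w, Xvs, yv, wv) {
  params <- nn_init_params(ncol(Xs), rep(spec$hidden_width, spec$n_hidden_layers))
  train_loop(
    params,
    n_train = nrow(Xs),
    forward_fn = function(par, idx, training) {
      nn_forward(par, Xs[idx, , drop = FALSE], spec$dropout, training)
    },
    backward_fn = function(par, fwd, idx) nn_backward(par, fwd, y[idx], w[idx]),
    val_fn = function(par) nn_loss(nn_forward(par, Xvs)$p, yv, wv),
    batch_size = spec$batch_size, max_epochs = spec$max_epochs,
    patience = spec$patience, lr = spec$learning_rate,
    weight_decay = spec$weight_decay
  )
}

fit_attention_core <- function(spec, seqs, y, w, seqs_v, yv, wv) {
  d_in <- ncol(seqs[[1]])
  par <- attn_init_params(d_in, spec$hidden_width, spec$n_attention_layers)
  m <- attn_zero_grads(par)
  v <- attn_zero_grads(par)
  t_step <- 0
  n <- length(seqs)
  best <- list(loss = Inf, params = par, epoch = 0)
  history <- numeric(0)
  wait <- 0
  val_loss <- function(par) {
    p <- vapply(seqs_v, function(Xi) attn_forward_one(par, Xi)$p, numeric(1))
    nn_loss(p, yv, wv)
  }
  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = spec$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + spec$batch_size - 1, n)]
      g <- attn_zero_grads(par)
      wsum <- sum(w[idx])
      for (i in idx) {
        fwd <- attn_forward_one(par, seqs[[i]], spec$dropout, training = TRUE)
        dz <- (fwd$p - y[i]) * w[i] / wsum
        g <- attn_add_grads(g, attn_backward_one(par, fwd, dz))
      }
      t_step <- t_step + 1
      upd <- attn_adam_step(par, g, m, v, t_step, spec$learning_rate,
        weight_decay = spec$weight_decay
      )
      par <- upd$par
      m <- upd$m
      v <- upd$v
    }
    vl <- val_loss(par)
    if (!is.finite(vl)) {
      abort(sprintf(
        "training diverged at epoch %d (learning rate %g)",
        epoch, spec$learning_rate
      ), class = "msprog_divergence_error")
    }
    history <- c(history, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = par, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= spec$patience) break
    }
  }
  list(
    params = best$params, best_epoch = best$epoch,
    epochs_run = length(history), val_history = history, best_loss = best$loss
  )
}

#' Predicted progression probabilities
#'
#' Scores episodes with a trained model. The Bayesian network averages
#' `mc_samples` stochastic forward passes with dropout active (seeded, hence
#' deterministic for a fixed model); the other architectures are
#' deterministic single passes with dropout off.
#'
#' @param model an `ms_model` from [train_model()].
#' @param features feature tibble or matrix in the layout the model was
#'   trained with.
#' @param sequences for `temporal_attention`: output of
#'   [build_longitudinal_sequences()] aligned with `features`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features, sequences = NULL) {
  stopifnot(inherits(model, "ms_model"))
  X <- as_feature_input(features)
  layout <- attr(X, "layout") %||% FEATURE_LAYOUT_VERSION
  if (!identical(layout, model$layout)) {
    abort(sprintf(
      "feature layout '%s' does not match the model's '%s'",
      layout, model$layout
    ), class = "msprog_version_error")
  }
  Xs <- apply_scaler(X, model$scaler)
  spec <- model$spec
  if (spec$architecture == "mlp") {
    return(nn_forward(model$params, Xs)$p)
  }
  if (spec$architecture == "bayesian_nn") {
    return(with_seed(spec$seed + 1L, {
      acc <- rep(0, nrow(Xs))
      for (s in seq_len(spec$mc_samples)) {
        acc <- acc + nn_forward(model$params, Xs, spec$dropout, training = TRUE)$p
      }
      acc / spec$mc_samples
    }))
  }
  if (is.null(sequences)) {
    abort("temporal_attention prediction requires sequences",
      class = "msprog_config_error"
    )
  }
  seqs <- assemble_attention_inputs(Xs, sequences, spec)
  vapply(seqs, function(Xi) attn_forward_one(model$params, Xi)$p, numeric(1))
}

#' @export
print.ms_model <- function(x, ...) {
  cat(sprintf(
    "<ms_model: %s> width %d, trained %d epoch(s) (best %d), val loss %.4f\n",
    x$spec$architecture, x$spec$hidden_width, x$meta$epochs_run,
    x$meta$best_epoch, x$meta$best_val_loss
  ))
  invisible(x)
}

#' Tidy a trained classifier's training history
#'
#' @param x an `ms_model`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `val_loss`.
#' @export
tidy.ms_model <- function(x, ...) {
  tibble(epoch = seq_along(x$meta$val_history), val_loss = x$meta$val_history)
}

#' One-row model summary
#'
#' @param x an `ms_model`.
#' @param ... unused.
#' @return one-row tibble: architecture, parameter count, epochs, best
#'   validation loss, training size.
#' @export
glance.ms_model <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  tibble(
    architecture = x$spec$architecture,
    n_parameters = n_par,
    epochs_run = x$meta$epochs_run,
    best_epoch = x$meta$best_epoch,
    best_val_loss = x$meta$best_val_loss,
    n_train = x$meta$n_train
  )
}
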