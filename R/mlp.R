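# From-scratch feedforward network: dense ReLU layers, softmax output,
# categorical cross-entropy, Adam. Matrix-only implementation so the
# classifier module carries no deep-learning framework dependency.

mlp_init <- function(n_in, widths) {
  sizes <- c(n_in, widths)
  layers <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  }
  layers
}

mlp_forward <- function(layers, x) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else mlp_softmax(z)
  }
  acts
}

mlp_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_cross_entropy <- function(p, y) {
  -mean(rowSums(y * log(pmax(p, 1e-12))))
}

# gradients of mean cross-entropy wrt weights, for a softmax output layer
mlp_gradients <- function(layers, acts, y) {
  L <- length(layers)
  n <- nrow(y)
  grads <- vector("list", L)
  delta <- (acts[[L + 1]] - y) / n
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(layers) {
  list(t = 0, m = rapply(layers, function(p) p * 0, how = "replace"),
       v = rapply(layers, function(p) p * 0, how = "replace"))
}

adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / corr1
      vhat <- state$v[[l]][[p]] / corr2
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# one full training run; returns final layers plus per-epoch loss curves
mlp_train <- function(x_train, y_train, x_test, y_test, spec) {
  layers <- mlp_init(ncol(x_train), spec$layer_widths)
  state <- adam_init(layers)
  n <- nrow(x_train)
  curves <- data.frame(epoch = seq_len(spec$epochs), train_loss = NA_real_,
                       test_loss = NA_real_)
  for (epoch in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = spec$batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + spec$batch_size - 1, n)]
      acts <- mlp_forward(layers, x_train[rows, , drop = FALSE])
      grads <- mlp_gradients(layers, acts, y_train[rows, , drop = FALSE])
      upd <- adam_step(layers, grads, state, spec$learning_rate)
      layers <- upd$layers
      state <- upd$state
    }
    p_train <- mlp_forward(layers, x_train)[[length(layers) + 1]]
    curves$train_loss[epoch] <- mlp_cross_entropy(p_train, y_train)
    if (!is.null(x_test) && nrow(x_test)) {
      p_test <- mlp_forward(layers, x_test)[[length(layers) + 1]]
      curves$test_loss[epoch] <- mlp_cross_entropy(p_test, y_test)
    }
    if (!is.finite(curves$train_loss[epoch])) {
      stop(sprintf("mlp_train: non-finite training loss at epoch %d", epoch))
    }
  }
  list(layers = layers, curves = curves)
}

mlp_predict_class <- function(layers, x) {
  p <- mlp_forward(layers, x)[[length(layers) + 1]]
  # which.max breaks ties toward the lowest class index, deterministically
  apply(p, 1, which.max)
}
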