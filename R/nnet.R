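# Base forecasters: a small MLP and single-layer LSTM / GRU networks mapping
# a truncated sedimentation window to the 60-min ESR value. Forward passes,
# backpropagation (through time) and the ADAM optimizer are implemented
# directly with matrix arithmetic; the networks are tiny (<= 15 hidden
# units) so full-batch training in R is fast and exactly reproducible.

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-broadcast bias addition (much cheaper than sweep() in the hot loop)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    identity = list(f = identity, df = function(x) x * 0 + 1),
    abort(sprintf("unknown activation '%s'.", name))
  )
}

#' Training configuration for the base forecasters
#'
#' Defaults follow the standard protocol for this task: mean-squared-error
#' loss, mini-batch ADAM with an exponentially decaying learning rate, at
#' most 300 epochs, and early stopping when the validation loss has not
#' improved for 15 epochs (the best-validation weights are restored).
#' Batches are drawn by a seeded shuffle each epoch, so training is exactly
#' reproducible.
#'
#' @param max_epochs Maximum number of epochs (default 300).
#' @param patience Early-stopping patience in epochs (default 15); must be
#'   below `max_epochs`.
#' @param lr Initial learning rate (default 0.01).
#' @param decay_rate,decay_steps Exponential schedule: the learning rate at
#'   optimizer step s is `lr * decay_rate^(s / decay_steps)` (defaults 0.96
#'   per 100 steps; one step per mini-batch).
#' @param batch_size Mini-batch size (default 32).
#' @param hidden Hidden-layer sizes; `NULL` uses the per-architecture
#'   defaults (MLP: 15 and 10 neurons; LSTM/GRU: one layer of 15 units).
#' @param activation MLP hidden activation: "relu" (default), "tanh" or
#'   "identity". Recurrent gates always use sigmoid/tanh.
#' @return A list of class `train_config`.
#' @examples
#' train_config(max_epochs = 50)
#' @export
train_config <- function(max_epochs = 300, patience = 15, lr = 0.01,
                         decay_rate = 0.96, decay_steps = 100,
                         batch_size = 32, hidden = NULL, activation = "relu") {
  assert_scalar_number(max_epochs, "max_epochs", lower = 1)
  assert_scalar_number(patience, "patience", lower = 1)
  assert_scalar_number(lr, "lr", lower = 1e-12)
  assert_scalar_number(decay_rate, "decay_rate", lower = 1e-12, upper = 1)
  assert_scalar_number(decay_steps, "decay_steps", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  if (patience >= max_epochs) {
    abort("`patience` must be smaller than `max_epochs`.")
  }
  act_fun(activation) # validates
  structure(
    list(
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      lr = lr, decay_rate = decay_rate, decay_steps = decay_steps,
      batch_size = as.integer(batch_size), hidden = hidden,
      activation = activation
    ),
    class = "train_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

default_hidden <- function(kind) {
  switch(kind, MLP = c(15L, 10L), LSTM = 15L, GRU = 15L)
}

init_weights <- function(kind, input_len, hidden = NULL, seed = 1) {
  hidden <- hidden %||% default_hidden(kind)
  withr::with_seed(as.integer(seed), {
    if (kind == "MLP") {
      stopifnot(length(hidden) == 2L)
      list(
        W1 = glorot(input_len, hidden[1]), b1 = numeric(hidden[1]),
        W2 = glorot(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
        W3 = glorot(hidden[2], 1L), b3 = 0
      )
    } else {
      H <- hidden[1]
      gates <- switch(kind, LSTM = c("i", "o", "f", "c"), GRU = c("g", "r", "h"))
      w <- list()
      for (g in gates) {
        w[[paste0("W_", g, "1")]] <- glorot(1L, H)
        w[[paste0("W_", g, "2")]] <- glorot(H, H)
        w[[paste0("b_", g)]] <- numeric(H)
      }
      w$V <- glorot(H, 1L)
      w$b_v <- 0
      w
    }
  })
}

#' Forward pass of the MLP forecaster
#'
#' Two hidden layers with activation `phi`, then a single linear output
#' neuron; the input window is treated as a flat feature vector (the MLP has
#' no notion of temporal order).
#'
#' @param weights Named list `W1, b1, W2, b2, W3, b3` (matrices / vectors
#'   with conforming shapes).
#' @param x Input matrix (n_samples x n_features) or a single vector.
#' @param activation Hidden activation name, see [train_config()].
#' @return Numeric vector of n_samples forecasts.
#' @examples
#' w <- esrstack:::init_weights("MLP", 4, seed = 1)
#' mlp_forward(w, matrix(runif(8), 2, 4))
#' @export
mlp_forward <- function(weights, x, activation = "relu") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  check_shapes_mlp(weights, ncol(x))
  phi <- act_fun(activation)$f
  a1 <- phi(x %*% weights$W1 + rep(weights$b1, each = nrow(x)))
  a2 <- phi(a1 %*% weights$W2 + rep(weights$b2, each = nrow(x)))
  drop(a2 %*% weights$W3 + weights$b3)
}

check_shapes_mlp <- function(w, p) {
  if (nrow(w$W1) != p) {
    abort(sprintf("MLP input size mismatch: weights expect %d features, got %d.", nrow(w$W1), p))
  }
  if (ncol(w$W1) != nrow(w$W2) || ncol(w$W2) != nrow(w$W3) || ncol(w$W3) != 1L) {
    abort("MLP weight shapes are inconsistent.")
  }
  invisible(TRUE)
}

#' One step of the LSTM recurrence
#'
#' Applies the gated update of a long short-term memory cell: input, output
#' and forget gates are sigmoids of affine maps of the current input and the
#' previous hidden state; the cell state is the forget-gated previous cell
#' plus the input-gated tanh candidate, and the hidden state is the
#' output-gated tanh of the cell state,
#' \deqn{i_t = \sigma(W_{i1} x_t + W_{i2} h_{t-1} + b_i)} and likewise for
#' \eqn{o_t, f_t}, then
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{c1} x_t + W_{c2} h_{t-1} + b_c),
#'       \quad h_t = o_t \odot \tanh(c_t).}
#'
#' @param state List with matrices `h` and `c` (n_samples x H); use zeros to
#'   start a sequence.
#' @param weights Named list `W_i1, W_i2, b_i, W_o1, W_o2, b_o, W_f1, W_f2,
#'   b_f, W_c1, W_c2, b_c` (input maps are 1 x H for the univariate series).
#' @param x_t Input at this time step: numeric vector of length n_samples.
#' @return Updated state list, additionally carrying the gate activations
#'   `i`, `o`, `f` and the tanh candidate `g`.
#' @examples
#' w <- esrstack:::init_weights("LSTM", 1, hidden = 3, seed = 1)
#' s <- list(h = matrix(0, 1, 3), c = matrix(0, 1, 3))
#' lstm_step(s, w, 0.9)
#' @export
lstm_step <- function(state, weights, x_t) {
  x <- matrix(x_t, ncol = 1)
  h <- state$h
  if (nrow(h) != nrow(x) || ncol(h) != ncol(weights$W_i2)) {
    abort("LSTM state/input shapes are inconsistent.")
  }
  i <- sigmoid(add_bias(x %*% weights$W_i1 + h %*% weights$W_i2, weights$b_i))
  o <- sigmoid(add_bias(x %*% weights$W_o1 + h %*% weights$W_o2, weights$b_o))
  f <- sigmoid(add_bias(x %*% weights$W_f1 + h %*% weights$W_f2, weights$b_f))
  g <- tanh(add_bias(x %*% weights$W_c1 + h %*% weights$W_c2, weights$b_c))
  c_new <- f * state$c + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, i = i, o = o, f = f, g = g)
}

#' One step of the GRU recurrence
#'
#' Gated recurrent unit update: update gate \eqn{g_t} and reset gate
#' \eqn{r_t} are sigmoids of affine maps of the input and previous hidden
#' state; the candidate state applies the reset gate to \eqn{h_{t-1}}
#' inside its affine map,
#' \deqn{\tilde h_t = \tanh(W_{h1} x_t + W_{h2}(r_t \odot h_{t-1}) + b_h),}
#' and the new hidden state interpolates
#' \deqn{h_t = (1 - g_t) \odot h_{t-1} + g_t \odot \tilde h_t.}
#'
#' @param state List with matrix `h` (n_samples x H).
#' @param weights Named list `W_g1, W_g2, b_g, W_r1, W_r2, b_r, W_h1, W_h2,
#'   b_h`.
#' @param x_t Input at this time step: numeric vector of length n_samples.
#' @return Updated state list, additionally carrying `g`, `r` and the
#'   candidate `hc`.
#' @examples
#' w <- esrstack:::init_weights("GRU", 1, hidden = 3, seed = 1)
#' gru_step(list(h = matrix(0, 1, 3)), w, 1)
#' @export
gru_step <- function(state, weights, x_t) {
  x <- matrix(x_t, ncol = 1)
  h <- state$h
  if (nrow(h) != nrow(x) || ncol(h) != ncol(weights$W_g2)) {
    abort("GRU state/input shapes are inconsistent.")
  }
  g <- sigmoid(add_bias(x %*% weights$W_g1 + h %*% weights$W_g2, weights$b_g))
  r <- sigmoid(add_bias(x %*% weights$W_r1 + h %*% weights$W_r2, weights$b_r))
  hc <- tanh(add_bias(x %*% weights$W_h1 + (r * h) %*% weights$W_h2, weights$b_h))
  h_new <- (1 - g) * h + g * hc
  list(h = h_new, g = g, r = r, hc = hc)
}

# Full-sequence forward pass. X is n x T (one column per 0.5-min step).
# Returns forecasts and, if keep_cache, the per-step states for BPTT.
net_forward <- function(kind, weights, X, activation = "relu", keep_cache = FALSE) {
  if (kind == "MLP") {
    phi <- act_fun(activation)
    z1 <- add_bias(X %*% weights$W1, weights$b1)
    a1 <- phi$f(z1)
    z2 <- add_bias(a1 %*% weights$W2, weights$b2)
    a2 <- phi$f(z2)
    yhat <- drop(a2 %*% weights$W3 + weights$b3)
    if (!keep_cache) {
      return(list(yhat = yhat))
    }
    return(list(yhat = yhat, cache = list(z1 = z1, a1 = a1, z2 = z2, a2 = a2)))
  }
  n <- nrow(X)
  H <- nrow(weights$V)
  state <- list(h = matrix(0, n, H), c = matrix(0, n, H))
  steps <- if (keep_cache) vector("list", ncol(X)) else NULL
  for (t in seq_len(ncol(X))) {
    prev_h <- state$h
    prev_c <- state$c
    state <- if (kind == "LSTM") {
      lstm_step(state, weights, X[, t])
    } else {
      gru_step(state, weights, X[, t])
    }
    if (keep_cache) {
      steps[[t]] <- c(state, list(h_prev = prev_h, c_prev = prev_c))
    }
  }
  yhat <- drop(state$h %*% weights$V + weights$b_v)
  list(yhat = yhat, h_final = state$h, cache = steps)
}

zero_like <- function(w) lapply(w, function(x) x * 0)

# Analytic gradients of the mean-squared-error loss wrt all weights.
net_grad <- function(kind, weights, X, y, activation = "relu") {
  n <- nrow(X)
  fwd <- net_forward(kind, weights, X, activation, keep_cache = TRUE)
  resid <- fwd$yhat - y
  loss <- mean(resid^2)
  dy <- matrix(2 * resid / n, ncol = 1)
  g <- zero_like(weights)

  if (kind == "MLP") {
    phi <- act_fun(activation)
    cc <- fwd$cache
    g$W3 <- t(cc$a2) %*% dy
    g$b3 <- sum(dy)
    dz2 <- (dy %*% t(weights$W3)) * phi$df(cc$z2)
    g$W2 <- t(cc$a1) %*% dz2
    g$b2 <- colSums(dz2)
    dz1 <- (dz2 %*% t(weights$W2)) * phi$df(cc$z1)
    g$W1 <- t(X) %*% dz1
    g$b1 <- colSums(dz1)
    return(list(loss = loss, grads = g, yhat = fwd$yhat))
  }

  steps <- fwd$cache
  T_len <- length(steps)
  h_T <- steps[[T_len]]$h
  g$V <- t(h_T) %*% dy
  g$b_v <- sum(dy)
  dh <- dy %*% t(weights$V)

  if (kind == "LSTM") {
    dc <- matrix(0, n, ncol(dh))
    for (t in rev(seq_len(T_len))) {
      st <- steps[[t]]
      x <- matrix(X[, t], ncol = 1)
      tc <- tanh(st$c)
      d_o <- dh * tc
      da_o <- d_o * st$o * (1 - st$o)
      dc <- dc + dh * st$o * (1 - tc^2)
      d_i <- dc * st$g
      da_i <- d_i * st$i * (1 - st$i)
      d_g <- dc * st$i
      da_c <- d_g * (1 - st$g^2)
      d_f <- dc * st$c_prev
      da_f <- d_f * st$f * (1 - st$f)
      g$W_i1 <- g$W_i1 + t(x) %*% da_i
      g$W_i2 <- g$W_i2 + t(st$h_prev) %*% da_i
      g$b_i <- g$b_i + colSums(da_i)
      g$W_o1 <- g$W_o1 + t(x) %*% da_o
      g$W_o2 <- g$W_o2 + t(st$h_prev) %*% da_o
      g$b_o <- g$b_o + colSums(da_o)
      g$W_f1 <- g$W_f1 + t(x) %*% da_f
      g$W_f2 <- g$W_f2 + t(st$h_prev) %*% da_f
      g$b_f <- g$b_f + colSums(da_f)
      g$W_c1 <- g$W_c1 + t(x) %*% da_c
      g$W_c2 <- g$W_c2 + t(st$h_prev) %*% da_c
      g$b_c <- g$b_c + colSums(da_c)
      dh <- da_i %*% t(weights$W_i2) + da_o %*% t(weights$W_o2) +
        da_f %*% t(weights$W_f2) + da_c %*% t(weights$W_c2)
      dc <- dc * st$f
    }
  } else { # GRU
    for (t in rev(seq_len(T_len))) {
      st <- steps[[t]]
      x <- matrix(X[, t], ncol = 1)
      d_g <- dh * (st$hc - st$h_prev)
      da_g <- d_g * st$g * (1 - st$g)
      d_hc <- dh * st$g
      da_h <- d_hc * (1 - st$hc^2)
      dh_prev <- dh * (1 - st$g)
      d_rh <- da_h %*% t(weights$W_h2) # gradient wrt (r * h_prev)
      d_r <- d_rh * st$h_prev
      da_r <- d_r * st$r * (1 - st$r)
      dh_prev <- dh_prev + d_rh * st$r
      g$W_g1 <- g$W_g1 + t(x) %*% da_g
      g$W_g2 <- g$W_g2 + t(st$h_prev) %*% da_g
      g$b_g <- g$b_g + colSums(da_g)
      g$W_r1 <- g$W_r1 + t(x) %*% da_r
      g$W_r2 <- g$W_r2 + t(st$h_prev) %*% da_r
      g$b_r <- g$b_r + colSums(da_r)
      g$W_h1 <- g$W_h1 + t(x) %*% da_h
      g$W_h2 <- g$W_h2 + t(st$r * st$h_prev) %*% da_h
      g$b_h <- g$b_h + colSums(da_h)
      dh <- dh_prev + da_g %*% t(weights$W_g2) + da_r %*% t(weights$W_r2)
    }
  }
  list(loss = loss, grads = g, yhat = fwd$yhat)
}

#' Train a base forecaster
#'
#' Trains an MLP, LSTM or GRU on (window, target) pairs with full-batch ADAM
#' under the mean-squared-error loss, an exponentially decaying learning
#' rate, and early stopping on the validation loss (best-validation weights
#' restored). Fully reproducible for a given seed.
#'
#' @param train,val Window tibbles from [make_windows()] (disjoint subjects,
#'   same window length).
#' @param kind One of "MLP", "LSTM", "GRU".
#' @param config A [train_config()].
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `esr_net` with elements `kind`, `weights`
#'   (best-validation), `log` (per-epoch tibble: epoch, lr, train_loss,
#'   val_loss), `best_epoch`, `L`, `config`, `seed`.
#' @examples
#' curves <- simulate_curves(20, 0, seed = 1)
#' w <- make_windows(curves, 15)
#' fit <- train_network(w[1:15, ], w[16:20, ], "MLP",
#'   config = train_config(max_epochs = 30, patience = 5), seed = 1
#' )
#' glance(fit)
#' @export
train_network <- function(train, val, kind = c("GRU", "LSTM", "MLP"),
                          config = train_config(), seed = 1) {
  kind <- match.arg(kind)
  if (!nrow(train) || !nrow(val)) {
    abort("`train` and `val` must both be nonempty.")
  }
  L <- attr(train, "L")
  if (!identical(attr(val, "L"), L)) {
    abort("`train` and `val` were built with different window lengths.")
  }
  X_tr <- window_matrix(train)
  y_tr <- train$target
  X_va <- window_matrix(val)
  y_va <- val$target
  if (ncol(X_tr) != ncol(X_va)) {
    abort("train/val window lengths differ.")
  }

  input_len <- if (kind == "MLP") ncol(X_tr) else 1L
  weights <- init_weights(kind, input_len, hidden = config$hidden, seed = seed)

  # ADAM state
  m <- zero_like(weights)
  v <- zero_like(weights)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8

  best <- list(val = Inf, weights = weights, epoch = 0L)
  wait <- 0L
  log <- vector("list", config$max_epochs)
  n_tr <- nrow(X_tr)
  batch_starts <- seq(1, n_tr, by = config$batch_size)
  shuffle_seeds <- derive_seeds(seed, config$max_epochs, salt = 17L)
  step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- withr::with_seed(shuffle_seeds[epoch], sample.int(n_tr))
    epoch_loss <- 0
    lr_t <- NA_real_
    for (s0 in batch_starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, n_tr)]
      gr <- net_grad(kind, weights, X_tr[idx, , drop = FALSE], y_tr[idx], config$activation)
      if (!is.finite(gr$loss)) {
        abort(sprintf(
          "%s training diverged at epoch %d (non-finite loss); try a lower learning rate.",
          kind, epoch
        ))
      }
      lr_t <- config$lr * config$decay_rate^(step / config$decay_steps)
      step <- step + 1L
      for (nm in names(weights)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gr$grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gr$grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        weights[[nm]] <- weights[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
      }
      epoch_loss <- epoch_loss + gr$loss * length(idx)
    }
    val_loss <- mean((net_forward(kind, weights, X_va, config$activation)$yhat - y_va)^2)
    log[[epoch]] <- c(
      epoch = epoch, lr = lr_t,
      train_loss = epoch_loss / n_tr, val_loss = val_loss
    )
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, weights = weights, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  log <- tibble::as_tibble(do.call(rbind, log[!vapply(log, is.null, logical(1))]))
  structure(
    list(
      kind = kind, weights = best$weights, log = log,
      best_epoch = best$epoch, best_val_loss = best$val,
      L = L, config = config, seed = as.integer(seed)
    ),
    class = "esr_net"
  )
}

#' @export
print.esr_net <- function(x, ...) {
  cat(sprintf(
    "<esr_net> %s forecaster (L = %s min), trained %d epochs, best val MSE %.3g at epoch %d\n",
    x$kind, format(x$L), nrow(x$log), x$best_val_loss, x$best_epoch
  ))
  invisible(x)
}

#' Predict ESR values with a trained forecaster
#'
#' @param object An `esr_net` from [train_network()].
#' @param newdata Window tibble from [make_windows()] with the same window
#'   length the model was trained on.
#' @param ... Unused.
#' @return Numeric vector of forecasts, aligned with the rows of `newdata`.
#' @export
predict.esr_net <- function(object, newdata, ...) {
  X <- window_matrix(newdata)
  n_in <- as.integer(2 * object$L + 1)
  if (ncol(X) != n_in) {
    abort(sprintf(
      "window length mismatch: model trained with %d inputs, newdata has %d.",
      n_in, ncol(X)
    ))
  }
  net_forward(object$kind, object$weights, X, object$config$activation)$yhat
}

#' @export
tidy.esr_net <- function(x, ...) x$log

#' @export
glance.esr_net <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, L = x$L, epochs_run = nrow(x$log),
    best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
    seed = x$seed
  )
}

# Framework-agnostic weight dump (layer name -> nested arrays), and loader.
#' Export / import network weights as JSON
#'
#' @param object An `esr_net`.
#' @param path File path for the JSON dump.
#' @return `write_weights_json()` returns `path` invisibly;
#'   `read_weights_json()` returns the named list of weight arrays.
#' @examples
#' curves <- simulate_curves(12, 0, seed = 1)
#' w <- make_windows(curves, 5)
#' fit <- train_network(w[1:9, ], w[10:12, ], "MLP",
#'   config = train_config(max_epochs = 20, patience = 5)
#' )
#' f <- tempfile(fileext = ".json")
#' write_weights_json(fit, f)
#' @export
write_weights_json <- function(object, path) {
  stopifnot(inherits(object, "esr_net"))
  jsonlite::write_json(
    list(kind = object$kind, L = object$L, weights = object$weights),
    path,
    digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
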