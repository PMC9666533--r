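test_that("window construction follows the 0.5-min grid arithmetic", {
  curves <- simulate_curves(3, 0, seed = 2)
  w15 <- make_windows(curves, 15)
  expect_true(all(lengths(w15$window) == 31))
  w5 <- make_windows(curves, 5)
  expect_true(all(lengths(w5$window) == 11))
  expect_equal(attr(w5, "L"), 5)
  # targets are the 60-min values
  finals <- dplyr::filter(curves, time_min == 60)
  expect_equal(w5$target, finals$h_ratio[match(w5$sample_id, finals$sample_id)])
  # off-grid and short lengths are rejected unless overridden
  expect_error(make_windows(curves, 9), "window grid")
  w60 <- make_windows(curves, 60, allow_any = TRUE)
  expect_true(all(lengths(w60$window) == 121))
  expect_equal(vapply(w60$window, function(x) x[121], numeric(1)), w60$target)
  expect_error(make_windows(curves[curves$time_min < 59, ], 15), "60 min")
})

test_that("MLP forward pass matches hand arithmetic", {
  # zero weights, tanh: output is exactly 0
  w0 <- list(
    W1 = matrix(0, 2, 3), b1 = numeric(3),
    W2 = matrix(0, 3, 2), b2 = numeric(2),
    W3 = matrix(0, 2, 1), b3 = 0
  )
  expect_equal(mlp_forward(w0, c(0.3, 0.7), activation = "tanh"), 0)
  # identity chain of unit weights propagates the input
  w1 <- list(
    W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0,
    W3 = matrix(1, 1, 1), b3 = 0
  )
  expect_equal(mlp_forward(w1, 2, activation = "identity"), 2)
  # random nets against an explicit matrix recomputation
  withr::local_seed(5)
  for (i in 1:25) {
    w <- esrstack:::init_weights("MLP", 4, hidden = c(3, 2), seed = i)
    x <- runif(4)
    relu <- function(z) pmax(z, 0)
    a1 <- relu(drop(x %*% w$W1) + w$b1)
    a2 <- relu(drop(a1 %*% w$W2) + w$b2)
    manual <- drop(a2 %*% w$W3) + w$b3
    expect_equal(mlp_forward(w, x), manual, tolerance = 1e-12)
  }
  expect_error(mlp_forward(w1, c(1, 2)), "mismatch")
})

test_that("LSTM step implements the gate equations", {
  H <- 3
  wz <- esrstack:::init_weights("LSTM", 1, hidden = H, seed = 1)
  for (nm in names(wz)) wz[[nm]] <- wz[[nm]] * 0
  s0 <- list(h = matrix(0, 1, H), c = matrix(0, 1, H))
  s1 <- lstm_step(s0, wz, 0.8)
  expect_equal(as.vector(s1$i), rep(0.5, H))
  expect_equal(as.vector(s1$o), rep(0.5, H))
  expect_equal(as.vector(s1$f), rep(0.5, H))
  expect_equal(as.vector(s1$c), rep(0, H))
  expect_equal(as.vector(s1$h), rep(0, H))

  # unit-dimension cell over two steps against scalar arithmetic
  w <- list(
    W_i1 = matrix(0.4, 1, 1), W_i2 = matrix(-0.2, 1, 1), b_i = 0.1,
    W_o1 = matrix(-0.3, 1, 1), W_o2 = matrix(0.5, 1, 1), b_o = -0.1,
    W_f1 = matrix(0.2, 1, 1), W_f2 = matrix(0.3, 1, 1), b_f = 0.2,
    W_c1 = matrix(0.7, 1, 1), W_c2 = matrix(-0.4, 1, 1), b_c = 0
  )
  s <- list(h = matrix(0, 1, 1), c = matrix(0, 1, 1))
  for (x in c(0.9, 0.6)) s <- lstm_step(s, w, x)
  ref <- manual_lstm(w, c(0.9, 0.6))
  expect_equal(drop(s$h), ref$h, tolerance = 1e-14)
  expect_equal(drop(s$c), ref$c, tolerance = 1e-14)

  # gates always lie strictly inside (0, 1)
  withr::local_seed(8)
  wr <- esrstack:::init_weights("LSTM", 1, hidden = 4, seed = 3)
  s <- list(h = matrix(rnorm(8), 2, 4), c = matrix(rnorm(8), 2, 4))
  st <- lstm_step(s, wr, c(0.5, 1.2))
  for (gate in list(st$i, st$o, st$f)) {
    expect_true(all(gate > 0 & gate < 1))
  }
})

test_that("GRU step implements the gate equations", {
  H <- 3
  wz <- esrstack:::init_weights("GRU", 1, hidden = H, seed = 1)
  for (nm in names(wz)) wz[[nm]] <- wz[[nm]] * 0
  s1 <- gru_step(list(h = matrix(0, 1, H)), wz, 1)
  expect_equal(as.vector(s1$h), rep(0, H))

  # saturated update gate hands the state to the candidate
  wg <- wz
  wg$b_g <- rep(30, H)
  wg$W_h1 <- matrix(c(0.5, -0.5, 0.25), 1, H)
  s2 <- gru_step(list(h = matrix(0.9, 1, H)), wg, 1)
  expect_equal(as.vector(s2$h), as.vector(tanh(c(0.5, -0.5, 0.25))), tolerance = 1e-10)

  # unit-dimension cell over two steps against scalar arithmetic
  w <- list(
    W_g1 = matrix(0.3, 1, 1), W_g2 = matrix(0.2, 1, 1), b_g = -0.1,
    W_r1 = matrix(-0.4, 1, 1), W_r2 = matrix(0.6, 1, 1), b_r = 0.05,
    W_h1 = matrix(0.8, 1, 1), W_h2 = matrix(-0.3, 1, 1), b_h = 0.1
  )
  s <- list(h = matrix(0, 1, 1))
  for (x in c(0.9, 0.6)) s <- gru_step(s, w, x)
  expect_equal(drop(s$h), manual_gru(w, c(0.9, 0.6)), tolerance = 1e-14)
})

test_that("analytic gradients match finite differences", {
  numgrad <- function(kind, w, X, y, act) {
    g <- lapply(w, function(m) m * 0)
    eps <- 1e-6
    for (nm in names(w)) {
      for (i in seq_along(w[[nm]])) {
        wp <- w
        wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w
        wm[[nm]][i] <- wm[[nm]][i] - eps
        lp <- mean((esrstack:::net_forward(kind, wp, X, act)$yhat - y)^2)
        lm <- mean((esrstack:::net_forward(kind, wm, X, act)$yhat - y)^2)
        g[[nm]][i] <- (lp - lm) / (2 * eps)
      }
    }
    g
  }
  withr::local_seed(42)
  X <- matrix(runif(20), 5, 4)
  y <- runif(5)
  for (kind in c("MLP", "LSTM", "GRU")) {
    act <- if (kind == "MLP") "tanh" else "relu"
    w <- esrstack:::init_weights(kind,
      if (kind == "MLP") 4 else 1,
      hidden = if (kind == "MLP") c(3, 2) else 3, seed = 1
    )
    an <- esrstack:::net_grad(kind, w, X, y, act)$grads
    nu <- numgrad(kind, w, X, y, act)
    err <- max(mapply(function(a, b) max(abs(a - b)), an, nu))
    expect_lt(err, 1e-6)
  }
})

test_that("training is seed-deterministic and early stopping obeys its patience", {
  w <- tiny_windows(5)
  cfg <- fast_config(max_epochs = 25, patience = 4)
  a <- train_network(w$train, w$val, "MLP", config = cfg, seed = 9)
  b <- train_network(w$train, w$val, "MLP", config = cfg, seed = 9)
  expect_identical(a$weights, b$weights)
  expect_identical(a$log, b$log)
  expect_false(identical(
    a$weights,
    train_network(w$train, w$val, "MLP", config = cfg, seed = 10)$weights
  ))
  # when stopped before the epoch cap, exactly `patience` epochs passed
  # without improvement after the best one
  if (nrow(a$log) < cfg$max_epochs) {
    expect_equal(nrow(a$log), a$best_epoch + cfg$patience)
  }
  # the restored weights reproduce the best validation loss
  val_mse <- mean((predict(a, w$val) - w$val$target)^2)
  expect_equal(val_mse, a$best_val_loss, tolerance = 1e-12)
  expect_equal(min(a$log$val_loss), a$best_val_loss, tolerance = 1e-12)
  # learning rate follows the exponential decay schedule
  expect_true(all(diff(a$log$lr) < 0))
  expect_error(train_network(w$train[0, ], w$val, "MLP"), "nonempty")
})

test_that("prediction is order-preserving and respects the output layer", {
  w <- tiny_windows(5)
  fit <- train_network(w$train, w$val, "MLP", config = fast_config(), seed = 1)
  p <- predict(fit, w$test)
  expect_true(all(is.finite(p)))
  perm <- c(3, 1, 2, 7, 5, 6, 4)
  expect_equal(predict(fit, w$test[perm, ]), p[perm])
  # zeroed output layer collapses all forecasts to the output bias
  fit0 <- fit
  fit0$weights$W3 <- fit0$weights$W3 * 0
  fit0$weights$b3 <- 0.42
  expect_equal(predict(fit0, w$test), rep(0.42, 7))
  expect_error(predict(fit, tiny_windows(7.5)$test), "mismatch")
})

test_that("a small MLP can overfit a tiny training set", {
  # well-separated inputs so the check probes capacity, not conditioning
  withr::local_seed(1)
  w <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    target = runif(8, 0.35, 0.86),
    window = lapply(1:8, function(i) runif(11))
  )
  attr(w, "L") <- 5
  fit <- train_network(w, w, "MLP",
    config = train_config(max_epochs = 300, patience = 299, batch_size = 2), seed = 4
  )
  expect_lt(mean((predict(fit, w) - w$target)^2), 1e-3)
})

test_that("trained networks beat the constant-mean predictor", {
  curves <- simulate_curves(60, 0, seed = 77)
  sp <- split_cohort(curves, c(40, 10, 10), seed = 2)
  w <- lapply(sp[c("train", "val", "test")], make_windows, L = 15)
  fit <- train_network(w$train, w$val, "MLP", config = train_config(), seed = 3)
  base_mape <- mape(w$test$target, rep(mean(w$train$target), nrow(w$test)))
  expect_lt(mape(w$test$target, predict(fit, w$test)), base_mape)
})

test_that("weight dumps round-trip through JSON", {
  w <- tiny_windows(5)
  fit <- train_network(w$train, w$val, "GRU",
    config = fast_config(max_epochs = 10, patience = 3), seed = 2
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_weights_json(fit, f)
  back <- read_weights_json(f)
  expect_equal(back$kind, "GRU")
  expect_equal(back$weights$W_g2, fit$weights$W_g2, tolerance = 1e-12)
  expect_equal(back$weights$b_v, fit$weights$b_v, tolerance = 1e-12)
})
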