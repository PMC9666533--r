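# Shared fixtures: a small simulated cohort and a fast training
# configuration reused across test files. All fixtures are generated in
# code under fixed seeds.

fast_config <- function(max_epochs = 30, patience = 8, ...) {
  train_config(max_epochs = max_epochs, patience = patience, ...)
}

# 40 normal + 4 patient subjects, default priors/noise
tiny_cohort <- simulate_curves(n_normal = 40, n_patient = 4, seed = 42)

tiny_split <- split_cohort(tiny_cohort, c(26, 7, 7), seed = 1)

tiny_windows <- function(L = 5) {
  lapply(tiny_split[c("train", "val", "test")], make_windows, L = L)
}

# Manual LSTM step on scalars, straight from the gate equations.
manual_lstm <- function(w, x_seq, h0 = 0, c0 = 0) {
  h <- h0
  cc <- c0
  sig <- function(z) 1 / (1 + exp(-z))
  for (x in x_seq) {
    i <- sig(w$W_i1 * x + w$W_i2 * h + w$b_i)
    o <- sig(w$W_o1 * x + w$W_o2 * h + w$b_o)
    f <- sig(w$W_f1 * x + w$W_f2 * h + w$b_f)
    cc <- f * cc + i * tanh(w$W_c1 * x + w$W_c2 * h + w$b_c)
    h <- o * tanh(cc)
  }
  list(h = drop(h), c = drop(cc))
}

# Manual GRU step on scalars (reset gate inside the candidate).
manual_gru <- function(w, x_seq, h0 = 0) {
  h <- h0
  sig <- function(z) 1 / (1 + exp(-z))
  for (x in x_seq) {
    g <- sig(w$W_g1 * x + w$W_g2 * h + w$b_g)
    r <- sig(w$W_r1 * x + w$W_r2 * h + w$b_r)
    hc <- tanh(w$W_h1 * x + w$W_h2 * (r * h) + w$b_h)
    h <- (1 - g) * h + g * hc
  }
  drop(h)
}

# Naive per-threshold Otsu scan: between-class variance computed directly
# on the two pixel groups for every candidate threshold.
otsu_scan_oracle <- function(img) {
  v <- as.integer(pmin(pmax(round(img), 0), 255))
  best_t <- NA_integer_
  best_var <- -Inf
  for (k in 0:254) {
    lo <- v[v <= k]
    hi <- v[v > k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) {
      best_var <- bc
      best_t <- k
    }
  }
  best_t
}

# Naive single-changepoint scan: per-cut segment SSE via mean().
changepoint_scan_oracle <- function(x) {
  n <- length(x)
  best_c <- 1L
  best_sse <- Inf
  for (cc in 1:(n - 1)) {
    left <- x[1:cc]
    right <- x[(cc + 1):n]
    sse <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_c <- cc
    }
  }
  best_c
}
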