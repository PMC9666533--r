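test_that("bootstrap resampling is seeded and asymptotically 63.2% unique", {
  expect_equal(bootstrap_indices(1, seed = 1), 1L)
  idx <- bootstrap_indices(10000, seed = 3)
  expect_length(idx, 10000)
  expect_true(all(idx >= 1 & idx <= 10000))
  uf <- length(unique(idx)) / 10000
  expect_gt(uf, 0.62)
  expect_lt(uf, 0.65)
  expect_identical(idx, bootstrap_indices(10000, seed = 3))
  expect_error(bootstrap_indices(0), "positive")
})

test_that("mean and median combiners follow their row-wise definitions", {
  Z1 <- cbind(c(0.4, 0.5), c(0.4, 0.5))
  expect_equal(combine_mean(Z1), c(0.4, 0.5))
  expect_equal(combine_mean(cbind(0.4, 0.6)), 0.5)
  expect_equal(combine_median(rbind(c(0.4, 0.5, 0.9))), 0.5)
  expect_equal(combine_median(rbind(c(0.1, 0.2, 0.8, 0.9))), 0.5)
  withr::local_seed(12)
  Z <- matrix(runif(60), 12, 5)
  expect_equal(combine_mean(Z), apply(Z, 1, function(r) sum(r) / length(r)))
  expect_equal(combine_median(Z), apply(Z, 1, function(r) {
    s <- sort(r)
    (s[3])
  }))
  # mean and median coincide for M <= 2 and for identical columns
  Z2 <- matrix(runif(20), 10, 2)
  expect_equal(combine_mean(Z2), combine_median(Z2))
  Zid <- matrix(rep(runif(10), 3), 10, 3)
  expect_equal(combine_mean(Zid), combine_median(Zid))
  expect_error(combine_mean(cbind(c(1, NA))), "non-finite")
})

test_that("LASSO meta-model recovers OLS at vanishing penalty", {
  withr::local_seed(20)
  Z <- matrix(rnorm(150), 50, 3)
  y <- drop(Z %*% c(0.5, -0.2, 0.1)) + 0.4 + rnorm(50, 0, 0.05)
  fit <- fit_meta_lasso(Z, y, lambda = c(1e-9, 1e-8), seed = 1)
  ols <- coef(lm(y ~ Z))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
  expect_equal(predict(fit, Z), unname(predict(lm(y ~ Z))), tolerance = 1e-6)
})

test_that("LASSO shrinks fully at large penalty and soft-thresholds one predictor", {
  withr::local_seed(21)
  Z <- matrix(rnorm(120), 40, 3)
  y <- rnorm(40, mean = 0.6, sd = 0.2)
  fit <- fit_meta_lasso(Z, y, lambda = c(1e4, 1e3), seed = 1)
  expect_equal(unname(coef(fit))[-1], rep(0, 3))
  expect_equal(predict(fit, Z), rep(mean(y), 40), tolerance = 1e-8)

  # single standardized predictor: coefficient is the soft-thresholded OLS
  # value (glmnet objective: (1/2n)RSS + lambda |beta|)
  n <- 60
  z <- rnorm(n)
  z <- (z - mean(z)) / sqrt(sum((z - mean(z))^2) / n)
  yy <- 0.8 * z + rnorm(n, 0, 0.3)
  lam <- 0.2
  fit1 <- fit_meta_lasso(matrix(z, ncol = 1), yy, lambda = c(lam, lam / 2), seed = 1)
  rho <- mean(z * (yy - mean(yy)))
  soft <- sign(rho) * max(abs(rho) - lam, 0)
  b <- as.numeric(coef(glmnet::glmnet(cbind(z, 0), yy,
    lambda = lam,
    standardize = FALSE, thresh = 1e-12
  ))[2])
  expect_equal(b, soft, tolerance = 1e-6)
  expect_equal(unname(coef(fit1)[2]),
    sign(rho) * max(abs(rho) - lam / 2, 0),
    tolerance = 1e-6
  )
})

test_that("LASSO cross-validation is reproducible and picks from the grid", {
  withr::local_seed(22)
  Z <- matrix(runif(200, 0.3, 0.9), 50, 4)
  y <- rowMeans(Z) + rnorm(50, 0, 0.02)
  a <- fit_meta_lasso(Z, y, seed = 5)
  b <- fit_meta_lasso(Z, y, seed = 5)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$cv, b$cv)
  expect_true(a$lambda %in% a$cv$lambda)
})

test_that("PLSR with all components reproduces least squares", {
  withr::local_seed(23)
  Z <- matrix(rnorm(200), 50, 4)
  y <- drop(Z %*% c(0.3, 0.1, -0.2, 0.4)) + 0.5 + rnorm(50, 0, 0.1)
  fit <- fit_meta_plsr(Z, y, J_grid = 4, seed = 1)
  expect_equal(predict(fit, Z), unname(predict(lm(y ~ Z))), tolerance = 1e-6)
})

test_that("PLSR captures a one-component structure with a single latent variable", {
  withr::local_seed(24)
  t_score <- rnorm(50)
  Z <- outer(t_score, c(1, 2, 3)) + matrix(rnorm(150, 0, 1e-4), 50, 3)
  y <- 2 * t_score
  fit <- fit_meta_plsr(Z, y, J_grid = 1, seed = 1)
  expect_lt(sqrt(mean((predict(fit, Z) - y)^2)), 1e-3)
})

test_that("PLSR handles rank-1 forecast matrices like univariate regression", {
  withr::local_seed(25)
  z <- runif(30, 0.4, 0.8)
  Z <- cbind(z, z, z)
  y <- 1.2 * z + rnorm(30, 0, 0.01)
  expect_warning(fit <- fit_meta_plsr(Z, y, J_grid = 3, seed = 1), "truncated")
  uni <- lm(y ~ z)
  expect_equal(predict(fit, Z), unname(predict(uni)), tolerance = 1e-8)
  expect_equal(fit$J, 1L)
})

test_that("PLSR training residual is non-increasing in the component count", {
  withr::local_seed(26)
  Z <- matrix(rnorm(250), 50, 5)
  y <- rnorm(50)
  res <- vapply(1:5, function(J) {
    fit <- fit_meta_plsr(Z, y, J_grid = J, seed = 1)
    sqrt(sum((predict(fit, Z) - y)^2))
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-10))
})

test_that("collinear forecasts favour LASSO/PLSR over the mean combiner", {
  # base forecasts = truth + shared bias + correlated noise; the mean
  # keeps the bias while the regression combiners calibrate it away
  withr::local_seed(27)
  reps <- 12
  err <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("mean", "lasso", "plsr")))
  for (r in seq_len(reps)) {
    y_fit <- runif(60, 0.35, 0.86)
    y_new <- runif(60, 0.35, 0.86)
    common_fit <- rnorm(60, 0, 0.02)
    common_new <- rnorm(60, 0, 0.02)
    mk <- function(y, common) {
      vapply(1:6, function(m) y + 0.04 + common + rnorm(60, 0, 0.01), numeric(60))
    }
    Z_fit <- mk(y_fit, common_fit)
    Z_new <- mk(y_new, common_new)
    fl <- fit_meta_lasso(Z_fit, y_fit, seed = r)
    fp <- fit_meta_plsr(Z_fit, y_fit, seed = r)
    err[r, ] <- c(
      rmse(y_new, combine_mean(Z_new)),
      rmse(y_new, predict(fl, Z_new)),
      rmse(y_new, predict(fp, Z_new))
    )
  }
  med <- apply(err, 2, median)
  expect_lt(med["lasso"], med["mean"])
  expect_lt(med["plsr"], med["mean"])
})

test_that("stacking with one base and mean meta reduces to that base", {
  w <- tiny_windows(5)
  st <- fit_stack(w$train, w$val,
    base = "MLP", n_base = 1, meta = "mean",
    config = fast_config(), seed = 6
  )
  expect_equal(predict(st, w$test), predict(st$bases[[1]], w$test))
})

test_that("stacking is bitwise reproducible under a fixed seed", {
  w <- tiny_windows(5)
  cfg <- fast_config(max_epochs = 15, patience = 4)
  a <- fit_stack(w$train, w$val, base = "MLP", n_base = 3, meta = "plsr", config = cfg, seed = 8)
  b <- fit_stack(w$train, w$val, base = "MLP", n_base = 3, meta = "plsr", config = cfg, seed = 8)
  expect_identical(predict(a, w$test), predict(b, w$test))
  expect_identical(a$boot_idx, b$boot_idx)
  expect_identical(coef(a$meta), coef(b$meta))
})

test_that("ensemble manifests record full provenance", {
  w <- tiny_windows(5)
  st <- fit_stack(w$train, w$val,
    base = "MLP", n_base = 2, meta = "lasso",
    config = fast_config(max_epochs = 12, patience = 4), seed = 3
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_stack_manifest(st, f)
  man <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(man$n_base, 2)
  expect_equal(man$meta_kind, "lasso")
  expect_length(man$boot_seeds, 2)
  expect_equal(unname(unlist(man$bootstrap_indices[1, ])), st$boot_idx[[1]])
  expect_true(is.numeric(man$lambda))
})
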