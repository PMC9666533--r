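# Two-stage stacking: N_B base forecasters trained on bootstrap resamples of
# the training split, and a meta-combiner (mean, median, LASSO or PLSR)
# fitted on the base forecasts of the validation split.

#' Bootstrap resample indices
#'
#' `n` draws with replacement from `1..n`, for bagging the base models.
#'
#' @param n Training-set size (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @examples
#' bootstrap_indices(10, seed = 1)
#' @export
bootstrap_indices <- function(n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive count.")
  }
  withr::with_seed(as.integer(seed), sample.int(n, n, replace = TRUE))
}

check_forecast_matrix <- function(Z) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (!is.numeric(Z) || ncol(Z) < 1L || any(!is.finite(Z))) {
    abort("forecast matrix `Z` must be numeric, with >= 1 column and no non-finite entries.")
  }
  Z
}

#' Mean and median forecast combination
#'
#' Row-wise combination of an n x M matrix of base-model forecasts: the mean
#' assigns equal weight to every base model; the median takes the middle
#' value of the sorted forecasts (mean of the two middle values when M is
#' even) and is less sensitive to outlying base models.
#'
#' @param Z Numeric matrix of base forecasts, one column per base model.
#' @return Numeric vector of combined forecasts, one per row.
#' @examples
#' Z <- cbind(c(0.4, 0.5), c(0.6, 0.7))
#' combine_mean(Z)
#' combine_median(Z)
#' @export
combine_mean <- function(Z) {
  Z <- check_forecast_matrix(Z)
  rowMeans(Z)
}

#' @rdname combine_mean
#' @export
combine_median <- function(Z) {
  Z <- check_forecast_matrix(Z)
  apply(Z, 1, median)
}

# Contiguous CV fold blocks after one seeded shuffle; recorded for
# reproducibility of the CV curves. The fold count shrinks toward
# leave-one-out when there are fewer rows than requested folds.
make_foldid <- function(n, nfolds, seed) {
  if (n < 3L) {
    abort(sprintf("need at least 3 rows for cross-validation, got %d.", n))
  }
  nfolds <- max(2L, min(as.integer(nfolds), n - 1L))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  foldid <- integer(n)
  blocks <- split(perm, cut(seq_len(n), nfolds, labels = FALSE))
  for (k in seq_along(blocks)) foldid[blocks[[k]]] <- k
  foldid
}

#' LASSO meta-model over base forecasts
#'
#' Fits the L1-penalized regression of the observed ESR values on the base
#' forecasts, with the penalty chosen by k-fold cross-validation (squared
#' error; folds are contiguous blocks after one seeded shuffle, so the CV
#' curve is reproducible). The final coefficients are refit on all rows at
#' the chosen penalty. An intercept is included via centering: ESR forecasts
#' are not centered at zero, so dropping the intercept would bias the
#' combination.
#'
#' The optimization is delegated to \pkg{glmnet}; `lambda` is therefore on
#' glmnet's scale (penalty applied to the mean, not the sum, of squared
#' errors). The grid spans 4 decades below the smallest penalty that zeroes
#' all slopes.
#'
#' @param Z Numeric n x M matrix of base forecasts.
#' @param y Observed ESR vector, length n.
#' @param lambda Optional penalty grid; default 50 log-spaced values.
#' @param nfolds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class `esr_meta` (kind "lasso") with elements
#'   `coefficients` (intercept first), `lambda` (chosen penalty), `cv`
#'   (tibble of the CV curve) and the underlying glmnet fit.
#' @examples
#' Z <- matrix(runif(200, 0.3, 0.9), 50, 4)
#' y <- rowMeans(Z) + rnorm(50, 0, 0.01)
#' fit <- fit_meta_lasso(Z, y, seed = 1)
#' coef(fit)
#' @export
fit_meta_lasso <- function(Z, y, lambda = NULL, nfolds = 5, seed = 1) {
  Z <- check_forecast_matrix(Z)
  n <- nrow(Z)
  if (length(y) != n || any(!is.finite(y))) {
    abort("`y` must be finite and aligned with the rows of `Z`.")
  }
  M <- ncol(Z)
  # glmnet needs >= 2 predictor columns; pad with an all-zero column whose
  # coefficient is identically zero when M = 1
  padded <- M == 1L
  Zg <- if (padded) cbind(Z, 0) else Z
  if (is.null(lambda)) {
    Zc <- scale(Zg, center = TRUE, scale = FALSE)
    lmax <- max(abs(crossprod(Zc, y - mean(y)))) / n
    lmax <- max(lmax, 1e-8)
    lambda <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50))
  }
  foldid <- make_foldid(n, nfolds, seed)
  cvfit <- glmnet::cv.glmnet(
    Zg, y,
    lambda = lambda, foldid = foldid,
    standardize = FALSE, thresh = 1e-9
  )
  chosen <- cvfit$lambda.min
  cf <- as.numeric(coef(cvfit$glmnet.fit, s = chosen, exact = TRUE, x = Zg, y = y))
  if (padded) cf <- cf[1:2]
  structure(
    list(
      kind = "lasso",
      coefficients = setNames(cf, c("(Intercept)", colnames(Z) %||% paste0("z", seq_len(M)))),
      lambda = chosen,
      cv = tibble::tibble(lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd),
      foldid = foldid, fit = cvfit, padded = padded, M = M
    ),
    class = "esr_meta"
  )
}

# Classical iterative PLS extraction (NIPALS) for a univariate response:
# each weight vector maximizes covariance between the X-score and y, and X
# is deflated by the extracted component. Exact and order-independent for a
# single response.
nipals_pls <- function(Zc, yc, J) {
  n <- nrow(Zc)
  M <- ncol(Zc)
  W <- matrix(0, M, J)
  P <- matrix(0, M, J)
  Tm <- matrix(0, n, J)
  q <- numeric(J)
  Xd <- Zc
  j_eff <- 0L
  for (j in seq_len(J)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # residual X carries no covariance with y
    w <- w / nw
    t_j <- drop(Xd %*% w)
    tt <- sum(t_j^2)
    if (tt < 1e-12) break
    p_j <- drop(crossprod(Xd, t_j)) / tt
    q_j <- sum(yc * t_j) / tt
    Xd <- Xd - tcrossprod(t_j, p_j)
    W[, j] <- w
    P[, j] <- p_j
    Tm[, j] <- t_j
    q[j] <- q_j
    j_eff <- j
  }
  if (j_eff == 0L) {
    return(list(beta = rep(0, M), J = 0L, W = W[, 0, drop = FALSE],
                P = P[, 0, drop = FALSE], scores = Tm[, 0, drop = FALSE], q = numeric(0)))
  }
  W <- W[, 1:j_eff, drop = FALSE]
  P <- P[, 1:j_eff, drop = FALSE]
  Tm <- Tm[, 1:j_eff, drop = FALSE]
  q <- q[1:j_eff]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  list(beta = beta, J = j_eff, W = W, P = P, scores = Tm, q = q)
}

#' Partial least squares meta-model over base forecasts
#'
#' Projects the (centered) base-forecast matrix onto `J` orthogonal latent
#' components chosen to maximize covariance with the observed ESR, then
#' regresses the response on the scores. Because the base forecasts all
#' target the same quantity they are highly collinear; PLS handles this by
#' construction. The number of components is selected by k-fold
#' cross-validation on squared error, and with all `M` components the fit
#' coincides with ordinary least squares. Components whose weight vector
#' vanishes (rank deficiency) are dropped with a warning when an explicit
#' grid requests them.
#'
#' @inheritParams fit_meta_lasso
#' @param J_grid Candidate component counts, a subset of `1..M` (default all).
#' @return An object of class `esr_meta` (kind "plsr") with `coefficients`
#'   (intercept first), chosen `J`, score/loading matrices (`scores`,
#'   `loadings`, `weights`, `q`) and the CV curve.
#' @examples
#' Z <- matrix(runif(200, 0.3, 0.9), 50, 4)
#' y <- rowMeans(Z) + rnorm(50, 0, 0.01)
#' fit <- fit_meta_plsr(Z, y, seed = 1)
#' glance(fit)
#' @export
fit_meta_plsr <- function(Z, y, J_grid = NULL, nfolds = 5, seed = 1) {
  Z <- check_forecast_matrix(Z)
  n <- nrow(Z)
  if (length(y) != n || any(!is.finite(y))) {
    abort("`y` must be finite and aligned with the rows of `Z`.")
  }
  M <- ncol(Z)
  J_grid <- J_grid %||% seq_len(M)
  if (any(J_grid < 1 | J_grid > M)) {
    abort("`J_grid` must be a subset of 1..M.")
  }
  foldid <- make_foldid(n, nfolds, seed)
  nfolds <- max(foldid)
  Jmax <- max(J_grid)
  cv_err <- matrix(NA_real_, nfolds, length(J_grid))
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    mu_z <- colMeans(Z[tr, , drop = FALSE])
    mu_y <- mean(y[tr])
    fitk <- nipals_pls(sweep(Z[tr, , drop = FALSE], 2, mu_z), y[tr] - mu_y, Jmax)
    for (jj in seq_along(J_grid)) {
      J <- min(J_grid[jj], fitk$J)
      beta_j <- if (J == 0) rep(0, M) else {
        drop(fitk$W[, 1:J, drop = FALSE] %*%
          solve(crossprod(fitk$P[, 1:J, drop = FALSE], fitk$W[, 1:J, drop = FALSE]), fitk$q[1:J]))
      }
      pred <- mu_y + drop(sweep(Z[!tr, , drop = FALSE], 2, mu_z) %*% beta_j)
      cv_err[k, jj] <- mean((y[!tr] - pred)^2)
    }
  }
  cvm <- colMeans(cv_err)
  J_star <- J_grid[which.min(cvm)]
  mu_z <- colMeans(Z)
  mu_y <- mean(y)
  fit <- nipals_pls(sweep(Z, 2, mu_z), y - mu_y, J_star)
  if (fit$J < J_star) {
    warn(sprintf("PLS component count truncated to %d (rank-deficient forecasts).", fit$J))
  }
  coefs <- c(mu_y - sum(fit$beta * mu_z), fit$beta)
  structure(
    list(
      kind = "plsr",
      coefficients = setNames(coefs, c("(Intercept)", colnames(Z) %||% paste0("z", seq_len(M)))),
      J = fit$J, weights = fit$W, loadings = fit$P, scores = fit$scores, q = fit$q,
      center = list(z = mu_z, y = mu_y),
      cv = tibble::tibble(J = J_grid, cvm = cvm),
      foldid = foldid, M = M
    ),
    class = "esr_meta"
  )
}

#' Construct a parameter-free meta-combiner
#'
#' @param kind "mean" or "median".
#' @return An `esr_meta` object.
#' @examples
#' predict(meta_combiner("median"), cbind(c(0.1, 0.2), c(0.5, 0.4), c(0.9, 0.9)))
#' @export
meta_combiner <- function(kind = c("mean", "median")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, coefficients = NULL), class = "esr_meta")
}

#' @export
predict.esr_meta <- function(object, newdata, ...) {
  Z <- check_forecast_matrix(newdata)
  switch(object$kind,
    mean = combine_mean(Z),
    median = combine_median(Z),
    lasso = ,
    plsr = {
      if (ncol(Z) != object$M) {
        abort(sprintf("meta model was fitted on %d base columns, got %d.", object$M, ncol(Z)))
      }
      cf <- object$coefficients
      drop(cf[1] + Z %*% cf[-1])
    }
  )
}

#' @export
coef.esr_meta <- function(object, ...) object$coefficients

#' @export
print.esr_meta <- function(x, ...) {
  extra <- switch(x$kind,
    lasso = sprintf(" (lambda = %.4g)", x$lambda),
    plsr = sprintf(" (J = %d components)", x$J),
    ""
  )
  cat(sprintf("<esr_meta> %s combiner%s\n", x$kind, extra))
  invisible(x)
}

#' @export
tidy.esr_meta <- function(x, ...) {
  if (is.null(x$coefficients)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.esr_meta <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    lambda = if (x$kind == "lasso") x$lambda else NA_real_,
    J = if (x$kind == "plsr") x$J else NA_integer_
  )
}

fit_meta <- function(kind, Z, y, seed) {
  switch(kind,
    mean = ,
    median = meta_combiner(kind),
    lasso = fit_meta_lasso(Z, y, seed = seed),
    plsr = fit_meta_plsr(Z, y, seed = seed),
    abort(sprintf("unknown meta kind '%s'.", kind))
  )
}

#' Fit a stacking ensemble of base forecasters
#'
#' First stage: `n_base` base models of one architecture, each trained on an
#' independent bootstrap resample of the training subjects. Second stage:
#' the meta-combiner is fitted on the base models' forecasts for the
#' *validation* subjects (fitting it on training forecasts would let
#' overfit bases dominate the combination). Prediction applies the bases and
#' then the combiner.
#'
#' @param train,val Window tibbles from [make_windows()], disjoint subjects.
#' @param base "GRU", "LSTM" or "MLP".
#' @param n_base Number of base models (N_B >= 1; 8 is the operating point
#'   used throughout).
#' @param meta "mean", "median", "lasso" or "plsr".
#' @param config A [train_config()] shared by the bases.
#' @param seed Master seed; per-base bootstrap and initialization seeds are
#'   derived from it and recorded.
#' @return An object of class `esr_stack` with the trained bases, bootstrap
#'   index sets, fitted meta model and provenance seeds.
#' @examples
#' curves <- simulate_curves(40, 0, seed = 3)
#' w <- make_windows(curves, 5)
#' st <- fit_stack(w[1:25, ], w[26:34, ],
#'   base = "MLP", n_base = 2, meta = "mean",
#'   config = train_config(max_epochs = 20, patience = 5), seed = 1
#' )
#' predict(st, w[35:40, ])
#' @export
fit_stack <- function(train, val, base = "GRU", n_base = 8,
                      meta = c("plsr", "lasso", "mean", "median"),
                      config = train_config(), seed = 1) {
  meta <- match.arg(meta)
  assert_scalar_number(n_base, "n_base", lower = 1)
  n_base <- as.integer(n_base)
  boot_seeds <- derive_seeds(seed, n_base, salt = 101L)
  init_seeds <- derive_seeds(seed, n_base, salt = 202L)
  boot_idx <- lapply(boot_seeds, function(s) bootstrap_indices(nrow(train), seed = s))
  bases <- vector("list", n_base)
  for (b in seq_len(n_base)) {
    bases[[b]] <- tryCatch(
      train_network(train[boot_idx[[b]], ], val, base, config = config, seed = init_seeds[b]),
      error = function(e) {
        abort(sprintf("base model %d failed to train: %s", b, conditionMessage(e)))
      }
    )
  }
  Z_val <- vapply(bases, predict, numeric(nrow(val)), newdata = val)
  Z_val <- matrix(Z_val, nrow = nrow(val), dimnames = list(NULL, paste0("base", seq_len(n_base))))
  meta_fit <- fit_meta(meta, Z_val, val$target, seed = derive_seeds(seed, 1, salt = 303L))
  structure(
    list(
      base_kind = base, meta_kind = meta, bases = bases, boot_idx = boot_idx,
      meta = meta_fit, L = attr(train, "L"), seed = as.integer(seed),
      boot_seeds = boot_seeds, init_seeds = init_seeds, Z_val = Z_val
    ),
    class = "esr_stack"
  )
}

# Base forecast matrix on new data.
stack_forecasts <- function(object, newdata) {
  Z <- vapply(object$bases, predict, numeric(nrow(newdata)), newdata = newdata)
  matrix(Z, nrow = nrow(newdata), dimnames = list(NULL, paste0("base", seq_along(object$bases))))
}

#' @export
predict.esr_stack <- function(object, newdata, ...) {
  predict(object$meta, stack_forecasts(object, newdata))
}

#' @export
print.esr_stack <- function(x, ...) {
  cat(sprintf(
    "<esr_stack> %d x %s bases (L = %s min) + %s meta-combiner\n",
    length(x$bases), x$base_kind, format(x$L), x$meta_kind
  ))
  invisible(x)
}

#' @export
tidy.esr_stack <- function(x, ...) tidy(x$meta)

#' @export
glance.esr_stack <- function(x, ...) {
  tibble::tibble(
    base_kind = x$base_kind, meta_kind = x$meta_kind,
    n_base = length(x$bases), L = x$L, seed = x$seed,
    lambda = if (x$meta_kind == "lasso") x$meta$lambda else NA_real_,
    J = if (x$meta_kind == "plsr") x$meta$J else NA_integer_
  )
}

#' Write an ensemble manifest as JSON
#'
#' Records full provenance of a fitted stack: seeds, bootstrap indices, the
#' meta kind and its selected tuning value, and the CV curve.
#'
#' @param object An `esr_stack`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stack_manifest <- function(object, path) {
  stopifnot(inherits(object, "esr_stack"))
  jsonlite::write_json(
    list(
      base_kind = object$base_kind, meta_kind = object$meta_kind,
      n_base = length(object$bases), L = object$L, seed = object$seed,
      boot_seeds = object$boot_seeds, init_seeds = object$init_seeds,
      bootstrap_indices = object$boot_idx,
      lambda = object$meta$lambda, J = object$meta$J,
      cv = object$meta$cv
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
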