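# Internal helpers: seed management and input validation.

# Derive `n` reproducible sub-seeds from one master seed without disturbing
# the caller's RNG state. All randomness in the package flows through this,
# so a single integer seed determines every draw (splits, weights,
# bootstraps, noise).
derive_seeds <- function(master_seed, n, salt = 0L) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed), n >= 0)
  if (n == 0L) {
    return(integer(0))
  }
  withr::with_seed(as.integer(master_seed) + as.integer(salt), {
    sample.int(2147483646L, n)
  })
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_curves <- function(curves) {
  if (!is.data.frame(curves)) {
    abort("`curves` must be a data frame (long format).")
  }
  needed <- c("sample_id", "time_min", "h_ratio")
  missing <- setdiff(needed, names(curves))
  if (length(missing)) {
    abort(paste0(
      "`curves` is missing column(s): ", paste(missing, collapse = ", "),
      ". Expected long format with sample_id, time_min, h_ratio."
    ))
  }
  invisible(curves)
}

# The fixed acquisition grid: one frame every 0.5 min for 60 min.
time_grid <- function() seq(0, 60, by = 0.5)

near_multiple_of_half <- function(x, tol = 1e-8) {
  abs(x * 2 - round(x * 2)) < tol
}
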