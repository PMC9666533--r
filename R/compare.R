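# Statistical model comparison: Friedman test with mean ranks, Nemenyi
# post-hoc critical distance, and Bland-Altman agreement analysis.

#' Friedman rank test over repeated error measurements
#'
#' Ranks the k models within each of the D repetitions (rank 1 = lowest
#' error = best, ties averaged) and tests the null that all models are
#' equivalent with the classical chi-square statistic
#' \deqn{\chi^2_F = \frac{12 D}{k(k+1)} \sum_j \left(\bar R_j -
#'   \frac{k+1}{2}\right)^2,}
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' The Iman-Davenport F-variant
#' \eqn{F = (D-1)\chi^2_F / (D(k-1) - \chi^2_F)} is available via `method`,
#' as is the exact permutation p-value (`method = "exact"`): full enumeration
#' of the \eqn{(k!)^D} within-row rank assignments, feasible for small
#' tables only, where the chi-square approximation is at its weakest.
#'
#' @param errors Numeric D x k matrix: one row per repetition (dataset), one
#'   column per model; lower is better. Column names become model labels.
#' @param method "chisq" (default), "f" for the Iman-Davenport variant, or
#'   "exact" for the enumerated permutation null (statistic reported on the
#'   chi-square scale).
#' @return A list of class `esr_friedman`: `statistic`, `p_value`,
#'   `mean_ranks` (named, length k), `ranks` (D x k), `k`, `D`, `method`.
#' @examples
#' set.seed(1)
#' e <- cbind(a = runif(10), b = runif(10) + 0.3, c = runif(10) + 0.6)
#' friedman_rank_test(e)
#' @export
friedman_rank_test <- function(errors, method = c("chisq", "f", "exact")) {
  method <- match.arg(method)
  errors <- as.matrix(errors)
  D <- nrow(errors)
  k <- ncol(errors)
  if (D < 2 || k < 2 || any(!is.finite(errors))) {
    abort("`errors` must be a finite matrix with >= 2 rows and >= 2 columns.")
  }
  ranks <- t(apply(errors, 1, rank))
  mean_ranks <- colMeans(ranks)
  names(mean_ranks) <- colnames(errors) %||% paste0("model", seq_len(k))
  chisq <- 12 * D / (k * (k + 1)) * sum((mean_ranks - (k + 1) / 2)^2)
  if (method == "chisq") {
    statistic <- chisq
    p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  } else if (method == "exact") {
    statistic <- chisq
    p <- friedman_exact_p(ranks, chisq)
  } else {
    denom <- D * (k - 1) - chisq
    statistic <- if (denom <= 0) Inf else (D - 1) * chisq / denom
    p <- pf(statistic, k - 1, (k - 1) * (D - 1), lower.tail = FALSE)
  }
  structure(
    list(
      statistic = statistic, p_value = p, mean_ranks = mean_ranks,
      ranks = ranks, k = k, D = D, method = method
    ),
    class = "esr_friedman"
  )
}

# Exact permutation null: every within-row reassignment of the observed
# (tie-averaged) rank vectors is equally likely under the null. Enumerates
# the (k!)^D product space; refuses tables where that exceeds ~2 million.
friedman_exact_p <- function(ranks, observed_chisq) {
  D <- nrow(ranks)
  k <- ncol(ranks)
  n_perm <- factorial(k)
  if (n_perm^D > 2e6) {
    abort("exact Friedman p-value needs (k!)^D <= 2e6; use method = 'chisq' or a Monte Carlo check.")
  }
  perms <- all_permutations(k)
  # per-row matrix of permuted rank vectors
  row_perms <- lapply(seq_len(D), function(d) {
    matrix(ranks[d, perms], nrow = n_perm)
  })
  idx <- as.matrix(expand.grid(rep(list(seq_len(n_perm)), D)))
  sums <- Reduce(`+`, lapply(seq_len(D), function(d) row_perms[[d]][idx[, d], , drop = FALSE]))
  stats <- 12 / (D * k * (k + 1)) * rowSums((sums - D * (k + 1) / 2)^2)
  mean(stats >= observed_chisq - 1e-9)
}

# All permutations of 1..k, built by inserting k into each position of the
# permutations of 1..(k-1).
all_permutations <- function(k) {
  if (k == 1L) {
    return(matrix(1L))
  }
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' @export
print.esr_friedman <- function(x, ...) {
  cat(sprintf(
    "<esr_friedman> %s statistic = %.4g, p = %.3g (k = %d models, D = %d repetitions)\n",
    if (x$method == "chisq") "chi-square" else "F", x$statistic, x$p_value, x$k, x$D
  ))
  invisible(x)
}

#' @export
tidy.esr_friedman <- function(x, ...) {
  tibble::tibble(model_id = names(x$mean_ranks), mean_rank = unname(x$mean_ranks))
}

#' @export
glance.esr_friedman <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, k = x$k, D = x$D,
    method = x$method
  )
}

#' Nemenyi critical distance
#'
#' The minimum difference in mean ranks for two of k models compared over D
#' repetitions to differ significantly,
#' \deqn{\mathrm{CD} = q_\alpha \sqrt{\frac{k(k+1)}{6D}},}
#' where \eqn{q_\alpha} is the upper-\eqn{\alpha} quantile of the
#' studentized range distribution (infinite degrees of freedom) divided by
#' \eqn{\sqrt{2}}. The quantile is computed exactly from the distribution
#' function rather than interpolated from a printed table.
#'
#' @param k Number of models (>= 2).
#' @param D Number of repetitions (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return Single numeric CD value.
#' @examples
#' nemenyi_cd(11, 30) # about 2.75
#' @export
nemenyi_cd <- function(k, D, alpha = 0.05) {
  assert_scalar_number(k, "k", lower = 2)
  assert_scalar_number(D, "D", lower = 1)
  assert_scalar_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  q_alpha <- qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q_alpha * sqrt(k * (k + 1) / (6 * D))
}

#' Pairwise Nemenyi significance
#'
#' Two models differ significantly when their mean ranks differ by at least
#' the critical distance.
#'
#' @param mean_ranks Named numeric vector of mean ranks.
#' @param cd Critical distance from [nemenyi_cd()].
#' @return Symmetric logical k x k matrix with a `FALSE` diagonal.
#' @examples
#' nemenyi_pairs(c(a = 1.2, b = 2.0, c = 4.5), cd = 2.75)
#' @export
nemenyi_pairs <- function(mean_ranks, cd) {
  assert_scalar_number(cd, "cd", lower = 1e-12)
  k <- length(mean_ranks)
  if (k < 2) abort("`mean_ranks` must have length >= 2.")
  diff <- abs(outer(mean_ranks, mean_ranks, "-"))
  sig <- diff >= cd
  diag(sig) <- FALSE
  dimnames(sig) <- list(names(mean_ranks), names(mean_ranks))
  sig
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between predicted and observed ESR values: the bias
#' is the mean difference (predicted minus observed) and the 95% limits of
#' agreement are bias +/- 1.96 SD of the differences (sample SD). About 95%
#' of differences should fall inside the limits when the differences are
#' roughly Gaussian.
#'
#' @param y_true Observed values (length >= 2).
#' @param y_pred Predicted values, same length.
#' @return A list of class `esr_blandaltman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, and `data` (tibble of per-sample mean and difference).
#' @examples
#' ba <- bland_altman(c(0.5, 0.6, 0.7), c(0.52, 0.58, 0.73))
#' glance(ba)
#' @export
bland_altman <- function(y_true, y_pred) {
  if (!is.numeric(y_true) || !is.numeric(y_pred) ||
    length(y_true) != length(y_pred) || length(y_true) < 2) {
    abort("`y_true` and `y_pred` must be equal-length numeric vectors, n >= 2.")
  }
  d <- y_pred - y_true
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(
      bias = bias, sd_diff = s,
      loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      data = tibble::tibble(mean = (y_pred + y_true) / 2, diff = d)
    ),
    class = "esr_blandaltman"
  )
}

#' @export
print.esr_blandaltman <- function(x, ...) {
  cat(sprintf(
    "<esr_blandaltman> bias = %.4g, 95%% limits of agreement [%.4g, %.4g] (n = %d)\n",
    x$bias, x$loa_low, x$loa_high, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.esr_blandaltman <- function(x, ...) x$data

#' @export
glance.esr_blandaltman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = nrow(x$data)
  )
}

# Maximal groups of mutually non-significant models, for the CD diagram:
# models ordered by mean rank; each group is a maximal run whose rank spread
# is below the critical distance.
nonsig_groups <- function(mean_ranks, cd) {
  ord <- order(mean_ranks)
  r <- mean_ranks[ord]
  k <- length(r)
  groups <- list()
  for (i in seq_len(k)) {
    j <- max(which(r - r[i] < cd))
    groups[[length(groups) + 1L]] <- names(r)[i:j]
  }
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && all(groups[[i]] %in% groups[[j]]) && length(groups[[i]]) < length(groups[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  unique(groups[keep])
}

#' Full statistical comparison of a repeated-evaluation table
#'
#' For each error metric: runs the Friedman test over the D x k table of
#' per-repetition errors; if significant at `alpha`, computes the Nemenyi
#' critical distance, the pairwise significance matrix, and the groups of
#' mutually non-significant models (the bars of a critical-difference
#' diagram).
#'
#' @param metrics An `esr_metrics` tibble from [repeated_eval()] (columns
#'   `model_id`, `rep`, and the metric columns).
#' @param alpha Significance level (default 0.05).
#' @param metric_cols Metric columns to analyse (default `mape` and `rmse`).
#' @return A list of class `esr_comparison`: per metric, the
#'   `esr_friedman` result, `cd`, `pairwise`, `groups` (or a note when the
#'   omnibus test is not significant); plus `alpha`, `k`, `D`.
#' @examples
#' \donttest{
#' curves <- simulate_curves(30, 0, seed = 1)
#' rec <- repeated_eval(curves, c("MLP", "GRU"),
#'   L = 5, D = 3, split = c(18, 6, 6),
#'   seed = 1, config = train_config(max_epochs = 30, patience = 5)
#' )
#' cmp <- compare_models(rec)
#' glance(cmp)
#' }
#' @export
compare_models <- function(metrics, alpha = 0.05, metric_cols = c("mape", "rmse")) {
  if (!all(c("model_id", "rep") %in% names(metrics))) {
    abort("`metrics` must have columns model_id and rep (see repeated_eval()).")
  }
  missing_cols <- setdiff(metric_cols, names(metrics))
  if (length(missing_cols)) {
    abort(paste0("metric column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  models <- unique(metrics$model_id)
  reps <- sort(unique(metrics$rep))
  k <- length(models)
  D <- length(reps)
  counts <- dplyr::count(metrics, .data$model_id)
  if (any(counts$n != D) || nrow(metrics) != k * D) {
    bad <- counts$model_id[counts$n != D]
    abort(paste0(
      "incomplete repetition table: expected ", D, " repetitions for every model; ",
      "problem models: ", paste(bad, collapse = ", ")
    ))
  }
  per_metric <- lapply(setNames(metric_cols, metric_cols), function(mc) {
    wide <- metrics |>
      dplyr::select(dplyr::all_of(c("model_id", "rep", mc))) |>
      tidyr::pivot_wider(names_from = "model_id", values_from = dplyr::all_of(mc)) |>
      dplyr::arrange(.data$rep)
    errors <- as.matrix(wide[models])
    fr <- friedman_rank_test(errors)
    if (fr$p_value < alpha) {
      cd <- nemenyi_cd(k, D, alpha)
      list(
        friedman = fr, cd = cd,
        pairwise = nemenyi_pairs(fr$mean_ranks, cd),
        groups = nonsig_groups(fr$mean_ranks, cd),
        note = NULL
      )
    } else {
      list(
        friedman = fr, cd = NA_real_, pairwise = NULL, groups = NULL,
        note = sprintf(
          "Friedman p = %.3g >= alpha = %g; post-hoc comparison skipped.",
          fr$p_value, alpha
        )
      )
    }
  })
  structure(
    c(per_metric, list(alpha = alpha, k = k, D = D)),
    class = "esr_comparison"
  )
}

comparison_metric_names <- function(x) {
  setdiff(names(x), c("alpha", "k", "D"))
}

#' @export
print.esr_comparison <- function(x, ...) {
  cat(sprintf("<esr_comparison> k = %d models, D = %d repetitions, alpha = %g\n", x$k, x$D, x$alpha))
  for (m in comparison_metric_names(x)) {
    res <- x[[m]]
    cat(sprintf(
      "  %s: Friedman p = %.3g%s\n", m, res$friedman$p_value,
      if (is.null(res$note)) sprintf(", CD = %.3f", res$cd) else paste0(" — ", res$note)
    ))
    if (is.null(res$note)) {
      best <- names(sort(res$friedman$mean_ranks))[1]
      cat(sprintf("    best mean rank: %s (%.2f)\n", best, min(res$friedman$mean_ranks)))
    }
  }
  invisible(x)
}

#' @export
tidy.esr_comparison <- function(x, ...) {
  purrr::map_dfr(comparison_metric_names(x), function(m) {
    fr <- x[[m]]$friedman
    tibble::tibble(
      metric = m,
      model_id = names(fr$mean_ranks),
      mean_rank = unname(fr$mean_ranks)
    ) |>
      dplyr::arrange(.data$mean_rank)
  })
}

#' @export
glance.esr_comparison <- function(x, ...) {
  purrr::map_dfr(comparison_metric_names(x), function(m) {
    fr <- x[[m]]$friedman
    tibble::tibble(
      metric = m, statistic = fr$statistic, p_value = fr$p_value,
      cd = x[[m]]$cd, k = x$k, D = x$D, alpha = x$alpha
    )
  })
}
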