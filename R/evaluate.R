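# Evaluation: MAPE / RMSE, the repeated-evaluation protocol (re-train D
# times under different initialization/bootstrap seeds, fixed data split),
# and the two experiment sweeps (window length, ensemble size).

#' Forecast error metrics
#'
#' Mean absolute percentage error,
#' \deqn{\mathrm{MAPE} = \frac{1}{n_s}\sum_{i=1}^{n_s}
#'   \left|\frac{y_i - \hat y_i}{y_i}\right| \times 100\,(\%),}
#' and root mean squared error,
#' \deqn{\mathrm{RMSE} = \sqrt{\frac{1}{n_s}\sum_{i=1}^{n_s} (y_i - \hat y_i)^2}.}
#' MAPE requires nonzero observed values; ESR targets are normalized heights
#' in (0, 1), so this always holds for valid data.
#'
#' @param y Observed values.
#' @param y_hat Forecasts, same length.
#' @return A single number: MAPE in percent, RMSE in the units of `y`.
#' @examples
#' mape(c(1, 2, 4), c(1.1, 1.8, 4.4)) # 10
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
mape <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  if (any(y == 0)) {
    abort("MAPE is undefined when an observed value is 0.")
  }
  mean(abs((y - y_hat) / y)) * 100
}

#' @rdname mape
#' @export
rmse <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  sqrt(mean((y - y_hat)^2))
}

check_metric_args <- function(y, y_hat) {
  if (!is.numeric(y) || !is.numeric(y_hat) || length(y) != length(y_hat) || !length(y)) {
    abort("`y` and `y_hat` must be numeric vectors of equal positive length.")
  }
  if (any(!is.finite(y)) || any(!is.finite(y_hat))) {
    abort("`y` and `y_hat` must be finite.")
  }
  invisible(TRUE)
}

# Parse model identifiers: "GRU", "LSTM", "MLP" are single networks;
# "<BASE>-<meta>" (e.g. "GRU-plsr") are stacking ensembles.
parse_model_id <- function(id) {
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  base <- toupper(parts[1])
  if (!base %in% c("MLP", "LSTM", "GRU")) {
    abort(sprintf("unknown base architecture in model id '%s'.", id))
  }
  if (length(parts) == 1L) {
    return(list(id = id, base = base, meta = NA_character_))
  }
  meta <- tolower(parts[2])
  if (length(parts) > 2L || !meta %in% c("mean", "median", "lasso", "plsr")) {
    abort(sprintf("unknown meta-combiner in model id '%s'.", id))
  }
  list(id = id, base = base, meta = meta)
}

#' The full model roster for the headline comparison
#'
#' The three individual networks plus the LSTM- and GRU-based ensembles with
#' all four meta-combiners: 11 models in total. MLP is not used as an
#' ensemble base (it is dominated by the recurrent bases as an individual
#' model already).
#'
#' @return Character vector of model ids understood by [repeated_eval()].
#' @examples
#' default_roster()
#' @export
default_roster <- function() {
  c(
    "MLP", "LSTM", "GRU",
    paste0("LSTM-", c("mean", "median", "lasso", "plsr")),
    paste0("GRU-", c("mean", "median", "lasso", "plsr"))
  )
}

#' Split a cohort into training, validation and test subjects
#'
#' One seeded shuffle of the normal-group subjects into disjoint splits.
#' Periodontitis subjects are never used for model fitting; they are
#' returned separately for out-of-cohort application.
#'
#' @param curves Long-format curve tibble.
#' @param sizes Integer vector `c(train, val, test)`; must sum to the number
#'   of normal subjects.
#' @param seed Integer seed for the shuffle.
#' @return Named list of curve tibbles: `train`, `val`, `test`, `patient`.
#' @examples
#' curves <- simulate_curves(10, 2, seed = 1)
#' sp <- split_cohort(curves, c(6, 2, 2), seed = 1)
#' @export
split_cohort <- function(curves, sizes, seed = 1) {
  assert_curves(curves)
  if (length(sizes) != 3L || any(sizes < 1)) {
    abort("`sizes` must be three positive counts c(train, val, test).")
  }
  sizes <- as.integer(sizes)
  has_group <- "group" %in% names(curves)
  normal_ids <- unique(curves$sample_id[if (has_group) curves$group == "normal" else TRUE])
  patient_ids <- if (has_group) unique(curves$sample_id[curves$group == "periodontitis"]) else character()
  if (sum(sizes) != length(normal_ids)) {
    abort(sprintf(
      "split sizes sum to %d but the cohort has %d normal subjects.",
      sum(sizes), length(normal_ids)
    ))
  }
  perm <- withr::with_seed(as.integer(seed), sample(normal_ids))
  assign_ids <- list(
    train = perm[seq_len(sizes[1])],
    val = perm[sizes[1] + seq_len(sizes[2])],
    test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
    patient = patient_ids
  )
  lapply(assign_ids, function(ids) dplyr::filter(curves, .data$sample_id %in% ids))
}

# Train/evaluate every model of a roster once (one repetition). Ensembles
# sharing a base architecture reuse the same trained bases across the four
# meta-combiners; the individual network of each architecture is trained
# once on the full (un-bootstrapped) training split.
eval_roster_once <- function(windows, models, n_base, config, rep_seed) {
  parsed <- lapply(models, parse_model_id)
  singles <- unique(vapply(Filter(function(p) is.na(p$meta), parsed), `[[`, "", "base"))
  ens_bases <- unique(vapply(Filter(function(p) !is.na(p$meta), parsed), `[[`, "", "base"))

  y_test <- windows$test$target
  pred <- list()

  for (b in singles) {
    fit <- train_network(windows$train, windows$val, b,
      config = config,
      seed = derive_seeds(rep_seed, 1, salt = match(b, c("MLP", "LSTM", "GRU")))
    )
    pred[[b]] <- predict(fit, windows$test)
  }
  for (b in ens_bases) {
    metas <- vapply(
      Filter(function(p) identical(p$base, b) && !is.na(p$meta), parsed),
      `[[`, "", "meta"
    )
    stack_seed <- derive_seeds(rep_seed, 1, salt = 10L + match(b, c("MLP", "LSTM", "GRU")))
    boot_seeds <- derive_seeds(stack_seed, n_base, salt = 101L)
    init_seeds <- derive_seeds(stack_seed, n_base, salt = 202L)
    boot_idx <- lapply(boot_seeds, function(s) bootstrap_indices(nrow(windows$train), seed = s))
    bases <- purrr::map2(boot_idx, init_seeds, function(idx, s) {
      train_network(windows$train[idx, ], windows$val, b, config = config, seed = s)
    })
    Z_val <- vapply(bases, predict, numeric(nrow(windows$val)), newdata = windows$val)
    Z_test <- vapply(bases, predict, numeric(nrow(windows$test)), newdata = windows$test)
    Z_val <- matrix(Z_val, nrow = nrow(windows$val))
    Z_test <- matrix(Z_test, nrow = nrow(windows$test))
    for (m in metas) {
      meta_fit <- fit_meta(m, Z_val, windows$val$target,
        seed = derive_seeds(stack_seed, 1, salt = 303L)
      )
      pred[[paste0(b, "-", m)]] <- predict(meta_fit, Z_test)
    }
  }

  purrr::map_dfr(models, function(id) {
    tibble::tibble(
      model_id = id,
      mape = mape(y_test, pred[[id]]),
      rmse = rmse(y_test, pred[[id]])
    )
  })
}

#' Repeated evaluation of a model roster
#'
#' Retrains and evaluates every model `D` times. The data split is fixed
#' once (derived from `seed`), and each repetition varies only the random
#' initialization of the network weights and the bootstrap resamples, via a
#' per-repetition sub-seed. The per-model mean over repetitions of MAPE and
#' RMSE is the headline performance figure; the per-repetition records feed
#' the Friedman/Nemenyi comparison.
#'
#' @param curves Long-format cohort tibble from [simulate_curves()] or
#'   [extract_curve()].
#' @param models Character vector of model ids, e.g. `"GRU"` or
#'   `"GRU-plsr"`; see [default_roster()].
#' @param L Input window length in minutes (default 15).
#' @param n_base Ensemble size N_B (default 8).
#' @param D Number of repetitions (default 30).
#' @param split Subject counts `c(train, val, test)`; must sum to the number
#'   of normal subjects (default 194/50/60 for a 304-subject cohort).
#' @param seed Master seed: drives the split and all repetition sub-seeds.
#' @param config A [train_config()].
#' @return A tibble of class `esr_metrics` with columns `model_id`, `rep`,
#'   `mape`, `rmse`, and attributes `seed`, `split_seed`, `rep_seeds`, `D`,
#'   `L`, `n_base` for provenance.
#' @examples
#' \donttest{
#' curves <- simulate_curves(30, 0, seed = 1)
#' rec <- repeated_eval(curves, c("MLP", "GRU"),
#'   L = 5, D = 2, split = c(18, 6, 6),
#'   seed = 1, config = train_config(max_epochs = 30, patience = 5)
#' )
#' }
#' @export
repeated_eval <- function(curves, models = default_roster(), L = 15, n_base = 8,
                          D = 30, split = c(194, 50, 60), seed = 1,
                          config = train_config()) {
  if (D < 2) abort("`D` must be at least 2 repetitions.")
  split_seed <- derive_seeds(seed, 1, salt = 7L)
  sp <- split_cohort(curves, split, seed = split_seed)
  windows <- list(
    train = make_windows(sp$train, L),
    val = make_windows(sp$val, L),
    test = make_windows(sp$test, L)
  )
  rep_seeds <- derive_seeds(seed, D, salt = 11L)
  out <- purrr::map_dfr(seq_len(D), function(r) {
    dplyr::mutate(
      eval_roster_once(windows, models, n_base, config, rep_seeds[r]),
      rep = r, .after = "model_id"
    )
  })
  structure(
    out,
    class = c("esr_metrics", class(out)),
    seed = as.integer(seed), split_seed = split_seed, rep_seeds = rep_seeds,
    D = as.integer(D), L = L, n_base = as.integer(n_base)
  )
}

summarise_metrics <- function(records, by) {
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "model_id")))) |>
    dplyr::summarise(
      mean_mape = mean(.data$mape), sd_mape = sd(.data$mape),
      mean_rmse = mean(.data$rmse), sd_rmse = sd(.data$rmse),
      .groups = "drop"
    )
}

#' Sweep the input window length
#'
#' Re-windows the cohort for every requested length and runs
#' [repeated_eval()] at each, aggregating MAPE/RMSE as mean and SD over the
#' repetitions. Prediction error decreases with window length for the
#' recurrent models and flattens around 15 min, which is the default
#' operating point elsewhere in the package.
#'
#' @inheritParams repeated_eval
#' @param lengths Window lengths in minutes (default 5 to 20 by 2.5).
#' @return A tibble of class `esr_sweep` (`axis = "L"`): one row per
#'   (length, model) with mean/SD of both metrics; the per-repetition
#'   records are attached as attribute `"records"`.
#' @export
sweep_sequence_length <- function(curves, models = c("MLP", "LSTM", "GRU"),
                                  lengths = seq(5, 20, by = 2.5), D = 30,
                                  split = c(194, 50, 60), seed = 1,
                                  n_base = 8, config = train_config()) {
  records <- purrr::map_dfr(lengths, function(L) {
    dplyr::mutate(
      repeated_eval(curves, models,
        L = L, n_base = n_base, D = D,
        split = split, seed = seed, config = config
      ),
      L = L, .before = 1
    )
  })
  out <- summarise_metrics(records, "L")
  structure(out,
    class = c("esr_sweep", class(out)),
    axis = "L", records = records, D = as.integer(D), seed = as.integer(seed)
  )
}

#' Sweep the ensemble size
#'
#' Runs [repeated_eval()] for stacking ensembles of one base architecture at
#' each ensemble size, for the given meta-combiners.
#'
#' @inheritParams repeated_eval
#' @param base Base architecture for the ensembles ("GRU" or "LSTM").
#' @param metas Meta-combiners to include.
#' @param sizes Ensemble sizes N_B to evaluate (default 3 to 10).
#' @return A tibble of class `esr_sweep` (`axis = "n_base"`), as in
#'   [sweep_sequence_length()].
#' @export
sweep_ensemble_size <- function(curves, base = "GRU",
                                metas = c("mean", "median", "lasso", "plsr"),
                                sizes = 3:10, L = 15, D = 30,
                                split = c(194, 50, 60), seed = 1,
                                config = train_config()) {
  models <- paste0(base, "-", metas)
  records <- purrr::map_dfr(sizes, function(nb) {
    dplyr::mutate(
      repeated_eval(curves, models,
        L = L, n_base = nb, D = D,
        split = split, seed = seed, config = config
      ),
      n_base = nb, .before = 1
    )
  })
  out <- summarise_metrics(records, "n_base")
  structure(out,
    class = c("esr_sweep", class(out)),
    axis = "n_base", records = records, D = as.integer(D), seed = as.integer(seed)
  )
}

#' @export
tidy.esr_sweep <- function(x, ...) attr(x, "records")

#' @export
glance.esr_sweep <- function(x, ...) {
  tibble::tibble(
    axis = attr(x, "axis"), D = attr(x, "D"), seed = attr(x, "seed"),
    n_cells = nrow(x)
  )
}
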