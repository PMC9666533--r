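# End-to-end workflow: configuration, staged pipeline (simulate -> extract
# -> evaluate -> compare -> report) with manifests and full seed provenance.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Defaults
#' reproduce the standard operating point of the method: a 304 + 6 subject
#' cohort, a 194/50/60 train/validation/test split, a 15-min input window,
#' GRU and LSTM ensembles of 8 bases with all four meta-combiners, 30
#' repetitions and a 0.05 significance level. Window lengths below 5 min
#' give extremely poor predictions and are rejected unless
#' `allow_short_sequence = TRUE`.
#'
#' @param n_normal,n_patient Cohort sizes for the simulation stage.
#' @param split Subject counts `c(train, val, test)` (must sum to
#'   `n_normal`).
#' @param L Input window length in minutes.
#' @param models Model roster (see [default_roster()]).
#' @param n_base Ensemble size N_B.
#' @param D Number of evaluation repetitions.
#' @param alpha Significance level for the comparison stage.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param noise_sd Measurement noise SD of the simulated curves.
#' @param render If `TRUE`, the simulate stage also renders image stacks and
#'   the extract stage re-measures the curves from them (slow; off by
#'   default, in which case the simulated curves feed the models directly).
#' @param render_subjects When rendering, how many subjects to render (the
#'   first ones; rendering all 310 stacks is rarely needed).
#' @param spec A [render_spec()] for the rendering stage.
#' @param priors Curve parameter priors (see [simulate_curves()]).
#' @param train A [train_config()].
#' @param allow_short_sequence Permit `L` < 5 min.
#' @return A list of class `esr_config`.
#' @examples
#' cfg <- pipeline_config(n_normal = 60, n_patient = 2, split = c(40, 10, 10), D = 3)
#' @export
pipeline_config <- function(n_normal = 304, n_patient = 6,
                            split = c(194, 50, 60), L = 15,
                            models = default_roster(), n_base = 8, D = 30,
                            alpha = 0.05, seed = 1, noise_sd = 0.004,
                            render = FALSE, render_subjects = 1,
                            spec = render_spec(), priors = default_curve_priors(),
                            train = train_config(),
                            allow_short_sequence = FALSE) {
  if (sum(split) != n_normal) {
    abort(sprintf(
      "split sizes (%s) must sum to n_normal = %d.",
      paste(split, collapse = "/"), n_normal
    ))
  }
  if (!near_multiple_of_half(L)) {
    abort("`L` must lie on the 0.5-min acquisition grid.")
  }
  if (L < 5 && !allow_short_sequence) {
    abort(paste0(
      "window length L = ", L, " min is below 5 min, where prediction is ",
      "extremely poor; set allow_short_sequence = TRUE to override."
    ))
  }
  lapply(models, parse_model_id) # validates the roster
  assert_scalar_number(D, "D", lower = 2)
  assert_scalar_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  structure(
    list(
      n_normal = as.integer(n_normal), n_patient = as.integer(n_patient),
      split = as.integer(split), L = L, models = models,
      n_base = as.integer(n_base), D = as.integer(D), alpha = alpha,
      seed = as.integer(seed), noise_sd = noise_sd,
      render = isTRUE(render), render_subjects = as.integer(render_subjects),
      spec = spec, priors = priors, train = train,
      allow_short_sequence = isTRUE(allow_short_sequence)
    ),
    class = "esr_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trips: `read_config(write_config(cfg, path))` reproduces
#' the configuration.
#'
#' @param config An `esr_config`.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns an `esr_config`.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_config(pipeline_config(n_normal = 60, split = c(40, 10, 10)), f)
#' cfg <- read_config(f)
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "esr_config"))
  plain <- unclass(config)
  plain$spec <- unclass(plain$spec)
  plain$train <- unclass(plain$train)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- do.call(render_spec, raw$spec[c(
    "column_height_px", "column_width_px",
    "erythrocyte_gray", "plasma_gray", "pixel_noise_sd"
  )])
  train <- do.call(train_config, raw$train[c(
    "max_epochs", "patience", "lr",
    "decay_rate", "decay_steps", "hidden", "activation"
  )])
  pipeline_config(
    n_normal = raw$n_normal, n_patient = raw$n_patient, split = raw$split,
    L = raw$L, models = raw$models, n_base = raw$n_base, D = raw$D,
    alpha = raw$alpha, seed = raw$seed, noise_sd = raw$noise_sd,
    render = raw$render, render_subjects = raw$render_subjects,
    spec = spec, priors = raw$priors, train = train,
    allow_short_sequence = raw$allow_short_sequence
  )
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Chains the stages: simulate a cohort (optionally render + re-extract some
#' subjects through the imaging pipeline), run the repeated evaluation of
#' the model roster, compare the models statistically, apply the best model
#' to the periodontitis group (Bland-Altman agreement), and write a
#' human-readable report. Every stage output is a CSV/JSON file under
#' `out_dir`; `manifest.json` records the configuration, every derived
#' seed, and the MD5 checksum of every table, so any stage can be re-run in
#' isolation and two runs with the same master seed are identical.
#'
#' @param config An [pipeline_config()] object (or a path to its YAML).
#' @param out_dir Output directory (created; must not contain a previous
#'   run's manifest unless `overwrite = TRUE`).
#' @param stages Stages to run, a subset of
#'   `c("simulate", "extract", "evaluate", "compare", "report")`; defaults
#'   to all. Later stages read the earlier stages' files from `out_dir`.
#' @param overwrite Allow writing into a directory holding a previous run.
#' @return `out_dir`, invisibly; side effect: stage files and
#'   `manifest.json` under `out_dir`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   n_normal = 24, n_patient = 2, split = c(14, 5, 5),
#'   L = 5, models = c("MLP", "GRU"), n_base = 2, D = 2,
#'   train = train_config(max_epochs = 20, patience = 5)
#' )
#' dir <- run_pipeline(cfg, tempfile())
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "extract", "evaluate", "compare", "report"),
                         overwrite = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "esr_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite && "simulate" %in% stages) {
    abort(sprintf("'%s' already holds a run; pass overwrite = TRUE to replace it.", out_dir))
  }

  paths <- list(
    curves = file.path(out_dir, "curves.csv"),
    extracted = file.path(out_dir, "extracted_curves.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    summary = file.path(out_dir, "metrics_summary.csv"),
    ranks = file.path(out_dir, "mean_ranks.csv"),
    comparison = file.path(out_dir, "comparison.json"),
    bland_altman = file.path(out_dir, "bland_altman.csv"),
    report = file.path(out_dir, "report.md")
  )
  stage_fail <- function(stage, msg) {
    abort(sprintf(
      "stage '%s' failed: %s\nRe-run with: run_pipeline(config, \"%s\", stages = \"%s\")",
      stage, msg, out_dir, stage
    ))
  }

  if ("simulate" %in% stages) {
    curves <- simulate_curves(config$n_normal, config$n_patient,
      seed = derive_seeds(config$seed, 1, salt = 1L),
      priors = config$priors, noise_sd = config$noise_sd
    )
    write_table(curves, paths$curves)
    if (config$render) {
      render_dir <- file.path(out_dir, "frames")
      ids <- head(unique(curves$sample_id), config$render_subjects)
      rseeds <- derive_seeds(config$seed, length(ids), salt = 2L)
      purrr::walk2(ids, rseeds, function(id, s) {
        fr <- render_frames(dplyr::filter(curves, .data$sample_id == id), config$spec, seed = s)
        write_frames(fr, file.path(render_dir, id))
      })
    }
  }

  if ("extract" %in% stages && config$render) {
    render_dir <- file.path(out_dir, "frames")
    if (!dir.exists(render_dir)) stage_fail("extract", "no rendered frames found; run 'simulate' with render = TRUE first")
    sub_dirs <- list.dirs(render_dir, recursive = FALSE)
    extracted <- purrr::map_dfr(sub_dirs, extract_curve)
    write_table(extracted, paths$extracted)
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(paths$curves)) stage_fail("evaluate", "curves.csv missing; run 'simulate' first")
    curves <- read_curves(paths$curves)
    metrics <- repeated_eval(curves, config$models,
      L = config$L,
      n_base = config$n_base, D = config$D, split = config$split,
      seed = derive_seeds(config$seed, 1, salt = 3L), config = config$train
    )
    write_table(metrics, paths$metrics)
    write_table(summarise_metrics(metrics, character()), paths$summary)
  }

  if ("compare" %in% stages) {
    if (!file.exists(paths$metrics)) stage_fail("compare", "metrics.csv missing; run 'evaluate' first")
    metrics <- tibble::as_tibble(utils::read.csv(paths$metrics))
    cmp <- compare_models(metrics, alpha = config$alpha)
    write_table(tidy(cmp), paths$ranks)
    jsonlite::write_json(
      list(
        glance = glance(cmp),
        groups = lapply(comparison_metric_names(cmp), function(m) cmp[[m]]$groups)
      ),
      paths$comparison,
      auto_unbox = TRUE, digits = NA, null = "null"
    )

    # out-of-cohort application: best-ranked model on the patient group
    curves <- read_curves(paths$curves)
    if (any(curves$group == "periodontitis")) {
      best <- tidy(cmp) |>
        dplyr::filter(.data$metric == "mape") |>
        dplyr::slice_min(.data$mean_rank, n = 1)
      best_id <- parse_model_id(best$model_id[1])
      sp <- split_cohort(curves, config$split,
        seed = derive_seeds(derive_seeds(config$seed, 1, salt = 3L), 1, salt = 7L)
      )
      w <- lapply(sp[c("train", "val", "patient")], make_windows,
        L = config$L,
        allow_any = config$allow_short_sequence
      )
      ba_seed <- derive_seeds(config$seed, 1, salt = 4L)
      pred <- if (is.na(best_id$meta)) {
        fit <- train_network(w$train, w$val, best_id$base, config = config$train, seed = ba_seed)
        predict(fit, w$patient)
      } else {
        st <- fit_stack(w$train, w$val,
          base = best_id$base, n_base = config$n_base,
          meta = best_id$meta, config = config$train, seed = ba_seed
        )
        predict(st, w$patient)
      }
      ba <- bland_altman(w$patient$target, pred)
      write_table(
        dplyr::bind_cols(
          tibble::tibble(
            sample_id = w$patient$sample_id, model_id = best$model_id[1],
            y_true = w$patient$target, y_pred = pred
          ),
          glance(ba)
        ),
        paths$bland_altman
      )
    }
  }

  if ("report" %in% stages) {
    pipeline_report(out_dir, config)
  }

  tables <- Filter(file.exists, unlist(paths))
  manifest <- list(
    package_version = as.character(utils::packageVersion("esrstack")),
    config = jsonlite::fromJSON(jsonlite::toJSON(
      {
        plain <- unclass(config)
        plain$spec <- unclass(plain$spec)
        plain$train <- unclass(plain$train)
        plain
      },
      auto_unbox = TRUE, digits = NA, null = "null"
    )),
    stage_seeds = list(
      simulate = derive_seeds(config$seed, 1, salt = 1L),
      evaluate = derive_seeds(config$seed, 1, salt = 3L),
      application = derive_seeds(config$seed, 1, salt = 4L)
    ),
    checksums = as.list(tools::md5sum(tables))
  )
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(out_dir)
}

#' Read curves from the CSV dialect used throughout
#'
#' @param path CSV with columns `sample_id`, `group` (optional), `time_min`,
#'   `h_ratio`.
#' @return Long-format curve tibble.
#' @export
read_curves <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_curves(df)
  if ("group" %in% names(df)) {
    df$group <- factor(df$group, levels = c("normal", "periodontitis"))
  }
  df
}

#' Render a markdown report for a completed run
#'
#' Every number in the report is read back from the stage tables under the
#' run directory; nothing is recomputed.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param config Optional `esr_config` (read from the manifest if absent).
#' @return The report path, invisibly.
#' @export
pipeline_report <- function(run_dir, config = NULL) {
  metrics_path <- file.path(run_dir, "metrics_summary.csv")
  ranks_path <- file.path(run_dir, "mean_ranks.csv")
  comparison_path <- file.path(run_dir, "comparison.json")
  for (p in c(metrics_path, ranks_path, comparison_path)) {
    if (!file.exists(p)) {
      abort(sprintf("missing stage output '%s'; run the earlier stages first.", basename(p)))
    }
  }
  summary <- utils::read.csv(metrics_path)
  ranks <- utils::read.csv(ranks_path)
  cmpj <- jsonlite::read_json(comparison_path, simplifyVector = TRUE)
  gl <- cmpj$glance

  lines <- c(
    "# ESR prediction run report",
    "",
    sprintf(
      "- Models compared: k = %d; repetitions: D = %d; alpha = %g",
      gl$k[1], gl$D[1], gl$alpha[1]
    ),
    sprintf(
      "- Friedman p (MAPE): %.3g; Friedman p (RMSE): %.3g",
      gl$p_value[gl$metric == "mape"], gl$p_value[gl$metric == "rmse"]
    ),
    sprintf("- Nemenyi critical distance: %.3f", gl$cd[gl$metric == "mape"]),
    "",
    "## Mean error over repetitions",
    "",
    "| model | mean MAPE (%) | SD | mean RMSE | SD |",
    "|---|---|---|---|---|",
    sprintf(
      "| %s | %.3f | %.3f | %.4f | %.4f |",
      summary$model_id, summary$mean_mape, summary$sd_mape,
      summary$mean_rmse, summary$sd_rmse
    ),
    "",
    "## Mean ranks (lower is better)",
    "",
    "| metric | model | mean rank |",
    "|---|---|---|",
    sprintf("| %s | %s | %.2f |", ranks$metric, ranks$model_id, ranks$mean_rank)
  )
  ba_path <- file.path(run_dir, "bland_altman.csv")
  if (file.exists(ba_path)) {
    ba <- utils::read.csv(ba_path)
    lines <- c(
      lines, "",
      "## Out-of-cohort application (periodontitis group)",
      "",
      sprintf(
        "Model %s: bias = %.4f, 95%% limits of agreement [%.4f, %.4f] (n = %d).",
        ba$model_id[1], ba$bias[1], ba$loa_low[1], ba$loa_high[1], nrow(ba)
      )
    )
  }
  report_path <- file.path(run_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
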