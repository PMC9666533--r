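# Synthetic sedimentation curves and rendered syringe image stacks.

#' Noiseless sedimentation curve model
#'
#' Normalized erythrocyte column height \eqn{H_E/H_T} as a function of time.
#' Sedimentation is modelled as a rescaled logistic decay with exact boundary
#' conditions: the column starts at the full height (\eqn{h(0) = 1}) and ends
#' at the ESR value (\eqn{h(60) = } `esr_final`). Writing \eqn{F} for the
#' logistic function with midpoint `t_mid` and steepness `rate`,
#' \deqn{h(t) = 1 - (1 - \mathrm{esr})\,\frac{F(t) - F(0)}{F(60) - F(0)}.}
#' The instantaneous sedimentation velocity \eqn{V_E = -dh/dt} then peaks at
#' `t_mid`, reproducing the three-phase behaviour of real sedimentation
#' records: a slow aggregation lag, a fast sedimentation phase, and a packing
#' plateau.
#'
#' @param t Time in minutes; all values must lie in \[0, 60\].
#' @param esr_final Normalized column height at 60 min (the ESR value), in
#'   (0, 1). Lower values mean faster sedimentation.
#' @param t_mid Sigmoid midpoint in minutes; the time of peak sedimentation
#'   velocity. Must be positive.
#' @param rate Sigmoid steepness in 1/min. Must be positive.
#'
#' @return Numeric vector of \eqn{H_E/H_T} values, same length as `t`.
#' @examples
#' sed_curve(c(0, 15, 60), esr_final = 0.5, t_mid = 15, rate = 0.3)
#' @export
sed_curve <- function(t, esr_final, t_mid, rate) {
  assert_scalar_number(esr_final, "esr_final", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(t_mid, "t_mid", lower = 1e-12)
  assert_scalar_number(rate, "rate", lower = 1e-12)
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.")
  }
  if (any(t < 0 | t > 60)) {
    abort("`t` must lie in [0, 60] minutes.")
  }
  f <- plogis(rate * (t - t_mid))
  f0 <- plogis(rate * (0 - t_mid))
  f60 <- plogis(rate * (60 - t_mid))
  1 - (1 - esr_final) * (f - f0) / (f60 - f0)
}

default_curve_priors <- function() {
  list(
    normal = list(
      esr_final = c(0.35, 0.86),
      t_mid = c(10, 20),
      rate = c(0.2, 0.4)
    ),
    periodontitis = list(
      esr_final = c(0.35, 0.55),
      t_mid = c(6, 16),
      rate = c(0.2, 0.4)
    )
  )
}

check_priors <- function(priors) {
  for (grp in c("normal", "periodontitis")) {
    p <- priors[[grp]]
    if (is.null(p)) abort(sprintf("priors must contain a `%s` entry.", grp))
    for (field in c("esr_final", "t_mid", "rate")) {
      b <- p[[field]]
      if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) || b[1] > b[2]) {
        abort(sprintf("prior `%s$%s` must be a finite increasing pair.", grp, field))
      }
    }
    if (p$esr_final[1] <= 0 || p$esr_final[2] >= 1) {
      abort(sprintf("prior `%s$esr_final` must lie strictly inside (0, 1).", grp))
    }
    if (p$t_mid[1] <= 0 || p$rate[1] <= 0) {
      abort(sprintf("prior `%s` t_mid and rate must be positive.", grp))
    }
  }
  invisible(priors)
}

#' Simulate a cohort of sedimentation curves
#'
#' Generates normalized sedimentation time series on the fixed 0.5-min
#' acquisition grid (121 points over 60 min). Each subject's noiseless curve
#' comes from [sed_curve()] with parameters drawn from uniform priors;
#' i.i.d. Gaussian measurement noise is added afterwards. Normal subjects
#' draw their final ESR value from \[0.35, 0.86\] (the range seen in
#' hematocrit-matched cohorts); the periodontitis group sediments faster:
#' lower `esr_final` and an earlier velocity peak.
#'
#' @param n_normal,n_patient Number of normal and periodontitis subjects.
#' @param seed Integer master seed; every curve gets a recorded sub-seed
#'   derived from it, so output is fully reproducible.
#' @param priors Nested list of uniform prior bounds per group, see
#'   `esrstack:::default_curve_priors()` for the structure and defaults.
#' @param noise_sd Standard deviation of additive Gaussian noise on
#'   \eqn{H_E/H_T} (dimensionless). Default 0.004.
#' @param monotone If `TRUE`, apply a cumulative-minimum projection so each
#'   noisy curve is non-increasing. Off by default; raw records are not
#'   post-processed.
#'
#' @return A tibble in long format with columns `sample_id`, `group`
#'   (factor: normal/periodontitis), `time_min`, `h_ratio`; 121 rows per
#'   subject. The generating parameters (including per-curve sub-seeds) are
#'   attached as the `"params"` attribute, a tibble with one row per subject.
#' @examples
#' curves <- simulate_curves(n_normal = 5, n_patient = 1, seed = 1)
#' dplyr::count(curves, sample_id)
#' @export
simulate_curves <- function(n_normal = 304, n_patient = 6, seed = 1,
                            priors = default_curve_priors(),
                            noise_sd = 0.004, monotone = FALSE) {
  stopifnot(n_normal >= 0, n_patient >= 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_priors(priors)

  groups <- c(rep("normal", n_normal), rep("periodontitis", n_patient))
  n <- length(groups)
  grid <- time_grid()
  if (n == 0L) {
    out <- tibble::tibble(
      sample_id = character(), group = factor(character(), levels = c("normal", "periodontitis")),
      time_min = numeric(), h_ratio = numeric()
    )
    attr(out, "params") <- tibble::tibble(
      sample_id = character(), group = character(), esr_final = numeric(),
      t_mid = numeric(), rate = numeric(), noise_sd = numeric(), sub_seed = integer()
    )
    return(out)
  }

  ids <- c(
    if (n_normal > 0) sprintf("N%04d", seq_len(n_normal)),
    if (n_patient > 0) sprintf("P%04d", seq_len(n_patient))
  )
  sub_seeds <- derive_seeds(seed, n)

  params <- purrr::map2_dfr(seq_len(n), sub_seeds, function(i, s) {
    p <- priors[[groups[i]]]
    withr::with_seed(s, {
      tibble::tibble(
        sample_id = ids[i], group = groups[i],
        esr_final = runif(1, p$esr_final[1], p$esr_final[2]),
        t_mid = runif(1, p$t_mid[1], p$t_mid[2]),
        rate = runif(1, p$rate[1], p$rate[2]),
        noise_sd = noise_sd, sub_seed = s
      )
    })
  })

  curves <- purrr::pmap_dfr(
    params[c("sample_id", "group", "esr_final", "t_mid", "rate", "sub_seed")],
    function(sample_id, group, esr_final, t_mid, rate, sub_seed) {
      h <- sed_curve(grid, esr_final, t_mid, rate)
      if (noise_sd > 0) {
        # noise drawn under the same sub-seed, after the parameter draws
        h <- h + withr::with_seed(sub_seed, {
          runif(3) # advance past the parameter draws
          rnorm(length(grid), 0, noise_sd)
        })
      }
      if (monotone) h <- cummin(h)
      tibble::tibble(
        sample_id = sample_id, group = group,
        time_min = grid, h_ratio = h
      )
    }
  )
  curves$group <- factor(curves$group, levels = c("normal", "periodontitis"))
  attr(curves, "params") <- params
  curves
}

#' Rendering specification for synthetic syringe frames
#'
#' Geometry and gray levels for rendering a sedimentation curve as a stack of
#' 8-bit grayscale frames: the settled erythrocyte column is dark, the
#' separated plasma above it bright.
#'
#' @param column_height_px,column_width_px Frame dimensions in pixels.
#' @param erythrocyte_gray,plasma_gray Gray levels (0-255) of the two phases;
#'   the erythrocyte column must be darker than the plasma.
#' @param pixel_noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units).
#' @return A list of class `render_spec`.
#' @examples
#' render_spec(column_height_px = 100)
#' @export
render_spec <- function(column_height_px = 200, column_width_px = 24,
                        erythrocyte_gray = 60, plasma_gray = 200,
                        pixel_noise_sd = 3) {
  assert_scalar_number(column_height_px, "column_height_px", lower = 2)
  assert_scalar_number(column_width_px, "column_width_px", lower = 1)
  assert_scalar_number(erythrocyte_gray, "erythrocyte_gray", lower = 0, upper = 255)
  assert_scalar_number(plasma_gray, "plasma_gray", lower = 0, upper = 255)
  assert_scalar_number(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  if (erythrocyte_gray >= plasma_gray) {
    abort("`erythrocyte_gray` must be strictly below `plasma_gray` (erythrocyte column is darker).")
  }
  structure(
    list(
      column_height_px = as.integer(column_height_px),
      column_width_px = as.integer(column_width_px),
      erythrocyte_gray = erythrocyte_gray,
      plasma_gray = plasma_gray,
      pixel_noise_sd = pixel_noise_sd
    ),
    class = "render_spec"
  )
}

render_one_frame <- function(h_ratio, spec) {
  hgt <- spec$column_height_px
  wid <- spec$column_width_px
  # top rows are plasma; the interface row index counts from the top
  n_plasma <- round((1 - h_ratio) * hgt)
  n_plasma <- max(0L, min(hgt, n_plasma))
  col <- c(rep(spec$plasma_gray, n_plasma), rep(spec$erythrocyte_gray, hgt - n_plasma))
  img <- matrix(col, nrow = hgt, ncol = wid)
  if (spec$pixel_noise_sd > 0) {
    img <- img + matrix(rnorm(hgt * wid, 0, spec$pixel_noise_sd), hgt, wid)
  }
  pmin(pmax(round(img), 0), 255)
}

#' Render a sedimentation curve as a grayscale image stack
#'
#' Produces one 8-bit grayscale frame per time point of a single subject's
#' curve: the top fraction \eqn{1 - H_E/H_T} of rows at the plasma gray
#' level, the rest at the erythrocyte gray level, plus optional pixel noise.
#' Row 1 is the top of the column (plasma side).
#'
#' @param curve Data frame with columns `time_min` and `h_ratio` for one
#'   subject (one row per frame).
#' @param spec A [render_spec()].
#' @param seed Integer seed for the pixel noise.
#' @return A list of class `frame_stack`: integer matrices (height x width,
#'   values 0-255), with attributes `times` and `sample_id`.
#' @examples
#' curve <- simulate_curves(1, 0, seed = 1, noise_sd = 0)
#' frames <- render_frames(curve, render_spec(pixel_noise_sd = 0), seed = 1)
#' length(frames)
#' @export
render_frames <- function(curve, spec = render_spec(), seed = 1) {
  assert_curves(curve)
  if (!inherits(spec, "render_spec")) {
    abort("`spec` must be created with render_spec().")
  }
  ids <- unique(curve$sample_id)
  if (length(ids) != 1L) {
    abort("`curve` must contain exactly one sample_id; got ", length(ids))
  }
  curve <- dplyr::arrange(curve, .data$time_min)
  frames <- withr::with_seed(as.integer(seed), {
    purrr::map(curve$h_ratio, render_one_frame, spec = spec)
  })
  structure(frames,
    times = curve$time_min, sample_id = ids,
    class = "frame_stack"
  )
}

#' Write / read a frame stack as PNG files
#'
#' Frames are stored one PNG per time point, named
#' `<sample_id>_t<minutes*10>.png` (zero-padded), so lexicographic order is
#' temporal order.
#'
#' @param frames A `frame_stack` from [render_frames()].
#' @param dir Directory to write to (created if needed).
#' @return `write_frames()` returns the file paths invisibly; `read_frames()`
#'   returns a `frame_stack`.
#' @examples
#' curve <- simulate_curves(1, 0, seed = 1, noise_sd = 0)
#' frames <- render_frames(curve, render_spec(pixel_noise_sd = 0))
#' d <- tempfile()
#' write_frames(frames, d)
#' stack2 <- read_frames(d)
#' @export
write_frames <- function(frames, dir) {
  stopifnot(inherits(frames, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  times <- attr(frames, "times")
  id <- attr(frames, "sample_id")
  paths <- file.path(dir, sprintf("%s_t%04d.png", id, as.integer(round(times * 10))))
  purrr::walk2(frames, paths, function(img, path) {
    png::writePNG(img / 255, target = path)
  })
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "_t\\d+\\.png$", full.names = TRUE))
  if (!length(paths)) {
    abort(sprintf("no frame PNGs found under '%s'.", dir))
  }
  base <- basename(paths)
  times <- as.numeric(sub(".*_t(\\d+)\\.png$", "\\1", base)) / 10
  id <- unique(sub("_t\\d+\\.png$", "", base))
  if (length(id) != 1L) {
    abort("frames in the directory belong to more than one sample.")
  }
  frames <- purrr::map(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  })
  structure(frames, times = times, sample_id = id, class = "frame_stack")
}
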