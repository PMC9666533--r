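# Imaging pipeline: binarize each frame, average horizontally, locate the
# erythrocyte/plasma interface by changepoint detection, and assemble the
# normalized height and sedimentation-velocity series.

#' Otsu threshold of a grayscale image
#'
#' Exhaustive Otsu threshold over the 256-bin histogram of an 8-bit image:
#' the returned threshold maximizes the between-class variance of the two
#' classes `<= threshold` and `> threshold`. Pixels above the threshold map
#' to 1 (the brighter class, plasma), others to 0.
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @return For `otsu_threshold()`, a single numeric threshold in
#'   \{0, ..., 254\}; for `otsu_binarize()`, a list with elements `binary`
#'   (0/1 matrix) and `threshold`.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' otsu_threshold(img)
#' @export
otsu_threshold <- function(image) {
  if (!is.numeric(image) || !length(image)) {
    abort("`image` must be a nonempty numeric matrix.")
  }
  v <- as.integer(pmin(pmax(round(image), 0), 255))
  if (length(unique(v)) < 2L) {
    abort("degenerate input: image has fewer than 2 distinct gray levels.")
  }
  counts <- as.numeric(tabulate(v + 1L, nbins = 256L))
  levels <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)            # pixels <= k
  m0 <- cumsum(counts * levels)   # first moment of class 0
  mu_total <- m0[256]
  # between-class variance for thresholds k = 0..254
  w0k <- w0[1:255]
  m0k <- m0[1:255]
  w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <-
    (m0k[valid] / w0k[valid] - (mu_total - m0k[valid]) / w1k[valid])^2 *
      (w0k[valid] * w1k[valid]) / (n * n)
  which.max(sigma_b) - 1L
}

#' @rdname otsu_threshold
#' @export
otsu_binarize <- function(image) {
  thr <- otsu_threshold(image)
  bin <- (image > thr) * 1
  list(binary = bin, threshold = thr)
}

#' Horizontal intensity profile
#'
#' Mean binary intensity per image row, top row first. On a binarized
#' sedimentation frame this is near 1 in the plasma region and near 0 in the
#' erythrocyte column, so the interface appears as a step.
#'
#' @param binary Numeric matrix (typically 0/1) with at least one row.
#' @return Numeric vector of row means, length `nrow(binary)`.
#' @examples
#' horizontal_profile(rbind(c(1, 1), c(0, 0)))
#' @export
horizontal_profile <- function(binary) {
  if (!is.matrix(binary) || !length(binary)) {
    abort("`binary` must be a nonempty matrix.")
  }
  rowMeans(binary)
}

#' Single least-squares changepoint of a profile
#'
#' Returns the cut position `c` (1 <= c <= length-1) that minimizes the total
#' sum of squared deviations of the two segments `x[1:c]` and
#' `x[(c+1):length]` from their own means — the standard single-changepoint,
#' squared-error criterion. `c` is the size of the first (upper) segment;
#' ties are broken toward the smallest `c`. The search is exhaustive, which
#' is exact at profile lengths used here.
#'
#' @param profile Numeric vector of length >= 2.
#' @return Integer cut position.
#' @examples
#' detect_interface(c(1, 1, 1, 0, 0)) # 3
#' @export
detect_interface <- function(profile) {
  n <- length(profile)
  if (!is.numeric(profile) || n < 2L) {
    abort("`profile` must be numeric with at least 2 elements.")
  }
  # SSE(segment) = sum(x^2) - sum(x)^2 / n, via cumulative sums
  cs <- cumsum(profile)
  cs2 <- cumsum(profile^2)
  c_cand <- 1:(n - 1)
  sse_left <- cs2[c_cand] - cs[c_cand]^2 / c_cand
  sum_r <- cs[n] - cs[c_cand]
  sum2_r <- cs2[n] - cs2[c_cand]
  sse_right <- sum2_r - sum_r^2 / (n - c_cand)
  which.min(sse_left + sse_right) # which.min takes the first minimum
}

# Per-frame interface measurement. The stack-level pooled threshold is the
# fallback for frames whose own histogram is effectively unimodal (e.g. the
# t = 0 frame, which is all erythrocyte plus noise): for those, Otsu would
# split the noise in half and the changepoint would be meaningless.
measure_frame <- function(img, pooled_threshold) {
  hgt <- nrow(img)
  res <- tryCatch(otsu_binarize(img), error = function(e) NULL)
  degenerate <- TRUE
  if (!is.null(res)) {
    v <- as.vector(img)
    cls <- v > res$threshold
    mu0 <- mean(v[!cls])
    mu1 <- mean(v[cls])
    s0 <- stats::var(v[!cls])
    s1 <- stats::var(v[cls])
    w1 <- mean(cls)
    s_within <- sqrt((1 - w1) * (if (is.na(s0)) 0 else s0) + w1 * (if (is.na(s1)) 0 else s1))
    # require the class means to be well separated relative to the pooled
    # within-class spread; otherwise treat the frame as single-phase
    degenerate <- is.na(mu0) || is.na(mu1) || (mu1 - mu0) < 4 * s_within
  }
  if (degenerate) {
    thr <- pooled_threshold
    frac_plasma <- mean(img > thr)
    cut <- max(0L, min(hgt, round(frac_plasma * hgt)))
    return(list(
      h_ratio = 1 - cut / hgt, threshold = thr, changepoint = cut,
      degenerate = TRUE
    ))
  }
  prof <- horizontal_profile(res$binary)
  cut <- detect_interface(prof)
  # polarity check: plasma (binary 1) is expected to be the upper segment;
  # the interface geometry (row 1 = top = plasma side) is unaffected, so a
  # reversed polarity only triggers a warning
  if (mean(prof[1:cut]) < mean(prof[(cut + 1):hgt])) {
    warn("binarization polarity reversed: upper segment darker than lower.")
  }
  list(h_ratio = 1 - cut / hgt, threshold = res$threshold, changepoint = cut, degenerate = FALSE)
}

#' Extract a sedimentation curve from an image stack
#'
#' Applies the frame-level measurement (Otsu binarization, horizontal
#' averaging, least-squares changepoint) to every frame of a stack and
#' assembles the normalized height series \eqn{H_E/H_T(t)}. Row 1 of each
#' frame is the top of the column, so `h_ratio = 1 - c / n_rows` where `c`
#' is the detected cut.
#'
#' Frames whose histogram is effectively single-phase (e.g. the first frame,
#' all erythrocyte) are classified against a threshold pooled over the whole
#' stack instead of their own Otsu threshold; a stack that is constant
#' everywhere falls back to the mid-gray level 127.5.
#'
#' @param frames A `frame_stack` (see [render_frames()] / [read_frames()]) or
#'   a directory containing frame PNGs, or a plain list of matrices.
#' @param times Time in minutes per frame; defaults to the stack's `times`
#'   attribute.
#' @param audit_json Optional path; if given, per-frame thresholds and
#'   changepoint indices are written there as JSON.
#' @return A tibble with columns `sample_id`, `time_min`, `h_ratio`, plus an
#'   `"audit"` attribute (tibble of per-frame threshold, changepoint and
#'   degenerate flag).
#' @examples
#' curve <- simulate_curves(1, 0, seed = 2, noise_sd = 0)
#' frames <- render_frames(curve, render_spec(pixel_noise_sd = 0))
#' rec <- extract_curve(frames)
#' max(abs(rec$h_ratio - curve$h_ratio))
#' @export
extract_curve <- function(frames, times = NULL, audit_json = NULL) {
  if (is.character(frames) && length(frames) == 1L) {
    frames <- read_frames(frames)
  }
  if (!length(frames)) {
    abort("empty frame stack.")
  }
  times <- times %||% attr(frames, "times")
  id <- attr(frames, "sample_id") %||% "sample"
  if (is.null(times)) {
    abort("`times` must be supplied when the stack carries no times attribute.")
  }
  if (length(times) != length(frames)) {
    abort("need exactly one frame per time point.")
  }
  pooled <- tryCatch(
    otsu_threshold(matrix(unlist(lapply(frames, as.vector)), ncol = 1)),
    error = function(e) 127.5
  )
  rows <- purrr::imap(frames, function(img, i) {
    tryCatch(measure_frame(img, pooled), error = function(e) {
      abort(sprintf("frame %d: %s", i, conditionMessage(e)))
    })
  })
  out <- tibble::tibble(
    sample_id = id,
    time_min = as.numeric(times),
    h_ratio = purrr::map_dbl(rows, "h_ratio")
  )
  audit <- tibble::tibble(
    time_min = as.numeric(times),
    threshold = purrr::map_dbl(rows, "threshold"),
    changepoint = purrr::map_int(rows, ~ as.integer(.x$changepoint)),
    degenerate = purrr::map_lgl(rows, "degenerate")
  )
  attr(out, "audit") <- audit
  if (!is.null(audit_json)) {
    jsonlite::write_json(audit, audit_json, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Instantaneous sedimentation velocity
#'
#' Computes \eqn{V_E = -dH_E/dt} per subject by finite differences: central
#' differences on interior points, one-sided at the ends. Sedimentation
#' (decreasing column height) gives positive velocity. If `total_height_mm`
#' is supplied the result is scaled to mm/min; otherwise the unit is
#' normalized height per minute.
#'
#' @param curves Long-format curve tibble (`sample_id`, `time_min`,
#'   `h_ratio`) on a uniform time grid, at least 3 points per subject.
#' @param total_height_mm Optional total column height in mm (e.g. 53).
#' @return Tibble with columns `sample_id`, `time_min`, `v_e`.
#' @examples
#' curves <- simulate_curves(2, 0, seed = 1, noise_sd = 0)
#' vel <- sediment_velocity(curves)
#' @export
sediment_velocity <- function(curves, total_height_mm = NULL) {
  assert_curves(curves)
  if (!is.null(total_height_mm)) {
    assert_scalar_number(total_height_mm, "total_height_mm", lower = 1e-9)
  }
  scale <- total_height_mm %||% 1
  curves |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3L) {
        abort(sprintf("sample '%s': need at least 3 points for velocity.", key$sample_id))
      }
      t <- df$time_min
      h <- df$h_ratio
      step <- diff(t)
      if (max(abs(step - step[1])) > 1e-8) {
        abort(sprintf("sample '%s': time grid is not uniform.", key$sample_id))
      }
      dh <- numeric(n)
      dh[1] <- (h[2] - h[1]) / step[1]
      dh[n] <- (h[n] - h[n - 1]) / step[1]
      dh[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / (2 * step[1])
      tibble::tibble(time_min = t, v_e = -dh * scale)
    }) |>
    dplyr::ungroup()
}
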