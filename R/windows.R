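# Truncated input windows: the forecasting task maps the first L minutes of
# a curve to its 60-min value.

#' Build forecasting windows from sedimentation curves
#'
#' For each subject, the model input is the sequence of \eqn{H_E/H_T} values
#' at 0, 0.5, ..., L minutes (2L + 1 points) and the target is the value at
#' 60 min (the ESR). Window lengths are restricted by default to the
#' 5-to-20-min range in 2.5-min steps; shorter windows carry too little of
#' the sedimentation phase to predict well, and values outside the grid need
#' `allow_any = TRUE`.
#'
#' @param curves Long-format curve tibble on the 0.5-min grid, reaching
#'   60 min.
#' @param L Window length in minutes.
#' @param allow_any Allow window lengths outside \{5, 7.5, ..., 20\}.
#' @return A tibble with one row per subject: `sample_id`, `group` (if
#'   present), `target`, and a list-column `window` of numeric input
#'   vectors; window length is attached as attribute `"L"`.
#' @examples
#' curves <- simulate_curves(3, 0, seed = 1)
#' w <- make_windows(curves, L = 15)
#' lengths(w$window) # all 31
#' @export
make_windows <- function(curves, L = 15, allow_any = FALSE) {
  assert_curves(curves)
  assert_scalar_number(L, "L", lower = 0.5, upper = 60)
  if (!near_multiple_of_half(L)) {
    abort("`L` must be a multiple of 0.5 min (the acquisition grid).")
  }
  default_grid <- seq(5, 20, by = 2.5)
  if (!allow_any && !any(abs(default_grid - L) < 1e-9)) {
    abort(paste0(
      "`L` = ", L, " is outside the supported window grid {5, 7.5, ..., 20}; ",
      "pass allow_any = TRUE to override."
    ))
  }
  has_group <- "group" %in% names(curves)
  out <- curves |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      in_win <- df$time_min <= L + 1e-9
      at60 <- abs(df$time_min - 60) < 1e-9
      if (!any(at60)) {
        abort(sprintf("sample '%s': no observation at 60 min.", key$sample_id))
      }
      expected <- as.integer(2 * L) + 1L
      if (sum(in_win) != expected) {
        abort(sprintf(
          "sample '%s': expected %d points in [0, %s] min, found %d.",
          key$sample_id, expected, L, sum(in_win)
        ))
      }
      tibble::tibble(
        group = if (has_group) df$group[1] else factor(NA),
        target = df$h_ratio[at60][1],
        window = list(df$h_ratio[in_win])
      )
    }) |>
    dplyr::ungroup()
  if (!has_group) out$group <- NULL
  attr(out, "L") <- L
  out
}

# Stack windows into an n x (2L+1) matrix for the trainers.
window_matrix <- function(windows) {
  stopifnot(is.data.frame(windows), "window" %in% names(windows))
  do.call(rbind, windows$window)
}
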