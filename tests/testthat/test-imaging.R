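test_that("Otsu threshold separates a two-level image and rejects constants", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_binarize(img)
  expect_gt(res$threshold, 9)
  expect_lt(res$threshold, 200)
  expect_equal(mean(res$binary), 0.5)
  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("Otsu threshold equals the exhaustive between-class-variance scan", {
  withr::local_seed(101)
  for (i in 1:60) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(otsu_threshold(img), otsu_scan_oracle(img))
  }
})

test_that("horizontal profile is the row-wise mean", {
  expect_equal(horizontal_profile(rbind(c(1, 1), c(0, 0))), c(1, 0))
  expect_equal(horizontal_profile(matrix(1, 5, 3)), rep(1, 5))
  withr::local_seed(7)
  b <- matrix(sample(0:1, 60, replace = TRUE), 10, 6)
  expect_equal(horizontal_profile(b), apply(b, 1, sum) / ncol(b))
})

test_that("changepoint detection matches the exhaustive least-squares scan", {
  expect_identical(detect_interface(c(1, 1, 1, 0, 0)), 3L)
  expect_identical(detect_interface(c(1, 1, 1, 1, 0.9, 0.1, 0, 0)),
                   changepoint_scan_oracle(c(1, 1, 1, 1, 0.9, 0.1, 0, 0)))
  # ties resolve to the smallest cut
  expect_identical(detect_interface(c(0.5, 0.5, 0.5, 0.5)), 1L)
  expect_error(detect_interface(1), "at least 2")
  withr::local_seed(31)
  for (i in 1:40) {
    n <- sample(2:120, 1)
    x <- rnorm(n) + c(rep(0, floor(n / 2)), rep(sample(c(0, 2), 1), ceiling(n / 2)))
    expect_identical(detect_interface(x), as.integer(changepoint_scan_oracle(x)))
  }
})

test_that("extraction recovers a rendered curve to pixel accuracy", {
  curve <- simulate_curves(1, 0, seed = 9, noise_sd = 0)
  spec <- render_spec(column_height_px = 120, column_width_px = 10, pixel_noise_sd = 0)
  frames <- render_frames(curve, spec, seed = 1)
  rec <- extract_curve(frames)
  expect_equal(rec$time_min, curve$time_min)
  expect_true(all(abs(rec$h_ratio - curve$h_ratio) <= 1 / spec$column_height_px))
  audit <- attr(rec, "audit")
  expect_true(audit$degenerate[1]) # t = 0 frame is all erythrocyte
  expect_equal(rec$h_ratio[1], 1)
})

test_that("degenerate and malformed stacks are handled explicitly", {
  dark <- matrix(60, 50, 4)
  rec <- extract_curve(structure(list(dark), class = "frame_stack"), times = 0)
  expect_equal(rec$h_ratio, 1)
  light <- matrix(220, 50, 4)
  rec2 <- extract_curve(structure(list(light), class = "frame_stack"), times = 0)
  expect_equal(rec2$h_ratio, 0)
  expect_error(extract_curve(list(), times = numeric()), "empty")
  expect_error(
    extract_curve(structure(list(dark), class = "frame_stack"), times = c(0, 1)),
    "one frame per time"
  )
})

test_that("inverted-polarity frames are flipped with a warning", {
  # erythrocyte phase rendered brighter than plasma: binary 1 lands on the
  # bottom segment and the polarity check must flip the ratio back
  img <- rbind(matrix(50, 30, 6), matrix(210, 70, 6))
  img <- img + matrix(rnorm(600, 0, 2), 100, 6)
  stack <- structure(list(pmin(pmax(round(img), 0), 255)), class = "frame_stack")
  expect_warning(rec <- extract_curve(stack, times = 10), "polarity")
  expect_equal(rec$h_ratio, 0.7, tolerance = 0.02)
})

test_that("audit sidecar JSON is written on request", {
  curve <- simulate_curves(1, 0, seed = 9)
  frames <- render_frames(curve, render_spec(column_height_px = 40, column_width_px = 4), seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  extract_curve(frames, audit_json = f)
  audit <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(audit), 121)
  expect_true(all(c("threshold", "changepoint", "degenerate") %in% names(audit)))
})

test_that("velocity reproduces linear, constant and smooth rates", {
  grid <- seq(0, 60, 0.5)
  lin <- tibble::tibble(sample_id = "a", time_min = grid, h_ratio = 1 - 0.01 * grid)
  v <- sediment_velocity(lin)
  expect_equal(v$v_e, rep(0.01, 121))
  const <- tibble::tibble(sample_id = "a", time_min = grid, h_ratio = rep(0.8, 121))
  expect_equal(sediment_velocity(const)$v_e, rep(0, 121))
  # central differences are second-order accurate on smooth curves
  smooth <- tibble::tibble(sample_id = "a", time_min = grid, h_ratio = cos(grid / 10))
  v3 <- sediment_velocity(smooth)
  true_rate <- sin(grid / 10) / 10
  interior <- 2:120
  expect_lt(max(abs(v3$v_e[interior] - true_rate[interior])), 1e-3)
  # mm/min scaling
  v_mm <- sediment_velocity(lin, total_height_mm = 53)
  expect_equal(v_mm$v_e, rep(0.53, 121))
  expect_error(sediment_velocity(lin[1:2, ]), "at least 3")
})

test_that("round-trip error grows with pixel noise but stays bounded", {
  curve <- simulate_curves(1, 0, seed = 14, noise_sd = 0)
  errs <- vapply(c(0, 10, 40), function(ns) {
    spec <- render_spec(column_height_px = 100, column_width_px = 8, pixel_noise_sd = ns)
    rec <- extract_curve(render_frames(curve, spec, seed = 3))
    mean(abs(rec$h_ratio - curve$h_ratio))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
  expect_lt(errs[1], 0.01)
})
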