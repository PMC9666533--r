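test_that("Friedman ranks and statistic follow the classical definitions", {
  # identical models: all ranks tie at (k+1)/2, statistic 0
  e0 <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  f0 <- friedman_rank_test(e0)
  expect_equal(f0$statistic, 0)
  expect_equal(unname(f0$mean_ranks), rep(2, 3))

  # strict dominance: hand-computed statistic 12D/(k(k+1)) * sum((R-2)^2) = 8
  e1 <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), 4, 3)
  f1 <- friedman_rank_test(e1)
  expect_equal(unname(f1$mean_ranks), c(1, 2, 3))
  expect_equal(f1$statistic, 8)
  expect_equal(f1$p_value, pchisq(8, 2, lower.tail = FALSE))

  # rank rows always sum to k(k+1)/2, ties included
  withr::local_seed(50)
  for (i in 1:20) {
    e <- matrix(sample(1:4, 15, replace = TRUE), 5, 3)
    fr <- friedman_rank_test(e)
    expect_equal(unname(rowSums(fr$ranks)), rep(6, 5))
  }
})

test_that("Friedman p-values agree with the reference implementation", {
  withr::local_seed(51)
  for (i in 1:10) {
    e <- matrix(rnorm(8 * 5), 8, 5)
    mine <- friedman_rank_test(e)
    ref <- stats::friedman.test(e)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("the exact permutation p-value enumerates the rank null", {
  # strict dominance at k = 3, D = 4: only the 6 constant column relabelings
  # of 1296 equally likely tables reach the maximal statistic 8
  e1 <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3), 4, 3)
  fe <- friedman_rank_test(e1, method = "exact")
  expect_equal(fe$statistic, 8)
  expect_equal(fe$p_value, 6 / 1296)
  # a constant table is the fully tied null: p = 1
  tied <- matrix(1, 4, 3)
  expect_equal(friedman_rank_test(tied, method = "exact")$p_value, 1)
  expect_error(friedman_rank_test(matrix(rnorm(200), 20, 10), method = "exact"), "2e6")
})

test_that("the Iman-Davenport variant transforms the chi-square statistic", {
  withr::local_seed(52)
  e <- matrix(rnorm(40), 10, 4)
  chi <- friedman_rank_test(e, method = "chisq")
  f <- friedman_rank_test(e, method = "f")
  k <- 4
  D <- 10
  expect_equal(f$statistic, (D - 1) * chi$statistic / (D * (k - 1) - chi$statistic))
  expect_equal(f$p_value, pf(f$statistic, k - 1, (k - 1) * (D - 1), lower.tail = FALSE))
})

test_that("the critical distance follows the studentized-range closed form", {
  # k = 2: q_alpha/sqrt(2) is the normal quantile 1.95996
  expect_equal(nemenyi_cd(2, 25), qnorm(0.975) * sqrt(2 * 3 / (6 * 25)), tolerance = 1e-6)
  expect_equal(nemenyi_cd(2, 25), 0.392, tolerance = 1e-3)
  # quadrupling D halves the CD exactly
  expect_equal(nemenyi_cd(7, 120), nemenyi_cd(7, 30) / 2)
  # monotone in k, decreasing in D
  cds_k <- vapply(2:12, nemenyi_cd, numeric(1), D = 30)
  expect_true(all(diff(cds_k) > 0))
  cds_d <- vapply(c(10, 20, 40, 80), function(D) nemenyi_cd(5, D), numeric(1))
  expect_true(all(diff(cds_d) < 0))
  expect_error(nemenyi_cd(1, 30), "k")
})

test_that("pairwise significance compares mean-rank gaps to the CD", {
  expect_false(any(nemenyi_pairs(c(a = 2, b = 2, c = 2), cd = 2.75)))
  m <- nemenyi_pairs(c(a = 1, b = 4), cd = 2.75)
  expect_true(m["a", "b"])
  expect_false(any(nemenyi_pairs(c(a = 1, b = 3), cd = 2.75)))
  m2 <- nemenyi_pairs(c(a = 1, b = 2.5, c = 5), cd = 2)
  expect_true(isSymmetric(m2))
  expect_false(any(diag(m2)))
})

test_that("Bland-Altman bias and limits follow the definitions", {
  ba0 <- bland_altman(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba1 <- bland_altman(c(0.5, 0.5), c(0.6, 0.4))
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, sqrt(0.02), tolerance = 1e-12) # sd of (+0.1, -0.1)
  expect_equal(ba1$loa_high, 1.96 * sqrt(0.02), tolerance = 1e-12)

  y <- runif(20)
  bac <- bland_altman(y, y + 0.05)
  expect_equal(bac$bias, 0.05)
  expect_equal(bac$loa_low, bac$loa_high)
  expect_equal(bac$data$diff, rep(0.05, 20))
  expect_equal(bac$data$mean, y + 0.025)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("the full comparison gates the post-hoc test on the omnibus p-value", {
  # one model strictly dominant over 6 repetitions of 3 models
  metrics <- tibble::tibble(
    model_id = rep(c("A", "B", "C"), each = 6),
    rep = rep(1:6, 3),
    mape = c(1:6 / 10, 1:6 / 10 + 1, 1:6 / 10 + 2),
    rmse = c(1:6 / 10, 1:6 / 10 + 1, 1:6 / 10 + 2)
  )
  cmp <- compare_models(metrics)
  expect_equal(cmp$k, 3)
  expect_equal(cmp$D, 6)
  expect_equal(unname(cmp$mape$friedman$mean_ranks["A"]), 1)
  expect_equal(tidy(cmp)$model_id[1], "A")
  expect_equal(cmp$mape$cd, nemenyi_cd(3, 6))
  expect_true("A" %in% cmp$mape$groups[[1]])

  # tied models: omnibus not significant, post-hoc skipped with a note
  flat <- tibble::tibble(
    model_id = rep(c("A", "B"), each = 4), rep = rep(1:4, 2),
    mape = c(1, 2, 3, 4, 2, 1, 4, 3), rmse = c(1, 2, 3, 4, 2, 1, 4, 3)
  )
  cf <- compare_models(flat)
  expect_match(cf$mape$note, "skipped")
  expect_true(is.na(cf$mape$cd))

  # incomplete tables are rejected with the offending model named
  expect_error(compare_models(metrics[-1, ]), "incomplete.*A")
})

test_that("comparison summaries are tidy and plottable", {
  metrics <- tibble::tibble(
    model_id = rep(c("A", "B", "C"), each = 10),
    rep = rep(1:10, 3),
    mape = runif(30, 1, 2) + rep(c(0, 1, 2), each = 10),
    rmse = runif(30, 0.01, 0.02) + rep(c(0, 0.01, 0.02), each = 10)
  )
  cmp <- compare_models(metrics)
  gl <- glance(cmp)
  expect_equal(gl$metric, c("mape", "rmse"))
  expect_true(all(gl$k == 3))
  expect_s3_class(autoplot(cmp), "ggplot")
  ba <- bland_altman(runif(10), runif(10))
  expect_s3_class(autoplot(ba), "ggplot")
})
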