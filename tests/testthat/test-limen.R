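test_that("crossing of an exactly linear decline is its midpoint", {
  fc <- fit_crossing(c(0, 25, 50, 75, 100), c(1, 0.75, 0.5, 0.25, 0),
                     threshold = 0.5)
  expect_equal(fc$o_star, 50)
  expect_false(fc$clamped)
  expect_equal(fc$slope, -0.01)
})

test_that("crossing matches the closed-form OLS solution on noisy points", {
  set.seed(6)
  x <- c(0, 20, 40, 60, 80, 97)
  y <- pmin(1, pmax(0, 1 - x / 90 + rnorm(6, 0, 0.05)))
  fc <- fit_crossing(x, y, threshold = 0.5)
  o <- ols_oracle(x, y)
  expect_equal(fc$slope, o$slope, tolerance = 1e-10)
  expect_equal(fc$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fc$o_star, (0.5 - o$intercept) / o$slope, tolerance = 1e-10)
})

test_that("degenerate inputs clamp to the framework extremes", {
  # everything discriminable: no crossing, d = 0, z = all mixtures
  fc <- fit_crossing(c(0, 50, 100), c(1, 1, 1), threshold = 0.5)
  expect_true(fc$clamped)
  expect_equal(fc$o_star, 100)
  # nothing discriminable: d = N, z at its smallest
  fc <- fit_crossing(c(0, 50, 100), c(0, 0, 0), threshold = 0.5)
  expect_true(fc$clamped)
  expect_equal(fc$o_star, 0)
  expect_error(fit_crossing(c(50, 50), c(1, 0), 0.5))
})

test_that("limen estimates keep the d / o_star coordinate identity", {
  smry <- tibble::tibble(
    N = 30, percent_overlap = c(0, 20, 40, 60, 80, 96.7),
    fraction_significant = c(1, 1, 0.9, 0.3, 0.05, 0),
    n_units = 20
  )
  est <- estimate_limen_significance(smry)
  expect_equal(est$d + est$N * est$o_star / 100, est$N, tolerance = 1e-12)
  b <- limen_bounds(est, C = 128)
  expect_true(b$log10_z_upper >= b$log10_z_lower)
  # all-significant summaries give the whole space
  smry$fraction_significant <- 1
  est <- estimate_limen_significance(smry)
  expect_equal(est$d, 0)
  expect_identical(limen_bounds(est, 128)$z_upper_exact,
                   as.character(binomial_exact(128, 30)))
  # none-significant summaries give the worst case
  smry$fraction_significant <- 0
  est <- estimate_limen_significance(smry)
  expect_equal(est$d, 30)
  expect_identical(limen_bounds(est, 128)$z_upper_exact, "4561")
})

test_that("fraction-threshold limen handles boundary thetas", {
  set.seed(7)
  tt <- generate_trials(design_n30(),
                        psychometric_params(subject_sd = 0), seed = 8)
  rec <- summarize_trials(tt, "pair")
  expect_error(estimate_limen_fraction(rec, theta = 1/3))
  # theta just above chance: nearly everything counts as discriminable
  # (the fitted line reaches chance slightly before 100% overlap)
  lo <- estimate_limen_fraction(rec, theta = 0.3335)
  expect_gt(lo$o_star, 85)
  expect_lt(lo$d, 4.5)
  # theta = 1 with imperfect data: nothing reaches perfection
  hi <- estimate_limen_fraction(rec, theta = 1)
  expect_lt(hi$o_star, 5)
  expect_gt(hi$d, 28.5)
})

test_that("d(theta) is monotone non-decreasing for logistic data", {
  tt <- generate_trials(design_n30(pairs_per_class = 40),
                        psychometric_params(subject_sd = 0), seed = 9)
  rec <- summarize_trials(tt, "pair")
  thetas <- seq(0.35, 1, by = 0.05)
  ds <- vapply(thetas, function(th) estimate_limen_fraction(rec, th)$d,
               numeric(1))
  expect_true(all(diff(ds) >= -1e-9))
})

test_that("per-subject limens agree with the pooled fit for clones", {
  # deterministic table: every subject answers identically
  ov <- c(0, 6, 12, 18, 24, 29)
  correct_by_class <- c(1, 1, 1, 0, 0, 0)
  tt <- tidyr::expand_grid(subject = 1:4, O = ov, t = 1:6) |>
    dplyr::mutate(subject_id = paste0("s", subject), N = 30,
                  pair_id = sprintf("O%02d_p%d", O, t),
                  correct = rep(rep(correct_by_class, each = 6), 4)) |>
    dplyr::select("subject_id", "N", "O", "pair_id", "correct")
  per <- per_subject_limens(tt, method = "fraction", threshold = 0.5)
  pooled <- estimate_limen_fraction(summarize_trials(tt, "subject"), 0.5)
  expect_equal(nrow(per), 4)
  expect_true(all(abs(per$o_star - pooled$o_star) < 1e-9))
})

test_that("a chance-level subject lands at the worst-case limen", {
  ov <- c(0, 10, 20, 29)
  tt <- tidyr::expand_grid(O = ov, t = 1:10) |>
    dplyr::mutate(subject_id = "s1", N = 30,
                  pair_id = sprintf("O%02d_p%d", O, t), correct = 0)
  per <- per_subject_limens(tt, method = "significance", alpha = 0.05)
  expect_equal(per$d, 30)
  expect_equal(per$log10_z_upper,
               packing_bounds(stimulus_space(128, 30), 30)$log10_z_upper)
})

test_that("per-subject medians separate for heterogeneous groups", {
  ov <- list(`30` = c(0, 6, 12, 18, 24, 29))
  hard <- generate_trials(
    experiment_design(N = 30, overlaps = ov, subjects = 6),
    psychometric_params(midpoint = 35, slope = 6, subject_sd = 0),
    seed = 10
  )
  easy <- generate_trials(
    experiment_design(N = 30, overlaps = ov, subjects = 6),
    psychometric_params(midpoint = 65, slope = 6, subject_sd = 0),
    seed = 11
  )
  easy$subject_id <- sub("^s", "e", easy$subject_id)
  both <- dplyr::bind_rows(hard, easy)
  per <- per_subject_limens(both, method = "fraction", threshold = 0.55)
  med_hard <- stats::median(per$o_star[grepl("^s", per$subject_id)])
  med_easy <- stats::median(per$o_star[grepl("^e", per$subject_id)])
  expect_lt(med_hard, med_easy)
})

test_that("subjects with a single overlap level are skipped with a warning", {
  tt <- tibble::tibble(
    subject_id = c(rep("s1", 4), rep("s2", 2)),
    N = 30, O = c(0, 0, 12, 12, 6, 6),
    pair_id = c("a", "b", "c", "d", "e", "f"),
    correct = c(1, 1, 0, 1, 1, 0)
  )
  expect_warning(per <- per_subject_limens(tt, method = "fraction",
                                           threshold = 0.5),
                 "s2")
  expect_equal(per$subject_id, "s1")
})
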