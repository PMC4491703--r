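make_table <- function(seed = 23, pairs_per_class = 20, subjects = 26,
                       params = psychometric_params(p_max = 0.9,
                                                    midpoint = 50,
                                                    slope = 12,
                                                    subject_sd = 4)) {
  generate_trials(design_n30(pairs_per_class, subjects), params,
                  seed = seed)
}

test_that("deterministic extrapolation at the observed size is the identity", {
  tt <- make_table()
  rec <- summarize_trials(tt, "pair")
  same <- extrapolate_counts(rec, 26)  # 26 subjects tested each pair
  expect_equal(same$successes, as.numeric(rec$successes))
  pipe0 <- estimate_z(tt, alpha = 0.05, axis = "pair")
  est <- odorspace:::estimates_from_records(same, 128, 0.05, "none",
                                            "significance", 0.5, 1/3,
                                            "log")
  expect_equal(est$log10_z_upper, pipe0$log10_z_upper)
})

test_that("a unit at exactly chance never becomes significant", {
  rec <- tibble::tibble(N = 30, O = 15, unit = "u1",
                        successes = 1, trials = 3)
  for (n in c(3, 30, 300, 3000)) {
    ex <- extrapolate_counts(rec, n)
    p <- binomial_tail_p(ex$successes, ex$trials, 1/3)
    expect_gt(p, 0.05)
  }
})

test_that("extrapolation flips significance exactly at the critical size", {
  rec <- tibble::tibble(N = 30, O = 15, unit = "u1",
                        successes = 10, trials = 20)  # 50% correct
  for (n in c(10, 20, 23, 24, 50, 100)) {
    ex <- extrapolate_counts(rec, n)
    sig <- binomial_tail_p(ex$successes, n, 1/3) <= 0.05
    crit <- critical_fraction(n, 0.05, 1/3)
    expect_identical(sig, !is.na(crit) && ex$fraction_correct >= crit,
                     info = paste("n =", n))
  }
})

test_that("bootstrap extrapolation is seeded and hits the right mean", {
  rec <- tibble::tibble(N = 30, O = rep(15, 400),
                        unit = paste0("u", 1:400),
                        successes = 10, trials = 20)
  b1 <- extrapolate_counts(rec, 100, mode = "bootstrap", seed = 24)
  b2 <- extrapolate_counts(rec, 100, mode = "bootstrap", seed = 24)
  expect_identical(b1$successes, b2$successes)
  expect_equal(mean(b1$fraction_correct), 0.5, tolerance = 0.01)
  expect_error(extrapolate_counts(rec, 100, mode = "bootstrap"))
})

test_that("z grows monotonically with alpha, T and S on graded data", {
  tt <- make_table()
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sw_t <- sweep_alpha_T(tt, alphas, t_grid = c(5, 20, 60, 185))
  sw_s <- sweep_alpha_S(tt, alphas, s_grid = c(7, 26, 60, 135))
  for (sw in list(sw_t, sw_s)) {
    ax <- intersect(c("T", "S"), names(sw))
    # along alpha within each sample size
    for (g in split(sw, sw[[ax]])) {
      expect_true(all(diff(g$log10_z_upper[order(g$alpha)]) >= -1e-9))
    }
    # along sample size within each alpha
    for (g in split(sw, sw$alpha)) {
      expect_true(all(diff(g$log10_z_upper[order(g[[ax]])]) >= -1e-9))
    }
  }
})

test_that("every sweep cell stays within the framework extremes", {
  tt <- make_table()
  sw <- sweep_alpha_T(tt, c(0.001, 0.05, 0.5), c(5, 20, 185))
  lims <- landmarks(stimulus_space(128, 30))
  expect_true(all(sw$log10_z_upper >= lims$smallest - 1e-9))
  expect_true(all(sw$log10_z_upper <= lims$all + 1e-9))
  # boundary cells carry the matching regime labels
  expect_true(all(sw$regime[abs(sw$log10_z_upper - lims$all) < 1e-9] ==
                    "All"))
  expect_true(all(sw$regime[abs(sw$log10_z_upper - lims$smallest) < 1e-9]
                  == "smallest possible"))
})

test_that("chance-level data land in the smallest-possible regime everywhere", {
  tt <- make_table(params = psychometric_params(p_max = 1/3 + 1e-12,
                                                subject_sd = 0))
  sw <- sweep_alpha_T(tt, c(0.01, 0.05), c(5, 20, 60))
  expect_true(all(sw$regime == "smallest possible"))
  expect_true(all(sw$d == 30))
})

test_that("saturated data land in the All regime regardless of S", {
  tt <- make_table(subjects = 8)
  tt$correct <- 1
  sw <- sweep_alpha_S(tt, 0.05, s_grid = c(8, 26, 135))
  expect_true(all(sw$regime == "All"))
})

test_that("regime classification picks the nearest landmark", {
  lims <- landmarks(stimulus_space(128, 30))
  expect_identical(classify_regime(lims$all, lims), "All")
  expect_identical(classify_regime(lims$smallest, lims),
                   "smallest possible")
  expect_identical(classify_regime(12, lims), "trillion")
  expect_identical(classify_regime(7.2, lims), "colors")
})

test_that("consistency curve with one rep equals the plain pipeline", {
  tt <- make_table()
  plain <- estimate_z(tt, alpha = 0.05, axis = "pair")
  cc <- consistency_curve(tt, axis = "S", grid = 26, reps = 1)
  expect_equal(cc$mean_log10_z, plain$log10_z_upper)
  expect_equal(cc$sd_log10_z, 0)
})

test_that("gradual performance yields an inconsistent, rising curve", {
  tt <- make_table()
  cc <- consistency_curve(tt, axis = "S", grid = c(7, 26, 80, 250))
  expect_true(all(diff(cc$mean_log10_z) >= -1e-9))
  expect_gt(cc$mean_log10_z[4] - cc$mean_log10_z[1], 5)
  # far beyond the trillion landmark once samples are large
  expect_gte(cc$mean_log10_z[4], 12)
})

test_that("a sharp psychometric step gives a far flatter curve", {
  # step-like discriminability: the estimate barely moves across a
  # 4-fold range of subject counts, unlike graded data on the same grid
  params <- psychometric_params(midpoint = 50, slope = 0.1,
                                subject_sd = 0)
  sharp <- consistency_curve(make_table(params = params),
                             axis = "S", grid = c(13, 26, 52))
  grad <- consistency_curve(make_table(), axis = "S",
                            grid = c(13, 26, 52))
  range_sharp <- max(sharp$mean_log10_z) - min(sharp$mean_log10_z)
  range_grad <- max(grad$mean_log10_z) - min(grad$mean_log10_z)
  expect_lt(range_sharp, 2)
  expect_gt(range_grad, range_sharp)
})

test_that("library-size scaling anchors at C = 128 and explodes upward", {
  curve <- z_vs_library_size(c(128, 200, 500, 2000), N = 30)
  expect_true(all(diff(curve$log10_z_upper) > 0))
  anchor <- packing_bounds(stimulus_space(128, 30), 30)
  expect_identical(curve$log10_z_upper[1], anchor$log10_z_upper)
  expect_error(z_vs_library_size(c(20), N = 30))
  expect_error(z_vs_library_size(c(128), N = 30, policy = "fixed_d"))
  fx <- z_vs_library_size(c(128, 256), N = 30, d = 14.7,
                          policy = "fixed_d")
  expect_gt(fx$log10_z_upper[2], fx$log10_z_upper[1])
})
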