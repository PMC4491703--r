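#' Extrapolate performance records to a new sample size
#'
#' Answers "what if the same units had been tested with more (or fewer)
#' trials, performing similarly?".  In deterministic mode each unit's
#' fraction correct is held fixed and its counts rescaled
#' (`successes = round(fraction * new_trials)`, rounding half away from
#' zero); in bootstrap mode each unit's trial outcomes are resampled
#' with replacement to the new count.
#'
#' @param records performance records (see [summarize_trials]).
#' @param new_trials target trial count per unit, `>= 1`.
#' @param mode `"deterministic"` or `"bootstrap"`.
#' @param seed integer seed (required for bootstrap mode).
#' @return records with rescaled `successes`, `trials` and
#'   `fraction_correct`.
#' @export
extrapolate_counts <- function(records, new_trials,
                               mode = c("deterministic", "bootstrap"),
                               seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), new_trials >= 1,
            new_trials == floor(new_trials))
  f <- records$successes / records$trials
  if (mode == "deterministic") {
    succ <- floor(f * new_trials + 0.5)  # round half away from zero
  } else {
    if (is.null(seed)) {
      stop("bootstrap extrapolation requires a seed")
    }
    succ <- withr::with_seed(seed,
      stats::rbinom(length(f), new_trials, f))
  }
  records$successes <- succ
  records$trials <- new_trials
  records$fraction_correct <- succ / new_trials
  records
}

#' Reference landmarks for the estimate
#'
#' The framework's possible outputs for a given space run from
#' `z(d = N)` (the smallest value it can produce) to `choose(C, N)` (all
#' possible mixtures).  Landmarks in between — a trillion, and the
#' commonly cited order of magnitude of discriminable colors — anchor
#' the regime classification of sweep cells.
#'
#' @param space a [stimulus_space].
#' @param colors landmark for the number of discriminable colors
#'   (configurable; default 1e7).
#' @return a list of log10 landmark values with class `landmarks`.
#' @export
landmarks <- function(space, colors = 1e7) {
  lm <- list(
    smallest = packing_bounds(space, space$N)$log10_z_upper,
    colors = log10(colors),
    trillion = 12,
    all = big_log10(space$n_stimuli)
  )
  stopifnot(lm$smallest < lm$colors, lm$colors < lm$trillion,
            lm$trillion < lm$all)
  structure(lm, class = "landmarks")
}

#' Classify an estimate by its nearest landmark
#'
#' @param log10_z log10 of the estimate; vectorized.
#' @param lms a [landmarks] object.
#' @return labels: `"All"`, `"smallest possible"`, `"colors"` or
#'   `"trillion"`; the boundary labels are applied exactly when the
#'   estimate equals (up to rounding) the framework's extremes.
#' @export
classify_regime <- function(log10_z, lms) {
  stopifnot(inherits(lms, "landmarks"))
  vapply(log10_z, function(z) {
    if (z >= lms$all - 1e-9) {
      return("All")
    }
    if (z <= lms$smallest + 1e-9) {
      return("smallest possible")
    }
    labs <- c("smallest possible", "colors", "trillion", "All")
    vals <- c(lms$smallest, lms$colors, lms$trillion, lms$all)
    labs[which.min(abs(vals - z))]
  }, character(1))
}

sweep_core <- function(records, alphas, size_grid, size_name, C,
                       correction, threshold, chance, interp, mode, seed) {
  spaces <- lapply(sort(unique(records$N)),
                   function(n) landmarks(stimulus_space(C, n)))
  names(spaces) <- sort(unique(records$N))
  cells <- list()
  for (i in seq_along(size_grid)) {
    sz <- size_grid[i]
    rec <- extrapolate_counts(records, sz, mode = mode,
                              seed = if (is.null(seed)) NULL else seed + i)
    for (a in alphas) {
      est <- estimates_from_records(rec, C, a, correction,
                                    "significance", threshold, chance,
                                    interp)
      est[[size_name]] <- sz
      est$alpha <- a
      est$regime <- vapply(seq_len(nrow(est)), function(r) {
        classify_regime(est$log10_z_upper[r],
                        spaces[[as.character(est$N[r])]])
      }, character(1))
      cells[[length(cells) + 1L]] <- est
    }
  }
  dplyr::bind_rows(cells)[, c("N", "alpha", size_name, "o_star", "d",
                              "log10_z_upper", "log10_z_lower",
                              "regime", "clamped")]
}

#' Sweep the estimate over significance level and tests per class
#'
#' For each grid cell, extrapolates every subject's per-class trial
#' count to `T` tests (each subject's fraction correct held fixed),
#' reruns the significance / limen / packing pipeline on the
#' per-subject axis, and records the resulting estimate and its regime.
#' The steep, systematic dependence of the estimate on these incidental
#' parameters is the estimator-inconsistency phenomenon this package
#' quantifies.
#'
#' @param table a trial tibble.
#' @param alphas grid of significance levels.
#' @param t_grid grid of per-class test counts `T`.
#' @param C library size.
#' @param correction multiple-comparison correction.
#' @param threshold crossing threshold for the limen.
#' @param chance chance rate.
#' @param interp ball interpolation scale.
#' @param mode extrapolation mode (see [extrapolate_counts]).
#' @param seed seed for bootstrap mode.
#' @return a long tibble with one row per (N, alpha, T): `o_star`, `d`,
#'   `log10_z_upper`, `log10_z_lower`, `regime`, `clamped`.
#' @export
sweep_alpha_T <- function(table, alphas, t_grid, C = 128,
                          correction = "none", threshold = 0.5,
                          chance = 1/3, interp = "log",
                          mode = "deterministic", seed = NULL) {
  stopifnot(length(alphas) > 0, length(t_grid) > 0)
  records <- summarize_trials(table, axis = "subject")
  if (length(unique(records$O)) < 2L) {
    stop("need at least two overlap classes to sweep")
  }
  sweep_core(records, alphas, t_grid, "T", C, correction, threshold,
             chance, interp, mode, seed)
}

#' Sweep the estimate over significance level and subject count
#'
#' Identical pipeline to [sweep_alpha_T] but on the per-pair axis: each
#' mixture pair's subject count is extrapolated to `S` subjects
#' performing similarly.
#'
#' @inheritParams sweep_alpha_T
#' @param s_grid grid of subject counts `S`.
#' @return a long tibble with one row per (N, alpha, S).
#' @export
sweep_alpha_S <- function(table, alphas, s_grid, C = 128,
                          correction = "none", threshold = 0.5,
                          chance = 1/3, interp = "log",
                          mode = "deterministic", seed = NULL) {
  stopifnot(length(alphas) > 0, length(s_grid) > 0)
  records <- summarize_trials(table, axis = "pair")
  if (length(unique(records$O)) < 2L) {
    stop("need at least two overlap classes to sweep")
  }
  sweep_core(records, alphas, s_grid, "S", C, correction, threshold,
             chance, interp, mode, seed)
}

#' Estimate as a function of sample size
#'
#' A consistent estimator should produce a flat curve: the estimate may
#' become less uncertain with more data, but should not drift.  This
#' traces mean and spread of `log10 z` across bootstrap replicates (or
#' the deterministic extrapolation when `reps = 1`) at each sample
#' size.
#'
#' @param table a trial tibble.
#' @param axis `"S"` (subjects; per-pair testing axis) or `"T"` (tests
#'   per class; per-subject axis).
#' @param grid sample sizes to evaluate.
#' @param reps bootstrap replicates per grid point (`1` =
#'   deterministic).
#' @param seed integer seed (required when `reps > 1`).
#' @param C library size.
#' @param alpha significance level.
#' @param correction,threshold,chance,interp pipeline parameters.
#' @return a tibble (N, sample_size, mean_log10_z, sd_log10_z).
#' @export
consistency_curve <- function(table, axis = c("S", "T"), grid, reps = 1,
                              seed = NULL, C = 128, alpha = 0.05,
                              correction = "none", threshold = 0.5,
                              chance = 1/3, interp = "log") {
  axis <- match.arg(axis)
  stopifnot(reps >= 1)
  if (reps > 1 && is.null(seed)) {
    stop("bootstrap consistency curves require a seed")
  }
  records <- summarize_trials(table,
                              axis = if (axis == "S") "pair" else "subject")
  rows <- list()
  for (i in seq_along(grid)) {
    reps_log10 <- list()
    for (r in seq_len(reps)) {
      rec <- if (reps == 1) {
        extrapolate_counts(records, grid[i], mode = "deterministic")
      } else {
        extrapolate_counts(records, grid[i], mode = "bootstrap",
                           seed = seed + 1000L * i + r)
      }
      est <- estimates_from_records(rec, C, alpha, correction,
                                    "significance", threshold, chance,
                                    interp)
      reps_log10[[r]] <- est[, c("N", "log10_z_upper")]
    }
    agg <- dplyr::bind_rows(reps_log10) |>
      dplyr::group_by(.data$N) |>
      dplyr::summarise(
        mean_log10_z = mean(.data$log10_z_upper),
        sd_log10_z = if (reps > 1) stats::sd(.data$log10_z_upper) else 0,
        .groups = "drop"
      )
    agg$sample_size <- grid[i]
    rows[[i]] <- agg
  }
  dplyr::bind_rows(rows)[, c("N", "sample_size", "mean_log10_z",
                             "sd_log10_z")]
}

#' Growth of the estimate with library size
#'
#' Evaluates the upper bound across a grid of library sizes `C`, either
#' at a fixed limen `d` or under the worst-case policy `d = N`
#' (performance as poor as the framework allows).  Even the worst case
#' grows explosively: at `N = 30` it passes 10^21 by `C = 2000` and
#' 10^61 by `C = 10^6`.
#'
#' @param C_grid library sizes, all `>= N`.
#' @param N mixture size.
#' @param d limen for the `"fixed_d"` policy.
#' @param policy `"worst_case"` (`d = N`) or `"fixed_d"`.
#' @param interp ball interpolation scale.
#' @return a tibble (C, N, d, log10_z_upper, log10_z_lower).
#' @export
z_vs_library_size <- function(C_grid, N = 30, d = NULL,
                              policy = c("worst_case", "fixed_d"),
                              interp = "log") {
  policy <- match.arg(policy)
  if (any(C_grid < N)) {
    stop("library size C must be at least the mixture size N")
  }
  if (policy == "fixed_d" && is.null(d)) {
    stop("fixed_d policy requires d")
  }
  d_use <- if (policy == "worst_case") N else d
  rows <- lapply(C_grid, function(cc) {
    b <- packing_bounds(stimulus_space(cc, N), d_use, interp)
    tibble::tibble(C = cc, N = N, d = d_use,
                   log10_z_upper = b$log10_z_upper,
                   log10_z_lower = b$log10_z_lower)
  })
  dplyr::bind_rows(rows)
}
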