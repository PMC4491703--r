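#' Threshold crossing of a fitted line
#'
#' Fits an ordinary least-squares line to (percent overlap, y) points
#' and solves for the overlap at which the line equals `threshold` —
#' the "linear regression and interpolation" step that converts
#' class-level summaries into a critical overlap.
#'
#' Discriminability is expected to fall with overlap, so a negative
#' slope is the regular case.  When the fitted slope is zero or positive
#' there is no meaningful crossing and the estimate is clamped to the
#' boundary consistent with the overall level of the data (mean y at or
#' above threshold gives 100% overlap, i.e. everything discriminable;
#' below threshold gives 0%).  Crossings outside `[0, 100]` are clamped
#' likewise, with the `clamped` flag set.
#'
#' @param percent_overlap numeric x-values in `[0, 100]`; at least two
#'   distinct values.
#' @param y numeric responses in `[0, 1]` (a fraction significant or a
#'   mean fraction correct).
#' @param threshold the y-level whose crossing defines the critical
#'   overlap.
#' @param weights optional non-negative case weights (e.g. units per
#'   class); unweighted by default.
#' @return a list with `o_star`, `slope`, `intercept`, `clamped`.
#' @export
#' @examples
#' fit_crossing(c(0, 100), c(1, 0), threshold = 0.5)  # o_star = 50
fit_crossing <- function(percent_overlap, y, threshold = 0.5,
                         weights = NULL) {
  stopifnot(length(percent_overlap) == length(y),
            all(is.finite(percent_overlap)), all(is.finite(y)))
  if (length(unique(percent_overlap)) < 2L) {
    stop("need at least two distinct overlap values to fit a line")
  }
  fit <- if (is.null(weights)) {
    stats::lm(y ~ percent_overlap)
  } else {
    stats::lm(y ~ percent_overlap, weights = weights)
  }
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  clamped <- FALSE
  if (!is.finite(slope) || slope >= 0) {
    o_star <- if (mean(y) >= threshold) 100 else 0
    clamped <- TRUE
  } else {
    o_star <- (threshold - intercept) / slope
    if (o_star < 0 || o_star > 100) {
      o_star <- min(100, max(0, o_star))
      clamped <- TRUE
    }
  }
  list(o_star = o_star, slope = slope, intercept = intercept,
       clamped = clamped)
}

new_limen_estimate <- function(method, threshold, N, cross) {
  structure(
    list(
      method = method, threshold = threshold, N = N,
      o_star = cross$o_star,
      d = N * (1 - cross$o_star / 100),
      regression = list(slope = cross$slope, intercept = cross$intercept),
      clamped = cross$clamped
    ),
    class = "limen_estimate"
  )
}

#' @export
print.limen_estimate <- function(x, ...) {
  cat(sprintf(
    "Difference limen (%s method, threshold %.3g): o* = %.2f%%, d = %.3f of N = %d%s\n",
    x$method, x$threshold, x$o_star, x$d, x$N,
    if (x$clamped) " [clamped]" else ""
  ))
  invisible(x)
}

#' Estimate the limen from the fraction significantly discriminable
#'
#' Applies [fit_crossing] to per-class fractions of significant units
#' (from [test_units]) and converts the critical overlap `o*` into a
#' limen distance `d = N (1 - o*/100)`.
#'
#' @param summary a per-class summary tibble for a single mixture size
#'   `N`, with columns `percent_overlap` and `fraction_significant`
#'   (and optionally `n_units` for weighting).
#' @param threshold fraction of significant units defining the crossing
#'   (default 0.5: "more likely than not").
#' @param weighted weight classes by `n_units` in the regression.
#' @return a `limen_estimate`.
#' @export
estimate_limen_significance <- function(summary, threshold = 0.5,
                                        weighted = FALSE) {
  stopifnot(is.data.frame(summary),
            all(c("N", "percent_overlap", "fraction_significant") %in%
                  names(summary)))
  N <- unique(summary$N)
  if (length(N) != 1L) {
    stop("summaries must share a single mixture size N; fit per N")
  }
  w <- if (weighted) summary$n_units else NULL
  cross <- fit_crossing(summary$percent_overlap,
                        summary$fraction_significant, threshold, w)
  new_limen_estimate("significance_threshold", threshold, N, cross)
}

#' Estimate the limen from the fraction discriminated directly
#'
#' The hypothesis-test-free variant: the same regression and
#' interpolation applied to the mean fraction correct per class, with a
#' threshold `theta` chosen between chance and 1.
#'
#' @param records performance records for a single mixture size (see
#'   [summarize_trials]).
#' @param theta fraction-correct threshold, strictly above `chance` and
#'   at most 1.
#' @param chance the chance rate (1/3 for 3-AFC).
#' @param weighted weight classes by their number of units.
#' @return a `limen_estimate`.
#' @export
estimate_limen_fraction <- function(records, theta, chance = 1/3,
                                    weighted = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("N", "percent_overlap", "fraction_correct") %in%
                  names(records)))
  if (!is.finite(theta) || theta <= chance || theta > 1) {
    stop("theta must lie in (chance, 1]")
  }
  N <- unique(records$N)
  if (length(N) != 1L) {
    stop("records must share a single mixture size N; fit per N")
  }
  cls <- records |>
    dplyr::group_by(.data$percent_overlap) |>
    dplyr::summarise(y = mean(.data$fraction_correct),
                     n_units = dplyr::n(), .groups = "drop")
  w <- if (weighted) cls$n_units else NULL
  cross <- fit_crossing(cls$percent_overlap, cls$y, theta, w)
  new_limen_estimate("fraction_threshold", theta, N, cross)
}

#' Convert a limen estimate into packing bounds
#'
#' @param estimate a `limen_estimate`.
#' @param C library size defining the space together with the estimate's
#'   `N`.
#' @param interp interpolation scale for the fractional radius.
#' @return a [packing_bounds] object.
#' @export
limen_bounds <- function(estimate, C = 128, interp = c("log", "linear")) {
  stopifnot(inherits(estimate, "limen_estimate"))
  packing_bounds(stimulus_space(C, estimate$N), estimate$d,
                 match.arg(interp))
}

#' Run the full estimation pipeline on a trial table
#'
#' Aggregates trials along the chosen axis, tests each unit against
#' chance, estimates the limen per mixture size, and converts it into
#' packing bounds — the complete path from raw 3-AFC judgments to a
#' count of discriminable stimuli.
#'
#' @param table a trial tibble.
#' @param C component-library size.
#' @param alpha significance level for the unit tests.
#' @param axis testing axis (see [summarize_trials]).
#' @param correction multiple-comparison correction (see [test_units]).
#' @param method `"significance"` (threshold on the fraction of
#'   significant units) or `"fraction"` (threshold on the mean fraction
#'   correct).
#' @param threshold crossing threshold: fraction significant for the
#'   significance method (default 0.5), or `theta` for the fraction
#'   method.
#' @param chance chance success rate.
#' @param interp ball interpolation scale.
#' @return a tibble with one row per mixture size `N`: `o_star`, `d`,
#'   `z_upper`, `z_lower`, `log10_z_upper`, `log10_z_lower`, `clamped`.
#' @export
estimate_z <- function(table, C = 128, alpha = 0.05,
                       axis = c("pair", "subject"),
                       correction = c("none", "bonferroni", "holm"),
                       method = c("significance", "fraction"),
                       threshold = 0.5, chance = 1/3,
                       interp = c("log", "linear")) {
  axis <- match.arg(axis)
  correction <- match.arg(correction)
  method <- match.arg(method)
  interp <- match.arg(interp)
  records <- summarize_trials(table, axis)
  estimates_from_records(records, C, alpha, correction, method,
                         threshold, chance, interp)
}

# shared back half of the pipeline, reused by the sensitivity sweeps
# (which extrapolate the records before estimation)
estimates_from_records <- function(records, C, alpha, correction, method,
                                   threshold, chance, interp) {
  out <- lapply(sort(unique(records$N)), function(n) {
    rec_n <- records[records$N == n, ]
    est <- if (method == "significance") {
      tst <- test_units(rec_n, alpha = alpha, chance = chance,
                        correction = correction)
      estimate_limen_significance(tst$summary, threshold)
    } else {
      estimate_limen_fraction(rec_n, theta = threshold, chance = chance)
    }
    b <- limen_bounds(est, C, interp)
    tibble::tibble(
      N = n, o_star = est$o_star, d = est$d,
      z_upper = b$z_upper, z_lower = b$z_lower,
      log10_z_upper = b$log10_z_upper, log10_z_lower = b$log10_z_lower,
      clamped = est$clamped
    )
  })
  dplyr::bind_rows(out)
}

#' Per-subject limen estimates
#'
#' Applies the chosen limen method to each subject's own data,
#' quantifying how much the derived `d` (and hence `z`) varies across
#' individuals.  Subjects tested at fewer than two overlap levels are
#' skipped with a warning.
#'
#' @param table a trial tibble for a single mixture size `N`.
#' @param method `"significance"` or `"fraction"`.
#' @param C library size.
#' @param alpha significance level (significance method: each
#'   subject-class record is flagged against chance and the 0/1 flags
#'   are regressed on overlap).
#' @param threshold crossing threshold (`theta` for the fraction
#'   method).
#' @param chance chance rate.
#' @param interp ball interpolation scale.
#' @return a tibble with one row per subject (`subject_id`, `o_star`,
#'   `d`, `log10_z_upper`, `clamped`) plus a `summary` attribute holding
#'   the median and quartiles of `d` and `log10_z_upper`.
#' @export
per_subject_limens <- function(table, method = c("significance", "fraction"),
                               C = 128, alpha = 0.05, threshold = 0.5,
                               chance = 1/3, interp = c("log", "linear")) {
  method <- match.arg(method)
  interp <- match.arg(interp)
  stopifnot(is.data.frame(table))
  if (length(unique(table$N)) != 1L) {
    stop("per-subject limens are fit within a single mixture size N")
  }
  rows <- lapply(unique(table$subject_id), function(sid) {
    sub <- table[table$subject_id == sid, ]
    if (length(unique(sub$O)) < 2L) {
      warning("subject ", sid, " has fewer than 2 overlap levels; skipped")
      return(NULL)
    }
    rec <- summarize_trials(sub, axis = "subject")
    est <- if (method == "significance") {
      flags <- test_units(rec, alpha = alpha, chance = chance,
                          correction = "none")
      cross <- fit_crossing(flags$summary$percent_overlap,
                            flags$summary$fraction_significant, threshold)
      new_limen_estimate("significance_threshold", threshold,
                         unique(sub$N), cross)
    } else {
      estimate_limen_fraction(rec, theta = threshold, chance = chance)
    }
    b <- limen_bounds(est, C, interp)
    tibble::tibble(subject_id = sid, o_star = est$o_star, d = est$d,
                   log10_z_upper = b$log10_z_upper, clamped = est$clamped)
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "summary") <- list(
    d = stats::quantile(res$d, c(0.25, 0.5, 0.75), names = FALSE),
    log10_z_upper = stats::quantile(res$log10_z_upper,
                                    c(0.25, 0.5, 0.75), names = FALSE)
  )
  res
}
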