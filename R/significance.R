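#' Exact one-sided binomial tail probability
#'
#' Probability of observing at least `successes` correct responses in
#' `trials` 3-AFC tests under the null hypothesis of chance responding.
#' This is the upper tail `P(X >= successes)` for
#' `X ~ Binomial(trials, chance)`, computed exactly.
#'
#' @param successes,trials non-negative integer counts,
#'   `successes <= trials`; vectorized.
#' @param chance null success probability, strictly inside (0, 1);
#'   1/3 for the three-alternative forced-choice task.
#' @return p-values in `[0, 1]`.
#' @export
#' @examples
#' binomial_tail_p(12, 20, 1/3)
binomial_tail_p <- function(successes, trials, chance = 1/3) {
  if (length(chance) != 1L || !is.finite(chance) || chance <= 0 || chance >= 1) {
    stop("chance must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(successes)) || any(!is.finite(trials)) ||
      any(successes < 0) || any(trials < 1) || any(successes > trials) ||
      any(successes != floor(successes)) || any(trials != floor(trials))) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  stats::pbinom(successes - 1, trials, chance, lower.tail = FALSE)
}

#' Smallest success count reaching significance
#'
#' @inheritParams binomial_tail_p
#' @param alpha significance level in (0, 1); a unit is significant when
#'   its tail probability is `<= alpha`.
#' @return the smallest `k` with `binomial_tail_p(k, trials, chance) <=
#'   alpha`, or `NA` when even `trials` successes do not reach
#'   significance (e.g. a single 3-AFC trial has minimum p = 1/3).
#' @export
critical_successes <- function(trials, alpha = 0.05, chance = 1/3) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0, alpha < 1)
  vapply(trials, function(n) {
    p <- binomial_tail_p(0:n, n, chance)
    k <- which(p <= alpha)
    if (length(k) == 0L) NA_real_ else k[1] - 1
  }, numeric(1))
}

#' Fraction correct required to reach significance
#'
#' The critical fraction `k*/trials` below which performance cannot be
#' distinguished from chance at level `alpha`.  This fraction varies
#' strongly with the number of trials, which is the root of the
#' sample-size sensitivity of any estimate built on counting significant
#' units.
#'
#' @inheritParams critical_successes
#' @return `k*/trials`, or `NA` (unattainable) when no success count
#'   reaches significance.
#' @export
#' @examples
#' critical_fraction(20, 0.05)   # 0.55: 11 of 20 needed
#' critical_fraction(1, 0.05)    # NA: a single trial can never reach p <= .05
critical_fraction <- function(trials, alpha = 0.05, chance = 1/3) {
  critical_successes(trials, alpha, chance) / trials
}

#' Test performance units against chance
#'
#' Flags each unit (a mixture pair tested by several subjects, or a
#' subject tested on several pairs of one class) whose fraction correct
#' is significantly above chance, and summarizes the fraction of
#' significant units per mixture class.
#'
#' @param records a data frame of performance records with columns `N`,
#'   `O`, `unit`, `successes`, `trials` (as produced by
#'   [summarize_trials]).
#' @param alpha significance level; ties at `p == alpha` count as
#'   significant.
#' @param chance null success probability.
#' @param correction multiple-comparison correction applied across all
#'   units in the call: `"none"` (the uncorrected analysis),
#'   `"bonferroni"` or `"holm"`.
#' @return a list with
#'   * `units`: the input records with `fraction_correct`, `p_value`,
#'     `p_adjusted` and `significant` columns added;
#'   * `summary`: one row per mixture class with `n_units`,
#'     `n_significant`, `fraction_significant` and `percent_overlap`.
#' @export
test_units <- function(records, alpha = 0.05, chance = 1/3,
                       correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(records),
            all(c("N", "O", "unit", "successes", "trials") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("no performance records to test")
  }
  bad <- records$trials < 1
  if (any(bad)) {
    stop("performance records with zero trials in class N=",
         records$N[bad][1], " O=", records$O[bad][1])
  }
  units <- records |>
    dplyr::mutate(
      fraction_correct = .data$successes / .data$trials,
      p_value = binomial_tail_p(.data$successes, .data$trials, chance),
      p_adjusted = stats::p.adjust(.data$p_value, method = correction),
      significant = .data$p_adjusted <= alpha
    )
  summary <- units |>
    dplyr::group_by(.data$N, .data$O) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      n_significant = sum(.data$significant),
      fraction_significant = mean(.data$significant),
      mean_fraction_correct = mean(.data$fraction_correct),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_overlap = 100 * .data$O / .data$N) |>
    dplyr::arrange(.data$N, .data$O)
  list(units = units, summary = summary,
       alpha = alpha, chance = chance, correction = correction)
}
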