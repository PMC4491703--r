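#' Define a mixture stimulus space
#'
#' The stimulus space is the set of all mixtures that can be assembled by
#' choosing `N` distinct components from a library of `C` components.
#' Its size is `choose(C, N)`, computed exactly; for the canonical
#' `C = 128`, `N = 30` design this is about 1.5e29 possible stimuli.
#'
#' @param C number of distinct components available in the library.
#' @param N number of distinct components per mixture, `0 < N <= C`.
#' @return an object of class `stimulus_space` with fields `C`, `N` and
#'   `n_stimuli` (a [bigint] holding the exact space size).
#' @export
#' @examples
#' sp <- stimulus_space(128, 30)
#' sp$n_stimuli
stimulus_space <- function(C, N) {
  stopifnot(length(C) == 1L, length(N) == 1L)
  if (!is.finite(C) || !is.finite(N) || C != floor(C) || N != floor(N) ||
      N <= 0 || N > C) {
    stop("stimulus_space requires integers 0 < N <= C")
  }
  structure(
    list(C = C, N = N, n_stimuli = binomial_exact(C, N)),
    class = "stimulus_space"
  )
}

#' @export
print.stimulus_space <- function(x, ...) {
  cat("Mixture stimulus space: N =", x$N, "components drawn from C =",
      x$C, "\n  possible stimuli:", as.character(x$n_stimuli),
      sprintf("(10^%.2f)\n", big_log10(x$n_stimuli)))
  invisible(x)
}

#' Describe a class of mixture pairs by size and overlap
#'
#' Mixture pairs are grouped into classes by mixture size `N` and overlap
#' `O` (number of shared components).  The inter-stimulus distance is
#' `D = N - O`, the number of components of one mixture not present in
#' the other.
#'
#' @param N mixture size.
#' @param O overlap, `0 <= O <= N`.
#' @return a list with `N`, `O`, `D` and `percent_overlap` (`100 * O / N`).
#' @export
mixture_class <- function(N, O) {
  stopifnot(is.finite(N), is.finite(O), N == floor(N), O == floor(O))
  if (N < 1 || O < 0 || O > N) {
    stop("mixture_class requires 0 <= O <= N, N >= 1")
  }
  list(N = N, O = O, D = N - O, percent_overlap = 100 * O / N)
}

#' Distance between two explicit mixtures
#'
#' @param mixture_a,mixture_b vectors of component identities, both of
#'   the same length `N` with no duplicates.
#' @return a [mixture_class] describing the pair.
#' @export
#' @examples
#' pair_distance(c("a", "b", "c"), c("a", "b", "d"))
pair_distance <- function(mixture_a, mixture_b) {
  if (anyDuplicated(mixture_a) || anyDuplicated(mixture_b)) {
    stop("mixtures must not contain duplicate components")
  }
  if (length(mixture_a) != length(mixture_b)) {
    stop("mixtures must have the same size N")
  }
  O <- length(intersect(mixture_a, mixture_b))
  mixture_class(length(mixture_a), O)
}

#' Volume of a ball in the mixture space
#'
#' Counts the mixtures within `r` component substitutions of a reference
#' mixture: `sum_{x=0}^{r} choose(N, x) * choose(C - N, x)`.  At `r = N`
#' the Vandermonde identity collapses the sum to the whole space,
#' `choose(C, N)`.
#'
#' For non-integer radii (which arise because the upper bound uses radius
#' `d/2` for an estimated, generally fractional, limen `d`) the volume is
#' interpolated between the two neighbouring integer radii, by default
#' linearly in `log(ball)` since the volume grows geometrically.
#'
#' @param space a [stimulus_space].
#' @param r radius in components, `0 <= r <= N`.
#' @param interpolate allow non-integer `r`.
#' @param interp interpolation scale for fractional radii: `"log"`
#'   (geometric, default) or `"linear"`.
#' @return a [bigint] for integer `r`; a double for fractional `r`
#'   (`Inf` if the interpolated volume exceeds double range — use
#'   [ball_volume_log10] in that regime).
#' @export
#' @examples
#' sp <- stimulus_space(128, 30)
#' ball_volume(sp, 0)  # 1
#' ball_volume(sp, 1)  # 1 + 30*98
ball_volume <- function(space, r, interpolate = FALSE,
                        interp = c("log", "linear")) {
  interp <- match.arg(interp)
  check_radius(space, r)
  if (r == floor(r)) {
    return(ball_volume_exact(space, r))
  }
  if (!interpolate) {
    stop("non-integer radius requires interpolate = TRUE")
  }
  lg <- ball_volume_log10(space, r, interp = interp)
  if (lg > 308) Inf else 10^lg
}

check_radius <- function(space, r) {
  stopifnot(inherits(space, "stimulus_space"))
  if (!is.finite(r) || r < 0 || r > space$N) {
    stop("radius must lie in [0, N]")
  }
  invisible(r)
}

ball_volume_exact <- function(space, r) {
  acc <- as_bigint(0)
  # terms with x > C - N vanish: there are no substitutes to swap in
  for (x in 0:min(r, space$C - space$N)) {
    acc <- big_add(acc, big_mul(
      binomial_exact(space$N, x),
      binomial_exact(space$C - space$N, x)
    ))
  }
  acc
}

#' log10 of the (possibly interpolated) ball volume
#'
#' @inheritParams ball_volume
#' @return a double, exact-to-rounding for integer `r`.
#' @export
ball_volume_log10 <- function(space, r, interp = c("log", "linear")) {
  interp <- match.arg(interp)
  check_radius(space, r)
  if (r == floor(r)) {
    return(big_log10(ball_volume_exact(space, r)))
  }
  lo <- big_log10(ball_volume_exact(space, floor(r)))
  hi <- big_log10(ball_volume_exact(space, ceiling(r)))
  w <- r - floor(r)
  if (interp == "log") {
    (1 - w) * lo + w * hi
  } else {
    # linear-scale interpolation, evaluated stably in log space
    hi + log10(w + (1 - w) * 10^(lo - hi))
  }
}

#' Packing bounds on the number of discriminable stimuli
#'
#' Given a difference limen `d` (the inter-stimulus distance at which
#' pairs are just discriminable), the number `z` of mutually
#' discriminable stimuli that can be packed into the space is bounded by
#' two classical constant-weight-code bounds:
#'
#' * **upper** (Hamming-type): `floor(choose(C, N) / ball(d / 2))` —
#'   non-overlapping balls of radius `d/2` around each codeword;
#' * **lower** (Gilbert–Varshamov-type): `max(1,
#'   floor(choose(C, N) / ball(d)))` — a maximal code must cover the
#'   space with radius-`d` balls.
#'
#' At `d = 0` both bounds equal the full space size; at `d = N` the lower
#' bound reaches 1 (a subject who can discriminate nothing perceives a
#' single stimulus) while the upper bound stays in the thousands for the
#' `C = 128`, `N = 30` space.
#'
#' All ratios are formed in exact integer arithmetic when the radius is
#' an integer; fractional radii use the interpolated ball volume and the
#' bound is then reported on the interpolated (real) scale.
#'
#' @param space a [stimulus_space].
#' @param d difference limen in components, `0 <= d <= N`; may be
#'   fractional.
#' @param interp interpolation scale for fractional radii (see
#'   [ball_volume]).
#' @return an object of class `packing_estimate`: a list with fields
#'   `C`, `N`, `d`, `z_upper`, `z_lower` (doubles; `Inf` beyond double
#'   range), `log10_z_upper`, `log10_z_lower`, and `z_upper_exact`,
#'   `z_lower_exact` (decimal strings when the radius was an integer,
#'   otherwise `NA`).
#' @export
#' @examples
#' sp <- stimulus_space(128, 30)
#' packing_bounds(sp, 30)   # worst case: upper 4561, lower 1
packing_bounds <- function(space, d, interp = c("log", "linear")) {
  interp <- match.arg(interp)
  check_radius(space, d)
  up <- bound_one(space, d / 2, interp)
  lo <- bound_one(space, d, interp)
  if (lo$z < 1) {
    lo$z <- 1
    lo$log10 <- 0
    lo$exact <- "1"
  }
  structure(
    list(
      C = space$C, N = space$N, d = d,
      z_upper = up$z, z_lower = lo$z,
      log10_z_upper = up$log10, log10_z_lower = lo$log10,
      z_upper_exact = up$exact, z_lower_exact = lo$exact
    ),
    class = "packing_estimate"
  )
}

bound_one <- function(space, r, interp) {
  if (r == floor(r)) {
    ball <- ball_volume_exact(space, r)
    q <- big_divmod(space$n_stimuli, ball)$q
    list(
      z = as.numeric(q),
      log10 = big_log10(space$n_stimuli) - big_log10(ball),
      exact = as.character(q)
    )
  } else {
    lg <- big_log10(space$n_stimuli) - ball_volume_log10(space, r, interp)
    z <- if (lg > 308) Inf else 10^lg
    # report the integer part where it is representable exactly
    if (is.finite(z) && z < 2^53) z <- floor(z)
    list(z = z, log10 = lg, exact = NA_character_)
  }
}

#' @rdname packing_bounds
#' @export
z_upper_bound <- function(space, d, interp = c("log", "linear")) {
  packing_bounds(space, d, interp)
}

#' @rdname packing_bounds
#' @export
z_lower_bound <- function(space, d, interp = c("log", "linear")) {
  packing_bounds(space, d, interp)
}

#' @export
print.packing_estimate <- function(x, ...) {
  cat(sprintf(
    "Packing bounds for C = %d, N = %d at limen d = %.3f\n", x$C, x$N, x$d
  ))
  cat(sprintf("  z_upper: %s (10^%.3f)\n",
              if (!is.na(x$z_upper_exact)) x$z_upper_exact else
                format(x$z_upper, digits = 4), x$log10_z_upper))
  cat(sprintf("  z_lower: %s (10^%.3f)\n",
              if (!is.na(x$z_lower_exact)) x$z_lower_exact else
                format(x$z_lower, digits = 4), x$log10_z_lower))
  invisible(x)
}
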