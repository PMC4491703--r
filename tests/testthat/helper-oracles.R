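# Independent brute-force oracles used across the suite.  These never
# call the code paths they check.

# All N-subsets of 1..C as a list of integer vectors.
enumerate_space <- function(C, N) {
  m <- utils::combn(C, N)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

subset_distance <- function(a, b) length(a) - length(intersect(a, b))

# Ball volume by exhaustive enumeration around the reference subset 1..N.
enum_ball <- function(C, N, r) {
  ref <- seq_len(N)
  as.numeric(sum(vapply(enumerate_space(C, N),
                        function(s) subset_distance(ref, s) <= r,
                        logical(1))))
}

# Greedy maximal packing: subsets kept if pairwise distance exceeds d.
# Any maximal code of minimum distance > d has size between the
# Gilbert-Varshamov and Hamming bounds.
greedy_packing <- function(C, N, d) {
  chosen <- list()
  for (s in enumerate_space(C, N)) {
    ok <- all(vapply(chosen, function(cc) subset_distance(cc, s) > d,
                     logical(1)))
    if (ok) chosen[[length(chosen) + 1L]] <- s
  }
  length(chosen)
}

# Upper binomial tail by direct summation of the mass function.
tail_oracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log1p(-p)))
}

# Closed-form OLS line through (x, y), solved from the normal equations.
ols_oracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = sl, intercept = mean(y) - sl * mean(x))
}

# Exact significance-crossing overlap of the generator's logistic link
# for homogeneous subjects: the overlap at which a unit tested by
# `trials` subjects is significant with probability 1/2.
true_crossing <- function(params, trials, alpha = 0.05, chance = 1/3) {
  kstar <- critical_successes(trials, alpha, chance)
  stats::uniroot(function(o) {
    stats::pbinom(kstar - 1, trials, success_probability(params, o),
                  lower.tail = FALSE) - 0.5
  }, c(0, 100))$root
}

# Small standard trial design for N = 30 pipelines.
design_n30 <- function(pairs_per_class = 20, subjects = 26) {
  experiment_design(
    N = 30, overlaps = list(`30` = c(0, 6, 12, 18, 24, 29)),
    pairs_per_class = pairs_per_class, subjects = subjects
  )
}
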