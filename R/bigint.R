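#' Arbitrary-precision non-negative integers
#'
#' The combinatorics of the mixture stimulus space routinely produce
#' integers far beyond the 2^53 limit of double precision (for example
#' `choose(128, 30)` is on the order of 10^29, and library-size sweeps
#' reach 10^160 and beyond).  Bounds computed from floating-point
#' approximations of those coefficients would be silently wrong in their
#' low-order digits, so all counting in this package is done on an exact
#' big-integer type.
#'
#' A `bigint` stores a non-negative integer as a little-endian vector of
#' base-10000 limbs.  Limbs are doubles holding exact integers < 1e4, so
#' every intermediate product and carry in the schoolbook algorithms
#' below stays well under 2^53 and is exact.
#'
#' @name bigint
#' @keywords internal
NULL

BIG_BASE <- 1e4
BIG_BASE_DIGITS <- 4L

new_bigint <- function(limbs) {
  structure(list(limbs = limbs), class = "bigint")
}

#' Convert a number or digit string to a bigint
#'
#' @param x a single non-negative integer-valued number below 2^53, a
#'   decimal digit string of any length, or a `bigint` (returned as is).
#' @return a `bigint`.
#' @export
#' @examples
#' as_bigint(12345)
#' as_bigint("154216754274170252614034817600")
as_bigint <- function(x) {
  if (inherits(x, "bigint")) {
    return(x)
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    s <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(s)
    starts <- rev(seq(n, 1L, by = -BIG_BASE_DIGITS))
    limbs <- rev(vapply(starts, function(i) {
      as.numeric(substr(s, max(1L, i - BIG_BASE_DIGITS + 1L), i))
    }, numeric(1)))
    return(new_bigint(big_trim(limbs)))
  }
  x <- as.numeric(x)
  stopifnot(length(x) == 1L, is.finite(x), x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- (x - x %% BIG_BASE) / BIG_BASE
    if (x == 0) break
  }
  new_bigint(limbs)
}

big_trim <- function(limbs) {
  k <- length(limbs)
  while (k > 1L && limbs[k] == 0) k <- k - 1L
  limbs[seq_len(k)]
}

# -1 / 0 / +1 comparison of two limb vectors
big_cmp_limbs <- function(a, b) {
  a <- big_trim(a)
  b <- big_trim(b)
  if (length(a) != length(b)) {
    return(if (length(a) > length(b)) 1L else -1L)
  }
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) {
      return(if (a[i] > b[i]) 1L else -1L)
    }
  }
  0L
}

big_add_limbs <- function(a, b) {
  n <- max(length(a), length(b))
  s <- c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- floor(s[i] / BIG_BASE)
    s[i] <- s[i] - carry * BIG_BASE
  }
  if (carry > 0) {
    extra <- numeric(0)
    while (carry > 0) {
      extra <- c(extra, carry %% BIG_BASE)
      carry <- floor(carry / BIG_BASE)
    }
    s <- c(s, extra)
  }
  big_trim(s)
}

# a - b, requires a >= b
big_sub_limbs <- function(a, b) {
  stopifnot(big_cmp_limbs(a, b) >= 0L)
  n <- length(a)
  d <- a - c(b, numeric(n - length(b)))
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + BIG_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  big_trim(d)
}

# multiply limb vector by a small non-negative integer m (m < ~2^40)
big_mul_small_limbs <- function(a, m) {
  stopifnot(m >= 0, m == floor(m))
  if (m == 0) {
    return(0)
  }
  p <- a * m
  out <- numeric(0)
  carry <- 0
  for (i in seq_along(p)) {
    v <- p[i] + carry
    carry <- floor(v / BIG_BASE)
    out <- c(out, v - carry * BIG_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  big_trim(out)
}

# exact division by a small positive integer; errors if not divisible
# unless remainder_ok
big_div_small_limbs <- function(a, m, remainder_ok = FALSE) {
  stopifnot(m >= 1, m == floor(m))
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]
    q[i] <- floor(cur / m)
    rem <- cur - q[i] * m
  }
  if (!remainder_ok && rem != 0) {
    stop("non-exact small division in bigint arithmetic")
  }
  list(q = big_trim(q), r = rem)
}

big_mul_limbs <- function(a, b) {
  if ((length(a) == 1L && a[1] == 0) || (length(b) == 1L && b[1] == 0)) {
    return(0)
  }
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- seq_along(b) + i - 1L
    out[idx] <- out[idx] + a[i] * b
    # normalize eagerly so partial sums stay far below 2^53
    carry <- floor(out / BIG_BASE)
    out <- out - carry * BIG_BASE + c(0, carry[-length(carry)])
    while (any(out >= BIG_BASE)) {
      carry <- floor(out / BIG_BASE)
      out <- out - carry * BIG_BASE + c(0, carry[-length(carry)])
    }
  }
  big_trim(out)
}

# schoolbook long division: returns quotient and remainder limb vectors
big_divmod_limbs <- function(a, b) {
  stopifnot(!(length(b) == 1L && b[1] == 0))
  if (big_cmp_limbs(a, b) < 0L) {
    return(list(q = 0, r = big_trim(a)))
  }
  if (length(b) == 1L) {
    res <- big_div_small_limbs(a, b[1], remainder_ok = TRUE)
    return(list(q = res$q, r = res$r))
  }
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    rem <- big_add_limbs(big_mul_small_limbs(rem, BIG_BASE), a[i])
    # binary search the largest digit with digit*b <= rem
    lo <- 0
    hi <- BIG_BASE - 1
    while (lo < hi) {
      mid <- ceiling((lo + hi) / 2)
      if (big_cmp_limbs(big_mul_small_limbs(b, mid), rem) <= 0L) {
        lo <- mid
      } else {
        hi <- mid - 1
      }
    }
    q[i] <- lo
    if (lo > 0) {
      rem <- big_sub_limbs(rem, big_mul_small_limbs(b, lo))
    }
  }
  list(q = big_trim(q), r = big_trim(rem))
}

big_add <- function(a, b) new_bigint(big_add_limbs(as_bigint(a)$limbs, as_bigint(b)$limbs))
big_sub <- function(a, b) new_bigint(big_sub_limbs(as_bigint(a)$limbs, as_bigint(b)$limbs))
big_mul <- function(a, b) new_bigint(big_mul_limbs(as_bigint(a)$limbs, as_bigint(b)$limbs))

big_cmp <- function(a, b) big_cmp_limbs(as_bigint(a)$limbs, as_bigint(b)$limbs)

#' Floor division of two bigints
#' @param a,b dividend and divisor (`bigint` or coercible).
#' @return list with `bigint` components `q` (quotient) and `r` (remainder).
#' @keywords internal
big_divmod <- function(a, b) {
  res <- big_divmod_limbs(as_bigint(a)$limbs, as_bigint(b)$limbs)
  list(q = new_bigint(big_trim(res$q)), r = new_bigint(big_trim(if (length(res$r) == 0) 0 else res$r)))
}

#' Base-10 logarithm of a bigint
#'
#' Accurate to about 1e-15: the top four limbs (up to 16 decimal
#' digits) are combined in double precision, losing at most one ulp.
#'
#' @param x a `bigint`.
#' @return a double.
#' @export
big_log10 <- function(x) {
  l <- as_bigint(x)$limbs
  k <- length(l)
  if (k == 1L && l[1] == 0) {
    return(-Inf)
  }
  top <- 0
  used <- 0L
  for (i in seq(k, max(1L, k - 3L))) {
    top <- top * BIG_BASE + l[i]
    used <- used + 1L
  }
  log10(top) + BIG_BASE_DIGITS * (k - used)
}

#' @export
as.character.bigint <- function(x, ...) {
  l <- x$limbs
  k <- length(l)
  head <- format(l[k], scientific = FALSE)
  if (k == 1L) {
    return(head)
  }
  rest <- vapply(rev(l[-k]), function(v) {
    formatC(v, width = BIG_BASE_DIGITS, flag = "0", format = "d")
  }, character(1))
  paste0(head, paste(rest, collapse = ""))
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.bigint <- function(x, ...) {
  lg <- big_log10(x)
  if (lg > 308) {
    return(Inf)
  }
  as.numeric(as.character(x))
}

#' @export
"==.bigint" <- function(e1, e2) big_cmp(e1, e2) == 0L

#' Exact binomial coefficient
#'
#' Computes `choose(n, k)` in exact integer arithmetic at any magnitude;
#' no floating-point rounding occurs at any step.  The iterative product
#' `prod (n-k+i)/i` is used, every intermediate division being exact.
#'
#' @param n,k non-negative integers with `k <= n`; `n` may exceed 10^6.
#' @return a [bigint].
#' @export
#' @examples
#' binomial_exact(5, 2)            # 10
#' as.character(binomial_exact(128, 30))
binomial_exact <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, is.finite(n), is.finite(k))
  if (n < 0 || k < 0 || k > n || n != floor(n) || k != floor(k)) {
    stop("binomial_exact requires integers 0 <= k <= n")
  }
  k <- min(k, n - k)
  acc <- as_bigint(1)
  if (k == 0) {
    return(acc)
  }
  limbs <- acc$limbs
  for (i in seq_len(k)) {
    limbs <- big_mul_small_limbs(limbs, n - k + i)
    limbs <- big_div_small_limbs(limbs, i)$q
  }
  new_bigint(limbs)
}
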