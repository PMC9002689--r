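# Exact rational arithmetic for metric computation.
#
# All metrics on an AAE decomposition are ratios of small integer counts.
# Accumulating them in floating point and rounding per term changes printed
# two-decimal values (e.g. an event-distinguishability mean), so sums and
# means are carried as exact numerator/denominator pairs and converted to
# double (or rounded half-up) only at the end. Numerators stay far below
# 2^53, where double-held integer arithmetic is exact.

q_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    r <- ifelse(b == 0, 0, a %% b)
    a <- ifelse(b == 0, a, b)
    b <- r
  }
  ifelse(a == 0, 1, a)
}

q_new <- function(num, den = 1) {
  if (any(den == 0)) stop("rational with zero denominator", call. = FALSE)
  n <- max(length(num), length(den))
  num <- rep_len(num, n); den <- rep_len(den, n)
  num <- num * sign(den); den <- abs(den)
  g <- q_gcd(num, den)
  structure(list(num = num / g, den = den / g), class = "aae_q")
}

q_add <- function(x, y) q_new(x$num * y$den + y$num * x$den, x$den * y$den)
q_mul <- function(x, y) q_new(x$num * y$num, x$den * y$den)
q_div <- function(x, y) q_new(x$num * y$den, x$den * y$num)

q_sum <- function(x) {
  acc <- q_new(0)
  for (i in seq_along(x$num)) acc <- q_add(acc, q_new(x$num[i], x$den[i]))
  acc
}

q_mean <- function(x) q_div(q_sum(x), q_new(length(x$num)))

q_value <- function(x) x$num / x$den

q_is_one <- function(x) x$num == x$den

# Half-up rounding computed on the exact fraction, so values landing exactly
# on a .5 boundary round up regardless of binary representation.
q_round <- function(x, digits = 2) {
  p <- 10^digits
  stopifnot(all(x$num >= 0))
  floor((2 * x$num * p + x$den) / (2 * x$den)) / p
}

#' Round half-up
#'
#' Decimal rounding where ties go away from zero (`0.675` at two decimals
#' gives `0.68`), matching the convention used for all printed metric
#' tables. Base R's [round()] rounds ties to even, which disagrees on
#' boundary values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.675, 0.684, 2/3), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
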