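# exact big-integer arithmetic on little-endian base-1e4 digit vectors;
# enough for protein-space products that overflow doubles
.big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0L)
  d <- integer(0)
  while (x > 0) {
    d <- c(d, as.integer(x %% 10000))
    x <- floor(x / 10000)
  }
  d
}

.big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    res[i:(i + length(b) - 1)] <- res[i:(i + length(b) - 1)] + a[i] * b
  }
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% 10000
    carry <- floor(v / 10000)
  }
  while (carry > 0) {
    res <- c(res, carry %% 10000)
    carry <- floor(carry / 10000)
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  as.integer(res)
}

.big_pow <- function(a, n) {
  out <- .big_from_num(1)
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) out <- .big_mul(out, base)
    base <- .big_mul(base, base)
    n <- n %/% 2
  }
  out
}

.big_to_string <- function(d) {
  if (identical(d, 0L)) return("0")
  paste0(d[length(d)],
         paste(sprintf("%04d", rev(d[-length(d)])), collapse = ""))
}

#' Exact repeat-level sequence space
#'
#' Product of the per-site alternative counts of one repeat module, e.g.
#' `c(87, 60, 16, 3)` for the dipeptide pairs 18-19 and 22-23, position 26 and
#' position 30.
#'
#' @param counts Non-negative integer vector of per-site alternative counts.
#' @return Exact integer product as a numeric (errors if it would exceed the
#'   exact double range; use [protein_space()] for larger products).
#' @export
repeat_space <- function(counts) {
  if (any(counts < 0)) abort("counts must be >= 0")
  p <- prod(counts)
  if (p > 2^53) abort("repeat space exceeds exact double range")
  p
}

#' Exact protein-level sequence space
#'
#' `ncap_space * repeat_space^n` for a protein with `n` internal repeats,
#' computed in exact arbitrary-precision integer arithmetic.
#'
#' @param repeat_space Repeat-level space (non-negative integer).
#' @param ncap_space N-cap variant count (default 1).
#' @param n Number of internal repeats (>= 0).
#' @return Character string holding the exact decimal integer, with attribute
#'   `approx` (numeric approximation).
#' @export
protein_space <- function(repeat_space, ncap_space = 1, n) {
  if (n < 0) abort("`n` must be >= 0")
  big <- .big_mul(.big_from_num(ncap_space),
                  .big_pow(.big_from_num(repeat_space), n))
  out <- .big_to_string(big)
  attr(out, "approx") <- ncap_space * repeat_space^n
  out
}

#' Expected number of distinct variants sampled by a library
#'
#' Under uniform sampling with replacement from a space of `space` equiprobable
#' variants, a library of `library_size` clones is expected to contain
#' `S * (1 - (1 - 1/S)^L)` distinct variants.
#'
#' @param library_size Number of clones L (>= 0).
#' @param space Size of the sequence space S (>= 1).
#' @return Expected distinct count (numeric, `<= min(L, S)`).
#' @export
expected_distinct <- function(library_size, space) {
  if (library_size < 0) abort("`library_size` must be >= 0")
  if (space < 1) abort("`space` must be >= 1")
  if (library_size == 0) return(0)
  space * (-expm1(library_size * log1p(-1 / space)))
}

#' Diversity report across repeat numbers
#'
#' Tabulates repeat-level and protein-level sequence space and the expected
#' distinct variants sampled by a library, for a range of repeat numbers.
#'
#' @param counts Per-site alternative counts of one repeat.
#' @param ncap_space N-cap variant count.
#' @param n_repeats Integer vector of repeat numbers.
#' @param library_size Library size L for coverage accounting.
#' @return Tibble with columns `n`, `repeat_space`, `protein_space` (exact
#'   decimal string), `log10_space`, `expected_distinct`,
#'   `fraction_of_space`.
#' @export
diversity_report <- function(counts, ncap_space = 1, n_repeats = 0:7,
                             library_size = 1.7e9) {
  rs <- repeat_space(counts)
  purrr::map(n_repeats, function(n) {
    ps <- protein_space(rs, ncap_space, n)
    approx <- attr(ps, "approx")
    ed <- if (approx <= 2^53) expected_distinct(library_size, max(approx, 1))
          else library_size  # space astronomically larger than any library
    tibble(n = n,
           repeat_space = rs,
           protein_space = as.character(ps),
           log10_space = log10(approx),
           expected_distinct = ed,
           fraction_of_space = ed / approx)
  }) |>
    bind_rows()
}
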