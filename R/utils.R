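## Small numeric utilities shared across the package.

#' Log binomial coefficient
#'
#' `lchoose2(n, k)` equals `log(choose(n, k))`, returning `-Inf` for
#' infeasible pairs (`k < 0` or `k > n`).
#'
#' @param n,k integer vectors (recycled).
#' @return numeric vector of log binomial coefficients.
#' @keywords internal
lchoose2 <- function(n, k) {
  out <- suppressWarnings(lchoose(n, k))
  out[k < 0 | k > n] <- -Inf
  out
}

#' Binomial ratio weighting emergent-lineage configurations
#'
#' For per-deme vectors of occupancy `n`, lineage count `l`, production `r`
#' and saturation `s`, computes
#' \deqn{\prod_i \binom{n_i-\ell_i}{r_i-s_i} \Big/ \prod_i \binom{n_i}{r_i}}
#' whenever \eqn{n_i \ge \ell_i} and \eqn{r_i \ge s_i \ge 0} for every deme
#' \eqn{i}, and 0 otherwise. This is the probability, under within-deme
#' exchangeability, that the lineages emerging from an event intersect the
#' observed genealogy in exactly the configuration described by `s`. The
#' value always lies in [0, 1].
#'
#' For occupancies up to 20 the computation is exact in integer arithmetic
#' (all binomials involved are small integers); otherwise it is carried out
#' in log space.
#'
#' @param n,l,r,s non-negative integer vectors of common length (one entry
#'   per deme): deme occupancy, lineage count, production, saturation.
#' @return a single number in [0, 1].
#' @examples
#' binomial_ratio(5, 2, 2, 2)  # C(3,0)/C(5,2) = 0.1
#' binomial_ratio(c(3, 5), c(1, 1), c(2, 1), c(1, 1))
#' @export
binomial_ratio <- function(n, l, r, s) {
  stopifnot(length(n) == length(l), length(n) == length(r), length(n) == length(s))
  if (any(s < 0) || any(r < s) || any(n < l)) return(0)
  if (any(r > n)) return(0)
  if (all(n <= 20L)) {
    num <- prod(choose(n - l, r - s))
    den <- prod(choose(n, r))
    if (den == 0) return(0)
    return(num / den)
  }
  lg <- sum(lchoose2(n - l, r - s)) - sum(lchoose2(n, r))
  exp(lg)
}

#' log(sum(exp(x))) without overflow
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Enumerate all compositions of `total` into `k` non-negative parts,
## returned as a matrix with k columns, one row per composition.
compositions <- function(total, k) {
  if (k == 1L) return(matrix(total, ncol = 1L))
  out <- vector("list", total + 1L)
  for (first in 0:total) {
    rest <- compositions(total - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

## Enumerate all vectors v with 0 <= v <= upper (componentwise), as rows.
## `upper` is a vector of small non-negative integers.
lattice_box <- function(upper) {
  grid <- lapply(upper, function(u) 0:u)
  as.matrix(rev(expand.grid(rev(grid))))
}
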