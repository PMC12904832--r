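## Exact summation of doubles via error-free transformations.
##
## Every IEEE 754 double is a rational number, so a finite set of doubles has
## an exact real sum. We represent it as a non-overlapping expansion of
## doubles (Shewchuk-style): the two-term transformation
## s = fl(a + b), err = (a - (s - bv)) + (b - bv) with bv = s - a recovers
## the rounding error of each addition exactly, and threading each input
## through the expansion keeps the invariant that the components sum to the
## exact total. This is the independent accuracy reference against which the
## pairwise-tree and left-fold summation orders are measured; no rounding
## error is incurred until the final read-out.

twoSum <- function(a, b) {
  s <- a + b
  bv <- s - a
  err <- (a - (s - bv)) + (b - bv)
  c(s, err)
}

#' Exact sum of doubles as a floating-point expansion
#'
#' @param values numeric vector (finite).
#' @return numeric vector of non-overlapping components whose exact
#'   mathematical sum equals the exact sum of \code{values}; components are
#'   ordered by increasing magnitude.
#' @examples
#' exactSum(c(1e16, 1, 1, -1e16))  # component 2: the bits 1e16 absorbs
#' @export
exactSum <- function(values) {
  if (length(values) == 0L) stop("empty reduction")
  if (any(!is.finite(values))) stop("exactSum requires finite values")
  e <- numeric(0)
  for (x in values) {
    q <- x
    enew <- numeric(0)
    for (comp in e) {
      r <- twoSum(q, comp)
      q <- r[1L]
      if (r[2L] != 0) enew <- c(enew, r[2L])
    }
    if (q != 0 || length(enew) == 0L) enew <- c(enew, q)
    e <- enew
  }
  e
}

#' Absolute error of an approximate sum against the exact sum
#'
#' Appends \code{-approx} to the exact expansion of \code{values} and reads
#' out the residual; the only rounding happens when collapsing the residual
#' expansion to one double, so the reported error is accurate to full double
#' precision.
#'
#' @param values numeric vector.
#' @param approx the approximate sum to score.
#' @return absolute error as a double.
#' @export
sumError <- function(values, approx) {
  resid <- exactSum(c(values, -approx))
  abs(sum(resid))  # components span disjoint magnitude ranges: safe read-out
}
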