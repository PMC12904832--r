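#' Build the fixed binary reduction tree over n elements
#'
#' Constructs the balanced binary tree whose post-order traversal defines the
#' bit-exact order in which the reduction operator is applied. An interval
#' \code{[a, b)} with two or more elements splits at \code{a + ceiling((b-a)/2)},
#' so the left half is never smaller than the right; singleton intervals are
#' leaves. The shape is a function of \code{n} alone -- it never depends on
#' the PE count or the data distribution -- and the sequential pairwise
#' oracle ([pairwiseReduce()]) evaluates the identical shape.
#'
#' @param n number of input elements (>= 1).
#' @return a \linkS4class{ReductionTree} with nodes numbered in post-order.
#' @examples
#' rt <- buildReductionTree(5)
#' nLeaves(rt)
#' @export
buildReductionTree <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("empty reduction: n must be >= 1 (no identity element is assumed)")
  m <- 2L * n - 1L
  parent <- integer(m)
  leftChild <- integer(m)
  rightChild <- integer(m)
  leafIndex <- rep(NA_integer_, m)
  intervalStart <- integer(m)
  intervalEnd <- integer(m)
  height <- integer(m)
  k <- 0L
  rec <- function(a, b) {
    if (b - a == 1L) {
      k <<- k + 1L
      leafIndex[k] <<- a
      intervalStart[k] <<- a
      intervalEnd[k] <<- b
      return(k)
    }
    mid <- a + (b - a + 1L) %/% 2L   # ceiling split
    l <- rec(a, mid)
    r <- rec(mid, b)
    k <<- k + 1L
    leftChild[k] <<- l
    rightChild[k] <<- r
    parent[l] <<- k
    parent[r] <<- k
    intervalStart[k] <<- a
    intervalEnd[k] <<- b
    height[k] <<- max(height[l], height[r]) + 1L
    k
  }
  rec(0L, n)
  new("ReductionTree", nLeaves = n, parent = parent, leftChild = leftChild,
      rightChild = rightChild, leafIndex = leafIndex,
      intervalStart = intervalStart, intervalEnd = intervalEnd,
      height = height)
}
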