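## Sequential oracles and the reproducible / non-reproducible baseline
## reductions that the distributed engine is measured against.

#' Sequential pairwise oracle: the bit-exact ground truth
#'
#' Evaluates the fixed balanced reduction tree left-to-right in post-order on
#' a single PE, applying the operator as (left subtree value) op (right
#' subtree value) at each internal node. Every distributed execution, for
#' every PE count, degree and ownership map, must reproduce this value
#' bitwise. Implemented directly by recursion on the ceiling-split interval
#' rule, independent of the schedule machinery it validates.
#'
#' @param values input array (length >= 1).
#' @param op a \linkS4class{ReductionOperator} (default \code{"float-add"}).
#' @return the reduction result.
#' @examples
#' pairwiseReduce(c("a", "b", "c"), makeOperator("concat"))  # "abc"
#' @export
pairwiseReduce <- function(values, op = makeOperator("float-add")) {
  n <- length(values)
  if (n == 0L) stop("empty reduction")
  rec <- function(a, b) {      # half-open [a, b), 0-based
    if (b - a == 1L) return(values[[a + 1L]])
    mid <- a + (b - a + 1L) %/% 2L
    op@fun(rec(a, mid), rec(mid, b))
  }
  rec(0L, n)
}

#' Strict left-to-right fold
#'
#' Reduces all elements in the fixed order e0 op e1 op ... op e(n-1), one
#' accumulator, rounding after every step. This is the reference semantics of
#' the Gather-Bcast baseline and the per-PE local reduction of the
#' non-reproducible baseline. (Note R's \code{sum()} may accumulate in
#' extended precision and is deliberately not used.)
#'
#' @inheritParams pairwiseReduce
#' @return the fold result.
#' @export
foldReduce <- function(values, op = makeOperator("float-add")) {
  n <- length(values)
  if (n == 0L) stop("empty reduction")
  acc <- values[[1L]]
  for (i in seq_len(n - 1L)) acc <- op@fun(acc, values[[i + 1L]])
  acc
}

#' Gather-Bcast: the reproducible-but-serial baseline
#'
#' Gathers all elements on the root PE, which reassembles the global element
#' order and folds left to right, then broadcasts the result. Reproducible
#' for any PE count and ownership (the result is bitwise
#' [foldReduce()]), but the root is a bottleneck: it receives p - 1 messages
#' and all n elements, and the fold has no parallelism.
#'
#' @param values input array of length n.
#' @param ownership integer length-n element-to-PE map (0-based).
#' @param op a \linkS4class{ReductionOperator}.
#' @param p PE count (defaults to the largest owner + 1).
#' @return list with \code{value} and \code{stats} (\code{rootMessages} =
#'   p - 1, \code{rootElements} = n).
#' @export
gatherBcastReduce <- function(values, ownership,
                              op = makeOperator("float-add"),
                              p = max(ownership) + 1L) {
  n <- length(values)
  ownership <- as.integer(ownership)
  if (length(ownership) != n) stop("ownership must cover all elements")
  if (any(ownership < 0L) || any(ownership >= p))
    stop("ownership references a PE outside [0, p)")
  ## gather: each PE ships (index, value) pairs; root restores global order,
  ## so the fold below is over e0..e(n-1) regardless of the distribution
  idxByPE <- split(0:(n - 1L), factor(ownership, levels = 0:(p - 1L)))
  gatheredIdx <- unlist(idxByPE, use.names = FALSE)
  gathered <- values[gatheredIdx + 1L]
  restored <- gathered[order(gatheredIdx)]
  list(value = foldReduce(restored, op),
       stats = list(rootMessages = p - 1L, rootElements = n))
}

#' Non-reproducible per-PE baseline reduction
#'
#' The conventional scheme: each PE left-folds its locally owned elements
#' (in global index order) into one intermediate per-PE result; the per-PE
#' partials are then folded in PE-rank order (PEs owning nothing contribute
#' no partial). Because the grouping -- and hence the rounding -- depends on
#' how elements are distributed, the floating-point result generally changes
#' with p: this is the phenomenon the fixed-order reduction removes.
#'
#' @param values input array of length n.
#' @param ownership integer length-n element-to-PE map (0-based).
#' @param p PE count.
#' @param op a \linkS4class{ReductionOperator}.
#' @return the (p-dependent, for floats) reduction value.
#' @export
naiveReduce <- function(values, ownership, p,
                        op = makeOperator("float-add")) {
  n <- length(values)
  p <- as.integer(p)
  ownership <- as.integer(ownership)
  if (length(ownership) != n) stop("ownership must cover all elements")
  if (any(ownership < 0L) || any(ownership >= p))
    stop("ownership references a PE outside [0, p)")
  idxByPE <- split(seq_len(n), factor(ownership, levels = 0:(p - 1L)))
  partials <- lapply(idxByPE[lengths(idxByPE) > 0L],
                     function(i) foldReduce(values[i], op))
  foldReduce(partials, op)
}
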