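## Built-in reduction operators. The engine applies every operator as
## (earlier post-order value) op (later post-order value), i.e. the value
## popped second combines with the value popped first; commutativity is never
## assumed, which is why the non-commutative concat monoid works and serves
## as a complete witness of the realized operation order.

operatorRegistry <- list(
  "float-add" = list(fun = function(a, b) a + b, commutative = TRUE,
                     nativeId = 1L),
  "float-mul" = list(fun = function(a, b) a * b, commutative = TRUE,
                     nativeId = 2L),
  "max" = list(fun = function(a, b) max(a, b), commutative = TRUE,
               nativeId = 3L),
  "int-add" = list(fun = function(a, b) a + b, commutative = TRUE,
                   nativeId = 4L),
  "concat" = list(fun = function(a, b) paste0(a, b), commutative = FALSE,
                  nativeId = 0L)
)

#' Create a built-in reduction operator
#'
#' Registry: \code{"float-add"}, \code{"float-mul"} and \code{"max"} over
#' 64-bit IEEE 754 doubles; \code{"int-add"} for integer-valued input (exact,
#' hence order-free, below 2^53); and \code{"concat"}, the non-commutative
#' token-concatenation monoid used as an order witness. Numeric operators
#' carry a compiled fast path; results are bitwise identical between the
#' compiled and the reference engine because both apply the same operations
#' in the same order in plain double arithmetic.
#'
#' @param name registry name.
#' @return a \linkS4class{ReductionOperator}.
#' @examples
#' op <- makeOperator("concat")
#' op@fun("x", "y")  # "xy"
#' @export
makeOperator <- function(name) {
  entry <- operatorRegistry[[name]]
  if (is.null(entry))
    stop(sprintf("unknown operator '%s'; available: %s", name,
                 paste(names(operatorRegistry), collapse = ", ")))
  new("ReductionOperator", name = name, fun = entry$fun,
      commutative = entry$commutative, nativeId = entry$nativeId)
}

#' Hexadecimal floating-point representation
#'
#' The canonical comparison format for bit-level equality of doubles:
#' decimal printing can mask differences in the last bits, the C99 \code{%a}
#' format cannot, and it round-trips exactly through [as.numeric()].
#'
#' @param x numeric vector.
#' @return character vector of hex-float literals.
#' @examples
#' hexFloat(0.1)
#' as.numeric(hexFloat(0.1)) == 0.1
#' @export
hexFloat <- function(x) sprintf("%a", x)
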