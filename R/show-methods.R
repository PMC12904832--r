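## show() methods and small accessors

#' Number of leaves / input elements
#' @param x a ReductionTree or Schedule
#' @return integer count of input elements
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @rdname nLeaves
#' @export
setMethod("nLeaves", "ReductionTree", function(x) x@nLeaves)

#' @rdname nLeaves
#' @export
setMethod("nLeaves", "Schedule", function(x) x@nLeaves)

#' Number of processing elements
#' @param x a CommTree or Schedule
#' @return integer PE count
#' @export
setGeneric("peCount", function(x) standardGeneric("peCount"))

#' @rdname peCount
#' @export
setMethod("peCount", "CommTree", function(x) x@nPE)

#' @rdname peCount
#' @export
setMethod("peCount", "Schedule", function(x) x@nPE)

#' Taxon labels
#' @param x an MSA or BipartitionSet
#' @return character vector of labels
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname taxa
#' @export
setMethod("taxa", "MSA", function(x) x@labels)

#' @rdname taxa
#' @export
setMethod("taxa", "BipartitionSet", function(x) x@taxa)

#' Number of alignment sites
#' @param x an MSA
#' @return integer site count
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname nSites
#' @export
setMethod("nSites", "MSA", function(x) ncol(x@seqs))

setMethod("show", "ReductionTree", function(object) {
  cat(sprintf("ReductionTree: %d leaves, %d internal nodes, height %d\n",
              object@nLeaves, object@nLeaves - 1L,
              max(object@height)))
})

setMethod("show", "CommTree", function(object) {
  cat(sprintf("CommTree: %d PEs, degree %d, %d edges, depth %d\n",
              object@nPE, object@degree, object@nPE - 1L, max(object@depth)))
})

setMethod("show", "ReductionOperator", function(object) {
  cat(sprintf("ReductionOperator '%s' (%scommutative%s)\n", object@name,
              if (object@commutative) "" else "non-",
              if (object@nativeId > 0L) ", native fast path" else ""))
})

setMethod("show", "Schedule", function(object) {
  nops <- vapply(object@programs, nrow, 1L)
  payload <- sum(lengths(object@manifests))
  cat(sprintf(paste0("Schedule: n = %d elements on p = %d PEs (degree %d)\n",
                     "  %d messages, %d transported values, ops/PE: %s\n"),
              object@nLeaves, object@nPE, object@degree,
              object@nPE - 1L, payload,
              paste(nops, collapse = " ")))
})

setMethod("show", "MSA", function(object) {
  cat(sprintf("MSA: %d taxa, %d sites\n", length(object@labels),
              ncol(object@seqs)))
})

setMethod("show", "BipartitionSet", function(object) {
  cat(sprintf("BipartitionSet: %d taxa, %d non-trivial splits\n",
              length(object@taxa), length(object@splits)))
})
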