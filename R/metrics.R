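## Divergence metrics between trees from repeated runs.

#' Non-trivial bipartitions of a tree
#'
#' Enumerates, for every inner edge, the split of the taxon set obtained by
#' cutting that edge. Trivial splits (a single taxon against the rest, or
#' the split induced by the root of a rooted representation) are dropped;
#' each remaining split is canonicalized as the sorted side that does not
#' contain the reference taxon (the lexicographically smallest label), so
#' split identity is independent of rooting and label order in the file.
#'
#' @param tree an \code{ape} \code{phylo}; multifurcations are allowed
#'   (they simply induce fewer splits).
#' @return a \linkS4class{BipartitionSet}.
#' @examples
#' t <- readNewickTree(text = "((A,B),(C,D));")
#' bipartitions(t)  # one split: {A,B}
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  if (anyDuplicated(labels)) stop("duplicate taxa in tree")
  nTip <- length(labels)
  ref <- sort(labels)[1L]
  splits <- list()
  if (nTip >= 4L) {
    tr <- ape::reorder.phylo(tree, "postorder")
    root <- nTip + 1L
    nNode <- max(tr$edge)
    below <- vector("list", nNode)
    for (i in seq_len(nTip)) below[[i]] <- labels[i]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
      below[[par]] <- c(below[[par]], below[[chd]])
    }
    inner <- tr$edge[, 2L][tr$edge[, 2L] > nTip & tr$edge[, 1L] >= root]
    seen <- character(0)
    for (v in inner) {
      side <- below[[v]]
      if (length(side) < 2L || length(side) > nTip - 2L) next
      if (ref %in% side) side <- setdiff(labels, side)
      side <- sort(side)
      key <- paste(side, collapse = "\r")
      if (key %in% seen) next   # the root's two child edges induce one split
      seen <- c(seen, key)
      splits <- c(splits, list(side))
    }
  }
  new("BipartitionSet", taxa = labels, splits = splits)
}

splitKeys <- function(bp) {
  vapply(bp@splits, function(s) paste(s, collapse = "\r"), "")
}

#' Relative Robinson-Foulds distance between two trees
#'
#' The proportion of non-trivial bipartitions that differ between the two
#' trees: |B1 symdiff B2| / (|B1| + |B2|), which for two fully binary trees
#' equals the classic RF distance normalized by 2(n - 3). Defined as 0 when
#' both trees have no non-trivial splits. A value of 0 means topologically
#' identical; 1 means no shared internal structure.
#'
#' @param t1,t2 \code{ape} \code{phylo} trees over the identical taxon set.
#' @return a number in [0, 1].
#' @examples
#' a <- readNewickTree(text = "((A,B),(C,D));")
#' b <- readNewickTree(text = "((A,C),(B,D));")
#' relativeRF(a, b)  # 1
#' @export
relativeRF <- function(t1, t2) {
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  if (!setequal(b1@taxa, b2@taxa)) stop("trees have different taxon sets")
  k1 <- splitKeys(b1); k2 <- splitKeys(b2)
  denom <- length(k1) + length(k2)
  if (denom == 0L) return(0)
  sym <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  sym / denom
}

#' Classify divergence among repeated runs
#'
#' Given records of runs that differ only in their parallelization setting,
#' reports whether the runs diverged (at least two topologically distinct
#' trees), how many distinct topologies occurred, the pairwise relative RF
#' matrix, and the maximum log-likelihood difference. Topologically distinct
#' pairs whose log-likelihood gap is below \code{llThreshold} (default 1e-3
#' log units) are treated as not significantly different; pairs exceeding it
#' are marked \code{"requires external AU test"} -- the significance test
#' itself is statistical software outside this package's scope.
#'
#' @param records list of run records, each a list with elements
#'   \code{label}, \code{tree} (an \code{ape} \code{phylo}) and
#'   \code{logLik}.
#' @param llThreshold log-likelihood equivalence threshold.
#' @return a list (class \code{divergenceReport}) with elements
#'   \code{diverging}, \code{nTopologies}, \code{rfMatrix},
#'   \code{maxLogLikDiff}, \code{exceedsThreshold} and \code{pairs} (a
#'   data.frame with one row per run pair).
#' @export
classifyDivergence <- function(records, llThreshold = 1e-3) {
  if (length(records) < 2L) stop("need at least 2 run records")
  labels <- vapply(records, function(r) as.character(r$label), "")
  lls <- vapply(records, function(r) as.numeric(r$logLik), 0)
  k <- length(records)
  taxa0 <- sort(records[[1L]]$tree$tip.label)
  for (r in records)
    if (!identical(sort(r$tree$tip.label), taxa0))
      stop("all runs must be over the identical taxon set")
  rf <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rf[i, j] <- rf[j, i] <- relativeRF(records[[i]]$tree, records[[j]]$tree)
  }
  ## distinct topologies: equivalence classes under RF == 0
  classId <- integer(k)
  nextId <- 0L
  for (i in seq_len(k)) {
    if (classId[i] > 0L) next
    nextId <- nextId + 1L
    classId[i] <- nextId
    if (i < k) for (j in (i + 1L):k)
      if (classId[j] == 0L && rf[i, j] == 0) classId[j] <- nextId
  }
  pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    do.call(rbind, lapply((i + 1L):k, function(j) {
      gap <- abs(lls[i] - lls[j])
      distinct <- rf[i, j] > 0
      data.frame(run1 = labels[i], run2 = labels[j], relRF = rf[i, j],
                 logLikDiff = gap,
                 assessment = if (!distinct) "same topology"
                 else if (gap < llThreshold) "not significantly different"
                 else "requires external AU test",
                 stringsAsFactors = FALSE)
    }))
  }))
  report <- list(
    diverging = nextId >= 2L,
    nTopologies = nextId,
    rfMatrix = rf,
    maxLogLikDiff = max(abs(outer(lls, lls, "-"))),
    exceedsThreshold = max(abs(outer(lls, lls, "-"))) >= llThreshold,
    llThreshold = llThreshold,
    pairs = pairs
  )
  class(report) <- "divergenceReport"
  report
}

#' @export
print.divergenceReport <- function(x, ...) {
  cat(sprintf("Divergence report: %s (%d distinct topolog%s among %d runs)\n",
              if (x$diverging) "DIVERGING" else "not diverging",
              x$nTopologies, if (x$nTopologies == 1L) "y" else "ies",
              nrow(x$rfMatrix)))
  cat(sprintf("max |log-likelihood difference| = %g (threshold %g%s)\n",
              x$maxLogLikDiff, x$llThreshold,
              if (x$exceedsThreshold) ", exceeded" else ""))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Serialize a divergence report to JSON
#'
#' @param report a report from [classifyDivergence()].
#' @param path optional output file.
#' @return the JSON string, or \code{path} invisibly.
#' @export
divergenceToJSON <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$rfMatrix <- as.data.frame(obj$rfMatrix)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
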