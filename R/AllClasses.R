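## Central S4 classes. Conventions used throughout the package:
##  - element indices and PE ids are 0-based (as in message-passing ranks);
##  - reduction-tree nodes are identified by their 1-based post-order position,
##    so children always carry a smaller id than their parent.

#' @import methods
NULL

## schedule opcodes
OP_PUSH_LOCAL <- 1L
OP_PUSH_RECV  <- 2L
OP_REDUCE     <- 3L
OPCODE_NAMES  <- c("PUSH_LOCAL", "PUSH_RECV", "REDUCE")

#' ReductionTree: the fixed binary operation-order tree
#'
#' A balanced binary tree over the \code{n} globally ordered input elements.
#' Its post-order traversal defines the exact order in which the associative
#' operator is applied; the shape depends only on \code{n}, never on the PE
#' count or the data distribution, which is what makes results
#' bit-reproducible. Nodes are indexed by post-order position (1-based);
#' leaves carry a 0-based element index, internal nodes carry their two
#' children, and every node records the half-open interval of leaf element
#' indices it covers.
#'
#' @slot nLeaves number of input elements (n >= 1).
#' @slot parent integer, post-order id of each node's parent (0 at the root).
#' @slot leftChild,rightChild integer, child ids (0 for leaves).
#' @slot leafIndex integer, 0-based element index (NA for internal nodes).
#' @slot intervalStart,intervalEnd integer, covered element interval [a, b),
#'   0-based.
#' @slot height integer, 0 for leaves, 1 + max(children) otherwise.
#'
#' @seealso [buildReductionTree()]
#' @export
setClass("ReductionTree",
  representation(
    nLeaves = "integer",
    parent = "integer",
    leftChild = "integer",
    rightChild = "integer",
    leafIndex = "integer",
    intervalStart = "integer",
    intervalEnd = "integer",
    height = "integer"
  )
)

setValidity("ReductionTree", function(object) {
  n <- object@nLeaves
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("nLeaves must be a single positive integer")
  m <- 2L * n - 1L
  slots <- list(object@parent, object@leftChild, object@rightChild,
                object@leafIndex, object@intervalStart, object@intervalEnd,
                object@height)
  if (any(vapply(slots, length, 1L) != m))
    return(sprintf("all node vectors must have length 2n-1 = %d", m))
  isLeaf <- object@leftChild == 0L
  if (sum(isLeaf) != n) return("a binary tree over n leaves has exactly n leaves")
  if (sum(!isLeaf) != n - 1L) return("expected n-1 internal nodes")
  if (anyNA(object@leafIndex[isLeaf]) ||
      !setequal(object@leafIndex[isLeaf], 0:(n - 1L)))
    return("leaves must carry each element index exactly once")
  int <- which(!isLeaf)
  if (length(int)) {
    l <- object@leftChild[int]; r <- object@rightChild[int]
    if (any(l >= int) || any(r >= int) || any(l >= r))
      return("post-order numbering violated (children must precede parent)")
    ok <- object@intervalStart[int] == object@intervalStart[l] &
      object@intervalEnd[int] == object@intervalEnd[r] &
      object@intervalEnd[l] == object@intervalStart[r]
    if (!all(ok))
      return("internal intervals must be the contiguous union of the children's")
  }
  if (object@parent[m] != 0L || any(object@parent[-m] == 0L))
    return("exactly the last (root) node may lack a parent")
  TRUE
})

#' CommTree: the k-nomial communication tree over PEs
#'
#' Defines who messages whom: each of the \code{p} PEs except the root (PE 0)
#' has exactly one parent, giving the minimal p-1 communication edges for a
#' reduction. The parent of PE r is obtained by clearing the lowest nonzero
#' base-k digit of r, which for k = 2 yields the classic binomial tree.
#' The tree depends only on (p, k).
#'
#' @slot nPE number of PEs (p >= 1).
#' @slot degree the k of the k-nomial construction (k >= 2; default trees use
#'   k = 2).
#' @slot parent integer vector of length p; entry r+1 is the parent PE of PE
#'   r (NA for the root, PE 0).
#' @slot depth integer vector of length p; number of edges to the root
#'   (= number of nonzero base-k digits of the rank).
#'
#' @seealso [buildCommTree()], [commLCA()]
#' @export
setClass("CommTree",
  representation(
    nPE = "integer",
    degree = "integer",
    parent = "integer",
    depth = "integer"
  )
)

setValidity("CommTree", function(object) {
  p <- object@nPE
  if (length(p) != 1L || is.na(p) || p < 1L) return("nPE must be >= 1")
  if (object@degree < 2L) return("degree must be >= 2")
  if (length(object@parent) != p || length(object@depth) != p)
    return("parent and depth must have length p")
  if (!is.na(object@parent[1L]) || object@depth[1L] != 0L)
    return("PE 0 must be the root")
  if (p > 1L) {
    par <- object@parent[-1L]
    if (anyNA(par) || any(par < 0L) || any(par >= (1:(p - 1L))))
      return("each non-root PE needs a parent with a smaller rank")
    if (any(object@depth[-1L] != object@depth[par + 1L] + 1L))
      return("depth must increase by one along each edge")
  }
  TRUE
})

#' ReductionOperator: an associative binary operation
#'
#' Wraps the binary function applied at every internal reduction-tree node.
#' The engine applies it strictly as (earlier post-order value, later
#' post-order value); commutativity is recorded for information only and is
#' never exploited, so non-commutative monoids (e.g. string concatenation)
#' are valid operators and serve as order witnesses.
#'
#' @slot name registry name of the operator.
#' @slot fun binary function of two values.
#' @slot commutative logical flag (informational).
#' @slot nativeId internal id (> 0) when a compiled fast path exists for the
#'   operator, 0 otherwise.
#'
#' @seealso [makeOperator()]
#' @export
setClass("ReductionOperator",
  representation(
    name = "character",
    fun = "function",
    commutative = "logical",
    nativeId = "integer"
  )
)

#' Schedule: compiled per-PE stack-machine programs
#'
#' The pre-processed artifact executed at reduce time. Each PE holds an
#' ordered list of ops -- PUSH_LOCAL(element index), PUSH_RECV(child PE),
#' REDUCE(node id) -- sorted by the global post-order position of the
#' corresponding reduction-tree node, plus a message manifest: for every
#' communication-tree edge, the ordered list of reduction-tree node ids whose
#' values the (single) message over that edge carries. A PE's residual stack
#' after its last op is, bottom to top, exactly its outgoing message.
#'
#' @slot nLeaves,nPE,degree the (n, p, k) the schedule was compiled for.
#' @slot ownership integer length-n map, element index (0-based) -> owner PE.
#' @slot programs list of length p; element r+1 is an integer matrix with
#'   columns \code{pos} (post-order node id), \code{opcode} (1 = PUSH_LOCAL,
#'   2 = PUSH_RECV, 3 = REDUCE) and \code{arg} (element index, sender PE, or
#'   node id respectively).
#' @slot manifests named list keyed by sending PE (as character); integer
#'   vectors of node ids in post-order, possibly empty. Every non-root PE has
#'   an entry (empty messages are kept for manifest uniformity).
#' @slot commParent the communication-tree parent vector (as in
#'   \linkS4class{CommTree}), kept so a schedule is self-contained at
#'   execution time.
#'
#' @seealso [compileSchedule()], [executeReduce()], [scheduleStats()]
#' @export
setClass("Schedule",
  representation(
    nLeaves = "integer",
    nPE = "integer",
    degree = "integer",
    ownership = "integer",
    programs = "list",
    manifests = "list",
    commParent = "integer"
  )
)

setValidity("Schedule", function(object) {
  n <- object@nLeaves; p <- object@nPE
  if (length(object@programs) != p) return("one program per PE required")
  if (length(object@ownership) != n) return("ownership must cover all n elements")
  if (any(object@ownership < 0L) || any(object@ownership >= p))
    return("ownership references a PE outside [0, p)")
  ops <- do.call(rbind, object@programs)
  if (sum(ops[, "opcode"] == OP_PUSH_LOCAL) != n)
    return("total PUSH_LOCAL count must equal n")
  if (sum(ops[, "opcode"] == OP_REDUCE) != n - 1L)
    return("total REDUCE count must equal n-1")
  for (prog in object@programs) {
    if (is.unsorted(prog[, "pos"], strictly = TRUE))
      return("each PE's ops must be strictly ordered by post-order position")
  }
  if (p > 1L && !setequal(names(object@manifests), as.character(1:(p - 1L))))
    return("every non-root PE must have a manifest entry")
  ## residual stack depth = outgoing message length (root: 1)
  for (r in seq_len(p) - 1L) {
    prog <- object@programs[[r + 1L]]
    depth <- sum(prog[, "opcode"] != OP_REDUCE) - sum(prog[, "opcode"] == OP_REDUCE)
    want <- if (r == 0L) 1L else length(object@manifests[[as.character(r)]])
    if (depth != want)
      return(sprintf("PE %d residual stack depth %d != expected %d", r, depth, want))
  }
  TRUE
})

#' MSA: a multiple sequence alignment with fixed site order
#'
#' Minimal alignment container for the likelihood demonstrator. The column
#' order as given in the input file is the global site order that fixes the
#' accumulation order of per-site log-likelihoods; sites are deliberately not
#' deduplicated. Alphabet: A, C, G, T, - and N (lowercase input is
#' uppercased; gaps and N contribute all-ones partials).
#'
#' @slot labels unique taxon labels.
#' @slot seqs character matrix (taxa x sites) of single characters.
#'
#' @seealso [readAlignment()], [siteLogLikelihoods()]
#' @export
setClass("MSA", representation(labels = "character", seqs = "matrix"))

setValidity("MSA", function(object) {
  if (length(object@labels) < 2L) return("an alignment needs at least 2 taxa")
  if (anyDuplicated(object@labels)) return("duplicate sequence labels")
  if (nrow(object@seqs) != length(object@labels))
    return("one sequence row per label required")
  if (ncol(object@seqs) < 1L) return("alignment has no sites")
  bad <- setdiff(unique(as.vector(object@seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    return(paste0("non-IUPAC character(s) in alignment: ",
                  paste(bad, collapse = " ")))
  TRUE
})

#' BipartitionSet: the non-trivial splits of a tree
#'
#' Each internal (inner) edge of an unrooted tree splits the taxon set in
#' two; the set of these non-trivial bipartitions fully describes the
#' topology and is the basis of the relative Robinson-Foulds distance. Splits
#' are stored canonically as the sorted side that does not contain the
#' reference taxon (the lexicographically smallest label of the universe).
#'
#' @slot taxa the taxon universe.
#' @slot splits list of character vectors, one canonical split per inner
#'   edge.
#'
#' @seealso [bipartitions()], [relativeRF()]
#' @export
setClass("BipartitionSet",
  representation(taxa = "character", splits = "list"))

setValidity("BipartitionSet", function(object) {
  n <- length(object@taxa)
  if (anyDuplicated(object@taxa)) return("duplicate taxa")
  for (s in object@splits) {
    if (length(s) < 2L || length(s) > n - 2L)
      return("splits must be non-trivial (2 <= size <= n-2)")
    if (!all(s %in% object@taxa)) return("split contains unknown taxon")
  }
  TRUE
})
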