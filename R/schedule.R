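#' Compile per-PE stack-machine schedules for a distributed reduction
#'
#' The pre-processing step run once per data distribution. Every leaf's
#' PUSH_LOCAL goes to the PE owning that element; every internal
#' reduction-tree node's REDUCE goes to the lowest common ancestor (in the
#' communication tree) of its children's PEs; the final result is routed to
#' the communication root, PE 0. A value produced on one PE and consumed on
#' an ancestor PE travels hop by hop along the communication tree, appearing
#' as a PUSH_RECV (at the producing node's post-order position) on every PE
#' it passes through -- forwarding included. Each PE's op list is sorted by
#' global post-order position, which guarantees that a sender's residual
#' stack already holds its outgoing message in exactly the order the receiver
#' expects.
#'
#' PEs that own no elements still occupy their communication-tree position;
#' if they have nothing to produce or forward they send an empty message
#' (kept, so every edge carries exactly one message and the manifest is
#' uniform).
#'
#' @param rt a \linkS4class{ReductionTree} over n elements.
#' @param ct a \linkS4class{CommTree} over p PEs.
#' @param ownership integer vector of length n mapping element index
#'   (0-based) to owner PE (0-based); arbitrary, not necessarily contiguous.
#' @return a \linkS4class{Schedule}.
#' @examples
#' rt <- buildReductionTree(4)
#' ct <- buildCommTree(2)
#' s <- compileSchedule(rt, ct, c(0, 0, 1, 1))
#' scheduleStats(s)$messages  # 1
#' @export
compileSchedule <- function(rt, ct, ownership) {
  stopifnot(is(rt, "ReductionTree"), is(ct, "CommTree"))
  n <- rt@nLeaves
  p <- ct@nPE
  k <- ct@degree
  ownership <- as.integer(ownership)
  if (length(ownership) != n)
    stop(sprintf("ownership must cover all %d elements", n))
  if (anyNA(ownership) || any(ownership < 0L))
    stop("ownership entries must be PE ids >= 0")
  if (any(ownership >= p))
    stop(sprintf("ownership references PE >= p = %d", p))

  m <- 2L * n - 1L
  isLeaf <- rt@leftChild == 0L
  leafIds <- which(isLeaf)

  ## 1. executing PE per node, bottom-up by height (children always have a
  ##    strictly smaller height, so level order is a valid evaluation order)
  exec <- integer(m)
  exec[leafIds] <- ownership[rt@leafIndex[leafIds] + 1L]
  if (n > 1L) {
    maxh <- rt@height[m]
    for (h in seq_len(maxh)) {
      idx <- which(rt@height == h & !isLeaf)
      if (length(idx))
        exec[idx] <- pairLCA(exec[rt@leftChild[idx]], exec[rt@rightChild[idx]], k)
    }
  }

  ## 2. consuming PE per node: the PE executing the parent REDUCE; the
  ##    overall result is consumed by the communication root, PE 0
  par <- rt@parent
  consumer <- exec[pmax(par, 1L)]
  consumer[par == 0L] <- 0L

  ## 3. route every value from its producer to its consumer along the
  ##    communication tree; each hop contributes one manifest entry and one
  ##    PUSH_RECV on the hop's receiving PE
  hopNode <- integer(0)
  hopSender <- integer(0)
  active <- which(exec != consumer)
  holder <- exec[active]
  while (length(active)) {
    hopNode <- c(hopNode, active)
    hopSender <- c(hopSender, holder)
    holder <- ct@parent[holder + 1L]
    keep <- holder != consumer[active]
    active <- active[keep]
    holder <- holder[keep]
  }
  hopReceiver <- if (length(hopSender)) ct@parent[hopSender + 1L] else integer(0)

  ## 4. assemble per-PE programs, ordered by post-order position
  leafPos <- integer(n)
  leafPos[rt@leafIndex[leafIds] + 1L] <- leafIds
  internal <- which(!isLeaf)
  pe <- c(ownership, exec[internal], hopReceiver)
  pos <- c(leafPos, internal, hopNode)
  opcode <- c(rep(OP_PUSH_LOCAL, n), rep(OP_REDUCE, length(internal)),
              rep(OP_PUSH_RECV, length(hopNode)))
  arg <- c(0:(n - 1L), internal, hopSender)
  ord <- order(pe, pos)
  pe <- pe[ord]; pos <- pos[ord]; opcode <- opcode[ord]; arg <- arg[ord]
  idxByPE <- split(seq_along(pe), factor(pe, levels = 0:(p - 1L)))
  programs <- lapply(idxByPE, function(i) {
    cbind(pos = pos[i], opcode = opcode[i], arg = arg[i])
  })
  names(programs) <- NULL

  ## 5. manifests: one (possibly empty) message per non-root PE, payload in
  ##    post-order of the producing nodes
  manifests <- list()
  if (p > 1L) {
    bySender <- split(hopNode, factor(hopSender, levels = 1:(p - 1L)))
    manifests <- lapply(bySender, function(v) as.integer(sort(v)))
    names(manifests) <- as.character(1:(p - 1L))
  }

  new("Schedule", nLeaves = n, nPE = p, degree = k, ownership = ownership,
      programs = programs, manifests = manifests, commParent = ct@parent)
}

#' Summarize a compiled schedule
#'
#' @param s a \linkS4class{Schedule}.
#' @return a list with components \code{messages} (number of messages per
#'   reduction, always p - 1), \code{payloadLengths} (named by edge
#'   \code{"sender->receiver"}), \code{valuesTransmitted},
#'   \code{opCounts} (matrix, one row per PE), \code{maxStackDepth} and
#'   \code{residualDepth} per PE.
#' @examples
#' s <- compileSchedule(buildReductionTree(8), buildCommTree(8), (0:7))
#' scheduleStats(s)$messages  # 7
#' @export
scheduleStats <- function(s) {
  stopifnot(is(s, "Schedule"))
  p <- s@nPE
  payload <- lengths(s@manifests)
  if (p > 1L)
    names(payload) <- sprintf("%s->%d", names(s@manifests),
                              s@commParent[as.integer(names(s@manifests)) + 1L])
  opCounts <- t(vapply(s@programs, function(prog) {
    c(pushLocal = sum(prog[, "opcode"] == OP_PUSH_LOCAL),
      pushRecv = sum(prog[, "opcode"] == OP_PUSH_RECV),
      reduce = sum(prog[, "opcode"] == OP_REDUCE))
  }, c(pushLocal = 0L, pushRecv = 0L, reduce = 0L)))
  rownames(opCounts) <- sprintf("PE%d", 0:(p - 1L))
  depths <- lapply(s@programs, function(prog) {
    if (nrow(prog) == 0L) return(0L)
    cumsum(ifelse(prog[, "opcode"] == OP_REDUCE, -1L, 1L))
  })
  list(
    messages = p - 1L,
    payloadLengths = payload,
    valuesTransmitted = sum(payload),
    opCounts = opCounts,
    maxStackDepth = vapply(depths, max, 0L),
    residualDepth = vapply(depths, function(d) d[length(d)], 0L)
  )
}

#' Serialize a schedule to JSON
#'
#' Layout: an object with scalar fields \code{n}, \code{p}, \code{degree};
#' \code{ownership}, the length-n element-to-PE map (0-based PEs);
#' \code{programs}, an object keyed by PE id whose values are arrays of
#' \code{[opcode, argument]} pairs (opcodes \code{"PUSH_LOCAL"} with the
#' 0-based element index, \code{"PUSH_RECV"} with the sending PE,
#' \code{"REDUCE"} with the 1-based post-order node id); and
#' \code{manifests}, an object keyed by sending PE whose values are arrays
#' of 1-based post-order node ids in message order.
#'
#' @param s a \linkS4class{Schedule}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return \code{path} invisibly, or the JSON string.
#' @seealso [scheduleFromJSON()]
#' @export
scheduleToJSON <- function(s, path = NULL) {
  stopifnot(is(s, "Schedule"))
  progs <- lapply(s@programs, function(prog) {
    lapply(seq_len(nrow(prog)), function(i) {
      op <- prog[i, "opcode"]
      list(OPCODE_NAMES[op],
           if (op == OP_REDUCE) prog[i, "pos"] else prog[i, "arg"])
    })
  })
  names(progs) <- as.character(0:(s@nPE - 1L))
  obj <- list(n = s@nLeaves, p = s@nPE, degree = s@degree,
              ownership = s@ownership, programs = progs,
              manifests = s@manifests)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Read a schedule back from its JSON serialization
#'
#' @param x a file path or a JSON string as produced by [scheduleToJSON()].
#' @return a \linkS4class{Schedule} (validated on construction).
#' @export
scheduleFromJSON <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  n <- as.integer(obj$n); p <- as.integer(obj$p)
  rtPos <- buildReductionTree(n)  # node positions needed to restore 'pos'
  isLeaf <- rtPos@leftChild == 0L
  leafPos <- integer(n)
  leafPos[rtPos@leafIndex[isLeaf] + 1L] <- which(isLeaf)
  programs <- lapply(0:(p - 1L), function(r) {
    entries <- obj$programs[[as.character(r)]]
    if (is.null(entries) || length(entries) == 0L)
      return(cbind(pos = integer(0), opcode = integer(0), arg = integer(0)))
    opcode <- match(vapply(entries, function(e) e[[1L]], ""), OPCODE_NAMES)
    arg <- vapply(entries, function(e) as.integer(e[[2L]]), 0L)
    pos <- ifelse(opcode == OP_PUSH_LOCAL, leafPos[arg + 1L],
                  ifelse(opcode == OP_REDUCE, arg, NA_integer_))
    ## PUSH_RECV positions: restored from the sender manifests below
    cbind(pos = as.integer(pos), opcode = opcode, arg = arg)
  })
  manifests <- lapply(obj$manifests, function(v) as.integer(unlist(v)))
  ## fill PUSH_RECV positions: each receiver consumes a sender's manifest
  ## in order
  for (r in seq_len(p) - 1L) {
    prog <- programs[[r + 1L]]
    rec <- which(prog[, "opcode"] == OP_PUSH_RECV)
    if (!length(rec)) next
    taken <- integer(p)
    for (i in rec) {
      sender <- prog[i, "arg"]
      taken[sender + 1L] <- taken[sender + 1L] + 1L
      prog[i, "pos"] <- manifests[[as.character(sender)]][taken[sender + 1L]]
    }
    programs[[r + 1L]] <- prog[order(prog[, "pos"]), , drop = FALSE]
  }
  ct <- buildCommTree(p, as.integer(obj$degree))
  new("Schedule", nLeaves = n, nPE = p, degree = as.integer(obj$degree),
      ownership = as.integer(unlist(obj$ownership)),
      programs = programs, manifests = manifests, commParent = ct@parent)
}
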