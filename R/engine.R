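## The deterministic simulated distributed execution engine.
##
## PEs are simulated processes: each runs its compiled stack program, sends
## its residual stack as one message to its communication-tree parent when it
## finishes, and blocks on PUSH_RECV until the sender's message is available.
## Messages flow strictly child -> parent, so every scheduling order that
## respects availability yields the same result; the reference engine can
## interleave PEs round-robin (forward or reverse) or run them in
## child-before-parent order, and tests assert these agree bitwise.

commDepthFromParent <- function(commParent) {
  p <- length(commParent)
  depth <- integer(p)
  for (r in seq_len(p - 1L))            # parents precede children in rank
    depth[r + 1L] <- depth[commParent[r + 1L] + 1L] + 1L
  depth
}

topoOrder <- function(commParent) {
  depth <- commDepthFromParent(commParent)
  order(-depth, seq_along(commParent)) - 1L
}

refEngineRun <- function(s, values, op, policy) {
  p <- s@nPE
  progs <- s@programs
  cyc <- switch(policy,
    roundrobin = 0:(p - 1L),
    reverse = (p - 1L):0,
    topo = topoOrder(s@commParent),
    stop("unknown scheduling policy"))
  pcs <- rep(1L, p)
  finished <- logical(p)
  stacks <- rep(list(list()), p)
  outbox <- vector("list", p)
  recvIdx <- integer(p)
  reduceCount <- 0L
  repeat {
    progress <- FALSE
    for (r in cyc) {
      if (finished[r + 1L]) next
      prog <- progs[[r + 1L]]
      while (pcs[r + 1L] <= nrow(prog)) {
        i <- pcs[r + 1L]
        opc <- prog[i, "opcode"]
        a <- prog[i, "arg"]
        if (opc == OP_PUSH_RECV && !finished[a + 1L]) break  # blocks
        st <- stacks[[r + 1L]]
        if (opc == OP_PUSH_LOCAL) {
          st[[length(st) + 1L]] <- values[[a + 1L]]
        } else if (opc == OP_PUSH_RECV) {
          recvIdx[a + 1L] <- recvIdx[a + 1L] + 1L
          st[[length(st) + 1L]] <- outbox[[a + 1L]][[recvIdx[a + 1L]]]
        } else {
          d <- length(st)
          if (d < 2L)
            stop(sprintf("REDUCE on PE %d popped an empty stack", r))
          node <- prog[i, "pos"]
          val <- tryCatch(op@fun(st[[d - 1L]], st[[d]]),
            error = function(e) stop(sprintf(
              "operator '%s' failed at node %d: %s", op@name, node,
              conditionMessage(e)), call. = FALSE))
          st[[d - 1L]] <- val
          st[[d]] <- NULL
          reduceCount <- reduceCount + 1L
        }
        stacks[[r + 1L]] <- st
        pcs[r + 1L] <- i + 1L
        progress <- TRUE
      }
      if (!finished[r + 1L] && pcs[r + 1L] > nrow(prog)) {
        finished[r + 1L] <- TRUE
        outbox[[r + 1L]] <- stacks[[r + 1L]]
        progress <- TRUE
      }
    }
    if (all(finished)) break
    if (!progress) stop("engine deadlock: schedule is invalid")
  }
  for (r in seq_len(p - 1L)) {
    if (recvIdx[r + 1L] != length(outbox[[r + 1L]]))
      stop(sprintf("PE %d left unconsumed received values", r))
  }
  if (length(outbox[[1L]]) != 1L)
    stop("root stack does not hold exactly the final result")
  list(value = outbox[[1L]][[1L]], reduceCount = reduceCount,
       residual = lengths(outbox))
}

#' Execute a compiled reduction schedule
#'
#' Runs the simulated distributed reduction. For every PE count, degree and
#' ownership map, the result is bitwise equal to the sequential pairwise
#' oracle ([pairwiseReduce()]) evaluated on one PE, because all engines
#' realize the identical fixed operation order of the reduction tree.
#'
#' @param s a \linkS4class{Schedule}.
#' @param values input array of length n (numeric, or e.g. character for the
#'   concat operator).
#' @param op a \linkS4class{ReductionOperator}.
#' @param engine \code{"auto"} picks the compiled fast path when the
#'   operator has one and the input is numeric, else the R reference engine.
#' @param policy PE scheduling order for the reference engine:
#'   \code{"roundrobin"} (default), \code{"reverse"} round-robin, or
#'   \code{"topo"} (children before parents). The result never depends on
#'   the policy.
#' @return a list with \code{value} (the result at the root, PE 0) and
#'   \code{trace} (counters: \code{messagesSent} = p - 1,
#'   \code{valuesTransmitted}, \code{opApplications} = n - 1,
#'   \code{finalStackSizes}, plus engine/policy provenance).
#' @examples
#' s <- compileSchedule(buildReductionTree(4), buildCommTree(2), c(0, 0, 1, 1))
#' executeReduce(s, c("a", "b", "c", "d"), makeOperator("concat"))$value
#' @export
executeReduce <- function(s, values, op,
                          engine = c("auto", "native", "reference"),
                          policy = c("roundrobin", "reverse", "topo")) {
  stopifnot(is(s, "Schedule"), is(op, "ReductionOperator"))
  engine <- match.arg(engine)
  policy <- match.arg(policy)
  if (length(values) != s@nLeaves)
    stop(sprintf("values length %d does not match schedule n = %d",
                 length(values), s@nLeaves))
  useNative <- switch(engine,
    auto = op@nativeId > 0L && is.numeric(values),
    native = TRUE,
    reference = FALSE)
  if (useNative) {
    if (op@nativeId == 0L)
      stop(sprintf("operator '%s' has no native fast path", op@name))
    if (!is.numeric(values))
      stop("native engine requires numeric values")
    res <- .cppExecuteReduce(
      lapply(s@programs, function(pr) pr[, "opcode"]),
      lapply(s@programs, function(pr) pr[, "arg"]),
      topoOrder(s@commParent), as.double(values), op@nativeId)
  } else {
    res <- refEngineRun(s, values, op, policy)
  }
  trace <- list(engine = if (useNative) "native" else "reference",
                policy = if (useNative) "topo" else policy,
                messagesSent = s@nPE - 1L,
                valuesTransmitted = sum(lengths(s@manifests)),
                opApplications = as.integer(res$reduceCount),
                finalStackSizes = as.integer(res$residual))
  list(value = res$value, trace = trace)
}

#' Execute an all-reduction: reduce to the root, then broadcast
#'
#' The reduction result materializes at PE 0 and is broadcast down the
#' communication tree, one message per edge, for 2(p - 1) messages in total.
#' Broadcast copies bits, so every PE holds a value bitwise equal to the
#' root's (and hence to the plain reduce result).
#'
#' @inheritParams executeReduce
#' @return a list with \code{values} (length-p list/vector, one result per
#'   PE), \code{value} (the root result) and \code{trace}; the trace's
#'   \code{messagesSent} is 2(p - 1).
#' @export
executeAllReduce <- function(s, values, op,
                             engine = c("auto", "native", "reference"),
                             policy = c("roundrobin", "reverse", "topo")) {
  red <- executeReduce(s, values, op, engine, policy)
  p <- s@nPE
  ## broadcast down the communication tree: parents forward to children
  held <- vector("list", p)
  held[[1L]] <- red$value
  bcastMessages <- 0L
  for (r in seq_len(p - 1L)) {           # parents precede children in rank
    held[[r + 1L]] <- held[[s@commParent[r + 1L] + 1L]]
    bcastMessages <- bcastMessages + 1L
  }
  trace <- red$trace
  trace$messagesSent <- trace$messagesSent + bcastMessages
  values_out <- if (is.numeric(red$value) || is.character(red$value))
    unlist(held) else held
  list(values = values_out, value = red$value, trace = trace)
}
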