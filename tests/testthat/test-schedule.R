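test_that("the worked 4-element, 2-PE schedule is produced", {
  s <- compileSchedule(buildReductionTree(4), buildCommTree(2),
                       c(0L, 0L, 1L, 1L))
  progText <- function(prog)
    paste(sprintf("%s(%d)", BitRepro:::OPCODE_NAMES[prog[, "opcode"]],
                  prog[, "arg"]), collapse = " ")
  # PE 1 reduces its two local elements and ships one intermediate value
  expect_match(progText(s@programs[[2]]),
               "^PUSH_LOCAL\\(2\\) PUSH_LOCAL\\(3\\) REDUCE\\(\\d+\\)$")
  # PE 0 reduces locals, receives PE 1's subtree result, reduces at the root
  ops0 <- s@programs[[1]][, "opcode"]
  expect_identical(BitRepro:::OPCODE_NAMES[ops0],
                   c("PUSH_LOCAL", "PUSH_LOCAL", "REDUCE", "PUSH_RECV",
                     "REDUCE"))
  st <- scheduleStats(s)
  expect_identical(st$messages, 1L)
  expect_identical(unname(st$payloadLengths), 1L)
})

test_that("a single PE needs no communication", {
  n <- 9L
  s <- makeSchedule(n, 1L)
  expect_identical(length(s@manifests), 0L)
  expect_identical(scheduleStats(s)$messages, 0L)
  opc <- s@programs[[1]][, "opcode"]
  expect_identical(sum(opc == 1L), n)       # n PUSH_LOCAL
  expect_identical(sum(opc == 3L), n - 1L)  # n-1 REDUCE
  expect_identical(sum(opc == 2L), 0L)
})

test_that("message minimum: p - 1 messages regardless of n and ownership", {
  s <- makeSchedule(100L, 8L, scheme = "random", seed = 3L)
  expect_identical(scheduleStats(s)$messages, 7L)
  expect_identical(sort(as.integer(names(s@manifests))), 1:7)
})

test_that("reduction-op conservation and determinism across configurations", {
  for (cfg in list(c(1L, 3L), c(17L, 4L), c(50L, 7L), c(64L, 16L))) {
    n <- cfg[1L]; p <- cfg[2L]
    for (scheme in c("contiguous", "round_robin", "random")) {
      s1 <- makeSchedule(n, p, 2L, scheme, seed = 5L)
      s2 <- makeSchedule(n, p, 2L, scheme, seed = 5L)
      expect_identical(s1, s2)   # byte-identical compilation
      ops <- do.call(rbind, s1@programs)
      expect_identical(sum(ops[, "opcode"] == 3L), n - 1L)
      expect_identical(sum(ops[, "opcode"] == 1L), n)
    }
  }
})

test_that("flattening REDUCE ops by post-order reconstructs the fixed tree", {
  n <- 33L
  rt <- buildReductionTree(n)
  internalSeq <- which(rt@leftChild != 0L)
  for (p in c(2L, 5L, 8L)) for (k in c(2L, 4L)) {
    s <- makeSchedule(n, p, k, "random", seed = p + k)
    ops <- do.call(rbind, s@programs)
    red <- ops[ops[, "opcode"] == 3L, , drop = FALSE]
    expect_identical(sort(red[, "pos"]), internalSeq)
    expect_identical(red[order(red[, "pos"]), "arg"], internalSeq)
  }
})

test_that("each internal node runs on an ancestor of its children's PEs", {
  n <- 40L; p <- 8L
  rt <- buildReductionTree(n)
  ct <- buildCommTree(p)
  own <- genOwnership(n, p, "random", seed = 17L)
  s <- compileSchedule(rt, ct, own)
  ops <- do.call(rbind, mapply(function(prog, r) cbind(prog, pe = r),
                               s@programs, 0:(p - 1L), SIMPLIFY = FALSE))
  execPE <- integer(2L * n - 1L)
  isLocal <- ops[, "opcode"] != 2L
  execPE[ops[isLocal, "pos"]] <- ops[isLocal, "pe"]
  ancestorOf <- function(anc, x) {
    while (!is.na(x)) {
      if (x == anc) return(TRUE)
      x <- ct@parent[x + 1L]
    }
    anc == 0L
  }
  for (v in which(rt@leftChild != 0L)) {
    expect_true(ancestorOf(execPE[v], execPE[rt@leftChild[v]]))
    expect_true(ancestorOf(execPE[v], execPE[rt@rightChild[v]]))
  }
})

test_that("ownership referencing a missing PE is rejected", {
  rt <- buildReductionTree(4)
  expect_error(compileSchedule(rt, buildCommTree(2), c(0L, 0L, 1L, 2L)),
               "references PE >= p")
  expect_error(compileSchedule(rt, buildCommTree(2), c(0L, 1L)),
               "must cover")
})

test_that("schedules round-trip through the JSON serialization", {
  for (cfg in list(c(7L, 3L, 2L), c(24L, 5L, 4L))) {
    s <- makeSchedule(cfg[1L], cfg[2L], cfg[3L], "random", seed = 2L)
    s2 <- scheduleFromJSON(scheduleToJSON(s))
    expect_identical(s2@programs, s@programs)
    expect_identical(s2@manifests, s@manifests)
    expect_identical(s2@ownership, s@ownership)
    # and a file round trip
    f <- tempfile(fileext = ".json")
    scheduleToJSON(s, f)
    expect_identical(scheduleFromJSON(f)@programs, s@programs)
    unlink(f)
  }
})

test_that("residual stack depths equal outgoing message lengths", {
  s <- makeSchedule(31L, 8L, 2L, "random", seed = 9L)
  st <- scheduleStats(s)
  expect_identical(unname(st$residualDepth[1L]), 1L)
  expect_identical(unname(st$residualDepth[-1L]),
                   unname(lengths(s@manifests)[as.character(1:7)]))
})
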