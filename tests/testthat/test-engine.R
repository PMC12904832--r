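test_that("the order-preserving concat monoid witnesses the global order", {
  s <- makeSchedule(4L, 2L, scheme = "round_robin")
  r <- executeReduce(s, c("a", "b", "c", "d"), concatOp)
  expect_identical(r$value, "abcd")
  # every configuration must return the global-order concatenation
  for (n in c(1L, 2L, 5L, 17L)) {
    want <- paste(tokenValues(n), collapse = "")
    for (p in c(1L, 2L, 3L, 5L)) for (k in c(2L, 4L)) {
      for (scheme in c("contiguous", "round_robin", "random")) {
        s <- makeSchedule(n, p, k, scheme, seed = n + p)
        expect_identical(executeReduce(s, tokenValues(n), concatOp)$value,
                         want)
      }
    }
  }
})

test_that("float reduction is bitwise equal to the pairwise oracle", {
  for (n in c(1L, 2L, 17L, 500L)) {
    v <- genValues(n, "cancellation", seed = n)
    want <- pairwiseReduce(v, addOp)
    for (p in c(1L, 3L, 8L)) for (k in c(2L, 4L)) {
      s <- makeSchedule(n, p, k, "random", seed = 7L)
      expect_bitIdentical(executeReduce(s, v, addOp)$value, want)
    }
  }
})

test_that("native and reference engines and all PE interleavings agree", {
  n <- 200L
  v <- genValues(n, "mixed_magnitude", seed = 4L)
  s <- makeSchedule(n, 7L, 2L, "random", seed = 8L)
  rn <- executeReduce(s, v, addOp, engine = "native")
  for (pol in c("roundrobin", "reverse", "topo")) {
    rr <- executeReduce(s, v, addOp, engine = "reference", policy = pol)
    expect_bitIdentical(rr$value, rn$value)
  }
})

test_that("other built-in operators reduce correctly", {
  v <- as.double(1:100)
  s <- makeSchedule(100L, 4L, scheme = "round_robin")
  expect_identical(executeReduce(s, v, makeOperator("int-add"))$value, 5050)
  expect_identical(executeReduce(s, v, makeOperator("max"))$value, 100)
  vm <- genValues(20L, "uniform01", seed = 2L)
  sm <- makeSchedule(20L, 3L)
  expect_bitIdentical(
    executeReduce(sm, vm, makeOperator("float-mul"))$value,
    pairwiseReduce(vm, makeOperator("float-mul")))
})

test_that("trace counters are exact", {
  n <- 64L; p <- 8L
  s <- makeSchedule(n, p, scheme = "random", seed = 1L)
  r <- executeReduce(s, genValues(n, "uniform01", 1L), addOp)
  expect_identical(r$trace$messagesSent, p - 1L)
  expect_identical(r$trace$opApplications, n - 1L)
  expect_identical(r$trace$valuesTransmitted,
                   sum(lengths(s@manifests)))
  expect_identical(r$trace$finalStackSizes[1L], 1L)
})

test_that("all-reduce broadcasts the root's bits to every PE", {
  n <- 40L; p <- 4L
  v <- genValues(n, "uniform01", seed = 6L)
  s <- makeSchedule(n, p)
  red <- executeReduce(s, v, addOp)
  ar <- executeAllReduce(s, v, addOp)
  expect_identical(ar$trace$messagesSent, 2L * (p - 1L))  # 6 messages
  expect_identical(length(ar$values), p)
  expect_true(all(hexFloat(ar$values) == hexFloat(ar$value)))
  expect_bitIdentical(ar$value, red$value)
})

test_that("input and operator errors carry context", {
  s <- makeSchedule(4L, 2L)
  expect_error(executeReduce(s, 1:3, addOp), "does not match schedule")
  boom <- new("ReductionOperator", name = "boom",
              fun = function(a, b) stop("bad pair"), commutative = FALSE,
              nativeId = 0L)
  expect_error(executeReduce(s, as.double(1:4), boom),
               "operator 'boom' failed at node \\d+: bad pair")
})

test_that("unknown operators are rejected with the registry listed", {
  expect_error(makeOperator("bogus"), "float-add.*concat")
  op <- makeOperator("concat")
  expect_false(op@fun("x", "y") == op@fun("y", "x"))
})
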