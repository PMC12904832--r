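# Shared helpers: fixtures are always generated in code, never stored.

addOp <- makeOperator("float-add")
concatOp <- makeOperator("concat")

# one-call compile for a generated configuration
makeSchedule <- function(n, p, k = 2L, scheme = "contiguous", seed = 1L) {
  compileSchedule(buildReductionTree(n), buildCommTree(p, k),
                  genOwnership(n, p, scheme, seed = seed))
}

expect_bitIdentical <- function(x, y) {
  expect_identical(hexFloat(x), hexFloat(y))
}

# deterministic letters for order-witness inputs
tokenValues <- function(n) {
  rep_len(c(letters, LETTERS), n)
}

newickTree <- function(txt) readNewickTree(text = txt)

msaFromStrings <- function(...) {
  seqs <- c(...)
  new("MSA", labels = names(seqs),
      seqs = matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                    byrow = TRUE))
}
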