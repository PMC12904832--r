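test_that("FASTA and relaxed PHYLIP readers preserve file order and validate", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">tax1", "acgt", ">tax2", "ACGA"), fa)
  msa <- readAlignment(fa)
  expect_identical(taxa(msa), c("tax1", "tax2"))
  expect_identical(nSites(msa), 4L)
  expect_identical(msa@seqs[1L, ], c("A", "C", "G", "T"))  # uppercased

  ph <- tempfile(fileext = ".phy")
  writeLines(c("2 4", "longname_one ACGT", "t2 ACGA"), ph)
  msa2 <- readAlignment(ph, "phylip")
  expect_identical(taxa(msa2), c("longname_one", "t2"))

  ragged <- tempfile()
  writeLines(c("2 4", "A ACGT", "B ACG"), ragged)
  expect_error(readAlignment(ragged, "phylip"), "unequal sequence lengths")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">A", "ACGT"), dup)
  expect_error(readAlignment(dup), "duplicate sequence labels")

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(readAlignment(empty), "empty alignment file")

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACXT", ">B", "ACGT"), bad)
  expect_error(readAlignment(bad), "non-IUPAC")
  unlink(c(fa, ph, ragged, dup, empty, bad))
})

test_that("Newick reading validates structure and branch lengths", {
  t1 <- newickTree("(A:0.1,B:0.2);")
  expect_identical(length(t1$tip.label), 2L)
  t2 <- newickTree("(A:0.1,(B:0.1,C:0.1):0.05);")
  expect_identical(length(t2$tip.label), 3L)
  expect_identical(sum(t2$edge[, 2L] > 3L), 1L)  # one internal branch
  expect_error(newickTree("((A,B);"), "unbalanced parentheses")
  expect_warning(t3 <- newickTree("(A,B);"), "no branch lengths")
  expect_identical(t3$edge.length, c(0, 0))
})

test_that("JC69 transition rows sum to one", {
  for (t in c(0, 0.1, 1, 10)) {
    expect_true(all(abs(rowSums(jc69Transition(t)) - 1) < 1e-12))
    expect_true(all(jc69Transition(t) >= 0))
  }
})

test_that("two-taxon site likelihoods match closed forms", {
  t0 <- newickTree("(A:0,B:0);")
  same <- msaFromStrings(A = "A", B = "A")
  expect_equal(siteLogLikelihood(t0, same, 1), log(0.25), tolerance = 1e-15)
  # impossible data at zero distance: likelihood 0, reported as -Inf
  diffr <- msaFromStrings(A = "A", B = "C")
  expect_identical(siteLogLikelihood(t0, diffr, 1), -Inf)
  # independence limit: total path length -> infinity gives 1/16
  tInf <- newickTree("(A:400,B:400);")
  expect_equal(siteLogLikelihood(tInf, same, 1), log(1 / 16),
               tolerance = 1e-12)
  # gaps contribute all-ones partials: a fully gapped site scores the
  # stationary normalization, ln(1) = 0 at any branch length
  gap <- msaFromStrings(A = "-", B = "N")
  expect_equal(siteLogLikelihood(t0, gap, 1), 0, tolerance = 1e-15)
  expect_error(siteLogLikelihood(t0, same, 9), "out of range")
})

test_that("likelihoods agree with an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  for (seed in c(3L, 11L)) {
    fix <- genMsaTree(6L, 150L, seed)
    mine <- sum(siteLogLikelihoods(fix$tree, fix$msa))
    m <- fix$msa@seqs
    rownames(m) <- taxa(fix$msa)
    fit <- phangorn::pml(fix$tree, phangorn::phyDat(m, type = "DNA"),
                         model = "JC")
    expect_equal(mine, as.numeric(stats::logLik(fit)), tolerance = 1e-9)
  }
})

test_that("the contiguous partition follows the stated block rule", {
  expect_identical(as.integer(table(partitionSites(10L, 3L))), c(4L, 3L, 3L))
  expect_identical(partitionSites(6L, 1L), rep(0L, 6L))
  own <- partitionSites(4L, 8L)
  expect_identical(own, 0:3)            # PEs 4..7 own nothing
  expect_identical(partitionSites(10L, 3L),
                   rep(c(0L, 1L, 2L), c(4L, 3L, 3L)))
})

test_that("repro totals are p-invariant; naive totals are not in general", {
  fix <- genMsaTree(8L, 400L, 5L)
  totals <- vapply(c(1L, 2L, 3L, 5L, 8L), function(p)
    hexFloat(treeLogLik(fix$tree, fix$msa, p, "repro")$total), "")
  expect_identical(length(unique(totals)), 1L)
  # the repro total is by construction the pairwise oracle of the per-site
  # vector
  r <- treeLogLik(fix$tree, fix$msa, 3L, "repro")
  expect_bitIdentical(r$total, pairwiseReduce(r$perSite))
  # per-site vectors themselves never depend on p or mode
  nv <- treeLogLik(fix$tree, fix$msa, 5L, "naive")
  expect_identical(nv$perSite, r$perSite)
  # and the naive accumulation differs from the fixed order on this fixture
  naive <- vapply(c(1L, 2L, 3L, 5L, 8L), function(p)
    hexFloat(treeLogLik(fix$tree, fix$msa, p, "naive")$total), "")
  expect_gt(length(unique(naive)), 1L)
})

test_that("zero-likelihood sites propagate to -Inf with a count", {
  t0 <- newickTree("(A:0,B:0);")
  msa <- msaFromStrings(A = "AAC", B = "ACC")
  r <- treeLogLik(t0, msa, 2L, "repro")
  expect_identical(r$total, -Inf)
  expect_identical(r$nInfSites, 1L)
  expect_error(treeLogLik(t0, msaFromStrings(A = "AA", X = "AA"), 1L),
               "taxa differ")
})
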