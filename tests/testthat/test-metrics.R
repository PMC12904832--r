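test_that("bipartition enumeration on hand-checkable trees", {
  b <- bipartitions(newickTree("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_identical(length(b@splits), 1L)
  # canonical side excludes the reference taxon A -> {C, D}
  expect_identical(b@splits[[1L]], c("C", "D"))

  star <- bipartitions(newickTree("(A:1,B:1,C:1,D:1);"))
  expect_identical(length(star@splits), 0L)

  cat5 <- bipartitions(newickTree("(A:1,(B:1,(C:1,(D:1,E:1):1):1):1);"))
  expect_identical(length(cat5@splits), 2L)   # 5-taxon caterpillar

  dup <- newickTree("((A:1,A:1):1,(C:1,D:1):1);")
  expect_error(bipartitions(dup), "duplicate taxa")
})

test_that("relative RF worked examples", {
  a <- newickTree("((A:1,B:1):1,(C:1,D:1):1);")
  b <- newickTree("((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(relativeRF(a, a), 0)
  expect_identical(relativeRF(a, b), 1)
  expect_identical(relativeRF(a, b), relativeRF(b, a))
  # star vs star: no non-trivial splits on either side -> defined as 0
  s <- newickTree("(A:1,B:1,C:1,D:1);")
  expect_identical(relativeRF(s, s), 0)
  # a resolved vs an unresolved tree: 1 split vs 0 -> 1/1
  expect_identical(relativeRF(a, s), 1)
  expect_error(relativeRF(a, newickTree("((A:1,B:1):1,(C:1,E:1):1);")),
               "different taxon sets")
})

test_that("relative RF is a pseudo-metric and matches an independent count", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  trees <- replicate(6, ape::rtree(6, tip.label = paste0("t", 1:6)),
                     simplify = FALSE)
  d <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    d[i, j] <- relativeRF(trees[[i]], trees[[j]])
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  # triangle inequality over all triples
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # binary 6-taxon trees: our |B1 sym B2| / (|B1|+|B2|) equals the classic
  # RF distance normalized by 2(n-3), counted independently by phangorn
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j],
                 phangorn::RF.dist(trees[[i]], trees[[j]],
                                   normalize = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("splitting commutes with relabeling", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
    perm <- setNames(paste0("x", sample(6)), tr$tip.label)
    relab <- tr
    relab$tip.label <- unname(perm[tr$tip.label])
    before <- lapply(bipartitions(tr)@splits, function(s) sort(unname(perm[s])))
    after <- bipartitions(relab)@splits
    canon <- function(splits, universe) {
      ref <- sort(universe)[1L]
      sort(vapply(splits, function(s) {
        if (ref %in% s) s <- setdiff(universe, s)
        paste(sort(s), collapse = "|")
      }, ""))
    }
    expect_identical(canon(before, relab$tip.label),
                     canon(after, relab$tip.label))
  }
})

test_that("divergence classification applies the log-likelihood filter", {
  t1 <- newickTree("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- newickTree("((A:1,C:1):1,(B:1,D:1):1);")
  same8 <- lapply(1:8, function(i)
    list(label = paste0("run", i), tree = t1, logLik = -1000 - i * 1e-5))
  rep1 <- classifyDivergence(same8)
  expect_false(rep1$diverging)
  expect_identical(rep1$nTopologies, 1L)

  two <- list(list(label = "a", tree = t1, logLik = -1000),
              list(label = "b", tree = t2, logLik = -1000.0005))
  rep2 <- classifyDivergence(two)
  expect_true(rep2$diverging)
  expect_identical(rep2$nTopologies, 2L)
  expect_false(rep2$exceedsThreshold)   # 5e-4 < 1e-3
  expect_identical(rep2$pairs$assessment, "not significantly different")

  far <- list(list(label = "a", tree = t1, logLik = -1000),
              list(label = "b", tree = t2, logLik = -1002))
  rep3 <- classifyDivergence(far)
  expect_true(rep3$exceedsThreshold)
  expect_identical(rep3$pairs$assessment, "requires external AU test")

  expect_error(classifyDivergence(two[1]), "at least 2")

  # JSON export carries the verdicts
  js <- jsonlite::fromJSON(divergenceToJSON(rep3))
  expect_true(js$diverging)
  expect_identical(js$pairs$assessment, "requires external AU test")
})
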