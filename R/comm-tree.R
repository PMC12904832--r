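#' Build the k-nomial communication tree over p PEs
#'
#' The parent of PE r > 0 is r with its lowest nonzero base-k digit cleared;
#' PE 0 is the root. For k = 2 this is the classic binomial tree used by
#' tree-based collectives; k = 4 is the wider variant that trades tree depth
#' for node degree. The construction depends only on (p, k), and the tree has
#' exactly p - 1 edges -- the theoretical minimum number of messages for a
#' reduction.
#'
#' @param p number of PEs (>= 1).
#' @param degree k of the k-nomial construction (>= 2, default 2).
#' @return a \linkS4class{CommTree}.
#' @examples
#' ct <- buildCommTree(4)
#' ct@parent   # NA 0 0 2: PEs 1,2 attach to 0; PE 3 to 2
#' @export
buildCommTree <- function(p, degree = 2L) {
  p <- as.integer(p); k <- as.integer(degree)
  if (length(p) != 1L || is.na(p) || p < 1L) stop("p must be >= 1")
  if (length(k) != 1L || is.na(k) || k < 2L) stop("degree must be >= 2")
  parent <- rep(NA_integer_, p)
  depth <- integer(p)
  if (p > 1L) {
    r <- as.double(1:(p - 1L))
    ## clear the lowest nonzero base-k digit (double arithmetic: exact
    ## for any representable rank)
    pw <- rep(1, p - 1L)
    done <- logical(p - 1L)
    par <- numeric(p - 1L)
    while (!all(done)) {
      d <- (r %/% pw) %% k
      hit <- !done & d > 0
      par[hit] <- r[hit] - d[hit] * pw[hit]
      done <- done | hit
      pw[!done] <- pw[!done] * k
    }
    parent[-1L] <- as.integer(par)
    ## depth = number of nonzero base-k digits
    t <- r
    dep <- numeric(p - 1L)
    while (any(t > 0)) {
      dep <- dep + ((t %% k) > 0)
      t <- t %/% k
    }
    depth[-1L] <- as.integer(dep)
  }
  new("CommTree", nPE = p, degree = k, parent = parent, depth = depth)
}

#' Lowest common ancestor of a set of PEs in the communication tree
#'
#' The deepest PE that is an ancestor of, or equal to, every PE in the set.
#' Intermediate reduction operations are assigned to the LCA-PE of the owners
#' of the elements below them, which is what lets intermediate results flow
#' strictly upward along the communication tree.
#'
#' @param ct a \linkS4class{CommTree}.
#' @param pes nonempty vector of PE ids (0-based).
#' @return a single PE id.
#' @examples
#' ct <- buildCommTree(4)
#' commLCA(ct, c(2, 3))  # 2
#' commLCA(ct, c(1, 3))  # 0
#' @export
commLCA <- function(ct, pes) {
  stopifnot(is(ct, "CommTree"))
  pes <- as.integer(pes)
  if (length(pes) == 0L) stop("LCA of an empty PE set is undefined")
  if (anyNA(pes) || any(pes < 0L) || any(pes >= ct@nPE))
    stop("PE id outside [0, p)")
  lca2 <- function(a, b) {
    while (ct@depth[a + 1L] > ct@depth[b + 1L]) a <- ct@parent[a + 1L]
    while (ct@depth[b + 1L] > ct@depth[a + 1L]) b <- ct@parent[b + 1L]
    while (a != b) {
      a <- ct@parent[a + 1L]
      b <- ct@parent[b + 1L]
    }
    a
  }
  Reduce(lca2, pes)
}

## Vectorized closed-form pairwise LCA for digit-clearing k-nomial trees:
## truncate both ranks above the highest base-k digit in which they differ.
## Used on hot paths by the schedule compiler; commLCA() (parent-chain walk)
## is the reference implementation the tests compare against.
pairLCA <- function(a, b, k) {
  a <- as.double(a); b <- as.double(b)
  res <- a
  pw <- 1
  trunc_pw <- rep(0, length(a))  # 0 = digits never differed (a == b)
  while (any(pmax(a, b) >= pw)) {
    differ <- ((a %/% pw) %% k) != ((b %/% pw) %% k)
    trunc_pw[differ] <- pw * k
    pw <- pw * k
  }
  diffed <- trunc_pw > 0
  res[diffed] <- (a[diffed] %/% trunc_pw[diffed]) * trunc_pw[diffed]
  as.integer(res)
}
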