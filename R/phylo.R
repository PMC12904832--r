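## Pruning-algorithm likelihood demonstrator.
##
## The point of this module is not model sophistication (the substitution
## model is fixed to Jukes-Cantor 1969): it demonstrates decoupling the
## accumulation order of per-site log-likelihoods from the p-dependent
## assignment of sites to PEs. Per-site values are computed identically
## regardless of p; only how they are summed differs between the fixed-order
## ("repro") and the per-PE-accumulator ("naive") modes.

#' Read a multiple sequence alignment
#'
#' Supports FASTA and relaxed (whitespace-separated labels) sequential
#' PHYLIP, preserving the file's site order -- that order is the global
#' accumulation order. Lowercase bases are accepted and uppercased; the
#' alphabet is restricted to A, C, G, T, - and N.
#'
#' @param path input file.
#' @param format \code{"auto"} (detect a leading \code{>}), \code{"fasta"}
#'   or \code{"phylip"}.
#' @return an \linkS4class{MSA}.
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty alignment file")
  if (format == "auto")
    format <- if (startsWith(trimws(lines[nzchar(trimws(lines))][1L]), ">"))
      "fasta" else "phylip"
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file")
    labels <- names(set)
    seqs <- toupper(as.character(set))
  } else {
    lines <- lines[nzchar(trimws(lines))]
    hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]),
                                                "\\s+")[[1L]]))
    if (length(hdr) < 2L || anyNA(hdr[1:2]))
      stop("malformed PHYLIP header (expected '<ntaxa> <nsites>')")
    ntax <- hdr[1L]; nchar_ <- hdr[2L]
    body <- lines[-1L]
    if (length(body) < ntax) stop("PHYLIP file has fewer rows than taxa")
    first <- strsplit(trimws(body[seq_len(ntax)]), "\\s+")
    labels <- vapply(first, `[[`, "", 1L)
    seqs <- vapply(first, function(x) paste(x[-1L], collapse = ""), "")
    ## continuation blocks (interleaved/wrapped): cycle taxa in order
    extra <- body[-seq_len(ntax)]
    for (i in seq_along(extra)) {
      r <- ((i - 1L) %% ntax) + 1L
      seqs[r] <- paste0(seqs[r], gsub("\\s+", "", extra[i]))
    }
    seqs <- toupper(seqs)
    if (any(nchar(seqs) != nchar_))
      stop("unequal sequence lengths (PHYLIP rows do not match the header)")
  }
  if (anyDuplicated(labels)) stop("duplicate sequence labels")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("unequal sequence lengths")
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(labels),
                byrow = TRUE)
  new("MSA", labels = labels, seqs = mat)
}

#' Read a Newick tree
#'
#' Thin validating wrapper around \code{ape::read.tree}. Missing branch
#' lengths default to 0 with a warning; parse failures (e.g. unbalanced
#' parentheses) are reported as errors.
#'
#' @param path file containing one Newick string, or \code{NULL} when
#'   \code{text} is given.
#' @param text optional literal Newick string.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewickTree <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) paste(readLines(path), collapse = "") else text
  nopen <- lengths(regmatches(src, gregexpr("(", src, fixed = TRUE)))
  nclose <- lengths(regmatches(src, gregexpr(")", src, fixed = TRUE)))
  if (nopen != nclose)
    stop("Newick parse error: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = src),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' JC69 transition probability matrix
#'
#' Under the Jukes-Cantor model with branch length t in expected
#' substitutions per site, a site keeps its state with probability
#' 1/4 + 3/4 exp(-4t/3) and changes to each other state with probability
#' 1/4 - 1/4 exp(-4t/3). Rows sum to one for every t >= 0.
#'
#' @param t branch length (>= 0).
#' @return a 4 x 4 matrix (rows: from-state A, C, G, T).
#' @export
jc69Transition <- function(t) {
  e <- exp(-4 * t / 3)
  pSame <- 0.25 + 0.75 * e
  pDiff <- 0.25 - 0.25 * e
  m <- matrix(pDiff, 4L, 4L,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- pSame
  m
}

tipPartial <- function(ch) {
  switch(ch,
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
    G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    "-" = , N = c(1, 1, 1, 1),
    stop(sprintf("non-IUPAC character '%s'", ch)))
}

checkTreeMsa <- function(tree, msa) {
  stopifnot(inherits(tree, "phylo"), is(msa, "MSA"))
  if (!setequal(tree$tip.label, msa@labels))
    stop("tree and alignment taxa differ")
  if (anyDuplicated(tree$tip.label)) stop("duplicate taxa in tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
}

#' Per-site log-likelihoods under JC69 via the pruning algorithm
#'
#' Felsenstein's dynamic program: conditional likelihood vectors are
#' propagated from the tips to the root (children folded in their stored
#' order, a fixed choice), and the root vector is dotted with the uniform
#' stationary frequencies (1/4 each). Gaps and N contribute all-ones
#' partials. A site whose likelihood is exactly 0 yields -Inf, which is
#' propagated, never clamped. The computation is self-contained per site and
#' completely independent of any parallelization, so the returned vector is
#' the same for every p; only the subsequent accumulation order can differ.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths; trees read
#'   unrooted are evaluated at their stored root node (JC69 is reversible,
#'   so the likelihood is rooting-invariant up to rounding; one fixed
#'   rooting is used throughout).
#' @param msa an \linkS4class{MSA} over the same taxa.
#' @param sites site indices (1-based; default all).
#' @return numeric vector of natural-log per-site likelihoods, in global
#'   site order.
#' @export
siteLogLikelihoods <- function(tree, msa, sites = seq_len(nSites(msa))) {
  checkTreeMsa(tree, msa)
  sites <- as.integer(sites)
  if (any(sites < 1L) || any(sites > nSites(msa)))
    stop("site index out of range")
  S <- length(sites)
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- max(tr$edge)
  tipRow <- match(tr$tip.label, msa@labels)
  partials <- vector("list", nNode)
  for (i in seq_len(nTip)) {
    chars <- msa@seqs[tipRow[i], sites]
    partials[[i]] <- vapply(chars, tipPartial, numeric(4L))
  }
  root <- nTip + 1L
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
    P <- jc69Transition(tr$edge.length[e])
    msg <- P %*% partials[[chd]]
    partials[[par]] <- if (is.null(partials[[par]])) msg
                       else partials[[par]] * msg
  }
  rp <- partials[[root]]
  lik <- 0.25 * rp[1L, ] + 0.25 * rp[2L, ] + 0.25 * rp[3L, ] +
    0.25 * rp[4L, ]
  unname(log(lik))
}

#' @rdname siteLogLikelihoods
#' @param site a single 1-based site index.
#' @export
siteLogLikelihood <- function(tree, msa, site) {
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L || site > nSites(msa))
    stop("site index out of range")
  siteLogLikelihoods(tree, msa, sites = site)
}

#' Contiguous-block site partition (p-dependent load balancer emulation)
#'
#' Splits the n sites into contiguous blocks of size ceiling(n/p) or
#' floor(n/p), earlier PEs receiving the larger blocks. This emulates the
#' defining property of production load balancers -- the assignment (order
#' and length) changes with the PE count -- without reproducing any
#' particular balancer.
#'
#' @param nSites_ number of sites (>= 1).
#' @param p number of PEs (>= 1); PEs beyond the available sites own
#'   nothing.
#' @return integer ownership vector (site index, 0-based order -> PE).
#' @examples
#' table(partitionSites(10, 3))  # blocks of 4, 3, 3
#' @export
partitionSites <- function(nSites_, p) {
  n <- as.integer(nSites_); p <- as.integer(p)
  if (is.na(n) || n < 1L) stop("nSites must be >= 1")
  if (is.na(p) || p < 1L) stop("p must be >= 1")
  base <- n %/% p
  r <- n %% p
  sizes <- rep(base, p)
  if (r > 0L) sizes[seq_len(r)] <- base + 1L
  rep(0:(p - 1L), times = sizes)
}

#' Total tree log-likelihood with a chosen accumulation strategy
#'
#' Computes the per-site log-likelihood vector (identical for every p), then
#' accumulates it over the p-dependent contiguous site partition either in
#' \code{"repro"} mode -- each value enters at its global site index and the
#' fixed-order reduction engine sums along the reduction tree, so the total
#' is bitwise independent of p -- or in \code{"naive"} mode -- each PE folds
#' its local values into an accumulator and the per-PE partials are folded
#' in rank order, so the total generally varies with p in the last bits.
#'
#' @param tree,msa as in [siteLogLikelihoods()].
#' @param p number of PEs.
#' @param mode \code{"repro"} or \code{"naive"}.
#' @param degree communication-tree degree for repro mode.
#' @return list with \code{total} (natural-log likelihood; -Inf if any site
#'   has zero likelihood), \code{nInfSites} (count of sites at -Inf),
#'   \code{perSite}, \code{mode} and \code{p}.
#' @export
treeLogLik <- function(tree, msa, p, mode = c("repro", "naive"),
                       degree = 2L) {
  mode <- match.arg(mode)
  perSite <- siteLogLikelihoods(tree, msa)
  n <- length(perSite)
  own <- partitionSites(n, p)
  total <- if (mode == "repro") {
    s <- compileSchedule(buildReductionTree(n), buildCommTree(p, degree), own)
    executeReduce(s, perSite, makeOperator("float-add"))$value
  } else {
    naiveReduce(perSite, own, p, makeOperator("float-add"))
  }
  list(total = total, nInfSites = sum(is.infinite(perSite)),
       perSite = perSite, mode = mode, p = as.integer(p))
}
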