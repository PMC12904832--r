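## Deterministic generators for all test inputs. One pseudo-random generator
## is fixed package-wide (Mersenne-Twister with inversion normals and
## rejection sampling) and recorded in every metadata sidecar, so fixtures
## are byte-portable across R versions and sessions. All generators are pure
## functions of their parameters and seed, and restore the caller's RNG
## state.

GENERATOR_RNG <- c(kind = "Mersenne-Twister", normal.kind = "Inversion",
                   sample.kind = "Rejection")

withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  oldKind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(oldKind))
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = GENERATOR_RNG[["kind"]],
           normal.kind = GENERATOR_RNG[["normal.kind"]],
           sample.kind = GENERATOR_RNG[["sample.kind"]])
  expr
}

#' Generate floating-point test arrays
#'
#' Three regimes of 64-bit doubles at desk scale:
#' \describe{
#'   \item{uniform01}{iid U(0, 1); benign, well-conditioned sums.}
#'   \item{mixed_magnitude}{random sign, uniform mantissa, decimal exponent
#'     drawn uniformly over +/- \code{magnitudeSpan} decades; stresses
#'     absorption of small addends by large ones.}
#'   \item{cancellation}{pairs (x + delta, -x) with x ~ U(0, 1) and tiny
#'     perturbations delta ~ U(0, 1e-8), randomly permuted; the exact sum is
#'     the perturbation total, so the computed sum is dominated by rounding
#'     and maximally sensitive to operation order.}
#' }
#'
#' @param n number of values (>= 1).
#' @param regime one of \code{"uniform01"}, \code{"mixed_magnitude"},
#'   \code{"cancellation"}.
#' @param seed integer seed; identical (n, regime, seed, span) gives
#'   byte-identical output.
#' @param magnitudeSpan decades of magnitude for \code{mixed_magnitude}
#'   (default 12).
#' @return numeric vector of length n.
#' @examples
#' identical(genValues(5, "uniform01", 1), genValues(5, "uniform01", 1))
#' @export
genValues <- function(n, regime = c("uniform01", "mixed_magnitude",
                                    "cancellation"),
                      seed, magnitudeSpan = 12) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  regime <- match.arg(regime)
  withSeed(seed, {
    switch(regime,
      uniform01 = stats::runif(n),
      mixed_magnitude = {
        sign <- sample(c(-1, 1), n, replace = TRUE)
        mant <- stats::runif(n)
        expo <- stats::runif(n, -magnitudeSpan, magnitudeSpan)
        sign * mant * 10^expo
      },
      cancellation = {
        m <- n %/% 2L
        out <- if (m > 0L) {
          x <- stats::runif(m)
          delta <- stats::runif(m) * 1e-8
          as.vector(rbind(x + delta, -x))
        } else numeric(0)
        if (n %% 2L == 1L) out <- c(out, stats::runif(1) * 1e-8)
        out[sample(n)]
      })
  })
}

#' Generate an element-to-PE ownership map
#'
#' Schemes: \code{contiguous} blocks (identical to [partitionSites()]:
#' earlier PEs get the ceil(n/p)-sized blocks), \code{round_robin}
#' (\code{index mod p}), or seeded \code{random} (iid uniform owner per
#' element; PEs may own nothing). Ownership is always total: every element
#' has exactly one owner.
#'
#' @param n number of elements (>= 1).
#' @param p number of PEs (>= 1).
#' @param scheme one of \code{"contiguous"}, \code{"round_robin"},
#'   \code{"random"}.
#' @param seed required for \code{"random"}.
#' @return integer vector of length n with values in [0, p).
#' @examples
#' genOwnership(4, 2, "round_robin")  # 0 1 0 1
#' @export
genOwnership <- function(n, p, scheme = c("contiguous", "round_robin",
                                          "random"), seed = NULL) {
  n <- as.integer(n); p <- as.integer(p)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (is.na(p) || p < 1L) stop("p must be >= 1")
  scheme <- match.arg(scheme)
  switch(scheme,
    contiguous = partitionSites(n, p),
    round_robin = (0:(n - 1L)) %% p,
    random = {
      if (is.null(seed)) stop("the random scheme requires a seed")
      withSeed(seed, sample(0:(p - 1L), n, replace = TRUE))
    })
}

#' Generate a random tree and a JC69-simulated alignment
#'
#' Topology: random binary tree (sequential random splits, via
#' \code{ape::rtree}) with branch lengths drawn from an exponential with
#' mean 0.1 expected substitutions per site. Sequences: the root state of
#' each site is drawn from the stationary distribution (1/4 each), then
#' evolved independently down every branch under the Jukes-Cantor model --
#' along a branch of length t a site keeps its state with probability
#' 1/4 + 3/4 exp(-4t/3) and otherwise changes to one of the three other
#' bases uniformly. Sites are iid, matching the independence assumption of
#' the pruning likelihood.
#'
#' @param nTaxa number of taxa (>= 2).
#' @param nSites number of sites (>= 1).
#' @param seed integer seed.
#' @return list with components \code{tree} (an \code{ape} \code{phylo})
#'   and \code{msa} (an \linkS4class{MSA} with taxa t1..tN).
#' @export
genMsaTree <- function(nTaxa, nSites, seed) {
  nTaxa <- as.integer(nTaxa); nSites <- as.integer(nSites)
  if (nTaxa < 2L) stop("need at least 2 taxa")
  if (nSites < 1L) stop("need at least 1 site")
  withSeed(seed, {
    tree <- ape::rtree(nTaxa, rooted = TRUE,
                       br = function(k) stats::rexp(k, rate = 10))
    nodes <- max(tree$edge)
    states <- matrix(NA_integer_, nrow = nodes, ncol = nSites)
    root <- nTaxa + 1L
    states[root, ] <- sample.int(4L, nSites, replace = TRUE)
    ## preorder edge walk: ape's default edge order visits parents first
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (i in seq_len(nrow(edges))) {
      par <- edges[i, 1L]; chd <- edges[i, 2L]
      pSame <- 0.25 + 0.75 * exp(-4 * lens[i] / 3)
      stay <- stats::runif(nSites) < pSame
      jump <- sample.int(3L, nSites, replace = TRUE)
      st <- states[par, ]
      moved <- ((st - 1L + jump) %% 4L) + 1L
      states[chd, ] <- ifelse(stay, st, moved)
    }
    bases <- c("A", "C", "G", "T")
    seqs <- matrix(bases[states[seq_len(nTaxa), , drop = FALSE]],
                   nrow = nTaxa, ncol = nSites)
    msa <- new("MSA", labels = tree$tip.label, seqs = seqs)
    list(tree = tree, msa = msa)
  })
}

#' Write / read value files (one hex-float literal per line)
#'
#' Hexadecimal floating-point literals round-trip doubles exactly, so value
#' fixtures stored as text preserve every bit. [writeValues()] also writes a
#' JSON metadata sidecar (\code{<path>.meta.json}) recording the provenance
#' passed in \code{meta} plus the fixed generator RNG.
#'
#' @param values numeric vector.
#' @param path output file.
#' @param meta optional named list recorded in the sidecar (e.g. seed,
#'   regime).
#' @return \code{path} invisibly.
#' @export
writeValues <- function(values, path, meta = list()) {
  writeLines(hexFloat(values), path)
  sidecar <- c(meta, list(format = "hex-float, one value per line",
                          n = length(values),
                          rng = as.list(GENERATOR_RNG),
                          package = "BitRepro"))
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeValues
#' @export
readValues <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- as.numeric(lines)
  if (anyNA(vals)) stop("unparseable float literal in values file")
  vals
}

#' Write an MSA as FASTA or relaxed PHYLIP
#'
#' @param msa an \linkS4class{MSA}.
#' @param path output file.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @return \code{path} invisibly.
#' @export
writeAlignment <- function(msa, path, format = c("fasta", "phylip")) {
  stopifnot(is(msa, "MSA"))
  format <- match.arg(format)
  seqs <- apply(msa@seqs, 1L, paste, collapse = "")
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", msa@labels), seqs)),
    phylip = c(sprintf("%d %d", length(msa@labels), ncol(msa@seqs)),
               sprintf("%s  %s", msa@labels, seqs)))
  writeLines(lines, path)
  invisible(path)
}
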